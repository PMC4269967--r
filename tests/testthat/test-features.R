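test_that("shape features approach circle values on a digital disk", {
  disk <- region_from_mask(make_disk(20L))
  sf <- shape_features(disk)
  expect_lt(sf[["eccentricity"]], 0.05)
  expect_lt(abs(sf[["axis_ratio"]] - 1), 0.05)
  # perimeter counted as boundary pixels underestimates 2*pi*r on a
  # digital circle, so the equivalent/actual ratio sits ~12% above 1
  # while staying within the (0, 1.2] band
  expect_gt(sf[["diameter_ratio"]], 0)
  expect_lte(sf[["diameter_ratio"]], 1.2)
})

test_that("ellipse eccentricity tracks the analytic value", {
  for (a in c(30, 40, 50)) {
    b <- a / 2
    sf <- shape_features(region_from_mask(make_ellipse(a, b)))
    expect_lt(abs(sf[["eccentricity"]] - sqrt(3) / 2), 0.03)
    expect_lt(abs(sf[["axis_ratio"]] - 2), 0.06)
  }
  # rotation must not matter
  sf45 <- shape_features(region_from_mask(make_ellipse(40, 20, pi / 4)))
  expect_lt(abs(sf45[["eccentricity"]] - sqrt(3) / 2), 0.03)
})

test_that("an overlap dumbbell is more eccentric and irregular than a disk", {
  disk <- make_disk(20L, pad = 30L)
  shifted <- cytoverlap:::mat_shift(disk, 0L, 24L, FALSE)
  dumbbell <- disk | shifted
  sf_d <- shape_features(region_from_mask(disk))
  sf_o <- shape_features(region_from_mask(dumbbell))
  expect_gt(sf_o[["eccentricity"]], sf_d[["eccentricity"]])
  expect_gt(sf_o[["axis_ratio"]], sf_d[["axis_ratio"]])
  # the wavy union boundary inflates the perimeter relative to a disk
  # of the same area, pulling the diameter ratio down
  expect_lt(sf_o[["diameter_ratio"]], sf_d[["diameter_ratio"]])
})

test_that("local minima match an exhaustive check on a hand-written patch", {
  # two chebyshev-distance valleys bottoming at (2,2) and (4,4)
  rows <- matrix(1:5, 5, 5); cols <- t(rows)
  d1 <- pmax(abs(rows - 2), abs(cols - 2))
  d2 <- pmax(abs(rows - 4), abs(cols - 4))
  patch <- 10 * pmin(d1, d2)
  region <- region_from_mask(matrix(TRUE, 5, 5))
  pts <- local_minima(patch, region)
  expect_equal(pts[order(pts[, 1]), , drop = FALSE],
               matrix(c(2L, 4L, 2L, 4L), 2, 2,
                      dimnames = list(NULL, c("row", "col"))))
  expect_equal(brute_minima_count(patch, region$filled_mask), 2L)
})

test_that("a flat plateau counts as a single minimum at its centroid", {
  g <- matrix(9, 7, 7)
  g[3:4, 3:4] <- 1                    # 2x2 plateau valley
  g[2, 2:5] <- 5; g[5, 2:5] <- 5; g[2:5, 2] <- 5; g[2:5, 5] <- 5
  pts <- local_minima(g, region_from_mask(matrix(TRUE, 7, 7)))
  expect_equal(nrow(pts), 1L)
  expect_true(all(pts[1, ] %in% 3:4))
})

test_that("tiny regions yield no minima but a warning", {
  m <- matrix(FALSE, 5, 5); m[2:3, 2:3] <- TRUE
  expect_warning(pts <- local_minima(matrix(1, 5, 5), region_from_mask(m)),
                 "too small")
  expect_equal(nrow(pts), 0L)
})

test_that("max minima distance equals the quadratic-scan oracle", {
  expect_equal(max_minima_distance(NULL), 0)
  expect_equal(max_minima_distance(matrix(c(5, 5), 1, 2)), 0)
  expect_equal(max_minima_distance(rbind(c(0, 0), c(3, 4))), 5)
  set.seed(10)
  for (rep in 1:5) {
    pts <- matrix(sample.int(200L, 12L), 6, 2)
    brute <- 0
    for (i in 1:5) for (j in (i + 1):6)
      brute <- max(brute, sqrt(sum((pts[i, ] - pts[j, ])^2)))
    expect_equal(max_minima_distance(pts), brute)
  }
})

test_that("the five features are translation and 90-degree rotation invariant", {
  scene <- small_scene(seed = 33L)
  gray <- to_grayscale(scene$image)
  obj <- scene$truth$objects[[1]]$mask
  region <- region_from_mask(obj)
  f0 <- extract_features(gray, list(region))

  dr <- 7L; dc <- 11L
  gray_s <- cytoverlap:::mat_shift(gray, dr, dc, 255)
  region_s <- region_from_mask(cytoverlap:::mat_shift(obj, dr, dc, FALSE))
  f1 <- extract_features(gray_s, list(region_s))
  expect_equal(f0[-1], f1[-1])

  sf0 <- shape_features(region)
  sf90 <- shape_features(region_from_mask(t(obj)[ncol(obj):1, ]))
  expect_equal(sf0, sf90, tolerance = 1e-12)
})

test_that("feature extraction handles empty input and round-trips via CSV", {
  empty <- extract_features(matrix(0, 5, 5), list())
  expect_equal(nrow(empty), 0L)
  expect_named(empty, c("label", "eccentricity", "axis_ratio",
                        "diameter_ratio", "n_minima", "max_minima_dist",
                        "flagged"))

  scene <- small_scene(seed = 34L)
  res <- detect_overlaps(scene$image)
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_csv(res$features, path)
  back <- read_feature_csv(path)
  expect_identical(back$eccentricity, res$features$eccentricity)
  expect_identical(back$max_minima_dist, res$features$max_minima_dist)
  expect_identical(back$n_minima, res$features$n_minima)
})

test_that("diameter ratio stays in (0, 1.2] across the fixture shapes", {
  shapes <- list(make_disk(10L), make_disk(25L), make_ellipse(30, 20),
                 make_ellipse(45, 15, pi / 6))
  for (m in shapes) {
    dr <- shape_features(region_from_mask(m))[["diameter_ratio"]]
    expect_gt(dr, 0)
    expect_lte(dr, 1.2)
  }
})
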