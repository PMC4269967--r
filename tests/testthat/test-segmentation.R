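test_that("Sobel magnitude matches hand convolution on a vertical step", {
  flat <- matrix(37, 7, 7)
  expect_true(all(gradient_magnitude(flat) == 0))

  step <- cbind(matrix(0, 7, 3), matrix(255, 7, 4))
  mag <- gradient_magnitude(step)
  # hand convolution: the +-1/+-2 kernel sums to 4 across the step, so
  # interior pixels of both step columns read 4*255
  expect_equal(mag[4, 3], 4 * 255)
  expect_equal(mag[4, 4], 4 * 255)
  expect_lt(max(mag[2:6, c(1, 2, 6, 7)]), 1e-9)  # flat columns (FFT residue)

  set.seed(8)
  rnd <- matrix(sample(0:255, 81, replace = TRUE), 9, 9)
  expect_equal(gradient_magnitude(t(rnd)), t(gradient_magnitude(rnd)))
})

test_that("edge filter output is empty on flat input, monotone in threshold", {
  expect_false(any(edge_filter(matrix(0, 20, 20))))
  expect_error(edge_filter(matrix(1, 9, 9), high_threshold = 1.4),
               "strictly inside")

  scene <- small_scene(seed = 71L)
  mag <- gradient_magnitude(to_grayscale(scene$image))
  e_lo <- edge_filter(mag, high_threshold = 0.3)
  e_hi <- edge_filter(mag, high_threshold = 0.6)
  # raising the high threshold only narrows the retained ridge band:
  # no new curves appear, and surviving curves stay close to the wider
  # band's centerlines
  n_lo <- max(cytoverlap:::label_components(e_lo))
  n_hi <- max(cytoverlap:::label_components(e_hi))
  expect_lte(n_hi, n_lo)
  ep <- which(e_hi, arr.ind = TRUE); lp <- which(e_lo, arr.ind = TRUE)
  d <- sqrt(outer(ep[, 1], lp[, 1], `-`)^2 + outer(ep[, 2], lp[, 2], `-`)^2)
  expect_lte(max(apply(d, 1, min)), 4)
})

test_that("edge filter traces the nucleus outline within 2 px", {
  scene <- generate_scene(scene_spec(width = 256L, height = 256L,
                                     n_single = 1L, n_overlap = 0L,
                                     nucleus_radius_range = c(14, 16),
                                     rng_seed = 81L))
  mag <- gradient_magnitude(to_grayscale(scene$image))
  edges <- edge_filter(mag)
  edges <- size_filter(edges, 20L, 5000L)
  obj <- scene$truth$objects[[1]]$mask
  outline <- obj & !cytoverlap:::erode3x3(obj)
  epix <- which(edges, arr.ind = TRUE)
  opix <- which(outline, arr.ind = TRUE)
  expect_gt(nrow(epix), 0)
  d <- sqrt(outer(epix[, 1], opix[, 1], `-`)^2 +
            outer(epix[, 2], opix[, 2], `-`)^2)
  # the thinned centerline sits at most ~3 px inside the analytic
  # outline (band thinning bias, compensated by region dilation later)
  expect_lte(max(apply(d, 1, min)), 3)
  # one closed curve: filling encloses interior pixels
  filled <- cytoverlap:::fill_interior(edges)
  expect_gt(sum(filled & !edges), 0)
})

test_that("size filter keeps only components inside the pixel-count window", {
  m <- matrix(FALSE, 40, 120)
  m[5, 1:5] <- TRUE                    # 5 px
  m[20, 1:30] <- TRUE                  # 30 px
  m[30:39, 41:80] <- TRUE              # 400 px
  out <- size_filter(m, 20L, 300L)
  lab <- cytoverlap:::label_components(out)
  expect_equal(max(lab), 1L)
  expect_equal(sum(out), 30L)
  expect_identical(size_filter(m, 0L, .Machine$integer.max), m)
  expect_error(size_filter(m, 10L, 5L), "min_pixels")
})

test_that("closed-contour filter distinguishes rings from arcs", {
  ring <- diamond_ring()
  expect_identical(closed_contour_filter(ring), ring)
  gap <- ring
  gap[4, 6] <- FALSE                 # 1-px gap opens the ring
  expect_false(any(closed_contour_filter(gap)))
  empty <- matrix(FALSE, 6, 6)
  expect_identical(closed_contour_filter(empty), empty)
})

test_that("bifurcation removal yields simple closed curves", {
  ring <- diamond_ring()
  expect_identical(remove_bifurcations(ring), ring)

  tailed <- ring
  tailed[9:12, 6] <- TRUE            # tail hanging off the bottom vertex
  expect_identical(remove_bifurcations(tailed), ring)

  whisker <- ring
  whisker[5, 6] <- TRUE              # internal whisker touching the ring
  cleaned <- remove_bifurcations(whisker)
  nc <- cytoverlap:::neighbor_count8(cleaned)
  expect_true(all(nc[cleaned] == 2L))
  expect_true(any(cleaned))
})

test_that("regions are filled, deterministic and restricted to the cluster", {
  ring <- diamond_ring()
  outside_cluster <- matrix(FALSE, nrow(ring), ncol(ring))
  expect_length(contours_to_regions(ring, outside_cluster, 1L), 0L)

  regions <- contours_to_regions(ring, NULL, 1L, region_dilate = 0L)
  expect_length(regions, 1L)
  expect_equal(regions[[1]]$area, 13L)  # 8-px ring plus 5 enclosed pixels

  scene <- small_scene(seed = 91L)
  res1 <- detect_overlaps(scene$image)
  res2 <- detect_overlaps(scene$image)
  expect_equal(length(res1$regions), 4L)  # 3 singles + 1 merged pair
  expect_identical(lapply(res1$regions, `[[`, "centroid"),
                   lapply(res2$regions, `[[`, "centroid"))
  # masks pairwise disjoint
  acc <- Reduce(`+`, lapply(res1$regions, function(r) r$filled_mask * 1L))
  expect_lte(max(acc), 1L)
})

test_that("filtering stages only remove edge pixels", {
  scene <- small_scene(seed = 95L)
  mag <- gradient_magnitude(to_grayscale(scene$image))
  e0 <- edge_filter(mag)
  e1 <- size_filter(e0, 8L, 2000L)
  e2 <- closed_contour_filter(e1)
  e3 <- remove_bifurcations(e2)
  expect_true(all(e1 <= e0))
  expect_true(all(e2 <= e1))
  expect_true(all(e3 <= e2))
})
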