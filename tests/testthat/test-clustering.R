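# independent oracle: minimum within-cluster sum of squares over every
# assignment of n points to two clusters
exhaustive_wcss2 <- function(points) {
  n <- nrow(points)
  best <- Inf
  for (code in 0:(2^n - 1)) {
    lab <- as.integer(intToBits(code))[1:n]
    obj <- 0
    for (g in 0:1) {
      sel <- points[lab == g, , drop = FALSE]
      if (nrow(sel) == 0L) next
      cen <- colMeans(sel)
      obj <- obj + sum(sweep(sel, 2L, cen, `-`)^2)
    }
    if (obj < best) best <- obj
  }
  best
}

test_that("k-means recovers trivial and exhaustively-verified optima", {
  pts <- matrix(c(0, 10), 2, 1)
  fit <- kmeans_fit(pts, k = 2L, rng_seed = 1L)
  expect_equal(sort(fit$centroids[, 1]), c(0, 10))
  expect_equal(fit$objective, 0)

  set.seed(42)
  pts8 <- matrix(rnorm(16, sd = 2), 8, 2)
  fit8 <- kmeans_fit(pts8, k = 2L, n_restarts = 10L, rng_seed = 2L)
  expect_equal(fit8$objective, exhaustive_wcss2(pts8), tolerance = 1e-9)

  # duplication leaves the centroids unchanged
  fit_dup <- kmeans_fit(rbind(pts8, pts8), k = 2L, rng_seed = 2L)
  ord <- order(fit8$centroids[, 1])
  ord_d <- order(fit_dup$centroids[, 1])
  expect_equal(fit_dup$centroids[ord_d, ], fit8$centroids[ord, ],
               tolerance = 1e-9)
})

test_that("k-means agrees with the reference implementation and descends", {
  cloud <- generate_feature_points(30L, c(0, 0, 0, 0, 0), c(4, 4, 4, 4, 4),
                                   spread = 1, rng_seed = 7L)
  fit <- kmeans_fit(cloud$points, k = 2L, n_restarts = 10L, rng_seed = 3L)
  ref <- stats::kmeans(cloud$points, centers = 2L, nstart = 20L)
  expect_equal(fit$objective, ref$tot.withinss, tolerance = 1e-6)
  expect_true(all(diff(fit$objective_trace) <= 1e-9))
  expect_lte(fit$objective, min(fit$objective_trace) + 1e-9)
})

test_that("fcm memberships are consistent, normalized and symmetric", {
  cloud <- generate_feature_points(20L, rep(0, 5), rep(6, 5),
                                   spread = 0.3, rng_seed = 8L)
  fit <- fcm_fit(cloud$points, c = 2L, m = 2, rng_seed = 4L)
  expect_true(fit$converged)
  expect_lt(max(abs(rowSums(fit$memberships) - 1)), 1e-9)
  expect_true(all(fit$memberships >= 0 & fit$memberships <= 1))
  # memberships >= 0.99 on well-separated tight clouds
  conf <- fit$memberships[cbind(seq_len(40), fit$assignment)]
  expect_true(all(conf >= 0.99))
  # self-consistency: final memberships reproduce the closed form
  d2 <- as.matrix(stats::dist(rbind(fit$centroids, cloud$points)))^2
  d2 <- d2[-(1:2), 1:2]
  u_ref <- 1 / (1 + (d2 / d2[, 2:1]))
  expect_lt(max(abs(fit$memberships - u_ref)), 1e-6)

  # equidistant point splits its membership evenly
  pts <- rbind(c(0, 0), c(2, 0), c(1, 0))
  u <- cytoverlap:::fcm_memberships(pts[3, , drop = FALSE],
                                    rbind(c(0, 0), c(2, 0)), 2)
  expect_equal(as.vector(u), c(0.5, 0.5))

  # coincident point takes the singularity rule
  u0 <- cytoverlap:::fcm_memberships(matrix(c(0, 0), 1, 2),
                                     rbind(c(0, 0), c(5, 5)), 2)
  expect_equal(as.vector(u0), c(1, 0))
  expect_error(fcm_fit(cloud$points, m = 1), "m must be > 1")
})

test_that("fcm matches e1071 cmeans on a reference cloud", {
  skip_if_not_installed("e1071")
  cloud <- generate_feature_points(25L, rep(0, 5), rep(5, 5),
                                   spread = 0.8, rng_seed = 12L)
  fit <- fcm_fit(cloud$points, c = 2L, m = 2, rng_seed = 5L)
  ref <- e1071::cmeans(cloud$points, centers = 2L, m = 2)
  ord <- order(fit$centroids[, 1]); ord_r <- order(ref$centers[, 1])
  expect_lt(max(abs(fit$centroids[ord, ] - ref$centers[ord_r, ])), 1e-2)
})

test_that("fcm near m = 1 reproduces k-means calls and ignores point order", {
  cloud <- generate_feature_points(15L, c(0.5, 1.2, 1.1, 1, 0),
                                   c(0.8, 2.2, 1.1, 75, 48),
                                   spread = c(0.05, 0.1, 0.1, 3, 4),
                                   rng_seed = 21L)
  km <- kmeans_fit(cloud$points, k = 2L, rng_seed = 6L)
  fc <- fcm_fit(cloud$points, c = 2L, m = 1.05, rng_seed = 6L)
  agree <- km$assignment == fc$assignment
  expect_true(all(agree) || all(!agree))  # up to label permutation

  perm <- sample(nrow(cloud$points))
  fc_p <- fcm_fit(cloud$points[perm, ], c = 2L, m = 2, rng_seed = 6L)
  fc_o <- fcm_fit(cloud$points, c = 2L, m = 2, rng_seed = 6L)
  ord_p <- order(fc_p$centroids[, 4]); ord_o <- order(fc_o$centroids[, 4])
  expect_equal(fc_p$centroids[ord_p, ], fc_o$centroids[ord_o, ],
               tolerance = 1e-4)
})

test_that("overlap calls pick the high-minima cluster with confidences", {
  features <- data.frame(label = 1:6,
                         eccentricity = c(0.2, 0.25, 0.3, 0.7, 0.75, 0.8),
                         axis_ratio = c(1.1, 1.1, 1.2, 1.6, 1.7, 1.8),
                         diameter_ratio = c(1.1, 1.1, 1.1, 1.0, 1.0, 1.0),
                         n_minima = c(1, 1, 1, 2, 3, 2),
                         max_minima_dist = c(0, 0, 0, 20, 22, 25),
                         flagged = FALSE)
  cl <- classify_regions(features, method = "kmeans", rng_seed = 2L)
  expect_setequal(cl$calls$predicted[4:6], "overlapped")
  expect_setequal(cl$calls$predicted[1:3], "single")
  expect_true(all(cl$calls$confidence == 1))  # one-hot k-means

  cf <- classify_regions(features, method = "fcm", rng_seed = 2L)
  expect_true(all(cf$calls$confidence >= 0.5 & cf$calls$confidence <= 1))
  expect_equal(cf$calls$predicted, cl$calls$predicted)

  # degenerate model with identical centroids must refuse to label
  bad <- list(centroids = matrix(1, 2, 5), memberships = matrix(0.5, 6, 2),
              assignment = rep(1L, 6))
  expect_error(call_overlap(bad, features), "indistinguishable")
})

test_that("fcm and k-means calls agree on seeded feature-space sweeps", {
  agree <- 0L; total <- 0L
  for (s in 1:10) {
    cloud <- generate_feature_points(
      20L, c(0.55, 1.31, 1.10, 1, 0), c(0.86, 2.39, 0.95, 5, 30),
      spread = c(0.08, 0.15, 0.05, 0.8, 6), rng_seed = 300L + s)
    df <- data.frame(label = seq_len(40L),
                     eccentricity = cloud$points[, 1],
                     axis_ratio = cloud$points[, 2],
                     diameter_ratio = cloud$points[, 3],
                     n_minima = cloud$points[, 4],
                     max_minima_dist = cloud$points[, 5],
                     flagged = FALSE)
    k <- classify_regions(df, method = "kmeans", rng_seed = s)
    f <- classify_regions(df, method = "fcm", rng_seed = s)
    agree <- agree + sum(k$calls$predicted == f$calls$predicted)
    total <- total + nrow(df)
  }
  expect_gte(agree / total, 0.9)
})
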