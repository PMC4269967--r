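# kmeans++-style seeding from a pre-seeded RNG: first centroid uniform,
# later centroids sampled with probability proportional to squared
# distance from the nearest chosen centroid.
seed_centroids <- function(points, k) {
  n <- nrow(points)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1L)
  if (k > 1L) {
    d2 <- rowSums(sweep(points, 2L, points[idx[1], ], `-`)^2)
    for (j in 2:k) {
      if (all(d2 == 0)) {
        idx[j] <- sample.int(n, 1L)
      } else {
        idx[j] <- sample.int(n, 1L, prob = d2)
      }
      d2 <- pmin(d2, rowSums(sweep(points, 2L, points[idx[j], ], `-`)^2))
    }
  }
  points[idx, , drop = FALSE]
}

sq_dist_to_centroids <- function(points, centroids) {
  # n x k matrix of squared Euclidean distances
  pp <- rowSums(points^2)
  cc <- rowSums(centroids^2)
  outer(pp, cc, `+`) - 2 * points %*% t(centroids)
}

#' k-means clustering (Lloyd iterations, kmeans++ restarts)
#'
#' Minimizes the within-cluster sum of squared Euclidean distances by
#' alternating nearest-centroid assignment and centroid re-estimation as
#' cluster means. The objective is non-increasing across iterations (the
#' per-iteration trace is returned for audit); the best of `n_restarts`
#' seedings is kept. A cluster that empties during iteration is reseeded
#' at the point farthest from its assigned centroid.
#'
#' @param points `N x p` numeric matrix of observations.
#' @param k Number of clusters, default 2.
#' @param n_restarts Independent kmeans++ seedings, default 10.
#' @param tol Convergence threshold on the objective decrease.
#' @param max_iter Iteration cap per restart.
#' @param rng_seed Integer seed; results are deterministic given it.
#' @return A `cluster_model` list: `method = "kmeans"`, `centroids`
#'   (`k x p`), `memberships` (`N x k`, one-hot), `assignment`,
#'   `objective`, `objective_trace`, `iterations_run`, `converged`.
#' @export
kmeans_fit <- function(points, k = 2L, n_restarts = 10L, tol = 1e-8,
                       max_iter = 100L, rng_seed = 1L) {
  points <- as.matrix(points)
  if (!all(is.finite(points))) stop("points must be finite")
  n <- nrow(points)
  if (n < k) stop("need at least k points")
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(rng_seed))
  best <- NULL
  for (r in seq_len(n_restarts)) {
    cen <- seed_centroids(points, k)
    trace <- numeric(0)
    assign_vec <- NULL
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      d2 <- sq_dist_to_centroids(points, cen)
      assign_vec <- max.col(-d2, ties.method = "first")
      # reseed empty clusters at the worst-fit point
      for (j in seq_len(k)) {
        if (!any(assign_vec == j)) {
          far <- which.max(d2[cbind(seq_len(n), assign_vec)])
          cen[j, ] <- points[far, ]
          assign_vec[far] <- j
        }
      }
      obj <- sum(d2[cbind(seq_len(n), assign_vec)])
      trace <- c(trace, obj)
      new_cen <- cen
      for (j in seq_len(k))
        new_cen[j, ] <- colMeans(points[assign_vec == j, , drop = FALSE])
      if (it > 1L && trace[it - 1L] - obj <= tol &&
          all(new_cen == cen)) {
        converged <- TRUE
        break
      }
      cen <- new_cen
    }
    # final objective with settled centroids
    d2 <- sq_dist_to_centroids(points, cen)
    assign_vec <- max.col(-d2, ties.method = "first")
    obj <- sum(d2[cbind(seq_len(n), assign_vec)])
    if (is.null(best) || obj < best$objective) {
      memb <- matrix(0, n, k)
      memb[cbind(seq_len(n), assign_vec)] <- 1
      best <- list(method = "kmeans", centroids = cen, memberships = memb,
                   assignment = assign_vec, objective = obj,
                   objective_trace = trace, fuzzifier_m = NA_real_,
                   iterations_run = length(trace), converged = converged)
    }
  }
  class(best) <- "cluster_model"
  best
}

#' Fuzzy c-means clustering
#'
#' Bezdek's alternating optimization: memberships are inverse-distance
#' ratios raised to `2/(m-1)`, centroids are `u^m`-weighted means.
#' Iteration stops when the largest absolute membership change drops
#' below `tol` or `max_iter` is reached. A point coinciding with a
#' centroid receives membership 1 for that cluster (0 for the others),
#' the standard singularity rule.
#'
#' @param points `N x p` numeric matrix.
#' @param c Number of clusters, default 2.
#' @param m Fuzzifier (> 1), default 2.
#' @param tol Threshold on the max membership change, default 1e-5.
#' @param max_iter Iteration cap.
#' @param rng_seed Integer seed for the kmeans++-style initialization.
#' @return A `cluster_model` list: `method = "fcm"`, `centroids`,
#'   `memberships` (rows sum to 1), `assignment` (max membership),
#'   `fuzzifier_m`, `iterations_run`, `converged`.
#' @export
fcm_fit <- function(points, c = 2L, m = 2.0, tol = 1e-5, max_iter = 300L,
                    rng_seed = 1L) {
  points <- as.matrix(points)
  if (!all(is.finite(points))) stop("points must be finite")
  if (m <= 1) stop("fuzzifier m must be > 1")
  n <- nrow(points)
  if (n < c) stop("need at least c points")
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(rng_seed))
  cen <- seed_centroids(points, c)
  u <- fcm_memberships(points, cen, m)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    um <- u^m
    cen <- t(um) %*% points / colSums(um)
    u_new <- fcm_memberships(points, cen, m)
    delta <- max(abs(u_new - u))
    u <- u_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  model <- list(method = "fcm", centroids = cen, memberships = u,
                assignment = max.col(u, ties.method = "first"),
                objective = sum((u^m) * sq_dist_to_centroids(points, cen)),
                fuzzifier_m = m, iterations_run = it, converged = converged)
  class(model) <- "cluster_model"
  model
}

# Closed-form membership update: u_ij = 1 / sum_l (d_ij/d_il)^(2/(m-1)).
fcm_memberships <- function(points, centroids, m) {
  d2 <- sq_dist_to_centroids(points, centroids)
  d2[d2 < 0] <- 0
  n <- nrow(d2); k <- ncol(d2)
  expo <- 1 / (m - 1)
  inv <- (1 / pmax(d2, .Machine$double.xmin))^expo
  u <- inv / rowSums(inv)
  zero <- d2 <= 0
  hit <- rowSums(zero) > 0
  if (any(hit)) {
    u[hit, ] <- 0
    u[hit, ] <- zero[hit, , drop = FALSE] / rowSums(zero[hit, , drop = FALSE])
  }
  u
}

#' Label clusters as overlapped vs. single and call each region
#'
#' Overlap increases the number of grayscale local minima inside a
#' region, so the cluster whose centroid has the larger `n_minima`
#' coordinate is labeled `"overlapped"` (ties broken by larger
#' `max_minima_dist`, then larger `axis_ratio`). Each region is assigned
#' its maximum-membership cluster; the confidence is that membership
#' (always 1 for k-means).
#'
#' @param model A `cluster_model` fitted on the feature matrix of
#'   `features` (in the same standardization, see `scaling` attribute
#'   set by [classify_regions()]).
#' @param features Feature data frame from [extract_features()].
#' @param feature_cols Names of the five descriptor columns in
#'   clustering order.
#' @return Data frame with columns `label`, `predicted` (`"single"` /
#'   `"overlapped"`) and `confidence` (in \[0.5, 1\] for two clusters).
#' @export
call_overlap <- function(model, features,
                         feature_cols = c("eccentricity", "axis_ratio",
                                          "diameter_ratio", "n_minima",
                                          "max_minima_dist")) {
  cen <- model$centroids
  i_min <- which(feature_cols == "n_minima")
  i_dist <- which(feature_cols == "max_minima_dist")
  i_ar <- which(feature_cols == "axis_ratio")
  pick <- function(col) {
    d <- cen[, col]
    if (abs(d[1] - d[2]) > 1e-12) which.max(d) else 0L
  }
  ov <- pick(i_min)
  if (ov == 0L) ov <- pick(i_dist)
  if (ov == 0L) ov <- pick(i_ar)
  if (ov == 0L) stop("clusters indistinguishable: identical centroids in ",
                     "n_minima, max_minima_dist and axis_ratio")
  cluster_names <- ifelse(seq_len(nrow(cen)) == ov, "overlapped", "single")
  conf <- model$memberships[cbind(seq_along(model$assignment),
                                  model$assignment)]
  data.frame(label = features$label,
             predicted = cluster_names[model$assignment],
             confidence = conf)
}

#' Cluster a feature table into overlapped vs. single nuclei
#'
#' Convenience wrapper: optionally z-score standardizes the five
#' descriptor columns (recommended -- the two minima features are
#' measured in counts/pixels and would otherwise dominate the Euclidean
#' metric), fits k-means or FCM, and calls each region.
#'
#' @param features Feature data frame from [extract_features()];
#'   flagged rows are excluded from clustering.
#' @param method `"fcm"` (default) or `"kmeans"`.
#' @param standardize Z-score features before clustering, default TRUE.
#' @param m Fuzzifier for FCM.
#' @param n_restarts Restarts for k-means.
#' @param tol,max_iter Convergence controls.
#' @param rng_seed Integer seed.
#' @return List with `model` (the `cluster_model`; its `centroids_raw`
#'   entry holds centroids back-transformed to feature units) and
#'   `calls` (data frame from [call_overlap()]).
#' @export
classify_regions <- function(features, method = c("fcm", "kmeans"),
                             standardize = TRUE, m = 2.0,
                             n_restarts = 10L, tol = 1e-5,
                             max_iter = 300L, rng_seed = 1L) {
  method <- match.arg(method)
  feature_cols <- c("eccentricity", "axis_ratio", "diameter_ratio",
                    "n_minima", "max_minima_dist")
  ok <- !features$flagged & stats::complete.cases(features[feature_cols])
  usable <- features[ok, , drop = FALSE]
  if (nrow(usable) < 2L)
    stop("need at least two usable regions to cluster")
  x <- as.matrix(usable[feature_cols])
  if (standardize) {
    mu <- colMeans(x)
    sdv <- apply(x, 2L, stats::sd)
    sdv[sdv == 0 | !is.finite(sdv)] <- 1
    xs <- sweep(sweep(x, 2L, mu, `-`), 2L, sdv, `/`)
  } else {
    mu <- rep(0, ncol(x)); sdv <- rep(1, ncol(x))
    xs <- x
  }
  model <- if (method == "kmeans")
    kmeans_fit(xs, k = 2L, n_restarts = n_restarts, tol = 1e-10,
               max_iter = max_iter, rng_seed = rng_seed)
  else
    fcm_fit(xs, c = 2L, m = m, tol = tol, max_iter = max_iter,
            rng_seed = rng_seed)
  model$centroids_raw <- sweep(sweep(model$centroids, 2L, sdv, `*`),
                               2L, mu, `+`)
  colnames(model$centroids_raw) <- feature_cols
  colnames(model$centroids) <- feature_cols
  calls <- call_overlap(model, usable, feature_cols)
  list(model = model, calls = calls)
}
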