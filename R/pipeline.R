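#' Pipeline configuration
#'
#' Collects every tunable of the detection pipeline with its default.
#' Size and area windows are quoted at the 1280x960 reference scale and
#' rescaled by image area at run time.
#'
#' @param hue_lo,hue_hi Hue gate limits (closed interval), defaults 0.2
#'   and 0.7.
#' @param close_radius Disk radius of the post-gate morphological
#'   closing, pixels.
#' @param canny_high Strong-edge threshold on the normalized gradient
#'   magnitude, default 0.4.
#' @param canny_low_ratio Low/high hysteresis ratio, default 0.4.
#' @param canny_sigma Gaussian sigma of the edge filter's internal
#'   smoothing, pixels.
#' @param size_min,size_max Edge-component pixel-count window at
#'   reference scale.
#' @param min_nucleus_area Minimum filled region area (px^2) at
#'   reference scale.
#' @param region_dilate One-pixel dilations applied to filled contours
#'   to compensate the inward bias of ridge-centerline thinning.
#' @param minima_sigma Pre-smoothing sigma for local-minima detection;
#'   the default 1 suppresses quantization/noise minima while leaving
#'   genuine intensity valleys intact.
#' @param standardize Z-score features before clustering.
#' @param method Clustering method, `"fcm"` or `"kmeans"`.
#' @param fuzzifier_m FCM fuzzifier.
#' @param tol Clustering convergence tolerance.
#' @param max_iter Clustering iteration cap.
#' @param n_restarts k-means restarts.
#' @param rng_seed Seed for all stochastic steps.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(hue_lo = 0.2, hue_hi = 0.7, close_radius = 5L,
                       canny_high = 0.4, canny_low_ratio = 0.4,
                       canny_sigma = 1.0,
                       size_min = 20L, size_max = 5000L,
                       min_nucleus_area = 50L,
                       region_dilate = 1L,
                       minima_sigma = 1.0,
                       standardize = TRUE,
                       method = c("fcm", "kmeans"),
                       fuzzifier_m = 2.0, tol = 1e-5, max_iter = 300L,
                       n_restarts = 10L, rng_seed = 1L) {
  cfg <- list(hue_lo = hue_lo, hue_hi = hue_hi,
              close_radius = as.integer(close_radius),
              canny_high = canny_high, canny_low_ratio = canny_low_ratio,
              canny_sigma = canny_sigma,
              size_min = as.integer(size_min),
              size_max = as.integer(size_max),
              min_nucleus_area = as.integer(min_nucleus_area),
              region_dilate = as.integer(region_dilate),
              minima_sigma = minima_sigma,
              standardize = isTRUE(standardize),
              method = match.arg(method),
              fuzzifier_m = fuzzifier_m, tol = tol,
              max_iter = as.integer(max_iter),
              n_restarts = as.integer(n_restarts),
              rng_seed = as.integer(rng_seed))
  class(cfg) <- "run_config"
  cfg
}

#' Detect overlapping nuclei in an RGB micrograph
#'
#' Runs the full pipeline: hue-gated cluster mask, grayscale conversion,
#' gradient/edge segmentation, five-feature extraction, and two-cluster
#' classification into overlapped vs. single nuclei.
#'
#' @param image `H x W x 3` 8-bit RGB array (e.g. from
#'   [read_image_rgb()] or [generate_scene()]).
#' @param config A [run_config()].
#' @param mask Optional precomputed labeled nucleus mask (integer
#'   matrix, 0 = background). When given, segmentation is skipped and
#'   each labeled object becomes a region directly (semi-automated
#'   mode).
#' @return List with `regions`, `features`, `calls`, `model`,
#'   `cluster_mask`, `gray`, and `config`. With fewer than two usable
#'   regions, `calls` and `model` are `NULL` and a warning is raised.
#' @export
detect_overlaps <- function(image, config = run_config(), mask = NULL) {
  gray <- to_grayscale(image)
  if (is.null(mask)) {
    cluster_mask <- hue_gate(image, config$hue_lo, config$hue_hi,
                             config$close_radius)
    regions <- segment_nuclei(gray, cluster_mask, config)
  } else {
    cluster_mask <- NULL
    regions <- regions_from_label_mask(mask)
  }
  features <- extract_features(gray, regions,
                               minima_sigma = config$minima_sigma)
  calls <- NULL; model <- NULL
  usable <- if (nrow(features)) sum(!features$flagged) else 0L
  if (usable >= 2L) {
    cl <- classify_regions(features, method = config$method,
                           standardize = config$standardize,
                           m = config$fuzzifier_m,
                           n_restarts = config$n_restarts,
                           tol = config$tol, max_iter = config$max_iter,
                           rng_seed = config$rng_seed)
    calls <- cl$calls; model <- cl$model
  } else {
    warning("fewer than two usable regions; no clustering performed")
  }
  list(regions = regions, features = features, calls = calls,
       model = model, cluster_mask = cluster_mask, gray = gray,
       config = config)
}

#' Build regions from a labeled instance mask (semi-automated mode)
#'
#' Each positive label of a human-drawn (or otherwise precomputed)
#' nucleus mask becomes one `nucleus_region`, bypassing the segmentation
#' stage.
#'
#' @param mask Integer label matrix, 0 = background.
#' @return List of `nucleus_region` objects in label order.
#' @export
regions_from_label_mask <- function(mask) {
  labels <- sort(unique(mask[mask > 0L]))
  out <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    m <- mask == labels[i]
    boundary <- m & !(
      mat_shift(m, 1, 0, FALSE) & mat_shift(m, -1, 0, FALSE) &
      mat_shift(m, 0, 1, FALSE) & mat_shift(m, 0, -1, FALSE))
    region <- list(label = as.integer(labels[i]),
                   boundary = mask_coords(boundary),
                   filled_mask = m,
                   bbox = mask_bbox(m),
                   area = sum(m),
                   centroid = colMeans(mask_coords(m)))
    class(region) <- "nucleus_region"
    out[[i]] <- region
  }
  out
}

#' Labeled raster of detected regions
#'
#' @param regions List of `nucleus_region` objects.
#' @param dim Image dimensions `c(H, W)`.
#' @return Integer matrix with each region's filled mask painted with
#'   its label.
#' @export
regions_to_label_mask <- function(regions, dim) {
  out <- matrix(0L, dim[1], dim[2])
  for (r in regions) out[r$filled_mask] <- r$label
  out
}

#' Evaluate pipeline output against scene ground truth
#'
#' Matches detected regions to merged ground-truth objects
#' ([match_regions()]) and scores the overlap calls of the matched
#' regions against the object classes ([classification_metrics()]).
#'
#' @param result Output of [detect_overlaps()].
#' @param truth A `ground_truth` from [generate_scene()].
#' @param min_iou Located threshold, default 0.5.
#' @return List with `matching` (from [match_regions()]) and `metrics`
#'   (from [classification_metrics()]; `NULL` when there are no calls).
#' @export
evaluate_against_truth <- function(result, truth, min_iou = 0.5) {
  matching <- match_regions(result$regions, truth, min_iou = min_iou)
  metrics <- NULL
  if (!is.null(result$calls) && nrow(matching$matches) > 0L) {
    located <- matching$matches[matching$matches$tanimoto >= min_iou, ,
                                drop = FALSE]
    calls <- result$calls[result$calls$label %in% located$region_label, ,
                          drop = FALSE]
    if (nrow(calls) > 0L) {
      truth_map <- located$truth_class
      names(truth_map) <- as.character(located$region_label)
      metrics <- classification_metrics(calls, truth_map)
    }
  }
  list(matching = matching, metrics = metrics)
}
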