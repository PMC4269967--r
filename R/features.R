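#' Shape features of a candidate nucleus region
#'
#' Fits an ellipse to the filled mask via its second central moments
#' (with the 1/12 pixel-variance correction used by standard
#' region-property implementations) and derives:
#' \describe{
#'   \item{eccentricity}{`sqrt(1 - b^2/a^2)` of the best-fit ellipse
#'     with semi-axes `a >= b`; 0 for a circle, approaching 1 for a
#'     line.}
#'   \item{axis_ratio}{Major over minor axis length, `a/b >= 1`.}
#'   \item{diameter_ratio}{Equivalent diameter `sqrt(4*Area/pi)` over
#'     the "actual" diameter `P_n/pi`, where the perimeter pixel count
#'     `P_n` is the number of region pixels with at least one 4-neighbor
#'     outside the region. Wavy, irregular boundaries inflate `P_n` and
#'     pull the ratio down.}
#' }
#'
#' @param region A `nucleus_region` (any list with a logical
#'   `filled_mask`).
#' @return Named numeric vector `c(eccentricity, axis_ratio,
#'   diameter_ratio)`.
#' @export
shape_features <- function(region) {
  mask <- region$filled_mask
  if (is.null(mask) || !any(mask)) stop("region has an empty filled_mask")
  xy <- mask_coords(mask)
  n <- nrow(xy)
  mu <- colMeans(xy)
  dr <- xy[, 1] - mu[1]; dc <- xy[, 2] - mu[2]
  # second central moments + 1/12 correction for unit-square pixels
  m20 <- sum(dr * dr) / n + 1 / 12
  m02 <- sum(dc * dc) / n + 1 / 12
  m11 <- sum(dr * dc) / n
  common <- sqrt((m20 - m02)^2 + 4 * m11^2)
  l1 <- (m20 + m02 + common) / 2
  l2 <- (m20 + m02 - common) / 2
  if (l2 <= .Machine$double.eps * l1) {
    warning("degenerate region (zero minor axis); eccentricity clamped")
    ecc <- 1 - 1e-9
    ratio <- sqrt(l1 / (.Machine$double.eps * l1))
  } else {
    ecc <- sqrt(max(0, 1 - l2 / l1))
    ratio <- sqrt(l1 / l2)
  }
  pn <- perimeter_pixel_count(mask)
  deq <- sqrt(4 * n / pi)
  dact <- pn / pi
  c(eccentricity = ecc, axis_ratio = ratio, diameter_ratio = deq / dact)
}

# P_n: pixels of the region with at least one 4-neighbor outside it.
perimeter_pixel_count <- function(mask) {
  inner <- mask &
    mat_shift(mask, 1, 0, FALSE) & mat_shift(mask, -1, 0, FALSE) &
    mat_shift(mask, 0, 1, FALSE) & mat_shift(mask, 0, -1, FALSE)
  sum(mask & !inner)
}

#' Grayscale local minima inside a region
#'
#' A pixel is a local minimum when no 8-neighbor has a strictly lower
#' gray value; a connected constant-intensity plateau of such pixels
#' counts as one minimum, reported at its centroid pixel. Only pixels
#' whose full 8-neighborhood lies inside the region are eligible, so
#' boundary artifacts cannot register as minima. Optionally the image is
#' Gaussian-smoothed first (`sigma`), which suppresses single-pixel
#' minima created by sensor noise and 8-bit quantization.
#'
#' @param gray Grayscale image matrix.
#' @param region A `nucleus_region` with `filled_mask`.
#' @param sigma Pre-smoothing sigma in pixels; 0 (default) analyses the
#'   raw gray values.
#' @return Integer `n x 2` matrix of (row, col) minima positions;
#'   regions of area < 9 yield zero rows with a warning.
#' @export
local_minima <- function(gray, region, sigma = 0) {
  mask <- region$filled_mask
  if (sum(mask) < 9L) {
    warning("region too small for local minima analysis (area < 9)")
    return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("row", "col"))))
  }
  bb <- mask_bbox(mask)
  r0 <- max(bb[1] - 2L, 1L); c0 <- max(bb[2] - 2L, 1L)
  r1 <- min(bb[3] + 2L, nrow(gray)); c1 <- min(bb[4] + 2L, ncol(gray))
  g <- matrix(as.numeric(gray[r0:r1, c0:c1]), r1 - r0 + 1L, c1 - c0 + 1L)
  m <- mask[r0:r1, c0:c1, drop = FALSE]
  if (sigma > 0) g <- gaussian_smooth(g, sigma)
  eligible <- erode3x3(m)
  if (!any(eligible))
    return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("row", "col"))))
  nmin <- neighbor_min8(g)
  cand <- eligible & (g <= nmin)
  if (!any(cand))
    return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("row", "col"))))
  # adjacent candidates necessarily share the same value (a higher
  # neighbor would have a darker neighbor and fail candidacy), so
  # connected candidate components are exactly the minimum plateaus
  lab <- label_components(cand, connectivity = 8L)
  n <- max(lab)
  pts <- matrix(0L, n, 2, dimnames = list(NULL, c("row", "col")))
  for (i in seq_len(n)) {
    cen <- colMeans(mask_coords(lab == i))
    pts[i, ] <- c(as.integer(round(cen[1])) + r0 - 1L,
                  as.integer(round(cen[2])) + c0 - 1L)
  }
  pts
}

#' Maximum pairwise Euclidean distance between minima
#'
#' @param minima `n x 2` matrix of (row, col) points.
#' @return Largest pairwise distance in pixels; 0 when fewer than two
#'   points are supplied.
#' @export
max_minima_distance <- function(minima) {
  if (is.null(minima) || NROW(minima) <= 1L) return(0)
  max(stats::dist(minima))
}

#' Extract the five-feature descriptor for each region
#'
#' One row per region, in region-label order: three shape features from
#' [shape_features()] and the two texture features `n_minima` (count of
#' grayscale local minima) and `max_minima_dist` (largest inter-minima
#' distance). A region whose shape computation fails yields a flagged
#' `NA` row rather than aborting the batch.
#'
#' @param gray Grayscale image matrix.
#' @param regions List of `nucleus_region` objects.
#' @param minima_sigma Pre-smoothing sigma forwarded to [local_minima()].
#' @return Data frame with columns `label`, `eccentricity`,
#'   `axis_ratio`, `diameter_ratio`, `n_minima`, `max_minima_dist`,
#'   `flagged`.
#' @export
extract_features <- function(gray, regions, minima_sigma = 0) {
  cols <- c("label", "eccentricity", "axis_ratio", "diameter_ratio",
            "n_minima", "max_minima_dist", "flagged")
  if (length(regions) == 0L) {
    out <- as.data.frame(matrix(numeric(0), 0, length(cols)))
    names(out) <- cols
    return(out)
  }
  rows <- lapply(regions, function(region) {
    rec <- tryCatch({
      sf <- shape_features(region)
      mins <- local_minima(gray, region, sigma = minima_sigma)
      data.frame(label = region$label,
                 eccentricity = unname(sf["eccentricity"]),
                 axis_ratio = unname(sf["axis_ratio"]),
                 diameter_ratio = unname(sf["diameter_ratio"]),
                 n_minima = nrow(mins),
                 max_minima_dist = max_minima_distance(mins),
                 flagged = FALSE)
    }, error = function(e) {
      warning("feature extraction failed for region ", region$label,
              ": ", conditionMessage(e))
      data.frame(label = region$label, eccentricity = NA_real_,
                 axis_ratio = NA_real_, diameter_ratio = NA_real_,
                 n_minima = NA_integer_, max_minima_dist = NA_real_,
                 flagged = TRUE)
    })
    rec
  })
  do.call(rbind, rows)
}

#' Write / read a feature table as CSV
#'
#' UTF-8, '.' decimal separator, full double precision so tables
#' round-trip bit-exactly.
#'
#' @param features Data frame from [extract_features()].
#' @param path CSV path.
#' @return `write_feature_csv` returns `path` invisibly;
#'   `read_feature_csv` returns the data frame.
#' @export
write_feature_csv <- function(features, path) {
  df <- features
  for (nm in c("eccentricity", "axis_ratio", "diameter_ratio",
               "max_minima_dist"))
    if (nm %in% names(df)) df[[nm]] <- sprintf("%.17g", df[[nm]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  for (nm in c("eccentricity", "axis_ratio", "diameter_ratio",
               "max_minima_dist"))
    if (nm %in% names(df)) df[[nm]] <- as.numeric(df[[nm]])
  df
}
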