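#' Sobel gradient magnitude
#'
#' Convolves the grayscale image with the standard 3x3 Sobel kernels in
#' x and y and combines the two responses as a Euclidean norm. Borders
#' are handled by edge replication.
#'
#' @param gray Numeric/integer `H x W` matrix of gray levels.
#' @return Floating-point `H x W` magnitude matrix.
#' @export
gradient_magnitude <- function(gray) {
  check_gray(gray)
  gray <- matrix(as.numeric(gray), nrow(gray), ncol(gray))
  # kernels in [row, col] convention: kx differentiates across columns
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  ky <- t(kx)
  gx <- EBImage::filter2(gray, kx, boundary = "replicate")
  gy <- EBImage::filter2(gray, ky, boundary = "replicate")
  sqrt(gx^2 + gy^2)
}

#' Canny-style edge filtering of a gradient-magnitude raster
#'
#' The magnitude raster is smoothed with a Gaussian (`sigma`), normalized
#' to \[0, 1\] by its maximum, and thresholded with hysteresis: pixels
#' above `high_threshold` are strong seeds, connected runs above
#' `low_ratio * high_threshold` are retained when they contain a seed.
#' The surviving ridge band is then thinned morphologically to 1-px-wide
#' curves. Thinning (rather than directional non-maximum suppression) is
#' used because the downstream stages require *closed* contours and
#' suppression tends to open diagonal gaps.
#'
#' @param gradient Magnitude raster from [gradient_magnitude()].
#' @param high_threshold Strong-edge threshold on the normalized
#'   magnitude, in (0, 1); default 0.4.
#' @param low_ratio Low/high hysteresis threshold ratio, default 0.4.
#' @param sigma Gaussian smoothing sigma applied to the magnitude before
#'   thresholding, default 1.
#' @return Logical `H x W` edge map of 1-px-wide curves.
#' @export
edge_filter <- function(gradient, high_threshold = 0.4, low_ratio = 0.4,
                        sigma = 1.0) {
  if (!is.matrix(gradient)) stop("gradient must be a matrix")
  if (high_threshold <= 0 || high_threshold >= 1)
    stop("high_threshold must lie strictly inside (0, 1)")
  g <- gaussian_smooth(gradient, sigma)
  mx <- max(g)
  if (mx <= 0) return(matrix(FALSE, nrow(g), ncol(g)))
  g <- g / mx
  strong <- g >= high_threshold
  if (!any(strong)) return(matrix(FALSE, nrow(g), ncol(g)))
  weak <- g >= low_ratio * high_threshold
  lab <- label_components(weak, connectivity = 8L)
  keep <- sort(unique(lab[strong]))
  band <- matrix(lab %in% keep, nrow(g), ncol(g)) & weak
  thin_band(band)
}

# Zhang-Suen thinning of a binary band to 8-connected 1-px curves.
thin_band <- function(mask) {
  m <- mask
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      p2 <- mat_shift(m, 1, 0, FALSE)   # north neighbor value at p
      p3 <- mat_shift(m, 1, -1, FALSE)
      p4 <- mat_shift(m, 0, -1, FALSE)
      p5 <- mat_shift(m, -1, -1, FALSE)
      p6 <- mat_shift(m, -1, 0, FALSE)
      p7 <- mat_shift(m, -1, 1, FALSE)
      p8 <- mat_shift(m, 0, 1, FALSE)
      p9 <- mat_shift(m, 1, 1, FALSE)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
           (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      if (phase == 1) {
        cond <- m & b >= 2 & b <= 6 & a == 1 &
          !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- m & b >= 2 & b <= 6 & a == 1 &
          !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) {
        m[cond] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

#' Remove edge components by pixel-count size
#'
#' Drops 8-connected components whose pixel count falls outside
#' \[`min_pixels`, `max_pixels`\]; surviving components are unchanged.
#'
#' @param edges Logical edge map.
#' @param min_pixels,max_pixels Inclusive size window.
#' @return Filtered logical edge map.
#' @export
size_filter <- function(edges, min_pixels = 20L, max_pixels = 5000L) {
  if (min_pixels > max_pixels) stop("min_pixels must be <= max_pixels")
  if (!any(edges)) return(edges)
  lab <- label_components(edges, connectivity = 8L)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_pixels & sizes <= max_pixels)
  matrix(lab %in% keep, nrow(edges), ncol(edges))
}

#' Keep only closed (enclosing) edge contours
#'
#' A component is closed when it encloses at least one interior pixel:
#' flood-filling the background from the image border leaves an unfilled
#' pocket. Open arcs enclose nothing and are removed.
#'
#' @param edges Logical edge map of thinned curves.
#' @return Edge map containing only enclosing components.
#' @export
closed_contour_filter <- function(edges) {
  if (!any(edges)) return(edges)
  filled <- fill_interior(edges)
  interior <- filled & !edges
  if (!any(interior)) return(matrix(FALSE, nrow(edges), ncol(edges)))
  lab <- label_components(edges, connectivity = 8L)
  near_interior <- dilate3x3(interior)
  keep <- sort(unique(lab[near_interior & edges]))
  keep <- keep[keep > 0L]
  matrix(lab %in% keep, nrow(edges), ncol(edges))
}

#' Prune spurs and bifurcation whiskers from closed contours
#'
#' Two passes per component: (1) iterative spur pruning deletes any edge
#' pixel with exactly one 8-neighbor on the edge set, repeated to a
#' fixpoint; (2) redundant junction pixels -- pixels with three or more
#' 8-neighbors whose removal keeps the component connected and keeps
#' every remaining pixel with at least two neighbors -- are deleted one
#' at a time in raster order. The result is a set of simple closed
#' curves in which every pixel has exactly two 8-neighbors. Components
#' that degenerate below 8 pixels during pruning are dropped.
#'
#' @param edges Logical edge map of closed contours.
#' @return Edge map of simple closed curves.
#' @export
remove_bifurcations <- function(edges) {
  if (!any(edges)) return(edges)
  m <- prune_spurs(edges)
  lab <- label_components(m, connectivity = 8L)
  out <- matrix(FALSE, nrow(m), ncol(m))
  for (i in seq_len(max(lab))) {
    comp <- simplify_closed_curve(lab == i)
    if (!is.null(comp)) out <- out | comp
  }
  out
}

prune_spurs <- function(m) {
  repeat {
    nc <- neighbor_count8(m)
    spur <- m & nc <= 1L
    if (!any(spur)) return(m)
    m[spur] <- FALSE
  }
}

# Reduce one 8-connected closed component to a simple closed curve.
# Returns NULL when the component degenerates below 8 pixels.
simplify_closed_curve <- function(comp) {
  coords <- mask_coords(comp)
  if (nrow(coords) < 8L) return(NULL)
  # work on a cropped copy for speed
  bb <- mask_bbox(comp)
  sub <- comp[bb[1]:bb[3], bb[2]:bb[4], drop = FALSE]
  sub <- prune_spurs(sub)
  # delete redundant junction pixels one at a time; a deletion is safe
  # when no remaining pixel drops below two neighbors, the component
  # stays 8-connected, and no enclosed interior pixel leaks out (the
  # contour stays closed)
  interior_of <- function(m) sum(fill_interior(m) & !m)
  repeat {
    nc <- neighbor_count8(sub)
    excess <- which(sub & nc >= 3L)
    if (length(excess) == 0L) break
    nr <- nrow(sub)
    ord <- order((excess - 1L) %% nr, (excess - 1L) %/% nr)  # raster order
    interior0 <- interior_of(sub)
    deleted <- FALSE
    for (idx in excess[ord]) {
      cand <- sub
      cand[idx] <- FALSE
      if (sum(cand) < 8L) next
      ncc <- neighbor_count8(cand)
      if (any(cand & ncc < 2L)) next
      if (!is_single_component(cand)) next
      if (interior_of(cand) < interior0) next
      sub <- cand
      deleted <- TRUE
      break
    }
    if (!deleted) break  # no safely removable junction pixel; accept as is
  }
  if (sum(sub) < 8L) return(NULL)
  out <- matrix(FALSE, nrow(comp), ncol(comp))
  out[bb[1]:bb[3], bb[2]:bb[4]] <- sub
  out
}

is_single_component <- function(mask) {
  lab <- label_components(mask, connectivity = 8L)
  max(lab) == 1L
}

#' Fill contours and emit candidate nucleus regions
#'
#' Each simple closed contour is filled (flood fill from the exterior of
#' its bounding box) and optionally dilated by `region_dilate` pixels:
#' the thinned contour is the centerline of a gradient band a few pixels
#' wide, which systematically excludes the outer half of the
#' dark-to-bright transition, and a one-pixel dilation (the default)
#' restores the full dark support. Regions whose centroid lies outside
#' the cell cluster mask or whose filled area is below
#' `min_nucleus_area` are discarded; when two candidates overlap (e.g. a
#' small pocket loop at the waist of a merged pair inside the main
#' outline) the larger is kept. Labels are assigned in raster-scan order
#' of region centroids, so the output is deterministic.
#'
#' @param edges Edge map of simple closed curves.
#' @param cluster_mask Logical cell-cluster support from [hue_gate()];
#'   `NULL` disables the cluster restriction.
#' @param min_nucleus_area Minimum filled area in pixels.
#' @param region_dilate Number of one-pixel dilations applied to each
#'   filled contour, default 1.
#' @return List of `nucleus_region` objects, each with `label`,
#'   `boundary` (n x 2 (row, col) matrix), `filled_mask` (logical
#'   matrix, full image frame), `bbox`, `area` and `centroid`.
#' @export
contours_to_regions <- function(edges, cluster_mask = NULL,
                                min_nucleus_area = 50L,
                                region_dilate = 1L) {
  h <- nrow(edges); w <- ncol(edges)
  if (!any(edges)) return(list())
  lab <- label_components(edges, connectivity = 8L)
  cands <- list()
  for (i in seq_len(max(lab))) {
    comp <- lab == i
    filled <- fill_interior(comp)
    if (region_dilate > 0)
      for (d in seq_len(region_dilate)) filled <- dilate3x3(filled)
    area <- sum(filled)
    if (area < min_nucleus_area) next
    cen <- colMeans(mask_coords(filled))
    cr <- as.integer(round(cen[1])); cc <- as.integer(round(cen[2]))
    if (!is.null(cluster_mask)) {
      cr <- min(max(cr, 1L), h); cc <- min(max(cc, 1L), w)
      if (!cluster_mask[cr, cc]) next
    }
    cands[[length(cands) + 1L]] <- list(
      boundary = mask_coords(comp),
      filled_mask = filled,
      area = area,
      centroid = cen)
  }
  if (length(cands) == 0L) return(list())
  cens <- t(vapply(cands, function(x) x$centroid, numeric(2)))
  areas <- vapply(cands, function(x) x$area, numeric(1))
  # accept larger candidates first so a spurious inner loop cannot
  # displace the enclosing outline; label accepted regions in
  # raster-scan order of their centroids
  ord_accept <- order(-areas, round(cens[, 1]), round(cens[, 2]))
  occupied <- matrix(FALSE, h, w)
  accepted <- integer(0)
  for (j in ord_accept) {
    cand <- cands[[j]]
    if (any(cand$filled_mask & occupied)) next  # keep regions disjoint
    occupied <- occupied | cand$filled_mask
    accepted <- c(accepted, j)
  }
  accepted <- accepted[order(round(cens[accepted, 1]),
                             round(cens[accepted, 2]))]
  out <- vector("list", length(accepted))
  for (i in seq_along(accepted)) {
    cand <- cands[[accepted[i]]]
    region <- list(label = i,
                   boundary = cand$boundary,
                   filled_mask = cand$filled_mask,
                   bbox = mask_bbox(cand$filled_mask),
                   area = cand$area,
                   centroid = cand$centroid)
    class(region) <- "nucleus_region"
    out[[i]] <- region
  }
  out
}

#' Full boundary-extraction stage
#'
#' Chains [gradient_magnitude()], [edge_filter()], [size_filter()],
#' [closed_contour_filter()], [remove_bifurcations()] and
#' [contours_to_regions()]. The size-filter window and minimum nucleus
#' area scale with image area relative to the 1280x960 reference frame.
#'
#' @param gray Grayscale image matrix.
#' @param cluster_mask Cell-cluster support (or `NULL`).
#' @param config A [run_config()] list.
#' @return List of `nucleus_region` objects.
#' @export
segment_nuclei <- function(gray, cluster_mask = NULL, config = run_config()) {
  scale <- (nrow(gray) * ncol(gray)) / (1280 * 960)
  mag <- gradient_magnitude(gray)
  edges <- edge_filter(mag, config$canny_high, config$canny_low_ratio,
                       config$canny_sigma)
  edges <- size_filter(edges,
                       max(4L, round(config$size_min * scale)),
                       max(8L, round(config$size_max * scale)))
  edges <- closed_contour_filter(edges)
  edges <- remove_bifurcations(edges)
  contours_to_regions(edges, cluster_mask,
                      max(9L, round(config$min_nucleus_area * scale)),
                      region_dilate = config$region_dilate)
}

check_gray <- function(gray) {
  if (!is.matrix(gray)) stop("expected an H x W grayscale matrix")
  if (nrow(gray) < 3L || ncol(gray) < 3L) stop("image must be at least 3x3")
  invisible(TRUE)
}
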