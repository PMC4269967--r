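# Internal raster helpers shared across modules.
#
# Convention used throughout the package: rasters are plain R matrices
# indexed [row, col], 0-based pixel coordinates are never used at the R
# level -- (row, col) pairs reported to the user are 1-based, origin at
# the top-left corner of the image.

# Shift a matrix by (dr, dc), padding the vacated band with `fill`.
mat_shift <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  src_r <- seq_len(nr) - dr
  src_c <- seq_len(nc) - dc
  ok_r <- src_r >= 1L & src_r <= nr
  ok_c <- src_c >= 1L & src_c <= nc
  out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
  out
}

NEIGHBOR_OFFSETS_8 <- cbind(
  dr = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
  dc = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
)

# Count of TRUE 8-neighbors for each pixel of a logical matrix.
neighbor_count8 <- function(mask) {
  acc <- matrix(0L, nrow(mask), ncol(mask))
  for (i in seq_len(8L)) {
    acc <- acc + mat_shift(mask, NEIGHBOR_OFFSETS_8[i, 1L],
                           NEIGHBOR_OFFSETS_8[i, 2L], fill = FALSE)
  }
  acc
}

# Minimum over the 8 neighbors of each pixel; borders padded with +Inf.
neighbor_min8 <- function(m) {
  acc <- matrix(Inf, nrow(m), ncol(m))
  for (i in seq_len(8L)) {
    acc <- pmin(acc, mat_shift(m, NEIGHBOR_OFFSETS_8[i, 1L],
                               NEIGHBOR_OFFSETS_8[i, 2L], fill = Inf))
  }
  acc
}

# TRUE where every pixel of the 3x3 neighborhood (pixel included) is TRUE.
erode3x3 <- function(mask) {
  acc <- mask
  for (i in seq_len(8L)) {
    acc <- acc & mat_shift(mask, NEIGHBOR_OFFSETS_8[i, 1L],
                           NEIGHBOR_OFFSETS_8[i, 2L], fill = FALSE)
  }
  acc
}

# TRUE where any pixel of the 3x3 neighborhood is TRUE.
dilate3x3 <- function(mask) {
  acc <- mask
  for (i in seq_len(8L)) {
    acc <- acc | mat_shift(mask, NEIGHBOR_OFFSETS_8[i, 1L],
                           NEIGHBOR_OFFSETS_8[i, 2L], fill = FALSE)
  }
  acc
}

# Connected-component labeling of a logical matrix.
#
# EBImage::bwlabel is 4-connected; 8-connectivity is obtained by merging
# 4-connected labels that touch diagonally (union-find over the label
# graph). Labels are renumbered 1..n in row-major order of each
# component's first pixel, so the result is deterministic.
label_components <- function(mask, connectivity = 8L) {
  stopifnot(connectivity %in% c(4L, 8L))
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  lab <- EBImage::bwlabel(mask * 1)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  nlab <- max(lab)
  if (connectivity == 8L && nlab > 1L) {
    pairs <- rbind(
      cbind(as.vector(lab[-nrow(lab), -ncol(lab)]), as.vector(lab[-1, -1])),
      cbind(as.vector(lab[-nrow(lab), -1]), as.vector(lab[-1, -ncol(lab)]))
    )
    pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L & pairs[, 1] != pairs[, 2], ,
                   drop = FALSE]
    if (nrow(pairs) > 0L) {
      parent <- seq_len(nlab)
      find <- function(i) {
        root <- i
        while (parent[root] != root) root <- parent[root]
        while (parent[i] != root) { nxt <- parent[i]; parent[i] <<- root; i <- nxt }
        root
      }
      for (k in seq_len(nrow(pairs))) {
        a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
        if (a != b) parent[max(a, b)] <- min(a, b)
      }
      root_of <- vapply(seq_len(nlab), find, integer(1))
      lab[lab > 0L] <- root_of[lab[lab > 0L]]
    }
  }
  relabel_raster_order(lab)
}

# Renumber positive labels 1..n by row-major order of first occurrence.
relabel_raster_order <- function(lab) {
  idx <- which(lab > 0L)
  if (length(idx) == 0L) return(lab)
  nr <- nrow(lab)
  r <- (idx - 1L) %% nr + 1L
  c <- (idx - 1L) %/% nr + 1L
  rowmajor <- (r - 1L) * ncol(lab) + c
  vals <- lab[idx]
  first <- tapply(rowmajor, vals, min)
  order_map <- integer(max(vals))
  order_map[as.integer(names(first))] <- rank(first, ties.method = "first")
  lab[idx] <- order_map[vals]
  lab
}

# Bounding box (row0, col0, row1, col1), 1-based inclusive, of a mask.
mask_bbox <- function(mask) {
  idx <- which(mask)
  nr <- nrow(mask)
  r <- (idx - 1L) %% nr + 1L
  c <- (idx - 1L) %/% nr + 1L
  c(min(r), min(c), max(r), max(c))
}

# (row, col) coordinate matrix of TRUE pixels.
mask_coords <- function(mask) {
  idx <- which(mask)
  nr <- nrow(mask)
  cbind(row = (idx - 1L) %% nr + 1L, col = (idx - 1L) %/% nr + 1L)
}

# Fill the interior of closed curves: pixels not reachable from the
# border of the (padded) complement under 4-connectivity.
fill_interior <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  comp <- !pad
  lab <- matrix(as.integer(EBImage::bwlabel(comp * 1)), nr + 2L, nc + 2L)
  outside <- lab[1L, 1L]  # padding ring is one 4-connected component
  filled <- pad | (lab != outside & comp)
  filled[2:(nr + 1L), 2:(nc + 1L)]
}

# Gaussian smoothing of a plain matrix with edge replication.
gaussian_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  radius <- max(1L, ceiling(3 * sigma))
  x <- seq(-radius, radius)
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  k <- outer(g, g)
  EBImage::filter2(m, k, boundary = "replicate")
}
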