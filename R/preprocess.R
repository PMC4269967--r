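#' Hue-gated cell-cluster mask
#'
#' Converts an RGB image to HSV (hue in \[0, 1\]) and keeps pixels whose
#' hue lies inside the closed interval \[`hue_lo`, `hue_hi`\]. Cervical
#' cytoplasmic material falls in the mid-hue band while the bright slide
#' background does not, so the gate isolates the cell clusters. The raw
#' gate is cleaned by morphological closing (disk radius `close_radius`)
#' followed by hole filling so the cluster support is a set of filled
#' blobs. Gating uses the hue channel only; saturation and value are
#' ignored.
#'
#' @param image `H x W x 3` array of 8-bit RGB values (0-255).
#' @param hue_lo,hue_hi Closed hue interval, defaults 0.2 and 0.7.
#' @param close_radius Disk radius (pixels) of the post-gate closing.
#' @return A logical `H x W` matrix with attributes `hue_lo`, `hue_hi`.
#'   If no pixel passes the gate a warning is raised and an all-`FALSE`
#'   mask returned, so callers can report "no cells found" rather than
#'   fail.
#' @export
hue_gate <- function(image, hue_lo = 0.2, hue_hi = 0.7, close_radius = 5L) {
  check_rgb(image)
  if (!(hue_lo >= 0 && hue_lo < hue_hi && hue_hi <= 1))
    stop("need 0 <= hue_lo < hue_hi <= 1")
  h <- dim(image)[1]; w <- dim(image)[2]
  rgb <- rbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
               as.vector(image[, , 3]))
  hue <- grDevices::rgb2hsv(rgb, maxColorValue = 255)[1L, ]
  mask <- matrix(hue >= hue_lo & hue <= hue_hi, h, w)
  if (!any(mask)) {
    warning("hue gate matched no pixels; no cell clusters found")
  } else {
    if (close_radius > 0) {
      brush <- EBImage::makeBrush(2L * as.integer(close_radius) + 1L,
                                  shape = "disc")
      mask <- EBImage::closing(mask * 1, brush) > 0
    }
    mask <- fill_interior(mask)
  }
  attr(mask, "hue_lo") <- hue_lo
  attr(mask, "hue_hi") <- hue_hi
  mask
}

#' Convert an RGB image to 8-bit grayscale
#'
#' Standard luma weighting 0.299 R + 0.587 G + 0.114 B, rounded half-up
#' to an integer gray level, so results are bit-exact across platforms.
#'
#' @param image `H x W x 3` array of 8-bit RGB values (0-255).
#' @return Integer `H x W` matrix of gray levels 0-255.
#' @export
to_grayscale <- function(image) {
  check_rgb(image)
  g <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  matrix(as.integer(floor(g + 0.5)), dim(image)[1], dim(image)[2])
}

#' Area-averaged downscaling
#'
#' Resamples an RGB image by exact area averaging: output pixel (i, j)
#' is the mean of its pre-image rectangle in the input, with fractional
#' row/column overlap handled exactly. The output size is
#' `round(input_size * factor)` per axis; a 2560x1920 input at factor
#' 1/2 yields 1280x960.
#'
#' @param image `H x W x 3` array of 8-bit RGB values.
#' @param factor Positive scale factor (< 1 shrinks).
#' @return Resampled `H' x W' x 3` array of 8-bit values.
#' @export
downscale <- function(image, factor) {
  check_rgb(image)
  if (!is.finite(factor) || factor <= 0) stop("factor must be > 0")
  h <- dim(image)[1]; w <- dim(image)[2]
  ho <- round(h * factor); wo <- round(w * factor)
  if (ho < 2 || wo < 2) stop("output image would be smaller than 2x2")
  if (ho == h && wo == w) return(image)
  R <- overlap_weights(ho, h)
  C <- overlap_weights(wo, w)
  out <- array(0L, dim = c(ho, wo, 3L))
  for (ch in 1:3)
    out[, , ch] <- as.integer(floor(R %*% image[, , ch] %*% t(C) + 0.5))
  out
}

# n_out x n_in row-stochastic matrix of interval-overlap weights:
# output cell i covers input interval [(i-1)*s, i*s), s = n_in/n_out.
overlap_weights <- function(n_out, n_in) {
  s <- n_in / n_out
  W <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    lo <- (i - 1) * s; hi <- i * s
    j0 <- floor(lo) + 1L; j1 <- ceiling(hi)
    for (j in j0:min(j1, n_in)) {
      ov <- min(hi, j) - max(lo, j - 1)
      if (ov > 0) W[i, j] <- ov
    }
    W[i, ] <- W[i, ] / sum(W[i, ])
  }
  W
}

check_rgb <- function(image) {
  if (length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("expected an H x W x 3 RGB array")
  if (dim(image)[1] < 3L || dim(image)[2] < 3L)
    stop("image must be at least 3x3")
  if (min(image) < 0 || max(image) > 255)
    stop("channel values must lie in [0, 255]")
  invisible(TRUE)
}

#' Read an image file as an 8-bit RGB array
#'
#' Supports PNG, TIFF and JPEG. Grayscale inputs are replicated across
#' channels; an alpha channel is dropped.
#'
#' @param path Image file path.
#' @return `H x W x 3` integer array of 8-bit channel values, rows =
#'   image rows (origin top-left).
#' @export
read_image_rgb <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), dim = c(dim(a), 3L))
  a <- a[, , 1:3, drop = FALSE]
  a <- aperm(a, c(2L, 1L, 3L))  # EBImage stores x (column) first
  array(as.integer(round(a * 255)), dim = dim(a))
}

#' Read a labeled instance mask from a 16-bit TIFF/PNG file
#'
#' @param path Mask file path; gray level k/65535 decodes to label k.
#' @return Integer label matrix.
#' @export
read_label_mask <- function(path) {
  if (!file.exists(path)) stop("cannot read mask: ", path)
  a <- if (grepl("\\.tiff?$", path, ignore.case = TRUE))
    tiff::readTIFF(path) else png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1]
  matrix(as.integer(round(a * 65535)), nrow(a), ncol(a))
}
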