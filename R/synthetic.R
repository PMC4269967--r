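#' Specification of a synthetic cervical scene
#'
#' Describes a synthetic Pap smear field of view: a bright background, one
#' mid-hue cytoplasmic cell cluster, and dark elliptical nuclei placed
#' inside the cluster. Single nuclei are rendered with a radially
#' darkening quadratic profile so that, before noise, each has exactly one
#' grayscale intensity minimum; an overlapped pair is the pixelwise
#' minimum of two such profiles and therefore carries at least two minima.
#'
#' @param width,height Scene size in pixels.
#' @param n_single Number of isolated nuclei.
#' @param n_overlap Number of overlapped nucleus *pairs*.
#' @param nucleus_radius_range Length-2 vector, min/max nucleus
#'   semi-axis length in pixels.
#' @param overlap_offset_fraction Center distance of an overlapped pair
#'   as a fraction of the sum of the two mean radii; must lie in (0, 1)
#'   so the pair genuinely intersects.
#' @param nucleus_intensity Gray level (0-255) at a nucleus center. The
#'   profile ramps quadratically to the midpoint of nucleus and cytoplasm
#'   intensity at the nucleus rim.
#' @param cytoplasm_intensity,background_intensity Gray levels (0-255) of
#'   the cytoplasmic cluster and the slide background. The invariant
#'   `nucleus < cytoplasm < background` reflects nuclei being among the
#'   darkest structures in a cervical sample.
#' @param noise_sigma Standard deviation of additive Gaussian pixel noise
#'   (gray levels) applied to the intensity channel before color
#'   synthesis.
#' @param rng_seed Integer seed; scenes are bit-reproducible given the
#'   seed.
#'
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(width = 1280L, height = 960L,
                       n_single = 14L, n_overlap = 3L,
                       nucleus_radius_range = c(12, 20),
                       overlap_offset_fraction = 0.6,
                       nucleus_intensity = 60,
                       cytoplasm_intensity = 200,
                       background_intensity = 225,
                       noise_sigma = 0,
                       rng_seed = 1L) {
  spec <- list(width = as.integer(width), height = as.integer(height),
               n_single = as.integer(n_single),
               n_overlap = as.integer(n_overlap),
               nucleus_radius_range = as.numeric(nucleus_radius_range),
               overlap_offset_fraction = overlap_offset_fraction,
               nucleus_intensity = nucleus_intensity,
               cytoplasm_intensity = cytoplasm_intensity,
               background_intensity = background_intensity,
               noise_sigma = noise_sigma,
               rng_seed = as.integer(rng_seed))
  class(spec) <- "scene_spec"
  validate_scene_spec(spec)
  spec
}

validate_scene_spec <- function(spec) {
  with(spec, {
    if (width < 32L || height < 32L)
      stop("scene must be at least 32x32 pixels")
    if (n_single < 0L || n_overlap < 0L || n_single + n_overlap < 1L)
      stop("need n_single >= 0, n_overlap >= 0 and at least one object")
    if (length(nucleus_radius_range) != 2L ||
        nucleus_radius_range[1] < 3 ||
        nucleus_radius_range[2] < nucleus_radius_range[1])
      stop("nucleus_radius_range must be an increasing pair >= 3 px")
    if (overlap_offset_fraction <= 0 || overlap_offset_fraction >= 1)
      stop("overlap_offset_fraction must lie strictly inside (0, 1)")
    if (!(nucleus_intensity < cytoplasm_intensity &&
          cytoplasm_intensity < background_intensity))
      stop("need nucleus_intensity < cytoplasm_intensity < background_intensity")
    if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  })
  invisible(spec)
}

# Fixed scene palette. Channel offsets are added to the quantized
# intensity channel, chosen so that (a) the hue of cytoplasm+nuclei is
# exactly 0.45 and of the background 0.95, and (b) the 0.299/0.587/0.114
# luma of the synthesized color is the intensity plus a *constant*
# offset. (b) guarantees that grayscale conversion of the rendered 8-bit
# RGB preserves the intensity ordering pixel-for-pixel, so the designed
# local-minima structure survives color synthesis and quantization.
CELL_OFFSETS <- c(r = -10L, g = 10L, b = 4L)   # hue (2 + 14/20)/6 = 0.45
BG_OFFSETS   <- c(r =  8L, g = -2L, b = 1L)    # hue (6 - 3/10)/6  = 0.95

#' Generate a ground-truthed synthetic cervical scene
#'
#' Renders the scene described by a [scene_spec()]: one large elliptical
#' cytoplasmic cluster on a bright background, with dark elliptical
#' nuclei placed inside it without unintended contact between distinct
#' ground-truth objects. Cytoplasm (and nuclei) pixels have hue 0.45,
#' background pixels hue 0.95, so the hue gate of [hue_gate()] separates
#' them cleanly.
#'
#' @param spec A [scene_spec()].
#' @return A list with elements
#'   \describe{
#'     \item{image}{`height x width x 3` array of 8-bit RGB values
#'       (integers 0-255).}
#'     \item{gray_reference}{`height x width` matrix of the noiseless
#'       pre-color intensity channel (gray levels).}
#'     \item{truth}{A `ground_truth` list: `instance_mask` (integer
#'       matrix, 0 = background, k = nucleus instance), `region_labels`
#'       (character vector mapping instance label to `"single"` or
#'       `"overlapped"`), `cluster_mask` (logical matrix of cytoplasmic
#'       support), and `objects` (per-connected-object list of masks and
#'       class labels, overlapped pairs merged).}
#'     \item{spec}{The input spec.}
#'   }
#' @export
generate_scene <- function(spec) {
  validate_scene_spec(spec)
  w <- spec$width; h <- spec$height
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(spec$rng_seed)

  rowm <- matrix(seq_len(h), h, w)
  colm <- matrix(seq_len(w), h, w, byrow = TRUE)

  # cytoplasmic cluster: one large axis-aligned ellipse with margins
  cy <- h / 2; cx <- w / 2
  ay <- 0.42 * h; ax <- 0.44 * w
  cluster_mask <- ((rowm - cy) / ay)^2 + ((colm - cx) / ax)^2 <= 1

  objects <- place_objects(spec, cy, cx, ay, ax)

  rim <- (spec$nucleus_intensity + spec$cytoplasm_intensity) / 2
  v <- matrix(spec$background_intensity, h, w)
  v[cluster_mask] <- spec$cytoplasm_intensity
  instance <- matrix(0L, h, w)
  e_best <- matrix(Inf, h, w)
  region_labels <- character(0)

  k <- 0L
  for (obj in objects) {
    for (ell in obj$ellipses) {
      k <- k + 1L
      region_labels[k] <- obj$class
      e2 <- ellipse_radius2(rowm, colm, ell)
      inside <- e2 <= 1
      prof <- spec$nucleus_intensity + (rim - spec$nucleus_intensity) * e2
      v[inside] <- pmin(v[inside], prof[inside])
      claim <- inside & (e2 < e_best)
      instance[claim] <- k
      e_best[claim] <- e2[claim]
    }
  }
  names(region_labels) <- as.character(seq_len(k))

  if (spec$noise_sigma > 0)
    v <- v + matrix(stats::rnorm(h * w, sd = spec$noise_sigma), h, w)
  vq <- round(pmin(pmax(v, 12), 244))

  img <- array(0L, dim = c(h, w, 3L))
  for (ch in 1:3) {
    off <- ifelse(cluster_mask, CELL_OFFSETS[ch], BG_OFFSETS[ch])
    img[, , ch] <- as.integer(pmin(pmax(vq + off, 0), 255))
  }

  truth <- list(instance_mask = instance,
                region_labels = region_labels,
                cluster_mask = cluster_mask)
  truth$objects <- ground_truth_objects(truth)
  class(truth) <- "ground_truth"

  list(image = img, gray_reference = vq, truth = truth, spec = spec)
}

# squared normalized elliptical radius of each pixel w.r.t. an ellipse
# given as list(cy, cx, a, b, theta); a, b are semi-axes, theta radians.
ellipse_radius2 <- function(rowm, colm, ell) {
  dy <- rowm - ell$cy; dx <- colm - ell$cx
  u <- dx * cos(ell$theta) + dy * sin(ell$theta)
  t <- -dx * sin(ell$theta) + dy * cos(ell$theta)
  (u / ell$a)^2 + (t / ell$b)^2
}

# Rejection-sample object placements inside the cluster core.
# Distinct ground-truth objects keep a clearance gap so they never touch.
place_objects <- function(spec, cy, cx, ay, ax, gap = 14, max_tries = 400L) {
  rng <- spec$nucleus_radius_range
  n_obj <- spec$n_overlap + spec$n_single
  classes <- c(rep("overlapped", spec$n_overlap), rep("single", spec$n_single))
  placed <- list()
  centers <- matrix(numeric(0), 0, 2)
  bounds <- numeric(0)
  for (i in seq_len(n_obj)) {
    cls <- classes[i]
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      a1 <- stats::runif(1, rng[1], rng[2])
      b1 <- stats::runif(1, max(rng[1], a1 / 1.5), a1)
      th1 <- stats::runif(1, 0, pi)
      if (cls == "single") {
        d <- 0; phi <- 0
        a2 <- b2 <- th2 <- NA_real_
        bound <- a1
      } else {
        a2 <- stats::runif(1, rng[1], rng[2])
        b2 <- stats::runif(1, max(rng[1], a2 / 1.5), a2)
        th2 <- stats::runif(1, 0, pi)
        r1 <- (a1 + b1) / 2; r2 <- (a2 + b2) / 2
        d <- spec$overlap_offset_fraction * (r1 + r2)
        phi <- stats::runif(1, 0, 2 * pi)
        bound <- d / 2 + max(a1, a2)
      }
      # center sampled so the whole object (bound + clearance) stays
      # strictly inside the cytoplasmic cluster
      ay_eff <- ay - bound - 10; ax_eff <- ax - bound - 10
      if (ay_eff <= 0 || ax_eff <= 0)
        stop("scene capacity exceeded: cluster too small for requested nuclei")
      oy <- cy + stats::runif(1, -1, 1) * ay_eff
      ox <- cx + stats::runif(1, -1, 1) * ax_eff
      if (((oy - cy) / ay_eff)^2 + ((ox - cx) / ax_eff)^2 > 1) next
      if (cls == "single") {
        ells <- list(list(cy = oy, cx = ox, a = a1, b = b1, theta = th1))
      } else {
        ells <- list(
          list(cy = oy - d / 2 * sin(phi), cx = ox - d / 2 * cos(phi),
               a = a1, b = b1, theta = th1),
          list(cy = oy + d / 2 * sin(phi), cx = ox + d / 2 * cos(phi),
               a = a2, b = b2, theta = th2))
      }
      clear <- TRUE
      if (nrow(centers) > 0) {
        dd <- sqrt((centers[, 1] - oy)^2 + (centers[, 2] - ox)^2)
        clear <- all(dd >= bounds + bound + gap)
      }
      if (clear) {
        centers <- rbind(centers, c(oy, ox))
        bounds <- c(bounds, bound)
        placed[[i]] <- list(class = cls, ellipses = ells)
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop("scene capacity exceeded: could not place object ", i,
           " after ", max_tries, " retries; reduce object count or size")
  }
  placed
}

#' Merge ground-truth instances into connected objects
#'
#' An overlapped pair renders as one connected dark object, which is what
#' the segmentation stage can recover; this helper groups instances into
#' such objects. An object is `"overlapped"` if it contains more than one
#' instance (or any instance labeled overlapped), `"single"` otherwise.
#'
#' @param truth A `ground_truth` list with `instance_mask` and
#'   `region_labels`.
#' @return A list, one element per object: `mask` (logical matrix),
#'   `class`, and `instances` (the instance labels merged into it).
#' @export
ground_truth_objects <- function(truth) {
  lab <- label_components(truth$instance_mask > 0L, connectivity = 8L)
  n <- max(lab)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    mask <- lab == i
    inst <- sort(unique(truth$instance_mask[mask]))
    inst <- inst[inst > 0L]
    cls <- if (length(inst) > 1L ||
               any(truth$region_labels[as.character(inst)] == "overlapped"))
      "overlapped" else "single"
    out[[i]] <- list(mask = mask, class = cls, instances = inst)
  }
  out
}

#' Generate two labeled Gaussian clouds in 5-D feature space
#'
#' Fixture generator for the clustering stage: two isotropic-by-dimension
#' Gaussian point clouds around given 5-vector centroids.
#'
#' @param n_per_class Points per class (>= 1).
#' @param centroid_a,centroid_b Numeric 5-vectors of class means.
#' @param spread Per-dimension standard deviation, length 1 or 5,
#'   strictly positive (a zero spread degenerates every point to its
#'   centroid and is allowed for limit tests).
#' @param rng_seed Integer seed.
#' @return A list with `points` (2·n x 5 matrix) and `labels` (integer
#'   vector, 1 for class a, 2 for class b).
#' @export
generate_feature_points <- function(n_per_class, centroid_a, centroid_b,
                                    spread = 0.1, rng_seed = 1L) {
  if (n_per_class < 1L) stop("n_per_class must be >= 1")
  if (length(centroid_a) != 5L || length(centroid_b) != 5L)
    stop("centroids must be 5-vectors")
  if (!all(is.finite(centroid_a)) || !all(is.finite(centroid_b)))
    stop("centroid entries must be finite")
  if (length(spread) == 1L) spread <- rep(spread, 5L)
  if (length(spread) != 5L || any(spread < 0))
    stop("spread must be a nonnegative scalar or 5-vector")
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(rng_seed))
  draw <- function(centroid) {
    pts <- matrix(stats::rnorm(n_per_class * 5L), n_per_class, 5L)
    sweep(sweep(pts, 2L, spread, `*`), 2L, centroid, `+`)
  }
  pa <- draw(centroid_a); pb <- draw(centroid_b)
  list(points = rbind(pa, pb),
       labels = rep(1:2, each = n_per_class))
}

#' Write a synthetic scene to disk
#'
#' Writes the RGB image as 8-bit PNG, the instance mask as 16-bit TIFF
#' (label k stored as gray level k/65535), and the spec plus region
#' labels as a JSON sidecar.
#'
#' @param scene Result of [generate_scene()].
#' @param dir Output directory (created if missing).
#' @param stem File name stem, default `"scene"`.
#' @return Invisibly, the named vector of written paths.
#' @export
write_scene <- function(scene, dir, stem = "scene") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(image = file.path(dir, paste0(stem, ".png")),
             mask = file.path(dir, paste0(stem, "_mask.tif")),
             sidecar = file.path(dir, paste0(stem, ".json")))
  png::writePNG(scene$image / 255, paths[["image"]])
  tiff::writeTIFF(scene$truth$instance_mask / 65535, paths[["mask"]],
                  bits.per.sample = 16L)
  sidecar <- list(spec = unclass(scene$spec),
                  region_labels = as.list(scene$truth$region_labels))
  jsonlite::write_json(sidecar, paths[["sidecar"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
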