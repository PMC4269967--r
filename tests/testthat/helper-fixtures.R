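# Shared fixtures: all test rasters are built in code.

make_disk <- function(r, pad = 3L) {
  d <- 2L * r + 2L * pad
  cx <- r + pad + 0.5
  rows <- matrix(seq_len(d), d, d)
  cols <- t(rows)
  (rows - cx)^2 + (cols - cx)^2 <= r^2
}

# axis-aligned (theta = 0) or rotated solid ellipse with semi-axes a, b
make_ellipse <- function(a, b, theta = 0, pad = 3L) {
  d <- 2L * ceiling(max(a, b)) + 2L * pad
  cx <- d / 2 + 0.5
  rows <- matrix(seq_len(d), d, d)
  cols <- t(rows)
  dy <- rows - cx; dx <- cols - cx
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

region_from_mask <- function(mask, label = 1L) {
  structure(list(label = label, filled_mask = mask,
                 boundary = NULL, bbox = NULL,
                 area = sum(mask), centroid = colMeans(which(mask, arr.ind = TRUE))),
            class = "nucleus_region")
}

# independent plateau-aware local-minima oracle (slow loops, small inputs)
brute_minima_count <- function(gray, mask) {
  nr <- nrow(gray); nc <- ncol(gray)
  eligible <- matrix(FALSE, nr, nc)
  for (i in 2:(nr - 1)) for (j in 2:(nc - 1)) {
    if (all(mask[(i - 1):(i + 1), (j - 1):(j + 1)])) eligible[i, j] <- TRUE
  }
  cand <- matrix(FALSE, nr, nc)
  for (i in which(eligible)) {
    r <- (i - 1) %% nr + 1; c <- (i - 1) %/% nr + 1
    nb <- gray[max(1, r - 1):min(nr, r + 1), max(1, c - 1):min(nc, c + 1)]
    if (all(gray[r, c] <= nb)) cand[r, c] <- TRUE
  }
  # group candidates into equal-valued 8-connected plateaus
  seen <- matrix(FALSE, nr, nc)
  count <- 0L
  for (i in which(cand)) {
    r0 <- (i - 1) %% nr + 1; c0 <- (i - 1) %/% nr + 1
    if (seen[r0, c0]) next
    count <- count + 1L
    stack <- list(c(r0, c0)); seen[r0, c0] <- TRUE
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (dr in -1:1) for (dc in -1:1) {
        rr <- p[1] + dr; cc <- p[2] + dc
        if (rr < 1 || cc < 1 || rr > nr || cc > nc) next
        if (cand[rr, cc] && !seen[rr, cc] &&
            gray[rr, cc] == gray[p[1], p[2]]) {
          seen[rr, cc] <- TRUE
          stack[[length(stack) + 1L]] <- c(rr, cc)
        }
      }
    }
  }
  count
}

# small scene used by unit tests (fast to render and segment)
small_scene <- function(seed = 11L, n_single = 3L, n_overlap = 1L,
                        noise_sigma = 0) {
  generate_scene(scene_spec(width = 520L, height = 400L,
                            n_single = n_single, n_overlap = n_overlap,
                            nucleus_radius_range = c(10, 15),
                            noise_sigma = noise_sigma, rng_seed = seed))
}

# hand-made 8-pixel diamond ring: a simple closed curve in which every
# pixel has exactly two 8-neighbors (all adjacencies diagonal)
diamond_ring <- function(size = 12L, cy = 6L, cx = 6L, r = 2L) {
  m <- matrix(FALSE, size, size)
  for (i in seq_len(size)) for (j in seq_len(size))
    if (abs(i - cy) + abs(j - cx) == r) m[i, j] <- TRUE
  m
}

# full-pipeline synthetic sweep, computed once per test run and cached
sweep_cache <- new.env(parent = emptyenv())

acceptance_sweep <- function() {
  if (!is.null(sweep_cache$result)) return(sweep_cache$result)
  records <- list()
  for (k in 1:10) {
    noise <- if (k %% 2 == 0) 1.5 else 0
    scene <- generate_scene(scene_spec(rng_seed = 200L + k,
                                       noise_sigma = noise))
    res <- suppressWarnings(detect_overlaps(scene$image))
    km <- classify_regions(res$features, method = "kmeans")
    matching <- match_regions(res$regions, scene$truth)
    located <- matching$matches[matching$matches$tanimoto >= 0.5, ,
                                drop = FALSE]
    truth_map <- located$truth_class
    names(truth_map) <- as.character(located$region_label)
    records[[k]] <- list(
      n_objects = length(scene$truth$objects),
      matching = matching,
      truth_map = truth_map,
      fcm_calls = res$calls, fcm_model = res$model,
      km_calls = km$calls, km_model = km$model)
  }
  sweep_cache$result <- records
  records
}

pooled_f1 <- function(records, which_calls) {
  tp <- fp <- fn <- 0L
  for (rec in records) {
    calls <- rec[[which_calls]]
    calls <- calls[as.character(calls$label) %in% names(rec$truth_map), ,
                   drop = FALSE]
    t_pos <- rec$truth_map[as.character(calls$label)] == "overlapped"
    p_pos <- calls$predicted == "overlapped"
    tp <- tp + sum(p_pos & t_pos)
    fp <- fp + sum(p_pos & !t_pos)
    fn <- fn + sum(!p_pos & t_pos)
  }
  if (tp == 0L) return(0)
  prec <- tp / (tp + fp); rec_ <- tp / (tp + fn)
  2 * prec * rec_ / (prec + rec_)
}
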