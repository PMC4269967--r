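#' Tanimoto (Jaccard) similarity of two binary masks
#'
#' `Nc / (Na + Nb + Nc)` where `Nc` is the count of common foreground
#' pixels, `Na` those only in `mask_a` and `Nb` those only in `mask_b`.
#' Two empty masks are defined as identical (similarity 1) with a
#' warning.
#'
#' @param mask_a,mask_b Logical (or 0/1) matrices of equal shape.
#' @return Similarity in \[0, 1\].
#' @export
tanimoto <- function(mask_a, mask_b) {
  if (!all(dim(mask_a) == dim(mask_b)))
    stop("mask shapes differ: ", paste(dim(mask_a), collapse = "x"),
         " vs ", paste(dim(mask_b), collapse = "x"))
  a <- mask_a > 0; b <- mask_b > 0
  nc <- sum(a & b)
  na <- sum(a & !b)
  nb <- sum(b & !a)
  if (nc + na + nb == 0L) {
    warning("both masks empty; Tanimoto defined as 1")
    return(1)
  }
  nc / (na + nb + nc)
}

#' Precision, recall and F1 of overlap calls
#'
#' Overlapped is the positive class. Undefined ratios (zero
#' denominators) are reported as 0 and flagged.
#'
#' @param predicted Data frame with columns `label` and `predicted`
#'   (`"single"`/`"overlapped"`), e.g. from [call_overlap()].
#' @param truth Named character vector mapping label (as character) to
#'   the true class.
#' @return List with `precision`, `recall`, `f1`, `counts` (Tp, Tn, Fp,
#'   Fn) and `flagged` (TRUE when any ratio was undefined).
#' @export
classification_metrics <- function(predicted, truth) {
  if (NROW(predicted) == 0L) stop("empty prediction list")
  key <- as.character(predicted$label)
  if (!all(key %in% names(truth)))
    stop("labels missing from truth: ",
         paste(setdiff(key, names(truth)), collapse = ", "))
  t_pos <- truth[key] == "overlapped"
  p_pos <- predicted$predicted == "overlapped"
  tp <- sum(p_pos & t_pos); fp <- sum(p_pos & !t_pos)
  fn <- sum(!p_pos & t_pos); tn <- sum(!p_pos & !t_pos)
  flagged <- FALSE
  ratio <- function(num, den) {
    if (den == 0L) { flagged <<- TRUE; return(0) }
    num / den
  }
  precision <- ratio(tp, tp + fp)
  recall <- ratio(tp, tp + fn)
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    flagged <- TRUE
    0
  }
  if (flagged) warning("undefined ratio (zero denominator) reported as 0")
  list(precision = precision, recall = recall, f1 = f1,
       counts = c(Tp = tp, Tn = tn, Fp = fp, Fn = fn),
       flagged = flagged)
}

#' Independent per-feature significance score
#'
#' The two-sample signal-to-noise score
#' `|mean1 - mean2| / sqrt(var1/n1 + var2/n2)` computed independently
#' per feature column; larger scores mark more discriminative features.
#' Zero pooled variance with distinct means yields an `Inf` sentinel
#' with a warning.
#'
#' @param features `N x p` numeric matrix (or data frame).
#' @param class_labels Length-`N` vector with exactly two distinct
#'   values; at least two samples per class.
#' @return Numeric vector of `p` scores.
#' @export
feature_significance <- function(features, class_labels) {
  x <- as.matrix(features)
  cls <- unique(class_labels)
  if (length(cls) != 2L) stop("need exactly two classes")
  i1 <- class_labels == cls[1]; i2 <- class_labels == cls[2]
  if (sum(i1) < 2L || sum(i2) < 2L) stop("need >= 2 samples per class")
  m1 <- colMeans(x[i1, , drop = FALSE]); m2 <- colMeans(x[i2, , drop = FALSE])
  v1 <- apply(x[i1, , drop = FALSE], 2L, stats::var)
  v2 <- apply(x[i2, , drop = FALSE], 2L, stats::var)
  se <- sqrt(v1 / sum(i1) + v2 / sum(i2))
  num <- abs(m1 - m2)
  out <- ifelse(num == 0, 0, num / se)
  if (any(se == 0 & num > 0)) {
    warning("zero within-class variance; score reported as Inf")
    out[se == 0 & num > 0] <- Inf
  }
  out
}

#' Match predicted regions to ground-truth objects
#'
#' Greedy one-to-one matching by decreasing Tanimoto similarity between
#' predicted filled masks and ground-truth object supports. A truth
#' object is "located" when its match reaches `min_iou`.
#'
#' @param predicted_regions List of `nucleus_region` objects.
#' @param truth Either a `ground_truth` (its merged `objects` are used)
#'   or a list of object masks/classes as built by
#'   [ground_truth_objects()].
#' @param min_iou Located threshold on Tanimoto, default 0.5.
#' @return List with `located_fraction`, `matches` (data frame:
#'   `truth_object`, `region_label`, `tanimoto`, `truth_class`),
#'   `tanimoto_mean`/`tanimoto_sd` over located matches, and
#'   `unmatched_regions` (labels of spurious predictions).
#' @export
match_regions <- function(predicted_regions, truth, min_iou = 0.5) {
  objects <- if (inherits(truth, "ground_truth")) truth$objects else truth
  n_t <- length(objects); n_p <- length(predicted_regions)
  if (n_t == 0L) stop("no ground-truth objects")
  if (n_p == 0L) {
    return(list(located_fraction = 0,
                matches = data.frame(truth_object = integer(0),
                                     region_label = integer(0),
                                     tanimoto = numeric(0),
                                     truth_class = character(0)),
                tanimoto_mean = NA_real_, tanimoto_sd = NA_real_,
                unmatched_regions = integer(0)))
  }
  sim <- matrix(0, n_t, n_p)
  for (i in seq_len(n_t)) {
    tm <- objects[[i]]$mask
    for (j in seq_len(n_p)) {
      pm <- predicted_regions[[j]]$filled_mask
      inter <- sum(tm & pm)
      if (inter == 0L) next
      sim[i, j] <- inter / (sum(tm) + sum(pm) - inter)
    }
  }
  matches <- data.frame(truth_object = integer(0), region_label = integer(0),
                        tanimoto = numeric(0), truth_class = character(0),
                        stringsAsFactors = FALSE)
  avail_t <- rep(TRUE, n_t); avail_p <- rep(TRUE, n_p)
  s <- sim
  repeat {
    s[!avail_t, ] <- -1
    s[, !avail_p] <- -1
    best <- which.max(s)
    if (s[best] <= 0) break
    i <- (best - 1L) %% n_t + 1L
    j <- (best - 1L) %/% n_t + 1L
    matches <- rbind(matches, data.frame(
      truth_object = i,
      region_label = predicted_regions[[j]]$label,
      tanimoto = sim[i, j],
      truth_class = objects[[i]]$class,
      stringsAsFactors = FALSE))
    avail_t[i] <- FALSE; avail_p[j] <- FALSE
    if (!any(avail_t) || !any(avail_p)) break
  }
  located <- matches[matches$tanimoto >= min_iou, , drop = FALSE]
  list(located_fraction = nrow(located) / n_t,
       matches = matches,
       tanimoto_mean = if (nrow(located)) mean(located$tanimoto) else NA_real_,
       tanimoto_sd = if (nrow(located) > 1) stats::sd(located$tanimoto)
                     else NA_real_,
       unmatched_regions = vapply(
         predicted_regions[avail_p], function(r) r$label, integer(1)))
}
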