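#' Prevalence filter
#'
#' Retains features observed (count > 0) in at least `min_samples`
#' samples; the inclusive boundary matches the usual "present in at least
#' N samples" filter applied before network construction.
#'
#' @param counts count matrix (features x samples).
#' @param min_samples minimum number of samples with a nonzero count.
#' @return filtered count matrix, feature order preserved.
#' @export
prevalence_filter <- function(counts, min_samples) {
  counts <- count_matrix(counts)
  if (min_samples < 1) fail("min_samples must be >= 1")
  if (min_samples > ncol(counts)) {
    fail("min_samples (%d) exceeds number of samples (%d)",
         min_samples, ncol(counts))
  }
  keep <- rowSums(counts > 0) >= min_samples
  counts[keep, , drop = FALSE]
}

#' Cumulative sum scaling normalization with log2(x + 1)
#'
#' Per sample, counts are divided by the cumulative sum of counts up to a
#' chosen quantile of the sample's positive counts, rescaled by a
#' constant, and log2-transformed after adding a pseudocount of 1. This
#' counters preferential-amplification bias from differences in
#' sequencing depth while keeping zero counts at exactly zero.
#'
#' For sample j with quantile level l: the quantile q_j(l) is taken over
#' the positive counts (linear interpolation); the scale s_j is the sum of
#' all counts <= q_j(l); output is log2(x_ij / s_j * C + 1).
#'
#' @param counts count matrix (features x samples); no all-zero sample.
#' @param quantile_mode `"fixed:<l>"` (default `"fixed:0.5"`) or
#'   `"adaptive"`, which picks the smallest grid quantile at which the
#'   median scale across samples becomes unstable (relative change over
#'   the preceding grid point > 0.1), falling back to 0.5 when the scales
#'   stay stable.
#' @param scaling rescaling constant C (default 1000).
#' @return numeric matrix of CSS-log2 abundances with attributes
#'   `transform = "css_log2"`, `quantile`, `scaling`.
#' @export
css_normalize <- function(counts, quantile_mode = "fixed:0.5", scaling = 1000) {
  counts <- count_matrix(counts)
  zero_samp <- colSums(counts) == 0
  if (any(zero_samp)) {
    fail("all-zero sample(s): %s",
         paste(colnames(counts)[zero_samp], collapse = ", "))
  }
  l <- resolve_quantile(counts, quantile_mode)
  s <- css_scales(counts, l)
  if (any(s == 0)) {
    fail("zero CSS scale for sample(s): %s",
         paste(colnames(counts)[s == 0], collapse = ", "))
  }
  out <- log2(sweep(counts, 2, s, "/") * scaling + 1)
  structure(out, transform = "css_log2", quantile = l, scaling = scaling)
}

# per-sample CSS scale: sum of counts at or below the l-quantile of the
# sample's positive counts
css_scales <- function(counts, l) {
  vapply(seq_len(ncol(counts)), function(j) {
    x <- counts[, j]
    pos <- x[x > 0]
    q <- stats::quantile(pos, probs = l, names = FALSE, type = 7)
    sum(x[x <= q])
  }, numeric(1))
}

resolve_quantile <- function(counts, quantile_mode) {
  if (startsWith(quantile_mode, "fixed:")) {
    l <- suppressWarnings(as.numeric(sub("fixed:", "", quantile_mode)))
    if (!is.finite(l) || l <= 0 || l > 1) fail("invalid quantile in '%s'", quantile_mode)
    return(l)
  }
  if (quantile_mode != "adaptive") fail("unknown quantile_mode '%s'", quantile_mode)
  grid <- seq(0.25, 0.95, by = 0.05)
  med <- vapply(grid, function(l) stats::median(css_scales(counts, l)), numeric(1))
  rel <- abs(diff(med)) / pmax(med[-length(med)], .Machine$double.eps)
  hit <- which(rel > 0.1)
  if (length(hit) == 0) 0.5 else grid[hit[1] + 1]
}

#' Centred log-ratio transform
#'
#' Per sample: log(x + pseudocount) minus the sample mean of those logs
#' (natural log). Each sample column sums to zero by construction.
#'
#' @param counts count matrix (features x samples).
#' @param pseudocount positive offset added before the log (default 1).
#' @return numeric matrix with attributes `transform = "clr"`,
#'   `pseudocount`.
#' @export
clr_transform <- function(counts, pseudocount = 1) {
  counts <- count_matrix(counts)
  if (pseudocount <= 0) fail("pseudocount must be > 0")
  lx <- log(counts + pseudocount)
  out <- sweep(lx, 2, colMeans(lx), "-")
  structure(out, transform = "clr", pseudocount = pseudocount)
}

#' RV configuration-correlation coefficient
#'
#' Escoufier's RV coefficient between two multivariate configurations of
#' the same samples: RV = tr(S_X S_Y) / sqrt(tr(S_X^2) tr(S_Y^2)) where
#' S = t(Xc) Xc is the cross-sample Gram matrix of the per-feature
#' centered data. RV lies in [0, 1]; 1 means the two feature sets induce
#' the same sample geometry up to rotation and scale.
#'
#' @param X,Y numeric matrices (features x samples) over the same samples.
#' @return RV coefficient in [0, 1].
#' @export
rv_coefficient <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (ncol(X) != ncol(Y)) fail("X and Y must share the sample set")
  Xc <- X - rowMeans(X)
  Yc <- Y - rowMeans(Y)
  if (all(abs(Xc) < 1e-300) || all(abs(Yc) < 1e-300)) {
    fail("zero-variance configuration")
  }
  # tr(S_X S_Y) = ||Xc t(Yc)||_F^2 with S = t(Mc) Mc
  num <- sum((Xc %*% t(Yc))^2)
  den <- sqrt(sum((Xc %*% t(Xc))^2) * sum((Yc %*% t(Yc))^2))
  num / den
}

#' Core-microbiome membership by group
#'
#' A feature belongs to a group's core when it is present (count > 0) in
#' at least `threshold` of that group's samples (inclusive). Also returns
#' the intersection across all groups.
#'
#' @param counts count matrix (features x samples).
#' @param group_labels character/factor vector, one label per sample.
#' @param threshold presence fraction (default 0.5).
#' @return list with `per_group` (named list of feature id vectors),
#'   `intersection`, and `threshold`.
#' @export
core_membership <- function(counts, group_labels, threshold = 0.5) {
  counts <- count_matrix(counts)
  if (length(group_labels) != ncol(counts)) {
    fail("one group label per sample required")
  }
  if (threshold <= 0 || threshold > 1) fail("threshold must be in (0, 1]")
  groups <- split(seq_len(ncol(counts)), as.character(group_labels))
  if (any(lengths(groups) == 0)) fail("empty group")
  per_group <- lapply(groups, function(idx) {
    frac <- rowMeans(counts[, idx, drop = FALSE] > 0)
    rownames(counts)[frac >= threshold]
  })
  list(per_group = per_group,
       intersection = Reduce(intersect, per_group),
       threshold = threshold)
}
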