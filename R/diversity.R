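#' Chao1 richness estimator
#'
#' Bias-corrected Chao1: S_obs + F1 (F1 - 1) / (2 (F2 + 1)), where F1 and
#' F2 are the numbers of singletons and doubletons. Features with zero
#' count carry no information and leave the estimate unchanged.
#'
#' @param sample_counts non-negative integer vector of one sample's
#'   feature counts.
#' @return Chao1 estimate (>= observed richness).
#' @export
chao1 <- function(sample_counts) {
  if (any(sample_counts < 0) || any(!is_wholenumber(sample_counts))) {
    fail("counts must be non-negative integers")
  }
  if (all(sample_counts == 0)) fail("all-zero sample")
  s_obs <- sum(sample_counts > 0)
  f1 <- sum(sample_counts == 1)
  f2 <- sum(sample_counts == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Aggregate counts by a taxonomy rank
#'
#' Sums ASV counts within each level of a taxonomic rank (e.g. family);
#' features with a missing rank are dropped. Useful for rank-level
#' diversity summaries.
#'
#' @param counts count matrix (features x samples).
#' @param taxonomy taxonomy data.frame (see [read_taxonomy()]).
#' @param rank rank column name, default `"family"`.
#' @return count matrix with one row per rank level.
#' @export
aggregate_taxa <- function(counts, taxonomy, rank = "family") {
  counts <- count_matrix(counts)
  if (!rank %in% names(taxonomy)) fail("unknown rank '%s'", rank)
  lab <- taxonomy[[rank]][match(rownames(counts), taxonomy$feature_id)]
  keep <- !is.na(lab)
  agg <- rowsum(counts[keep, , drop = FALSE], lab[keep])
  count_matrix(as.matrix(agg))
}

#' Bray-Curtis dissimilarity matrix
#'
#' d(x, y) = 1 - 2 sum_i min(x_i, y_i) / (sum_i x_i + sum_i y_i), bounded
#' between 0 and 1, computed between all sample pairs.
#'
#' @param counts count matrix (features x samples), at least 2 samples.
#' @return symmetric sample-by-sample matrix with zero diagonal and
#'   attribute `metric = "bray_curtis"`.
#' @export
bray_curtis <- function(counts) {
  counts <- count_matrix(counts)
  n <- ncol(counts)
  if (n < 2) fail("at least 2 samples required")
  tot <- colSums(counts)
  d <- matrix(0, n, n, dimnames = list(colnames(counts), colnames(counts)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (tot[i] + tot[j] == 0) {
        fail("sample pair (%s, %s) with zero totals", colnames(counts)[i],
             colnames(counts)[j])
      }
      d[i, j] <- d[j, i] <-
        1 - 2 * sum(pmin(counts[, i], counts[, j])) / (tot[i] + tot[j])
    }
  }
  structure(d, metric = "bray_curtis")
}

#' Principal coordinates analysis
#'
#' Classical metric scaling: eigendecomposition of the Gower
#' double-centered matrix -1/2 J D^2 J. Axes are ordered by eigenvalue;
#' explained fractions are relative to the sum of positive eigenvalues.
#' Negative eigenvalues (possible for non-Euclidean dissimilarities such
#' as Bray-Curtis) are reported but given no coordinates.
#'
#' @param D symmetric dissimilarity matrix with zero diagonal, n >= 3.
#' @return list with `coordinates` (samples x positive axes),
#'   `explained` (fraction per axis), `eigenvalues` (all, decreasing),
#'   `negative_eigenvalues`.
#' @export
pcoa <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 3) fail("PCoA needs at least 3 samples")
  if (max(abs(D - t(D))) > 1e-12 || any(diag(D) != 0)) {
    fail("D must be symmetric with zero diagonal")
  }
  G <- -0.5 * D^2
  G <- sweep(G, 1, rowMeans(G))
  G <- sweep(G, 2, colMeans(G))
  G <- G + mean(-0.5 * D^2)
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-10
  pos <- e$values > tol
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), sum(pos))
  rownames(coords) <- rownames(D)
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  list(coordinates = coords,
       explained = e$values[pos] / sum(e$values[pos]),
       eigenvalues = e$values,
       negative_eigenvalues = e$values[e$values < -tol])
}

#' Permutation PERMANOVA (one-way)
#'
#' Distance-based pseudo-F: with SS_total = sum of squared distances over
#' all pairs divided by N and SS_within the analogous within-group sum,
#' F = (SS_between / (a - 1)) / (SS_within / (N - a)). The p-value is
#' obtained by uniformly permuting group labels, with
#' p = (1 + #\{F_perm >= F_obs\}) / (1 + n_permutations), so it is never 0.
#'
#' @param D symmetric dissimilarity matrix.
#' @param group_labels one label per sample; at least 2 non-empty groups.
#' @param n_permutations number of label permutations (default 999).
#' @param seed integer seed for the permutation stream.
#' @return list with `pseudo_F`, `p_value`, `n_permutations`, `seed`,
#'   `ss_between`, `ss_within`, `ss_total`.
#' @export
permanova <- function(D, group_labels, n_permutations = 999, seed = 1) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (length(group_labels) != n) fail("one group label per sample required")
  labels <- as.character(group_labels)
  a <- length(unique(labels))
  if (a < 2) fail("at least 2 groups required")
  if (any(table(labels) == 0)) fail("empty group")
  d2 <- D^2
  ss_total <- sum(d2[upper.tri(d2)]) / n

  ss_within <- function(lab) {
    ss <- 0
    for (g in unique(lab)) {
      idx <- which(lab == g)
      if (length(idx) > 1) {
        sub <- d2[idx, idx]
        ss <- ss + sum(sub[upper.tri(sub)]) / length(idx)
      }
    }
    ss
  }
  f_stat <- function(lab) {
    ss_w <- ss_within(lab)
    ss_b <- ss_total - ss_w
    if (ss_w <= .Machine$double.eps * max(1, ss_total)) {
      if (ss_b <= .Machine$double.eps) return(0)  # fully degenerate
      return(Inf)
    }
    (ss_b / (a - 1)) / (ss_w / (n - a))
  }

  f_obs <- f_stat(labels)
  set.seed(seed)
  f_perm <- vapply(seq_len(n_permutations),
                   function(i) f_stat(sample(labels)), numeric(1))
  p <- (1 + sum(f_perm >= f_obs)) / (1 + n_permutations)
  ss_w_obs <- ss_within(labels)
  list(pseudo_F = f_obs, p_value = p, n_permutations = n_permutations,
       seed = seed, ss_between = ss_total - ss_w_obs, ss_within = ss_w_obs,
       ss_total = ss_total)
}
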