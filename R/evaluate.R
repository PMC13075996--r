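#' Random-ASV baseline R^2
#'
#' Draws `n_draws` random sets of `m` ASVs (without replacement) from the
#' prevalence-filtered pool, fits each as OLS predictors of the
#' phenotype, and reports the per-draw and mean R^2. This is the null
#' reference a network-selected ASV panel must beat.
#'
#' @param pool_ids ASV ids eligible for sampling (the full
#'   post-filter pool of the dataset).
#' @param abundances numeric matrix (features x samples) containing all
#'   pool ids as rows.
#' @param y numeric phenotype, one value per sample (matching columns of
#'   `abundances`).
#' @param m panel size per draw (typically the number of network-selected
#'   ASVs).
#' @param n_draws number of random draws (default 10).
#' @param seed integer seed.
#' @param exclude_ids optional ids to exclude from the pool before
#'   drawing (off by default).
#' @return list with `r2` (one per draw), `mean_r2`, `draws` (id sets),
#'   `m`, `seed`.
#' @export
random_baseline <- function(pool_ids, abundances, y, m, n_draws = 10,
                            seed = 1, exclude_ids = NULL) {
  pool <- setdiff(pool_ids, exclude_ids)
  if (m > length(pool)) fail("m = %d exceeds pool size %d", m, length(pool))
  if (n_draws < 1) fail("n_draws must be >= 1")
  missing_rows <- setdiff(pool, rownames(abundances))
  if (length(missing_rows)) fail("pool ids missing from abundances: %s",
                                 paste(head(missing_rows, 5), collapse = ", "))
  set.seed(seed)
  draws <- lapply(seq_len(n_draws), function(i) sample(pool, m))
  r2 <- vapply(draws, function(ids) {
    suppressWarnings(ols_r2(t(abundances[ids, , drop = FALSE]), y))
  }, numeric(1))
  list(r2 = r2, mean_r2 = mean(r2), draws = draws, m = m, seed = seed)
}

#' k-fold cross-validated R^2
#'
#' One seeded shuffle with round-robin fold assignment (fold sizes differ
#' by at most one). Per fold, an OLS model fitted on the training samples
#' predicts the held-out samples, and CV-R^2 is the square of the Pearson
#' correlation between observed and predicted values in the held-out fold
#' — deliberately not 1 - SSE/SST, which differs out of sample. A fold
#' whose observed or predicted values are constant has an undefined
#' correlation; it is recorded as `NA` with a warning and excluded from
#' the mean.
#'
#' @param X numeric predictor matrix (samples x features).
#' @param y numeric response.
#' @param k number of folds (default 5); requires n >= 2k.
#' @param seed integer seed for the shuffle.
#' @return list with `fold` (assignment per sample), `per_fold` CV-R^2,
#'   `mean_cv_r2`, `k`, `seed`.
#' @export
kfold_cv <- function(X, y, k = 5, seed = 1) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k < 2) fail("k must be >= 2")
  if (n < 2 * k) fail("need n >= 2k samples")
  if (length(y) != n) fail("X and y sizes differ")
  set.seed(seed)
  fold <- integer(n)
  fold[sample.int(n)] <- rep(seq_len(k), length.out = n)
  per_fold <- rep(NA_real_, k)
  for (f in seq_len(k)) {
    test <- fold == f
    df_train <- data.frame(y = y[!test], X[!test, , drop = FALSE])
    df_test <- data.frame(X[test, , drop = FALSE])
    fit <- suppressWarnings(stats::lm(y ~ ., data = df_train))
    pred <- suppressWarnings(as.numeric(predict(fit, newdata = df_test)))
    if (sd(y[test]) == 0 || sd(pred) == 0 || anyNA(pred)) {
      warn("fold %d has constant observed or predicted values; CV-R^2 undefined", f)
      next
    }
    per_fold[f] <- stats::cor(y[test], pred)^2
  }
  list(fold = fold, per_fold = per_fold,
       mean_cv_r2 = mean(per_fold, na.rm = TRUE), k = k, seed = seed)
}

#' Summarize predictive performance across trait x dataset rows
#'
#' Takes base columns per combination — full-model size and R^2, the
#' random-baseline mean R^2, selected-panel size and R^2, optionally the
#' mean CV-R^2 — and computes the derived comparison columns:
#' `improvement_full` (full minus random), `improvement_selected`
#' (selected minus random), `retention_pct` (100 x selected/full R^2) and
#' `reduction_pct` (100 x (1 - selected/full panel size)). Aggregate
#' statistics over the rows are attached.
#'
#' @param rows data.frame with columns `dataset`, `trait`, `n_full`,
#'   `r2_full`, `r2_random_mean`, `n_selected`, `r2_selected` and
#'   optionally `cv_r2_mean`.
#' @return list with `table` (rows plus derived columns) and
#'   `aggregates` (mean/min/max improvement_full, min
#'   improvement_selected, min/max retention_pct and reduction_pct).
#' @export
summarize_performance <- function(rows) {
  need <- c("dataset", "trait", "n_full", "r2_full", "r2_random_mean",
            "n_selected", "r2_selected")
  miss <- setdiff(need, names(rows))
  if (length(miss)) fail("missing base column(s): %s", paste(miss, collapse = ", "))
  tab <- as.data.frame(rows, stringsAsFactors = FALSE)
  tab$improvement_full <- tab$r2_full - tab$r2_random_mean
  tab$improvement_selected <- tab$r2_selected - tab$r2_random_mean
  tab$retention_pct <- 100 * tab$r2_selected / tab$r2_full
  tab$reduction_pct <- 100 * (1 - tab$n_selected / tab$n_full)
  aggregates <- list(
    mean_improvement_full = mean(tab$improvement_full),
    min_improvement_full = min(tab$improvement_full),
    max_improvement_full = max(tab$improvement_full),
    min_improvement_selected = min(tab$improvement_selected),
    min_retention_pct = min(tab$retention_pct),
    max_retention_pct = max(tab$retention_pct),
    min_reduction_pct = min(tab$reduction_pct),
    max_reduction_pct = max(tab$reduction_pct)
  )
  list(table = tab, aggregates = aggregates)
}
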