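#' Coefficient of determination of an OLS fit
#'
#' Ordinary least squares with intercept; R^2 = 1 - SSE/SST. A
#' rank-deficient design is fitted on its column space (pivoted QR, the
#' projection a pseudo-inverse would give) with a warning.
#'
#' @param X numeric matrix of predictors (samples x features); may have
#'   zero columns, giving R^2 = 0.
#' @param y numeric response.
#' @return R^2 in [0, 1].
#' @export
ols_r2 <- function(X, y) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) fail("X and y sizes differ")
  sst <- sum((y - mean(y))^2)
  if (sst == 0) fail("response has zero variance")
  if (ncol(X) == 0) return(0)
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X), y)
  if (fit$rank < ncol(X) + 1) {
    warn("rank-deficient design (rank %d < %d); R^2 computed on the column space",
         fit$rank, ncol(X) + 1)
  }
  r2 <- 1 - sum(fit$residuals^2) / sst
  min(max(r2, 0), 1)
}

#' All-subsets regression path
#'
#' For each model size k = 1..p, finds the predictor subset with the
#' highest R^2. Engines:
#' * `exhaustive` — enumerates all subsets of each size (guarded by
#'   `p_exhaustive_max`).
#' * `branch_and_bound` (default of `auto` up to `p_exhaustive_max`) —
#'   a search tree over subsets pruned with the monotone bound that a
#'   subset's R^2 never exceeds that of any superset; gives exactly the
#'   exhaustive answer.
#' * `forward` — greedy stepwise addition; a flagged fallback for large
#'   p whose path is not guaranteed best-of-size.
#'
#' Ties in R^2 (within 1e-12) are broken by the lexicographically
#' smallest subset of original column positions, making the path
#' deterministic.
#'
#' @param X numeric matrix (samples x features) with column names.
#' @param y numeric response.
#' @param mode `"auto"`, `"exhaustive"`, `"branch_and_bound"` or
#'   `"forward"`.
#' @param p_exhaustive_max largest p for which full-search engines are
#'   allowed (default 20).
#' @return object of class `subset_path`: list with `k`, `r2`, `subsets`
#'   (feature-name vectors), `mode`, `full_r2`, `feature_ids`.
#' @export
best_subsets <- function(X, y,
                         mode = c("auto", "branch_and_bound", "exhaustive",
                                  "forward"),
                         p_exhaustive_max = 20) {
  mode <- match.arg(mode)
  X <- as.matrix(X)
  p <- ncol(X)
  if (p < 1) fail("at least one predictor required")
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(p))
  if (mode == "auto") {
    mode <- if (p <= p_exhaustive_max) "branch_and_bound" else "forward"
  }
  if (mode %in% c("exhaustive", "branch_and_bound") && p > p_exhaustive_max) {
    fail(paste("p = %d exceeds p_exhaustive_max = %d for mode '%s';",
               "raise p_exhaustive_max or use mode = 'forward'"),
         p, p_exhaustive_max, mode)
  }

  ## cross-moment cache: R^2(S) = Sxy[S]' solve(Sxx[S,S]) Sxy[S] / Syy
  Xc <- sweep(X, 2, colMeans(X))
  yc <- y - mean(y)
  Syy <- sum(yc^2)
  if (Syy == 0) fail("response has zero variance")
  Sxx <- crossprod(Xc)
  Sxy <- drop(crossprod(Xc, yc))
  r2_of <- function(s) {
    b <- tryCatch(solve(Sxx[s, s, drop = FALSE], Sxy[s]),
                  error = function(e) NULL)
    r2 <- if (is.null(b)) {
      q <- qr(Xc[, s, drop = FALSE])
      sum(qr.fitted(q, yc)^2) / Syy
    } else {
      sum(b * Sxy[s]) / Syy
    }
    min(max(r2, 0), 1)
  }

  tol <- 1e-12
  lex_less <- function(a, b) {
    d <- which(a != b)
    if (!length(d)) return(FALSE)
    a[d[1]] < b[d[1]]
  }
  better <- function(r2_new, set_new, r2_old, set_old) {
    if (is.null(set_old)) return(TRUE)
    if (r2_new > r2_old + tol) return(TRUE)
    if (r2_new < r2_old - tol) return(FALSE)
    lex_less(set_new, set_old)
  }

  best_r2 <- rep(-Inf, p)
  best_set <- vector("list", p)
  consider <- function(s) {
    r2 <- r2_of(s)
    k <- length(s)
    if (better(r2, s, best_r2[k], best_set[[k]])) {
      best_r2[k] <<- r2
      best_set[[k]] <<- s
    }
  }

  if (mode == "exhaustive") {
    for (k in seq_len(p)) {
      sets <- combn(p, k)
      for (j in seq_len(ncol(sets))) consider(sets[, j])
    }
  } else if (mode == "branch_and_bound") {
    ## search order: most marginally correlated first, for tight early bounds
    ord <- order(-(Sxy^2 / pmax(diag(Sxx), .Machine$double.eps)))
    recurse <- function(fixed, cand) {
      if (!length(cand)) return()
      bound <- r2_of(sort(c(fixed, cand)))
      ks <- (length(fixed) + 1):(length(fixed) + length(cand))
      if (all(bound < best_r2[ks] - tol)) return()
      for (i in seq_along(cand)) {
        s <- sort(c(fixed, cand[i]))
        consider(s)
        rest <- cand[-seq_len(i)]
        if (length(rest)) recurse(c(fixed, cand[i]), rest)
      }
    }
    recurse(integer(0), ord)
  } else {  # forward
    current <- integer(0)
    remaining <- seq_len(p)
    for (k in seq_len(p)) {
      cand_r2 <- vapply(remaining, function(j) r2_of(sort(c(current, j))),
                        numeric(1))
      ties <- remaining[cand_r2 >= max(cand_r2) - tol]
      pick <- min(ties)
      current <- sort(c(current, pick))
      remaining <- setdiff(remaining, pick)
      best_r2[k] <- r2_of(current)
      best_set[[k]] <- current
    }
  }

  full_r2 <- r2_of(seq_len(p))
  if (mode != "forward" && any(diff(best_r2) < -1e-10)) {
    fail("internal error: non-monotone best-subset path")
  }
  structure(list(k = seq_len(p), r2 = best_r2,
                 subsets = lapply(best_set, function(s) colnames(X)[s]),
                 mode = mode, full_r2 = full_r2,
                 feature_ids = colnames(X)),
            class = "subset_path")
}

#' @export
print.subset_path <- function(x, ...) {
  cat(sprintf("best-subsets path (%s), p = %d, full-model R^2 = %.4f\n",
              x$mode, length(x$k), x$full_r2))
  df <- data.frame(k = x$k, R2 = round(x$r2, 4),
                   subset = vapply(x$subsets, paste, "", collapse = ","))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Minimal predictor subset retaining a fraction of full-model R^2
#'
#' Applies the retention rule: the smallest model size k whose best R^2
#' reaches `threshold` times the full-model R^2. Reports the retained
#' fraction and the reduction in predictor count.
#'
#' @param path a `subset_path` from [best_subsets()].
#' @param threshold fraction of full-model R^2 to retain (default 0.95).
#' @return list with `minimal_k`, `subset`, `r2_selected`, `r2_full`,
#'   `retention` (= r2_selected / r2_full), `reduction`
#'   (= 1 - minimal_k / p), `threshold`.
#' @export
minimal_subset <- function(path, threshold = 0.95) {
  if (!inherits(path, "subset_path")) fail("path must be a subset_path")
  if (threshold <= 0 || threshold > 1) fail("threshold must be in (0, 1]")
  r2_full <- path$full_r2
  if (r2_full <= 0) fail("full-model R^2 is 0; nothing to retain")
  ok <- which(path$r2 >= threshold * r2_full - 1e-12)
  if (!length(ok)) fail("no subset reaches the retention threshold")
  k <- ok[1]
  list(minimal_k = k, subset = path$subsets[[k]],
       r2_selected = path$r2[k], r2_full = r2_full,
       retention = path$r2[k] / r2_full,
       reduction = 1 - k / length(path$k),
       threshold = threshold)
}
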