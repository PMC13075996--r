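test_that("ols_r2 reproduces textbook identities", {
  set.seed(51)
  x <- rnorm(30); y <- 2 * x + rnorm(30)
  expect_equal(ols_r2(matrix(x), y), cor(x, y)^2, tolerance = 1e-12)

  X <- matrix(rnorm(90), 30, 3)
  y_exact <- X %*% c(1, -2, 0.5) + 3
  expect_equal(ols_r2(X, y_exact), 1)

  y3 <- X %*% c(0.5, 1, -1) + rnorm(30)
  expect_equal(ols_r2(X, y3), r2_oracle(X, y3), tolerance = 1e-10)

  # rank-deficient design: column-space R^2 with a warning
  Xdef <- cbind(X, X[, 1] + X[, 2])
  expect_warning(r2d <- ols_r2(Xdef, y3), "rank-deficient")
  expect_equal(r2d, ols_r2(X, y3), tolerance = 1e-10)

  expect_equal(ols_r2(X[, 0, drop = FALSE], y3), 0)
  expect_error(ols_r2(X, rep(1, 30)), "zero variance")
})

test_that("orthogonal predictors rank by marginal squared correlation", {
  set.seed(52)
  raw <- matrix(rnorm(40 * 4), 40, 4)
  X <- qr.Q(qr(cbind(1, raw)))[, -1]  # orthonormal and mean-centered columns
  colnames(X) <- paste0("V", 1:4)
  y <- X %*% c(0.3, -0.9, 0.6, 0.1) + rnorm(40, sd = 0.3)
  path <- best_subsets(X, y, mode = "exhaustive")
  r2_marg <- vapply(1:4, function(j) cor(X[, j], y)^2, numeric(1))
  for (k in 1:4) {
    expect_setequal(path$subsets[[k]],
                    colnames(X)[order(-r2_marg)[seq_len(k)]])
  }
  expect_equal(path$subsets[[4]], colnames(X))
  expect_equal(path$r2[4], path$full_r2)
})

test_that("branch-and-bound equals exhaustive enumeration and the oracle", {
  for (s in 1:8) {
    set.seed(s)
    p <- sample(3:8, 1)
    X <- matrix(rnorm(40 * p), 40, p,
                dimnames = list(NULL, paste0("V", seq_len(p))))
    y <- X %*% rnorm(p) + rnorm(40)
    bb <- best_subsets(X, y, mode = "branch_and_bound")
    ex <- best_subsets(X, y, mode = "exhaustive")
    expect_identical(bb$subsets, ex$subsets)
    expect_equal(bb$r2, ex$r2, tolerance = 1e-12)
    # independent brute-force oracle
    ora <- subsets_oracle(X, y)
    for (k in seq_len(p)) {
      expect_setequal(bb$subsets[[k]], colnames(X)[ora[[k]]$set])
      expect_equal(bb$r2[k], ora[[k]]$r2, tolerance = 1e-10)
    }
    expect_true(all(diff(bb$r2) >= -1e-10))  # monotone path
  }
})

test_that("engine guards and fallbacks behave as documented", {
  set.seed(53)
  X <- matrix(rnorm(50 * 25), 50, 25)
  y <- rnorm(50)
  expect_error(best_subsets(X, y, mode = "exhaustive"), "p_exhaustive_max")
  fw <- best_subsets(X, y, mode = "auto")  # silently falls back
  expect_equal(fw$mode, "forward")
  expect_length(fw$subsets, 25)
  # forward nests its subsets
  for (k in 2:25) {
    expect_true(all(fw$subsets[[k - 1]] %in% fw$subsets[[k]]))
  }
})

test_that("duplicate predictors resolve by the lexicographic tie rule", {
  set.seed(54)
  x <- rnorm(30)
  X <- cbind(a = x, b = x, c = rnorm(30))
  y <- x + rnorm(30, sd = 0.5)
  path <- best_subsets(X, y, mode = "exhaustive")
  expect_identical(path$subsets[[1]], "a")  # 'a' and 'b' tie; first position wins
  bb <- best_subsets(X, y, mode = "branch_and_bound")
  expect_identical(bb$subsets[[1]], "a")
})

test_that("the minimal-subset retention rule picks the smallest adequate k", {
  fake <- structure(list(k = 1:4, r2 = c(0.30, 0.50, 0.58, 0.60),
                         subsets = list("a", c("a", "b"), c("a", "b", "c"),
                                        letters[1:4]),
                         mode = "exhaustive", full_r2 = 0.60,
                         feature_ids = letters[1:4]),
                    class = "subset_path")
  sel <- minimal_subset(fake, 0.95)
  expect_equal(sel$minimal_k, 3)        # 0.58 >= 0.95 * 0.60
  expect_equal(sel$retention, 0.58 / 0.60)
  expect_equal(sel$reduction, 1 - 3 / 4)

  # boundary: threshold 1 demands the full R^2
  expect_equal(minimal_subset(fake, 1)$minimal_k, 4)
  # a single adequate predictor gives k = 1
  fake2 <- fake; fake2$r2 <- c(0.59, 0.59, 0.59, 0.60); fake2$full_r2 <- 0.60
  expect_equal(minimal_subset(fake2, 0.95)$minimal_k, 1)
  # raising the threshold never decreases minimal_k
  ks <- vapply(c(0.5, 0.8, 0.9, 0.97, 1), function(t)
    minimal_subset(fake, t)$minimal_k, numeric(1))
  expect_true(all(diff(ks) >= 0))

  fake0 <- fake; fake0$full_r2 <- 0
  expect_error(minimal_subset(fake0, 0.95), "nothing to retain")
})
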