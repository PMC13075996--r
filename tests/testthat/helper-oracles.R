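# Independent reference implementations used as oracles. These are kept
# deliberately naive (triple loops, exhaustive enumeration, direct normal
# equations) and share no code with the package internals.

# brute-force PCIT trio scan: returns sorted "a|b" keys of retained edges
pcit_oracle <- function(r, guard = 1e-12) {
  n <- nrow(r)
  flagged <- matrix(FALSE, n, n)
  for (x in 1:(n - 2)) for (y in (x + 1):(n - 1)) for (z in (y + 1):n) {
    rxy <- r[x, y]; rxz <- r[x, z]; ryz <- r[y, z]
    den <- c(abs(rxy), abs(rxz), abs(ryz),
             1 - rxy^2, 1 - rxz^2, 1 - ryz^2)
    if (any(den < guard)) next
    p_xy <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
    p_xz <- (rxz - rxy * ryz) / sqrt((1 - rxy^2) * (1 - ryz^2))
    p_yz <- (ryz - rxy * rxz) / sqrt((1 - rxy^2) * (1 - rxz^2))
    eps <- (p_xy / rxy + p_xz / rxz + p_yz / ryz) / 3
    if (abs(rxy) < abs(eps * rxz) && abs(rxy) < abs(eps * ryz)) {
      flagged[x, y] <- flagged[y, x] <- TRUE
    }
    if (abs(rxz) < abs(eps * rxy) && abs(rxz) < abs(eps * ryz)) {
      flagged[x, z] <- flagged[z, x] <- TRUE
    }
    if (abs(ryz) < abs(eps * rxy) && abs(ryz) < abs(eps * rxz)) {
      flagged[y, z] <- flagged[z, y] <- TRUE
    }
  }
  ids <- rownames(r)
  keys <- character(0)
  for (x in 1:(n - 1)) for (y in (x + 1):n) {
    if (!flagged[x, y] && r[x, y] != 0) {
      keys <- c(keys, paste(sort(c(ids[x], ids[y])), collapse = "|"))
    }
  }
  sort(keys)
}

# edge keys of a coassoc_network, for comparison with the oracle
network_keys <- function(net) {
  e <- net$edges
  sort(paste(pmin(e$node_a, e$node_b), pmax(e$node_a, e$node_b), sep = "|"))
}

# random correlation matrix from Gaussian data (so it is always a valid
# sample correlation matrix)
random_corr <- function(p, n = 15, seed = 1) {
  set.seed(seed)
  r <- cor(matrix(rnorm(n * p), n, p))
  dimnames(r) <- list(paste0("n", seq_len(p)), paste0("n", seq_len(p)))
  diag(r) <- 1
  r
}

# OLS R^2 by direct normal equations
r2_oracle <- function(X, y) {
  Z <- cbind(1, as.matrix(X))
  b <- solve(t(Z) %*% Z, t(Z) %*% y)
  1 - sum((y - Z %*% b)^2) / sum((y - mean(y))^2)
}

# exhaustive best-of-size-k subsets by direct enumeration with r2_oracle
subsets_oracle <- function(X, y) {
  p <- ncol(X)
  out <- vector("list", p)
  for (k in seq_len(p)) {
    sets <- combn(p, k)
    r2 <- apply(sets, 2, function(s) r2_oracle(X[, s, drop = FALSE], y))
    best <- which(r2 > max(r2) - 1e-12)[1]  # ties: first in combn order
    out[[k]] <- list(set = sets[, best], r2 = max(r2))
  }
  out
}

# hypergeometric upper tail P(X >= x) by exhaustive subset enumeration:
# draw n from N of which K are marked
hyper_oracle <- function(N, K, n, x) {
  marked <- seq_len(K)
  sets <- combn(N, n)
  mean(apply(sets, 2, function(s) sum(s %in% marked)) >= x)
}

# orthogonal Procrustes residual between two configurations (rows =
# points), after centering and optimal rotation/reflection
procrustes_error <- function(A, B) {
  A <- scale(A, scale = FALSE)
  B <- scale(B, scale = FALSE)
  s <- svd(t(B) %*% A)
  R <- s$v %*% t(s$u)
  sqrt(sum((A %*% R - B)^2))
}

# small random count fixture
make_counts <- function(n_feat, n_samp, seed = 1, lambda = 3) {
  set.seed(seed)
  m <- matrix(rpois(n_feat * n_samp, lambda), n_feat, n_samp,
              dimnames = list(paste0("ASV", seq_len(n_feat)),
                              paste0("S", seq_len(n_samp))))
  storage.mode(m) <- "integer"
  m
}
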