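test_that("chao1 matches hand-computed values and ignores zero counts", {
  expect_equal(chao1(c(5, 5, 5)), 3)                   # no singletons
  expect_equal(chao1(c(1, 1, 2, 5)), 4 + 2 * 1 / (2 * 2))  # = 4.5
  expect_equal(chao1(c(1, 1, 2, 5, 0, 0)), 4.5)        # zeros carry nothing
  expect_error(chao1(c(0, 0)), "all-zero")
  expect_error(chao1(c(1.5, 2)), "integers")
  # agrees with the vegan estimator on random samples
  for (s in 1:5) {
    x <- make_counts(40, 1, seed = s, lambda = 1.2)[, 1]
    if (all(x == 0)) next
    ref <- unname(vegan::estimateR(x)["S.chao1"])
    expect_equal(chao1(x), ref)
  }
})

test_that("Bray-Curtis matches its formula, bounds, and vegan", {
  m <- matrix(c(2L, 2L, 1L, 1L), 2, 2,
              dimnames = list(c("A", "B"), c("S1", "S2")))
  expect_equal(bray_curtis(m)["S1", "S2"], 1 / 3)
  ident <- cbind(S1 = c(3L, 1L), S2 = c(3L, 1L))
  rownames(ident) <- c("A", "B")
  expect_equal(bray_curtis(ident)["S1", "S2"], 0)
  disj <- cbind(S1 = c(1L, 0L), S2 = c(0L, 1L))
  rownames(disj) <- c("A", "B")
  expect_equal(bray_curtis(disj)["S1", "S2"], 1)

  cc <- make_counts(25, 8, seed = 4)
  d <- bray_curtis(cc)
  expect_equal(d, t(d), ignore_attr = TRUE)
  expect_true(all(d >= 0 & d <= 1))
  expect_true(all(diag(d) == 0))
  # appending all-zero features changes nothing
  cc0 <- rbind(cc, ZZ = rep(0L, 8))
  expect_equal(unname(bray_curtis(cc0)), unname(d))
  # vegan::vegdist as the independent reference
  ref <- as.matrix(vegan::vegdist(t(cc), method = "bray"))
  expect_equal(unname(d), unname(ref), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("PCoA recovers known geometry", {
  # 3 equidistant points: two equal positive eigenvalues, each 50%
  D <- matrix(1, 3, 3) - diag(3)
  dimnames(D) <- list(paste0("S", 1:3), paste0("S", 1:3))
  p <- pcoa(D)
  expect_equal(p$explained, c(0.5, 0.5))
  expect_equal(p$eigenvalues[1], p$eigenvalues[2])

  # Euclidean input: configuration recovered up to rotation/reflection
  set.seed(12)
  X <- matrix(rnorm(20), 10, 2)
  D2 <- as.matrix(dist(X))
  p2 <- pcoa(D2)
  expect_lt(procrustes_error(p2$coordinates[, 1:2], X), 1e-8)
  expect_equal(sum(p2$explained), 1)

  # duplicated sample gets its twin's coordinates
  cc <- make_counts(15, 5, seed = 6)
  cc <- cbind(cc, S5dup = cc[, 5])
  p3 <- pcoa(bray_curtis(cc))
  expect_equal(p3$coordinates["S5", ], p3$coordinates["S5dup", ],
               tolerance = 1e-8)

  expect_error(pcoa(D[1:2, 1:2]), "at least 3")
})

test_that("PERMANOVA pseudo-F matches vegan and the p-value honors +1", {
  set.seed(21)
  cc <- make_counts(30, 16, seed = 21)
  g <- rep(c("a", "b"), each = 8)
  d <- bray_curtis(cc)
  res <- permanova(d, g, n_permutations = 99, seed = 5)
  ref <- vegan::adonis2(as.dist(d) ~ g, permutations = 99)
  expect_equal(res$pseudo_F, ref$F[1], tolerance = 1e-10)
  expect_gt(res$p_value, 0)
  expect_equal((res$p_value * 100) %% 1, 0)  # exact (1+k)/(1+n_perm) grid

  # degenerate equality: identical samples everywhere -> F = 0, p = 1
  eq <- cbind(S1 = c(2L, 1L), S2 = c(2L, 1L), S3 = c(2L, 1L), S4 = c(2L, 1L))
  rownames(eq) <- c("A", "B")
  de <- bray_curtis(eq)
  r0 <- permanova(de, c("a", "a", "b", "b"), n_permutations = 19, seed = 1)
  expect_true(is.finite(r0$pseudo_F))
  expect_equal(r0$p_value, 1)
  expect_error(permanova(d, rep("a", 16)), "2 groups")
})

test_that("PERMANOVA detects a planted between-group shift", {
  rejections <- 0
  for (s in 1:20) {
    set.seed(s)
    n <- 40
    base <- matrix(rpois(30 * n, 5), 30, n)
    base[1:10, 21:40] <- base[1:10, 21:40] + matrix(rpois(10 * 20, 4), 10, 20)
    dimnames(base) <- list(paste0("F", 1:30), paste0("S", 1:n))
    storage.mode(base) <- "integer"
    g <- rep(c("lo", "hi"), each = 20)
    res <- permanova(bray_curtis(base), g, n_permutations = 99, seed = s)
    if (res$p_value <= 0.05) rejections <- rejections + 1
  }
  expect_gte(rejections, 16)
})

test_that("taxon aggregation sums counts within a rank", {
  d <- simulate_dataset(sim_config(n_samples = 12, n_asvs = 40, seed = 3,
                                   n_direct_asvs = 2, n_mediated_asvs = 2))
  fam <- aggregate_taxa(d$counts, d$taxonomy, "family")
  f1 <- rownames(fam)[1]
  members <- d$taxonomy$feature_id[!is.na(d$taxonomy$family) &
                                     d$taxonomy$family == f1]
  expect_equal(unname(fam[f1, ]),
               unname(colSums(d$counts[members, , drop = FALSE])))
  expect_error(aggregate_taxa(d$counts, d$taxonomy, "kingdom"), "unknown rank")
})
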