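test_that("the generator is bit-identical under a fixed seed", {
  cfg <- sim_config(n_samples = 20, n_asvs = 40, seed = 11,
                    n_direct_asvs = 3, n_mediated_asvs = 4)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a, b)
  c <- simulate_dataset(sim_config(n_samples = 20, n_asvs = 40, seed = 12,
                                   n_direct_asvs = 3, n_mediated_asvs = 4))
  expect_false(identical(a$counts, c$counts))
})

test_that("planted structure is internally consistent", {
  d <- simulate_dataset(sim_config(n_samples = 24, n_asvs = 60, seed = 2,
                                   n_direct_asvs = 4, n_mediated_asvs = 6))
  direct <- unlist(lapply(d$truth$direct, function(x) x$asv_id))
  med <- d$truth$mediated$asv_id
  # direct and mediated sets disjoint; all ids resolvable
  expect_length(intersect(direct, med), 0)
  expect_true(all(c(direct, med) %in% rownames(d$counts)))
  expect_true(all(d$truth$mediated$mediator_id %in% direct))
  # the enriched family exists and holds a plurality of direct ASVs
  fam <- d$truth$family[direct]
  expect_true(d$truth$enriched_family %in% fam)
  expect_gte(sum(fam == d$truth$enriched_family, na.rm = TRUE),
             length(direct) / 3)
  # per-phenotype direct sets are disjoint
  expect_equal(anyDuplicated(direct), 0)
})

test_that("realized sparsity and phenotype moments match the configuration", {
  zf <- vapply(1:3, function(s) {
    mean(simulate_dataset(sim_config(seed = s))$counts == 0)
  }, numeric(1))
  expect_true(all(abs(zf - 0.55) < 0.1))

  d <- simulate_dataset(sim_config(n_samples = 500, seed = 4))
  ph <- d$phenotypes
  expect_true(all(ph$CH4Y > 0) && all(ph$ACET_PROP > 0))
  expect_lt(abs(mean(ph$EFF) - 0.97) / 0.97, 0.1)
  expect_lt(abs(sd(ph$CH4Y) - 4.11) / 4.11, 0.1)
  expect_lt(abs(mean(ph$ACET_PROP) - 4.92) / 4.92, 0.1)
  # CH4Y and ACET_PROP are positively inter-correlated by construction
  expect_gt(cor(ph$CH4Y, ph$ACET_PROP), 0.2)
})

test_that("realized direct-effect correlations on the CSS-log2 scale hit the target", {
  rs <- c()
  for (s in 1:6) {
    d <- simulate_dataset(sim_config(n_samples = 500, seed = s))
    ab <- css_normalize(d$counts)
    for (ph in c("EFF", "CH4Y", "ACET_PROP")) {
      ids <- d$truth$direct[[ph]]$asv_id
      rs <- c(rs, abs(cor(t(ab[ids, , drop = FALSE]), d$phenotypes[[ph]])))
    }
  }
  expect_lt(abs(mean(rs) - 0.3), 0.08)
  # signs of realized correlations agree with the planted signs
  d <- simulate_dataset(sim_config(n_samples = 500, seed = 1))
  ab <- css_normalize(d$counts)
  tr <- d$truth$direct$EFF
  realized <- as.numeric(cor(t(ab[tr$asv_id, , drop = FALSE]), d$phenotypes$EFF))
  expect_true(all(sign(realized) == tr$sign))
})

test_that("a no-effect configuration behaves like the null", {
  cutoff <- {
    # Bonferroni-style two-sided cutoff for n_asvs tests at n = 56
    t <- qt(1 - 0.025 / 350, df = 54)
    sqrt(t^2 / (t^2 + 54))
  }
  max_r <- vapply(1:20, function(s) {
    d <- simulate_dataset(sim_config(seed = s, n_direct_asvs = 0,
                                     n_mediated_asvs = 0))
    ab <- css_normalize(d$counts)
    keep <- apply(ab, 1, sd) > 0
    max(abs(cor(t(ab[keep, ]),
                as.matrix(d$phenotypes[c("EFF", "CH4Y", "ACET_PROP")]))))
  }, numeric(1))
  expect_lt(quantile(max_r, 0.95), cutoff)
})

test_that("infeasible configurations are rejected with named violations", {
  expect_error(sim_config(sparsity_target = 1), "sparsity_target")
  expect_error(sim_config(effect_size_r = 1.2), "effect_size_r")
  expect_error(sim_config(n_asvs = 20, n_direct_asvs = 6, n_mediated_asvs = 5),
               "exceed")
})

test_that("degenerate fixtures have their defining properties", {
  tiny <- degenerate_fixture("tiny_counts")
  expect_true(is.integer(tiny) && all(tiny >= 0))
  expect_lte(nrow(tiny), 10)

  cp <- degenerate_fixture("collinear_pair")
  expect_identical(cp[1, ], cp[2, ])

  mt <- degenerate_fixture("mediated_trio")
  r <- cor(t(mt))
  p_xy_z <- (r["X", "Y"] - r["X", "Z"] * r["Y", "Z"]) /
    sqrt((1 - r["X", "Z"]^2) * (1 - r["Y", "Z"]^2))
  expect_gt(r["X", "Y"], 0.25)       # clear marginal association
  expect_lt(abs(p_xy_z), 0.1)        # vanishing partial given the mediator

  expect_error(degenerate_fixture("nope"), "unknown")
})
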