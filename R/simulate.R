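#' Simulation configuration for synthetic ASV datasets
#'
#' Defines the generative conditions for a synthetic rumen/faecal amplicon
#' study: sample and feature counts, log-normal sequencing depth, a
#' Dirichlet base composition tempered to hit a target zero fraction, and
#' planted microbe-phenotype structure. Effects are injected on the latent
#' log-abundance scale before count sampling so that the association
#' survives CSS-log2 transformation; `effect_size_r` is the target
#' magnitude of the realized Pearson correlation between a direct ASV's
#' CSS-log2 abundance and its phenotype. Mediated ASVs are noisy copies of
#' a direct ASV's latent deviation with no independent phenotype term, so
#' their phenotype correlation is entirely indirect — the structure a
#' partial-correlation network filter should remove.
#'
#' @param n_samples number of animals (default 56).
#' @param n_asvs number of ASVs after prevalence filtering (default 350).
#' @param n_families number of taxonomic families (default 25), assigned
#'   with Zipf-like skew.
#' @param library_size_log_mean,library_size_log_sd log-normal sequencing
#'   depth parameters.
#' @param dirichlet_concentration symmetric Dirichlet parameter of the
#'   base composition.
#' @param sparsity_target desired fraction of zero cells (default 0.55).
#' @param n_direct_asvs direct-effect ASVs per phenotype (default 8).
#' @param effect_size_r target |Pearson r| between each direct ASV
#'   (CSS-log2 scale) and its phenotype (default 0.3).
#' @param phenotype_noise_sd phenotype noise relative to its unit-variance
#'   latent driver (default 0.4).
#' @param n_mediated_asvs total ASVs correlated with phenotypes only
#'   through a direct ASV (default 10).
#' @param mediated_cor latent correlation between a mediated ASV and its
#'   mediator (default 0.7).
#' @param phenotype_correlation target CH4Y-ACET_PROP latent correlation
#'   (default +0.5).
#' @param seed integer random seed; recorded in every output.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_samples = 56, n_asvs = 350, n_families = 25,
                       library_size_log_mean = log(20000),
                       library_size_log_sd = 0.35,
                       dirichlet_concentration = 0.3,
                       sparsity_target = 0.55,
                       n_direct_asvs = 8, effect_size_r = 0.3,
                       phenotype_noise_sd = 0.4,
                       n_mediated_asvs = 10, mediated_cor = 0.7,
                       phenotype_correlation = 0.5, seed = 1) {
  cfg <- list(n_samples = n_samples, n_asvs = n_asvs, n_families = n_families,
              library_size_log_mean = library_size_log_mean,
              library_size_log_sd = library_size_log_sd,
              dirichlet_concentration = dirichlet_concentration,
              sparsity_target = sparsity_target,
              n_direct_asvs = n_direct_asvs, effect_size_r = effect_size_r,
              phenotype_noise_sd = phenotype_noise_sd,
              n_mediated_asvs = n_mediated_asvs, mediated_cor = mediated_cor,
              phenotype_correlation = phenotype_correlation,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_samples < 8) fail("n_samples must be at least 8")
  if (cfg$n_asvs < 10) fail("n_asvs must be at least 10")
  if (cfg$sparsity_target < 0 || cfg$sparsity_target >= 1) {
    fail("sparsity_target must be in [0, 1)")
  }
  if (cfg$effect_size_r < 0 || cfg$effect_size_r >= 1) {
    fail("effect_size_r must be in [0, 1)")
  }
  if (3 * cfg$n_direct_asvs + cfg$n_mediated_asvs > cfg$n_asvs) {
    fail("n_direct_asvs and n_mediated_asvs exceed n_asvs")
  }
  if (abs(cfg$phenotype_correlation) >= 1) {
    fail("phenotype_correlation must be in (-1, 1)")
  }
  if (cfg$dirichlet_concentration <= 0) fail("dirichlet_concentration must be > 0")
  invisible(cfg)
}

# phenotype summary targets the generator rescales to (beef-heifer-like:
# efficiency ratio, g methane / kg DMI, molar acetate:propionate)
.pheno_targets <- data.frame(
  phenotype = c("EFF", "CH4Y", "ACET_PROP"),
  mean = c(0.97, 24.95, 4.92),
  sd = c(0.22, 4.11, 0.42),
  stringsAsFactors = FALSE
)

# latent log-abundance SD of idiosyncratic (per cell) biological noise
.sigma_w <- 0.7
# fraction of |r| lost between the latent log scale and the realized
# CSS-log2 count scale (counting noise + zeros); calibration constant of
# the generator, chosen once for the default depth/sparsity regime
.count_attenuation <- 0.78

#' Generate a synthetic ASV dataset with planted effects
#'
#' Draws a Dirichlet base composition (tempered so the expected zero
#' fraction matches `sparsity_target`), log-normal library sizes, and
#' multinomial counts around per-sample latent log abundances. Three
#' inter-correlated phenotypes (EFF, CH4Y, ACET_PROP) are driven by latent
#' standard-normal signals; each phenotype's direct ASVs load on its
#' signal with a sign and a loading calibrated so the realized CSS-log2
#' abundance-phenotype correlation is close to `effect_size_r`. Mediated
#' ASVs copy a direct ASV's latent deviation with noise. One mid-sized
#' family is intentionally over-represented among direct ASVs so that
#' enrichment recovery can be tested. A balanced two-level sampling-week
#' label with no planted effect is included for PERMANOVA checks.
#'
#' @param config a [sim_config()].
#' @return list with elements `counts` (integer matrix, ASV x sample),
#'   `taxonomy` (data.frame as from [read_taxonomy()]), `phenotypes`
#'   (data.frame with `sample_id`, `EFF`, `CH4Y`, `ACET_PROP`, `week`),
#'   and `truth` (planted ground truth: per-phenotype direct ASVs with
#'   signs, mediated ASVs with their mediator, family map, the enriched
#'   family, and the seed).
#' @export
simulate_dataset <- function(config = sim_config()) {
  validate_sim_config(config)
  set.seed(config$seed)
  ns <- config$n_samples
  np <- config$n_asvs
  asv_ids <- sprintf("ASV%04d", seq_len(np))
  sample_ids <- sprintf("S%03d", seq_len(ns))
  phenos <- .pheno_targets$phenotype

  ## taxonomy: Zipf-skewed family assignment
  fam_names <- sprintf("Family%02d", seq_len(config$n_families))
  fam_prob <- seq_len(config$n_families)^-1.2
  family <- sample(fam_names, np, replace = TRUE, prob = fam_prob / sum(fam_prob))

  ## base composition, tempered to the sparsity target
  g <- rgamma(np, shape = config$dirichlet_concentration, rate = 1)
  g[g < 1e-300] <- 1e-300
  p0 <- g / sum(g)
  lib <- pmax(100L, as.integer(round(rlnorm(ns, config$library_size_log_mean,
                                            config$library_size_log_sd))))
  p_base <- temper_to_sparsity(p0, lib, config$sparsity_target)

  ## latent phenotype drivers (CH4Y and ACET_PROP share structure)
  z <- matrix(rnorm(ns * 3), ns, 3, dimnames = list(sample_ids, phenos))
  rho <- config$phenotype_correlation
  z[, "ACET_PROP"] <- rho * z[, "CH4Y"] + sqrt(1 - rho^2) * z[, "ACET_PROP"]

  ## direct ASVs: drawn from the abundant half so the planted signal is
  ## observable through counting noise; one mid-sized family over-represented
  abundant <- asv_ids[rank(-p_base, ties.method = "first") <= ceiling(np / 2)]
  fam_sizes <- table(family)
  enriched_family <- names(fam_sizes)[which.min(abs(fam_sizes - 15))]
  enr_pool <- intersect(abundant, asv_ids[family == enriched_family])
  direct <- list()
  taken <- character(0)
  for (ph in phenos) {
    n_enr <- min(length(setdiff(enr_pool, taken)), ceiling(config$n_direct_asvs / 2))
    pick_enr <- sample(setdiff(enr_pool, taken), n_enr)
    pool <- setdiff(abundant, c(taken, pick_enr))
    pick_rest <- sample(pool, config$n_direct_asvs - n_enr)
    ids <- sample(c(pick_enr, pick_rest))  # shuffle order
    taken <- c(taken, ids)
    direct[[ph]] <- data.frame(asv_id = ids,
                               sign = sample(c(-1, 1), length(ids), replace = TRUE),
                               stringsAsFactors = FALSE)
  }

  ## loading calibrated so the realized CSS-log2 correlation ~ effect_size_r
  rho_p <- 1 / sqrt(1 + config$phenotype_noise_sd^2)
  lat_r <- min(0.99, config$effect_size_r / (rho_p * .count_attenuation))
  gamma <- .sigma_w * lat_r / sqrt(1 - lat_r^2)

  ## latent log-abundance deviations
  u <- matrix(rnorm(np * ns, sd = .sigma_w), np, ns,
              dimnames = list(asv_ids, sample_ids))
  for (ph in phenos) {
    d <- direct[[ph]]
    u[d$asv_id, ] <- u[d$asv_id, ] + gamma * (d$sign %o% z[, ph])
  }

  ## mediated ASVs: noisy copies of a direct ASV's total latent deviation
  mediated <- data.frame(asv_id = character(0), mediator_id = character(0),
                         phenotype = character(0), stringsAsFactors = FALSE)
  if (config$n_mediated_asvs > 0) {
    med_ids <- sample(setdiff(asv_ids, taken), config$n_mediated_asvs)
    med_ph <- sample(phenos, config$n_mediated_asvs, replace = TRUE)
    kap <- config$mediated_cor
    sigma_m <- sqrt(gamma^2 + .sigma_w^2)
    mediators <- character(config$n_mediated_asvs)
    for (i in seq_len(config$n_mediated_asvs)) {
      m <- sample(direct[[med_ph[i]]]$asv_id, 1)
      mediators[i] <- m
      u[med_ids[i], ] <- kap * (.sigma_w / sigma_m) * u[m, ] +
        sqrt(1 - kap^2) * rnorm(ns, sd = .sigma_w)
    }
    mediated <- data.frame(asv_id = med_ids, mediator_id = mediators,
                           phenotype = med_ph, stringsAsFactors = FALSE)
  }

  ## counts: per-sample multinomial around exp(latent log abundance)
  eta <- log(p_base) + u
  counts <- matrix(0L, np, ns, dimnames = list(asv_ids, sample_ids))
  for (j in seq_len(ns)) {
    pj <- exp(eta[, j] - max(eta[, j]))
    counts[, j] <- as.integer(rmultinom(1, size = lib[j], prob = pj / sum(pj)))
  }

  ## phenotypes: latent driver + noise, rescaled to the summary targets
  pheno_df <- data.frame(sample_id = sample_ids, stringsAsFactors = FALSE)
  for (ph in phenos) {
    raw <- rho_p * z[, ph] +
      sqrt(1 - rho_p^2) * rnorm(ns)
    tgt <- .pheno_targets[.pheno_targets$phenotype == ph, ]
    pheno_df[[ph]] <- tgt$mean + tgt$sd * as.numeric(scale(raw))
  }
  pheno_df$week <- sample(rep(c(1L, 2L), length.out = ns))

  ## taxonomy strings; ~5% of non-planted ASVs get an unclassified family
  planted <- c(taken, mediated$asv_id)
  maskable <- setdiff(asv_ids, planted)
  masked <- sample(maskable, round(0.05 * length(maskable)))
  fam_out <- family
  names(fam_out) <- asv_ids
  fam_disk <- ifelse(asv_ids %in% masked, "", fam_out)
  genus <- sprintf("Genus%03d", sample.int(80, np, replace = TRUE))
  phylum <- sprintf("Phylum%02d", (match(fam_out, fam_names) %% 5) + 1)
  lineage <- sprintf("d__Bacteria; p__%s; c__Class%02d; o__Order%02d; f__%s; g__%s",
                     phylum, (match(fam_out, fam_names) %% 8) + 1,
                     (match(fam_out, fam_names) %% 12) + 1, fam_disk, genus)
  taxonomy <- cbind(data.frame(feature_id = asv_ids, lineage = lineage,
                               stringsAsFactors = FALSE),
                    parse_lineage(lineage))

  fam_truth <- fam_out
  fam_truth[asv_ids %in% masked] <- NA_character_
  truth <- list(direct = direct, mediated = mediated,
                family = fam_truth, enriched_family = enriched_family,
                effect_size_r = config$effect_size_r, seed = config$seed)

  list(counts = count_matrix(counts), taxonomy = taxonomy,
       phenotypes = pheno_df, truth = truth)
}

# choose a tempering exponent t for the base composition p ~ p0^t such
# that the expected zero fraction (Poisson approximation, exp(-p*N))
# matches the target
temper_to_sparsity <- function(p0, lib, target) {
  expected_zeros <- function(t) {
    lp <- t * log(p0)
    p <- exp(lp - max(lp))
    p <- p / sum(p)
    mean(vapply(lib, function(N) mean(exp(-p * N)), numeric(1)))
  }
  lo <- 0.05; hi <- 6
  if (expected_zeros(lo) >= target) return(normalize_temper(p0, lo))
  if (expected_zeros(hi) <= target) return(normalize_temper(p0, hi))
  t <- stats::uniroot(function(t) expected_zeros(t) - target,
                      c(lo, hi), tol = 1e-4)$root
  normalize_temper(p0, t)
}

normalize_temper <- function(p0, t) {
  lp <- t * log(p0)
  p <- exp(lp - max(lp))
  p / sum(p)
}

#' Small deterministic fixtures for unit tests
#'
#' * `tiny_counts`: 5 ASVs x 6 samples of small integers.
#' * `collinear_pair`: 4 ASVs x 8 samples where two features have
#'   identical counts (correlation exactly 1).
#' * `mediated_trio`: 3 features x 12 samples where features X and Y are
#'   both driven by Z, so they carry a clear marginal correlation
#'   (~0.3, within the moderate regime the PCIT tolerance can resolve)
#'   while their partial correlation given Z is near zero.
#'
#' @param name one of `"tiny_counts"`, `"collinear_pair"`,
#'   `"mediated_trio"`.
#' @return a count matrix.
#' @export
degenerate_fixture <- function(name) {
  switch(name,
    tiny_counts = count_matrix(matrix(
      c(1L, 0L, 2L, 5L, 0L, 1L,
        0L, 3L, 1L, 0L, 2L, 0L,
        4L, 4L, 4L, 4L, 4L, 4L,
        0L, 0L, 1L, 0L, 0L, 2L,
        7L, 1L, 0L, 3L, 5L, 0L),
      nrow = 5, byrow = TRUE,
      dimnames = list(paste0("ASV", 1:5), paste0("S", 1:6)))),
    collinear_pair = count_matrix(matrix(
      c(2L, 5L, 1L, 8L, 3L, 0L, 6L, 4L,
        2L, 5L, 1L, 8L, 3L, 0L, 6L, 4L,
        9L, 0L, 4L, 2L, 7L, 5L, 1L, 3L,
        1L, 1L, 0L, 5L, 2L, 6L, 3L, 2L),
      nrow = 4, byrow = TRUE,
      dimnames = list(paste0("ASV", 1:4), paste0("S", 1:8)))),
    mediated_trio = count_matrix(matrix(
      c(18L, 19L, 25L, 6L, 17L, 16L, 3L, 28L, 11L, 13L, 24L, 35L,
        18L, 12L, 29L, 15L, 20L, 27L, 12L, 26L, 27L, 23L, 17L, 19L,
        6L, 2L, 8L, 2L, 10L, 18L, 4L, 12L, 10L, 6L, 10L, 16L),
      nrow = 3, byrow = TRUE,
      dimnames = list(c("X", "Y", "Z"), paste0("S", 1:12)))),
    fail("unknown fixture name: %s", name)
  )
}
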