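#' Configuration for a full pipeline run
#'
#' Bundles every tunable of the simulate -> preprocess -> diversity ->
#' network -> enrichment -> selection -> evaluation pipeline. Each
#' stochastic stage draws its seed deterministically from the master seed
#' and the stage name, so adding a stage never perturbs another stage's
#' randomness.
#'
#' @param sim a [sim_config()] used when `simulate = TRUE`.
#' @param simulate generate inputs (default) or read them from
#'   `counts_path`/`taxonomy_path`/`phenotypes_path`.
#' @param counts_path,taxonomy_path,phenotypes_path input files when
#'   `simulate = FALSE`.
#' @param min_samples prevalence filter (default 20 samples).
#' @param quantile_mode CSS quantile mode (default `"fixed:0.5"`).
#' @param core_threshold core-microbiome presence fraction (default 0.5).
#' @param phenotypes phenotype column names.
#' @param selection_threshold retention rule threshold (default 0.95).
#' @param baseline_draws random-baseline draws (default 10).
#' @param cv_folds cross-validation folds (default 5).
#' @param permutations PERMANOVA permutations (default 999).
#' @param p_exhaustive_max largest predictor count for the full-search
#'   subset engines (default 20; larger panels fall back to forward
#'   search).
#' @param seed master seed.
#' @return object of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), simulate = TRUE,
                       counts_path = NULL, taxonomy_path = NULL,
                       phenotypes_path = NULL,
                       min_samples = 20, quantile_mode = "fixed:0.5",
                       core_threshold = 0.5,
                       phenotypes = c("EFF", "CH4Y", "ACET_PROP"),
                       selection_threshold = 0.95, baseline_draws = 10,
                       cv_folds = 5, permutations = 999,
                       p_exhaustive_max = 20, seed = 1) {
  cfg <- list(sim = sim, simulate = simulate, counts_path = counts_path,
              taxonomy_path = taxonomy_path, phenotypes_path = phenotypes_path,
              min_samples = min_samples, quantile_mode = quantile_mode,
              core_threshold = core_threshold, phenotypes = phenotypes,
              selection_threshold = selection_threshold,
              baseline_draws = baseline_draws, cv_folds = cv_folds,
              permutations = permutations,
              p_exhaustive_max = p_exhaustive_max, seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

#' Validate a run configuration
#'
#' Collects every violation rather than stopping at the first; a valid
#' configuration returns an empty character vector.
#'
#' @param config a [run_config()].
#' @return character vector of violations (empty when valid).
#' @export
validate_config <- function(config) {
  v <- character(0)
  add <- function(msg) v <<- c(v, msg)
  if (config$min_samples < 1) add("min_samples must be >= 1")
  if (isTRUE(config$simulate)) {
    ok <- tryCatch({ validate_sim_config(config$sim); TRUE },
                   error = function(e) { add(conditionMessage(e)); FALSE })
    if (ok && config$min_samples > config$sim$n_samples) {
      add("min_samples exceeds simulated n_samples")
    }
  } else {
    for (p in c("counts_path", "taxonomy_path", "phenotypes_path")) {
      if (is.null(config[[p]])) add(sprintf("%s required when simulate = FALSE", p))
    }
  }
  if (config$selection_threshold <= 0 || config$selection_threshold > 1) {
    add("selection_threshold must be in (0, 1]")
  }
  if (config$baseline_draws < 1) add("baseline_draws must be >= 1")
  if (config$cv_folds < 2) add("cv_folds must be >= 2")
  if (config$permutations < 1) add("permutations must be >= 1")
  if (!startsWith(config$quantile_mode, "fixed:") &&
      config$quantile_mode != "adaptive") {
    add("quantile_mode must be 'fixed:<l>' or 'adaptive'")
  }
  v
}

#' Run the full co-association analysis pipeline
#'
#' Executes simulate (or load) -> prevalence filter -> CSS-log2 ->
#' diversity (Chao1, Bray-Curtis, PCoA, sampling-week PERMANOVA) -> PCIT
#' network -> phenotype edges -> family enrichment -> best-subsets
#' selection -> random baseline + cross-validation -> summary. Every
#' artifact is written as a deterministic text table under `out_dir`,
#' along with `manifest.json` (inputs, derived seeds, parameter values,
#' stage feature counts) and a human-readable `report.md`. A rerun with
#' the same configuration reproduces every file byte for byte.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the in-memory results: `data`,
#'   `filtered`, `abundance`, `diversity`, `network`, `edges`,
#'   `enrichment`, `selection`, `evaluation`, `summary`, `manifest`.
#' @export
run_all <- function(config, out_dir) {
  violations <- validate_config(config)
  if (length(violations)) {
    fail("invalid configuration:\n- %s", paste(violations, collapse = "\n- "))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- vapply(c("simulate", "network", "baseline", "cv", "permanova"),
                  function(s) derive_seed(config$seed, s), integer(1))

  ## stage 1: inputs
  if (isTRUE(config$simulate)) {
    sim <- config$sim
    sim$seed <- seeds[["simulate"]]
    data <- simulate_dataset(sim)
    jsonlite::write_json(truth_as_json(data$truth),
                         file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    data <- list(counts = read_count_table(config$counts_path),
                 taxonomy = read_taxonomy(config$taxonomy_path),
                 phenotypes = read_phenotypes(config$phenotypes_path),
                 truth = NULL)
  }
  write_count_table(data$counts, file.path(out_dir, "counts.tsv"))
  write_taxonomy(data$taxonomy, file.path(out_dir, "taxonomy.tsv"))
  write_phenotypes(data$phenotypes, file.path(out_dir, "phenotypes.tsv"))

  ## stage 2: preprocess
  filtered <- prevalence_filter(data$counts, config$min_samples)
  abundance <- css_normalize(filtered, config$quantile_mode)
  write.table(data.frame(feature_id = rownames(abundance),
                         round(abundance, 6), check.names = FALSE),
              file.path(out_dir, "abundance_css_log2.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  ## stage 3: diversity and the sampling-week check
  alpha <- apply(filtered, 2, chao1)
  bc <- bray_curtis(filtered)
  ord <- pcoa(bc)
  week <- data$phenotypes$week
  perm <- if (!is.null(week)) {
    permanova(bc, week, n_permutations = config$permutations,
              seed = seeds[["permanova"]])
  } else NULL
  write.table(data.frame(sample_id = names(alpha), chao1 = round(alpha, 6)),
              file.path(out_dir, "alpha_chao1.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample_id = rownames(ord$coordinates),
                         round(ord$coordinates[, seq_len(min(3, ncol(ord$coordinates))),
                                               drop = FALSE], 6)),
              file.path(out_dir, "pcoa_coordinates.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  ## stage 4: PCIT network and phenotype edges
  corr <- correlation_matrix(abundance, data$phenotypes,
                             phenotype_names = config$phenotypes)
  network <- pcit(corr)
  edges <- phenotype_edges(network, config$phenotypes)
  write_edge_list(network, file.path(out_dir, "network_edges.tsv"))
  pheno_edges_df <- do.call(rbind, lapply(names(edges), function(ph) {
    if (nrow(edges[[ph]]) == 0) return(NULL)
    data.frame(node_a = ph, node_b = edges[[ph]]$asv_id,
               correlation = edges[[ph]]$correlation,
               edge_type = "asv-phenotype", stringsAsFactors = FALSE)
  }))
  if (!is.null(pheno_edges_df)) {
    write_edge_list(pheno_edges_df, file.path(out_dir, "phenotype_edges.tsv"))
  }

  ## stage 5: enrichment against the network ASV background
  background <- setdiff(network$node_ids, config$phenotypes)
  enrichment <- lapply(edges, function(e) {
    if (nrow(e) == 0) return(NULL)
    family_enrichment(e$asv_id, background, data$taxonomy)
  })

  ## stages 6-7: subset selection and evaluation per phenotype
  selection <- list()
  evaluation <- list()
  rows <- NULL
  for (ph in config$phenotypes) {
    e <- edges[[ph]]
    if (is.null(e) || nrow(e) == 0) next
    y <- data$phenotypes[[ph]][match(colnames(abundance),
                                     data$phenotypes$sample_id)]
    Xfull <- t(abundance[e$asv_id, , drop = FALSE])
    r2_full <- suppressWarnings(ols_r2(Xfull, y))
    path <- best_subsets(Xfull, y, mode = "auto",
                         p_exhaustive_max = config$p_exhaustive_max)
    sel <- minimal_subset(path, config$selection_threshold)
    base <- random_baseline(rownames(abundance), abundance, y,
                            m = nrow(e), n_draws = config$baseline_draws,
                            seed = derive_seed(seeds[["baseline"]], ph))
    cv <- kfold_cv(t(abundance[sel$subset, , drop = FALSE]), y,
                   k = config$cv_folds,
                   seed = derive_seed(seeds[["cv"]], ph))
    selection[[ph]] <- sel
    evaluation[[ph]] <- list(baseline = base, cv = cv, path = path)
    rows <- rbind(rows, data.frame(
      dataset = "synthetic", trait = ph, n_full = nrow(e),
      r2_full = r2_full, r2_random_mean = base$mean_r2,
      n_selected = sel$minimal_k, r2_selected = sel$r2_selected,
      cv_r2_mean = cv$mean_cv_r2, stringsAsFactors = FALSE))
  }
  summary <- if (!is.null(rows)) summarize_performance(rows) else NULL
  if (!is.null(summary)) {
    out_tab <- summary$table
    num <- vapply(out_tab, is.numeric, logical(1))
    out_tab[num] <- lapply(out_tab[num], function(x) round(x, 6))
    write.table(out_tab, file.path(out_dir, "summary.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("pcitnet")),
    master_seed = config$seed,
    stage_seeds = as.list(seeds),
    parameters = config[c("min_samples", "quantile_mode", "core_threshold",
                          "selection_threshold", "baseline_draws", "cv_folds",
                          "permutations", "p_exhaustive_max")],
    simulated = isTRUE(config$simulate),
    sim = if (isTRUE(config$simulate)) unclass(config$sim) else NULL,
    counts = list(n_features_raw = nrow(data$counts),
                  n_features_filtered = nrow(filtered),
                  n_samples = ncol(data$counts)),
    network = list(n_nodes = length(network$node_ids),
                   n_edges = nrow(network$edges),
                   n_phenotype_edges = vapply(edges, nrow, integer(1)),
                   n_skipped_trios = network$n_skipped_trios),
    permanova = if (!is.null(perm)) perm[c("pseudo_F", "p_value",
                                           "n_permutations", "seed")] else NULL
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  write_report(file.path(out_dir, "report.md"), manifest, summary, enrichment, perm)

  invisible(list(data = data, filtered = filtered, abundance = abundance,
                 diversity = list(alpha = alpha, bray_curtis = bc, pcoa = ord,
                                  permanova = perm),
                 network = network, edges = edges, enrichment = enrichment,
                 selection = selection, evaluation = evaluation,
                 summary = summary, manifest = manifest))
}

truth_as_json <- function(truth) {
  list(direct = truth$direct,
       mediated = truth$mediated,
       family = as.list(truth$family),
       enriched_family = truth$enriched_family,
       effect_size_r = truth$effect_size_r,
       seed = truth$seed)
}

write_report <- function(path, manifest, summary, enrichment, perm) {
  lines <- c("# Co-association pipeline report", "",
             sprintf("- master seed: %d", manifest$master_seed),
             sprintf("- features: %d raw, %d after prevalence filter",
                     manifest$counts$n_features_raw,
                     manifest$counts$n_features_filtered),
             sprintf("- network: %d nodes, %d retained edges",
                     manifest$network$n_nodes, manifest$network$n_edges))
  if (!is.null(perm)) {
    lines <- c(lines, sprintf(
      "- sampling-week PERMANOVA: pseudo-F = %.4f, p = %.4f (%d permutations)",
      perm$pseudo_F, perm$p_value, perm$n_permutations))
  }
  lines <- c(lines, "", "## Phenotype edge counts", "")
  for (ph in names(manifest$network$n_phenotype_edges)) {
    lines <- c(lines, sprintf("- %s: %d ASVs", ph,
                              manifest$network$n_phenotype_edges[[ph]]))
  }
  if (!is.null(summary)) {
    lines <- c(lines, "", "## Performance summary", "",
               paste(capture_table(summary$table), collapse = "\n"))
  }
  for (ph in names(enrichment)) {
    e <- enrichment[[ph]]
    if (is.null(e) || nrow(e) == 0) next
    top <- e[1, ]
    lines <- c(lines, "", sprintf("- top enriched family for %s: %s (score %.2f)",
                                  ph, top$family, top$score))
  }
  writeLines(lines, path)
}

capture_table <- function(df) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) round(x, 3))
  utils::capture.output(print(df, row.names = FALSE))
}
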