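# pcitnet

Microbial co-association networks and minimal predictor selection for
livestock phenotypes.

## What problem this solves

Rumen and faecal microbial communities carry signal about hard-to-measure
production traits — feed efficiency (EFF, output per kg dry-matter
intake), methane yield (CH4Y, g CH4 per kg dry-matter intake) and the
rumen acetate:propionate ratio (ACET_PROP). Raw correlation screens over
hundreds of amplicon sequence variants (ASVs) are dominated by indirect
associations: two taxa that track a third, or a taxon that tracks a
phenotype only through another taxon. `pcitnet` is for microbiome
researchers who want to go from an ASV count table plus per-animal
phenotypes to a small, defensible panel of candidate predictor taxa,
with every step reproducible and testable against planted ground truth.

## The method

1. **Normalize**: cumulative sum scaling per sample (counts divided by
   the cumulative sum up to a chosen quantile of the positive counts,
   scaled by C = 1000) followed by log2(x + 1); a centred log-ratio
   transform and Escoufier's RV coefficient are provided to check that
   both transforms induce the same sample geometry.
2. **Network**: Pearson correlations over all nodes (ASVs + phenotypes),
   filtered by the Partial Correlation and Information Theory (PCIT)
   algorithm. For every trio (x, y, z) the three first-order partial
   correlations, e.g.

   r_xy.z = (r_xy − r_xz r_yz) / sqrt((1 − r_xz²)(1 − r_yz²)),

   define a tolerance ε = mean of the partial-to-direct ratios; the edge
   x–y is discarded when |r_xy| < |ε r_xz| and |r_xy| < |ε r_yz| in some
   trio, i.e. when a third variable explains it. ASVs keeping a direct
   edge to a phenotype are its candidate predictors.
3. **Enrichment**: hypergeometric upper-tail test (score = −log10 p) for
   taxonomic families over-represented among phenotype-connected ASVs.
4. **Selection**: all-subsets regression (branch-and-bound, exact) finds
   the best R² panel of every size; the minimal panel retaining ~95 % of
   the full-model R² is reported.
5. **Evaluation**: size-matched random-ASV baselines (10 draws) and a
   seeded 5-fold cross-validation where CV-R² is the squared Pearson
   correlation between observed and out-of-fold predicted phenotypes.

A seeded synthetic generator (`simulate_dataset()`) plants known direct
and mediated ASV–phenotype effects in realistic sparse count tables so
that recovery, enrichment and baseline comparisons can be tested end to
end.

## Worked example

```r
library(pcitnet)

d      <- simulate_dataset(sim_config(seed = 1))        # 56 animals x 350 ASVs
counts <- prevalence_filter(d$counts, min_samples = 20) # 160 ASVs remain
ab     <- css_normalize(counts)
net    <- pcit(correlation_matrix(ab, d$phenotypes))
net
#> PCIT co-association network: 163 nodes, 1030 retained edges (3 phenotype nodes)
#> skipped degenerate trios: 0

edges <- phenotype_edges(net)
sapply(edges, nrow)
#>       EFF      CH4Y ACET_PROP
#>        13        12        16

y    <- d$phenotypes$CH4Y
path <- best_subsets(t(ab[edges$CH4Y$asv_id, ]), y, mode = "auto")
sel  <- minimal_subset(path, threshold = 0.95)
sel[c("minimal_k", "r2_selected", "r2_full", "retention", "reduction")]
#> $minimal_k   [1] 6
#> $r2_selected [1] 0.650
#> $r2_full     [1] 0.676
#> $retention   [1] 0.962
#> $reduction   [1] 0.5

random_baseline(rownames(ab), ab, y, m = nrow(edges$CH4Y), seed = 1)$mean_r2
#> [1] 0.258

kfold_cv(t(ab[sel$subset, ]), y, k = 5, seed = 1)$mean_cv_r2
#> [1] 0.494
```

Reading: of the 12 ASVs the network connects directly to methane yield,
6 suffice to keep 96 % of the full panel's R² (0.65 vs 0.68), more than
double the mean R² of 12 randomly drawn ASVs (0.26), and the selected
panel predicts held-out animals with mean CV-R² 0.49. The planted truth
in `d$truth` lets you check which of those ASVs carry real effects.

The whole pipeline, including diversity summaries, a sampling-week
PERMANOVA, enrichment and a manifest for byte-identical reruns, is one
call:

```r
res <- run_all(run_config(seed = 1), "run1")
res$summary$table
```

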