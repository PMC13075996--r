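---
title: "Co-association networks and minimal microbial predictor panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-association networks and minimal microbial predictor panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`pcitnet` implements a network-guided feature-selection pipeline for
microbiome–phenotype studies: amplicon sequence variant (ASV) counts from
rumen or faecal samples are normalized, joined with continuous animal
phenotypes — feed efficiency (EFF, output per kg dry-matter intake),
methane yield (CH4Y, g CH4 per kg dry-matter intake) and the molar
acetate:propionate ratio (ACET_PROP) — into a partial-correlation
co-association network, and the ASVs directly connected to each phenotype
are distilled into a minimal predictor panel by all-subsets regression.
This vignette records the model, the tunable parameters, the numerical
conventions, and the design decisions behind each stage, together with
what the synthetic data generator does and does not emulate.

```{r setup}
library(pcitnet)
```

## The PCIT network model

The network stage treats every ASV (on the CSS-log2 abundance scale) and
every phenotype as a node and computes the full Pearson correlation
matrix over complete-case samples. The partial correlation and
information theory (PCIT) filter then scans every unordered trio of
nodes $(x, y, z)$. For each trio it computes the three first-order
partial correlations, e.g.

$$r_{xy \cdot z} = \frac{r_{xy} - r_{xz} r_{yz}}
  {\sqrt{(1 - r_{xz}^2)(1 - r_{yz}^2)}},$$

and the data-driven tolerance
$\varepsilon = \tfrac{1}{3}\left(\frac{r_{xy\cdot z}}{r_{xy}} +
\frac{r_{xz\cdot y}}{r_{xz}} + \frac{r_{yz\cdot x}}{r_{yz}}\right)$,
the average ratio of partial to direct correlation in the trio. The edge
$x\!-\!y$ is *flagged* in this trio when
$|r_{xy}| < |\varepsilon\, r_{xz}|$ **and**
$|r_{xy}| < |\varepsilon\, r_{yz}|$ — that is, when the association is
small enough to be explained by the third variable. An edge survives
only if no trio flags it; the retained edges are the direct,
conditionally independent associations. The result does not depend on
node order or trio enumeration order, and the compiled scan is checked
against a brute-force pure-R triple loop in the test suite.

Two numerical conventions matter:

* **Degenerate trios are skipped, not flagged.** If any direct
  correlation magnitude or any $\sqrt{1-r^2}$ denominator falls below a
  guard of $10^{-12}$ (which includes exactly collinear node pairs,
  $|r| = 1$), the trio carries no usable conditional information; it is
  skipped and counted in `n_skipped_trios`. A perfectly collinear
  feature pair therefore stays connected rather than producing
  undefined partials.
* **The tolerance is built from signed ratios, compared on
  magnitudes**, matching the "average ratio of partial to direct
  correlation" construction with an "exceeds the tolerance" retention
  test.

A property of this rule worth knowing: in a pure mediation trio
($x \leftarrow z \rightarrow y$, so $r_{xy} \approx r_{xz} r_{yz}$),
flagging the indirect edge requires both mediator links to fall below
$\varepsilon \le \tfrac{2}{3} + \text{small}$, which caps the removable
indirect correlation at roughly $|r_{xy}| \lesssim 0.45$. Very strong
mediation chains produce indirect edges that PCIT deliberately keeps,
because at that strength the trio cannot distinguish mediation from
direct interaction. The `mediated_trio` fixture is therefore built in
the moderate regime (mediator links $\approx 0.57$ and $0.60$, indirect
edge $\approx 0.30$, partial $\approx -0.05$), where the filter
provably removes exactly the indirect edge — also the regime of the
moderate ASV–phenotype correlations this pipeline targets.

## Abundance transforms

**CSS-log2** (the working scale of the network): for sample $j$ with
quantile level $l$, the scale $s_j$ is the sum of the counts at or below
the $l$-th quantile of the sample's *positive* counts (linear
interpolation; zeros are excluded from the quantile but included in the
sum, where they add nothing), and the transformed value is
$\log_2(x_{ij}/s_j \cdot C + 1)$. Zeros map to exactly zero and scalar
multiples of a sample column transform identically. Defaults:
`quantile_mode = "fixed:0.5"` and $C = 1000$; both are recorded in the
output's attributes because the choice of quantile is a genuine free
parameter of CSS — the adaptive mode picks the smallest grid level
(0.25–0.95, step 0.05) at which the median scale across samples becomes
unstable (relative change over the previous grid point above 0.1),
falling back to 0.5 when the scales stay stable throughout.

**CLR** uses natural log with a pseudocount of 1 on counts, centred per
sample; each sample column sums to zero by construction. The pseudocount
of 1 mirrors the CSS-log2 convention so the two transforms are
comparable.

**RV coefficient.** The agreement between the two geometries is
quantified by Escoufier's RV on the per-feature-centred configurations,
$\mathrm{RV} = \mathrm{tr}(S_X S_Y) / \sqrt{\mathrm{tr}(S_X^2)\,
\mathrm{tr}(S_Y^2)}$ with $S = X_c^\top X_c$ the cross-sample Gram
matrix. On the default synthetic data the CSS-log2 and CLR geometries
agree closely (RV $\approx 0.92$–$0.97$ across seeds), the qualitative
analogue of the near-unity agreement reported for real rumen amplicon
tables; sparser or noisier data lower the RV.

## Diversity conventions

* **Chao1** is the bias-corrected estimator
  $S_{obs} + F_1(F_1 - 1)/(2(F_2 + 1))$; all-zero samples are an error.
* **Bray–Curtis** follows
  $1 - 2\sum_i \min(x_i, y_i)/(\sum_i x_i + \sum_i y_i)$ on raw counts,
  at the supplied aggregation level (`aggregate_taxa()` provides
  family-level tables when rank-level diversity is wanted; the
  ASV-level default keeps diversity and network stages on the same
  features).
* **PCoA** eigendecomposes the Gower double-centred matrix
  $-\tfrac12 J D^2 J$. Negative eigenvalues (expected for non-Euclidean
  dissimilarities) are reported but receive no coordinates and no
  correction (no Cailliez constant); explained fractions are relative
  to the sum of positive eigenvalues, so they sum to one over the
  returned axes.
* **PERMANOVA** uses the one-way pseudo-F from squared distances,
  $F = (SS_B/(a-1)) / (SS_W/(N-a))$, with whole-label permutations and
  the add-one rule $p = (1 + \#\{F^\ast \ge F\})/(1 + n_{perm})$, so p
  is never zero and is exactly reproducible from the seed. A fully
  degenerate distance matrix (all zeros) yields $F = 0$, $p = 1$. The
  pipeline applies this to a two-level sampling-week label as a nuisance
  check, with 999 permutations by default.

## Subset selection and the retention rule

`best_subsets()` reproduces an all-possible-subsets R² search: for every
model size $k$ it reports the predictor set with the highest OLS R²
(intercept always included; predictors unstandardized, which leaves R²
unchanged). Three engines share one moment cache
($R^2(S) = S_{xy}[S]^\top S_{xx}[S,S]^{-1} S_{xy}[S] / S_{yy}$ on
centred data, with a pivoted-QR fallback for singular subsets):

* `exhaustive` — plain enumeration, guarded by `p_exhaustive_max`
  (default 20);
* `branch_and_bound` — the default full-search engine; a subset tree
  pruned with the monotone bound that no subset can beat the R² of its
  superset of remaining candidates, with candidates visited in order of
  marginal correlation. Pruning is strict (a node is cut only when its
  bound is clearly below every incumbent), so the engine returns exactly
  the exhaustive answer, ties included;
* `forward` — greedy stepwise addition, the explicit flagged fallback
  for panels larger than `p_exhaustive_max`; its path is nested and not
  guaranteed best-of-size.

R² ties (within $10^{-12}$) are broken by the lexicographically smallest
subset of original column positions, making paths deterministic across
platforms.

`minimal_subset()` applies the retention rule: the smallest $k$ whose
best R² reaches `threshold` (default 0.95) times the full-model R². The
threshold is configuration, not constant, because the retention target
is a modelling choice ("about 95 %"); retention and reduction are
computed from unrounded R² values.

## Evaluation

* **Random baselines** draw size-matched ASV panels from the full
  prevalence-filtered pool (10 draws by default). Network-selected ASVs
  are *not* excluded from the pool — exclusion is available via
  `exclude_ids` but changes the null being tested.
* **CV-R²** is the square of the Pearson correlation between observed
  and predicted values in the held-out fold, *not* $1 - SSE/SST$; the
  two differ out of sample and the test suite pins the distinction. One
  seeded 5-fold split with round-robin assignment is used (fold sizes
  differ by at most one); a fold with constant observations or
  predictions has no defined correlation and is excluded from the mean
  with a warning.
* **`summarize_performance()`** recomputes all derived comparison
  columns (improvements over random, retention %, reduction %) from the
  base columns, so published summary tables can be fed in directly and
  re-derived exactly.

## What the synthetic generator emulates

`simulate_dataset()` provides ground truth for every downstream stage.
Its defaults are the study conditions: 56 animals, 350
prevalence-filtered ASVs, three inter-correlated phenotypes (CH4Y and
ACET_PROP share a latent driver with correlation +0.5), 8 direct-effect
ASVs per phenotype with target CSS-log2 correlation magnitude 0.3, 10
mediated ASVs, and a target zero fraction of 0.55.

Key design choices:

* **Effects are injected on the latent log-abundance scale before count
  sampling.** Each phenotype has a standard-normal latent driver; its
  direct ASVs add a signed loading of that driver to their latent log
  abundance, and the phenotype itself is driver plus noise, rescaled to
  realistic summary statistics (EFF 0.97 ± 0.22, CH4Y 24.95 ± 4.11 g/kg,
  ACET_PROP 4.92 ± 0.42). Because counting noise and zeros attenuate the
  latent correlation, the loading is calibrated with a fixed attenuation
  constant (0.78) chosen once for the default depth/sparsity regime so
  that the *realized* correlation on the CSS-log2 scale matches the
  configured target (verified at $n = 500$ in the tests).
* **Direct ASVs are placed in the abundant half** of the composition so
  the planted signal is observable through multinomial sampling; an
  effect planted on a feature that is zero in most samples would be
  unrecoverable by any method at $n = 56$.
* **Mediated ASVs are noisy copies of a direct ASV's total latent
  deviation** (correlation 0.7 by default) with no independent phenotype
  term — the structure whose phenotype edge a partial-correlation filter
  should remove.
* **Sparsity is hit by tempering.** A symmetric Dirichlet base
  composition is raised to a power chosen by root-finding so that the
  expected zero fraction under a Poisson approximation,
  $\overline{\exp(-p_i N_j)}$, equals `sparsity_target` given the drawn
  log-normal library sizes. This keeps depth, skew and sparsity mutually
  consistent instead of treating them as independent dials.
* **Families follow a Zipf-like distribution** over 25 names, and one
  mid-sized family (closest to 15 members) is intentionally
  over-represented among the direct ASVs, giving the enrichment stage a
  recoverable signal against a realistic skewed background; about 5 % of
  unplanted ASVs get an unclassified family to exercise the
  missing-rank rules.

What it does **not** emulate: phylogenetic correlation among related
ASVs, batch or run effects, compositional interactions beyond the shared
multinomial denominator, taxonomic mis-assignment, or overdispersion
beyond the log-normal cell noise. Passing the recovery tests therefore
shows the pipeline recovers planted structure under idealized
independence assumptions — not that it would attain the same operating
characteristics on real rumen data, where effect sizes, confounding and
zero patterns are less benign.

## Enrichment conventions

Family enrichment of a selected ASV set against the network background
uses the hypergeometric upper tail $P(X \ge x)$ with score
$-\log_{10} p$ — the printed-score convention in which larger means more
enriched (a raw upper-tail probability cannot itself grow with
enrichment, so scores around 3 correspond to $p \approx 10^{-3}$). ASVs
without a family assignment are excluded from both the background and
the selection rather than pooled into a pseudo-family, so classification
failure cannot manufacture enrichment. Families are reported when at
least `min_count = 2` selected members hit them; no multiple-testing
correction is applied to the scores, but a Benjamini–Hochberg column is
emitted alongside as clearly-labelled extra output.

## Reproducibility and problem sizes

`run_all()` derives each stage's seed deterministically from the master
seed and the stage name, so adding a stage never perturbs earlier
stages, and a rerun with the same configuration reproduces every output
file byte for byte (no timestamps are written; per-stage progress goes
to the console only). The test suite exercises PCIT against its
brute-force oracle on matrices up to 12 nodes, branch-and-bound against
exhaustive enumeration up to $p = 12$, hypergeometric tails against full
subset enumeration up to $N = 12$, recovery on ten full 56 × 350
replicates, and PERMANOVA calibration over 200 null simulations — sizes
chosen so the whole suite stays well under a minute per property while
still covering the study-scale regime. A full 56 × 350 pipeline run
takes a few seconds; the compiled trio scan handles a 350-node network
(about 7 million trios) in well under a second, so the roughly 160-node
networks that remain after prevalence-filtering the default 55 %-sparse
table are far from its limit.

## Known limitations

* PCIT has no significance filter; at small $n$ the retained edge set
  includes noise edges, and the moderate-correlation regime
  (|r| ≈ 0.2–0.4) is exactly where its tolerance is most informative.
* The forward fallback for panels above `p_exhaustive_max` predictors is
  not guaranteed best-of-size; its use is flagged in the `subset_path`.
* With panel sizes approaching the sample count, full-model R² saturates
  and the selected-vs-random comparison loses meaning; the retention
  rule mitigates but does not remove this.
* PERMANOVA here is one-way only (the sampling-week nuisance check);
  multi-factor designs need a full linear-model decomposition of the
  distance matrix.
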