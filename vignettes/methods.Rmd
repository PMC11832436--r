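---
title: "Methods: stratified cohort analysis by index-gene expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stratified cohort analysis by index-gene expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fgf21strat)
```

# The model and its assumptions

The pipeline analyses a gene × sample matrix of non-negative, linear-scale,
already-normalised expression values for a cohort of patients and healthy
controls. It makes three structural assumptions:

* **A pooled control reference is meaningful.** Per-gene reference values are
  the arithmetic mean of the control samples on the linear scale (a geometric
  mean is available via `control_reference(..., method = "geomean")`). Fold
  changes are patient-versus-pooled-reference, not patient-versus-matched
  control: the data model has no matching scheme, and a per-study reference
  is deliberately left out of the defaults (the generator emits a single
  homogeneous batch; see limitations).
* **Fold changes carry the biology.** The signed convention maps a ratio
  r ≥ 1 to +r and r < 1 to −1/r, so magnitudes are symmetric about ±1 and a
  threshold of 1.5 means "at least 1.5-fold in either direction". The
  classification boundary is *inclusive* (FC = +1.5 is "up") because the
  observed stratum ranges begin exactly at ±1.5-fold.
* **Nonparametric location tests are appropriate per gene.** Cohort DEG
  calling uses the Wilcoxon–Mann–Whitney test per gene, with
  Benjamini–Hochberg FDR across all tested genes. BH is chosen as the field
  default where the upstream description says only "false discovery rate
  corrected". No expression floor is applied; the only exclusion is genes
  whose control reference is zero (no finite ratio exists).

# Parameters that matter

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| stratification threshold | 1.5 | fold change | boundary of the observed up/down ranges |
| DEG rule | q < .05 and \|FC\| ≥ 1.5 | — | joint FDR + effect-size filter |
| exact rank-sum switch | total n ≤ 12 | samples | C(12,6) = 924 assignments enumerate instantly; beyond that the tie-corrected, continuity-corrected normal approximation is accurate |
| zero-patient-value cap | −64 | signed FC | a finite stand-in for "below detection"; configurable |
| recurrence threshold | 10 | patients | a regulator direction must recur in ≥ 10 patients of a stratum |
| enrichment weight | 1 | — | standard weighted-KS statistic on \|score\| |
| permutations | 1000 | — | gene-label permutations, seeded |
| pass rules | p < .05 ∧ \|NES\| > 1 (pathways); p < .05 ∧ NES > 1 (immune markers) | — | both flags always reported; the collection's category selects the applicable one |
| α policy | .05/3 = .017, .05/2 = .025 | — | Bonferroni-style division for three-/two-way comparisons; reported at 3 dp, used unrounded |
| Shapiro–Wilk α | .05 | — | dispatch between parametric and nonparametric branches |
| median CI level | .95 | — | order-statistic (binomial) interval |

# The synthetic-cohort generator

`sim_config()` defaults encode the study conditions the pipeline targets:
66 healthy controls and 396 patients in planted strata of 117 (up), 159
(down) and 120 (unchanged); index-gene signed fold changes drawn
log-uniformly within the observed ranges [1.5, 21.3] and [−7.5, −1.5];
planted expression programs with per-stratum directions; and ordinal
histology scores (steatosis 0–3, lobular inflammation 0–3, ballooning 0–2,
NAS = their sum, fibrosis 0–4) drawn from stratum-specific categorical
distributions whose defaults give the down-stratum more advanced histology —
matching the *direction* of the clinical tables, not their values.

Generation happens on the log2 scale: per-gene control baselines uniform on
log2 [3, 10] (arbitrary but seed-fixed), planted signed FCs added as log2
ratios, additive Gaussian noise (`noise_sd`, default 0.25), then
exponentiation. Additive-on-log2 equals multiplicative log-normal noise on
the linear scale and makes fold-change semantics exact: as `noise_sd → 0`
planted fold changes are recovered at machine precision, which the tests
exploit. One RNG stream is seeded from the config; gene-set generation uses a
deterministic sub-seed.

**What the generator does not emulate:** probe-level microarray artefacts,
batch structure across pooled source studies, count-based RNA-seq sampling
noise, gene–gene correlation beyond the planted programs, and missing
metadata patterns. Passing recovery and calibration tests therefore
demonstrates correctness of the *machinery* under the planted model, not
robustness to those real-data features.

**"Strong effects, small noise" runs.** Label-recovery checks (and the
acceptance script) use index FC ranges [2, 21.3] / [−7.5, −2], the unchanged
stratum inside (−1.25, 1.25), and `noise_sd = 0.1`. With patient noise of
0.1 on log2 and the nearest planted effect ≥ 4 noise SDs from the
log2(1.5) ≈ 0.585 boundary, misclassification is rare enough that ≥ 99% of
396 labels are recovered; drawing effects all the way down to the 1.5-fold
boundary would place patients *on* the decision line, where any noise flips
the label half the time — a property of the boundary, not a defect of the
classifier.

# Numerical choices

* **Exact rank-sum p-values** enumerate U over all rank assignments of the
  pooled *mid-ranks*, so the exact branch remains valid under ties; the
  two-sided p is P(|U − μ| ≥ |u − μ|) with a 1e-12 slack against fp noise.
  Exhaustive enumeration at n = 6 + 6 shows the normal approximation tracks
  the exact p within 0.0155 (worst at U = 12), which bounds what any
  agreement test can assert.
* **BH, Kruskal–Wallis, Shapiro–Wilk, ANOVA, t, Spearman** delegate to the
  standard `stats` implementations (`p.adjust`, `kruskal.test`, ...);
  Spearman uses mid-ranks and the t approximation at n − 2 df, erroring
  (rather than returning NaN) on zero rank variance.
* **G-test**: 0·ln(0/E) is defined as 0; a zero *expected* cell is an error,
  never smoothed; Williams' divisor always exceeds 1 for finite N, so the
  corrected p is never smaller than the uncorrected one.
* **Enrichment ES**: the running-sum maximum deviation resolves ties in
  |deviation| (exact, or within 1e-12 of fp jitter) to the earliest list
  position, making the ES sign deterministic; rankings break score ties by
  gene id. Sets covering the whole ranked list (miss increment undefined) and
  sets with empty overlap are distinct errors, not zero enrichments.
* **NES**: normalisation by the mean |ES| of same-sign permutations;
  add-one smoothing keeps p in (0, 1]; absence of any same-sign permutation
  ES yields an explicit "NES undefined, not passing" diagnostic.
* **Median CI**: largest j with P(Bin(n, ½) < j) ≤ (1 − level)/2, upper
  index n + 1 − j; when unattainable (n ≤ 5 at 95%) the widest interval is
  returned with `attained = FALSE` and its sub-nominal coverage.
* **Degenerate inputs**: identical groups give H = 0, p = 1 (not an error);
  a patient value of exactly 0 maps to the −64 cap; all-zero control rows
  are excluded and reported.

# Open design decisions, and how they were settled

* **Recurrence counting** is per direction per stratum (a gene may pass "up
  in the up-stratum" and "down in the down-stratum" independently), matching
  the paired-bar reading of the regulator frequency chart; pooled counting
  across strata is available via `recurrence_filter(..., pooled = TRUE)`.
* **Ranking metric for enrichment** (fold change vs test statistic) is a
  declared argument — both are supported; examples and the acceptance script
  use the signed FC.
* **Cohort-level FC aggregation** uses the cohort median patient value
  against the control reference; the median is robust to the handful of
  extreme responders the fold-change ranges imply.
* **α rounding**: thresholds are reported at 3 decimals (.017, .025) but
  applied unrounded.

# Problem sizes used by the shipped tests

The suite runs cohorts of 200–500 genes and tens-to-hundreds of patients:
label recovery at the full (117, 159, 120) split with 200 genes; DEG-caller
null calibration over 200 seeded cohorts of 150 genes (20 controls vs 38
null patients); G-test type-I calibration over 10,000 draws at N = 50;
median-CI coverage over 10,000 Gaussian samples at n = 50; and exhaustive
enrichment-oracle fuzz over every gene set of every list up to length 8.
These sizes give stable Monte-Carlo estimates while keeping the whole suite
under a minute.

# Known limitations

* Fold changes are computed against pooled controls; per-study references
  are a config hook, not implemented, and no batch correction is applied.
* The enrichment null permutes gene labels, not phenotypes (phenotype labels
  are consumed upstream by the stratification); gene-set p-values are not
  FDR-corrected across sets, mirroring the upstream filter on raw p and NES.
* The DEG test is unmoderated; with very few samples per stratum a
  moderated-variance model would be more powerful.
* Clinical-table p-values other than the two-cell sex balance depend on the
  unpublished construction of the three-group tables and are not reproduced.
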