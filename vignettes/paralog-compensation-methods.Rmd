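---
title: "Methods: screening for paralog compensation and collateral loss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening for paralog compensation and collateral loss}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paracomp)
```

## The question and the two designs

Paralogs often retain overlapping functions, and cells can buffer the
loss of one paralog by adjusting the protein abundance of its partner.
`paracomp` quantifies two directed responses of a protein A1 to the loss
of its paralog gene A2: *compensation* (A1 goes up) and *collateral
loss* (A1 goes down). Two complementary designs are implemented.

**Isogenic knockouts.** A panel of single-gene knockout clones is
profiled by label-free quantification against a shared wild-type
replicate pool. After preprocessing, each clone's knockout is verified
(the targeted protein must drop significantly), and each paralog of a
verified target is tested with a two-tailed pooled-variance t-test of
knockout versus wild-type replicates. With the default four knockout and
twelve wild-type replicates every test has 14 degrees of freedom. The
verification t-tests and the paralog-response t-tests form two separate
Benjamini–Hochberg families — a clone's verification never competes for
FDR with a response test.

**Matched tumour cohorts.** Given aligned protein, mRNA and gene-level
thresholded copy-number matrices over one sample universe, each
surviving directed pair (A2 lost, A1 responding) is tested with an OLS
fit of A1's abundance on a binary A2-hemizygous-loss indicator, study
(cancer-type) one-hot covariates, and A1's own thresholded copy-number
call. Samples where A2 is amplified or homozygously deleted are
excluded, so the contrast is strictly one lost copy versus two. Study
absorbs tissue-specific expression; the self-copy-number covariate
prevents A1's own dosage from masquerading as a response to A2.

A hit must clear *both* an FDR threshold (BH across all testable rows of
a layer) and an uncorrected p threshold, and its class is the sign of
the loss coefficient. The same machinery runs unchanged on the mRNA
layer and on a protein-residual layer.

## Assumptions

* Abundances are on a log2-like scale where study effects, dosage
  effects and paralog coupling are approximately additive.
* Loss acts through a binary state (one copy lost); dose-response beyond
  the hemizygous state is out of scope.
* Errors are homoscedastic enough for t-based inference; no robust or
  weighted variants are provided.
* Proteomic missingness is left-censored (low-abundance cells go
  undetected), which motivates both the per-sample minimum imputation in
  the isogenic pipeline and the coverage/quantification floors in the
  cohort pipeline.

## Thresholds that matter (`screen_config()`)

| parameter | default | units | role |
|---|---|---|---|
| `fdr_threshold` | 0.05 | fraction | BH FDR required for a hit |
| `p_threshold` | 0.05 | fraction | uncorrected p also required |
| `min_lost_samples` | 20 | samples | loss-eligibility floor, applied both to lost samples and to lost samples with quantified protein, and again per-test after listwise deletion |
| `min_study_size` | 90 | samples | studies below this are dropped at alignment |
| `coverage_fraction` | 0.5 | fraction | each pair member's protein must be observed in at least half the samples |
| `identity_min_exclusive` | 0.2 | fraction | pairs at or below are excluded |
| `family_size_max_exclusive` | 20 | count | pairs at or above are excluded |
| `exclude_same_chromosome` | on (cohort) / off (isogenic) | flag | guards against linkage and co-deletion confounding; isogenic knockouts carry no such confounding, so same-chromosome pairs stay testable there |
| `min_paired_samples` | 30 | samples | pairing floor for the residual layer |

Loss *validation* (a nominally significant negative effect of a gene's
own loss on its own protein) gates all layers, including mRNA and
residual screens. This keeps the tested pair set identical across
layers, which the mechanism classifier requires; re-validating per layer
would silently change the hypothesis family between layers.

## The protein-residual layer

Post-transcriptional signal is isolated in two stages, per gene: first
protein and mRNA are each residualized on study one-hots (study may act
on transcription and on protein stability differently), then
study-corrected protein is regressed on study-corrected mRNA (with
intercept) and the residuals kept. The residual screen omits the study
and self-copy-number covariates — they are already regressed out, and
re-including them would only burn degrees of freedom. Because both
stages are linear projections, the residuals are exactly orthogonal to
the study indicators and to corrected mRNA; the test suite checks this
at 1e-8 and checks the two-stage construction against an explicit
single-projection oracle.

Mechanism calls per directed hit sign: *transcriptional* (mRNA hit, no
residual hit), *post_transcriptional* (residual hit, no mRNA hit),
*both_layers*, *protein_only*, or *none*.

## What the generator emulates — and what it does not

`generate_cohort()` draws, per gene, a baseline abundance, per-study
offsets (SD `sd_study` = 0.3), a hemizygous-loss frequency uniform on
[0.05, 0.25] (with rare −2 and +1 states), an mRNA dosage slope of
`cn_mrna_slope` = 0.5 log2 units per call unit, and independent mRNA and
protein noise (SDs 0.4 each; protein tracks the realized mRNA value plus
its own noise). Planted pairs add ±`effect_size_delta` to the responder
in samples where the partner's call is −1, on the mRNA (transcriptional
mechanism), the protein only (post-transcriptional), or both. The
mechanism mix defaults to equal thirds — neither design gives a reason
to prefer one mechanism a priori. Missingness is left-censored: the
lowest `missing_rate` fraction of protein cells is removed.

Two placement rules keep the planted truth recoverable by construction:
planted pairs sit on distinct chromosomes (so the same-chromosome filter
never removes truth), and planted-pair genes receive above-median
baselines (so left-censoring cannot strip a truth pair of coverage or of
quantified lost samples). Planted lost genes are rejection-sampled to at
least 20 hemizygously lost samples. `generate_hap1()` applies the same
baseline protection to knockout targets and planted responders.

Deliberately *not* modelled: peptide-level effects and shared peptides,
lysis-batch structure, correlated copy-number segments (each gene's
calls are drawn independently), inter-gene expression correlation beyond
the planted coupling, and missingness in the mRNA layer. Passing tests
therefore show that the statistics behave as designed under the stated
generative model — not that real cohorts satisfy that model.

`generate_feature_tables()` produces the annotation inputs with a single
`feature_bias` dial: at 0 all features are independent of the planted
labels (the null used for calibration tests); at the default 1,
compensation pairs receive stochastically higher degree, shared
neighbours, more-essential neighbours, complex co-membership, responder
ubiquitination/conservation, and synthetic-lethality rates.

## Numerical choices

* **OLS collinearity.** Design columns are scanned in their given order
  and kept only if they raise the rank, so the first-listed member of a
  collinear group survives deterministically; a design reduced to its
  intercept is a degenerate-fit error.
* **Exact 2×2 test.** The odds ratio is the sample cross-product
  `ad/bc` (unconditional MLE; `Inf` when `bc = 0` with `ad > 0`, `NaN`
  when both products vanish). The two-sided p sums hypergeometric point
  probabilities no larger than the observed one — the point-probability
  rule.
* **Rank-sum test.** Cliff's delta counts strict pairwise wins minus
  losses; the p-value is exact for tie-free problems up to
  `|x|·|y| ≤ 400`, else the normal approximation with tie correction.
* **AUC.** Midrank-based, equal to the rank-sum statistic normalized by
  `n⁺·n⁻`; ties count one half.
* **Closest pairs.** Ties at a gene's maximum identity qualify.
* **Lasso convention.** `lasso_select()` minimizes
  `‖β‖₁ + C · (summed log-loss)`, so `C` weights the data fit and
  smaller `C` shrinks harder; `C = 0.01` is the default. Internally this
  maps to a penalized-likelihood weight of `λ = 1/(C·n)` with an
  unpenalized intercept and no internal standardization (features are
  z-scored upstream by `prepare_design()`, which standardizes after
  listwise deletion, on the actual analysis set).
* **Feature orientation.** Asymmetric pair features (degree, neighbour
  essentiality, conservation, lengths, responder ubiquitination) take
  their lost/responder roles from the directed hit that made the pair a
  hit; for non-hits, the tested direction with the smaller p-value is
  used, which is deterministic and symmetric in expectation under the
  null.
* **One-hot reference.** The lexicographically first study is the
  dropped reference level — irrelevant to the loss term's inference,
  fixed for reproducibility.

## Open design points, resolved

* A layer's multiple-testing correction operates on the p-values of the
  loss-term t-statistics (the only reading under which BH is defined).
* The responder's own copy number enters as the thresholded call
  (−2..2), not a continuous value.
* Loss validation computed on the protein layer is reused by the mRNA
  and residual screens (identical pair families across layers).
* Validation regressions use the same call ∈ {−1, 0} restriction as the
  pair tests, for consistency.
* Neighbour essentiality defaults to the median over neighbours (mean
  available via an argument).
* Wild-type replicates form a single pool; batch is not modelled as a
  covariate in the isogenic t-tests.

## Problem sizes used by the test suite

The acceptance-style tests run the generator at its default cohort size
(600 samples, 2000 genes, 500 pairs): 20 replicate cohorts for the
false-discovery check, 5 for signed recovery at `effect_size_delta` =
1.5 with `sd_protein` = 0.2, and 2 three-layer replicates at low noise
for mechanism recovery. Null calibration of the feature batteries uses
10 replicates of a 200-sample, 200-pair configuration with
`feature_bias` = 0. Unit tests use miniature hand-built fixtures whose
expected values were derived by enumeration or closed form.

## Known limitations

* In-sample AUCs only; no cross-validation or external validation.
* No homozygous-deletion or per-cancer-type stratified screens.
* Listwise deletion throughout; no imputation in the cohort pipeline.
* The symmetric-pair enrichment needs pairs tested in both directions;
  under the generator's unidirectional planting it is typically null.
* Perfect separation in logistic models is flagged, not resolved
  (no penalized fallback for the final model).
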