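---
title: "Quantifying miRNA target-site abundance under alternative polyadenylation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying miRNA target-site abundance under alternative polyadenylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(numts)
```

## The quantity: numTS

A miRNA's regulatory effect depends not only on how much miRNA is present
but on how many binding sites the transcriptome currently exposes. Tumors
remodel 3'UTRs through alternative polyadenylation (APA): when a gene shifts
toward its proximal polyA site, the distal part of its 3'UTR — and every
miRNA target site on it — disappears from most transcripts. The per-sample,
per-miRNA-family target-site abundance we call numTS captures this.

For gene $x$ and miRNA family $j$, with the 3'UTR split at the predicted
proximal polyA boundary into a constitutive proximal segment (pUTR, on all
isoforms) and a distal segment (dUTR, on long isoforms only),

$$\mathrm{sites}(x, j) = \big(\mathrm{pUTR}(x,j) + \mathrm{dUTR}(x,j)\cdot
\mathrm{PDUI}(x)\big)\cdot \mathrm{FPKM}(x),$$

where PDUI is the fraction of the gene's transcripts carrying the long
isoform, and FPKM scales the site count by how many transcripts are actually
present. Summing over all expressed genes gives the family-by-sample matrix

$$\mathrm{numTS}(j) = \sum_x \mathrm{sites}(x, j).$$

FPKM enters untransformed — the quantity is an expected number of exposed
sites, which is linear in transcript abundance. Log transforms appear only
in downstream preprocessing.

### Site partitioning and edge cases

* A site is proximal only if its whole interval lies 5' of the boundary.
  A site straddling the boundary is assigned to the distal segment: proximal
  polyadenylation truncates it, so only the long isoform carries an intact
  copy. The tests verify this against an isoform-enumeration oracle that
  checks interval containment in the short and long isoform explicitly.
* Genes with no APA record are treated as non-APA, i.e. full-length 3'UTR
  (PDUI of 1; equivalently all sites constitutive). The alternative —
  dropping them — would discard most of the transcriptome.
* Missing PDUI for a (gene, sample) pair is handled conservatively: the gene
  contributes nothing to that sample (`missing_pdui = "skip"`). Cohort-mean
  imputation is available behind `missing_pdui = "mean"`, never silently.
* Coordinates are transcript-local and 0-based half-open internally. Readers
  convert 1-based inclusive genomic input once, at the boundary, and
  normalize minus-strand loci to transcript orientation, so all downstream
  code is strand-free.

### Tumor-normal change

`delta_numts()` computes per-patient, per-family
$\log_2(\mathrm{numTS}_T + 1) - \log_2(\mathrm{numTS}_N + 1)$. The log scale
is a deliberate choice: numTS spans orders of magnitude across families, and
raw differences would let a handful of high-abundance families dominate any
penalized survival fit. `transform = "raw"` exposes plain differences.

## Association analyses

`correlation_profile()` computes per-family Spearman correlation between
numTS and miRNA expression across samples, its square, and BH-adjusted
q-values. Spearman p-values use the exact distribution for $n \le 10$ and
the t approximation above, standard practice for rank correlations.
Families constant in either matrix are undefined and excluded from the BH
adjustment rather than imputed.

`disruption_test()` compares the squared-correlation distributions of two
profiles (normal vs. tumor) with a two-sided Wilcoxon rank-sum test, as an
unpaired comparison; a paired signed-rank variant is available via
`paired = TRUE` for matched family universes, arguably more powerful but not
the default.

## Separability metrics

`preprocess_lcs()` applies `log2(x+1)`, then centers and scales each
feature; constant features are dropped with a warning.
`between_group_rate()` reports
$100\cdot\sum_f SS_{between}(f) / \sum_f SS_{total}(f)$ after per-feature
unit-variance scaling. The aggregation across features (ratio of sums vs.
mean of per-feature ratios) was an open choice; after unit scaling every
feature has the same total sum of squares, so the ratio of sums equals the
mean of ratios and the estimand is unambiguous. It is affine-invariant per
feature by construction.

`mahalanobis_group_distance()` computes, for every pair of groups, the
distance between centroids under the pooled within-group covariance *of that
pair* (not the global covariance): pairwise separability is what per-group
confidence ellipses illustrate, and a global covariance would let a third,
distant group inflate the apparent separation of a pair. Distances are
reported on the distance scale (the square root of the quadratic form).
Confidence-ellipse rendering is a plotting concern and out of scope; the
distance matrix is the computational contract.

Hierarchical clustering uses complete linkage by default (deterministic,
common for expression heatmaps); average and Ward linkage are flags.

## Predictive models

`nested_cv_rmse()` follows the nested cross-validation design: each outer
repeat holds out a random 25% of samples (the complement of a 75% train
set), the inner 10-fold CV searches the elastic-net grid — the 11-point
mixing grid $\alpha \in \{0, 0.1, \dots, 1\}$ crossed with the full lambda
path — and the one-SE rule picks the most parsimonious grid point whose CV
error is within one standard error of the minimum (ties: larger lambda,
then smaller $\alpha$). Standardization happens inside the training split
only; the held-out RMSE is the performance metric. The default is 300
repeats; the per-repeat seed is `seed + repeat`, so
`compare_feature_sets()` runs two feature sets on *identical* outer splits
and the percent RMSE decrease is a paired comparison.

`bootstrap_stability_selection()` resamples the samples with replacement
`B = 200` times, fits an elastic net per resample with lambda chosen by
10-fold CV (one-SE rule, consistent with the nested-CV selection), and
reports per-feature selection frequencies. The CV folds are assigned at the
level of *original* samples, so every bootstrap copy of a sample lands in
the same fold: with naive per-row folds, duplicated rows appear in both
training and validation folds, the CV-chosen lambda becomes
anti-conservative, and a feature spuriously correlated with a pure-noise
outcome gets selected in a majority of resamples — a stable false positive.
Duplicate-aware folds eliminate that artifact (the tests verify a clean
noise null at the 70% rule) without affecting strong-signal recovery. For the per-resample fits we fix
the mixing parameter at $\alpha = 0.5$ rather than re-searching the
$\alpha$ grid 200 times: the selection frequencies, not the prediction
error, are the output, and a mid-path elastic net is the standard choice
for stability selection where ridge ($\alpha = 0$) would select everything
and the lasso can drop correlated features erratically. Two rules map
frequencies to a predictive set: the top 50% of candidate features (those
selected at least once) with ties at the cutoff included, or a fixed 70%
frequency cutoff. `hypergeometric_overlap()` then gives the exact
upper-tail replication p-value between two cohorts' predictive sets over an
explicit universe — the universe must be supplied by the caller, since the
eligible feature set is a design decision, not something the overlap test
should guess.

A note on numerical behavior: selection frequencies are invariant to
feature order only up to glmnet's coordinate-descent tolerance; borderline
features can shift by a bootstrap or two under column permutation. The
tests assert invariance at that tolerance.

## Survival models

Three Cox models are compared: clinical-only, numTS-clinical, and
expr-clinical. `lasso_cox_select()` fits a penalized Cox model in which the
clinical covariates carry zero penalty (always retained) and the
numTS-change features carry the lasso penalty; lambda comes from 10-fold CV
(`lambda.min` by default — the selection step optimizes recovery, not
parsimony; `one_se` is a flag). Because a likelihood-ratio test on
penalized fits is not valid, both augmented models are *refit unpenalized*
on the selected covariates before any likelihood comparison — standard
post-selection practice; the resulting inference is descriptive, not
selective-inference-corrected. Ties use the Efron approximation. Risk
groups split at the median linear predictor (near-balanced groups), are
compared with the two-sided log-rank test, and `lrt_compare()` reports
$2\Delta\ell \sim \chi^2_{df}$ with df equal to the number of added
covariates. Age is continuous, stage ordinal-as-numeric, gender binary.

## The synthetic cohort

The generator produces data with exactly the structure the analyses assume,
so every stage is testable without controlled-access data:

* FPKM and TPM are lognormal (`meanlog` 2 and 1, `sdlog` 1) — the right
  order of magnitude and skew for bulk RNA-seq abundances.
* PDUI is Beta(5, 2) in normal tissue (mean 0.71, moderate spread); tumor
  tissue shifts the mean down by `tumor_pdui_shift = 0.2` at constant
  concentration — pervasive but partial 3'UTR shortening.
* Target-site counts per (gene, family) are Poisson(0.5), split uniformly
  between the proximal and distal segments, with uniform site positions —
  most pairs carry no site, as in real target annotations.
* The numTS-expression coupling is a Gaussian-copula rank coupling on the
  normal scores of the realized numTS, with latent Pearson
  $r = 2\sin(\pi\rho/6)$ so the *Spearman* correlation hits the target
  $\rho$ exactly in expectation: $\rho = 0.8$ in normal tissue, $0$ in
  tumor. This is the coupling-then-decoupling structure the disruption test
  is designed to detect.
* Outcome scores are linear in the standardized numTS of 5 planted families
  (unit coefficients, unit Gaussian noise).
* Survival times are Weibull (shape 1.5) proportional hazards with log-HR
  0.7 per SD of planted numTS change plus small clinical effects; censoring
  is uniform with its upper bound calibrated by root-finding to the target
  censoring fraction (default 30%).
* The ICB design plants a log2 fold-change of 1 on the FPKM of the planted
  families' target genes in responder-post samples only — at the default
  scales roughly 2-5 within-group SDs of those families' numTS — leaving
  the other three groups exchangeable.

Default sizes (300 genes, 100 families, 200 samples, 40 tumor-normal pairs,
4 x 25 ICB samples) are desk-scale: large enough for stable selection and
calibration checks, small enough that the full test suite runs in minutes.
The generator's ground-truth numTS is computed by a direct per-site loop,
deliberately independent of the vectorized pipeline computation, and the
two must agree to 1e-9 — a self-consistency the test suite enforces.

What the simulator does **not** emulate: real TCGA marginal distributions,
gene-gene co-expression structure, batch effects, isoform-level complexity
beyond the two-segment UTR model, or informative censoring. Passing tests
demonstrate that the algorithms are implemented correctly and behave as
designed under their own assumptions — not that numTS will separate cancer
types or predict outcomes in any particular real cohort.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 1)
cohort <- simulate_cohort(cfg)
counts <- partition_sites(cohort$sites, cohort$apa)
numts_mat <- compute_numts_matrix(cohort$expr, cohort$apa, counts)

profile <- correlation_profile(numts_mat, cohort$mirna_expr)
significant_correlated_set(profile)$fraction_nonsignificant

sel <- bootstrap_stability_selection(numts_mat, cohort$outcome, B = 200,
                                     seed = 1)
intersect(sel$predictive_set, cohort$truth$planted_outcome_families)
```

## Known limitations

* Post-selection Cox inference is descriptive; selected-feature p-values are
  optimistic.
* The one-SE rule compares CV errors across different $\alpha$ values using
  the SE at the global minimum; alternatives (per-alpha one-SE) exist and
  differ in edge cases.
* The hypergeometric replication test assumes both cohorts selected from the
  same universe under exchangeability; cohort-specific filtering violates
  this and should be resolved before calling it.
* The straddling-site rule is a biological modeling choice; sites exactly at
  the boundary are rare in practice and do not affect the reported
  properties.
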