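---
title: "Methods: a cell-type-aware methylation risk index from cervical smears"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a cell-type-aware methylation risk index from cervical smears}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(widoc)
```

## The problem and the model

A cervical smear is a bulk sample: mostly squamous epithelium, with
variable admixtures of immune cells and fibroblasts, and — in women with a
gynaecological cancer — possibly traces of tumour DNA. Methylation arrays
report, per CpG, a beta value in [0, 1]: the proportion of methylated
molecules, which for a mixed sample is a *fraction-weighted average* over
the cell types present,

$$\beta_{obs} = \sum_{ct} f_{ct}\,\beta_{ct}, \qquad \sum_{ct} f_{ct} = 1 .$$

Everything in this package follows from taking that convexity seriously:

* a case/control difference confined to the epithelial compartment is
  attenuated by a factor of roughly the epithelial fraction, so naive
  differential methylation under-detects it (the *intercept method*
  de-attenuates it);
* the risk index, being linear in beta values, is linear under admixture,
  which is what makes the tumour-contamination simulation exact rather
  than approximate;
* per-CpG beta distributions in a mixed cohort are two-component mixtures
  with *known, sample-specific* weights (the deconvolved immune fraction),
  so compartment variances are estimable by maximum likelihood.

## Pipeline stages and their key parameters

**QC** (`qc_filter_impute()`). A probe call with detection p-value above
`p_thresh = 0.01` is a failure. Samples with more than 10% failures are
dropped first, then probes failing in more than 10% of the retained
samples; the remaining failures are imputed from the `k = 10` nearest
fully-observed probes by Euclidean distance over the target probe's
observed samples. The method (kNN over probes) is standard for arrays; the
neighbour count and metric are our defaults since only the method itself
is conventionally fixed. The raw-intensity sample filter (median
(un)methylated intensity < 9.5) needs IDAT-level data, which is out of
scope here; the QC report records it as not applied. Order of operations
(samples, then probes, then imputation) follows the order in which the
filters are conventionally described; the report makes the consequences of
that choice explicit.

**Deconvolution** (`build_reference_panel()`, `estimate_fractions()`).
Markers are CpGs where one cell type differs from all others: one-vs-rest
two-sided Wilcoxon rank-sum tests, Benjamini–Hochberg adjusted per type,
intersected with an absolute mean-difference threshold (default 0.5, or
auto-tuned to a per-type marker budget). Note the selection direction:
markers must be *significant* (adjusted p below the threshold) — the
conjunction with a large delta makes any other reading of the published
threshold description nonsensical. Fractions are obtained by non-negative
least squares of a sample's marker betas on the panel centroids, followed
by sum-to-one renormalization. This is a deterministic variant of the
reference-based deconvolution family; robust-regression flavours differ
only below the fidelity our tests probe. The hierarchical immune-subtype
split is collapsed to one immune class: all downstream stages use only the
total immune fraction (IC). Tumour fraction inherits a dependence on
epithelial content in healthy samples; `correct_tumour_fraction()` fits a
loess (span 0.75, degree 2) of tumour on epithelial *in controls only* and
uses residuals as the corrected estimate — deliberately unnormalized, so
slightly negative values are possible and meaningful as noise around zero.
Outside the controls' epithelial range the smooth is extended linearly
from the boundary slope and the sample flagged.

**Intercept method** (`estimate_delta_betas()`). Per CpG and per group,
ordinary least squares of beta on IC. The case-minus-control intercept
difference at IC = 0 estimates the *epithelial* delta-beta; the difference
of fitted values at IC = 1 the *immune* delta-beta. With exact IC and
noiseless linear mixing this is an identity, which the test suite asserts
to float precision. Betas are regressed untransformed (not M-values):
the convex-mixing identity holds on the beta scale and would be destroyed
by the logit. CpGs are ranked by *absolute* delta — both hyper- and
hypo-methylated CpGs carry signal; the combined ranking uses the larger of
the two absolute deltas, a definition we fix because only the ranking's
inputs, not its rule, are conventionally stated. Groups with zero IC
spread yield flagged-unavailable records, never silent zeros.

**Index** (`sweep_index_size()`, `finalize_index()`, `compute_index()`).
Penalized logistic regression (glmnet; ridge α = 0 or lasso α = 1,
binomial deviance, 10-fold stratified CV over 100 geometric lambdas down
to 1e-4 of the data-driven maximum) on the top-n ranked CpGs; n is swept
and chosen by validation AUC (ties to the smaller n; each n re-tunes its
own lambda, matching per-fit CV tuning). The final model is refit on the
entire discovery set with lambda fixed, and the index is
$(\sum_i w_i x_i - \mu)/\sigma$ with μ, σ the training mean and SD of the
weighted sum — so training scores are zero-mean unit-SD by construction,
and the classifier intercept is irrelevant (it cancels in the scaling).
At scoring time up to 5% of model CpGs may be absent; they are imputed at
their stored training means and reported. Missing more than 5% is an
error rather than a silent degradation.

**Variance attribution** (`fit_beta_mixture()`). Per CpG the observed
betas follow $(1-\rho_i)\,Beta(a_0,b_0) + \rho_i\,Beta(a_1,b_1)$ with
known ρᵢ. We minimize the negative average log-likelihood over
log-parameterized shapes with Nelder-Mead from three method-of-moments
starts (low-ρ subset, high-ρ subset, global); the best local optimum is
returned with a convergence flag. Betas are clipped to
[1e-6, 1 − 1e-6] because the beta density is unbounded or undefined at
the boundary for shapes below 1. With all ρᵢ = 0 the immune component is
unidentifiable and the fit honestly reduces to a single beta. A CpG is
called *epithelial* when its epithelial variance exceeds `ratio = 2`
times the immune variance, *immune* in the mirrored case, *shared*
otherwise; the published three-way percentages do not come with a stated
rule, so the ratio is a surfaced configuration value, and those
percentages are not treated as reproducible targets.

**Contamination** (`contamination_shift_curve()`). Mixing a tumour profile
into controls at proportion ρ moves the mean index by exactly
ρ · shift(1) in control-SD units — a corollary of index linearity that the
suite asserts to 1e-10 — so the contamination ρ* needed to mimic an
observed case/control separation (e.g. 1.25 SD) is read off the curve by
linear interpolation, and a target beyond shift(1) is reported
unreachable, never extrapolated. The control SD in the denominator is
computed on the unmixed subset.

**Evaluation**. AUC is the Mann–Whitney statistic with ties counted one
half; its CI uses the DeLong placement-value variance (cross-checked
against pROC in the tests). Odds ratios use the *median-unbiased mid-p*
estimator: the OR at which the mid-p tail of Fisher's noncentral
hypergeometric distribution (conditioning on both margins of the 2×2
table) equals one half, with CI bounds inverting the tails at α/2 by
root-finding to 1e-6 relative tolerance; tails are computed by direct
summation over the support with log-scale weights. This estimator, not
the cross-product ratio, reproduces the published per-quartile odds
ratios to two decimals — the printed values are systematically attenuated
relative to cross-products exactly as median-unbiased estimation
predicts. Quartile cutpoints are the type-7 (linear-interpolation)
quartiles of the *control* reference distribution, intervals closed on
the right; 297 controls then split 75/74/74/74, matching the published
control column and fixing the cutpoint convention. Adjusted ORs come from
logistic regression on quartile indicators plus covariates with Wald
intervals; non-convergence is flagged, not dropped.

## The synthetic-data generator

`generate_profiles()` gives every CpG one beta distribution per cell type.
Non-marker CpGs share a baseline mean (uniform on [0.1, 0.9]) with small
per-type offsets (SD 0.02); precisions a+b are drawn per type so that
epithelial betas are the most variable (a+b in [8, 30]) and immune betas
the most stable ([60, 150]) — the variance asymmetry the attribution model
exploits. A configurable fraction of CpGs per cell type (5% default) are
markers with means 0.85–0.90 in the owning type versus 0.10–0.15 in all
others (or mirrored), guaranteeing the ≥ 0.5 separation the panel
construction needs. Annotation assigns region classes at EPIC-like
proportions (Island 20%, Shore 25%, Shelf 10%, Open Sea 45%).

`generate_cohort()` draws per-sample cell fractions (Dirichlet(3, 0.5,
2.5) by default; the `ic_uniform` model with IC ~ U(0, 0.8) for
index-development cohorts; or fixed), per-sample per-cell-type betas
(biological variability within type, required for the variance
decomposition to be meaningful), mixes them convexly, optionally adds a
tumour compartment at per-sample ρ, adds Gaussian noise on the beta scale
clipped to [0, 1], and plants the case effect as a mean shift of the
epithelial compartment at the informative CpGs. The default planted
effect, Δβ = 0.1 at 500 of 10,000 CpGs with noise SD 0.02, is the scale of
epithelial-specific differences the intercept method is designed to
recover. The tumour compartment carries the same signature amplified
(3 × Δβ, saturating at means of 0.05/0.95): a tumour arising from the
at-risk epithelium is methylomically an exaggerated case, which is the
premise that makes the in-silico contamination experiment informative.
Detection failures are planted at a configurable rate with detection
p-values above threshold.

What the generator does *not* emulate: probe-type (I/II) chemistry,
spatial/batch structure, raw intensities, age trends by default (an
optional hook exists), correlated CpG blocks, or realistic
linkage between region class and methylation level. Passing tests
therefore demonstrate correctness of the estimators under the stated
mixing model — not performance claims about real cervical-smear cohorts,
whose headline AUCs require the access-restricted source data.

## Numerical choices and degenerate inputs

Seeds: every stochastic function takes an explicit seed; the pipeline
expands its global seed into per-stage seeds (seed + stage index) so
stages can be rerun in isolation; identical configs give byte-identical
summaries. Ranking ties break lexicographically by CpG id, making ranks
total and reproducible. NNLS degenerate outputs (all-zero fits) fall back
to uniform fractions. The kNN imputer requires more fully-observed probes
than k and errors otherwise. Constant CpGs in the association scan and
zero-IC-variance groups in the intercept method yield flagged NA records.
Quartile tables with empty case margins report NA odds ratios with a
warning, mirroring how a failed adjustment is reported rather than
dropped. JSON round-trips of index models preserve scores to ~1 ulp.

## Scale of the shipped checks

The end-to-end acceptance run uses 600 samples × 10,000 CpGs (500
informative), the size at which the full pipeline — QC with vectorized kNN
imputation, 800-marker panel, NNLS for 600 samples, three swept ridge fits
— completes in about a minute; recovery suites use n = 400 cohorts, N =
2,000 mixture samples, and 100-sample deconvolution sets. These sizes are
the package's chosen demonstration scale; the estimators themselves are
size-agnostic.

## Interfaces

This is an analysis package: the exported functions, `run_pipeline()`,
and `scripts/acceptance.R` are its interfaces; no shell entry point is
shipped. Matrices are exchanged as TSV (first column `cpg_id`), sample
sheets and per-sample tables as CSV, models and reports as JSON,
blocklists as one id per line.

## Known limitations

The immune compartment is one aggregate class; no immune-subtype
resolution. Betas are modelled directly, with no probe-type or batch
correction. The loess correction assumes controls span the epithelial
range of interest; far outside it the linear extension is a guess and is
flagged as such. The three-way origin-class percentages published for the
real index depend on an unstated rule and restricted data, and are out of
reach by design. The mid-p CI flavour matches the published intervals
closely but the published CI method is not stated; our CIs are validated
by their defining tail-inversion property, not against printed intervals.
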