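---
title: "Methods: dual tumor-associated antigen screening and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual tumor-associated antigen screening and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Single-target cancer therapies directed at antigens such as EGFR are limited
by on-target, off-tumor toxicity: the antigen is abundant on tumor cells but
rarely absent from normal epithelium. Dual-targeting modalities (bispecific
antibodies, dual-gated CAR constructs) relax this constraint — what must be
tumor-specific is the *pair*, not either antigen alone. `dualtaa` implements
the computational arm of that strategy: screening candidate
tumor-associated antigens (TAAs) in single-cell RNA-seq, quantifying how
specifically an anchor/partner pair co-occurs in malignant versus stromal
cells, translating protein-level immunohistochemistry (IHC) evidence into
RNA thresholds, and estimating how much of a patient cohort a dual-positive
rule would cover and how it stratifies survival.

Every stage runs on synthetic inputs with known ground truth, so the
package's statistical behavior is testable end to end without access to
controlled patient data.

# Single-cell preprocessing

Cells are filtered with three rules: fewer than 3 detected genes, fewer than
200 total UMIs, or more than 20% mitochondrial UMIs (symbol prefix `MT-`,
case-insensitive, configurable regex). The 3-detected-genes floor is
unusually permissive for droplet data — many toolchains use a few hundred —
but it is applied literally as the convention here and is configurable
through `qc_thresholds()`. All three cut-offs are closed on the retained
side: a cell at exactly 200 UMIs or exactly 20% mitochondrial content
survives.

Normalization rescales each cell to a fixed total of $10^6$ and applies
`log1p`. The log base is the natural log, the default of the single-cell
toolchains this step mirrors; the base is recorded in the object metadata so
downstream consumers need not guess. Zero counts map to exactly zero, so
sparsity is preserved.

Highly variable genes are ranked by *binned normalized dispersion*:
dispersion is variance/mean of the pre-log normalized values, genes are
placed into 20 equal-frequency mean bins, and dispersions are z-scored
within bins to remove the mean–dispersion trend. This is a deterministic,
library-independent formulation of the standard HVG recipe. Zero-variance
genes are assigned $-\infty$ so a constant gene can never displace a
variable one; remaining ties break alphabetically by symbol.

PCA centers genes and keeps the top 30 components. Batch (dataset-of-origin)
effects are removed from the embedding by per-feature ridge regression on
one-hot batch indicators: with the design matrix orthogonal by construction,
the ridge solution is the per-batch mean deviation shrunk by
$n_b/(n_b+\lambda)$. The correction is recentered to be mean-zero across
cells, so global feature means are untouched; $\lambda = 0$ equalizes batch
means exactly and $\lambda \to \infty$ leaves the input unchanged. Default
$\lambda = 1$.

The marker annotator assigns each cell the type whose marker set has the
highest mean log-normalized expression, with ties broken by the declared
order of the marker list and all-zero cells labeled `unassigned`. It is a
deliberately simple stand-in for reference-based annotation: the pipeline
consumes malignant/normal labels as *input* and never infers malignancy
from copy-number profiles.

# Screening statistics

The expressing cell fraction (ECF) of a gene in a cell group is the
fraction of cells with raw count $> 0$. It is defined on raw counts and is
therefore invariant to normalization.

Gene ranking uses a random forest (1000 trees) classifying malignant vs
normal cells from expression profiles. Cells are split 6:2:2 into
training/testing/validation strata (stratified by label); the forest is fit
on the training split, the testing-split AUC is the model-selection metric,
and the validation AUC is reported untouched. When a grid of `mtry` values
is supplied, 10-fold cross-validation within the training split picks the
value with the best mean AUC before the final fit; with the single default
`mtry` the cross-validation loop is skipped because there is nothing to
select. Importance is permutation importance — mean decrease in out-of-bag
accuracy — with negative values kept and ranked as-is rather than clipped:
a gene whose permutation *improves* accuracy is informative about
overfitting and should sink to the bottom honestly.

The surfaceome step is rank-then-filter: the full ranking is computed, then
restricted to the surfaceome list, then truncated to the top 100. A
`genes =` argument on `rank_features()` supports the alternative
filter-then-rank order for users who want the classifier itself restricted
to surface proteins; the two orders answer slightly different questions and
both are legitimate, but rank-then-filter is the default because the
candidate list should inherit the ranking of the full discriminative model.

# Co-expression specificity

Co-expression of an anchor and a partner in a cell is both raw counts
$> 0$; per (patient, cell-group) fractions follow. Fractions are symmetric
in the two genes and obey the Fréchet bound
$f_{AB} \le \min(\mathrm{ECF}_A, \mathrm{ECF}_B)$. Groups with fewer than
10 cells for a patient are flagged invalid and excluded from summaries —
a fraction estimated from a handful of cells is noise; the floor is
configurable.

The patient-level summary reports, per cell group, the share of patients
whose fraction strictly exceeds 10%. The malignant-vs-stromal comparison is
a two-sided Wilcoxon rank-sum test of per-patient malignant fractions
against pooled per-(patient, stromal-group) fractions — one observation per
patient per stromal cluster, matching how per-cluster distributions are
usually displayed. The exact null distribution is used when both sides have
at most 12 untied observations, the normal approximation with tie and
continuity correction otherwise. When every observation is tied the test is
vacuous and the p-value is 1 by construction.

# IHC quantification and calibration

The H-score weights the percentage of tumor cells at each staining
intensity: $H = 1\,p_{1+} + 2\,p_{2+} + 3\,p_{3+} \in [0, 300]$. Tiers are
nested — positive ($H > 0$), medium ($H \ge 100$), high ($H \ge 200$), both
upper cut-offs inclusive. Two distinct positivity notions coexist on
purpose: *calibration labels* use $H > 0$ (any staining), while
*sample-level dual positivity* requires at least 1% of cells stained for
both markers regardless of intensity. Cohort percentages are rounded
half-up to one decimal, which reproduces every printed rate exactly from
its counts (e.g. 63/64 → 98.4).

RNA thresholds are calibrated from paired IHC/RNA samples. The ROC sweeps
thresholds over the unique scores (positive call at score $\ge$ threshold);
AUC is the trapezoid-rule area, which equals the Mann–Whitney concordance
probability with ties counted one half — an identity the tests verify
against an independent pair-counting oracle and against `pROC`. The
operating threshold maximizes Youden's $J = \mathrm{TPR} - \mathrm{FPR}$
and is reported as the midpoint between the adjacent unique scores; ties in
$J$ break towards the smallest threshold, i.e. maximal sensitivity, since a
screening cut-off should err towards calling marginal expressors positive.

TPM conversion divides counts by effective gene length and rescales each
sample to $10^6$; expression enters all downstream rules as
$\log_2(\mathrm{TPM}+1)$. Cohort positivity applies the calibrated
threshold with a closed boundary (score $\ge \theta$), so a threshold at or
below the observed minimum yields exactly 100% coverage. The published PDX
reference values (cut-offs 2.23 for EGFR and 1.5 for MUC1; LUAD AUCs 0.97
and 0.6) ship as the documented constants `taa_reference_cutoffs`; they
cannot be recomputed without the original paired PDX data and the package
does not pretend to.

# Survival stratification

Survival analysis restricts to advanced-stage (III/IV) patients — the
population that would actually receive a systemic dual-targeting therapy —
and dichotomizes each gene as high/low. The cut rule is a genuine open
choice: the default is a per-gene median split within the stage-filtered
cohort (the most common unstated convention for expression survival
curves), with the calibrated-threshold rule available as an alternative;
the rule used is recorded in the output. Both clinical contrasts are
supported: dual-high vs all other patients, and dual-high vs dual-low.

Kaplan–Meier estimation, the log-rank test, and the univariate Cox model
(Breslow ties, Wald confidence intervals) wrap the `survival` package — the
standard implementation in this field. The tests hold them against
hand-computed product-limit and $O - E / V$ oracles, and check the
classical equivalence of the Cox score test with the log-rank statistic on
binary covariates to $10^{-6}$.

# What the generators emulate — and what they do not

`simulate_sc_cohort()` draws zero-inflated negative binomial counts: gene
$g$ in a cell of type $t$ is expressed with probability $\pi(g,t)$, and
expressed counts follow a *zero-truncated* NB with untruncated mean
$\lambda(g,t)$ and dispersion 0.5 (variance $\mu + 0.5\mu^2$, typical of
UMI data). The truncation makes $\pi$ exactly the expressing-cell
probability the ECF estimates; without it the ECF would be
$\pi \cdot P(\mathrm{NB} > 0)$ and every marginal check would need a
nuisance correction. Batch effects are multiplicative log-normal
per-(batch, gene) factors (sdlog 0.15 by default) — strong enough for the
ridge regression to have something detectable to remove. The first
$\lceil 0.05\, n_\mathrm{genes} \rceil$ genes carry the `MT-` prefix so QC
has a mitochondrial annotation. Default per-gene baselines
($\pi \sim U(0.05, 0.5)$, $\lambda \sim 1 + \Gamma(3, 1.5)$) are calibrated
so a few-hundred-gene panel produces several hundred UMIs per cell, the
scale at which the standard QC thresholds are meaningful.

`simulate_paired_panel()` draws a latent positive state at the configured
prevalence; RNA scores sit `separation/2` within-class standard deviations
above (positives) or below (negatives) the true threshold $\theta^*$, so
`separation` directly controls the achievable AUC
($\mathrm{AUC} = \Phi(\mathrm{separation}/\sqrt 2)$ before truncation at
zero). IHC staining percentages make the H-score positive exactly when the
latent state is positive; `h_score_noise` flips calls with a probability
that peaks for samples whose RNA score sits near $\theta^*$, reproducing
the medium-AUC regime in which IHC and RNA genuinely disagree near the
boundary.

`simulate_cohort()` draws independent per-gene positivity states (defaults
0.975 for EGFR and 1.0 for MUC1, mirroring reported TCGA-LUAD positivity),
well-separated normal expression for the two states, stages from a
categorical distribution, and exponential survival with the hazard
multiplied by the configured ratio for dual-positive samples. Censoring is
Bernoulli at the configured rate with the censored time drawn uniformly
before the latent event time, so the configured rate is exactly the
expected censored fraction.

None of the generators model gene–gene correlation beyond cell-type
structure, doublets, ambient RNA, patient-level expression heterogeneity
within a cell type, or non-proportional hazards. Passing tests therefore
demonstrate that the *statistics* do what they claim under their own
assumptions — not that those assumptions hold in any particular tumor
atlas.

# Numerical conventions

* Percentages print with half-up rounding to one decimal.
* ROC thresholds are the unique scores plus a below-minimum sentinel;
  Youden cut-offs are midpoints; all boundary comparisons are closed
  ($\ge$).
* Random-forest fits are single-threaded with a fixed seed, and every
  stage of the pipeline derives its own child seed from the global one, so
  a pipeline run is bit-reproducible (`report.md5` digests are compared in
  the tests).
* The patient-threshold rule is a strict inequality (fraction $> 10\%$),
  so a patient at exactly the threshold does not count.
* Degenerate inputs fail loudly and early: percentages summing past 100,
  zero-total cells at normalization, single-class labels, single-batch
  correction (warning + identity), empty cell groups.

# Problem sizes

The bundled demo configuration simulates 6 patients × 150 cells over 300
genes in 2 batches, 200 paired IHC/RNA samples per marker, and a
500-sample survival cohort; a full `run_pipeline()` on these sizes takes
well under a minute on one CPU. The test suite's largest exercise — 20
independent screens of a planted malignant-specific gene in 2000 cells ×
500 genes with 1000-tree forests — was sized to keep the whole suite in
the single-digit minutes while leaving the forest at its full production
tree count.

# Limitations

* Malignant labels are an input contract; the package ships no
  copy-number-based malignancy caller.
* Consecutive-section co-localization is approximated at sample level; no
  image registration or per-cell protein co-localization is attempted.
* The Cox interface is univariate only; multivariate adjustment is out of
  scope.
* The published PDX cut-offs are constants, not reproducible outputs.
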