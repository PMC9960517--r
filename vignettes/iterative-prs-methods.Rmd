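---
title: "Methods: iterative aggregation for stable polygenic risk scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: iterative aggregation for stable polygenic risk scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind `iterprs`, the
parameters that matter, the numerical choices made where the design was
genuinely open, what the synthetic-cohort generator does and does not
emulate, and the package's known limitations. It states no empirical
result beyond what the test suite and `scripts/acceptance.R` themselves
compute.

## The model

For a quantitative phenotype $y$ and dosage matrix $G \in \{0,1,2\}^{n
\times m}$ (copies of each variant's effect allele), a polygenic risk
score is a weighted dosage sum

$$\mathrm{PRS}_s = \frac{1}{D}\sum_{i=1}^{k} \beta_i\, G_{si},$$

where the $\beta_i$ are per-variant effect estimates and $D$ is a
normalizing denominator. Three denominator conventions are implemented
(`denominator_mode`): twice the per-sample count of non-missing model
variants (the default, matching the average-over-included-alleles
convention of standard PRS software), the literal cohort sample count,
and none. On complete data all three are positive affine transforms of
one another, so the incremental $R^2$ below and min–max-normalized scores
are identical across modes; the choice only matters for the raw score
scale. This equivalence is asserted by tests.

The figure of merit throughout is the **incremental (full-minus-reduced)
$R^2$**:

$$R^2_{\mathrm{PRS}} \;=\; R^2\!\left(y \sim \mathrm{PRS} +
\mathbf{C}\right) \;-\; R^2\!\left(y \sim \mathbf{C}\right),$$

with $\mathbf{C}$ the covariates (sex, age, two binary disease statuses
by default) plus any selected principal components. It is computed by
projecting both $y$ and the score onto the orthogonal complement of the
covariate space (numerically identical to fitting both nested OLS models;
a two-`lm()` oracle agrees to $10^{-10}$ in the tests), and is
non-negative by construction.

## One derivation iteration

Each iteration draws a random 80/20 train/test split and then:

1. **Summary statistics (training split).** For every variant, the
   phenotype is regressed on dosage plus covariates and PCs. Two
   mathematically distinct engines sit behind one interface: `wald_ols`
   (exact OLS t-test on the dosage coefficient, via Frisch–Waugh
   residualization) and `score_test` (1-df score test under the
   covariate-only null). Externally computed summary-statistic tables can
   be substituted where real GWAS tooling is preferred. Engines are
   compared at the end by mean per-iteration PRS $R^2$ and the best one
   feeds aggregation — the comparative-selection logic is the point, not
   the particular engines.
2. **Clumping + thresholding (test split).** Variants are greedily pruned
   in ascending-p order so that no retained pair within 250 kb has
   squared dosage correlation above 0.1 (PRSice-like defaults; both
   exposed). For each threshold in a descending-inclusive grid
   $\{5\times10^{-8},\dots,0.5,1\}$, the clumped variants with $p \le$
   threshold form a candidate score evaluated on the held-out split; the
   best threshold's model and fit are recorded. Ties resolve toward the
   stricter threshold, i.e. fewer SNPs.

The per-iteration best $R^2$ values form the engine's **baseline
distribution** — the empirical reference against which any aggregated
score is later judged.

## Aggregation, penalization, selection

Across iterations, a variant's **appearance frequency** is the number of
selected models containing it; variants appearing fewer than `min_freq`
(default 5 of 100) times are discarded and surviving effects are averaged
over the iterations where the variant appears. For every observed
frequency $f$, the candidate score "all variants appearing $\ge f$
times" is evaluated on the stored test splits (candidates are nested:
higher $f$, fewer SNPs). Mean $R^2$ is penalized for score size,

$$R^2_P = \frac{R^2_{\mathrm{PRS}}}{\log N},$$

local maxima of $R^2_P$ along the size-ordered candidate sequence are
the pre-final set, and the global maximum wins (ties toward fewer SNPs,
consistent with preferring compact scores). The winner's significance is
the empirical bootstrap $p = \#\{b \in \text{baseline} : b >
\bar{R}^2_{\mathrm{agg}}\}/|\text{baseline}|$. Final evaluation holds out
5–50% of samples in 5% steps (10 repetitions each), refits full and
reduced models on the retained portion, and also reports a whole-dataset
fit and optionally an alternative phenotype column.

Open design points resolved here:

* **Penalty log base** — natural log by default, configurable: the base
  rescales the whole penalized curve monotonically *within* a fixed $N$
  but can move the argmax across candidates, hence exposed.
* **Plateaus** in the local-maxima scan keep the first index of each run
  of equal values; single-candidate scans select that candidate.
* **"10-fold cross-validation" vs percentage holdouts** — the evaluation
  is implemented as repeated random holdouts (`reps_per_frac = 10`) at
  each left-out fraction, the interpretation that covers both readings.
* **Candidate evaluation splits** — candidates are scored on the *stored*
  per-iteration test splits, not fresh ones, so baseline and candidate
  values share split noise and the bootstrap comparison is like-for-like.

## Stratification correction

PCA runs on dosages standardized per variant to mean $2p$ and scale
$\sqrt{p(1-p)}$ ($p$ = allele frequency; monomorphic columns skipped),
via the eigendecomposition of the sample-by-sample covariance. The
number of components carried into the regressions is selected
sequentially with the Tracy–Widom statistic: for each leading eigenvalue
the effective marker count is estimated from the remaining spectrum by
the moment estimator $n_{\mathrm{eff}} = (k+1)S_1^2/\bigl((k-1)S_2 -
S_1^2\bigr)$, the eigenvalue is centred and scaled to the TW(1) variable,
and testing stops at the first non-significant component
($\alpha = 0.05$ default; critical values embedded as a static quantile
table over $\alpha \in [0.001, 0.10]$, interpolated in $\log_{10}\alpha$).
This moment normalization is the main under-specified numerical detail
of the procedure and is documented in code.

**PCA mode.** By default PCs are computed once on the full dataset
(`pca_mode = "global"`). A `per_split` mode recomputes them inside every
training split (and on each test split for its evaluation regression,
since projection of unseen samples is out of scope). Per-split PCA costs
one dense $n_{\mathrm{train}} \times n_{\mathrm{train}}$
eigendecomposition per iteration — at the default study size that
multiplies the runtime of a 100-iteration run several-fold while leaving
the association models essentially unchanged (the PCs differ only by
sampling noise), so global is the default and per-split remains available
for strict train/test separation studies.

## Harmonization and imputation

Merging two filesets classifies every shared variant by allele pair:
identical, strand-flip (complemented), allele-switch (order reversed,
dosage recoded $d \to 2-d$), both, or irreconcilable (dropped).
Palindromic A/T and C/G pairs are ambiguous under flips and are dropped
unless an offline allele-authority table (id → risk allele) resolves
their orientation — a pluggable stand-in for online annotation lookups,
chosen so tests are hermetic. Shared ids with conflicting coordinates
are a hard error. The merged dataset keeps cohort A's orientation, the
union of samples and retained variants, and missing blocks where a
cohort lacked a panel.

Missingness is then filled in two passes: (1) iterative **regression
imputation** — each variant with missing entries is regressed (OLS) on
its `window_snps = 10` nearest neighbours among samples with complete
predictors; predictions are made only when training $R^2 \ge$
`r2_min = 0.8`, rounded to hard calls in $\{0,1,2\}$, and whole-dataset
passes repeat (≤ `max_rounds = 10`) until nothing changes; (2) **k-NN
imputation** — remaining holes take the modal dosage of the $k = 10$
nearest samples under mean-absolute-dosage distance over mutually
observed variants, with cohort-modal fallback (warned) for pathological
samples. Hard calls keep the dosage domain closed at the cost of
discarding fractional posterior information; the window/threshold
defaults follow the conventions of the imputation tooling this mirrors
and are all exposed. Reference-panel haplotype imputation is explicitly
out of scope: externally imputed datasets are accepted with per-variant
INFO scores, filtered at 0.9.

## Quality control

Defaults follow standard array-QC practice: INFO ≥ 0.9, SNP call rate ≥
95%, MAF ≥ 5% (from non-missing calls), sample call rate ≥ 90%, then a
second pass dropping variants with exact Hardy–Weinberg $p < 10^{-9}$ on
all retained samples. The HWE test is the exact conditional enumeration
(two-sided: summing probabilities of heterozygote counts no more likely
than observed) rather than the $\chi^2$ approximation, because a
$10^{-9}$ tail is far outside the $\chi^2$'s reliable range; an
independent enumeration oracle covers every table with ≤ 30 alleles in
the tests. Whether HWE should use controls only is a known ambiguity in
case-control settings; it is applied to all samples here as the
phenotype is quantitative.

## The synthetic-cohort generator

`simulate_cohort()` provides the ground truth every downstream test
leans on. Genotypes are two latent-Gaussian haplotype indicator draws
per variant (first-order autoregressive copula, `ld_rho = 0.3` adjacent
correlation, so clumping and regression imputation have structure to
work with); with `n_pops > 1`, per-population allele frequencies come
from the Balding–Nichols model at differentiation `fst`. Causal effects
are $N(0, h^2/n_{\mathrm{causal}})$ on the standardized-genotype scale,
de-standardized per variant; the phenotype adds covariate terms (sex,
age, two binary statuses — effects 1.0, 0.05/yr, 0.5, 0.5, chosen as
modest confounding on a BMI-like scale) and Gaussian noise scaled so the
genetic score's share of total variance hits the target heritability.
All randomness flows from one integer seed through named substreams
(genotypes, effects, noise, missingness, ...), so runs are exactly
reproducible and adding one draw does not shift the others.
`perturb_for_merge()` re-expresses a cohort as a second genotyping-array
view (flips, switches, panel-unique and unresolvable variants) with a
manifest for round-trip checks.

What the generator does *not* emulate: realistic human LD block
structure (only first-order adjacency), allele-frequency spectra skewed
toward rare variants, genotyping batch effects, non-Gaussian phenotypes,
and genuinely polygenic architectures with thousands of sub-threshold
effects. Passing tests therefore demonstrate correctness of the
machinery and recovery of planted parameters, not field performance on
real array data.

## Problem sizes and determinism

The default study configuration — 2,000 samples × 5,000 variants, 50
causal, $h^2 = 0.3$, 100 iterations, two engines — was chosen so a full
derivation runs in minutes on one CPU; unit tests use cohorts of tens to
hundreds of samples. Runtime-critical inner steps are vectorized: a
banded LD cache (block cross-products within the clumping window) is
built once per dataset, threshold and frequency candidates are scored by
single matrix products over nested weight vectors, and per-variant
regressions use one QR of the covariate block per split. Two pipeline
runs with identical config and master seed produce byte-identical
artifacts; this is asserted end to end in the tests.

## Limitations

* **The stabilization bootstrap is regime-dependent.** The aggregated
  score's mean test-split $R^2$ is bounded by the heritability, while
  each baseline value is a per-split maximum over thresholds and
  therefore overshoots on lucky splits. When single iterations already
  recover most of the signal — few causal variants, each with strong
  per-SNP power, as in the default synthetic architecture where each
  causal SNP carries $h^2/50 \approx 0.6\%$ of variance — the baseline
  distribution crowds the ceiling and no aggregated score can exceed its
  maximum: the bootstrap p-value settles well above zero even for the
  true causal model with true effects (the acceptance runs compute this
  explicitly). The dramatic regime — unstable SNP sets, order-of-
  magnitude gains, bootstrap $p = 0$ — arises when the marker panel is
  vastly larger than the causal signal and single-split selection is
  noise-dominated. The test suite demonstrates both regimes: with 100
  small causal effects at 600 samples the aggregated score's mean R²
  is several times the baseline mean and exceeds every baseline value
  (bootstrap p = 0), while with 50 strong effects at 2,000 samples the
  baselines crowd the ceiling and the bootstrap p-value stays large.
  Causal-variant enrichment of the final score is strong in both.
* Binary-trait (logistic) models, mixed models, kinship filtering and
  Bayesian shrinkage weights are out of scope.
* The Tracy–Widom test assumes independent markers; under simulated LD
  it flags a few extra components, which is conservative for its use as
  covariate selection.
* `clump()` measures LD on the supplied dataset (by default the whole
  cohort, computed once); per-split LD differs only by sampling noise
  but is not recomputed.
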