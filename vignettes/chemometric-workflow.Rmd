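---
title: "A chemometric workflow for untargeted LC-MS cell metabolomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A chemometric workflow for untargeted LC-MS cell metabolomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemomet)
```

## The problem

Untargeted LC-MS metabolomics of cultured cells produces a feature table —
samples by features, each feature a peak with an m/z and retention time —
whose variance mixes the biology of interest (here, four treatment groups of
intestinal epithelial cells: control, an antioxidant extract, oxidative
stress, and their combination) with technical nuisance: per-sample dilution
differences, instrumental drift, and batch structure shared across
injections. `chemomet` implements a complete chemometric path from raw
feature table to validated classification and pathway-level interpretation,
together with the mass arithmetic that underlies metabolite annotation and
semi-quantification.

The stages, in order:

1. **Normalization** — median-by-row scaling, then probabilistic quotient
   normalization (PQN) against the element-wise median spectrum of the
   control class, then log10, then autoscaling.
2. **Exploratory PCA** on all samples (technical replicates and pooled QC
   injections included) to locate components dominated by technical
   structure.
3. **Component removal and reconstruction** — subtracting the selected
   score-loading product from the data, then averaging technical
   replicates and refitting PCA with Hotelling T² group ellipses and
   threshold-based loading selection.
4. **PLS-DA** validated by repeated double cross-validation (rDCV) with an
   inner venetian-blinds loop for latent-variable selection, permutation
   testing, and VIP-score feature selection.
5. **Over-representation analysis** of the selected metabolites against a
   pathway library (hypergeometric tail).
6. **Annotation and quantification arithmetic** — monoisotopic masses,
   adduct m/z, ppm errors, calibration curves with LOD/LOQ, and
   equivalents-per-gram conversion.

## Normalization model

Let `x_ij` be the intensity of feature `j` in sample `i` (strictly
positive; zeros are lifted by a pseudo-intensity equal to half the smallest
non-zero value — the default `zero_policy`). Median-by-row normalization
divides each sample by its own median. PQN then estimates a per-sample
dilution factor `s_i = median_j (x_ij / r_j)` where `r_j` is the
element-wise median spectrum of the control class, and divides the sample
by it. Both steps are invariant to multiplying a sample by any positive
constant, which is the defining property a dilution correction must have.
The reference spectrum is the *element-wise median spectrum* of the control
group, not a scalar control median; the scalar reading collapses PQN back
to a single global factor and loses the quotient robustness that motivates
the method. Log10 stabilizes multiplicative variance; autoscaling (mean 0,
unit SD per feature, sample SD with the n−1 denominator) gives every
feature equal leverage in the multivariate models. The n−1 convention is
stated because it perturbs loadings slightly relative to the population SD.

Features whose SD is numerically indistinguishable from rounding noise
(below `1e-10` relative to their mean) are treated as constant and dropped
with a warning before autoscaling.

All fitted constants — the PQN reference, the log offset, the column means
and SDs — are stored in a state object, and `apply_preprocess()` replays
them on held-out samples. Inside cross-validation only training-fold
constants ever touch test samples.

## PCA, component removal, reconstruction

PCA is computed by SVD on the autoscaled matrix with a fixed sign
convention (the largest-magnitude element of each loading vector is made
positive) so loadings and quadrant assignments are reproducible. Explained
variance fractions use all singular values, so they refer to total
variance rather than modelled variance.

Removing a component reconstructs the data as `X - t_d p_d'`. This retains
every source of variance other than the dropped component, including
residual variance beyond the fitted components — the minimal intervention
for excising one systematic artifact. The alternative (rebuilding from the
retained components only) also discards the residual subspace and was
rejected for that reason. The reconstructed matrix is *not* re-autoscaled
before the final PCA: its columns remain near unit scale, and re-scaling
would reinflate exactly the direction that was just removed. Both choices
are switchable by the caller.

Which component to drop is an explicit argument. The helper
`rank_components_by_covariate()` ranks components by correlation with a
nuisance covariate (batch score, injection order), but nothing is dropped
automatically — the decision is a judgment call made by inspecting the
diagnostic PCA, and silently automating it would hide a consequential step.

Group ellipses use Hotelling's T²: with `n` group samples and 2-D score
covariance `S`, the boundary is the set where the quadratic form equals
`c = (2(n-1)/(n-2)) F(0.95; 2, n-2)`; semi-axes are `sqrt(c * eigenvalue)`.
Monte-Carlo coverage of this form is verified in the tests at 10^5 points
(0.95 ± 0.005). Other critical-value variants exist (scaling by `(n+1)/n`
for a new observation); the form above is the one implemented and
documented.

## PLS-DA and validation

PLS-DA regresses a centered one-hot class matrix on the (centered,
optionally scaled) feature matrix. Each latent variable's weight vector is
the dominant left singular vector of the current `X'Y` cross-covariance —
the fixed point NIPALS PLS2 iterates to — followed by standard t/p/q
deflation; this is exactly deterministic, which matters because every
validation layer assumes reruns reproduce bit-identical models. Class
assignment is argmax over predicted responses with ties resolved by class
order.

The latent-variable count is selected by venetian-blinds cross-validation
(after class-stratified ordering, sample `i` goes to fold `i mod k`),
minimizing misclassification with ties to the smaller count. rDCV wraps
this: per repetition, a stratified random split into `outer` cancellation
groups; per outer fold, the inner loop selects the component count on the
training samples only, and a model fit on those samples predicts the
held-out group. Accuracy, per-class sensitivity and specificity are
reported as mean ± SD **over repetitions** (the natural reading of a
repeated procedure; per-fold aggregation would mix two variance sources).
VIP scores use the standard formula
`VIP_j = sqrt(p * sum_a ssy_a (w_aj/||w_a||)^2 / sum_a ssy_a)`, whose mean
square is 1 by construction; the selection frequency counts VIP > 1 across
all outer models, 1 being the natural "above average importance" cutoff.

The permutation test reruns a single-repetition rDCV on label-shuffled
data `B` times and reports `p = (#{null >= observed} + 1)/(B + 1)` — the
add-one form is unbiased and can never return zero. Running the full
repeated procedure inside every permutation would multiply cost by the
repeat count without changing the null's location, so each permutation
uses one repetition.

## Synthetic data: what it emulates and what it does not

`generate_dataset()` produces the study design the analysis assumes: four
classes (control first), biological times technical replicates, pooled QC
injections, and three nuisance processes — a rank-one batch component
(normal scores times a fixed unit loading, on the log10 scale), uniform
per-replicate dilution factors, and i.i.d. log10-scale noise. Intensities
are `10^(baseline + class shift + batch + noise) * dilution`, i.e.
log-normal, matching the pipeline's log transform. Class effects are
planted on a subset of informative features, each affecting one
non-control class with alternating sign; QC samples receive every
technical effect but no class effect, which is what makes them useful as
technical-variance references. The first ten informative features carry
the HMDB identifiers of the bundled example metabolites so the enrichment
stage has realistic input.

Defaults: 5 biological replicates per class, 3 technical replicates, 6
QCs, 200 features of which 20 informative, effect size 1.0 (log10), batch
SD 0.5, dilution in [0.8, 1.25], noise SD 0.1, baselines N(5, 1). The
group sizes are a design choice for a plausible cell-culture experiment —
the underlying study does not report them — and are configurable, not
asserted. The batch effect is rank one because the workflow removes
exactly one component; a single master seed drives every sub-stream.

The generator does **not** simulate raw spectra, retention-time drift,
peak detection, heteroscedastic detector noise, or structured missingness.
Tests passing on this generator therefore demonstrate that the pipeline's
algebra and logic are correct under its stated model, not that the model
captures every pathology of real LC-MS data.

One geometric subtlety the tests respect: autoscaling divides each column
by its SD, so the planted batch loading must be mapped into autoscaled
coordinates (`loading_j / sd_j`, renormalized) before comparing it with
fitted PCA loadings; in raw coordinates the expected cosine is bounded
near `sqrt(2/pi)` for normal loadings and the comparison is meaningless.

## Annotation arithmetic

Monoisotopic masses use fixed atomic constants (H 1.007825032, C 12 exact,
N 14.003074005, O 15.994914620, S 31.972071174, P 30.973761998); adduct
m/z for the registered singly charged forms is
`m*M + dp*1.007276467 - w*18.010565` (multiplicity `m`, proton delta `dp`,
water losses `w`). The electron mass is absorbed into the proton-mass
constant; the difference is orders of magnitude below printed precision.
ppm error is computed at the ion level. Published tables typically print
m/z to 4–5 decimals, which bounds agreement of recomputed ppm errors to
roughly ±0.5 ppm — the bundled ten-record example stays comfortably inside
the 5 ppm identification tolerance. LOD and LOQ use 3.3 and 10 times a
response SD over the slope; the SD is the regression residual SD by
default (the intercept's standard error is selectable), since "the SD of
the calibration curve" is ambiguous in common usage.

## Enrichment

Over-representation uses the exact hypergeometric upper tail via
`phyper`; the test suite cross-checks it against brute-force enumeration
of all draws for universes up to N = 12. Raw p-values are compared with
alpha = 0.05 and no multiple-testing adjustment by default (Benjamini-
Hochberg is available), mirroring common practice for small curated
libraries. The bundled library is a compact curated example (five
pathways, HMDB-coded members, synthetic background identifiers padding the
universe); p-values depend strongly on the universe definition, so the
universe size is always carried in the result table.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run at deliberately small
scale: feature tables of 40–60 features and 20 averaged samples, rDCV with
10 × 10 cancellation groups and 10 repetitions, permutation tests with
B = 99, and Monte-Carlo ellipse coverage at 10^5 points. These sizes keep
a full run around a minute while leaving every statistical property
testable; all of them are arguments, and production-scale settings
(50 repetitions, B = 1000) are a single call away.

Degenerate inputs are handled explicitly: rows with non-positive medians,
all-zero PQN references and zero-variance features are errors or
warnings naming the offender; venetian folds that lose a class raise an
error rather than silently mis-estimating; exact prediction ties resolve
deterministically to the first class in sort order.

## A worked run

```{r example, eval = FALSE}
library(chemomet)

report <- run_pipeline(
  sim_config = simulation_config(n_features = 60, seed = 7),
  drop_pcs = 1,          # after inspecting the diagnostic PCA
  repeats = 10, permutations = 99, seed = 7,
  out_dir = "pipeline_out")
print(report)
```

The report carries the explained-variance fractions before and after
removal, rDCV accuracy with SD, per-class sensitivity/specificity, the
VIP frequency table, the permutation p-value, and the enrichment table;
`write_pipeline_report()` serializes all of it to CSV/JSON.

## Known limitations

- The PQN reference requires a designated control class; unsupervised
  references (overall median spectrum) are a one-line change but not the
  default here.
- rDCV with 10 outer groups and 5 samples per class necessarily produces
  unbalanced cancellation groups (a warning is raised); with very small
  classes the sensitivity SDs are dominated by fold granularity.
- The enrichment stage tests membership only; topology-based pathway
  impact metrics are out of scope, and the optional degree-style weighting
  hooks are deliberately not implemented rather than shipped half-faithful.
- Mass arithmetic covers C/H/N/O/S/P and the six registered adduct forms;
  isotope patterns, multiply charged ions and MS² matching are out of
  scope.
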