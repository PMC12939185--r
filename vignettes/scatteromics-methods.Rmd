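---
title: "Methods: envelope-statistics scatteromics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: envelope-statistics scatteromics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models, estimators, design
choices and limitations. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The problem

Ultrasound speckle carries microstructural information: the probability
distribution of the demodulated echo amplitude (the *envelope*) reflects the
number, organization and strength of sub-resolution scatterers. Fully
developed speckle — many comparable scatterers per resolution cell — has a
Rayleigh envelope. Sparse scatterers, or scatterers with widely varying
cross-sections, produce heavier-tailed *pre-Rayleigh* statistics. Liver
fibrosis increases the variance of scattering cross-sections and drives the
envelope pre-Rayleigh; hepatic steatosis increases the number of scatterers
and pushes it back toward Rayleigh. Because both processes move the same
scalar summaries, single-parameter imaging confounds them; the package's
purpose is the *scatteromics* workflow, which classifies subjects from a
small, interpretable set of first-order statistics computed over several
envelope-statistics parametric maps at once.

## Envelope models and estimators

Three models of backscattered envelope statistics are used side by side.

**Nakagami.** The envelope amplitude $A$ has intensity $I = A^2$ following a
gamma law; the shape $m$ is estimated by the moment estimator
$\hat m = \overline{I}^2 / \widehat{\operatorname{Var}}(I)$ with the
population (1/n) variance, and the scale by $\hat\Omega = \overline{I}$.
$m = 1$ at Rayleigh; $m < 1$ pre-Rayleigh.

**Homodyned K (HK).** The envelope is
$A = |\varepsilon + X + iY|$ with mixing variable
$z \sim \mathrm{Gamma}(\alpha, 1)$ and diffuse quadratures
$X, Y \mid z \sim N(0, \sigma^2 z)$. $\alpha$ is the scatterer clustering
parameter. The coherent amplitude is parameterized as
$\varepsilon = k\,\sigma\sqrt{2\alpha}$ so that
$k^2 = \varepsilon^2 / (2\sigma^2\alpha)$ is exactly the coherent-to-diffuse
power ratio; the simulator (`sample_hk()`) and the estimator
(`hk_estimate_xu()`) share this one convention, which is what makes
estimator-recovery tests meaningful.

The XU estimator works from two scale-invariant intensity log-moments,
$U = \mathbb{E}[\log I] - \log \mathbb{E}[I]$ and
$X = \mathbb{E}[I \log I]/\mathbb{E}[I] - \mathbb{E}[\log I]$. The forward
map $(\alpha, k) \mapsto (U, X)$ is computed by Gauss–Legendre quadrature
over the gamma mixing density, using the Poisson-mixture representation of
the conditional noncentral-$\chi^2$ intensity, whose log-moments reduce to
fast Poisson-weighted digamma sums (exact truncated sums below
$\theta = 500$, a fourth-order cumulant expansion above). Inversion is
three-staged:

1. **Parsimony gate.** The K-distribution submodel ($k = 0$) is fitted from
   $U$ alone. If the residual in $X$ is within `gate_tau` (default 2.5)
   plug-in standard errors — estimated from the sample by the delta method —
   the $k = 0$ solution is kept. Near the $k = 0$ boundary the joint
   $(U, X) \to (\alpha, k)$ inversion is badly conditioned (the two Jacobian
   columns become nearly collinear), and the gate removes most of the
   boundary variance at negligible cost elsewhere.
2. **Grid initialization.** A lazily built, session-cached 61 × 41 table of
   the forward map over $\alpha \in [0.1, 100]$ (log-spaced),
   $k \in [0, 3]$ provides the nearest starting cell and a continuous
   bilinear-surface minimization.
3. **Refinement.** Up to `refine_iter` (default 3) damped Gauss–Newton steps
   on the exact quadrature forward model polish the estimate. Estimates are
   clipped to the covered domain with a `boundary` flag.

A genuine limitation, documented rather than hidden: at large $\alpha$ with
small-to-moderate $k$ (for example $\alpha = 8$, $k = 0.4$), a 10 % change
in $\alpha$ moves $(U, X)$ by roughly the sampling error of those statistics
at $n = 10^6$. No inversion built on these two log-moments can beat that
identifiability floor, so occasional larger excursions there are intrinsic
to the estimator contract, not numerical defects.

**Entropy.** Shannon entropy $H$ of the envelope sample, by the histogram
method: equal-width bins between the sample min and max (default
`entropy_bins = 40`, a few dozen bins being the conventional choice; the
exact count used in prior art is not standardized), probabilities from
counts, $H = -\sum p_i \log_2 p_i$ in bits. With bins tracking the sample
range, $H$ is scale-invariant.

## Parametric imaging

Maps are computed with the sliding-window technique at 50 % overlap (steps =
⌈side/2⌉). Window sides are physical: 3 pulse lengths for the Nakagami map,
5 for the HK maps, and 1 for entropy, converted per axis (axial spacing
$c/2f_s$; lateral pitch from the acquisition metadata). The pulse length is
read from the frame metadata — the simulator writes its ground truth, and
real acquisitions would supply the transducer specification; no
autocorrelation-based measurement is attempted. How the lateral window size
should be derived on a convex probe is not standardized; the physical-square
convention is this package's choice and is recorded here for anyone
comparing against other systems. Map cells are window centers on a 0-offset
grid recorded in `origin`, so ROI masks drawn on the image grid can be
resampled onto map grids (a cell is in-ROI iff its center pixel is masked).
Windows with fewer than 10 samples, or on which an estimator fails (e.g.
zero variance), yield flagged-invalid `NA` cells rather than errors.

## The simplified feature set

Each subject contributes 13 first-order statistics per map × 4 maps = 52
features. Definitions follow the conventional formulas: 1/n moments, excess
kurtosis (normal ⇒ 0), type-7 (linear-interpolation) quantiles, and — since
the mode of continuous data is otherwise ill-defined — the center of the
maximal-count bin of a 50-bin equal-width histogram, ties to the lowest bin.
`first_order_features()` accepts any ≥ 2 finite values (all 13 statistics
are well defined there); the scientifically motivated minimum of 5 valid
cells is enforced at ROI extraction. Zero-variance inputs flag skewness and
kurtosis as `NA`; in phantom cohorts with a weak coherent component the k
map is often uniformly zero inside the ROI, so `k_skewness`/`k_kurtosis`
are legitimately degenerate and drop out of selection.

## Feature selection

Per training fold only: Z-score normalization (parameters frozen and applied
to validation/test data), LASSO logistic regression over a 50-point
log-spaced penalty grid on $[10^{-4}, 10]$ with the penalty chosen by
internal stratified 5-fold cross-validated deviance (minimum rule; the
binary outcome makes the logistic family the natural reading of "LASSO
regression"), then redundancy pruning: pairs with Spearman $|\rho| > 0.8$
are processed in descending $|\rho|$, and the member with the smaller raw
(pre-normalization) dynamic range is removed — after Z-scoring all ranges
are nearly equal and the rule would be vacuous. Tied ranges drop the second
member of the pair. Retention probabilities are the fraction of cycles in
which each feature survives both stages.

## Classification and validation

`scatteromics()` runs 30 repeats of stratified 5-fold cross-validation (150
cycles at the defaults), with the entire selection pipeline refit inside
every training fold — the no-leakage property is asserted by tests that
check bit-identical selection under permuted held-out data and exact
subject-level partitions. Three classifier families are trained per cycle:

* **SVM** — kernels {linear, RBF, polynomial degree 3} × 5 log-spaced box
  constraints in $[0.1, 10]$, chosen by inner stratified 5-fold
  misclassification; probabilities via a monotone logistic (Platt) map
  fitted on inner out-of-fold decision values.
* **Random forest** — trees {100, 250, 500, 1000} × minimum leaf sizes
  {1, 5, 10, 20}, same inner-CV rule; probabilities from vote fractions.
* **LDA** — no hyperparameters; posterior probabilities; the discriminant
  coefficients are exported as feature weights (`$weights`), which is this
  package's concrete reading of "discriminant-based feature weighting".

Each cycle's operating threshold maximizes the Youden index
$J = \text{sens} + \text{spec} - 1$ over midpoints between sorted unique
validation scores (ties → lowest threshold). Per kind, the model from the
highest-validation-accuracy cycle is stored — accuracy at the Youden
threshold, ties to the earlier cycle — together with its normalization and
selection state, and applied to independent test tables without refitting
anything.

## Evaluation

AUROC is the pairwise concordance (Mann–Whitney) statistic, ties counting
one half; its 95 % CI uses the Hanley–McNeil asymptotic variance (the CI
method is recorded in report metadata so a resampling CI can be swapped in).
The confusion panel reports sensitivity, specificity, PPV, NPV,
$F_1 = 2\,\mathrm{PPV}\cdot\mathrm{sens}/(\mathrm{PPV}+\mathrm{sens})$,
$LR^+ = \mathrm{sens}/(1-\mathrm{spec})$,
$LR^- = (1-\mathrm{sens})/\mathrm{spec}$ and balanced accuracy, with zero
denominators flagged (`Inf`/`NA`) rather than erroring. Calibration uses ten
equally spaced probability bins of pooled out-of-fold predictions (empty
bins kept and flagged), alongside the Brier score. Group comparisons of
per-subject map means use the classical one-way equal-variance ANOVA F;
no multiple-testing correction is applied, matching per-parameter
reporting conventions.

## The phantom: what it emulates and what it does not

The simulator builds each scan line as a 1-D convolution of a random
point-scatterer reflectivity train with a Gaussian-modulated sinusoid
(default 3.5 MHz center frequency, 12 MHz sampling, fractional bandwidth
0.6 — the acquisition constants of the motivating clinical protocol; the
quoted pulse length is the −20 dB amplitude extent, ≈ 0.59 mm). Scatterer
density is expressed per resolution cell, and the rate is normalized by the
*equivalent width* $(\sum w^2)^2 / \sum w^4$ of the squared point-spread
function per axis — with a Gaussian lateral beam kernel spanning
`cell_lines` (default 2) scan lines — so that the effective number of
independent contributors per cell equals the nominal density. Without this
normalization the Gaussian taper silently deflates the effective scatterer
number by ~3× and "20 per cell" would not produce Rayleigh speckle.

Two physical axes generate class structure:

* **Density** (steatosis axis): more scatterers per cell ⇒ Rayleigh-ward
  shift (higher m, α, H). Steatosis-flagged subjects (fraction 0.6 per
  class, matching the ~57–68 % steatosis prevalence of the motivating
  cohort) receive a ×1.5 density multiplier.
* **Cross-section heterogeneity** (fibrosis axis): per-scatterer lognormal
  cross-sections with log-sd $h$ lower the effective scatterer number by
  $\approx e^{-4h^2}$ at unchanged density, driving the envelope
  pre-Rayleigh — the stated mechanism by which fibrosis alters speckle.

A sub-resolution periodic lattice (spacing 0.44 mm ≈ two carrier
wavelengths, amplitude 0.3) adds a weak coherent component. The class
presets were calibrated by stochastic search against the published
training-cohort class means of windowed m and α (healthy-like: m 0.82,
α 7.43; early-fibrosis-like: m 0.73, α 4.18) at a target tolerance of
±10 % on class means; the frozen presets share one median density (4.3 per
cell) and differ in heterogeneity ($h$ 0.15 vs 0.33) and between-subject
spread (density log-sd 0.5 vs 0.3, reproducing the wider healthy-class
dispersion). The windowed $\hat m$ and $\hat\alpha$ class means are
confined to a one-dimensional manifold in this simulator — anything that
raises one raises the other — so all four targets cannot be met jointly:
the frozen calibration realizes α means within about +5 to +11 % and m
means about 11–12 % low (precisely measured over pooled 90-subject-per-
class replicates), which approximately minimizes the worst-case violation.
Deliberately *not* reproduced: the published k (≈ 0.44) and H (≈ 5.22)
class means — a coherent component strong enough for k ≈ 0.44 drives m far
above its target in this simulator, and the entropy level is capped by the
one-pulse-window sample count; m and α were prioritized as the parameters
with the broader dynamic range (k shows no significant stage effect in the
motivating data). Also not modeled: beamforming and convex-probe scan
geometry, attenuation/TGC, acquisition noise (optional white noise is off
by default), anatomically realistic liver structure, and any within-subject
multi-scan variability. Passing tests on this phantom therefore demonstrate
the *pipeline's* correctness and its null calibration and power under a
controlled two-mechanism world — not clinical performance.

## Problem sizes

Default test-scale conditions: frames of 1024 axial samples × 64 lines
(pipeline tests and the reproduction script), 30 subjects per class, and
5 repeats × 5 folds for cohort-level cross-validation (the reproduction
script replicates the cohort experiment three times); unit tests use
smaller frames and the feature-space generator `demo_feature_table()`. The
structural 150-cycle count runs the full 30 × 5 outer CV with single-point
hyperparameter grids, since the count is outer-loop bookkeeping and
independent of grid size. Estimator-recovery checks use $n = 10^5$
(Nakagami) and $n = 10^6$ (homodyned K) samples.

## Numerical conventions

* Sub-seeds for every stochastic step derive from one master seed via a
  32-bit linear-congruential hash; identical spec + seed ⇒ bit-identical
  cohorts, cross-validation runs and serialized reports.
* Quantiles: type 7; variance: 1/n where the feature-set formulas say so,
  $n-1$ in Z-score normalization (the usual `sd()` convention; the
  difference is absorbed by the frozen normalization parameters).
* Histogram binning: `findInterval` with the right edge closed on the last
  bin, so the sample maximum is counted.
* Degenerate inputs are flagged, not fatal: invalid map cells, empty-ROI
  errors naming the subject, constant features excluded from selection with
  a log, zero-denominator metrics flagged `Inf`/`NA`, boundary-clipped HK
  estimates flagged.
* The ANOVA worked example in the test suite fixes
  $F = (54/2)/(6/6) = 27$ for the groups {1,2,3}, {4,5,6}, {7,8,9},
  cross-checked against `stats::oneway.test(var.equal = TRUE)`.

## Known limitations

* Two-log-moment HK estimation has an intrinsic identifiability floor at
  large α (see above); boundary flags should be inspected when mapping
  tissue with near-Rayleigh statistics.
* The phantom's two-axis class structure is a deliberate simplification;
  real liver texture adds spatial correlation structure, attenuation and
  operator variability that the feature distributions here do not contain.
* With ~50 training subjects the LASSO + grid-search pipeline is variance-
  dominated; cycle AUROCs spread widely, which is why validation checks
  compare medians over cycles rather than single splits.
* At 30 subjects per class the cohort draw itself is a major variance
  source: because the healthy-like class has a broad lognormal density
  spread, individual 60-subject cohorts range from strongly separable
  (median cycle AUROC near 0.9) to nearly uninformative (a selection-free
  random forest on the weakest observed draw reached only 0.57). The
  reproduction script therefore replicates the cohort experiment three
  times and pools cycle AUROCs; single-cohort results should be read with
  this spread in mind.
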