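---
title: "Estimating intrinsic neural timescales and their mediation structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating intrinsic neural timescales and their mediation structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurotime)
```

## The statistic

The intrinsic neural timescale (INT) of a voxel is defined from the
sample autocorrelation function (ACF) of its preprocessed BOLD series.
With $\hat\rho(k)$ the biased ($1/n$-normalised) autocorrelation of the
mean-centred series at lag $k$, and $m$ the number of leading lags whose
autocorrelation is strictly positive before the ACF first reaches zero,

$$\mathrm{INT} = \mathrm{TR}\cdot\sum_{k=1}^{m}\hat\rho(k).$$

The statistic is a unit-width (left Riemann) area under the initial
positive segment of the ACF, in seconds. It is nonnegative by
construction, zero exactly when $\hat\rho(1)\le 0$, and invariant to
affine rescaling of the input because the ACF is scale- and
shift-invariant. For a stationary AR(1) process with coefficient $\varphi$
the population analogue has the closed form
$\mathrm{TR}\cdot\varphi/(1-\varphi)$, which is how the synthetic
generator converts latent timescales into AR coefficients
(`ar1_int()` / `ar1_phi_for_int()`).

Estimator conventions, each exposed as an argument:

* **Lag 0 is excluded** by default. Its contribution is identically
  $\mathrm{TR}\cdot 1$ for every voxel, so including it
  (`include_lag0 = TRUE`) shifts every map by a constant and leaves group
  differences and correlations untouched; the flag exists for
  compatibility checks against implementations that include it.
* **Termination is at the first lag with $\hat\rho \le 0$** — a tie at
  exactly zero ends the window.
* **The biased ACF estimator** is used rather than the $1/(n-k)$
  unbiased one: it guarantees damping at long lags on short series,
  the standard choice in the timescale literature.
* **Riemann vs trapezoid.** The default treats ACF values as unit-width
  bars; `method = "trapezoid"` integrates the polyline through
  $(0, 1), (1, \hat\rho(1)), \ldots$ instead.
* The lag horizon defaults to half the series length; in practice the
  positive window terminates far earlier, and `int_from_series()`
  extends an initially short horizon adaptively.

Degenerate voxels (zero variance, non-finite values) are flagged
undefined (`NA`) and excluded from every downstream average — never
silently zero-filled, which would bias regional means downward.

## Preprocessing

The temporal chain is fixed in the order discard → confound regression →
band-pass:

* `discard_initial_volumes()` drops the scanner-equilibration lead-in
  (default 5 volumes).
* `regress_confounds()` removes an intercept plus the six motion
  parameters and the white-matter and CSF signals by least squares.
  Residuals are orthogonal to every confound column to numerical
  precision. Columns enter on their native scales (projection is
  scale-invariant). A 24-parameter motion expansion (derivatives and
  squares) is available via `expand_motion = TRUE`; six parameters is
  the default, with no claim that either matches any particular upstream
  pipeline.
* `bandpass_filter()` applies a zero-phase forward–backward Butterworth
  band-pass, order 2 per pass, 0.01–0.1 Hz by default — the conventional
  resting-state band. Because the zero-phase filter is one fixed linear
  operator for a given series length, the package materialises it once
  (by filtering the identity basis) and applies it as a matrix product
  across all voxels. Edge transients on short series are suppressed by
  odd-reflection padding of at least one low-frequency period.
* `framewise_displacement()` uses the Power-style sum of absolute
  backward differences, with rotations converted to arc length on a
  50 mm sphere. Subject exclusion (`qc_filter_subjects()`) is by mean
  motion above 3 mm by default; a maximum-FD criterion is available.

Both regression and filtering are linear operators, and the test suite
asserts linearity directly, along with pass-band (0.05 Hz tone retained
within 10%) and stop-band (0.2 Hz tone attenuated below 20%) contracts at
TR 2.2 s.

## Smoothing and summarisation

`smooth_map()` smooths INT maps with a separable Gaussian kernel,
$\sigma_{mm} = \mathrm{FWHM}/\sqrt{8\ln 2}$ (8 mm FWHM default, i.e.
$\sigma = 0.849$ voxels on the 4 mm grid). Smoothing is mask-aware: the
map (undefined voxels as zero mass) and the defined-voxel indicator are
smoothed with the same kernel and their ratio taken, so background never
dilutes in-mask values and a constant map is reproduced exactly.

Network summaries are arithmetic means over all defined voxels of the
parcels assigned to a network; spherical ROIs (`sphere_roi()`, 4 mm
radius default) include every voxel whose centre lies within the radius,
boundary inclusive — on a 4 mm grid a 4 mm sphere centred on a voxel
centre therefore contains exactly 7 voxels, which keeps the ROI
nondegenerate and exactly testable. Partial-volume weighting is
deliberately not used.

## Group statistics

* `two_sample_t()` is the pooled-variance Student test. The pooled form
  (not Welch) is chosen because the reported degrees of freedom in this
  literature equal $n_a + n_b - 2$, which identifies it.
  $\eta^2 = t^2/(t^2+df)$ is attached to every result.
* `pearson_bootstrap()` resamples subject pairs with replacement; the
  two-tailed p is twice the smaller zero-crossing fraction of the
  bootstrap correlations, floored at $1/n_{boot}$. A percentile
  construction is used rather than BCa — the simplest choice consistent
  with "non-parametric bootstrap", and it is labelled as such in outputs.
* `cluster_fwe_perm()` implements cluster-level family-wise error
  control by permutation rather than random-field theory: voxelwise
  t maps from the GLM (intercept, group, age, sex) are thresholded at a
  two-tailed $p < 0.001$ cluster-forming level, clusters are labelled by
  face (6-)connectivity (18/26 available), and each observed cluster's
  $p_{FWE}$ is the fraction of group-label permutations whose maximal
  cluster size reaches the observed size. Only the group labels are
  permuted; covariates stay fixed. Permutation makes no distributional
  or smoothness assumptions, at the cost of a granularity of
  $1/n_{perm}$ in the p values (default 1000 permutations).

## Mediation

`fit_mediation()` estimates the standard three-variable paths by OLS:
$a$ from $M \sim X$, $b$ and $c'$ from $Y \sim X + M$, $c$ from
$Y \sim X$, indirect effect $ab$. For nested OLS fits on one sample the
decomposition $c = c' + ab$ holds exactly, and the tests assert it to
$10^{-10}$. Inference is by resampling subjects with replacement,
percentile CIs, and the same sign-crossing two-tailed p as the
correlations. Two-tailed p values are reported throughout (the
alternative was not specified in the tradition this follows, and
two-tailed is conservative). Variables enter on their native scales; no
covariates are included inside the mediation regressions by default
(nuisance adjustment is confined to the voxelwise GLM), though a
`covariates` hook exists.

`run_model_suite()` fits the full battery per focal ROI: both
orientations of the local-INT / network-INT / symptom chain, the
structural models with GMV as the exogenous variable, the reversed
sensitivity model with GMV as mediator, and the six control-network
substitutions. Each model is gated by the pairwise-correlation
precondition screen (mediation is only interpretable when all three
pairs correlate); gated-out models are reported "not evaluated" with the
failing pair named. Bonferroni correction is applied over focal ROIs
within each model family.

## Cognitive components

`componentize()` z-scores each raw test against a reference population —
by default the CN group, since no external norms are assumed — inverts
the Trail-Making completion times so that higher always means better,
and averages member tests within multi-test components with equal
weights (the combination rule is a package choice; analysing members
separately is a reasonable alternative). Pearson correlations are
invariant to the affine z-scoring, so the reference choice affects the
z values but not the component–INT correlations; only the averaging
weights of multi-test components can shift them. Bonferroni correction
uses $m = 5$ components, and per-component complete-case sample sizes are
reported because missingness differs across tests.

## The synthetic cohort

`cohort_spec()` defines the study conditions; `simulate_cohort()` is a
pure function of it (every random stream is derived from the master seed
by stable hashing of the subject id, so cohorts are byte-reproducible).

Defaults mirror the acquisition and sample this package targets: 138 CN
and 32 AD subjects (so the group t test has 168 df), TR 2.2 s, 160
retained volumes after a 5-volume lead-in (≈ 6 min of data), a
20×20×12 grid at 4 mm isotropic resolution. The toy atlas holds a DMN
core, focal AG and SMG parcels (all three DMN members), and six disjoint
control networks.

The generative model is latent-timescale based:

* each subject draws a latent AG timescale around their group mean
  (CN φ = 0.65 vs AD φ = 0.45 in the AG — the planted focal deficit —
  with between-subject spread 1.2 s);
* the latent DMN timescale follows the planted slope
  $\tau_{DMN} = a_{gen}\,\tau_{AG} + \varepsilon$ with $a_{gen} = 0.8$;
* AG grey-matter volume is a linear function of the latent AG timescale
  (coupling 0.35 a.u./s, residual SD 0.8 — giving a GMV–INT correlation
  near 0.45); SMG GMV has a group offset but no timescale coupling, so
  the structural chain is planted for the AG only;
* MMSE is generated from the *latent* timescales
  ($b_{gen} = 0.6$ per second of DMN timescale, direct effect
  $c'_{gen} = 0$), then rounded and clamped to [0, 30]. Generating
  symptoms from the latent rather than the estimated timescales keeps
  simulation and inference separate: estimator noise then attenuates
  recovered paths but cannot bias them upward;
* only digit span (the attention component) is coupled to the latent DMN
  timescale; the other six battery scores are independent noise, so the
  component analysis has a one-hot ground truth;
* nuisance signals — slow sinusoidal motion traces, low-frequency
  white-matter/CSF noise — are mixed into all parcel voxels with random
  weights, giving the confound-regression stage real work; background
  voxels are pure white noise.

These coefficient choices were fixed once, to land the planted
correlations near the magnitudes reported for real cohorts of this kind
(local-to-network INT correlation ≈ 0.8, GMV–INT ≈ 0.45, network
INT–symptom ≈ 0.5–0.6), i.e. for realistic statistical power rather than
to match any unpublished value ranges.

What the generator does **not** emulate: haemodynamic response shape,
spatial autocorrelation of the noise (beyond the explicit smoothing
stage), scanner drift nonstationarity, T1 anatomy (GMV enters as per-ROI
scalars because voxel-based morphometry is out of scope), and spatial
normalisation (volumes are born aligned). Passing tests therefore
demonstrate the correctness and calibration of the estimators and
inference machinery under a known ground truth — not robustness to the
full physics of real acquisitions.

## Numerical and design choices

* Timescale latents are clamped to $[0.1, 6]\cdot\mathrm{TR}$ so AR
  coefficients stay inside (0, 1).
* The estimated INT is attenuated relative to the latent timescale —
  band-pass filtering reshapes the ACF and finite series truncate the
  positive window. All downstream inference uses monotone recovery
  (ordering, correlation), never absolute agreement with the latent
  value, and the tests assert strict monotonicity of mean estimated INT
  in φ.
* Permutation p values use the plain exceedance fraction; a planted
  effect can therefore report $p_{FWE} = 0$ at finite $n_{perm}$, which
  is read as $p < 1/n_{perm}$.
* Pipeline TSV outputs are rounded to 6 decimals so reruns are
  byte-identical across platforms.
* One master seed fans out to per-subject and per-stage streams through
  a stable multiplicative string hash (`derive_seed()`), keeping every
  derived seed below $2^{31}$.

## Validation problem sizes

The acceptance-style tests run at desk scale, chosen as this package's
own simulation-study sizes: estimator–oracle equivalence on 50 series of
$10^5$ points per φ ∈ {0.2, 0.5, 0.8}; mediation recovery over 20
replicates of n = 200 (and a 100-replicate null for type-I error of the
indirect effect, asserted ≤ 0.08 at nominal 0.05, the product test being
conservative); model-suite asymmetry over 20 replicate cohorts with 100
AD subjects using the parcel-series summary path (`cohort_summary()`,
which averages the estimator over a few independent series per parcel to
emulate map-level averaging without volumetric cost); permutation-FWE
calibration over 20 null image cohorts of 12 + 12 subjects at 300
permutations, with detection checked on a planted AG deficit
(φ 0.8 vs 0.5, 15 + 15 subjects, 500 permutations); and byte-level
determinism of two identical pipeline runs.

## Known limitations

* The mediation models are associational: no counterfactual estimands,
  no longitudinal ordering. The asymmetry between a significant forward
  model and a null reversed model is evidence of consistency with the
  planted chain, not proof of causation.
* The ACF-area statistic is one of several timescale definitions;
  spectral (Lorentzian knee) and exponential-fit estimators are distinct
  literatures and intentionally out of scope.
* Cluster inference on the toy grid uses few voxels; real-resolution
  maps would make the permutation loop the dominant cost, and the
  cluster-forming threshold (0.001 two-tailed) would deserve
  sensitivity analysis there.
* The motion-exclusion rule is a subject-level mean-displacement
  threshold; frame censoring/scrubbing is not implemented (exclusion,
  not censoring, is the modelled policy).
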