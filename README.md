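# neurotime

Intrinsic neural timescale (INT) mapping and mediation analysis for
resting-state fMRI, with a fully synthetic validation cohort.

## The scientific problem

Cortical regions differ in how long they integrate their inputs. A
practical, model-free index of this "intrinsic neural timescale" can be
read off the temporal autocorrelation of the resting-state BOLD signal: at
every voxel, estimate the sample autocorrelation function (ACF) of the
preprocessed series, sum it over the initial run of positive lags, and
scale by the repetition time:

```
INT = TR * sum_{k=1..m} rho(k),   m = last lag before rho first reaches 0
```

Long-INT regions (default mode network, frontoparietal cortex) integrate
information over seconds; sensory cortices are fast. In
neurodegeneration, focal atrophy of a hub region — the left angular gyrus
(AG) of the default mode network (DMN) — is hypothesised to shorten that
region's timescale, destabilise the timescale of the whole network, and
thereby contribute to cognitive symptoms. Testing that chain requires, on
top of the voxelwise INT estimator:

* temporal preprocessing (lead-in volume discard, nuisance regression of
  motion/white-matter/CSF signals, 0.01–0.1 Hz band-pass, motion QC),
* mask-aware Gaussian smoothing and network / spherical-ROI summaries,
* group statistics: pooled-variance t tests with η² = t²/(t²+df),
  bootstrap Pearson correlations (10 000 resamples), Bonferroni
  correction, a voxelwise GLM with age/sex covariates, and
  permutation-based cluster-level family-wise error control,
* non-parametric bootstrap mediation over
  (regional grey-matter volume, local INT, network INT, MMSE), fitting
  paths `a` (X→M), `b` (M→Y|X), `c` (total), `c'` (direct) and the
  indirect effect `ab` with percentile confidence intervals,
* z-scored cognitive-component correlations (attention, processing speed,
  executive, memory, language; Trail-Making scores inverted).

`neurotime` implements this whole chain as tidyverse-style R functions
(tibbles in, tibbles out; `tidy()`/`glance()`/`autoplot()` methods), plus
a synthetic two-group cohort generator whose voxels are AR(1) processes
with known region- and group-dependent timescales and a *planted*
mediation structure (GMV → AG INT → DMN INT → MMSE). Because the ground
truth is known, every stage can be validated: estimator consistency,
filter contracts, permutation calibration, and recovery of the planted
causal chain.

## Worked example

```r
library(neurotime)

cfg <- default_config(seed = 42)   # 138 CN + 32 AD, TR 2.2 s, 160 volumes
cfg$stats$n_perm <- 500
man <- run_pipeline(cfg, "results/full_run")
r <- man$results

r$group$dmn_test
#> t(161) = 1.964, p = 0.05121, eta^2 = 0.023
r$group$dmn_mmse
#> r = 0.649 (n = 30), bootstrap p = 0.0001, 95% CI [0.491, 0.779]
r$clusters
#>   cluster size_voxels peak_t peak_x_mm peak_y_mm peak_z_mm p_fwe
#> 1       1          27   7.04       -26        14        -2 0.002
dplyr::filter(r$mediation, evaluated)[, c("model", "ab", "p", "p_bonferroni")]
#>   local_to_network  2.261  0.0436  0.0872
#>   network_to_local  1.121  0.5550  1.0000
#>   gmv_to_network    0.104  0.0012  0.0024
#>   gmv_to_symptoms   0.460  0.0010  0.0020
#>   reversed_gmv     -0.031  0.6334  1.0000
```

Reading the output: the AD group's DMN timescale is shorter (the group
test borders significance at this cohort size), the voxelwise comparison
finds exactly one supra-threshold cluster, whose peak sits in the AG
parcel and survives permutation FWE (p = 0.002); within the AD group the
DMN timescale tracks MMSE (r = 0.65); the mediation suite recovers the
planted structural chain — GMV → AG INT → DMN INT is significant while
the reversed model (AG INT → AG GMV → DMN INT) is null — and of the five
cognitive components only attention correlates with DMN INT after
Bonferroni correction (r = 0.70, corrected p = 0.001). That is precisely
the planted ground truth.

Individual stages are ordinary functions and compose with the pipe:

```r
spec   <- cohort_spec(n_cn = 20, n_ad = 20, seed = 7)
cohort <- simulate_cohort(spec)
s      <- cohort$subjects[["AD001"]]
map <- s$bold |>
  preprocess_bold(s$confounds) |>
  compute_int_map(mask = cohort$atlas$labels > 0) |>
  smooth_map(fwhm_mm = 8)
network_mean(map, cohort$atlas, "DMN")
autoplot(map)
```

A minimal shell interface is installed at
`system.file("scripts/ntpipe.R", package = "neurotime")`
(`Rscript ntpipe.R run --out DIR --seed N`, or `simulate` to write the
synthetic NIfTI/TSV cohort only).

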