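#' Population intrinsic timescale of an AR(1) process
#'
#' For a stationary AR(1) process the population autocorrelation is
#' `phi^k`, all lags positive, so the timescale defined as the
#' repetition-time-scaled sum of the ACF over positive lags has the closed
#' form `tr_s * phi / (1 - phi)`. `ar1_phi_for_int()` is the inverse map,
#' used by the cohort generator to translate a subject's latent timescale
#' (seconds) into the AR(1) coefficient of their voxel series.
#'
#' @param phi AR(1) coefficient in `(0, 1)`.
#' @param int_s Timescale in seconds, `>= 0`.
#' @param tr_s Repetition time in seconds.
#' @return A numeric vector.
#' @export
ar1_int <- function(phi, tr_s) {
  stopifnot(all(abs(phi) < 1), tr_s > 0)
  tr_s * phi / (1 - phi)
}

#' @rdname ar1_int
#' @export
ar1_phi_for_int <- function(int_s, tr_s) {
  stopifnot(all(int_s >= 0), tr_s > 0)
  int_s / (int_s + tr_s)
}

#' Simulate a stationary AR(1) time series
#'
#' `x_t = phi * x_{t-1} + e_t` with `e_t ~ N(0, sd^2)`, initialised from the
#' stationary distribution `N(0, sd^2 / (1 - phi^2))` so the whole series is
#' stationary from the first sample. Reproducible for a given seed.
#'
#' @param phi AR(1) coefficient, `|phi| < 1`.
#' @param n Number of time points, `>= 2`.
#' @param sd Innovation standard deviation, `> 0`.
#' @param seed Integer seed.
#' @return Numeric vector of length `n`.
#' @export
simulate_ar1 <- function(phi, n, sd = 1, seed = 1) {
  if (!is.numeric(phi) || length(phi) != 1 || !is.finite(phi) || abs(phi) >= 1) {
    abort("`phi` must satisfy |phi| < 1 (stationarity)")
  }
  stopifnot(.is_count(n), n >= 2, sd > 0)
  withr::with_seed(seed, {
    x0 <- rnorm(1, 0, sd / sqrt(1 - phi^2))
    e <- rnorm(n - 1, 0, sd)
    c(x0, as.numeric(stats::filter(e, phi, method = "recursive", init = x0)))
  })
}

#' Specify a synthetic two-group cohort
#'
#' Captures every knob of the synthetic study: group sizes, acquisition
#' parameters, the AR(1) coefficient of each parcel in each group, the
#' between-subject spread of latent timescales, the grey-matter-volume
#' coupling, the planted mediation coefficients (local AG timescale ->
#' network DMN timescale -> MMSE), confound amplitudes and the master seed.
#'
#' Defaults mirror the study conditions the package targets: 138 cognitively
#' normal (CN) and 32 Alzheimer's-type (AD) subjects (so a two-sample t on
#' the groups has 168 degrees of freedom), TR 2.2 s, 160 retained volumes
#' after discarding 5 lead-in volumes, an AD-specific timescale deficit in
#' the AG parcel, GMV coupled to the generative AG timescale, and symptom
#' scores generated from the generative (not estimated) timescales.
#'
#' @param n_cn,n_ad Subjects per group.
#' @param n_timepoints Retained volumes per subject.
#' @param n_discard Lead-in volumes prepended by the scanner model.
#' @param tr_s Repetition time, seconds.
#' @param phi_by_region_and_group Named list with elements `CN` and `AD`,
#'   each a named vector mapping parcel name to the group-mean AR(1)
#'   coefficient.
#' @param tau_sd_s Named vector: between-subject SD (seconds) of the latent
#'   timescale for `ag`, `dmn` (residual about the planted slope) and
#'   `other` parcels.
#' @param noise_sd Innovation SD of the voxel AR(1) processes.
#' @param gmv_int_coupling Slope of AG grey-matter volume on the generative
#'   AG timescale (a.u. per second).
#' @param gmv_sd Residual SD of the GMV scalars.
#' @param smg_gmv_offset_ad Additive AD shift of SMG GMV (a.u.); SMG GMV is
#'   deliberately uncoupled from the SMG timescale.
#' @param mediation_coeffs Named vector `a_gen` (AG timescale -> DMN
#'   timescale), `b_gen` (DMN timescale -> MMSE), `cprime_gen` (direct AG
#'   timescale -> MMSE).
#' @param mmse_base Named vector of group baseline MMSE (`CN`, `AD`).
#' @param mmse_sd Residual SD of MMSE before rounding/clamping.
#' @param confound_amplitudes Named vector `motion` (mm), `wmcsf` (a.u.):
#'   scale of the planted nuisance signals; set to zero for confound-free
#'   data.
#' @param motion_outlier_rate Fraction of subjects given mean motion above
#'   the usual 3 mm exclusion threshold.
#' @param battery_missing_rate Per-score missingness rate of the cognitive
#'   battery.
#' @param seed Master seed; every artifact of the cohort derives from it.
#' @return An object of class `cohort_spec` (a validated list).
#' @export
cohort_spec <- function(n_cn = 138, n_ad = 32,
                        n_timepoints = 160, n_discard = 5, tr_s = 2.2,
                        phi_by_region_and_group = NULL,
                        tau_sd_s = c(ag = 1.2, dmn = 0.8, other = 0.5),
                        noise_sd = 1,
                        gmv_int_coupling = 0.35,
                        gmv_sd = 0.8,
                        smg_gmv_offset_ad = -0.9,
                        mediation_coeffs = c(a_gen = 0.8, b_gen = 0.6, cprime_gen = 0),
                        mmse_base = c(CN = 28.5, AD = 22),
                        mmse_sd = 1,
                        confound_amplitudes = c(motion = 0.1, wmcsf = 1),
                        motion_outlier_rate = 0.05,
                        battery_missing_rate = 0.08,
                        seed = 1L) {
  if (is.null(phi_by_region_and_group)) {
    cn <- c(`DMN-core` = 0.65, AG = 0.65, SMG = 0.65,
            frontoparietal = 0.60, dorsal_attention = 0.50,
            ventral_attention = 0.50, limbic = 0.40,
            somatomotor = 0.35, visual = 0.30)
    ad <- cn
    ad[["AG"]] <- 0.45       # the planted focal deficit
    ad[["DMN-core"]] <- 0.60 # a small network-wide shortening
    phi_by_region_and_group <- list(CN = cn, AD = ad)
  }
  stopifnot(
    .is_count(n_cn), .is_count(n_ad), .is_count(n_timepoints),
    n_discard >= 0, tr_s > 0, noise_sd > 0,
    all(c("CN", "AD") %in% names(phi_by_region_and_group)),
    all(abs(unlist(phi_by_region_and_group)) < 1),
    all(c("a_gen", "b_gen", "cprime_gen") %in% names(mediation_coeffs)),
    all(confound_amplitudes >= 0),
    motion_outlier_rate >= 0, motion_outlier_rate <= 1
  )
  structure(
    list(
      n_cn = as.integer(n_cn), n_ad = as.integer(n_ad),
      n_timepoints = as.integer(n_timepoints),
      n_discard = as.integer(n_discard), tr_s = tr_s,
      phi_by_region_and_group = phi_by_region_and_group,
      tau_sd_s = tau_sd_s, noise_sd = noise_sd,
      gmv_int_coupling = gmv_int_coupling, gmv_sd = gmv_sd,
      smg_gmv_offset_ad = smg_gmv_offset_ad,
      mediation_coeffs = mediation_coeffs,
      mmse_base = mmse_base, mmse_sd = mmse_sd,
      confound_amplitudes = confound_amplitudes,
      motion_outlier_rate = motion_outlier_rate,
      battery_missing_rate = battery_missing_rate,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

#' A cohort specification with no group differences and no planted effects
#'
#' Convenience wrapper around [cohort_spec()] for null-calibration studies:
#' both groups share the CN coefficients, the mediation chain and the GMV
#' coupling are zeroed, and the MMSE baselines are equal.
#'
#' @param ... Passed on to [cohort_spec()].
#' @export
null_cohort_spec <- function(...) {
  base <- cohort_spec(...)
  base$phi_by_region_and_group$AD <- base$phi_by_region_and_group$CN
  base$mediation_coeffs[] <- 0
  base$gmv_int_coupling <- 0
  base$smg_gmv_offset_ad <- 0
  base$mmse_base[] <- mean(base$mmse_base)
  base
}

# clamp a latent timescale (s) into a range whose phi stays inside (0, 1)
.clamp_tau <- function(tau, tr_s) pmin(pmax(tau, 0.1 * tr_s), 6 * tr_s)

# per-subject latent timescales + phenotype row; all draws from one stream
.draw_subject_latents <- function(spec, id, group, seed) {
  phis <- spec$phi_by_region_and_group[[group]]
  tau_means <- vapply(phis, ar1_int, numeric(1), tr_s = spec$tr_s)
  mc <- spec$mediation_coeffs
  withr::with_seed(seed, {
    tau_ag <- .clamp_tau(tau_means[["AG"]] + rnorm(1, 0, spec$tau_sd_s[["ag"]]), spec$tr_s)
    dmn_intercept <- tau_means[["DMN-core"]] - mc[["a_gen"]] * tau_means[["AG"]]
    tau_dmn <- .clamp_tau(
      dmn_intercept + mc[["a_gen"]] * tau_ag + rnorm(1, 0, spec$tau_sd_s[["dmn"]]),
      spec$tr_s
    )
    other <- setdiff(names(phis), c("AG", "DMN-core"))
    tau_other <- .clamp_tau(
      tau_means[other] + rnorm(length(other), 0, spec$tau_sd_s[["other"]]),
      spec$tr_s
    )
    taus <- c(AG = tau_ag, `DMN-core` = tau_dmn, tau_other)

    ag_gmv <- 6 + spec$gmv_int_coupling * tau_ag + rnorm(1, 0, spec$gmv_sd)
    smg_gmv <- 6 + (group == "AD") * spec$smg_gmv_offset_ad + rnorm(1, 0, spec$gmv_sd)

    cn_phis <- spec$phi_by_region_and_group$CN
    mmse_raw <- spec$mmse_base[[group]] +
      mc[["b_gen"]] * (tau_dmn - ar1_int(cn_phis[["DMN-core"]], spec$tr_s)) +
      mc[["cprime_gen"]] * (tau_ag - ar1_int(cn_phis[["AG"]], spec$tr_s)) +
      rnorm(1, 0, spec$mmse_sd)
    mmse <- as.integer(pmin(30, pmax(0, round(mmse_raw))))

    age <- round(rnorm(1, if (group == "AD") 74 else 72, 6))
    sex <- sample(c("F", "M"), 1)
    mean_motion <- if (runif(1) < spec$motion_outlier_rate) {
      runif(1, 3.2, 5)
    } else {
      abs(rnorm(1, 0.4, 0.3))
    }

    # cognitive battery: only digit span (attention) is coupled to the
    # generative DMN timescale; every other score is independent noise
    z_dmn <- (tau_dmn - tau_means[["DMN-core"]]) / max(spec$tau_sd_s[["dmn"]], 1e-8)
    battery <- c(
      digit_span = round(9 + 0.6 * z_dmn + rnorm(1, 0, 1), 1),
      tmt_a = round(exp(3.6 + rnorm(1, 0, 0.30)), 1),
      digit_symbol = round(35 + rnorm(1, 0, 8), 1),
      tmt_b = round(exp(4.5 + rnorm(1, 0, 0.35)), 1),
      logical_memory = round(8 + rnorm(1, 0, 3), 1),
      boston_naming = round(40 + rnorm(1, 0, 6), 1),
      category_fluency = round(12 + rnorm(1, 0, 4), 1)
    )
    battery[runif(length(battery)) < spec$battery_missing_rate] <- NA_real_

    list(
      taus = taus,
      row = tibble::tibble(
        id = id, group = group, age = age, sex = sex, mmse = mmse,
        mean_motion_mm = round(mean_motion, 3),
        ag_gmv = round(ag_gmv, 4), smg_gmv = round(smg_gmv, 4),
        gen_tau_ag = round(tau_ag, 6), gen_tau_dmn = round(tau_dmn, 6),
        gen_tau_smg = round(taus[["SMG"]], 6),
        !!!as.list(battery)
      )
    )
  })
}

# nuisance signals over n volumes: slow sinusoidal motion traces, low
# frequency wm/csf noise; returned as a full n x 8 matrix
.confound_signals <- function(n, tr_s, amplitudes, seed) {
  t_s <- (seq_len(n) - 1) * tr_s
  withr::with_seed(seed, {
    motion <- vapply(1:6, function(j) {
      f <- runif(1, 0.005, 0.02)
      a <- amplitudes[["motion"]] * runif(1, 0.5, 1.5) * if (j <= 3) 1 else 1 / 50
      a * sin(2 * pi * f * t_s + runif(1, 0, 2 * pi))
    }, numeric(n))
    tissue <- vapply(1:2, function(j) {
      rowSums(vapply(1:3, function(k) {
        f <- runif(1, 0.003, 0.03)
        amplitudes[["wmcsf"]] * runif(1, 0.5, 1) / sqrt(3) *
          sin(2 * pi * f * t_s + runif(1, 0, 2 * pi))
      }, numeric(n)))
    }, numeric(n))
    m <- cbind(motion, tissue)
    colnames(m) <- c("trans_x", "trans_y", "trans_z",
                     "rot_x", "rot_y", "rot_z", "wm", "csf")
    m
  })
}

#' Simulate one subject's 4D BOLD volume and confound table
#'
#' Every voxel of a labelled parcel follows a stationary AR(1) process whose
#' coefficient comes from the parcel's entry for the subject's group (or
#' from `phi`, the per-subject realisation used by [simulate_cohort()]).
#' Scaled nuisance signals (sinusoidal motion traces, low-frequency
#' white-matter/CSF noise) are mixed into all parcel voxels with random
#' per-voxel weights; background voxels are pure white noise. `n_discard`
#' lead-in volumes are prepended so the preprocessing stage has volumes to
#' discard; the confound table covers the retained volumes only.
#'
#' @param spec A [cohort_spec()].
#' @param atlas A `parcellation`.
#' @param subject One-row phenotype (needs `id` and `group`).
#' @param seed Integer seed.
#' @param phi Optional named vector of per-parcel AR(1) coefficients
#'   overriding the group-level map.
#' @return A list with `bold` (a `bold_4d`) and `confounds` (a tibble with
#'   the motion/wm/csf columns, one row per retained volume).
#' @export
simulate_subject_bold <- function(spec, atlas, subject, seed, phi = NULL) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(atlas, "parcellation"))
  group <- subject$group
  parcels <- unname(atlas$label_names)
  if (is.null(phi)) {
    phimap <- spec$phi_by_region_and_group[[group]]
    missing <- setdiff(parcels, names(phimap))
    if (length(missing) > 0) {
      abort(sprintf("no AR(1) coefficient for parcel(s) %s in group %s",
                    paste(sQuote(missing), collapse = ", "), group))
    }
    phi <- phimap[parcels]
  } else {
    missing <- setdiff(parcels, names(phi))
    if (length(missing) > 0) {
      abort(sprintf("no AR(1) coefficient for parcel(s) %s",
                    paste(sQuote(missing), collapse = ", ")))
    }
  }
  dims <- atlas$geometry$grid_dims
  nvox <- prod(dims)
  n_total <- spec$n_timepoints + spec$n_discard

  lab <- as.integer(atlas$labels)
  phi_vox <- numeric(nvox) # background: phi 0 -> white noise
  for (l in names(atlas$label_names)) {
    phi_vox[lab == as.integer(l)] <- phi[[atlas$label_names[[l]]]]
  }

  conf_full <- .confound_signals(n_total, spec$tr_s, spec$confound_amplitudes,
                                 derive_seed(seed, "confounds"))
  X <- withr::with_seed(seed, {
    E <- matrix(rnorm(n_total * nvox, 0, spec$noise_sd), n_total, nvox)
    X <- E
    X[1, ] <- rnorm(nvox, 0, spec$noise_sd / sqrt(1 - phi_vox^2))
    for (t in 2:n_total) X[t, ] <- phi_vox * X[t - 1, ] + E[t, ]
    inside <- lab != 0L
    if (any(inside) && any(spec$confound_amplitudes > 0)) {
      W <- matrix(rnorm(8 * sum(inside)), 8, sum(inside))
      X[, inside] <- X[, inside] + conf_full %*% W
    }
    X
  })
  bold <- structure(
    list(values = array(t(X), dim = c(dims, n_total)),
         tr_s = spec$tr_s, geometry = atlas$geometry),
    class = "bold_4d"
  )
  confounds <- tibble::as_tibble(as.data.frame(
    conf_full[(spec$n_discard + 1):n_total, , drop = FALSE]
  ))
  list(bold = bold, confounds = confounds)
}

#' Simulate a full synthetic cohort
#'
#' Draws per-subject latent timescales (with the planted mediation chain
#' GMV -> AG timescale -> DMN timescale -> MMSE), phenotypes and, when
#' `images = TRUE`, each subject's 4D BOLD volume plus confound table. All
#' randomness descends from `spec$seed`; per-subject streams are derived by
#' stable hashing of the subject id, so the cohort is a pure function of the
#' specification.
#'
#' @param spec A [cohort_spec()].
#' @param atlas A `parcellation`; defaults to [toy_atlas()].
#' @param images Generate 4D volumes (set `FALSE` for phenotype-only use).
#' @return A list with `phenotypes` (tibble), `latents` (named list of
#'   per-subject parcel timescales, seconds), `subjects` (named list of
#'   `list(bold, confounds)`, or `NULL`), `atlas` and `spec`.
#' @export
simulate_cohort <- function(spec, atlas = toy_atlas(), images = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  ids <- c(sprintf("CN%03d", seq_len(spec$n_cn)), sprintf("AD%03d", seq_len(spec$n_ad)))
  groups <- c(rep("CN", spec$n_cn), rep("AD", spec$n_ad))
  latents <- list()
  rows <- vector("list", length(ids))
  subjects <- if (images) vector("list", length(ids)) else NULL
  for (i in seq_along(ids)) {
    sseed <- derive_seed(spec$seed, ids[i])
    drawn <- .draw_subject_latents(spec, ids[i], groups[i], sseed)
    latents[[ids[i]]] <- drawn$taus
    rows[[i]] <- drawn$row
    if (images) {
      phi <- ar1_phi_for_int(drawn$taus, spec$tr_s)
      subjects[[i]] <- simulate_subject_bold(
        spec, atlas, drawn$row, derive_seed(sseed, "bold"), phi = phi
      )
    }
  }
  if (images) names(subjects) <- ids
  list(
    phenotypes = dplyr::bind_rows(rows),
    latents = latents,
    subjects = subjects,
    atlas = atlas,
    spec = spec
  )
}

#' Desk-scale per-subject summary table without volumetric simulation
#'
#' The replicate-study path: instead of synthesising, preprocessing and
#' mapping full 4D volumes, each subject's parcel-level timescale estimates
#' are obtained by applying the package's ACF-area estimator to
#' `n_series` independent AR(1) draws at the subject's realised coefficient
#' and averaging — emulating the noise reduction of averaging an INT map
#' over a parcel. The DMN summary is the parcel-size-weighted mean over the
#' parcels assigned to the DMN.
#'
#' @param spec A [cohort_spec()].
#' @param atlas A `parcellation` (for parcel sizes / network membership).
#' @param n_series Independent series averaged per parcel estimate.
#' @return A tibble: phenotypes plus `ag_int`, `smg_int`, `dmn_int` and one
#'   `<network>_int` column per control network (estimated, seconds).
#' @export
cohort_summary <- function(spec, atlas = toy_atlas(), n_series = 9) {
  stopifnot(inherits(spec, "cohort_spec"))
  cohort <- simulate_cohort(spec, atlas = atlas, images = FALSE)
  ph <- cohort$phenotypes
  sizes <- parcel_sizes(atlas)
  est_one <- function(tau, seed) {
    phi <- ar1_phi_for_int(tau, spec$tr_s)
    mean(vapply(seq_len(n_series), function(k) {
      x <- simulate_ar1(phi, spec$n_timepoints, spec$noise_sd, derive_seed(seed, paste0("s", k)))
      int_from_series(x, spec$tr_s)
    }, numeric(1)))
  }
  parcels <- unname(atlas$label_names)
  est <- matrix(NA_real_, nrow(ph), length(parcels),
                dimnames = list(NULL, parcels))
  for (i in seq_len(nrow(ph))) {
    sseed <- derive_seed(spec$seed, paste0("summary-", ph$id[i]))
    taus <- cohort$latents[[ph$id[i]]]
    for (p in parcels) est[i, p] <- est_one(taus[[p]], derive_seed(sseed, p))
  }
  dmn_parcels <- sizes$name[sizes$network == "DMN"]
  w <- sizes$n_voxels[match(dmn_parcels, sizes$name)]
  out <- ph
  out$ag_int <- est[, "AG"]
  out$smg_int <- est[, "SMG"]
  out$dmn_int <- as.numeric(est[, dmn_parcels, drop = FALSE] %*% (w / sum(w)))
  for (net in setdiff(unique(sizes$network), "DMN")) {
    nm <- sizes$name[sizes$network == net]
    wn <- sizes$n_voxels[match(nm, sizes$name)]
    out[[paste0(net, "_int")]] <-
      as.numeric(est[, nm, drop = FALSE] %*% (wn / sum(wn)))
  }
  out
}
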