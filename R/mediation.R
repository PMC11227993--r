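#' Pairwise correlation preconditions for a mediation model
#'
#' A mediation analysis is only interpretable when the independent
#' variable, mediator and outcome are pairwise correlated; this screens the
#' three pairs with bootstrap Pearson correlations and flags whether all
#' three reach `alpha`.
#'
#' @param data Data frame of subject-level variables.
#' @param x,m,y Column names: independent variable, mediator, outcome.
#' @param n_boot Bootstrap resamples per correlation.
#' @param seed Integer seed.
#' @param alpha Significance level for the gate.
#' @return A tibble with one row per pair (`pair`, `var1`, `var2`, `r`,
#'   `p_boot`, `n`, `pass`) and attribute `all_pass`.
#' @export
precondition_correlations <- function(data, x, m, y, n_boot = 10000,
                                      seed = 1, alpha = 0.05) {
  for (v in c(x, m, y)) {
    if (!v %in% names(data)) abort(sprintf("column '%s' not found", v))
    vv <- data[[v]][is.finite(data[[v]])]
    if (length(vv) > 0 && sd(vv) == 0) {
      abort(sprintf("column '%s' is constant", v))
    }
  }
  cc <- data[complete.cases(data[, c(x, m, y)]), c(x, m, y)]
  if (nrow(cc) < 4) abort("need at least 4 complete cases")
  pairs <- list(xm = c(x, m), my = c(m, y), xy = c(x, y))
  rows <- purrr::imap(pairs, function(vars, nm) {
    ct <- pearson_bootstrap(cc[[vars[1]]], cc[[vars[2]]], n_boot,
                            derive_seed(seed, nm))
    tibble::tibble(pair = nm, var1 = vars[1], var2 = vars[2],
                   r = ct$r, p_boot = ct$p_boot, n = ct$n,
                   pass = ct$p_boot < alpha)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "all_pass") <- all(out$pass)
  out
}

# OLS mediation paths on complete-case columns; returns a, b, c, c_prime
.mediation_paths <- function(xv, mv, yv) {
  a <- cov(xv, mv) / var(xv)
  fit2 <- stats::lm.fit(cbind(1, xv, mv), yv)
  c_total <- cov(xv, yv) / var(xv)
  list(a = a, b = unname(fit2$coefficients[3]),
       c = c_total, c_prime = unname(fit2$coefficients[2]))
}

#' Fit a three-variable mediation model with bootstrap inference
#'
#' Point estimates by ordinary least squares: path `a` from `M ~ X`, paths
#' `b` and `c'` from `Y ~ X + M`, total effect `c` from `Y ~ X`; indirect
#' effect `ab = a * b`. For nested OLS fits on the same sample the
#' decomposition `c = c' + ab` holds exactly. Inference on `ab` (and `c'`)
#' is by non-parametric bootstrap: subjects are resampled with replacement
#' `n_boot` times, the paths re-estimated, the confidence interval taken as
#' the 2.5/97.5 percentiles and the two-tailed p as twice the smaller
#' zero-crossing fraction, floored at `1/n_boot`. Variables are used on
#' their native scales.
#'
#' @inheritParams precondition_correlations
#' @param n_boot Bootstrap resamples (default 10000).
#' @param covariates Optional character vector of additional adjustment
#'   columns included in both regressions.
#' @return A `mediation_fit` object.
#' @export
fit_mediation <- function(data, x, m, y, n_boot = 10000, seed = 1,
                          covariates = character(0)) {
  vars <- c(x, m, y, covariates)
  for (v in vars) if (!v %in% names(data)) abort(sprintf("column '%s' not found", v))
  cc <- data[complete.cases(data[, vars]), vars, drop = FALSE]
  n <- nrow(cc)
  if (n < 5) abort("need at least 5 complete cases")
  xv <- cc[[x]]; mv <- cc[[m]]; yv <- cc[[y]]
  if (abs(cor(xv, mv)) >= 1 - 1e-12) {
    abort("X and M are perfectly collinear; paths not identifiable")
  }
  Z <- if (length(covariates) > 0) as.matrix(cc[, covariates, drop = FALSE]) else NULL
  paths_fun <- if (is.null(Z)) {
    function(idx) .mediation_paths(xv[idx], mv[idx], yv[idx])
  } else {
    function(idx) {
      Xa <- cbind(1, xv[idx], Z[idx, , drop = FALSE])
      a <- unname(stats::lm.fit(Xa, mv[idx])$coefficients[2])
      f2 <- stats::lm.fit(cbind(1, xv[idx], mv[idx], Z[idx, , drop = FALSE]), yv[idx])
      c_t <- unname(stats::lm.fit(Xa, yv[idx])$coefficients[2])
      list(a = a, b = unname(f2$coefficients[3]),
           c = c_t, c_prime = unname(f2$coefficients[2]))
    }
  }
  pt_est <- paths_fun(seq_len(n))
  boot <- withr::with_seed(seed, {
    ab <- numeric(n_boot); cp <- numeric(n_boot)
    for (i in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      if (sd(xv[idx]) == 0 || sd(mv[idx]) == 0) {
        ab[i] <- NA_real_; cp[i] <- NA_real_
        next
      }
      p <- paths_fun(idx)
      ab[i] <- p$a * p$b
      cp[i] <- p$c_prime
    }
    list(ab = ab[is.finite(ab)], cp = cp[is.finite(cp)])
  })
  p_two <- function(v) min(1, max(2 * min(mean(v <= 0), mean(v >= 0)), 1 / n_boot))
  structure(
    list(
      x = x, m = m, y = y, n = n, n_boot = n_boot, seed = seed,
      a = pt_est$a, b = pt_est$b, c = pt_est$c, c_prime = pt_est$c_prime,
      ab = pt_est$a * pt_est$b,
      ci_low = unname(quantile(boot$ab, 0.025)),
      ci_high = unname(quantile(boot$ab, 0.975)),
      p = p_two(boot$ab),
      c_prime_ci = unname(quantile(boot$cp, c(0.025, 0.975))),
      p_c_prime = p_two(boot$cp),
      boot_ab = boot$ab
    ),
    class = "mediation_fit"
  )
}

#' @export
print.mediation_fit <- function(x, ...) {
  cat(sprintf("<mediation_fit> %s -> %s -> %s (n = %d)\n", x$x, x$m, x$y, x$n))
  cat(sprintf("  a = %.4f, b = %.4f, c = %.4f, c' = %.4f\n",
              x$a, x$b, x$c, x$c_prime))
  cat(sprintf("  indirect ab = %.4f, 95%% CI [%.4f, %.4f], p = %.4g (%d boots)\n",
              x$ab, x$ci_low, x$ci_high, x$p, x$n_boot))
  invisible(x)
}

#' @export
tidy.mediation_fit <- function(x, ...) {
  tibble::tibble(
    term = c("a", "b", "c", "c_prime", "ab"),
    estimate = c(x$a, x$b, x$c, x$c_prime, x$ab),
    conf.low = c(NA, NA, NA, x$c_prime_ci[1], x$ci_low),
    conf.high = c(NA, NA, NA, x$c_prime_ci[2], x$ci_high),
    p.value = c(NA, NA, NA, x$p_c_prime, x$p)
  )
}

#' @export
glance.mediation_fit <- function(x, ...) {
  fit <- x
  tibble::tibble(x = fit$x, m = fit$m, y = fit$y, n = fit$n,
                 ab = fit$ab, conf.low = fit$ci_low, conf.high = fit$ci_high,
                 p.value = fit$p, n_boot = fit$n_boot)
}

#' Run the full mediation model suite over focal ROIs
#'
#' For each focal ROI `<roi>` (expecting columns `<roi>_int` and optionally
#' `<roi>_gmv`, plus `dmn_int` and `mmse`) the suite fits:
#' \describe{
#'   \item{local_to_network}{X = ROI INT, M = DMN INT, Y = MMSE — does the
#'     network timescale carry the local effect on symptoms?}
#'   \item{network_to_local}{X = DMN INT, M = ROI INT, Y = MMSE — the
#'     reversed orientation.}
#'   \item{gmv_to_network}{X = ROI GMV, M = ROI INT, Y = DMN INT — does
#'     local atrophy shorten the local timescale and thereby the network's?}
#'   \item{gmv_to_symptoms}{X = ROI GMV, M = ROI INT, Y = MMSE.}
#'   \item{reversed_gmv}{X = ROI INT, M = ROI GMV, Y = DMN INT — the
#'     sensitivity model with structure as mediator.}
#'   \item{control_<network>}{model `local_to_network` with each named
#'     control network's INT substituted for DMN INT.}
#' }
#' Pairwise-correlation preconditions gate each fit; models whose
#' preconditions fail are reported `evaluated = FALSE` with the failing
#' pair named. Bonferroni correction over the focal ROIs is applied to each
#' model family.
#'
#' @param data Subject-level tibble.
#' @param roi_names Focal ROI prefixes (default `c("ag", "smg")`).
#' @param network_names Control-network prefixes whose `<network>_int`
#'   columns exist.
#' @param n_boot Bootstrap resamples per fit.
#' @param seed Integer seed.
#' @param alpha Significance level used by the precondition gate.
#' @param gate Apply the precondition gate (set `FALSE` to force all fits).
#' @return A tibble, one row per (model, ROI): paths, CI, `p`,
#'   `p_bonferroni`, `evaluated`, `failed_pair`, plus a `fits` list-column
#'   of `mediation_fit` objects.
#' @export
run_model_suite <- function(data, roi_names = c("ag", "smg"),
                            network_names = c("frontoparietal",
                                              "dorsal_attention",
                                              "ventral_attention", "limbic",
                                              "somatomotor", "visual"),
                            n_boot = 10000, seed = 1, alpha = 0.05,
                            gate = TRUE) {
  models <- list()
  for (roi in roi_names) {
    ri <- paste0(roi, "_int"); rg <- paste0(roi, "_gmv")
    models[[paste0("local_to_network.", roi)]] <-
      list(model = "local_to_network", roi = roi, x = ri, m = "dmn_int", y = "mmse")
    models[[paste0("network_to_local.", roi)]] <-
      list(model = "network_to_local", roi = roi, x = "dmn_int", m = ri, y = "mmse")
    models[[paste0("gmv_to_network.", roi)]] <-
      list(model = "gmv_to_network", roi = roi, x = rg, m = ri, y = "dmn_int")
    models[[paste0("gmv_to_symptoms.", roi)]] <-
      list(model = "gmv_to_symptoms", roi = roi, x = rg, m = ri, y = "mmse")
    models[[paste0("reversed_gmv.", roi)]] <-
      list(model = "reversed_gmv", roi = roi, x = ri, m = rg, y = "dmn_int")
    for (net in network_names) {
      models[[paste0("control_", net, ".", roi)]] <-
        list(model = paste0("control_", net), roi = roi,
             x = ri, m = paste0(net, "_int"), y = "mmse")
    }
  }
  rows <- purrr::imap(models, function(mod, id) {
    base <- tibble::tibble(
      model = mod$model, roi = mod$roi, x = mod$x, m = mod$m, y = mod$y,
      evaluated = FALSE, failed_pair = NA_character_,
      a = NA_real_, b = NA_real_, c = NA_real_, c_prime = NA_real_,
      ab = NA_real_, ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
      n = NA_integer_, fits = list(NULL)
    )
    missing <- setdiff(c(mod$x, mod$m, mod$y), names(data))
    if (length(missing) > 0) {
      base$failed_pair <- paste("missing column:", paste(missing, collapse = ", "))
      return(base)
    }
    pre <- precondition_correlations(data, mod$x, mod$m, mod$y,
                                     n_boot = n_boot,
                                     seed = derive_seed(seed, paste0("pre.", id)),
                                     alpha = alpha)
    if (gate && !attr(pre, "all_pass")) {
      bad <- pre$pair[!pre$pass]
      base$failed_pair <- paste(bad, collapse = ",")
      return(base)
    }
    fit <- fit_mediation(data, mod$x, mod$m, mod$y, n_boot = n_boot,
                         seed = derive_seed(seed, paste0("fit.", id)))
    tibble::tibble(
      model = mod$model, roi = mod$roi, x = mod$x, m = mod$m, y = mod$y,
      evaluated = TRUE, failed_pair = NA_character_,
      a = fit$a, b = fit$b, c = fit$c, c_prime = fit$c_prime,
      ab = fit$ab, ci_low = fit$ci_low, ci_high = fit$ci_high, p = fit$p,
      n = fit$n, fits = list(fit)
    )
  })
  out <- dplyr::bind_rows(rows)
  dplyr::mutate(
    dplyr::group_by(out, .data$model),
    p_bonferroni = bonferroni_correct(.data$p, length(roi_names)),
    .after = "p"
  ) |> dplyr::ungroup()
}
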