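# test -> component map; TMT scores are completion times (higher = worse)
.BATTERY <- list(
  attention = c("digit_span"),
  processing_speed = c("tmt_a", "digit_symbol"),
  executive = c("tmt_b"),
  memory = c("logical_memory"),
  language = c("boston_naming", "category_fluency")
)
.INVERTED <- c("tmt_a", "tmt_b")

#' Convert a raw neuropsychological battery into component z scores
#'
#' Each raw score is z-scored against a reference population; Trail-Making
#' completion times are negated after z-scoring so higher always means
#' better. Components backed by several tests (processing speed, language)
#' are the unweighted mean of the member z scores that are available; a
#' subject missing every member of a component gets `NA` for it.
#'
#' @param data Tibble with an `id` column and the raw battery columns
#'   `digit_span`, `tmt_a`, `digit_symbol`, `tmt_b`, `logical_memory`,
#'   `boston_naming`, `category_fluency` (missing values allowed).
#' @param reference Reference statistics: a data frame with columns `test`,
#'   `mean`, `sd`. Default: computed from the `group == "CN"` rows of
#'   `data` (the cognitively normal reference).
#' @return Tibble: `id` plus the five component columns `attention`,
#'   `processing_speed`, `executive`, `memory`, `language`.
#' @export
componentize <- function(data, reference = NULL) {
  tests <- unique(unlist(.BATTERY))
  present <- intersect(tests, names(data))
  if (length(present) == 0) abort("no battery columns found")
  if (is.null(reference)) {
    ref_rows <- if ("group" %in% names(data)) data[data$group == "CN", ] else data
    if (nrow(ref_rows) < 3) abort("too few reference subjects to z-score against")
    reference <- tibble::tibble(
      test = present,
      mean = vapply(present, function(t) mean(ref_rows[[t]], na.rm = TRUE), numeric(1)),
      sd = vapply(present, function(t) sd(ref_rows[[t]], na.rm = TRUE), numeric(1))
    )
    # tests with no usable reference data drop out (their z's become NA)
    reference <- reference[is.finite(reference$sd) & reference$sd > 0, , drop = FALSE]
    present <- reference$test
    if (length(present) == 0) abort("no battery column has usable reference data")
  }
  reference <- as.data.frame(reference)
  if (any(!is.finite(reference$sd)) || any(reference$sd == 0)) {
    abort("degenerate reference: zero or undefined sd")
  }
  z <- sapply(present, function(t) {
    r <- reference[reference$test == t, , drop = FALSE]
    if (nrow(r) == 0) return(rep(NA_real_, nrow(data)))
    zt <- (data[[t]] - r$mean[1]) / r$sd[1]
    if (t %in% .INVERTED) -zt else zt
  })
  z <- matrix(z, nrow = nrow(data), dimnames = list(NULL, present))
  out <- tibble::tibble(id = data$id)
  for (comp in names(.BATTERY)) {
    members <- intersect(.BATTERY[[comp]], present)
    out[[comp]] <- if (length(members) == 0) {
      NA_real_
    } else {
      rowMeans(z[, members, drop = FALSE], na.rm = TRUE)
    }
  }
  out[is.na(out)] <- NA # rowMeans of all-NA gives NaN; normalise to NA
  out
}

#' Correlate cognitive components with the network timescale
#'
#' Bootstrap Pearson correlation of each of the five components against
#' `dmn_int`, with Bonferroni correction over the five components and the
#' per-component complete-case n reported (sample sizes differ when scores
#' are missing). Components with fewer than `min_n` complete cases are
#' reported as not evaluated.
#'
#' @param components Output of [componentize()] (or any tibble with `id`
#'   and the component columns).
#' @param data Tibble with `id` and `dmn_int`.
#' @param n_boot Bootstrap resamples per component.
#' @param seed Integer seed.
#' @param min_n Minimum complete cases per component.
#' @param alpha Significance level applied to the corrected p.
#' @return Tibble: `component`, `n`, `r`, `p_boot`, `p_bonferroni`,
#'   `significant`, `evaluated`.
#' @export
component_correlations <- function(components, data, n_boot = 10000,
                                   seed = 1, min_n = 4, alpha = 0.05) {
  joined <- dplyr::inner_join(components, data[, c("id", "dmn_int")], by = "id")
  comps <- names(.BATTERY)
  rows <- purrr::map(comps, function(comp) {
    xs <- joined[[comp]]; ys <- joined$dmn_int
    keep <- is.finite(xs) & is.finite(ys)
    if (sum(keep) < min_n || sd(xs[keep]) == 0) {
      return(tibble::tibble(component = comp, n = sum(keep), r = NA_real_,
                            p_boot = NA_real_, evaluated = FALSE))
    }
    ct <- pearson_bootstrap(xs[keep], ys[keep], n_boot, derive_seed(seed, comp))
    tibble::tibble(component = comp, n = ct$n, r = ct$r,
                   p_boot = ct$p_boot, evaluated = TRUE)
  })
  out <- dplyr::bind_rows(rows)
  out$p_bonferroni <- bonferroni_correct(out$p_boot, length(comps))
  out$significant <- !is.na(out$p_bonferroni) & out$p_bonferroni < alpha
  out
}
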