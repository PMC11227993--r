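#' Default end-to-end pipeline configuration
#'
#' Defaults: discard 5 lead-in volumes, regress motion/wm/csf confounds,
#' band-pass 0.01-0.1 Hz, 3 mm mean-motion exclusion, 8 mm FWHM smoothing,
#' Riemann ACF area without the lag-0 term, 10 000 bootstrap resamples,
#' 1000 group-label permutations at a 0.001 two-tailed cluster-forming
#' threshold with face connectivity, and 4 mm spherical ROIs centred on the
#' AG and SMG parcel centroids.
#'
#' @param seed Master seed (fans out to per-stage streams).
#' @param cohort A [cohort_spec()]; defaults to `cohort_spec(seed = seed)`.
#' @return A nested configuration list.
#' @export
default_config <- function(seed = 1L, cohort = NULL) {
  if (is.null(cohort)) cohort <- cohort_spec(seed = derive_seed(seed, "cohort"))
  list(
    cohort = cohort,
    preprocessing = list(discard_n = 5L, band = c(0.01, 0.1),
                         motion_threshold_mm = 3, expand_motion = FALSE),
    int = list(fwhm_mm = 8, include_lag0 = FALSE, auc = "riemann"),
    stats = list(n_boot = 10000L, n_perm = 1000L, cluster_p = 0.001,
                 connectivity = 6L),
    rois = NULL, # default: spheres at the AG / SMG parcel centroids
    roi_radius_mm = 4,
    write_images = FALSE,
    seed = as.integer(seed)
  )
}

#' Validate a pipeline configuration
#'
#' @param config A configuration list as produced by [default_config()].
#' @return Character vector of problems; empty iff the configuration is
#'   valid. Each problem names the offending field.
#' @export
validate_config <- function(config) {
  problems <- character(0)
  need <- function(cond, msg) if (!isTRUE(cond)) problems <<- c(problems, msg)
  need(!is.null(config$seed) && is.numeric(config$seed), "seed: missing or non-numeric")
  need(inherits(config$cohort, "cohort_spec"), "cohort: not a cohort_spec")
  pp <- config$preprocessing
  need(is.numeric(pp$discard_n) && pp$discard_n >= 0, "preprocessing$discard_n: must be >= 0")
  if (!is.null(pp$band)) {
    need(length(pp$band) == 2 && pp$band[1] > 0 && pp$band[1] < pp$band[2],
         sprintf("preprocessing$band: [%s] is not an increasing positive band",
                 paste(pp$band, collapse = ", ")))
    if (inherits(config$cohort, "cohort_spec")) {
      need(pp$band[2] < 1 / (2 * config$cohort$tr_s),
           "preprocessing$band: upper edge at or above Nyquist")
    }
  }
  need(is.numeric(pp$motion_threshold_mm) && pp$motion_threshold_mm > 0,
       "preprocessing$motion_threshold_mm: must be > 0")
  need(is.numeric(config$int$fwhm_mm) && config$int$fwhm_mm > 0,
       "int$fwhm_mm: must be > 0")
  need(config$int$auc %in% c("riemann", "trapezoid"),
       "int$auc: must be 'riemann' or 'trapezoid'")
  st <- config$stats
  need(is.numeric(st$n_boot) && st$n_boot >= 100, "stats$n_boot: must be >= 100")
  need(is.numeric(st$n_perm) && st$n_perm >= 100, "stats$n_perm: must be >= 100")
  need(is.numeric(st$cluster_p) && st$cluster_p > 0 && st$cluster_p < 1,
       "stats$cluster_p: must lie in (0, 1)")
  need(st$connectivity %in% c(6, 18, 26), "stats$connectivity: must be 6, 18 or 26")
  problems
}

# centroid (mm) of a named parcel, for default ROI placement
.parcel_centroid_mm <- function(parc, parcel) {
  lab <- as.integer(names(parc$label_names)[parc$label_names == parcel][1])
  idx <- which(parc$labels == lab)
  colMeans(.voxel_to_mm(arrayInd(idx, dim(parc$labels)), parc$geometry))
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes, in order: cohort simulation; per-subject preprocessing
#' (discard, confound regression, band-pass); INT mapping and smoothing;
#' motion QC; network/parcel/ROI summarisation; DMN group test with
#' bootstrap MMSE correlation; voxelwise group GLM with permutation
#' cluster FWE; the mediation model suite (within the AD group, as the
#' focal clinical question concerns symptom variation among patients); and
#' the cognitive-component correlations. All tabular outputs are written
#' as TSV/JSON under `out_dir` together with a manifest recording the
#' configuration hash, per-stage status and seeds.
#'
#' @param config Configuration list (see [default_config()]).
#' @param out_dir Output directory (created if needed; must be writable).
#' @return The manifest list, invisibly; all results are also returned in
#'   the `results` element.
#' @export
run_pipeline <- function(config, out_dir) {
  problems <- validate_config(config)
  if (length(problems) > 0) {
    abort(paste0("invalid configuration:\n", paste("-", problems, collapse = "\n")))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  probe <- file.path(out_dir, ".write_probe")
  ok <- tryCatch({ writeLines("x", probe); TRUE }, error = function(e) FALSE,
                 warning = function(w) FALSE)
  if (!ok) abort(sprintf("output directory '%s' is not writable", out_dir))
  unlink(probe)

  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA, force = TRUE)
  cfg_file <- file.path(out_dir, "config.json")
  writeLines(cfg_json, cfg_file)
  config_hash <- unname(tools::md5sum(cfg_file))

  stage_status <- list()
  run_stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      stage_status[[name]] <<- paste("failed:", conditionMessage(e))
      .write_manifest(out_dir, config_hash, config$seed, stage_status)
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
    stage_status[[name]] <<- "ok"
    res
  }

  # -- simulate ------------------------------------------------------------
  cohort <- run_stage("simulate", simulate_cohort(config$cohort))
  atlas <- cohort$atlas
  mask <- atlas$labels > 0L

  # -- qc ------------------------------------------------------------------
  qc <- run_stage("qc", qc_filter_subjects(cohort$phenotypes,
                                           config$preprocessing$motion_threshold_mm))
  kept_ids <- qc$kept$id

  # -- preprocess + int map ------------------------------------------------
  maps <- run_stage("intmap", {
    out <- list()
    for (id in kept_ids) {
      sub <- cohort$subjects[[id]]
      clean <- preprocess_bold(sub$bold, sub$confounds,
                               discard_n = config$preprocessing$discard_n,
                               band = config$preprocessing$band,
                               expand_motion = isTRUE(config$preprocessing$expand_motion))
      m <- compute_int_map(clean, mask = mask,
                           include_lag0 = isTRUE(config$int$include_lag0),
                           method = config$int$auc)
      out[[id]] <- smooth_map(m, config$int$fwhm_mm)
      cohort$subjects[[id]] <- NULL # free the 4D volume
    }
    out
  })
  if (isTRUE(config$write_images)) {
    img_dir <- file.path(out_dir, "int_maps")
    dir.create(img_dir, showWarnings = FALSE)
    for (id in names(maps)) {
      write_int_map(maps[[id]], file.path(img_dir, paste0(id, "_int.nii.gz")),
                    options = config$int)
    }
  }

  # -- summarize -----------------------------------------------------------
  rois <- config$rois
  if (is.null(rois)) {
    rois <- list(
      ag = sphere_roi(.parcel_centroid_mm(atlas, "AG"), config$roi_radius_mm,
                      atlas$geometry),
      smg = sphere_roi(.parcel_centroid_mm(atlas, "SMG"), config$roi_radius_mm,
                       atlas$geometry)
    )
  }
  summary_tbl <- run_stage("summarize",
                           summarize_int(maps, atlas, qc$kept, rois = rois))
  readr::write_tsv(.round_tbl(summary_tbl), file.path(out_dir, "summary.tsv"))
  readr::write_tsv(
    dplyr::select(dplyr::mutate(cohort$phenotypes, kept = .data$id %in% kept_ids),
                  dplyr::all_of(c("id", "group", "mean_motion_mm", "kept"))),
    file.path(out_dir, "qc.tsv")
  )

  # -- group stats ---------------------------------------------------------
  stats_res <- run_stage("stats", {
    cn <- summary_tbl$dmn_int[summary_tbl$group == "CN"]
    ad <- summary_tbl$dmn_int[summary_tbl$group == "AD"]
    dmn_test <- two_sample_t(cn, ad)
    ad_tbl <- summary_tbl[summary_tbl$group == "AD", ]
    sw <- normality_test(ad_tbl$mmse)
    dmn_mmse <- pearson_bootstrap(ad_tbl$dmn_int, ad_tbl$mmse,
                                  config$stats$n_boot,
                                  derive_seed(config$seed, "dmn_mmse"))
    list(dmn_test = dmn_test, shapiro_mmse = sw, dmn_mmse = dmn_mmse)
  })
  group_tbl <- dplyr::bind_cols(tibble::tibble(test = "dmn_int_cn_vs_ad"),
                                tidy(stats_res$dmn_test))
  readr::write_tsv(.round_tbl(group_tbl), file.path(out_dir, "group_tests.tsv"))

  clusters <- run_stage("clusters", cluster_fwe_perm(
    maps, qc$kept,
    cluster_forming_p = config$stats$cluster_p,
    n_perm = config$stats$n_perm,
    seed = derive_seed(config$seed, "perm"),
    connectivity = config$stats$connectivity
  ))
  readr::write_tsv(.round_tbl(clusters), file.path(out_dir, "clusters.tsv"))

  # -- mediation (within the AD group) ------------------------------------
  suite <- run_stage("mediate", {
    ad_tbl <- summary_tbl[summary_tbl$group == "AD", ]
    run_model_suite(ad_tbl, n_boot = config$stats$n_boot,
                    seed = derive_seed(config$seed, "mediate"))
  })
  readr::write_tsv(.round_tbl(dplyr::select(suite, -"fits")),
                   file.path(out_dir, "mediation.tsv"))
  jsonlite::write_json(dplyr::select(suite, -"fits"),
                       file.path(out_dir, "mediation.json"),
                       auto_unbox = TRUE, digits = 10, na = "null")

  # -- cognitive components ------------------------------------------------
  components_res <- run_stage("components", {
    comp <- componentize(summary_tbl)
    ad_ids <- summary_tbl$id[summary_tbl$group == "AD"]
    component_correlations(comp[comp$id %in% ad_ids, ], summary_tbl,
                           n_boot = config$stats$n_boot,
                           seed = derive_seed(config$seed, "components"))
  })
  readr::write_tsv(.round_tbl(components_res), file.path(out_dir, "components.tsv"))

  manifest <- .write_manifest(out_dir, config_hash, config$seed, stage_status)
  manifest$results <- list(
    qc = qc, summary = summary_tbl, group = stats_res, clusters = clusters,
    mediation = suite, components = components_res
  )
  invisible(manifest)
}

# deterministic text output: round numerics to a fixed precision
.round_tbl <- function(tbl, digits = 6) {
  dplyr::mutate(tbl, dplyr::across(dplyr::where(is.numeric), ~ round(.x, digits)))
}

.write_manifest <- function(out_dir, config_hash, seed, stage_status) {
  manifest <- list(
    package = "neurotime",
    version = as.character(utils::packageVersion("neurotime")),
    config_hash = config_hash,
    seed = seed,
    stages = stage_status
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest
}
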