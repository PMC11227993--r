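# Shared fixture builders: everything is generated in code at test time.

# a 6x6x4 two-parcel atlas for fast image-level tests
tiny_atlas <- function() {
  make_toy_atlas(
    atlas_geometry(c(6L, 6L, 4L), 4),
    list(
      boxA = list(box = rbind(c(1, 3), c(1, 3), c(1, 2)), network = "netA"),
      boxB = list(box = rbind(c(4, 6), c(4, 6), c(3, 4)), network = "netB")
    )
  )
}

# a small planted-deficit cohort specification (AG slowed in AD)
deficit_spec <- function(n_per_group = 15, phi_cn_ag = 0.8, phi_ad_ag = 0.5,
                         seed = 1) {
  phis <- cohort_spec()$phi_by_region_and_group
  phis$CN[["AG"]] <- phi_cn_ag
  phis$AD[["AG"]] <- phi_ad_ag
  phis$AD[["DMN-core"]] <- phis$CN[["DMN-core"]]
  cohort_spec(n_cn = n_per_group, n_ad = n_per_group,
              phi_by_region_and_group = phis, seed = seed,
              motion_outlier_rate = 0)
}

# run the per-subject image chain and return smoothed INT maps
cohort_maps <- function(cohort, fwhm_mm = 8) {
  atlas <- cohort$atlas
  mask <- atlas$labels > 0L
  maps <- list()
  for (id in cohort$phenotypes$id) {
    s <- cohort$subjects[[id]]
    clean <- preprocess_bold(s$bold, s$confounds)
    maps[[id]] <- smooth_map(compute_int_map(clean, mask), fwhm_mm)
  }
  maps
}

# an int_map built directly from a 3D array (for ROI / smoothing tests)
map_from_array <- function(values, voxel_mm = 4, tr_s = 2.2, mask = NULL) {
  geom <- atlas_geometry(dim(values), voxel_mm)
  if (is.null(mask)) mask <- array(TRUE, dim = dim(values))
  structure(list(values = values, mask = mask, geometry = geom, tr_s = tr_s),
            class = "int_map")
}
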