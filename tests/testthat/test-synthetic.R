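test_that("toy atlas construction labels disjoint boxes and rejects overlap", {
  geom <- atlas_geometry(c(10L, 10L, 6L), 4)
  parc <- make_toy_atlas(geom, list(
    a = list(box = rbind(c(1, 3), c(1, 3), c(1, 2)), network = "n1"),
    b = list(box = rbind(c(5, 8), c(5, 8), c(3, 5)), network = "n2")
  ))
  expect_setequal(unique(as.vector(parc$labels)), c(0L, 1L, 2L))
  expect_equal(sum(parc$labels == 1L), 3 * 3 * 2)
  expect_equal(sum(parc$labels == 2L), 4 * 4 * 3)

  expect_error(
    make_toy_atlas(geom, list(
      a = list(box = rbind(c(1, 4), c(1, 4), c(1, 3)), network = "n1"),
      b = list(box = rbind(c(3, 6), c(3, 6), c(2, 4)), network = "n2")
    )),
    "'a' and 'b' overlap"
  )
  expect_error(
    make_toy_atlas(geom, list(
      a = list(box = rbind(c(1, 11), c(1, 3), c(1, 2)), network = "n1")
    )),
    "outside"
  )
})

test_that("a layout covering every voxel leaves no background", {
  geom <- atlas_geometry(c(4L, 4L, 2L), 4)
  parc <- make_toy_atlas(geom, list(
    left = list(box = rbind(c(1, 2), c(1, 4), c(1, 2)), network = "n1"),
    right = list(box = rbind(c(3, 4), c(1, 4), c(1, 2)), network = "n2")
  ))
  expect_false(any(parc$labels == 0L))
})

test_that("default atlas has the DMN membership structure and six controls", {
  at <- toy_atlas()
  expect_equal(unname(at$network_of[c("AG", "SMG", "DMN-core")]),
               rep("DMN", 3))
  expect_length(setdiff(unique(unname(at$network_of)), "DMN"), 6)
})

test_that("atlas NIfTI round-trip preserves labels and lookup tables", {
  at <- tiny_atlas()
  path <- file.path(withr::local_tempdir(), "atlas.nii.gz")
  write_atlas(at, path)
  back <- read_atlas(path)
  expect_identical(back$labels, at$labels)
  expect_equal(back$network_of, at$network_of)
  expect_equal(back$geometry$origin_mm, at$geometry$origin_mm)
})

test_that("simulate_ar1 is stationary, reproducible, and matches theory", {
  # white noise: lag-1 autocorrelation near zero
  w <- simulate_ar1(0, 5000, 1, seed = 3)
  expect_lt(abs(sample_acf(w, 1)$values[1]), 3 / sqrt(5000))
  # phi = 0.8 at large n: sample lag-1 within +/- 0.01 of theory
  x <- simulate_ar1(0.8, 100000, 1, seed = 11)
  expect_lt(abs(sample_acf(x, 1)$values[1] - 0.8), 0.01)
  # determinism
  expect_identical(simulate_ar1(0.5, 100, 2, seed = 9),
                   simulate_ar1(0.5, 100, 2, seed = 9))
  expect_error(simulate_ar1(1, 100), "phi")
  expect_error(simulate_ar1(-1.2, 100), "phi")
})

test_that("subject volumes have the lead-in bookkeeping and parcel AR structure", {
  spec <- cohort_spec(n_cn = 1, n_ad = 1, confound_amplitudes = c(motion = 0, wmcsf = 0),
                      seed = 5)
  at <- toy_atlas()
  sub <- tibble::tibble(id = "CN001", group = "CN")
  out <- simulate_subject_bold(spec, at, sub, seed = 21)
  expect_equal(dim(out$bold$values)[4], 165)
  expect_equal(nrow(out$confounds), 160)
  retained <- discard_initial_volumes(out$bold, 5)
  expect_equal(dim(retained$values)[4], 160)

  # with confounds off, a parcel voxel's lag-1 ACF matches its phi
  lab_ag <- which(at$label_names == "AG")
  vox <- which(at$labels == lab_ag)
  Y <- matrix(retained$values, prod(dim(retained$values)[1:3]), 160)[vox, ]
  rho1 <- apply(Y, 1, function(v) sample_acf(v, 1)$values[1])
  phi_ag <- spec$phi_by_region_and_group$CN[["AG"]]
  # mean over 27 voxels: Monte-Carlo tolerance ~3 * sd/sqrt(27)
  expect_lt(abs(mean(rho1) - phi_ag), 0.06)

  expect_error(
    simulate_subject_bold(spec, at, sub, seed = 1,
                          phi = c(AG = 0.5)),
    "DMN-core"
  )
})

test_that("confound contamination is removable by regression", {
  spec0 <- cohort_spec(n_cn = 1, n_ad = 1,
                       confound_amplitudes = c(motion = 0.5, wmcsf = 3), seed = 5)
  at <- toy_atlas()
  sub <- tibble::tibble(id = "CN001", group = "CN")
  out <- simulate_subject_bold(spec0, at, sub, seed = 77)
  retained <- discard_initial_volumes(out$bold, 5)
  resid <- regress_confounds(retained, out$confounds)
  vox <- which(at$labels > 0)
  v_before <- apply(matrix(retained$values, length(at$labels), 160)[vox, ], 1, var)
  v_after <- apply(matrix(resid$values, length(at$labels), 160)[vox, ], 1, var)
  expect_lt(mean(v_after), mean(v_before))
})

test_that("cohorts are pure functions of their specification", {
  spec <- cohort_spec(n_cn = 3, n_ad = 3, seed = 42)
  ph1 <- simulate_cohort(spec, images = FALSE)$phenotypes
  ph2 <- simulate_cohort(spec, images = FALSE)$phenotypes
  expect_identical(ph1, ph2)
  # and the planted deficit orders the generative timescales
  spec_gap <- deficit_spec(n_per_group = 25, seed = 8)
  ph <- simulate_cohort(spec_gap, images = FALSE)$phenotypes
  expect_lt(mean(ph$gen_tau_ag[ph$group == "AD"]),
            mean(ph$gen_tau_ag[ph$group == "CN"]))
})

test_that("null cohorts give non-significant network group tests at ~nominal rate", {
  # no planted differences: the DMN group t-test should be non-significant
  # in >= 90% of replicates (5% nominal type-I error per replicate)
  p_vals <- vapply(1:20, function(r) {
    spec <- null_cohort_spec(n_cn = 12, n_ad = 12, seed = 1000 + r)
    st <- cohort_summary(spec, n_series = 3)
    two_sample_t(st$dmn_int[st$group == "CN"], st$dmn_int[st$group == "AD"])$p
  }, numeric(1))
  expect_gte(mean(p_vals > 0.05), 0.9)
})
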