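geom1 <- atlas_geometry(c(2L, 2L, 1L), 4)

bold_from_matrix <- function(M, tr_s = 2.2) {
  # M: t x 4 -> 2x2x1xt volume
  bold_4d(array(t(M), dim = c(2, 2, 1, nrow(M))), tr_s, geom1)
}

test_that("initial-volume discard keeps TR and geometry and rejects emptying", {
  M <- matrix(rnorm(4 * 165), 165, 4)
  b <- bold_from_matrix(M)
  d <- discard_initial_volumes(b, 5)
  expect_equal(dim(d$values)[4], 160)
  expect_equal(d$tr_s, b$tr_s)
  expect_equal(as.vector(d$values[1, 1, 1, ]), M[6:165, 1])
  expect_identical(discard_initial_volumes(b, 0), b)
  expect_error(discard_initial_volumes(b, 165), "empty")
})

test_that("framewise displacement follows the backward-difference formula", {
  m <- matrix(0, 10, 6,
              dimnames = list(NULL, c("trans_x", "trans_y", "trans_z",
                                      "rot_x", "rot_y", "rot_z")))
  expect_equal(framewise_displacement(m), rep(0, 10))
  m2 <- m; m2[5:10, "trans_x"] <- 1 # one step of +1 mm at frame 5
  fd <- framewise_displacement(m2)
  expect_equal(fd[5], 1.0)
  expect_equal(fd[-5], rep(0, 9))
  m3 <- m; m3[4:10, "rot_y"] <- 0.02 # 0.02 rad at 50 mm radius -> 1 mm
  expect_equal(framewise_displacement(m3, radius_mm = 50)[4], 1.0)
  expect_error(framewise_displacement(m[1, , drop = FALSE]), "two frames")
  m4 <- m; m4[3, 1] <- NA
  expect_error(framewise_displacement(m4), "finite")
})

test_that("confound regression projects exactly and reports collinearity", {
  set.seed(1)
  n <- 120
  conf <- tibble::tibble(wm = rnorm(n), csf = rnorm(n))
  # voxel 1 = the wm column itself; voxel 2 = orthogonal zero-mean series
  ortho <- qr.resid(qr(cbind(1, conf$wm, conf$csf)), rnorm(n))
  M <- cbind(conf$wm, ortho, rnorm(n), rnorm(n))
  b <- bold_from_matrix(M)
  r <- regress_confounds(b, conf)
  R <- matrix(r$values, 4, n) # voxels x time
  expect_lt(max(abs(R[1, ])), 1e-10)
  expect_equal(R[2, ], ortho, tolerance = 1e-10)
  # residuals orthogonal to every confound column (relative inner product)
  for (j in 1:2) {
    ip <- abs(colSums(t(R) * conf[[j]])) / (sqrt(colSums(t(R)^2)) * sqrt(sum(conf[[j]]^2)))
    expect_lt(max(ip[is.finite(ip)]), 1e-8)
  }
  expect_error(
    regress_confounds(b, tibble::tibble(wm = conf$wm, wm2 = 2 * conf$wm)),
    "collinear"
  )
  expect_error(regress_confounds(b, conf[1:50, ]), "rows")
})

test_that("band-pass keeps in-band tones, rejects out-of-band power and DC", {
  tr <- 2.2; n <- 512; tt <- (0:(n - 1)) * tr
  amp <- function(bold) {
    v <- as.vector(bold$values)[51:(n - 50)]
    sqrt(mean(v^2)) * sqrt(2)
  }
  tone <- function(f) bold_4d(array(rep(sin(2 * pi * f * tt), each = 4),
                                    dim = c(2, 2, 1, n)), tr, geom1)
  expect_gt(amp(bandpass_filter(tone(0.05))), 0.9)
  expect_lt(amp(bandpass_filter(tone(0.2))), 0.2)
  dc <- bold_4d(array(1, dim = c(2, 2, 1, n)), tr, geom1)
  expect_lt(mean(abs(as.vector(bandpass_filter(dc)$values))), 1e-3)
  expect_error(bandpass_filter(tone(0.05), 0.1, 0.01), "band")
  expect_error(bandpass_filter(tone(0.05), 0.01, 0.3), "Nyquist")
})

test_that("regression and filtering are linear operators", {
  set.seed(2)
  n <- 160
  conf <- tibble::tibble(wm = rnorm(n), csf = rnorm(n))
  X <- matrix(rnorm(4 * n), n, 4)
  Y <- matrix(rnorm(4 * n), n, 4)
  lin_err <- function(f) {
    fx <- f(bold_from_matrix(X))$values
    fy <- f(bold_from_matrix(Y))$values
    fxy <- f(bold_from_matrix(2 * X - 3 * Y))$values
    max(abs(fxy - (2 * fx - 3 * fy))) / max(abs(fxy))
  }
  expect_lt(lin_err(function(b) regress_confounds(b, conf)), 1e-8)
  expect_lt(lin_err(function(b) bandpass_filter(b)), 1e-8)
})

test_that("preprocessing recovers the band-passed AR(1) autocorrelation", {
  # contaminated voxels, after the full chain, should match the lag-1 ACF of
  # the same filter applied to confound-free AR(1) draws (the oracle)
  spec <- cohort_spec(n_cn = 1, n_ad = 1,
                      confound_amplitudes = c(motion = 0.3, wmcsf = 2), seed = 3)
  at <- toy_atlas()
  sub <- tibble::tibble(id = "CN001", group = "CN")
  out <- simulate_subject_bold(spec, at, sub, seed = 13)
  clean <- preprocess_bold(out$bold, out$confounds)
  lab_core <- which(at$label_names == "DMN-core")
  vox <- which(at$labels == lab_core)
  Y <- matrix(clean$values, length(at$labels), 160)[vox, ]
  rho1 <- mean(apply(Y, 1, function(v) sample_acf(v, 1)$values[1]))

  phi <- spec$phi_by_region_and_group$CN[["DMN-core"]]
  ref <- vapply(1:60, function(i) {
    x <- simulate_ar1(phi, 160, 1, seed = 9000 + i)
    b <- bold_4d(array(rep(x, each = 4), dim = c(2, 2, 1, 160)), spec$tr_s, geom1)
    sample_acf(as.vector(bandpass_filter(b)$values[1, 1, 1, ]), 1)$values[1]
  }, numeric(1))
  expect_lt(abs(rho1 - mean(ref)), 0.05)
})

test_that("motion QC partitions subjects exhaustively", {
  subs <- tibble::tibble(id = c("a", "b"), mean_motion_mm = c(1.0, 3.5))
  qc <- qc_filter_subjects(subs, 3)
  expect_equal(qc$kept$id, "a")
  expect_equal(qc$excluded$id, "b")
  expect_equal(nrow(qc$kept) + nrow(qc$excluded), nrow(subs))
  all_low <- tibble::tibble(id = c("a", "b"), mean_motion_mm = c(0.2, 1.1))
  expect_equal(nrow(qc_filter_subjects(all_low, 3)$excluded), 0)
  expect_error(qc_filter_subjects(subs, 0), "positive")
})
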