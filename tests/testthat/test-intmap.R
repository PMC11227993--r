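test_that("sample ACF matches closed forms", {
  # alternating series: biased lag-1 estimate is -(n-1)/n
  alt <- rep(c(1, -1), 50)
  expect_equal(sample_acf(alt, 1)$values[1], -99 / 100, tolerance = 1e-12)
  # AR(1) phi = 0.6 at large n: rho(k) ~ phi^k
  x <- simulate_ar1(0.6, 100000, 1, seed = 4)
  a <- sample_acf(x, 2)
  expect_lt(abs(a$values[1] - 0.6), 0.01)
  expect_lt(abs(a$values[2] - 0.36), 0.02)
  # white noise stays inside the 3/sqrt(n) band at lags 1..5 for most seeds
  inside <- vapply(1:50, function(s) {
    w <- simulate_ar1(0, 400, 1, seed = 100 + s)
    all(abs(sample_acf(w, 5)$values) < 3 / sqrt(400))
  }, logical(1))
  expect_gte(mean(inside), 0.95)
  expect_error(sample_acf(rep(1, 50), 3), "constant")
  expect_error(sample_acf(rnorm(5), 10), "short")
})

test_that("the ACF-area timescale follows its definition on hand cases", {
  expect_equal(int_from_acf(c(0.5, -0.2, 0.4), 2.2), 1.1)
  expect_equal(int_from_acf(c(-0.4, 0.5), 2.2), 0)
  expect_equal(int_from_acf(c(0.3, 0.2, 0, 0.5), 2.2), 2.2 * 0.5) # tie at 0 terminates
  expect_equal(int_from_acf(c(0.5, -0.2), 2.2, include_lag0 = TRUE), 2.2 * 1.5)
  # trapezoid: nodes 1, 0.5 then the window ends -> area 0.75
  expect_equal(int_from_acf(c(0.5, -0.2), 2.2, method = "trapezoid"), 2.2 * 0.75)
})

test_that("timescale is nonnegative, scale invariant, and zero iff rho1 <= 0", {
  for (s in 1:10) {
    x <- simulate_ar1(runif(1, -0.5, 0.9), 200, 1, seed = 300 + s)
    i1 <- int_from_series(x, 2.2)
    expect_gte(i1, 0)
    expect_equal(int_from_series(3.5 * x - 2, 2.2), i1, tolerance = 1e-12)
    rho1 <- sample_acf(x, 1)$values[1]
    if (rho1 <= 0) expect_equal(i1, 0)
  }
})

test_that("mean estimated timescale is strictly increasing in phi", {
  phis <- c(0.2, 0.4, 0.6, 0.8)
  means <- vapply(phis, function(phi) {
    mean(vapply(1:50, function(s) {
      int_from_series(simulate_ar1(phi, 160, 1, seed = round(phi * 1e4) + s), 2.2)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("INT maps respect masks, degenerate voxels, and parcel ordering", {
  at <- tiny_atlas()
  d <- at$geometry$grid_dims
  nt <- 160
  vals <- array(rnorm(prod(d) * nt), dim = c(d, nt))
  labA <- which(at$label_names == "boxA")
  labB <- which(at$label_names == "boxB")
  for (v in which(at$labels == labA)) {
    idx <- arrayInd(v, d)
    vals[idx[1], idx[2], idx[3], ] <- simulate_ar1(0.8, nt, 1, seed = 5000 + v)
  }
  for (v in which(at$labels == labB)) {
    idx <- arrayInd(v, d)
    vals[idx[1], idx[2], idx[3], ] <- simulate_ar1(0.2, nt, 1, seed = 6000 + v)
  }
  bold <- bold_4d(vals, 2.2, at$geometry)
  mask <- at$labels > 0
  m <- compute_int_map(bold, mask)
  expect_gt(median(m$values[at$labels == labA], na.rm = TRUE),
            median(m$values[at$labels == labB], na.rm = TRUE))
  expect_true(all(is.na(m$values[!mask])))

  # a constant voxel inside the mask is flagged undefined, the rest computed
  vals2 <- vals
  vals2[1, 1, 1, ] <- 7
  m2 <- compute_int_map(bold_4d(vals2, 2.2, at$geometry), mask)
  expect_true(is.na(m2$values[1, 1, 1]))
  expect_equal(attr(m2, "n_undefined"), 1L)
  expect_equal(m2$values[4, 4, 3], m$values[4, 4, 3])

  # locality: background content cannot change in-mask values
  vals3 <- vals
  vals3[!array(rep(mask, nt), dim = c(d, nt))] <- rnorm(sum(!mask) * nt, 50, 9)
  m3 <- compute_int_map(bold_4d(vals3, 2.2, at$geometry), mask)
  expect_equal(m3$values[mask], m$values[mask])

  expect_error(compute_int_map(bold, array(FALSE, dim = d)), "mask")
})

test_that("estimated INT agrees with an independent brute-force oracle", {
  # straight-line reimplementation of the definition, on shorter series
  oracle <- function(x, tr) {
    xc <- x - mean(x); n <- length(x); s0 <- sum(xc^2)
    total <- 0
    for (k in 1:floor(n / 2)) {
      r <- sum(xc[1:(n - k)] * xc[(k + 1):n]) / s0
      if (r <= 0) break
      total <- total + r
    }
    tr * total
  }
  for (phi in c(0.3, 0.7)) {
    for (s in 1:10) {
      x <- simulate_ar1(phi, 2000, 1, seed = 700 + s)
      expect_equal(int_from_series(x, 2.2), oracle(x, 2.2), tolerance = 1e-12)
    }
  }
})

test_that("mask-aware smoothing preserves constants, mass, and kernel shape", {
  at <- tiny_atlas()
  d <- at$geometry$grid_dims
  mask <- at$labels > 0

  uniform <- array(NA_real_, dim = d); uniform[mask] <- 5
  sm <- smooth_map(map_from_array(uniform, mask = mask), 8)
  expect_equal(sm$values[mask], rep(5, sum(mask)), tolerance = 1e-6)

  # impulse on a full mask: mass conserved within 1%, kernel ratio matches
  # sigma = 8 / (4 * sqrt(8 log 2)) = 0.849 voxels
  big <- array(0, dim = c(11, 11, 11))
  big[6, 6, 6] <- 1
  smi <- smooth_map(map_from_array(big), 8)
  expect_equal(sum(smi$values), 1, tolerance = 0.01)
  sigma <- 8 / (4 * sqrt(8 * log(2)))
  expect_equal(smi$values[7, 6, 6] / smi$values[6, 6, 6],
               exp(-1 / (2 * sigma^2)), tolerance = 1e-6)

  # group ordering of parcel means survives smoothing
  vals <- array(NA_real_, dim = d)
  labA <- which(at$label_names == "boxA"); labB <- which(at$label_names == "boxB")
  vals[at$labels == labA] <- 4; vals[at$labels == labB] <- 2
  smp <- smooth_map(map_from_array(vals, mask = mask), 8)
  expect_gt(mean(smp$values[at$labels == labA]),
            mean(smp$values[at$labels == labB]))
})

test_that("INT map NIfTI round-trip preserves values and TR", {
  at <- tiny_atlas()
  vals <- array(NA_real_, dim = at$geometry$grid_dims)
  vals[at$labels > 0] <- runif(sum(at$labels > 0), 1, 5)
  m <- map_from_array(vals, mask = array(TRUE, dim = dim(vals)))
  path <- file.path(withr::local_tempdir(), "int.nii.gz")
  write_int_map(m, path)
  back <- read_int_map(path)
  expect_equal(back$tr_s, 2.2)
  expect_equal(back$values, m$values, tolerance = 1e-6)
})
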