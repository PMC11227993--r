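test_that("eta-squared identity reproduces hand and printed values", {
  expect_equal(eta_squared_from_t(0, 100), 0)
  expect_equal(round(eta_squared_from_t(2.33, 168), 2), 0.03)
  expect_equal(round(eta_squared_from_t(5.77, 168), 2), 0.17)
  expect_error(eta_squared_from_t(1, 0), "df")
})

test_that("pooled-variance t test matches hand evaluation and is antisymmetric", {
  r <- two_sample_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$t, -3 / sqrt(2 / 3), tolerance = 1e-12) # = -3.674
  expect_equal(r$df, 4)
  expect_equal(r$eta2, r$t^2 / (r$t^2 + r$df), tolerance = 1e-12)
  r2 <- two_sample_t(c(4, 5, 6), c(1, 2, 3))
  expect_equal(r2$t, -r$t)
  expect_equal(r2$p, r$p)

  same <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_equal(same$eta2, 0)
  expect_error(two_sample_t(c(1, 1), c(1, 1)), "variance")
  expect_error(two_sample_t(1, c(1, 2)), "at least 2")

  td <- tidy(r)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$eta2, r$eta2)
})

test_that("bootstrap correlation handles exact, null and noisy cases", {
  x <- 1:20
  exact <- pearson_bootstrap(x, 2 * x, n_boot = 500, seed = 1)
  expect_equal(exact$r, 1)
  expect_equal(exact$p_boot, 1 / 500)

  set.seed(4)
  a <- rnorm(50)
  b <- qr.resid(qr(cbind(1, a)), rnorm(50)) # exactly orthogonal, zero-mean
  orth <- pearson_bootstrap(a, b, n_boot = 500, seed = 2)
  expect_lt(abs(orth$r), 1e-12)
  expect_gt(orth$p_boot, 0.5)

  # mean sample r across replicates is close to the population rho
  rs <- vapply(1:200, function(i) {
    withr::with_seed(3000 + i, {
      x <- rnorm(100); y <- 0.6 * x + sqrt(1 - 0.36) * rnorm(100)
      pearson_bootstrap(x, y, n_boot = 50, seed = i)$r
    })
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.6), 0.03)

  sw <- pearson_bootstrap(a, b, n_boot = 500, seed = 2)
  sw2 <- pearson_bootstrap(b, a, n_boot = 500, seed = 2)
  expect_equal(sw$p_boot, sw2$p_boot) # relabelling invariance
  expect_error(pearson_bootstrap(rep(1, 10), rnorm(10)), "constant")
  expect_error(pearson_bootstrap(1:2, 2:1), "3 complete")
})

test_that("normality screen has nominal level and power against skew", {
  p_norm <- vapply(1:50, function(s) {
    withr::with_seed(s, normality_test(rnorm(100))$p.value)
  }, numeric(1))
  expect_gte(mean(p_norm > 0.05), 0.9)
  p_skew <- vapply(1:50, function(s) {
    withr::with_seed(s, normality_test(exp(rnorm(100)))$p.value)
  }, numeric(1))
  expect_gte(mean(p_skew < 0.05), 0.9)
  expect_error(normality_test(c(1, 2)), "3")
})

test_that("Bonferroni correction multiplies and caps", {
  expect_equal(bonferroni_correct(0.008, 2), 0.016)
  expect_equal(bonferroni_correct(0.007, 5), 0.035)
  expect_equal(bonferroni_correct(0.7, 2), 1)
  expect_error(bonferroni_correct(1.2, 2), "0, 1")
})

test_that("voxelwise GLM reduces to the two-sample t and is calibrated under the null", {
  at <- tiny_atlas()
  d <- at$geometry$grid_dims
  set.seed(9)
  n <- 24
  groups <- rep(c("CN", "AD"), each = n / 2)
  maps <- lapply(seq_len(n), function(i) {
    map_from_array(array(rnorm(prod(d)), dim = d))
  })
  names(maps) <- sprintf("s%02d", seq_len(n))
  pheno <- tibble::tibble(id = names(maps), group = groups,
                          age = rnorm(n, 70, 5), sex = rep(c("F", "M"), n / 2))
  glm0 <- voxelwise_glm_t(maps, pheno, covariates = character(0))
  v <- c(2, 2, 1)
  tt <- two_sample_t(
    vapply(maps[groups == "CN"], function(m) m$values[v[1], v[2], v[3]], numeric(1)),
    vapply(maps[groups == "AD"], function(m) m$values[v[1], v[2], v[3]], numeric(1))
  )
  expect_equal(glm0$t_map[v[1], v[2], v[3]], tt$t, tolerance = 1e-6)

  # null calibration with covariates: ~5% of voxels above the 0.05 critical value
  glm1 <- voxelwise_glm_t(maps, pheno)
  tcrit <- qt(0.975, glm1$df)
  frac <- mean(abs(glm1$t_map[is.finite(glm1$t_map)]) > tcrit)
  expect_lt(abs(frac - 0.05), 0.05)
})

test_that("cluster labelling respects connectivity", {
  m <- array(FALSE, dim = c(5, 5, 5))
  m[2:4, 2:4, 2:4] <- TRUE
  lab <- label_clusters(m, 6)
  expect_equal(max(lab), 1)
  expect_equal(sum(lab == 1), 27)
  # two voxels touching only at a corner: separate at 6, joined at 26
  m2 <- array(FALSE, dim = c(4, 4, 4))
  m2[1, 1, 1] <- TRUE; m2[2, 2, 2] <- TRUE
  expect_equal(max(label_clusters(m2, 6)), 2)
  expect_equal(max(label_clusters(m2, 26)), 1)
  expect_equal(max(label_clusters(array(FALSE, dim = c(3, 3, 3)))), 0)
})

test_that("permutation cluster FWE detects a planted block and returns empty under none", {
  at <- tiny_atlas()
  d <- at$geometry$grid_dims
  set.seed(12)
  n <- 20
  groups <- rep(c("CN", "AD"), each = n / 2)
  block <- array(FALSE, dim = d); block[1:3, 1:3, 1:3] <- TRUE
  maps <- lapply(seq_len(n), function(i) {
    v <- array(rnorm(prod(d)), dim = d)
    if (groups[i] == "CN") v[block] <- v[block] + 10
    map_from_array(v)
  })
  names(maps) <- sprintf("s%02d", seq_len(n))
  pheno <- tibble::tibble(id = names(maps), group = groups,
                          age = rnorm(n, 70, 5), sex = rep(c("F", "M"), n / 2))
  cl <- cluster_fwe_perm(maps, pheno, n_perm = 200, seed = 7)
  expect_gte(nrow(cl), 1)
  expect_equal(cl$size_voxels[1], 27)
  expect_lte(cl$p_fwe[1], 1 / 200 + 0.01)

  null_maps <- lapply(seq_len(n), function(i) map_from_array(array(rnorm(prod(d)), dim = d)))
  names(null_maps) <- names(maps)
  cl0 <- cluster_fwe_perm(null_maps, pheno, cluster_forming_p = 1e-8, n_perm = 100, seed = 7)
  expect_equal(nrow(cl0), 0)
})
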