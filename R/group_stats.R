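#' Eta-squared effect size of a t statistic
#'
#' `eta^2 = t^2 / (t^2 + df)` — the share of variance in the outcome
#' attributable to the group factor. Conventional anchors: 0.01 small,
#' 0.06 medium, 0.14 large.
#'
#' @param t t statistic.
#' @param df Degrees of freedom, `>= 1`.
#' @return Numeric in `[0, 1]`.
#' @examples
#' eta_squared_from_t(2.33, 168) # ~0.03
#' @export
eta_squared_from_t <- function(t, df) {
  if (!is.numeric(df) || any(df < 1)) abort("`df` must be >= 1")
  t^2 / (t^2 + df)
}

#' Pooled-variance two-sample t test with effect size
#'
#' Student's two-sample t with pooled variance, `df = n_a + n_b - 2`,
#' two-tailed p, and eta-squared via [eta_squared_from_t()]. The pooled
#' (not Welch) form is used so that the degrees of freedom equal the
#' combined sample size minus two.
#'
#' @param a,b Numeric vectors, each of length `>= 2`.
#' @return A `group_test` object (one-row-tibble-friendly list): `t`, `df`,
#'   `p`, `eta2`, `mean_a`, `mean_b`, `n_a`, `n_b`.
#' @export
two_sample_t <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2) abort("each group needs at least 2 values")
  na <- length(a); nb <- length(b)
  df <- na + nb - 2
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / df
  if (sp2 <= 0) abort("zero pooled variance: groups are constant")
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  structure(
    list(t = t, df = df, p = 2 * pt(-abs(t), df),
         eta2 = eta_squared_from_t(t, df),
         mean_a = mean(a), mean_b = mean(b), n_a = na, n_b = nb),
    class = "group_test"
  )
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("t(%d) = %.3f, p = %.4g, eta^2 = %.3f\n", x$df, x$t, x$p, x$eta2))
  invisible(x)
}

#' @export
tidy.group_test <- function(x, ...) {
  tibble::tibble(t = x$t, df = x$df, p.value = x$p, eta2 = x$eta2,
                 estimate = x$mean_a - x$mean_b)
}

#' @export
glance.group_test <- function(x, ...) tidy(x)

#' Pearson correlation with a non-parametric bootstrap p value
#'
#' The correlation is the ordinary sample Pearson r. Significance comes
#' from resampling subject pairs with replacement `n_boot` times: the
#' two-tailed p is twice the smaller of the fractions of bootstrap
#' correlations at or below / at or above zero (the sign-crossing
#' percentile construction), floored at `1/n_boot`. Robust to the
#' non-normal score distributions that rule out parametric tests.
#'
#' @param x,y Numeric vectors (pairs with missing values are dropped);
#'   `n >= 3` complete pairs, both non-constant.
#' @param n_boot Bootstrap resamples.
#' @param seed Integer seed.
#' @return A `cor_boot` object: `r`, `p_boot`, `ci_low`, `ci_high`
#'   (percentile 95%), `n`, `n_boot`.
#' @export
pearson_bootstrap <- function(x, y, n_boot = 10000, seed = 1) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) abort("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) abort("constant input: correlation undefined")
  r <- cor(x, y)
  rb <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      xs <- x[idx]; ys <- y[idx]
      if (sd(xs) == 0 || sd(ys) == 0) return(NA_real_)
      cor(xs, ys)
    }, numeric(1))
  })
  rb <- rb[is.finite(rb)]
  p <- 2 * min(mean(rb <= 0), mean(rb >= 0))
  p <- min(1, max(p, 1 / n_boot))
  structure(
    list(r = r, p_boot = p,
         ci_low = unname(quantile(rb, 0.025)),
         ci_high = unname(quantile(rb, 0.975)),
         n = n, n_boot = n_boot),
    class = "cor_boot"
  )
}

#' @export
print.cor_boot <- function(x, ...) {
  cat(sprintf("r = %.3f (n = %d), bootstrap p = %.4g, 95%% CI [%.3f, %.3f]\n",
              x$r, x$n, x$p_boot, x$ci_low, x$ci_high))
  invisible(x)
}

#' @export
tidy.cor_boot <- function(x, ...) {
  tibble::tibble(estimate = x$r, p.value = x$p_boot,
                 conf.low = x$ci_low, conf.high = x$ci_high,
                 n = x$n, n_boot = x$n_boot)
}

#' Shapiro-Wilk normality screen
#'
#' Thin wrapper over [stats::shapiro.test()], used to gate which p value is
#' reported in summaries (the bootstrap p is always computed regardless).
#'
#' @param x Numeric vector, `3 <= n <= 5000`, non-constant.
#' @return Tibble with `W` and `p.value`.
#' @export
normality_test <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 3) abort("Shapiro-Wilk needs at least 3 values")
  if (sd(x) == 0) abort("constant input")
  s <- stats::shapiro.test(x)
  tibble::tibble(W = unname(s$statistic), p.value = s$p.value)
}

#' Bonferroni correction
#'
#' @param p Uncorrected p value(s) in `[0, 1]`.
#' @param m Number of comparisons, `>= 1`.
#' @return `min(1, m * p)`, vectorised over `p`.
#' @examples
#' bonferroni_correct(0.008, 2) # 0.016
#' @export
bonferroni_correct <- function(p, m) {
  if (!.is_count(m)) abort("`m` must be a positive integer")
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("`p` must lie in [0, 1]")
  pmin(1, m * p)
}

# t statistics for one design column across all voxel columns of Y
# X: n x p design, Y: n x v responses, col: coefficient index
.glm_t_matrix <- function(X, Y, col) {
  qx <- qr(X)
  if (qx$rank < ncol(X)) abort("voxelwise design is rank deficient")
  coefs <- qr.coef(qx, Y)
  res <- qr.resid(qx, Y)
  df <- nrow(X) - ncol(X)
  sigma2 <- colSums(res^2) / df
  xtxinv <- solve(crossprod(X))[col, col]
  list(t = coefs[col, ] / sqrt(sigma2 * xtxinv), df = df)
}

#' Voxelwise group comparison with nuisance covariates
#'
#' Fits, at every voxel defined in all subjects, the linear model
#' `INT ~ intercept + group + age + sex` and returns the t map of the group
#' contrast (coded CN minus AD, so positive t means longer timescales in
#' the CN group).
#'
#' @param maps Named list of `int_map`, one per subject, common grid.
#' @param pheno Phenotype tibble with `id`, `group` (`"CN"`/`"AD"`), `age`,
#'   `sex`; rows matched to `maps` by `id`.
#' @param covariates Character vector of nuisance columns (default
#'   `c("age", "sex")`; may be empty).
#' @return A list: `t_map` (3D array, `NA` where undefined), `df`, `mask`
#'   (voxels tested), `geometry`.
#' @export
voxelwise_glm_t <- function(maps, pheno, covariates = c("age", "sex")) {
  stopifnot(length(maps) >= 2, !is.null(names(maps)))
  pheno <- pheno[match(names(maps), pheno$id), , drop = FALSE]
  if (anyNA(pheno$id)) abort("every map needs a phenotype row with matching id")
  if (min(table(pheno$group)) < 3) abort("need at least 3 subjects per group")
  d <- dim(maps[[1]]$values)
  Y <- vapply(maps, function(m) as.vector(m$values), numeric(prod(d)))
  defined <- rowSums(!is.finite(Y)) == 0 & as.vector(maps[[1]]$mask)
  if (!any(defined)) abort("no voxel is defined in every subject")
  X <- .group_design(pheno, covariates)
  fit <- .glm_t_matrix(X, t(Y[defined, , drop = FALSE]), col = 2L)
  t_map <- array(NA_real_, dim = d)
  t_map[defined] <- fit$t
  list(t_map = t_map, df = fit$df,
       mask = array(defined, dim = d), geometry = maps[[1]]$geometry)
}

.group_design <- function(pheno, covariates) {
  g <- ifelse(pheno$group == "CN", 1, 0)
  X <- cbind(intercept = 1, group = g)
  for (cv in covariates) {
    v <- pheno[[cv]]
    if (is.character(v) || is.factor(v)) v <- as.numeric(factor(v)) - 1
    X <- cbind(X, v)
    colnames(X)[ncol(X)] <- cv
  }
  X
}

#' Label connected components of a 3D logical array
#'
#' @param mask 3D logical array.
#' @param connectivity 6 (faces), 18 (faces+edges) or 26 (full).
#' @return Integer array of component labels (0 = background).
#' @export
label_clusters <- function(mask, connectivity = 6) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3,
            connectivity %in% c(6, 18, 26))
  d <- dim(mask)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nz <- rowSums(abs(offs))
  offs <- switch(as.character(connectivity),
                 "6" = offs[nz == 1, , drop = FALSE],
                 "18" = offs[nz >= 1 & nz <= 2, , drop = FALSE],
                 "26" = offs[nz >= 1, , drop = FALSE])
  labels <- array(0L, dim = d)
  lin_all <- which(mask)
  if (length(lin_all) == 0) return(labels)
  coord <- arrayInd(lin_all, d)
  in_mask <- array(FALSE, dim = d)
  in_mask[lin_all] <- TRUE
  current <- 0L
  for (s in seq_along(lin_all)) {
    if (labels[lin_all[s]] != 0L) next
    current <- current + 1L
    queue <- matrix(coord[s, ], 1)
    labels[lin_all[s]] <- current
    while (nrow(queue) > 0) {
      nxt <- NULL
      for (q in seq_len(nrow(queue))) {
        nb <- sweep(offs, 2, queue[q, ], `+`)
        ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
              nb[, 2] >= 1 & nb[, 2] <= d[2] &
              nb[, 3] >= 1 & nb[, 3] <= d[3]
        nb <- nb[ok, , drop = FALSE]
        if (nrow(nb) == 0) next
        lin <- nb[, 1] + d[1] * (nb[, 2] - 1) + d[1] * d[2] * (nb[, 3] - 1)
        new <- lin[in_mask[lin] & labels[lin] == 0L]
        if (length(new) > 0) {
          labels[new] <- current
          nxt <- rbind(nxt, arrayInd(new, d))
        }
      }
      queue <- if (is.null(nxt)) matrix(numeric(0), 0, 3) else unique(nxt)
    }
  }
  labels
}

#' Permutation-based cluster-level family-wise error correction
#'
#' Thresholds the voxelwise group t map at the two-tailed cluster-forming
#' level, labels supra-threshold clusters of `|t|`, and assigns each
#' cluster a family-wise-error p value as the fraction of group-label
#' permutations whose maximal supra-threshold cluster size is at least the
#' observed size. Nuisance covariates stay fixed; only the group labels are
#' permuted.
#'
#' @inheritParams voxelwise_glm_t
#' @param cluster_forming_p Two-tailed voxel-level threshold (default
#'   0.001).
#' @param n_perm Number of permutations, `>= 100`.
#' @param seed Integer seed.
#' @param connectivity Cluster connectivity (6, 18 or 26).
#' @return A tibble, one row per observed cluster (possibly empty):
#'   `cluster`, `size_voxels`, `peak_t`, `peak_x_mm`, `peak_y_mm`,
#'   `peak_z_mm`, `p_fwe`.
#' @export
cluster_fwe_perm <- function(maps, pheno, covariates = c("age", "sex"),
                             cluster_forming_p = 0.001, n_perm = 1000,
                             seed = 1, connectivity = 6) {
  if (!.is_count(n_perm) || n_perm < 100) abort("`n_perm` must be >= 100")
  pheno <- pheno[match(names(maps), pheno$id), , drop = FALSE]
  d <- dim(maps[[1]]$values)
  Y_full <- vapply(maps, function(m) as.vector(m$values), numeric(prod(d)))
  defined <- rowSums(!is.finite(Y_full)) == 0 & as.vector(maps[[1]]$mask)
  if (!any(defined)) abort("no voxel is defined in every subject")
  Y <- t(Y_full[defined, , drop = FALSE])
  X <- .group_design(pheno, covariates)
  df <- nrow(X) - ncol(X)
  tcrit <- qt(1 - cluster_forming_p / 2, df)

  observed <- .glm_t_matrix(X, Y, 2L)$t
  def_idx <- which(defined)
  cluster_sizes <- function(tvals) {
    supra <- array(FALSE, dim = d)
    supra[def_idx[abs(tvals) > tcrit]] <- TRUE
    if (!any(supra)) return(list(labels = NULL, sizes = integer(0)))
    labs <- label_clusters(supra, connectivity)
    list(labels = labs, sizes = tabulate(labs[labs > 0]))
  }
  obs <- cluster_sizes(observed)
  if (length(obs$sizes) == 0) {
    return(tibble::tibble(cluster = integer(0), size_voxels = integer(0),
                          peak_t = numeric(0), peak_x_mm = numeric(0),
                          peak_y_mm = numeric(0), peak_z_mm = numeric(0),
                          p_fwe = numeric(0)))
  }
  max_null <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(p) {
      Xp <- X
      Xp[, 2] <- X[sample.int(nrow(X)), 2]
      tv <- .glm_t_matrix(Xp, Y, 2L)$t
      sz <- cluster_sizes(tv)$sizes
      if (length(sz) == 0) 0L else max(sz)
    }, integer(1))
  })
  geometry <- maps[[1]]$geometry
  t_map <- array(NA_real_, dim = d)
  t_map[defined] <- observed
  rows <- lapply(seq_along(obs$sizes), function(cl) {
    vox <- which(obs$labels == cl)
    peak <- vox[which.max(abs(t_map[vox]))]
    mm <- .voxel_to_mm(arrayInd(peak, d), geometry)
    tibble::tibble(
      cluster = cl, size_voxels = obs$sizes[cl], peak_t = t_map[peak],
      peak_x_mm = mm[1], peak_y_mm = mm[2], peak_z_mm = mm[3],
      p_fwe = mean(max_null >= obs$sizes[cl])
    )
  })
  dplyr::arrange(dplyr::bind_rows(rows), dplyr::desc(.data$size_voxels))
}
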