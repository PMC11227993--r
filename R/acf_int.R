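#' Biased sample autocorrelation of a time series
#'
#' Mean-centres the series and computes the 1/n-normalised (biased) sample
#' autocorrelations at lags `1..max_lag`. The biased estimator guarantees
#' damping at long lags on short series, the standard choice in the
#' timescale literature.
#'
#' @param series Numeric vector, length `>= max_lag + 2`, non-constant.
#' @param max_lag Largest lag, `>= 1`.
#' @return An `acf_series` object: `values` (lags `1..max_lag`), `n_used`,
#'   `max_lag`. Lag 0 is identically 1 and not stored.
#' @export
sample_acf <- function(series, max_lag) {
  x <- as.numeric(series)
  n <- length(x)
  stopifnot(.is_count(max_lag))
  if (n < max_lag + 2) {
    abort(sprintf("series of length %d too short for max_lag = %d", n, max_lag))
  }
  .assert_finite(x, "series")
  xc <- x - mean(x)
  s0 <- sum(xc^2)
  if (s0 == 0) abort("constant series has no autocorrelation (zero variance)")
  rho <- vapply(seq_len(max_lag), function(k) {
    sum(xc[seq_len(n - k)] * xc[(k + 1):n]) / s0
  }, numeric(1))
  structure(
    list(values = rho, n_used = n, max_lag = as.integer(max_lag)),
    class = "acf_series"
  )
}

#' @export
print.acf_series <- function(x, ...) {
  cat(sprintf("<acf_series> %d lags from %d points; rho(1) = %.4f\n",
              x$max_lag, x$n_used, x$values[1]))
  invisible(x)
}

#' Intrinsic neural timescale from an autocorrelation function
#'
#' The timescale is the area under the ACF over the initial run of strictly
#' positive values, scaled by the repetition time: with `m` the number of
#' leading lags (from lag 1) whose autocorrelation exceeds zero before the
#' first lag at or below zero, `INT = tr_s * sum(rho(1..m))`. If `rho(1) <=
#' 0` the timescale is 0. The first lag at or below zero terminates the
#' window (ties at exactly zero included). `include_lag0 = TRUE` adds the
#' constant `tr_s * 1` contribution of lag 0 — a uniform offset that leaves
#' group differences and correlations unchanged. `method = "trapezoid"`
#' replaces the unit-width Riemann sum by the trapezoidal rule over nodes
#' `rho(0) = 1, rho(1), ..., rho(m)`.
#'
#' @param acf An `acf_series` (or bare numeric vector of lag-1.. values).
#' @param tr_s Repetition time, seconds.
#' @param include_lag0 Add the lag-0 contribution.
#' @param method `"riemann"` (default) or `"trapezoid"`.
#' @return Timescale in seconds, `>= 0`.
#' @export
int_from_acf <- function(acf, tr_s, include_lag0 = FALSE,
                         method = c("riemann", "trapezoid")) {
  method <- match.arg(method)
  vals <- if (inherits(acf, "acf_series")) acf$values else as.numeric(acf)
  if (length(vals) == 0) abort("empty ACF")
  stopifnot(tr_s > 0)
  nonpos <- which(vals <= 0)
  m <- if (length(nonpos) == 0) length(vals) else nonpos[1] - 1
  if (method == "riemann") {
    base <- if (m == 0) 0 else sum(vals[seq_len(m)])
    if (include_lag0) base <- base + 1
    tr_s * base
  } else {
    if (m == 0 && !include_lag0) return(0)
    nodes <- c(1, vals[seq_len(m)])
    area <- sum((head(nodes, -1) + tail(nodes, -1)) / 2)
    if (include_lag0) area <- area + 0.5 # the half-bar behind lag 0
    tr_s * area
  }
}

#' Timescale of a single series
#'
#' Convenience wrapper: estimates the sample ACF adaptively (starting at a
#' short horizon and extending, up to half the series length, until the
#' positive initial run has terminated) and applies [int_from_acf()].
#'
#' @inheritParams int_from_acf
#' @param series Numeric vector.
#' @param max_lag Optional fixed lag horizon; default adaptive.
#' @return Timescale in seconds; `NA` for a degenerate (constant or
#'   non-finite) series.
#' @export
int_from_series <- function(series, tr_s, max_lag = NULL,
                            include_lag0 = FALSE,
                            method = c("riemann", "trapezoid")) {
  method <- match.arg(method)
  x <- as.numeric(series)
  n <- length(x)
  if (n < 4 || !all(is.finite(x)) || var(x) == 0) return(NA_real_)
  cap <- max(1L, floor(n / 2))
  if (!is.null(max_lag)) {
    a <- sample_acf(x, min(max_lag, n - 2))
    return(int_from_acf(a, tr_s, include_lag0, method))
  }
  L <- min(64L, cap)
  repeat {
    a <- sample_acf(x, L)
    if (any(a$values <= 0) || L >= cap) {
      return(int_from_acf(a, tr_s, include_lag0, method))
    }
    L <- min(2L * L, cap)
  }
}

#' Compute a whole-brain INT map
#'
#' Applies the ACF-area timescale estimator to every masked voxel of a
#' preprocessed BOLD volume. Degenerate voxels (zero variance or
#' non-finite) are flagged undefined (`NA`) rather than zero-filled and are
#' excluded from all downstream averages.
#'
#' @param bold A preprocessed `bold_4d`.
#' @param mask 3D logical array (default: all voxels).
#' @param max_lag Lag horizon; default half the series length.
#' @inheritParams int_from_acf
#' @return An `int_map`: `values` (3D, seconds, `NA` where undefined),
#'   `mask`, `geometry`, `tr_s`, and attribute `n_undefined`.
#' @export
compute_int_map <- function(bold, mask = NULL, max_lag = NULL,
                            include_lag0 = FALSE,
                            method = c("riemann", "trapezoid")) {
  method <- match.arg(method)
  stopifnot(inherits(bold, "bold_4d"))
  d <- dim(bold$values)
  if (is.null(mask)) mask <- array(TRUE, dim = d[1:3])
  stopifnot(is.logical(mask), all(dim(mask) == d[1:3]))
  if (!any(mask)) abort("empty mask")
  nt <- d[4]
  if (is.null(max_lag)) max_lag <- max(1L, floor(nt / 2))
  max_lag <- min(max_lag, nt - 2L)

  Y <- .bold_matrix(bold)[, as.vector(mask), drop = FALSE]
  Yc <- sweep(Y, 2, colMeans(Y), `-`)
  s0 <- colSums(Yc^2)
  ok <- is.finite(s0) & s0 > 0

  ints <- rep(NA_real_, ncol(Y))
  if (any(ok)) {
    A <- Yc[, ok, drop = FALSE]
    v0 <- s0[ok]
    # running Riemann/trapezoid sum over the leading positive ACF window,
    # vectorised across voxels
    alive <- rep(TRUE, ncol(A))
    total <- numeric(ncol(A))
    prev <- rep(1, ncol(A)) # rho(0)
    for (k in seq_len(max_lag)) {
      if (!any(alive)) break
      rho <- colSums(A[seq_len(nt - k), , drop = FALSE] *
                     A[(k + 1):nt, , drop = FALSE]) / v0
      pos <- alive & rho > 0
      if (method == "riemann") {
        total[pos] <- total[pos] + rho[pos]
      } else {
        total[pos] <- total[pos] + (prev[pos] + rho[pos]) / 2
      }
      prev <- rho
      alive <- pos
    }
    if (include_lag0) total <- total + if (method == "riemann") 1 else 0.5
    ints[ok] <- bold$tr_s * total
  }
  vol <- array(NA_real_, dim = d[1:3])
  vol[mask] <- ints
  structure(
    list(values = vol, mask = mask, geometry = bold$geometry, tr_s = bold$tr_s),
    n_undefined = sum(!ok),
    class = "int_map"
  )
}

#' @export
print.int_map <- function(x, ...) {
  v <- x$values[x$mask]
  cat(sprintf("<int_map> %s grid, %d masked voxels (%d undefined), median %.3g s\n",
              paste(dim(x$values), collapse = "x"), sum(x$mask),
              sum(!is.finite(v)), stats::median(v, na.rm = TRUE)))
  invisible(x)
}

#' Mask-aware Gaussian smoothing of an INT map
#'
#' Separable Gaussian smoothing with `sigma_mm = fwhm_mm / sqrt(8 * log 2)`
#' converted to voxels per axis. Both the map (undefined voxels treated as
#' zero mass) and the binary defined-mask are smoothed with the same kernel
#' and the ratio taken, so out-of-mask and undefined voxels never dilute
#' in-mask values; a uniform map is exactly preserved.
#'
#' @param map An `int_map`.
#' @param fwhm_mm Kernel full-width at half maximum, mm, `> 0`.
#' @return A smoothed `int_map` over the same mask.
#' @export
smooth_map <- function(map, fwhm_mm = 8) {
  stopifnot(inherits(map, "int_map"), is.numeric(fwhm_mm), fwhm_mm > 0)
  sigma_vox <- fwhm_mm / sqrt(8 * log(2)) / map$geometry$voxel_size_mm
  vals <- map$values
  w <- array(0, dim = dim(vals))
  defined <- map$mask & is.finite(vals)
  w[defined] <- 1
  num <- vals
  num[!defined] <- 0
  for (axis in 1:3) {
    num <- .gauss_smooth_axis(num, sigma_vox[axis], axis)
    w <- .gauss_smooth_axis(w, sigma_vox[axis], axis)
  }
  out <- array(NA_real_, dim = dim(vals))
  nz <- defined & w > 0
  out[nz] <- num[nz] / w[nz]
  map$values <- out
  map
}

# 1D truncated-Gaussian convolution along one axis of a 3D array
# (zero-padded; renormalisation is the caller's job)
.gauss_smooth_axis <- function(arr, sigma, axis) {
  if (sigma <= 0) return(arr)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  d <- dim(arr)
  out <- array(0, dim = d)
  for (j in seq_along(k)) {
    off <- j - r - 1L
    src_lo <- max(1L, 1L - off); src_hi <- min(d[axis], d[axis] - off)
    if (src_lo > src_hi) next
    dst <- (src_lo + off):(src_hi + off)
    src <- src_lo:src_hi
    if (axis == 1) {
      out[dst, , ] <- out[dst, , , drop = FALSE] + k[j] * arr[src, , , drop = FALSE]
    } else if (axis == 2) {
      out[, dst, ] <- out[, dst, , drop = FALSE] + k[j] * arr[, src, , drop = FALSE]
    } else {
      out[, , dst] <- out[, , dst, drop = FALSE] + k[j] * arr[, , src, drop = FALSE]
    }
  }
  out
}

#' Write / read an INT map as NIfTI with a JSON sidecar
#'
#' The sidecar records TR, estimator options and the undefined-voxel count;
#' undefined voxels are written as NaN.
#'
#' @param map An `int_map`.
#' @param path NIfTI path.
#' @param options Named list of estimator options to record.
#' @return `path`, invisibly.
#' @export
write_int_map <- function(map, path, options = list()) {
  img <- RNifti::asNifti(map$values)
  RNifti::pixdim(img) <- map$geometry$voxel_size_mm
  RNifti::writeNifti(img, path, datatype = "float")
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(
    c(list(tr_s = map$tr_s,
           n_undefined = sum(map$mask & !is.finite(map$values)),
           voxel_size_mm = map$geometry$voxel_size_mm,
           origin_mm = map$geometry$origin_mm),
      options),
    sidecar, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_int_map
#' @export
read_int_map <- function(path) {
  img <- RNifti::readNifti(path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  vals <- array(as.numeric(img), dim = dim(img))
  vals[is.nan(vals)] <- NA_real_
  geometry <- atlas_geometry(dim(img), meta$voxel_size_mm, meta$origin_mm)
  structure(
    list(values = vals, mask = array(TRUE, dim = dim(img)),
         geometry = geometry, tr_s = meta$tr_s),
    class = "int_map"
  )
}
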