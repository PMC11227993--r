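#' Construct a 4D BOLD container
#'
#' @param values 4D numeric array `(x, y, z, t)` with `t >= 2`.
#' @param tr_s Repetition time, seconds.
#' @param geometry An [atlas_geometry()] matching the spatial dimensions.
#' @return A `bold_4d` object.
#' @export
bold_4d <- function(values, tr_s, geometry) {
  stopifnot(is.array(values), length(dim(values)) == 4, dim(values)[4] >= 2,
            tr_s > 0, inherits(geometry, "atlas_geometry"),
            all(dim(values)[1:3] == geometry$grid_dims))
  .assert_finite(values, "BOLD values")
  structure(list(values = values, tr_s = tr_s, geometry = geometry),
            class = "bold_4d")
}

#' @export
print.bold_4d <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<bold_4d> %dx%dx%d voxels, %d volumes, TR %.3g s\n",
              d[1], d[2], d[3], d[4], x$tr_s))
  invisible(x)
}

# internal: bold <-> (t x nvox) matrix
.bold_matrix <- function(bold) {
  d <- dim(bold$values)
  t(matrix(bold$values, prod(d[1:3]), d[4]))
}

.matrix_bold <- function(M, bold) {
  d <- dim(bold$values)
  bold$values <- array(t(M), dim = c(d[1:3], nrow(M)))
  bold
}

#' Discard initial volumes
#'
#' Removes the first `n` volumes (scanner equilibration lead-in); TR and
#' geometry are unchanged.
#'
#' @param bold A `bold_4d`.
#' @param n Number of volumes to drop, `0 <= n < t`.
#' @return A `bold_4d` with `t - n` volumes.
#' @export
discard_initial_volumes <- function(bold, n = 5) {
  stopifnot(inherits(bold, "bold_4d"))
  nt <- dim(bold$values)[4]
  if (!is.numeric(n) || length(n) != 1 || n < 0 || n != floor(n)) {
    abort("`n` must be a nonnegative integer")
  }
  if (n >= nt) {
    abort(sprintf("cannot discard %d of %d volumes (empty result)", n, nt))
  }
  if (n == 0) return(bold)
  bold$values <- bold$values[, , , (n + 1):nt, drop = FALSE]
  bold
}

#' Framewise displacement from realignment parameters
#'
#' Power-style FD: the sum of absolute backward differences of the three
#' translations (mm) plus the rotation differences (rad) converted to arc
#' length on a sphere of radius `radius_mm`. The first frame has FD 0.
#'
#' @param motion Data frame or matrix with columns `trans_x, trans_y,
#'   trans_z, rot_x, rot_y, rot_z` (or the first six columns in that order).
#' @param radius_mm Head radius used for the rotation conversion.
#' @return Numeric vector of per-frame FD (mm), same length as rows.
#' @export
framewise_displacement <- function(motion, radius_mm = 50) {
  m <- as.matrix(as.data.frame(motion))
  cols <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  if (all(cols %in% colnames(m))) m <- m[, cols, drop = FALSE]
  if (ncol(m) < 6) abort("motion parameters need six columns (3 translations, 3 rotations)")
  m <- m[, 1:6, drop = FALSE]
  if (nrow(m) < 2) abort("need at least two frames to compute displacement")
  .assert_finite(m, "motion parameters")
  d <- abs(diff(m))
  fd <- rowSums(d[, 1:3, drop = FALSE]) + radius_mm * rowSums(d[, 4:6, drop = FALSE])
  c(0, fd)
}

#' Summarise head motion for quality control
#'
#' @param confounds Confound table with the six motion columns.
#' @param radius_mm Head radius for the FD rotation conversion.
#' @return One-row tibble: `max_fd_mm`, `mean_fd_mm`.
#' @export
motion_summary <- function(confounds, radius_mm = 50) {
  fd <- framewise_displacement(confounds, radius_mm)
  tibble::tibble(max_fd_mm = max(fd), mean_fd_mm = mean(fd))
}

#' Regress confounds out of every voxel time series
#'
#' Replaces each voxel series by its least-squares residual against an
#' intercept plus the confound columns. Residuals are orthogonal to every
#' confound column up to numerical precision. Columns are used on their
#' native scales (residuals are scale-invariant); with
#' `expand_motion = TRUE` the six motion columns are augmented with their
#' backward derivatives and the squares of both (a 24-parameter model).
#'
#' @param bold A `bold_4d`.
#' @param confounds Data frame of per-volume confounds (rows must match the
#'   retained volume count).
#' @param expand_motion Use the 24-parameter motion expansion.
#' @return A `bold_4d` of residuals.
#' @export
regress_confounds <- function(bold, confounds, expand_motion = FALSE) {
  stopifnot(inherits(bold, "bold_4d"))
  C <- as.matrix(as.data.frame(confounds))
  nt <- dim(bold$values)[4]
  if (nrow(C) != nt) {
    abort(sprintf("confound rows (%d) must equal retained volumes (%d)", nrow(C), nt))
  }
  .assert_finite(C, "confounds")
  if (expand_motion) {
    mcols <- intersect(c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z"),
                       colnames(C))
    if (length(mcols) == 6) {
      M <- C[, mcols, drop = FALSE]
      dM <- rbind(0, diff(M))
      C <- cbind(C, dM, M^2, dM^2)
    }
  }
  X <- cbind(intercept = 1, C)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    abort(sprintf("confound design is rank deficient; collinear column(s): %s",
                  paste(bad, collapse = ", ")))
  }
  Y <- .bold_matrix(bold)
  R <- qr.resid(qx, Y)
  .matrix_bold(R, bold)
}

# Zero-phase (forward-backward) IIR filtering of every column of X, with
# odd-reflection padding at both ends to suppress edge transients.
.filtfilt_matrix <- function(b, a, X, n_pad) {
  pass <- function(M) {
    n <- nrow(M)
    np <- min(n_pad, n - 1)
    top <- 2 * M[rep(1, np), , drop = FALSE] - M[np:1 + 1, , drop = FALSE]
    bot <- 2 * M[rep(n, np), , drop = FALSE] - M[n - (1:np), , drop = FALSE]
    P <- rbind(top, M, bot)
    nb <- length(b); na_ <- length(a)
    Y <- matrix(0, nrow(P), ncol(P))
    for (t in seq_len(nrow(P))) {
      acc <- b[1] * P[t, ]
      if (nb > 1) for (i in 2:nb) if (t - i + 1 >= 1) acc <- acc + b[i] * P[t - i + 1, ]
      if (na_ > 1) for (j in 2:na_) if (t - j + 1 >= 1) acc <- acc - a[j] * Y[t - j + 1, ]
      Y[t, ] <- acc / a[1]
    }
    Y[(np + 1):(np + n), , drop = FALSE]
  }
  fwd <- pass(X)
  rev_idx <- nrow(fwd):1
  bwd <- pass(fwd[rev_idx, , drop = FALSE])
  bwd[rev_idx, , drop = FALSE]
}

#' Band-pass filter every voxel time series
#'
#' Zero-phase (forward-backward) Butterworth band-pass of order
#' `order` per pass, applied identically to every voxel; odd-reflection
#' padding suppresses edge transients on short series. The default band
#' (0.01-0.1 Hz) is the conventional resting-state frequency range.
#'
#' @param bold A `bold_4d`.
#' @param low_hz,high_hz Band edges in Hz; must satisfy
#'   `0 < low_hz < high_hz < 1 / (2 * tr_s)`.
#' @param order Butterworth order per edge per pass.
#' @return A filtered `bold_4d`.
#' @export
bandpass_filter <- function(bold, low_hz = 0.01, high_hz = 0.1, order = 2) {
  stopifnot(inherits(bold, "bold_4d"))
  nyq <- 1 / (2 * bold$tr_s)
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq)) {
    abort(sprintf("band [%g, %g] Hz must lie strictly inside (0, Nyquist = %.4g) Hz",
                  low_hz, high_hz, nyq))
  }
  flt <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  Y <- .bold_matrix(bold)
  n_pad <- min(nrow(Y) - 1, max(3 * (2 * order + 1), ceiling(1 / (low_hz * bold$tr_s))))
  Fop <- .filtfilt_operator(flt$b, flt$a, nrow(Y), n_pad)
  .matrix_bold(Fop %*% Y, bold)
}

# The zero-phase filter is linear and identical for every voxel, so for a
# given series length it is a fixed n x n operator: build it once by
# filtering the identity basis and cache it (applying it is then one
# matrix multiply per subject).
.filtfilt_cache <- new.env(parent = emptyenv())

.filtfilt_operator <- function(b, a, n, n_pad) {
  key <- paste(signif(c(b, a), 12), n, n_pad, collapse = "|")
  cached <- .filtfilt_cache[[key]]
  if (!is.null(cached)) return(cached)
  Fop <- .filtfilt_matrix(b, a, diag(n), n_pad)
  .filtfilt_cache[[key]] <- Fop
  Fop
}

#' Quality-control partition of subjects by head motion
#'
#' Splits a phenotype table into retained and excluded subjects; the
#' partition is exhaustive and disjoint. By default subjects whose
#' `mean_motion_mm` exceeds `threshold_mm` are excluded; `criterion =
#' "max_fd_mm"` switches to a maximum-FD rule when that column is present.
#'
#' @param subjects Phenotype tibble with the motion column.
#' @param threshold_mm Exclusion threshold, `> 0`.
#' @param criterion Column used for the rule.
#' @return A list of tibbles `kept` and `excluded`.
#' @export
qc_filter_subjects <- function(subjects, threshold_mm = 3,
                               criterion = c("mean_motion_mm", "max_fd_mm")) {
  criterion <- match.arg(criterion)
  if (!is.numeric(threshold_mm) || threshold_mm <= 0) {
    abort("`threshold_mm` must be strictly positive")
  }
  if (!criterion %in% names(subjects)) {
    abort(sprintf("column '%s' not found in the subject table", criterion))
  }
  bad <- subjects[[criterion]] > threshold_mm
  list(kept = subjects[!bad, , drop = FALSE],
       excluded = subjects[bad, , drop = FALSE])
}

#' Run the full temporal preprocessing chain on one subject
#'
#' Fixed order: discard lead-in volumes, regress confounds, band-pass
#' filter.
#'
#' @param bold A `bold_4d` (raw, including lead-in volumes).
#' @param confounds Confound table for the retained volumes.
#' @param discard_n Lead-in volumes to drop.
#' @param band Two-element band in Hz.
#' @param expand_motion Use the 24-parameter motion model.
#' @return A preprocessed `bold_4d`.
#' @export
preprocess_bold <- function(bold, confounds, discard_n = 5,
                            band = c(0.01, 0.1), expand_motion = FALSE) {
  bold |>
    discard_initial_volumes(discard_n) |>
    regress_confounds(confounds, expand_motion = expand_motion) |>
    bandpass_filter(band[1], band[2])
}
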