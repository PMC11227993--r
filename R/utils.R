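#' @importFrom rlang abort warn .data
#' @importFrom stats rnorm runif sd var cor coef lm qt pt quantile complete.cases
#' @importFrom utils head tail
NULL

# Largest signed 32-bit integer; all derived seeds stay strictly below it.
.SEED_MOD <- 2147483647

#' Derive a reproducible child seed from a parent seed and a string tag
#'
#' Stable across sessions and platforms: a small multiplicative hash of the
#' tag's UTF-8 bytes folded into the parent seed, reduced mod 2^31 - 1.
#' Used to fan one top-level seed out to per-subject and per-stage streams.
#'
#' @param seed Integer parent seed.
#' @param tag Character scalar naming the stream (e.g. a subject id).
#' @return An integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(tag), length(tag) == 1)
  h <- as.double(seed %% .SEED_MOD)
  for (b in utf8ToInt(tag)) {
    h <- (h * 31 + b) %% .SEED_MOD
  }
  as.integer(h %% (.SEED_MOD - 2) + 1)
}

.assert_finite <- function(x, what) {
  if (!all(is.finite(x))) {
    abort(sprintf("%s must contain only finite values", what))
  }
  invisible(x)
}

.is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 1 && x == floor(x)
}

# mm coordinate of the centre of voxel index (1-based) along each axis
.voxel_to_mm <- function(idx, geometry) {
  sweep(sweep(idx - 1, 2, geometry$voxel_size_mm, `*`), 2, geometry$origin_mm, `+`)
}

.mm_to_voxel <- function(mm, geometry) {
  sweep(sweep(mm, 2, geometry$origin_mm, `-`), 2, geometry$voxel_size_mm, `/`) + 1
}
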