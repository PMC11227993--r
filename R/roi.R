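#' Mean timescale over a named network
#'
#' Arithmetic mean of the defined (finite, in-mask) voxel values over every
#' parcel assigned to the network.
#'
#' @param map An `int_map`.
#' @param parc A `parcellation` on the same grid.
#' @param network Network name (a value of `parc$network_of`).
#' @return Scalar mean, seconds.
#' @export
network_mean <- function(map, parc, network) {
  stopifnot(inherits(map, "int_map"), inherits(parc, "parcellation"))
  parcels <- names(parc$network_of)[parc$network_of == network]
  if (length(parcels) == 0) {
    abort(sprintf("network '%s' has no parcels in this parcellation", network))
  }
  labs <- as.integer(names(parc$label_names)[parc$label_names %in% parcels])
  sel <- parc$labels %in% labs & map$mask
  v <- map$values[sel]
  v <- v[is.finite(v)]
  if (length(v) == 0) {
    abort(sprintf("network '%s' contains no defined voxels", network))
  }
  mean(v)
}

#' Mean timescale over a single parcel
#'
#' @param map An `int_map`.
#' @param parc A `parcellation`.
#' @param parcel Parcel name (a value of `parc$label_names`).
#' @return Scalar mean, seconds.
#' @export
parcel_mean <- function(map, parc, parcel) {
  stopifnot(inherits(map, "int_map"), inherits(parc, "parcellation"))
  if (!parcel %in% parc$label_names) {
    abort(sprintf("parcel '%s' not found", parcel))
  }
  lab <- as.integer(names(parc$label_names)[parc$label_names == parcel][1])
  v <- map$values[parc$labels == lab & map$mask]
  v <- v[is.finite(v)]
  if (length(v) == 0) abort(sprintf("parcel '%s' contains no defined voxels", parcel))
  mean(v)
}

#' Define a spherical ROI around an MNI-style coordinate
#'
#' Includes exactly the voxels whose centres lie within `radius_mm`
#' (Euclidean, boundary inclusive) of `center_mm`. Never empty: if no voxel
#' centre falls inside the sphere, the single nearest voxel is included.
#'
#' @param center_mm Length-3 mm coordinate; must lie inside the grid's
#'   bounding box.
#' @param radius_mm Sphere radius, mm, `> 0`.
#' @param geometry An [atlas_geometry()].
#' @return A `sphere_roi`: `center_mm`, `radius_mm`, `voxel_indices`
#'   (matrix of 1-based index triples).
#' @export
sphere_roi <- function(center_mm, radius_mm, geometry) {
  stopifnot(inherits(geometry, "atlas_geometry"),
            length(center_mm) == 3, radius_mm > 0)
  d <- geometry$grid_dims
  lo <- .voxel_to_mm(matrix(c(1, 1, 1), 1), geometry) - geometry$voxel_size_mm / 2
  hi <- .voxel_to_mm(matrix(d, 1), geometry) + geometry$voxel_size_mm / 2
  if (any(center_mm < lo) || any(center_mm > hi)) {
    abort("sphere centre lies outside the grid bounding box")
  }
  idx <- as.matrix(expand.grid(seq_len(d[1]), seq_len(d[2]), seq_len(d[3])))
  colnames(idx) <- c("i", "j", "k")
  mm <- .voxel_to_mm(idx, geometry)
  dist <- sqrt(rowSums(sweep(mm, 2, as.numeric(center_mm))^2))
  inside <- dist <= radius_mm
  if (!any(inside)) inside[which.min(dist)] <- TRUE
  structure(
    list(center_mm = as.numeric(center_mm), radius_mm = radius_mm,
         voxel_indices = idx[inside, , drop = FALSE]),
    class = "sphere_roi"
  )
}

#' @export
print.sphere_roi <- function(x, ...) {
  cat(sprintf("<sphere_roi> r = %g mm at (%s) mm, %d voxels\n",
              x$radius_mm, paste(format(x$center_mm), collapse = ", "),
              nrow(x$voxel_indices)))
  invisible(x)
}

#' Mean timescale over a spherical ROI
#'
#' @param map An `int_map`.
#' @param roi A [sphere_roi()].
#' @return Mean over the defined ROI voxels, seconds.
#' @export
roi_mean <- function(map, roi) {
  stopifnot(inherits(map, "int_map"), inherits(roi, "sphere_roi"))
  d <- dim(map$values)
  idx <- roi$voxel_indices
  lin <- idx[, 1] + d[1] * (idx[, 2] - 1) + d[1] * d[2] * (idx[, 3] - 1)
  sel <- map$mask[lin]
  v <- map$values[lin][sel]
  v <- v[is.finite(v)]
  if (length(v) == 0) abort("ROI contains no defined voxels")
  mean(v)
}

#' Summarise a cohort's INT maps over networks, parcels and ROIs
#'
#' Produces the tidy per-subject table consumed by the group-statistics and
#' mediation stages: one row per subject with the network means, the focal
#' parcel means and any spherical-ROI means, joined to the phenotypes.
#'
#' @param maps Named list of `int_map` (names are subject ids).
#' @param parc A `parcellation`.
#' @param phenotypes Phenotype tibble with an `id` column.
#' @param rois Optional named list of [sphere_roi()]s; each adds a
#'   `<name>_roi_int` column.
#' @param parcels Parcel names to summarise (default `AG` and `SMG`,
#'   lower-cased as `<parcel>_int`).
#' @return A tibble.
#' @export
summarize_int <- function(maps, parc, phenotypes, rois = NULL,
                          parcels = c("AG", "SMG")) {
  stopifnot(is.list(maps), !is.null(names(maps)), "id" %in% names(phenotypes))
  nets <- unique(unname(parc$network_of))
  rows <- purrr::imap(maps, function(map, id) {
    out <- list(id = id)
    for (net in nets) {
      out[[paste0(tolower(net), "_int")]] <- network_mean(map, parc, net)
    }
    for (p in parcels) {
      out[[paste0(tolower(p), "_int")]] <- parcel_mean(map, parc, p)
    }
    for (nm in names(rois)) {
      out[[paste0(tolower(nm), "_roi_int")]] <- roi_mean(map, rois[[nm]])
    }
    tibble::as_tibble(out)
  })
  dplyr::left_join(dplyr::bind_rows(rows), phenotypes, by = "id")
}
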