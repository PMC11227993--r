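#' Define the geometry of a voxel grid
#'
#' The geometry ties voxel indices to nominal MNI-style millimetre
#' coordinates through an invertible affine map: the centre of voxel
#' `(1, 1, 1)` sits at `origin_mm`, and each step along an axis advances by
#' `voxel_size_mm`.
#'
#' @param grid_dims Integer triple of grid dimensions (voxels), all `>= 1`.
#' @param voxel_size_mm Positive real triple (or scalar, recycled), mm.
#' @param origin_mm Real triple: mm coordinate of the first voxel's centre.
#' @return An object of class `atlas_geometry`.
#' @examples
#' atlas_geometry(c(20, 20, 12), 4)
#' @export
atlas_geometry <- function(grid_dims, voxel_size_mm, origin_mm = NULL) {
  grid_dims <- as.integer(grid_dims)
  stopifnot(length(grid_dims) == 3, all(grid_dims >= 1))
  voxel_size_mm <- rep_len(as.double(voxel_size_mm), 3)
  if (any(voxel_size_mm <= 0)) abort("voxel_size_mm must be strictly positive")
  if (is.null(origin_mm)) {
    # centre the grid on the mm origin
    origin_mm <- -(grid_dims - 1) / 2 * voxel_size_mm
  }
  origin_mm <- rep_len(as.double(origin_mm), 3)
  structure(
    list(grid_dims = grid_dims, voxel_size_mm = voxel_size_mm, origin_mm = origin_mm),
    class = "atlas_geometry"
  )
}

#' @export
print.atlas_geometry <- function(x, ...) {
  cat(sprintf(
    "<atlas_geometry> %s voxels at %s mm, origin (%s) mm\n",
    paste(x$grid_dims, collapse = "x"),
    paste(format(x$voxel_size_mm), collapse = "x"),
    paste(format(x$origin_mm), collapse = ", ")
  ))
  invisible(x)
}

#' Build a labelled toy parcellation from box-shaped regions
#'
#' Constructs an integer label volume plus name and network lookup tables
#' from a list of axis-aligned boxes. Regions must be disjoint and lie
#' within the grid; label 0 is reserved for background.
#'
#' @param geometry An [atlas_geometry()].
#' @param layout Named list; each element is a list with `box` (a 3x2 matrix
#'   or list of three `c(lo, hi)` index ranges, 1-based inclusive) and
#'   `network` (character network name).
#' @return An object of class `parcellation`: integer `labels` array,
#'   `label_names` (integer -> name), `network_of` (name -> network),
#'   and the geometry.
#' @export
make_toy_atlas <- function(geometry, layout) {
  stopifnot(inherits(geometry, "atlas_geometry"))
  if (is.null(names(layout)) || any(!nzchar(names(layout)))) {
    abort("every region in `layout` must be named")
  }
  dims <- geometry$grid_dims
  labels <- array(0L, dim = dims)
  owner <- character(prod(dims)) # which region claimed each voxel, for clash reporting
  label_names <- character(0)
  network_of <- character(0)
  for (i in seq_along(layout)) {
    nm <- names(layout)[i]
    region <- layout[[i]]
    box <- region$box
    if (is.list(box)) box <- do.call(rbind, box)
    box <- matrix(as.integer(box), nrow = 3)
    if (any(box[, 1] < 1) || any(box[, 2] > dims) || any(box[, 1] > box[, 2])) {
      abort(sprintf("region '%s' extends outside the %s grid", nm,
                    paste(dims, collapse = "x")))
    }
    idx <- as.matrix(expand.grid(
      box[1, 1]:box[1, 2], box[2, 1]:box[2, 2], box[3, 1]:box[3, 2]
    ))
    lin <- idx[, 1] + dims[1] * (idx[, 2] - 1) + dims[1] * dims[2] * (idx[, 3] - 1)
    clash <- labels[lin] != 0L
    if (any(clash)) {
      abort(sprintf("regions '%s' and '%s' overlap", owner[lin[which(clash)[1]]], nm))
    }
    labels[lin] <- i
    owner[lin] <- nm
    label_names[as.character(i)] <- nm
    network_of[nm] <- region$network
  }
  structure(
    list(labels = labels, label_names = label_names,
         network_of = network_of, geometry = geometry),
    class = "parcellation"
  )
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf("<parcellation> %s parcels on a %s grid\n",
              length(x$label_names), paste(x$geometry$grid_dims, collapse = "x")))
  for (lab in names(x$label_names)) {
    nm <- x$label_names[[lab]]
    cat(sprintf("  %2s %-12s net=%-12s %d voxels\n", lab, nm,
                x$network_of[[nm]], sum(x$labels == as.integer(lab))))
  }
  invisible(x)
}

#' Voxel count per parcel
#' @param parc A [make_toy_atlas()] parcellation.
#' @return A tibble with columns `label`, `name`, `network`, `n_voxels`.
#' @export
parcel_sizes <- function(parc) {
  stopifnot(inherits(parc, "parcellation"))
  labs <- as.integer(names(parc$label_names))
  tibble::tibble(
    label = labs,
    name = unname(parc$label_names[as.character(labs)]),
    network = unname(parc$network_of[.data$name]),
    n_voxels = vapply(labs, function(l) sum(parc$labels == l), integer(1))
  )
}

#' The default desk-scale atlas
#'
#' A 20 x 20 x 12 grid at 4 mm isotropic resolution holding a default-mode
#' core, focal angular-gyrus (AG) and supramarginal-gyrus (SMG) parcels —
#' all three assigned to the DMN — and six disjoint control-network parcels
#' (frontoparietal, dorsal attention, ventral attention, limbic,
#' somatomotor, visual). Background voxels remain label 0.
#'
#' @param geometry Optional [atlas_geometry()]; defaults to the 20x20x12,
#'   4 mm grid.
#' @return A `parcellation`.
#' @export
toy_atlas <- function(geometry = atlas_geometry(c(20L, 20L, 12L), 4)) {
  box <- function(x, y, z) list(box = rbind(x, y, z))
  layout <- list(
    `DMN-core` = c(box(c(8, 13), c(8, 13), c(5, 8)), network = "DMN"),
    AG = c(box(c(3, 5), c(14, 16), c(5, 7)), network = "DMN"),
    SMG = c(box(c(16, 18), c(12, 14), c(5, 7)), network = "DMN"),
    frontoparietal = c(box(c(3, 6), c(3, 6), c(8, 11)), network = "frontoparietal"),
    dorsal_attention = c(box(c(14, 17), c(3, 6), c(8, 11)), network = "dorsal_attention"),
    ventral_attention = c(box(c(14, 17), c(16, 19), c(8, 11)), network = "ventral_attention"),
    limbic = c(box(c(3, 6), c(16, 19), c(1, 4)), network = "limbic"),
    somatomotor = c(box(c(8, 13), c(3, 5), c(9, 11)), network = "somatomotor"),
    visual = c(box(c(8, 13), c(16, 18), c(1, 3)), network = "visual")
  )
  make_toy_atlas(geometry, layout)
}

#' Write / read a parcellation as NIfTI + JSON sidecar
#'
#' @param parc A `parcellation`.
#' @param path Path of the NIfTI file to write; a `.json` sidecar holding
#'   label names, networks and the affine origin is written next to it.
#' @return `path`, invisibly.
#' @export
write_atlas <- function(parc, path) {
  stopifnot(inherits(parc, "parcellation"))
  img <- RNifti::asNifti(parc$labels)
  RNifti::pixdim(img) <- parc$geometry$voxel_size_mm
  RNifti::writeNifti(img, path, datatype = "int16")
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(
    list(
      label_names = as.list(parc$label_names),
      network_of = as.list(parc$network_of),
      voxel_size_mm = parc$geometry$voxel_size_mm,
      origin_mm = parc$geometry$origin_mm
    ),
    sidecar, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(path) {
  img <- RNifti::readNifti(path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  labels <- array(as.integer(img), dim = dim(img))
  geometry <- atlas_geometry(dim(img), meta$voxel_size_mm, meta$origin_mm)
  structure(
    list(labels = labels,
         label_names = unlist(meta$label_names),
         network_of = unlist(meta$network_of),
         geometry = geometry),
    class = "parcellation"
  )
}
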