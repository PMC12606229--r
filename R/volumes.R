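#' Volume containers
#'
#' Lightweight S3 containers for the four volumetric encodings the pipeline
#' touches. All grids are indexed `(x, y, z)`, matching the fastest-to-slowest
#' on-disk order of NIFTI-1; every module in the package uses this one axis
#' convention.
#'
#' * `volume3d()` — a scalar voxel grid (binary masks, integer counts, or
#'   real-valued fields such as thickness in mm).
#' * `rgb_volume()` — a colour grid stored as an `(nx, ny, nz, 3)` integer
#'   array with channel values in `[0, 255]`.
#' * `tensor_volume()` — a per-voxel symmetric 3x3 matrix grid stored as an
#'   `(nx, ny, nz, 6)` array in NIFTI lower-triangle component order
#'   `(a11, a21, a22, a31, a32, a33)`.
#' * `label_volume()` — a non-negative integer label grid with a
#'   label-to-name mapping; label 0 is background.
#'
#' @param values the voxel data array (3D for `volume3d`/`label_volume`,
#'   4D with a trailing channel/component axis for the others).
#' @param spacing physical voxel edge lengths in mm, one per axis.
#' @param origin physical offset of the first voxel in mm.
#' @param label_names named character vector mapping label value (name of the
#'   element, coercible to integer) to region name; must cover every nonzero
#'   label present.
#' @return an object of the corresponding class.
#' @name volumes
NULL

#' @rdname volumes
#' @export
volume3d <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("volume3d: 'values' must be a 3D array")
  check_spacing(spacing)
  if (!all(is.finite(values)))
    stop("volume3d: values must be finite")
  structure(list(values = values, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "volume3d")
}

#' @rdname volumes
#' @export
rgb_volume <- function(values, spacing = c(1, 1, 1)) {
  values <- as.array(values)
  d <- dim(values)
  if (length(d) != 4L || d[4] != 3L)
    stop("rgb_volume: 'values' must be an (nx, ny, nz, 3) array")
  check_spacing(spacing)
  if (min(values) < 0 || max(values) > 255)
    stop("rgb_volume: channel values must lie in [0, 255]")
  storage.mode(values) <- "integer"
  structure(list(values = values, spacing = as.numeric(spacing)),
            class = "rgb_volume")
}

#' @rdname volumes
#' @export
tensor_volume <- function(values, spacing = c(1, 1, 1)) {
  values <- as.array(values)
  d <- dim(values)
  if (length(d) != 4L || d[4] != 6L)
    stop("tensor_volume: 'values' must be an (nx, ny, nz, 6) array")
  check_spacing(spacing)
  if (!all(is.finite(values)))
    stop("tensor_volume: values must be finite")
  structure(list(values = values, spacing = as.numeric(spacing)),
            class = "tensor_volume")
}

#' @rdname volumes
#' @export
label_volume <- function(values, spacing = c(1, 1, 1), label_names = NULL) {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("label_volume: 'values' must be a 3D array")
  check_spacing(spacing)
  if (min(values) < 0)
    stop("label_volume: labels must be non-negative")
  storage.mode(values) <- "integer"
  present <- setdiff(sort(unique(as.vector(values))), 0L)
  if (is.null(label_names)) {
    label_names <- stats::setNames(paste0("label_", present),
                                   as.character(present))
  }
  missing <- setdiff(as.character(present), names(label_names))
  if (length(missing) > 0)
    stop("label_volume: labels without names: ", paste(missing, collapse = ", "))
  structure(list(values = values, spacing = as.numeric(spacing),
                 label_names = label_names),
            class = "label_volume")
}

check_spacing <- function(spacing) {
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive finite numbers (mm)")
  invisible(TRUE)
}

#' @export
print.volume3d <- function(x, ...) {
  cat(sprintf("<volume3d> %s voxels, spacing %s mm, values in [%g, %g]\n",
              paste(dim(x$values), collapse = " x "),
              paste(format(x$spacing), collapse = " x "),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.rgb_volume <- function(x, ...) {
  cat(sprintf("<rgb_volume> %s voxels, spacing %s mm\n",
              paste(dim(x$values)[1:3], collapse = " x "),
              paste(format(x$spacing), collapse = " x ")))
  invisible(x)
}

#' @export
print.tensor_volume <- function(x, ...) {
  cat(sprintf("<tensor_volume> %s voxels (6 components each), spacing %s mm\n",
              paste(dim(x$values)[1:3], collapse = " x "),
              paste(format(x$spacing), collapse = " x ")))
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("<label_volume> %s voxels, spacing %s mm, %d labelled regions\n",
              paste(dim(x$values), collapse = " x "),
              paste(format(x$spacing), collapse = " x "),
              length(x$label_names)))
  invisible(x)
}

# internal: shape of the spatial grid for any volume kind
vol_dim <- function(vol) dim(vol$values)[1:3]

# internal: TRUE for a {0,1} scalar grid
is_binary_volume <- function(vol) {
  inherits(vol, "volume3d") && all(vol$values %in% c(0, 1))
}

# internal: isometric spacing check with tolerance for float pixdims
assert_isometric <- function(vol, caller) {
  s <- vol$spacing
  if (diff(range(s)) > 1e-9 * max(s))
    stop(caller, ": requires isometric spacing, got (",
         paste(format(s), collapse = ", "), ")")
  s[1]
}

# internal: extract a binary integer mask array from volume3d/label_volume
as_mask_array <- function(vol) {
  m <- vol$values > 0
  storage.mode(m) <- "integer"
  m
}
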