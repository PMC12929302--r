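#' Label volume: a 3D voxel grid of integer labels with physical spacing
#'
#' The universal carrier of masks throughout the pipeline. Voxels are stored
#' as a 3D integer array in R's native column-major `(x, y, z)` order with
#' 1-based indices; `spacing` and `origin` are given per axis in the same
#' order, in millimetres. The axial (scanner slice) direction is identified
#' by `axial_axis` and defaults to the third array dimension. The physical
#' position of voxel `(i, j, k)` is `origin + (c(i, j, k) - 1) * spacing`.
#'
#' @param voxels 3D array of non-negative integer labels (0 = background).
#' @param spacing numeric(3), strictly positive voxel size in mm per axis.
#' @param origin numeric(3), physical position of voxel (1,1,1) in mm.
#' @param axial_axis integer in 1:3; index of the axial (slice) axis.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         axial_axis = 3L) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("voxels must be a 3D array", call. = FALSE)
  if (length(voxels) == 0L)
    stop("voxels must be non-empty", call. = FALSE)
  v <- as.vector(voxels)
  if (any(is.na(v)) || any(v < 0) || any(v != round(v)))
    stop("labels must be integers >= 0", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 strictly positive values (mm)", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be 3 finite values (mm)", call. = FALSE)
  axial_axis <- as.integer(axial_axis)
  if (!axial_axis %in% 1:3)
    stop("axial_axis must be 1, 2 or 3", call. = FALSE)
  voxels <- array(as.integer(voxels), dim = dim(voxels))  # strip stray attrs
  structure(list(voxels = voxels, spacing = spacing, origin = origin,
                 axial_axis = axial_axis),
            class = "label_volume")
}

#' @export
dim.label_volume <- function(x) dim(x$voxels)

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<label_volume> %d x %d x %d voxels, spacing (%g, %g, %g) mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  foreground voxels: %d, distinct labels: %d, axial axis: %d\n",
              sum(x$voxels != 0L), length(setdiff(unique(as.vector(x$voxels)), 0L)),
              x$axial_axis))
  invisible(x)
}

is_binary_volume <- function(vol) all(vol$voxels %in% c(0L, 1L))

stop_if_not_binary <- function(vol, what = "volume") {
  if (!is_binary_volume(vol))
    stop(sprintf("%s must be binary (labels in {0, 1})", what), call. = FALSE)
  invisible(vol)
}

stop_if_grid_mismatch <- function(a, b) {
  if (!identical(dim(a$voxels), dim(b$voxels)))
    stop("volume shapes differ", call. = FALSE)
  if (!isTRUE(all.equal(a$spacing, b$spacing, tolerance = 1e-6)))
    stop("volume spacings differ", call. = FALSE)
  invisible(NULL)
}

#' Read a label volume from a NIfTI file
#'
#' Voxel data must be integer-valued; spacing and origin are taken from the
#' NIfTI header. The axial axis is identified from the orientation string
#' (the axis mapped to the Inferior-Superior direction); for volumes without
#' usable orientation metadata it falls back to the third axis.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return A [label_volume].
#' @export
read_label_volume <- function(path) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (is.null(d) || length(d) != 3L)
    stop(sprintf("not a 3D image: %s (dims: %s)", path,
                 paste(d, collapse = "x")), call. = FALSE)
  v <- as.array(img)
  if (any(abs(v - round(v)) > 1e-6) || any(v < 0))
    stop(sprintf("voxel data not non-negative integers: %s", path),
         call. = FALSE)
  sp <- RNifti::pixdim(img)[1:3]
  xf <- tryCatch(RNifti::xform(img), error = function(e) NULL)
  origin <- if (!is.null(xf)) as.numeric(xf[1:3, 4]) else c(0, 0, 0)
  axial <- 3L
  orient <- tryCatch(RNifti::orientation(img), error = function(e) NULL)
  if (is.character(orient) && nchar(orient) == 3L) {
    hit <- which(strsplit(orient, "")[[1]] %in% c("I", "S"))
    if (length(hit) == 1L) axial <- as.integer(hit)
  }
  label_volume(round(v), spacing = sp, origin = origin, axial_axis = axial)
}

#' Write a label volume to a NIfTI file
#'
#' The written file round-trips through [read_label_volume()] with
#' bit-identical voxels, spacing and origin.
#'
#' @param vol a [label_volume].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(vol, path) {
  stopifnot(inherits(vol, "label_volume"))
  dir <- dirname(path)
  if (!dir.exists(dir))
    stop(sprintf("directory does not exist: %s", dir), call. = FALSE)
  img <- RNifti::asNifti(vol$voxels)
  RNifti::pixdim(img) <- vol$spacing
  # RAS affine carrying spacing and origin; axial axis stays the third axis
  aff <- diag(c(vol$spacing, 1))
  aff[1:3, 4] <- vol$origin
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path, datatype = "int32")
  invisible(path)
}

#' Render a component back into a binary volume
#'
#' @param component a component as returned by [connected_components()].
#' @param shape integer(3) grid dimensions.
#' @param spacing,origin,axial_axis metadata for the output volume.
#' @return A binary [label_volume] with foreground exactly at the
#'   component's voxels.
#' @export
component_mask <- function(component, shape, spacing = c(1, 1, 1),
                           origin = c(0, 0, 0), axial_axis = 3L) {
  stopifnot(inherits(component, "ln_component"))
  shape <- as.integer(shape)
  idx <- component$indices
  if (any(idx < 1L) || any(idx[, 1] > shape[1]) || any(idx[, 2] > shape[2]) ||
      any(idx[, 3] > shape[3]))
    stop("component indices out of bounds for the requested shape", call. = FALSE)
  arr <- array(0L, dim = shape)
  arr[idx] <- 1L
  label_volume(arr, spacing = spacing, origin = origin, axial_axis = axial_axis)
}

#' Extract one label of a multilabel volume as a binary mask
#'
#' @param vol a [label_volume].
#' @param label the integer label to select (or a vector of labels).
#' @return A binary [label_volume], foreground where `voxels` matched.
#' @export
binarize_label <- function(vol, label) {
  stopifnot(inherits(vol, "label_volume"))
  arr <- array(as.integer(vol$voxels %in% as.integer(label)),
               dim = dim(vol$voxels))
  label_volume(arr, spacing = vol$spacing, origin = vol$origin,
               axial_axis = vol$axial_axis)
}

# linear (column-major) voxel ids for fast set operations between index sets
linear_ids <- function(idx, shape) {
  (idx[, 3] - 1) * (shape[1] * shape[2]) + (idx[, 2] - 1) * shape[1] + idx[, 1]
}
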