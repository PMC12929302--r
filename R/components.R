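#' 3D connected components of a binary volume
#'
#' Partitions the foreground of a binary volume into maximal connected sets
#' under 6-, 18- or 26-connectivity. Component ids are assigned in order of
#' first encounter during a column-major scan, which makes labelling
#' deterministic across runs and platforms.
#'
#' @param vol a binary [label_volume].
#' @param connectivity one of 6, 18, 26 (default 26: face, edge and corner
#'   neighbours all connect, the most permissive choice, which avoids
#'   splitting thin structures).
#' @return A list of components (class `ln_component`), each with fields
#'   `id`, `indices` (n x 3 matrix of 1-based `(i, j, k)` voxel indices),
#'   `voxel_count` and `centroid_mm` (physical-space centroid).
#' @export
connected_components <- function(vol, connectivity = 26L) {
  stopifnot(inherits(vol, "label_volume"))
  stop_if_not_binary(vol, "connected_components input")
  d <- dim(vol$voxels)
  lab <- .cc_label3d(as.integer(vol$voxels), as.integer(d), as.integer(connectivity))
  n_comp <- if (length(lab)) max(lab) else 0L
  if (n_comp == 0L) return(list())
  fg <- which(lab != 0L)
  idx_all <- arrayInd(fg, d)
  comps <- vector("list", n_comp)
  lab_fg <- lab[fg]
  ord <- order(lab_fg, fg)
  idx_all <- idx_all[ord, , drop = FALSE]
  lab_fg <- lab_fg[ord]
  starts <- c(1L, which(diff(lab_fg) != 0L) + 1L)
  ends <- c(starts[-1L] - 1L, length(lab_fg))
  for (c_id in seq_len(n_comp)) {
    idx <- idx_all[starts[c_id]:ends[c_id], , drop = FALSE]
    comps[[c_id]] <- new_component(c_id, idx, vol$spacing, vol$origin)
  }
  comps
}

new_component <- function(id, indices, spacing, origin) {
  indices <- matrix(as.integer(indices), ncol = 3)
  centroid_idx <- colMeans(indices)
  structure(list(id = as.integer(id),
                 indices = indices,
                 voxel_count = nrow(indices),
                 centroid_mm = origin + (centroid_idx - 1) * spacing),
            class = "ln_component")
}

#' @export
print.ln_component <- function(x, ...) {
  cat(sprintf("<component %d> %d voxels, centroid (%.1f, %.1f, %.1f) mm\n",
              x$id, x$voxel_count, x$centroid_mm[1], x$centroid_mm[2],
              x$centroid_mm[3]))
  invisible(x)
}

#' Fill enclosed cavities in a binary volume
#'
#' Background cavities not connected to the volume border become foreground;
#' existing foreground is never removed, and the operation is idempotent.
#' Filling is 3D by default (components are 3D objects); 2D per-axial-slice
#' filling is available for workflows that treat slices independently.
#'
#' @param vol a binary [label_volume].
#' @param method `"3d"` (default) or `"2d"` (per axial slice).
#' @return A binary [label_volume] with holes filled.
#' @export
fill_holes <- function(vol, method = c("3d", "2d")) {
  stopifnot(inherits(vol, "label_volume"))
  stop_if_not_binary(vol, "fill_holes input")
  method <- match.arg(method)
  d <- dim(vol$voxels)
  out <- vol$voxels
  if (method == "3d") {
    reach <- .border_background3d(as.integer(out), as.integer(d))
    out[reach == 0L] <- 1L
  } else {
    ax <- vol$axial_axis
    n_slices <- d[ax]
    for (k in seq_len(n_slices)) {
      sl <- extract_slice(out, ax, k)
      # embed the slice between two solid layers so that only in-plane
      # border voxels seed the background flood
      slab <- array(1L, dim = c(dim(sl), 3L))
      slab[, , 2] <- sl
      reach <- array(.border_background3d(as.integer(slab),
                                          as.integer(dim(slab))),
                     dim = dim(slab))
      sl[reach[, , 2] == 0L] <- 1L
      out <- assign_slice(out, ax, k, sl)
    }
  }
  label_volume(out, spacing = vol$spacing, origin = vol$origin,
               axial_axis = vol$axial_axis)
}

extract_slice <- function(arr, axis, k) {
  switch(axis, arr[k, , ], arr[, k, ], arr[, , k])
}

assign_slice <- function(arr, axis, k, sl) {
  if (axis == 1L) arr[k, , ] <- sl
  else if (axis == 2L) arr[, k, ] <- sl
  else arr[, , k] <- sl
  arr
}

#' Remove small connected components
#'
#' Components whose voxel count is at or below `min_voxels` are discarded:
#' at typical chest CT resolution a 30-voxel object is roughly 3 mm across,
#' below the size of a measurable lymph node.
#'
#' @param components list of components from [connected_components()].
#' @param min_voxels inclusive removal threshold (default 30: a component of
#'   exactly 30 voxels is removed, 31 is kept).
#' @return A list with `kept` and `removed` component lists; input order is
#'   preserved and every component appears in exactly one of the two.
#' @export
remove_small_components <- function(components, min_voxels = 30L) {
  if (min_voxels < 0) stop("min_voxels must be non-negative", call. = FALSE)
  if (length(components) == 0L) return(list(kept = list(), removed = list()))
  counts <- vapply(components, function(c) c$voxel_count, integer(1))
  small <- counts <= min_voxels
  list(kept = components[!small], removed = components[small])
}
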