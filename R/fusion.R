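#' Fuse ensemble prediction masks into one pseudolabel mask
#'
#' Combines the binary prediction masks of the ensemble members voxel-wise.
#' The default `"union"` strategy marks a voxel foreground if at least one
#' member predicted it: a recall-first choice that minimises irrecoverably
#' missed lymph nodes at the cost of false positives, which the anatomical
#' filter removes downstream. More conservative `"majority"` and `"k_of_n"`
#' strategies are provided for ablation only.
#'
#' @param masks non-empty list of binary [label_volume]s sharing one grid.
#' @param strategy `"union"` (default), `"majority"`, or `"k_of_n"`.
#' @param k minimum number of member votes, used when `strategy = "k_of_n"`.
#' @return A binary [label_volume] on the shared grid.
#' @export
union_fuse <- function(masks, strategy = c("union", "majority", "k_of_n"),
                       k = 1L) {
  strategy <- match.arg(strategy)
  if (length(masks) == 0L) stop("need at least one mask", call. = FALSE)
  for (m in masks) {
    stopifnot(inherits(m, "label_volume"))
    stop_if_not_binary(m, "ensemble mask")
    stop_if_grid_mismatch(masks[[1]], m)
  }
  votes <- Reduce(`+`, lapply(masks, function(m) m$voxels))
  need <- switch(strategy,
                 union = 1L,
                 majority = floor(length(masks) / 2) + 1L,
                 k_of_n = as.integer(k))
  out <- array(ifelse(votes >= need, 1L, 0L), dim = dim(masks[[1]]$voxels))
  label_volume(out, spacing = masks[[1]]$spacing, origin = masks[[1]]$origin,
               axial_axis = masks[[1]]$axial_axis)
}

#' Postprocess a fused mask into lymph-node candidate components
#'
#' The shared postprocessing applied both at pseudolabel generation and at
#' inference: fill enclosed holes, extract 3D connected components, and
#' drop components of `min_voxels` or fewer voxels.
#'
#' @param mask a binary [label_volume].
#' @param min_voxels inclusive small-component threshold (default 30).
#' @param connectivity component connectivity (default 26).
#' @return List of kept components with deterministic ids.
#' @export
postprocess <- function(mask, min_voxels = 30L, connectivity = 26L) {
  filled <- fill_holes(mask)
  comps <- connected_components(filled, connectivity = connectivity)
  remove_small_components(comps, min_voxels = min_voxels)$kept
}

#' Fuse ensemble masks and postprocess in one step
#'
#' @inheritParams union_fuse
#' @inheritParams postprocess
#' @return List of kept components of the fused mask.
#' @export
fuse_and_postprocess <- function(masks, min_voxels = 30L, connectivity = 26L,
                                 strategy = "union", k = 1L) {
  postprocess(union_fuse(masks, strategy = strategy, k = k),
              min_voxels = min_voxels, connectivity = connectivity)
}
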