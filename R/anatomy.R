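#' Canonical names of the 17 mediastinal filter structures
#'
#' Bilateral vessels are split into left/right entries, which brings the
#' anatomical list (trachea, bronchi, lungs, subclavian arteries, superior
#' vena cava, pulmonary veins, common carotid arteries, brachiocephalic
#' veins, brachiocephalic trunk, left atrial appendage, aorta, heart,
#' esophagus, pulmonary arteries) to 17 masks.
#'
#' @return Character vector of 17 structure names.
#' @export
mediastinal_structures <- function() {
  c("trachea", "bronchi", "lungs",
    "subclavian_artery_left", "subclavian_artery_right",
    "superior_vena_cava", "pulmonary_veins",
    "common_carotid_artery_left", "common_carotid_artery_right",
    "brachiocephalic_vein_left", "brachiocephalic_vein_right",
    "brachiocephalic_trunk", "left_atrial_appendage",
    "aorta", "heart", "esophagus", "pulmonary_artery")
}

#' Anatomy atlas: named binary structure masks on one grid
#'
#' Holds the binary masks driving anatomical filtering. `lung_left` and
#' `lung_right` are required and must be non-empty; a combined `lungs` mask
#' is derived from them when absent. Filter structures (see
#' [mediastinal_structures()]) may be empty but must share the grid.
#'
#' @param structures named list of binary [label_volume]s.
#' @return An object of class `anatomy_atlas`.
#' @export
anatomy_atlas <- function(structures) {
  if (is.null(names(structures)) || any(names(structures) == ""))
    stop("structures must be a named list", call. = FALSE)
  for (nm in c("lung_left", "lung_right"))
    if (is.null(structures[[nm]]))
      stop(sprintf("missing required lung mask: %s", nm), call. = FALSE)
  ref <- structures[[1]]
  for (nm in names(structures)) {
    stopifnot(inherits(structures[[nm]], "label_volume"))
    stop_if_not_binary(structures[[nm]], nm)
    stop_if_grid_mismatch(ref, structures[[nm]])
  }
  for (nm in c("lung_left", "lung_right"))
    if (sum(structures[[nm]]$voxels) == 0L)
      stop(sprintf("%s mask is empty", nm), call. = FALSE)
  if (is.null(structures[["lungs"]])) {
    both <- structures[["lung_left"]]$voxels | structures[["lung_right"]]$voxels
    structures[["lungs"]] <- label_volume(
      array(as.integer(both), dim = dim(ref$voxels)),
      spacing = ref$spacing, origin = ref$origin, axial_axis = ref$axial_axis)
  }
  structure(list(structures = structures), class = "anatomy_atlas")
}

#' @export
print.anatomy_atlas <- function(x, ...) {
  cat(sprintf("<anatomy_atlas> %d structures on a %s grid\n",
              length(x$structures),
              paste(dim(x$structures[[1]]$voxels), collapse = " x ")))
  invisible(x)
}

#' Read an anatomy atlas from a structure-name manifest
#'
#' The manifest is a JSON or YAML map from structure name to NIfTI file
#' path (relative paths resolved against the manifest's directory).
#'
#' @param path path to the manifest file.
#' @return An [anatomy_atlas].
#' @export
read_anatomy_atlas <- function(path) {
  if (!file.exists(path)) stop(sprintf("manifest not found: %s", path), call. = FALSE)
  mapping <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required to read YAML manifests", call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  base <- dirname(path)
  vols <- lapply(mapping, function(p) {
    if (!file.exists(p) && file.exists(file.path(base, p))) p <- file.path(base, p)
    read_label_volume(p)
  })
  anatomy_atlas(vols)
}

#' Mediastinal region of interest from the lung masks
#'
#' On each axial slice where both lungs appear, the ROI is the tight 2D
#' bounding box enclosing both lung cross-sections minus all lung voxels —
#' the inter-lung compartment where mediastinal nodes reside. Slices
#' lacking either lung contribute no ROI.
#'
#' @param atlas an [anatomy_atlas] with non-empty `lung_left`, `lung_right`.
#' @return A binary [label_volume]: the ROI mask.
#' @export
mediastinal_roi <- function(atlas) {
  stopifnot(inherits(atlas, "anatomy_atlas"))
  ll <- atlas$structures[["lung_left"]]
  lr <- atlas$structures[["lung_right"]]
  ax <- ll$axial_axis
  d <- dim(ll$voxels)
  roi <- array(0L, dim = d)
  inplane <- setdiff(1:3, ax)
  for (k in seq_len(d[ax])) {
    sl_l <- extract_slice(ll$voxels, ax, k)
    sl_r <- extract_slice(lr$voxels, ax, k)
    if (!any(sl_l != 0L) || !any(sl_r != 0L)) next
    both <- which(sl_l != 0L | sl_r != 0L, arr.ind = TRUE)
    r1 <- range(both[, 1]); r2 <- range(both[, 2])
    box <- matrix(0L, nrow = d[inplane[1]], ncol = d[inplane[2]])
    box[r1[1]:r1[2], r2[1]:r2[2]] <- 1L
    box[sl_l != 0L | sl_r != 0L] <- 0L
    roi <- assign_slice(roi, ax, k, box)
  }
  label_volume(roi, spacing = ll$spacing, origin = ll$origin, axial_axis = ax)
}

new_filter_decision <- function(component_id, kept, reason = NA_character_,
                                structure = NA_character_, overlap = NA_real_) {
  data.frame(component_id = as.integer(component_id), kept = kept,
             reason = reason, structure = structure, overlap = overlap,
             stringsAsFactors = FALSE)
}

empty_decisions <- function() {
  data.frame(component_id = integer(0), kept = logical(0),
             reason = character(0), structure = character(0),
             overlap = numeric(0), stringsAsFactors = FALSE)
}

#' Extramediastinal filtering against the lung-derived ROI
#'
#' A candidate component is kept iff its centroid voxel lies inside the
#' ROI; components inside the lungs or lateral to them are tagged
#' `extramediastinal`. Centroid membership is the default rule because it
#' is robust for nodes abutting the ROI border; `rule = "any_voxel"` and
#' `"majority"` are available alternatives.
#'
#' @param components list of components on the ROI grid.
#' @param roi binary [label_volume] from [mediastinal_roi()].
#' @param rule `"centroid"` (default), `"any_voxel"` or `"majority"`.
#' @return data.frame of decisions, one row per component, with columns
#'   `component_id`, `kept`, `reason`, `structure`, `overlap`.
#' @export
extramediastinal_filter <- function(components, roi,
                                    rule = c("centroid", "any_voxel", "majority")) {
  rule <- match.arg(rule)
  d <- dim(roi$voxels)
  rows <- lapply(components, function(comp) {
    inside <- switch(rule,
      centroid = {
        ci <- round((comp$centroid_mm - roi$origin) / roi$spacing) + 1
        ci <- pmin(pmax(as.integer(ci), 1L), d)
        roi$voxels[matrix(ci, ncol = 3)] != 0L
      },
      any_voxel = any(roi$voxels[comp$indices] != 0L),
      majority = mean(roi$voxels[comp$indices] != 0L) > 0.5)
    if (inside) new_filter_decision(comp$id, TRUE)
    else new_filter_decision(comp$id, FALSE, reason = "extramediastinal")
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Fraction of a component's voxels inside a structure mask
#'
#' @param component a component.
#' @param structure binary [label_volume] on the same grid.
#' @return `|component voxels inside structure| / voxel_count`, in \[0, 1\].
#' @export
overlap_fraction <- function(component, structure) {
  stopifnot(inherits(component, "ln_component"))
  if (component$voxel_count == 0L) stop("empty component", call. = FALSE)
  sum(structure$voxels[component$indices] != 0L) / component$voxel_count
}

#' Intramediastinal filtering by overlap with mediastinal structures
#'
#' Removes a component when its overlap fraction with any single filter
#' structure reaches `threshold` (inclusive: at least 40% of voxels labeled
#' in both removes). Fractions are taken per structure — the maximum over
#' structures decides, fractions are never summed — because nodes naturally
#' abut several vessels at once with small individual overlaps. The
#' decision records the argmax structure and its fraction.
#'
#' @param components list of components on the atlas grid.
#' @param atlas an [anatomy_atlas] containing every structure in
#'   `structures` (a configuration error lists any absent names).
#' @param threshold inclusive removal fraction, default 0.40.
#' @param structures structure names to test; defaults to the 17-name
#'   vocabulary of [mediastinal_structures()].
#' @return data.frame of decisions as in [extramediastinal_filter()], with
#'   `reason = "overlap"` for removals.
#' @export
intramediastinal_filter <- function(components, atlas, threshold = 0.40,
                                    structures = mediastinal_structures()) {
  stopifnot(inherits(atlas, "anatomy_atlas"))
  absent <- setdiff(structures, names(atlas$structures))
  if (length(absent))
    stop(sprintf("atlas is missing structure masks: %s",
                 paste(absent, collapse = ", ")), call. = FALSE)
  rows <- lapply(components, function(comp) {
    fr <- vapply(structures,
                 function(nm) overlap_fraction(comp, atlas$structures[[nm]]),
                 numeric(1))
    worst <- which.max(fr)
    if (fr[worst] >= threshold)
      new_filter_decision(comp$id, FALSE, reason = "overlap",
                          structure = structures[worst], overlap = fr[worst])
    else
      new_filter_decision(comp$id, TRUE, overlap = fr[worst])
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Apply both anatomical filters in pipeline order
#'
#' Extramediastinal filtering runs first, then intramediastinal filtering
#' on the survivors, so a lung-interior component is tagged
#' `extramediastinal` even if it also overlaps a vessel. Every input
#' component receives exactly one decision.
#'
#' @inheritParams intramediastinal_filter
#' @param roi optional precomputed ROI; computed from the atlas when NULL.
#' @param rule extramediastinal membership rule, see
#'   [extramediastinal_filter()].
#' @return List with `kept` (components surviving both stages) and
#'   `decisions` (data.frame covering every input component once).
#' @export
apply_filters <- function(components, atlas, threshold = 0.40, roi = NULL,
                          rule = "centroid",
                          structures = mediastinal_structures()) {
  if (is.null(roi)) roi <- mediastinal_roi(atlas)
  if (length(components) == 0L)
    return(list(kept = list(), decisions = empty_decisions()))
  dec1 <- extramediastinal_filter(components, roi, rule = rule)
  survivors <- components[dec1$kept]
  dec2 <- if (length(survivors))
    intramediastinal_filter(survivors, atlas, threshold = threshold,
                            structures = structures)
  else empty_decisions()
  decisions <- rbind(dec1[!dec1$kept, , drop = FALSE], dec2)
  decisions <- decisions[order(decisions$component_id), , drop = FALSE]
  rownames(decisions) <- NULL
  kept_ids <- decisions$component_id[decisions$kept]
  ids <- vapply(components, function(c) c$id, integer(1))
  list(kept = components[ids %in% kept_ids], decisions = decisions)
}

#' Filtering summary in reduction-percent form
#'
#' @param n_before number of candidate nodes before filtering (> 0).
#' @param n_removed number removed by filtering (0..n_before).
#' @return List with `n_before`, `n_removed`, `n_after` and
#'   `reduction_pct` = `100 * n_removed / n_before` rounded to one decimal.
#' @export
filtering_report <- function(n_before, n_removed) {
  if (n_before <= 0) stop("n_before must be positive", call. = FALSE)
  if (n_removed < 0 || n_removed > n_before)
    stop("n_removed must be in [0, n_before]", call. = FALSE)
  list(n_before = n_before, n_removed = n_removed,
       n_after = n_before - n_removed,
       reduction_pct = round(100 * n_removed / n_before, 1))
}
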