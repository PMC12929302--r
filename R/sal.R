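#' 2D axial cross-sections of a 3D component
#'
#' Splits a component into its per-axial-slice cross-sections, each further
#' split into 2D-connected subsets (8-connectivity in plane), since the
#' caliper equations are defined on a connected 2D region.
#'
#' @param component a component.
#' @param shape integer(3) grid dimensions of the parent volume.
#' @param axial_axis axial axis index (default 3).
#' @return Named list keyed by slice index; each element is a list of
#'   n x 2 matrices of in-plane voxel indices.
#' @export
axial_cross_sections <- function(component, shape, axial_axis = 3L) {
  stopifnot(inherits(component, "ln_component"))
  idx <- component$indices
  inplane <- setdiff(1:3, axial_axis)
  by_slice <- split(seq_len(nrow(idx)), idx[, axial_axis])
  out <- lapply(by_slice, function(rows) {
    ij <- idx[rows, inplane, drop = FALSE]
    # label the 2D set with 8-connectivity by embedding it in a local grid
    r1 <- range(ij[, 1]); r2 <- range(ij[, 2])
    nx <- r1[2] - r1[1] + 1L; ny <- r2[2] - r2[1] + 1L
    grid <- array(0L, dim = c(nx, ny, 1L))
    loc <- cbind(ij[, 1] - r1[1] + 1L, ij[, 2] - r2[1] + 1L, 1L)
    grid[loc] <- 1L
    lab <- array(.cc_label3d(as.integer(grid), c(nx, ny, 1L), 26L),
                 dim = c(nx, ny, 1L))
    labs <- lab[loc]
    lapply(split(seq_len(nrow(ij)), labs), function(r) ij[r, , drop = FALSE])
  })
  names(out) <- names(by_slice)
  out
}

#' Contour of a 2D cross-section in physical coordinates
#'
#' Boundary voxels are those with at least one 4-neighbour outside the set
#' (voxels on the section's bounding edge count, since their neighbour off
#' the set is background). Voxel centers are scaled by the in-plane spacing
#' to mm.
#'
#' @param cross_section n x 2 matrix of in-plane voxel indices (1-based).
#' @param spacing numeric(2) in-plane voxel size in mm.
#' @param slice_index axial slice index carried along for reporting.
#' @return Object of class `contour2d` with `points` (m x 2 matrix, mm) and
#'   `slice_index`.
#' @export
boundary_points <- function(cross_section, spacing = c(1, 1), slice_index = NA_integer_) {
  stopifnot(is.matrix(cross_section), ncol(cross_section) == 2, nrow(cross_section) >= 1)
  i <- cross_section[, 1]; j <- cross_section[, 2]
  key <- paste(i, j)
  interior <- (paste(i - 1L, j) %in% key) & (paste(i + 1L, j) %in% key) &
    (paste(i, j - 1L) %in% key) & (paste(i, j + 1L) %in% key)
  pts <- cross_section[!interior, , drop = FALSE]
  mm <- cbind((pts[, 1] - 1) * spacing[1], (pts[, 2] - 1) * spacing[2])
  structure(list(points = mm, slice_index = as.integer(slice_index)),
            class = "contour2d")
}

# canonicalize a pair of point-row indices so the lexicographically smaller
# point (by first then second coordinate) comes first, then return the pair
# that is lexicographically smallest among candidate pairs of equal length
canonical_best_pair <- function(pts, ia, ib) {
  a <- pts[ia, , drop = FALSE]
  b <- pts[ib, , drop = FALSE]
  swap <- (a[, 1] > b[, 1]) | (a[, 1] == b[, 1] & a[, 2] > b[, 2])
  p1 <- a; p1[swap, ] <- b[swap, , drop = FALSE]
  p2 <- b; p2[swap, ] <- a[swap, , drop = FALSE]
  ord <- order(p1[, 1], p1[, 2], p2[, 1], p2[, 2])[1]
  rbind(p1[ord, ], p2[ord, ])
}

new_axis_measurement <- function(endpoints, degenerate = FALSE) {
  len <- sqrt(sum((endpoints[1, ] - endpoints[2, ])^2))
  dir <- if (len > 0) (endpoints[1, ] - endpoints[2, ]) / len else c(NA_real_, NA_real_)
  structure(list(endpoints = endpoints, length = len, direction = dir,
                 degenerate = degenerate),
            class = "axis_measurement")
}

#' Long axis of a contour
#'
#' The pair of contour points maximising the pairwise Euclidean distance
#' (the diameter of the point set). Since diameter endpoints are convex-hull
#' vertices, the search is restricted to the hull; ties are broken by the
#' lexicographically smallest endpoint pair so results are deterministic.
#' The direction is the normalised vector from the first endpoint to the
#' second.
#'
#' @param contour a `contour2d`.
#' @return An `axis_measurement` with `endpoints` (2 x 2, mm), `length`
#'   (mm) and unit `direction`; a 1-point contour yields length 0.
#' @export
long_axis <- function(contour) {
  pts <- contour$points
  n <- nrow(pts)
  if (n == 1L)
    return(new_axis_measurement(rbind(pts[1, ], pts[1, ]), degenerate = TRUE))
  hull <- unique(grDevices::chull(pts))
  h <- pts[hull, , drop = FALSE]
  dx <- outer(h[, 1], h[, 1], `-`)
  dy <- outer(h[, 2], h[, 2], `-`)
  d2 <- dx * dx + dy * dy
  best <- max(d2)
  hits <- which(d2 == best & upper.tri(d2), arr.ind = TRUE)
  if (nrow(hits) == 0L)  # all hull points coincide cannot happen (distinct pts)
    hits <- which(d2 == best, arr.ind = TRUE)[1, , drop = FALSE]
  new_axis_measurement(canonical_best_pair(h, hits[, 1], hits[, 2]))
}

#' Short axis (SAL) of a contour given its long axis
#'
#' The longest chord between contour points perpendicular to the long-axis
#' direction. Exact perpendicularity is measure-zero on a discrete grid, so
#' pairs within `angle_tol_deg` of perpendicular qualify; if no pair
#' qualifies the tolerance doubles (3, 6, 12, 24, then capped at 45
#' degrees) until one does, or the result is flagged degenerate with length
#' 0. Ties are broken like [long_axis()].
#'
#' @param contour a `contour2d`.
#' @param la the `axis_measurement` from [long_axis()] on the same contour.
#' @param angle_tol_deg starting angular tolerance in degrees (default 3).
#' @return An `axis_measurement`; `degenerate = TRUE` with length 0 when no
#'   perpendicular chord exists within 45 degrees.
#' @export
short_axis <- function(contour, la, angle_tol_deg = 3) {
  pts <- contour$points
  n <- nrow(pts)
  if (n == 1L || la$length == 0)
    return(new_axis_measurement(rbind(pts[1, ], pts[1, ]), degenerate = TRUE))
  u <- la$direction
  dx <- outer(pts[, 1], pts[, 1], `-`)
  dy <- outer(pts[, 2], pts[, 2], `-`)
  d2 <- dx * dx + dy * dy
  dot <- dx * u[1] + dy * u[2]
  tol <- angle_tol_deg
  repeat {
    s <- sin(tol * pi / 180)
    ok <- (dot * dot <= d2 * (s * s)) & upper.tri(d2)
    if (any(ok)) {
      best <- max(d2[ok])
      hits <- which(ok & d2 == best, arr.ind = TRUE)
      return(new_axis_measurement(canonical_best_pair(pts, hits[, 1], hits[, 2])))
    }
    if (tol >= 45) break
    tol <- min(tol * 2, 45)
  }
  new_axis_measurement(rbind(pts[1, ], pts[1, ]), degenerate = TRUE)
}

#' Classify a short-axis length as normal or enlarged
#'
#' The clinical size criterion: enlarged iff SAL >= 10 mm.
#'
#' @param sal_mm non-negative short-axis length in mm.
#' @param threshold_mm classification threshold (default 10).
#' @return `"normal"` or `"enlarged"`.
#' @export
classify_node <- function(sal_mm, threshold_mm = 10) {
  if (any(sal_mm < 0)) stop("sal_mm must be non-negative", call. = FALSE)
  ifelse(sal_mm >= threshold_mm, "enlarged", "normal")
}

#' Measure a lymph-node component: reference slice, long axis and SAL
#'
#' Computes the long and short axes on every axial cross-section (per
#' 2D-connected subset when a slice intersects the node in several pieces)
#' and takes as the node's SAL the maximum per-slice SAL, with the argmax
#' slice as the reference slice — the node measured at its widest short
#' axis, matching the clinical per-axial-slice caliper protocol. Ties go to
#' the lowest slice index.
#'
#' @param component a component.
#' @param shape integer(3) grid dimensions of the parent volume.
#' @param spacing numeric(3) voxel spacing in mm.
#' @param axial_axis axial axis index (default 3).
#' @param threshold_mm normal/enlarged threshold (default 10 mm).
#' @param angle_tol_deg perpendicularity tolerance for [short_axis()].
#' @return An object of class `sal_measurement` with fields `node_id`,
#'   `reference_slice`, `long_axis`, `short_axis`, `sal_mm`, `size_class`.
#' @export
measure_node <- function(component, shape, spacing, axial_axis = 3L,
                         threshold_mm = 10, angle_tol_deg = 3) {
  inplane_sp <- spacing[setdiff(1:3, axial_axis)]
  sections <- axial_cross_sections(component, shape, axial_axis = axial_axis)
  best <- NULL
  # slices iterate in ascending order, so keeping the first strict maximum
  # implements the lowest-slice tie-break
  for (slice_name in names(sections)) {
    slice_idx <- as.integer(slice_name)
    for (subset in sections[[slice_name]]) {
      ct <- boundary_points(subset, spacing = inplane_sp, slice_index = slice_idx)
      la <- long_axis(ct)
      sa <- short_axis(ct, la, angle_tol_deg = angle_tol_deg)
      sal <- if (sa$degenerate) 0 else sa$length
      if (is.null(best) || sal > best$sal_mm)
        best <- list(reference_slice = slice_idx, long_axis = la,
                     short_axis = sa, sal_mm = sal)
    }
  }
  structure(list(node_id = component$id,
                 reference_slice = best$reference_slice,
                 long_axis = best$long_axis,
                 short_axis = best$short_axis,
                 sal_mm = best$sal_mm,
                 size_class = classify_node(best$sal_mm, threshold_mm)),
            class = "sal_measurement")
}

#' @export
print.sal_measurement <- function(x, ...) {
  cat(sprintf("<sal_measurement node %s> SAL %.2f mm (%s), long axis %.2f mm, slice %d\n",
              x$node_id, x$sal_mm, x$size_class, x$long_axis$length,
              x$reference_slice))
  invisible(x)
}

#' Pairwise differences between two SAL measurements of the same node
#'
#' @param m1,m2 `sal_measurement` objects for the same node.
#' @return List with `dsal_mm` (absolute SAL difference), `dslice`
#'   (absolute reference-slice difference) and `dangle_deg` (angle between
#'   the two short-axis directions folded to \[0, 90\] degrees, since an
#'   axis is undirected; `NA` when either axis is degenerate).
#' @export
delta_metrics <- function(m1, m2) {
  dsal <- abs(m1$sal_mm - m2$sal_mm)
  dslice <- abs(m1$reference_slice - m2$reference_slice)
  dangle <- if (isTRUE(m1$short_axis$degenerate) || isTRUE(m2$short_axis$degenerate)) {
    NA_real_
  } else {
    cosang <- abs(sum(m1$short_axis$direction * m2$short_axis$direction))
    acos(pmin(1, cosang)) * 180 / pi
  }
  list(dsal_mm = dsal, dslice = dslice, dangle_deg = dangle)
}

#' Measure every component in a list
#'
#' @param components list of components.
#' @inheritParams measure_node
#' @return data.frame with one row per component: `node_id`,
#'   `reference_slice`, `sal_mm`, `long_axis_mm`, `size_class` and axis
#'   endpoints in mm.
#' @export
measure_nodes <- function(components, shape, spacing, axial_axis = 3L,
                          threshold_mm = 10, angle_tol_deg = 3) {
  rows <- lapply(components, function(comp) {
    m <- measure_node(comp, shape, spacing, axial_axis = axial_axis,
                      threshold_mm = threshold_mm, angle_tol_deg = angle_tol_deg)
    data.frame(node_id = m$node_id, reference_slice = m$reference_slice,
               sal_mm = m$sal_mm, long_axis_mm = m$long_axis$length,
               size_class = m$size_class,
               sa_x1 = m$short_axis$endpoints[1, 1], sa_y1 = m$short_axis$endpoints[1, 2],
               sa_x2 = m$short_axis$endpoints[2, 1], sa_y2 = m$short_axis$endpoints[2, 2],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
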