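#' Specification of a synthetic thorax label phantom
#'
#' Describes a deterministic, fully synthetic stand-in for the label-volume
#' inputs of the pipeline: two ellipsoidal "lungs", tubular "vessels" drawn
#' from the 17-structure vocabulary, and ellipsoidal lymph nodes of known
#' geometry. Nodes are axis-aligned so their axial SAL truth is exact: the
#' equatorial cross-section of an ellipsoid with in-plane semi-axes
#' `a >= b` is an ellipse of long axis `2a` and short axis `2b`.
#'
#' @param shape integer(3) grid dimensions `(x, y, z)`; default
#'   `c(128, 128, 96)` with z axial.
#' @param spacing numeric(3) voxel size in mm; default `c(0.7, 0.7, 1)`,
#'   anisotropic as on CT.
#' @param lungs list of two lung descriptors (`center` mm, `semi_axes` mm);
#'   defaults place ellipsoidal lungs left and right of a mediastinal gap.
#' @param tubes list of structure tubes: `name` (from
#'   [mediastinal_structures()]), in-plane `center` mm, `radius` mm;
#'   rasterised as full-height cylinders along z.
#' @param nodes list of node descriptors from [phantom_node()].
#' @param seed integer seed threading every random draw.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(128L, 128L, 96L),
                         spacing = c(0.7, 0.7, 1),
                         lungs = default_phantom_lungs(),
                         tubes = list(list(name = "aorta",
                                           center = c(44.8, 30), radius = 6)),
                         nodes = list(),
                         seed = 1L) {
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 lungs = lungs, tubes = tubes, nodes = nodes,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

default_phantom_lungs <- function() {
  list(list(center = c(22, 45, 48), semi_axes = c(16, 28, 40)),
       list(center = c(67, 45, 48), semi_axes = c(16, 28, 40)))
}

#' Describe one planted lymph node for the phantom
#'
#' @param center numeric(3) center in mm (ignored for `vessel_fp`, whose
#'   position is solved for; the z component still places its slice).
#' @param semi_axes numeric(3) ellipsoid semi-axes `(a, b, c)` in mm with
#'   `a` the in-plane major (x), `b` the in-plane minor (y) and `c` axial;
#'   analytic SAL = `2 * b`.
#' @param kind `"true"` (a real node, expected to survive the pipeline),
#'   `"lung_fp"` (planted inside a lung, expected extramediastinal
#'   removal), `"vessel_fp"` (planted to overlap `structure` at
#'   `target_overlap`, expected overlap removal), or `"speck"` (random
#'   connected blob of `n_voxels`, expected small-component removal).
#' @param structure structure name a `vessel_fp` must overlap.
#' @param target_overlap target overlap fraction in `(0, 1]` for
#'   `vessel_fp`; realised within 0.02.
#' @param n_voxels voxel count for `speck` nodes.
#' @return A node descriptor list.
#' @export
phantom_node <- function(center, semi_axes = c(5, 4, 4),
                         kind = c("true", "lung_fp", "vessel_fp", "speck"),
                         structure = "aorta", target_overlap = 0.5,
                         n_voxels = 20L) {
  kind <- match.arg(kind)
  if (kind == "vessel_fp" && (target_overlap <= 0 || target_overlap > 1))
    stop("target_overlap must be in (0, 1]", call. = FALSE)
  if (kind == "speck" && n_voxels < 1)
    stop("speck n_voxels must be >= 1", call. = FALSE)
  if (kind != "speck" && any(semi_axes <= 0))
    stop("semi_axes must be positive", call. = FALSE)
  list(center = center, semi_axes = semi_axes, kind = kind,
       structure = structure, target_overlap = target_overlap,
       n_voxels = as.integer(n_voxels))
}

#' The canonical five-node validation phantom
#'
#' Two true nodes (one enlarged, SAL 12 mm; one normal, SAL 7 mm), one
#' false positive inside the left lung, one false positive overlapping the
#' aorta at 50%, and one 20-voxel speck — one planted example for each
#' pipeline decision path.
#'
#' @param seed integer seed.
#' @return A [phantom_spec()].
#' @export
canonical_phantom_spec <- function(seed = 42L) {
  phantom_spec(nodes = list(
    phantom_node(center = c(44.8, 50, 40), semi_axes = c(6.5, 6, 5), kind = "true"),
    phantom_node(center = c(44.8, 62, 55), semi_axes = c(5, 3.5, 4), kind = "true"),
    phantom_node(center = c(22, 45, 48), semi_axes = c(5, 4, 4), kind = "lung_fp"),
    phantom_node(center = c(44.8, 30, 30), semi_axes = c(5, 4, 4),
                 kind = "vessel_fp", structure = "aorta", target_overlap = 0.5),
    phantom_node(center = c(44.8, 60, 70), kind = "speck", n_voxels = 20L)
  ), seed = seed)
}

# voxel-center coordinate vectors (mm) per axis
axis_coords <- function(shape, spacing) {
  lapply(1:3, function(a) (seq_len(shape[a]) - 1) * spacing[a])
}

# rasterise an axis-aligned ellipsoid; returns linear voxel ids
rasterize_ellipsoid <- function(center, semi_axes, shape, spacing) {
  co <- axis_coords(shape, spacing)
  rng <- lapply(1:3, function(a) {
    which(co[[a]] >= center[a] - semi_axes[a] & co[[a]] <= center[a] + semi_axes[a])
  })
  if (any(vapply(rng, length, integer(1)) == 0L)) return(integer(0))
  xs <- (co[[1]][rng[[1]]] - center[1]) / semi_axes[1]
  ys <- (co[[2]][rng[[2]]] - center[2]) / semi_axes[2]
  zs <- (co[[3]][rng[[3]]] - center[3]) / semi_axes[3]
  g <- expand.grid(x = xs^2, y = ys^2, z = zs^2)
  keep <- g$x + g$y + g$z <= 1
  if (!any(keep)) return(integer(0))
  gi <- expand.grid(i = rng[[1]], j = rng[[2]], k = rng[[3]])[keep, , drop = FALSE]
  (gi$k - 1) * (shape[1] * shape[2]) + (gi$j - 1) * shape[1] + gi$i
}

rasterize_tube <- function(center_xy, radius, shape, spacing) {
  co <- axis_coords(shape, spacing)
  in_circle <- outer((co[[1]] - center_xy[1])^2, (co[[2]] - center_xy[2])^2, `+`) <=
    radius^2
  ij <- which(in_circle, arr.ind = TRUE)
  if (nrow(ij) == 0L) return(integer(0))
  base <- (ij[, 2] - 1) * shape[1] + ij[, 1]
  as.vector(outer(base, (seq_len(shape[3]) - 1) * (shape[1] * shape[2]), `+`))
}

# grow a random connected blob of n voxels from a seed voxel (6-connectivity)
grow_speck <- function(start_idx, n_voxels, shape, occupied) {
  nxy <- shape[1] * shape[2]
  neighbors <- function(lin) {
    i <- ((lin - 1) %% shape[1]) + 1
    j <- (((lin - 1) %/% shape[1]) %% shape[2]) + 1
    k <- ((lin - 1) %/% nxy) + 1
    cand <- c(if (i > 1) lin - 1, if (i < shape[1]) lin + 1,
              if (j > 1) lin - shape[1], if (j < shape[2]) lin + shape[1],
              if (k > 1) lin - nxy, if (k < shape[3]) lin + nxy)
    cand
  }
  blob <- start_idx
  frontier <- setdiff(neighbors(start_idx), occupied)
  while (length(blob) < n_voxels && length(frontier) > 0) {
    pick <- frontier[sample.int(length(frontier), 1L)]
    blob <- c(blob, pick)
    frontier <- setdiff(union(frontier, neighbors(pick)), c(blob, occupied))
  }
  blob
}

#' Build the phantom volumes and their analytic ground truth
#'
#' Rasterises the lungs, structure tubes and nodes of a [phantom_spec()]
#' onto its grid. `vessel_fp` nodes are positioned by a line search along
#' the direction away from their target structure so that the realised
#' voxel overlap fraction lies within 0.02 of the requested target.
#' Everything is deterministic for a fixed seed.
#'
#' @param spec a [phantom_spec()].
#' @return List with `atlas` (an [anatomy_atlas()] holding the lungs and
#'   all 17 filter structures, empty where the spec plants no tube),
#'   `nodes` (a [label_volume] with one distinct label per planted node,
#'   including false positives and specks), `gt_nodes` (the same volume
#'   restricted to `kind == "true"` nodes) and `truth` (data.frame:
#'   `node_id`, `kind`, analytic `sal_mm`, `size_class`, `expected_outcome`).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  shape <- spec$shape; sp <- spec$spacing
  vol0 <- function() array(0L, dim = shape)
  as_lv <- function(arr) label_volume(arr, spacing = sp, axial_axis = 3L)

  lung_arrays <- lapply(spec$lungs, function(lg) {
    a <- vol0()
    a[rasterize_ellipsoid(lg$center, lg$semi_axes, shape, sp)] <- 1L
    a
  })
  structures <- list(lung_left = as_lv(lung_arrays[[1]]),
                     lung_right = as_lv(lung_arrays[[2]]))
  struct_arrays <- stats::setNames(
    lapply(mediastinal_structures(), function(nm) vol0()),
    mediastinal_structures())
  for (tube in spec$tubes) {
    if (!tube$name %in% names(struct_arrays))
      stop(sprintf("unknown structure name: %s", tube$name), call. = FALSE)
    struct_arrays[[tube$name]][rasterize_tube(tube$center, tube$radius, shape, sp)] <- 1L
  }
  struct_arrays[["lungs"]] <- array(
    as.integer(lung_arrays[[1]] | lung_arrays[[2]]), dim = shape)
  for (nm in names(struct_arrays)) structures[[nm]] <- as_lv(struct_arrays[[nm]])
  atlas <- anatomy_atlas(structures)

  nodes_arr <- vol0()
  occupied <- integer(0)
  truth_rows <- list()
  for (n_id in seq_along(spec$nodes)) {
    nd <- spec$nodes[[n_id]]
    lin <- switch(nd$kind,
      true = ,
      lung_fp = rasterize_ellipsoid(nd$center, nd$semi_axes, shape, sp),
      vessel_fp = place_vessel_fp(nd, struct_arrays[[nd$structure]], shape, sp),
      speck = {
        start <- find_background_voxel(nd$center, shape, sp, occupied,
                                       lung_arrays, struct_arrays)
        grow_speck(start, nd$n_voxels, shape, occupied)
      })
    if (length(lin) == 0L)
      stop(sprintf("node %d rasterised to zero voxels", n_id), call. = FALSE)
    if (any(nodes_arr[lin] != 0L))
      stop(sprintf("node %d overlaps an earlier node", n_id), call. = FALSE)
    nodes_arr[lin] <- n_id
    occupied <- c(occupied, lin)
    sal <- if (nd$kind == "speck") NA_real_ else 2 * nd$semi_axes[2]
    truth_rows[[n_id]] <- data.frame(
      node_id = n_id, kind = nd$kind, sal_mm = sal,
      size_class = if (is.na(sal)) NA_character_ else classify_node(sal),
      expected_outcome = switch(nd$kind, true = "kept",
                                lung_fp = "extramediastinal",
                                vessel_fp = "overlap", speck = "size"),
      stringsAsFactors = FALSE)
  }
  gt_arr <- nodes_arr
  true_ids <- which(vapply(spec$nodes, function(n) n$kind == "true", logical(1)))
  gt_arr[!(gt_arr %in% true_ids)] <- 0L
  list(atlas = atlas,
       nodes = as_lv(nodes_arr),
       gt_nodes = as_lv(gt_arr),
       truth = do.call(rbind, c(truth_rows, list(make.row.names = FALSE))))
}

# line search along +y from the node spec's nominal center so the realised
# overlap with the structure hits the target fraction within 0.02
place_vessel_fp <- function(nd, struct_arr, shape, sp, tol = 0.02) {
  if (!any(struct_arr != 0L))
    stop(sprintf("vessel_fp target structure '%s' is empty", nd$structure),
         call. = FALSE)
  step <- sp[2] / 4
  offsets <- seq(-2 * nd$semi_axes[2], 4 * nd$semi_axes[2], by = step)
  best <- NULL
  for (off in offsets) {
    center <- nd$center + c(0, off, 0)
    lin <- rasterize_ellipsoid(center, nd$semi_axes, shape, sp)
    if (length(lin) == 0L) next
    f <- sum(struct_arr[lin] != 0L) / length(lin)
    if (is.null(best) || abs(f - nd$target_overlap) < best$err)
      best <- list(lin = lin, err = abs(f - nd$target_overlap))
    if (best$err == 0) break
  }
  if (is.null(best) || best$err > tol)
    stop(sprintf("could not place vessel_fp within %.2f of target overlap %.2f",
                 tol, nd$target_overlap), call. = FALSE)
  best$lin
}

find_background_voxel <- function(center, shape, sp, occupied, lung_arrays,
                                  struct_arrays) {
  idx <- pmin(pmax(round(center / sp) + 1, 1), shape)
  lin <- (idx[3] - 1) * shape[1] * shape[2] + (idx[2] - 1) * shape[1] + idx[1]
  busy <- lung_arrays[[1]][lin] != 0L || lung_arrays[[2]][lin] != 0L ||
    any(vapply(struct_arrays, function(a) a[lin] != 0L, logical(1))) ||
    lin %in% occupied
  if (busy)
    stop("speck seed position is not background; move the node center",
         call. = FALSE)
  lin
}

# one round of 6-neighbourhood dilation/erosion via array shifts
morph_step <- function(v, op = c("dilate", "erode")) {
  op <- match.arg(op)
  d <- dim(v)
  shift <- function(ax, by) {
    out <- array(FALSE, dim = d)  # border treated as background
    n <- d[ax]
    src <- seq_len(n) - by
    valid <- src >= 1 & src <= n
    to <- which(valid); from <- src[valid]
    if (ax == 1) out[to, , ] <- v[from, , ]
    else if (ax == 2) out[, to, ] <- v[, from, ]
    else out[, , to] <- v[, , from]
    out
  }
  s <- list(shift(1, 1), shift(1, -1), shift(2, 1), shift(2, -1),
            shift(3, 1), shift(3, -1))
  if (op == "dilate") v | s[[1]] | s[[2]] | s[[3]] | s[[4]] | s[[5]] | s[[6]]
  else v & s[[1]] & s[[2]] & s[[3]] & s[[4]] & s[[5]] & s[[6]]
}

#' Generate perturbed ensemble-member predictions from planted nodes
#'
#' Emulates the diverse outputs of a snapshot ensemble: per member, each
#' node is independently dropped with probability `drop_prob`; kept nodes
#' are morphologically jittered by a dilation (positive) or erosion
#' (negative) radius drawn uniformly from `-jitter_radius:jitter_radius`
#' voxels (an erosion that would erase a node reverts to the original);
#' `speck_count` spurious specks of about `speck_voxels` voxels are added
#' at random background sites. Deterministic for a fixed seed.
#'
#' @param nodes_vol a labelled [label_volume] of planted nodes (one label
#'   per node, as produced by [make_phantom()]); a binary volume is first
#'   split into 26-connected components.
#' @param n_members number of ensemble members to emulate.
#' @param jitter_radius maximum morphological jitter in voxels (default 1).
#' @param drop_prob per-node, per-member drop probability in \[0, 1\].
#' @param speck_count spurious specks added per member.
#' @param speck_voxels voxels per spurious speck.
#' @param seed integer seed.
#' @return List of `n_members` binary [label_volume]s.
#' @export
perturb_prediction <- function(nodes_vol, n_members = 24L, jitter_radius = 1L,
                               drop_prob = 0, speck_count = 0L,
                               speck_voxels = 20L, seed = 1L) {
  stopifnot(inherits(nodes_vol, "label_volume"))
  if (drop_prob < 0 || drop_prob > 1)
    stop("drop_prob must be in [0, 1]", call. = FALSE)
  set.seed(seed)
  shape <- dim(nodes_vol$voxels)
  labs <- setdiff(sort(unique(as.vector(nodes_vol$voxels))), 0L)
  node_lin <- lapply(labs, function(l) which(nodes_vol$voxels == l))
  all_occ <- which(nodes_vol$voxels != 0L)
  out <- vector("list", n_members)
  for (m in seq_len(n_members)) {
    arr <- array(FALSE, dim = shape)
    for (nl in node_lin) {
      if (runif(1) < drop_prob) next
      v <- array(FALSE, dim = shape)
      v[nl] <- TRUE
      r <- if (jitter_radius > 0)
        sample(seq(-jitter_radius, jitter_radius), 1L) else 0L
      if (r > 0) for (s in seq_len(r)) v <- morph_step(v, "dilate")
      if (r < 0) {
        v2 <- v
        for (s in seq_len(-r)) v2 <- morph_step(v2, "erode")
        if (any(v2)) v <- v2
      }
      arr <- arr | v
    }
    if (speck_count > 0) {
      for (s in seq_len(speck_count)) {
        free <- which(!arr)
        free <- setdiff(free, all_occ)
        start <- free[sample.int(length(free), 1L)]
        arr[grow_speck(start, speck_voxels, shape, which(arr))] <- TRUE
      }
    }
    out[[m]] <- label_volume(array(as.integer(arr), dim = shape),
                             spacing = nodes_vol$spacing,
                             origin = nodes_vol$origin,
                             axial_axis = nodes_vol$axial_axis)
  }
  out
}

#' Run the full pipeline on a phantom and score it against planted truth
#'
#' Generates perturbed member predictions, fuses and postprocesses them,
#' applies the anatomical filters, measures the surviving nodes, and
#' compares every planted node's fate and SAL against the phantom's
#' analytic truth. Detection precision/recall are computed against the
#' true-node ground truth.
#'
#' @param spec a [phantom_spec()].
#' @param n_members ensemble members to emulate (default 3).
#' @param jitter_radius,drop_prob,speck_count perturbation parameters
#'   passed to [perturb_prediction()]; defaults are the identity
#'   perturbation so planted truth maps exactly onto expected outcomes.
#' @param min_voxels,threshold pipeline parameters.
#' @return List with `per_node` (data.frame: planted node id, kind,
#'   expected and observed outcome, `correct`, measured and true SAL and
#'   their absolute error), `precision`, `recall`, `n_kept` and the kept
#'   components' measurement table.
#' @export
end_to_end_check <- function(spec, n_members = 3L, jitter_radius = 0L,
                             drop_prob = 0, speck_count = 0L,
                             min_voxels = 30L, threshold = 0.40) {
  ph <- make_phantom(spec)
  preds <- perturb_prediction(ph$nodes, n_members = n_members,
                              jitter_radius = jitter_radius,
                              drop_prob = drop_prob,
                              speck_count = speck_count,
                              seed = spec$seed + 1L)
  fused <- union_fuse(preds)
  comps <- postprocess(fused, min_voxels = min_voxels)
  filt <- apply_filters(comps, ph$atlas, threshold = threshold)
  shape <- dim(fused$voxels)
  meas <- if (length(filt$kept))
    measure_nodes(filt$kept, shape, fused$spacing) else NULL

  comp_lin <- lapply(comps, function(c) linear_ids(c$indices, shape))
  per_node <- ph$truth
  per_node$observed_outcome <- NA_character_
  per_node$measured_sal_mm <- NA_real_
  for (r in seq_len(nrow(per_node))) {
    nl <- which(ph$nodes$voxels == per_node$node_id[r])
    in_fused <- any(fused$voxels[nl] != 0L)
    hit <- which(vapply(comp_lin, function(cl) length(intersect(cl, nl)) > 0,
                        logical(1)))
    if (length(hit) == 0L) {
      per_node$observed_outcome[r] <- if (in_fused) "size" else "missing"
      next
    }
    hit_id <- comps[[hit[1]]]$id
    dec <- filt$decisions[filt$decisions$component_id == hit_id, ]
    if (nrow(dec) && !dec$kept[1]) {
      per_node$observed_outcome[r] <- dec$reason[1]
    } else {
      per_node$observed_outcome[r] <- "kept"
      if (!is.null(meas)) {
        mrow <- meas[meas$node_id == hit_id, ]
        if (nrow(mrow)) per_node$measured_sal_mm[r] <- mrow$sal_mm[1]
      }
    }
  }
  per_node$correct <- per_node$observed_outcome == per_node$expected_outcome
  per_node$sal_error_mm <- abs(per_node$measured_sal_mm - per_node$sal_mm)

  gt_comps <- connected_components(label_volume(
    array(as.integer(ph$gt_nodes$voxels != 0L), dim = shape),
    spacing = fused$spacing, axial_axis = fused$axial_axis))
  pr <- if (length(gt_comps) || length(filt$kept)) {
    precision_recall(match_components(filt$kept, gt_comps, shape))
  } else c(precision = NA_real_, recall = NA_real_)

  list(per_node = per_node, precision = unname(pr["precision"]),
       recall = unname(pr["recall"]), n_kept = length(filt$kept),
       measurements = meas)
}
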