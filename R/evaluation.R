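#' Match predicted components to ground-truth components
#'
#' Detection hit criterion: a predicted and a ground-truth component are
#' candidate partners when they share at least one voxel. Candidates are
#' resolved one-to-one greedily by descending voxel overlap, ties by
#' (predicted id, ground-truth id). An IoU threshold can additionally be
#' required per pair.
#'
#' @param pred,gt lists of components on the same grid.
#' @param shape integer(3) grid dimensions.
#' @param min_iou optional minimum intersection-over-union for a candidate
#'   pair (default 0 = any-voxel overlap).
#' @return List with `pairs` (data.frame `pred_id`, `gt_id`, `overlap`),
#'   `unmatched_pred` and `unmatched_gt` id vectors.
#' @export
match_components <- function(pred, gt, shape, min_iou = 0) {
  pid <- vapply(pred, function(c) c$id, integer(1))
  gid <- vapply(gt, function(c) c$id, integer(1))
  plin <- lapply(pred, function(c) linear_ids(c$indices, shape))
  glin <- lapply(gt, function(c) linear_ids(c$indices, shape))
  cand <- list()
  for (a in seq_along(pred)) for (b in seq_along(gt)) {
    ov <- length(intersect(plin[[a]], glin[[b]]))
    if (ov >= 1) {
      iou <- ov / (length(plin[[a]]) + length(glin[[b]]) - ov)
      if (iou >= min_iou)
        cand[[length(cand) + 1L]] <- c(pid[a], gid[b], ov)
    }
  }
  pairs <- data.frame(pred_id = integer(0), gt_id = integer(0), overlap = integer(0))
  if (length(cand)) {
    cm <- do.call(rbind, cand)
    cm <- cm[order(-cm[, 3], cm[, 1], cm[, 2]), , drop = FALSE]
    used_p <- integer(0); used_g <- integer(0)
    for (r in seq_len(nrow(cm))) {
      if (cm[r, 1] %in% used_p || cm[r, 2] %in% used_g) next
      pairs <- rbind(pairs, data.frame(pred_id = cm[r, 1], gt_id = cm[r, 2],
                                       overlap = cm[r, 3]))
      used_p <- c(used_p, cm[r, 1]); used_g <- c(used_g, cm[r, 2])
    }
  }
  list(pairs = pairs,
       unmatched_pred = setdiff(pid, pairs$pred_id),
       unmatched_gt = setdiff(gid, pairs$gt_id))
}

#' Detection precision and recall from a match result
#'
#' @param match result of [match_components()].
#' @return Named numeric: `precision` = TP / (TP + FP), `recall` =
#'   TP / (TP + FN); `NA` when the denominator is zero.
#' @export
precision_recall <- function(match) {
  tp <- nrow(match$pairs)
  fp <- length(match$unmatched_pred)
  fn <- length(match$unmatched_gt)
  c(precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
}

#' Dice overlap coefficient of two binary volumes
#'
#' `2|A intersect B| / (|A| + |B|)`; two empty masks score 1.0 by the
#' perfect-agreement convention (a message notes the convention).
#'
#' @param a,b binary [label_volume]s on the same grid.
#' @return Dice score in \[0, 1\].
#' @export
dice <- function(a, b) {
  stop_if_not_binary(a); stop_if_not_binary(b)
  stop_if_grid_mismatch(a, b)
  na <- sum(a$voxels); nb <- sum(b$voxels)
  if (na + nb == 0) {
    message("dice: both masks empty, returning 1 by convention")
    return(1)
  }
  2 * sum(a$voxels & b$voxels) / (na + nb)
}

surface_points_mm <- function(vol) {
  v <- vol$voxels != 0L
  d <- dim(v)
  shift <- function(ax, by) {
    out <- array(FALSE, dim = d)
    n <- d[ax]
    src <- seq_len(n) - by
    valid <- src >= 1 & src <= n
    idx_to <- which(valid); idx_from <- src[valid]
    if (ax == 1) out[idx_to, , ] <- v[idx_from, , ]
    else if (ax == 2) out[, idx_to, ] <- v[, idx_from, ]
    else out[, , idx_to] <- v[, , idx_from]
    out
  }
  covered <- shift(1, 1) & shift(1, -1) & shift(2, 1) & shift(2, -1) &
    shift(3, 1) & shift(3, -1)
  surf <- which(v & !covered)
  idx <- arrayInd(surf, d)
  sweep(sweep(idx - 1, 2, vol$spacing, `*`), 2, vol$origin, `+`)
}

#' Average symmetric surface distance between two binary masks
#'
#' Surface voxels are foreground voxels with at least one 6-neighbour
#' outside the mask (the volume border counts as outside). The directed
#' mean nearest-surface distance (mm) is computed in each direction and
#' the two means are averaged.
#'
#' @param a,b non-empty binary [label_volume]s on the same grid.
#' @return ASSD in mm; symmetric in its arguments.
#' @export
assd <- function(a, b) {
  stop_if_not_binary(a); stop_if_not_binary(b)
  stop_if_grid_mismatch(a, b)
  if (sum(a$voxels) == 0 || sum(b$voxels) == 0)
    stop("assd is undefined for empty masks", call. = FALSE)
  sa <- surface_points_mm(a)
  sb <- surface_points_mm(b)
  nn_mean <- function(p, q) {
    # chunked nearest-neighbour search to bound the distance-matrix size
    step <- max(1L, floor(2e6 / nrow(q)))
    mins <- numeric(nrow(p))
    for (s in seq(1, nrow(p), by = step)) {
      rows <- s:min(s + step - 1, nrow(p))
      d2 <- outer(p[rows, 1], q[, 1], `-`)^2 +
        outer(p[rows, 2], q[, 2], `-`)^2 +
        outer(p[rows, 3], q[, 3], `-`)^2
      mins[rows] <- sqrt(apply(d2, 1, min))
    }
    mean(mins)
  }
  (nn_mean(sa, sb) + nn_mean(sb, sa)) / 2
}

#' Classification confusion matrix and per-category agreement statistics
#'
#' Bins index-aligned SAL measurements of the same nodes by the two raters'
#' normal/enlarged classes, and computes per-bin means and standard
#' deviations of each rater's SAL and of the pairwise differences
#' (delta SAL, delta slice, delta angle).
#'
#' @param meas_a,meas_b lists of `sal_measurement` objects, index-aligned
#'   on the same nodes.
#' @return List with `confusion` (2 x 2 matrix, rater A in rows) and
#'   `stats` (data.frame per category: n, mean/sd of each rater's SAL and
#'   of the deltas).
#' @export
sal_agreement <- function(meas_a, meas_b) {
  if (length(meas_a) != length(meas_b))
    stop("measurement lists must be index-aligned (equal length)", call. = FALSE)
  cls <- c("normal", "enlarged")
  ca <- factor(vapply(meas_a, function(m) m$size_class, character(1)), levels = cls)
  cb <- factor(vapply(meas_b, function(m) m$size_class, character(1)), levels = cls)
  confusion <- table(rater_a = ca, rater_b = cb)
  deltas <- Map(delta_metrics, meas_a, meas_b)
  sal_a <- vapply(meas_a, function(m) m$sal_mm, numeric(1))
  sal_b <- vapply(meas_b, function(m) m$sal_mm, numeric(1))
  dsal <- vapply(deltas, `[[`, numeric(1), "dsal_mm")
  dslice <- vapply(deltas, `[[`, numeric(1), "dslice")
  dangle <- vapply(deltas, `[[`, numeric(1), "dangle_deg")
  rows <- list()
  for (la in cls) for (lb in cls) {
    sel <- ca == la & cb == lb
    rows[[length(rows) + 1L]] <- data.frame(
      class_a = la, class_b = lb, n = sum(sel),
      sal_a_mean = mean(sal_a[sel]), sal_a_sd = sd(sal_a[sel]),
      sal_b_mean = mean(sal_b[sel]), sal_b_sd = sd(sal_b[sel]),
      dsal_mean = mean(dsal[sel]), dsal_sd = sd(dsal[sel]),
      dslice_mean = mean(dslice[sel]), dslice_sd = sd(dslice[sel]),
      dangle_mean = mean(dangle[sel], na.rm = TRUE),
      dangle_sd = sd(dangle[sel], na.rm = TRUE),
      stringsAsFactors = FALSE)
  }
  list(confusion = unclass(confusion),
       stats = do.call(rbind, c(rows, list(make.row.names = FALSE))))
}

#' Percent classification agreement from a 2x2 confusion matrix
#'
#' @param cm 2x2 matrix of counts (rater A rows, rater B columns).
#' @return List with `percent` (diagonal share of the total, rounded to
#'   the nearest integer) and `n_agree` (the diagonal count).
#' @export
percent_agreement <- function(cm) {
  cm <- as.matrix(cm)
  if (!all(dim(cm) == c(2, 2))) stop("cm must be 2x2", call. = FALSE)
  if (any(cm < 0)) stop("counts must be non-negative", call. = FALSE)
  total <- sum(cm)
  if (total == 0) stop("total count must be positive", call. = FALSE)
  n_agree <- sum(diag(cm))
  list(percent = round(100 * n_agree / total), n_agree = n_agree)
}
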