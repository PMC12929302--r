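test_that("component matching is greedy one-to-one by descending overlap", {
  shape <- c(20, 20, 6)
  gt_vol <- box_volume(shape, xr = 2:4, yr = 2:4, zr = 2:3)
  gt_vol$voxels[10:12, 10:12, 2:3] <- 1L
  gt_vol$voxels[16:18, 16:18, 2:3] <- 1L
  gt <- connected_components(gt_vol)

  # perfect prediction: all matched, nothing unmatched
  m <- match_components(gt, gt, shape)
  expect_equal(nrow(m$pairs), 3)
  expect_length(m$unmatched_pred, 0)
  expect_length(m$unmatched_gt, 0)

  # 2 preds, one overlapping one of 2 gt: 1 pair, 1 unmatched on each side
  pred_vol <- box_volume(shape, xr = 3:5, yr = 2:4, zr = 2:3)   # hits gt 1
  pred_vol$voxels[16:18, 2:4, 5] <- 1L                          # hits nothing
  pred <- connected_components(pred_vol)
  m2 <- match_components(pred, gt[1:2], shape)
  expect_equal(nrow(m2$pairs), 1)
  expect_length(m2$unmatched_pred, 1)
  expect_length(m2$unmatched_gt, 1)

  # one pred overlapping two gt pairs with the larger overlap only
  wide <- connected_components(box_volume(shape, xr = 2:11, yr = 2:11, zr = 2:3))
  m3 <- match_components(wide, gt[1:2], shape)
  expect_equal(nrow(m3$pairs), 1)
  # gt 1 is fully covered (18 voxels) vs gt 2 partially (8): greedy picks gt 1
  expect_equal(m3$pairs$gt_id, gt[[1]]$id)
  expect_equal(m3$pairs$overlap, 18)

  # an IoU floor can reject weak hits
  m4 <- match_components(wide, gt[1:2], shape, min_iou = 0.5)
  expect_equal(nrow(m4$pairs), 0)
})

test_that("precision and recall follow the matched-pair counts", {
  mk <- function(tp, fp, fn) list(pairs = data.frame(pred_id = seq_len(tp)),
                                  unmatched_pred = seq_len(fp),
                                  unmatched_gt = seq_len(fn))
  expect_equal(precision_recall(mk(3, 0, 0)), c(precision = 1, recall = 1))
  expect_equal(precision_recall(mk(1, 1, 1)), c(precision = 0.5, recall = 0.5))
  pr <- precision_recall(mk(0, 0, 2))
  expect_true(is.na(pr["precision"]))
  expect_equal(unname(pr["recall"]), 0)
})

test_that("Dice is the voxel-overlap coefficient with the both-empty convention", {
  shape <- c(8, 8, 4)
  a <- box_volume(shape, xr = 2:3, yr = 2:3, zr = 2)   # 4 voxels
  expect_equal(dice(a, a), 1.0)
  b <- box_volume(shape, xr = 6:7, yr = 6:7, zr = 3)
  expect_equal(dice(a, b), 0.0)
  # |A| = |B| = 4, overlap 2
  c2 <- box_volume(shape, xr = 2:3, yr = 3:4, zr = 2)
  expect_equal(dice(a, c2), 0.5)
  expect_equal(dice(a, c2), dice(c2, a))
  expect_message(d <- dice(box_volume(shape), box_volume(shape)), "empty")
  expect_equal(d, 1.0)
  # removing voxels from a perfect match monotonically lowers Dice
  coords <- cbind(as.matrix(expand.grid(i = 2:3, j = 2:3)), 2)
  scores <- sapply(0:3, function(drop) {
    v <- a
    if (drop > 0) v$voxels[coords[seq_len(drop), , drop = FALSE]] <- 0L
    dice(a, v)
  })
  expect_true(all(diff(scores) < 0))
})

test_that("ASSD measures mean symmetric surface distance in mm", {
  shape <- c(6, 6, 9)
  a <- box_volume(shape, xr = 1:6, yr = 1:6, zr = 3)
  b <- box_volume(shape, xr = 1:6, yr = 1:6, zr = 6)  # 3 slices = 3 mm away
  expect_equal(assd(a, a), 0.0)
  expect_equal(assd(a, b), 3.0)
  expect_equal(assd(a, b), assd(b, a))
  # spacing scales physical distances
  a2 <- label_volume(a$voxels, spacing = c(1, 1, 2))
  b2 <- label_volume(b$voxels, spacing = c(1, 1, 2))
  expect_equal(assd(a2, b2), 6.0)
  expect_error(assd(a, box_volume(shape)), "empty")
})

test_that("SAL agreement bins nodes by the two raters' classes", {
  mk <- function(sal, slice = 5, angle = 0) {
    dir <- c(cos(angle * pi / 180), sin(angle * pi / 180))
    structure(list(sal_mm = sal, reference_slice = slice,
                   size_class = classify_node(sal),
                   short_axis = list(direction = dir, degenerate = FALSE)),
              class = "sal_measurement")
  }
  a <- list(mk(8), mk(12), mk(9), mk(11))
  b <- list(mk(7), mk(13), mk(11), mk(8))   # (n,n), (e,e), (n,e), (e,n)
  ag <- sal_agreement(a, b)
  expect_equal(as.vector(ag$confusion), c(1, 1, 1, 1))

  # identical lists: all mass on the diagonal, zero deltas
  ag2 <- sal_agreement(a, a)
  expect_equal(sum(diag(ag2$confusion)), 4)
  expect_equal(sum(ag2$confusion) - sum(diag(ag2$confusion)), 0)
  expect_true(all(ag2$stats$dsal_mean[ag2$stats$n > 0] == 0))

  # a 9 mm vs 11 mm node lands in (normal, enlarged) with delta-SAL 2
  ag3 <- sal_agreement(list(mk(9)), list(mk(11)))
  expect_equal(ag3$confusion["normal", "enlarged"], 1)
  row <- ag3$stats[ag3$stats$class_a == "normal" & ag3$stats$class_b == "enlarged", ]
  expect_equal(row$dsal_mean, 2)

  expect_error(sal_agreement(a, b[1:2]), "index-aligned")
})

test_that("simulated cohorts recover their per-bin delta-SAL means", {
  set.seed(5)
  mk <- function(sal, slice = 5, angle = 0) {
    structure(list(sal_mm = sal, reference_slice = slice,
                   size_class = classify_node(sal),
                   short_axis = list(direction = c(cos(angle), sin(angle)),
                                     degenerate = FALSE)),
              class = "sal_measurement")
  }
  n <- 400
  base <- runif(n, 4, 16)
  shift <- rnorm(n, mean = 1.2, sd = 0.4)
  a <- lapply(base, mk)
  b <- lapply(base + shift, mk)
  ag <- sal_agreement(a, b)
  expect_equal(sum(ag$confusion), n)
  pooled <- sum(ag$stats$dsal_mean * ag$stats$n, na.rm = TRUE) / n
  expect_equal(pooled, mean(abs(shift)), tolerance = 0.1)
})

test_that("percent agreement reproduces printed inter-observer percentages", {
  cm_rr <- matrix(c(371, 10, 18, 52), nrow = 2)   # rater rows: nn, en, ne, ee
  pa <- percent_agreement(cm_rr)
  expect_equal(pa$percent, 94)
  expect_equal(pa$n_agree, 423)
  pa_r1 <- percent_agreement(matrix(c(368, 9, 21, 53), nrow = 2))
  expect_equal(pa_r1$percent, 93)
  expect_equal(pa_r1$n_agree, 421)
  pa_r2 <- percent_agreement(matrix(c(361, 16, 20, 54), nrow = 2))
  expect_equal(pa_r2$percent, 92)
  expect_equal(percent_agreement(matrix(c(5, 0, 0, 7), 2))$percent, 100)
  expect_error(percent_agreement(matrix(0, 2, 2)), "positive")
})
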