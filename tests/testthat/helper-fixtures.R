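# Fixture builders and independent oracles used across the test files.

# rasterise an axis-aligned ellipsoid into a fresh volume (independent of
# the package's internal rasteriser: plain expand.grid membership test)
ellipsoid_volume <- function(center, semi, shape, spacing) {
  g <- expand.grid(i = seq_len(shape[1]), j = seq_len(shape[2]),
                   k = seq_len(shape[3]))
  x <- (g$i - 1) * spacing[1]
  y <- (g$j - 1) * spacing[2]
  z <- (g$k - 1) * spacing[3]
  inside <- ((x - center[1]) / semi[1])^2 + ((y - center[2]) / semi[2])^2 +
    ((z - center[3]) / semi[3])^2 <= 1
  arr <- array(0L, dim = shape)
  arr[as.matrix(g)[inside, , drop = FALSE]] <- 1L
  label_volume(arr, spacing = spacing)
}

box_volume <- function(shape, spacing = c(1, 1, 1), xr = NULL, yr = NULL, zr = NULL) {
  arr <- array(0L, dim = shape)
  if (!is.null(xr)) arr[xr, yr, zr] <- 1L
  label_volume(arr, spacing = spacing)
}

voxel_volume <- function(shape, idx, spacing = c(1, 1, 1)) {
  arr <- array(0L, dim = shape)
  arr[matrix(idx, ncol = 3)] <- 1L
  label_volume(arr, spacing = spacing)
}

# a tiny box-lung atlas on a 20 x 20 x 5 grid: lungs on slices 2:4 (left)
# and 2:3 (right), so slice 4 has only one lung
tiny_atlas <- function() {
  shape <- c(20L, 20L, 5L)
  ll <- box_volume(shape, xr = 2:5, yr = 5:15, zr = 2:4)
  lr <- box_volume(shape, xr = 14:17, yr = 5:15, zr = 2:3)
  empty <- box_volume(shape)
  structures <- c(list(lung_left = ll, lung_right = lr),
                  stats::setNames(rep(list(empty), 17),
                                  mediastinal_structures()))
  structures$lungs <- NULL # let the constructor derive it
  anatomy_atlas(structures)
}

# --- brute-force caliper oracles: all-pairs evaluation of the two argmax
# --- definitions, with the same canonical tie-break as the package
canonical_pair <- function(pts, ia, ib) {
  a <- pts[ia, , drop = FALSE]; b <- pts[ib, , drop = FALSE]
  swap <- (a[, 1] > b[, 1]) | (a[, 1] == b[, 1] & a[, 2] > b[, 2])
  p1 <- a; p1[swap, ] <- b[swap, , drop = FALSE]
  p2 <- b; p2[swap, ] <- a[swap, , drop = FALSE]
  ord <- order(p1[, 1], p1[, 2], p2[, 1], p2[, 2])[1]
  rbind(p1[ord, ], p2[ord, ])
}

oracle_long_axis <- function(pts) {
  n <- nrow(pts)
  best <- -1; ias <- integer(0); ibs <- integer(0)
  for (a in seq_len(n - 1)) {
    b <- (a + 1):n
    dx <- pts[a, 1] - pts[b, 1]
    dy <- pts[a, 2] - pts[b, 2]
    d2 <- dx * dx + dy * dy
    m <- max(d2)
    if (m > best) { best <- m; ias <- rep(a, sum(d2 == m)); ibs <- b[d2 == m] }
    else if (m == best) { ias <- c(ias, rep(a, sum(d2 == m))); ibs <- c(ibs, b[d2 == m]) }
  }
  ep <- canonical_pair(pts, ias, ibs)
  len <- sqrt(sum((ep[1, ] - ep[2, ])^2))
  list(endpoints = ep, length = len, direction = (ep[1, ] - ep[2, ]) / len)
}

oracle_short_axis <- function(pts, u, angle_tol_deg = 3) {
  n <- nrow(pts)
  tol <- angle_tol_deg
  repeat {
    s <- sin(tol * pi / 180)
    best <- -1; ias <- integer(0); ibs <- integer(0)
    for (a in seq_len(n - 1)) {
      b <- (a + 1):n
      dx <- pts[a, 1] - pts[b, 1]
      dy <- pts[a, 2] - pts[b, 2]
      d2 <- dx * dx + dy * dy
      dot <- dx * u[1] + dy * u[2]
      ok <- dot * dot <= d2 * (s * s)
      if (!any(ok)) next
      m <- max(d2[ok])
      hit <- ok & d2 == m
      if (m > best) { best <- m; ias <- rep(a, sum(hit)); ibs <- b[hit] }
      else if (m == best) { ias <- c(ias, rep(a, sum(hit))); ibs <- c(ibs, b[hit]) }
    }
    if (best >= 0) {
      ep <- canonical_pair(pts, ias, ibs)
      return(list(endpoints = ep, length = sqrt(best), degenerate = FALSE))
    }
    if (tol >= 45) return(list(length = 0, degenerate = TRUE))
    tol <- min(tol * 2, 45)
  }
}

# random distinct lattice contour (lattice points force distance ties, a
# stress test for the deterministic tie-break)
random_contour <- function(n, scale = 0.5) {
  w <- max(4L, ceiling(sqrt(n * 3)))
  cells <- sample.int(w * w, n)
  pts <- cbind(((cells - 1) %% w) * scale, ((cells - 1) %/% w) * scale)
  structure(list(points = pts, slice_index = 1L), class = "contour2d")
}
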