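make_contour <- function(pts, slice = 1L) {
  structure(list(points = pts, slice_index = as.integer(slice)),
            class = "contour2d")
}

test_that("axial cross-sections split a component by slice and 2D connectivity", {
  shape <- c(10, 10, 6)
  # vertical 3-slice column
  col <- connected_components(voxel_volume(shape, cbind(4, 4, 2:4)))[[1]]
  cs <- axial_cross_sections(col, shape)
  expect_length(cs, 3)
  expect_equal(names(cs), c("2", "3", "4"))
  expect_length(cs[["3"]], 1)
  expect_equal(nrow(cs[["3"]][[1]]), 1)

  # U-shape: middle slice has two disconnected arms
  idx <- rbind(cbind(2, 2:6, 2),          # bottom bar on slice 2
               cbind(2, 2, 3), cbind(2, 6, 3),  # two arms on slice 3
               cbind(2, 2, 4), cbind(2, 6, 4))
  u <- connected_components(voxel_volume(shape, idx))[[1]]
  cs_u <- axial_cross_sections(u, shape)
  expect_length(cs_u[["2"]], 1)
  expect_length(cs_u[["3"]], 2)
  expect_length(cs_u[["4"]], 2)
})

test_that("contour extraction keeps voxels with an exposed 4-neighbour", {
  # single voxel: the contour is its own center
  ct1 <- boundary_points(cbind(3L, 3L), spacing = c(1, 1))
  expect_equal(nrow(ct1$points), 1)

  # 3x3 solid square: 8 boundary points, center excluded
  sq <- as.matrix(expand.grid(i = 2:4, j = 2:4))
  ct <- boundary_points(sq, spacing = c(1, 1))
  expect_equal(nrow(ct$points), 8)
  expect_false(any(ct$points[, 1] == 2 & ct$points[, 2] == 2)) # center (3,3) -> mm (2,2)

  # 2x2 square: no interior, all 4 points on the contour
  sq2 <- as.matrix(expand.grid(i = 1:2, j = 1:2))
  expect_equal(nrow(boundary_points(sq2, c(1, 1))$points), 4)

  # in-plane spacing scales the points to mm
  ct_sp <- boundary_points(cbind(c(1L, 2L), c(1L, 1L)), spacing = c(0.5, 2))
  expect_equal(sort(ct_sp$points[, 1]), c(0, 0.5))
})

test_that("long axis maximises pairwise distance with a deterministic tie-break", {
  # two points 5 mm apart
  la <- long_axis(make_contour(rbind(c(0, 0), c(5, 0))))
  expect_equal(la$length, 5)

  # unit square: both diagonals tie at sqrt(2); lexicographically smallest pair wins
  sq <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  la_sq <- long_axis(make_contour(sq))
  expect_equal(la_sq$length, sqrt(2))
  expect_equal(la_sq$endpoints, rbind(c(0, 0), c(1, 1)))

  # digitized disc of radius 10 mm at 0.5 mm pixels: diameter within a pixel diagonal
  g <- as.matrix(expand.grid(i = 1:45, j = 1:45))
  mm <- (g - 23) * 0.5
  disc <- g[rowSums(mm^2) <= 100, , drop = FALSE]
  ct <- boundary_points(disc, spacing = c(0.5, 0.5))
  la_d <- long_axis(ct)
  expect_lt(abs(la_d$length - 20), sqrt(2) * 0.5)

  # single point: degenerate, zero length
  expect_equal(long_axis(make_contour(rbind(c(1, 1))))$length, 0)
})

test_that("short axis is the longest near-perpendicular chord", {
  # diamond: long axis 10 mm along x, short axis 6 mm along y (exactly perpendicular)
  dia <- rbind(c(-5, 0), c(5, 0), c(0, -3), c(0, 3))
  ct <- make_contour(dia)
  la <- long_axis(ct)
  expect_equal(la$length, 10)
  sa <- short_axis(ct, la)
  expect_equal(sa$length, 6)
  expect_equal(sa$endpoints, rbind(c(0, -3), c(0, 3)))
  expect_false(sa$degenerate)
  expect_lte(sa$length, la$length)

  # axis-aligned digitized ellipse semi-axes 10 x 4 mm, 0.5 mm pixels: SAL ~ 8
  g <- as.matrix(expand.grid(i = 1:45, j = 1:21))
  x <- (g[, 1] - 23) * 0.5; y <- (g[, 2] - 11) * 0.5
  ell <- g[(x / 10)^2 + (y / 4)^2 <= 1, , drop = FALSE]
  ct_e <- boundary_points(ell, spacing = c(0.5, 0.5))
  la_e <- long_axis(ct_e)
  sa_e <- short_axis(ct_e, la_e)
  expect_lt(abs(sa_e$length - 8), sqrt(2) * 0.5)

  # two collinear points: no perpendicular chord even at 45 degrees -> degenerate
  sa_col <- short_axis(make_contour(rbind(c(0, 0), c(3, 0))),
                       long_axis(make_contour(rbind(c(0, 0), c(3, 0)))))
  expect_true(sa_col$degenerate)
  expect_equal(sa_col$length, 0)
})

test_that("caliper lengths are translation-, rotation- and scale-equivariant", {
  set.seed(21)
  for (rep in 1:20) {
    ct <- random_contour(sample(5:60, 1))
    la <- long_axis(ct); sa <- short_axis(ct, la)

    shifted <- make_contour(sweep(ct$points, 2, c(13.7, -4.2), `+`))
    la_s <- long_axis(shifted)
    expect_equal(la_s$length, la$length)
    expect_equal(short_axis(shifted, la_s)$length, sa$length)

    rot <- make_contour(cbind(-ct$points[, 2], ct$points[, 1])) # exact 90 degrees
    la_r <- long_axis(rot)
    expect_equal(la_r$length, la$length)
    expect_equal(short_axis(rot, la_r)$length, sa$length)

    scaled <- make_contour(ct$points * 3)
    la_c <- long_axis(scaled)
    expect_equal(la_c$length, 3 * la$length)
    expect_equal(short_axis(scaled, la_c)$length, 3 * sa$length)

    # SAL never exceeds the diameter
    expect_lte(sa$length, la$length)
  }
})

test_that("node measurement picks the widest-SAL slice and classifies at 10 mm", {
  # single voxel node
  shape <- c(8, 8, 4)
  v1 <- connected_components(voxel_volume(shape, c(3, 3, 2)))[[1]]
  m1 <- measure_node(v1, shape, c(1, 1, 1))
  expect_equal(m1$sal_mm, 0)
  expect_equal(m1$size_class, "normal")

  # axis-aligned ellipsoid (6, 4, 3) mm: equatorial slice, SAL ~ 8 mm
  sp <- c(0.7, 0.7, 1)
  ell <- ellipsoid_volume(c(14, 14, 10), c(6, 4, 3), c(40, 40, 20), sp)
  comp <- connected_components(ell)[[1]]
  m <- measure_node(comp, dim(ell$voxels), sp)
  diag_px <- sqrt(sum(sp[1:2]^2))
  expect_lt(abs(m$sal_mm - 8), diag_px)
  expect_equal(m$reference_slice, 11)  # z = 10 mm at 1 mm slices, 1-based
  expect_equal(m$size_class, "normal")
  expect_lte(m$sal_mm, m$long_axis$length)

  # doubling the node doubles the SAL and flips the class to enlarged
  ell2 <- ellipsoid_volume(c(17.5, 17.5, 14), c(12, 8, 6), c(56, 56, 30), sp)
  m2 <- measure_node(connected_components(ell2)[[1]], dim(ell2$voxels), sp)
  expect_lt(abs(m2$sal_mm - 16), diag_px)
  expect_equal(m2$size_class, "enlarged")
})

test_that("classification applies the inclusive 10 mm enlargement rule", {
  expect_equal(classify_node(9.9), "normal")
  expect_equal(classify_node(10.0), "enlarged")
  expect_equal(classify_node(0.0), "normal")
  expect_error(classify_node(-1), "non-negative")
})

test_that("delta metrics fold the axis angle to [0, 90] degrees", {
  mk <- function(sal, slice, angle_deg) {
    dir <- c(cos(angle_deg * pi / 180), sin(angle_deg * pi / 180))
    structure(list(sal_mm = sal, reference_slice = slice,
                   short_axis = list(direction = dir, degenerate = FALSE)),
              class = "sal_measurement")
  }
  d0 <- delta_metrics(mk(8, 5, 30), mk(8, 5, 30))
  expect_equal(unlist(d0), c(dsal_mm = 0, dslice = 0, dangle_deg = 0))

  expect_equal(delta_metrics(mk(8, 5, 0), mk(8, 5, 90))$dangle_deg, 90)
  expect_equal(delta_metrics(mk(8, 5, 10), mk(8, 5, 170))$dangle_deg, 20,
               tolerance = 1e-8)
  d <- delta_metrics(mk(9, 4, 0), mk(11, 7, 45))
  expect_equal(d$dsal_mm, 2)
  expect_equal(d$dslice, 3)
  expect_equal(d$dangle_deg, 45)

  degen <- structure(list(sal_mm = 0, reference_slice = 1,
                          short_axis = list(direction = c(NA, NA), degenerate = TRUE)),
                     class = "sal_measurement")
  expect_true(is.na(delta_metrics(mk(8, 5, 0), degen)$dangle_deg))
})

test_that("optimized caliper routines agree exactly with the all-pairs oracle", {
  set.seed(99)
  for (rep in 1:60) {
    ct <- random_contour(sample(3:80, 1))
    la <- long_axis(ct)
    or_la <- oracle_long_axis(ct$points)
    expect_identical(la$endpoints, or_la$endpoints)
    expect_identical(la$length, or_la$length)
    sa <- short_axis(ct, la)
    or_sa <- oracle_short_axis(ct$points, la$direction)
    expect_identical(sa$degenerate, or_sa$degenerate)
    if (!sa$degenerate) {
      expect_identical(sa$endpoints, or_sa$endpoints)
      expect_identical(sa$length, or_sa$length)
    }
  }
})
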