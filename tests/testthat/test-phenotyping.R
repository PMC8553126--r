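test_that("contour extraction recovers a rendered circle within half a pixel", {
  r <- render_leaf(leaf_shape_params("circle", a = 50))
  ct <- extract_contour(r)
  ctr <- r$origin_px / r$pixels_per_mm
  d <- sqrt((ct$x - ctr[1])^2 + (ct$y - ctr[2])^2)
  expect_lt(max(abs(d - 50)) * r$pixels_per_mm, 0.5)
})

test_that("largest component wins and empty images error", {
  img <- matrix(0L, 80, 80)
  img[10:40, 10:40] <- 1L   # ~960 px blob
  img[60:62, 60:62] <- 1L   # 9 px blob
  ct <- extract_contour(img, pixels_per_mm = 1)
  expect_true(all(ct$x < 45))
  expect_error(extract_contour(matrix(0L, 10, 10)), "no leaf found")
})

test_that("component touching the border is flagged", {
  img <- matrix(0L, 30, 30)
  img[1:15, 5:25] <- 1L
  expect_warning(ct <- extract_contour(img, pixels_per_mm = 1), "border")
  expect_true("border_touch" %in% attr(ct, "flags"))
})

test_that("orientation normalization recovers a known tilt", {
  p <- leaf_shape_params("ellipse", a = 60, b = 40)
  poly <- leafgwas:::shape_polygon(p, 2000)
  th <- 30 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  nc <- normalize_orientation(leaf_contour(poly %*% t(R)))
  ax <- eigen(leafgwas:::poly_covariance(leafgwas:::contour_matrix(nc)))$vectors[, 1]
  angle_off <- acos(abs(ax[2])) * 180 / pi
  expect_lt(angle_off, 1)
  expect_lt(sqrt(sum(contour_centroid(nc)^2)), 1e-8)
})

test_that("normalization is idempotent and warns on near-circular outlines", {
  nc <- normalize_orientation(ellipse_contour(normalized = FALSE))
  nc2 <- normalize_orientation(nc)
  expect_equal(leafgwas:::contour_matrix(nc2), leafgwas:::contour_matrix(nc),
               tolerance = 1e-10)
  circ <- ellipse_contour(a = 50, b = 50, normalized = FALSE)
  expect_warning(nn <- normalize_orientation(circ), "ambiguous")
  expect_true("axis_ambiguous" %in% attr(nn, "flags"))
})

test_that("centroid is the area centroid, not the vertex mean", {
  tri <- leaf_contour(cbind(c(0, 3, 0), c(0, 0, 3)))
  expect_equal(unname(contour_centroid(tri)), c(1, 1))
  # circle centered off-origin
  th <- seq(-pi, pi, length.out = 101)[-101]
  circ <- leaf_contour(cbind(10 + 20 * cos(th), -5 + 20 * sin(th)))
  expect_equal(unname(contour_centroid(circ)), c(10, -5), tolerance = 1e-6)
  # resampling invariance: dense vs sparse, uneven vertex spacing
  th2 <- sort(runif(60, -pi, pi))
  sparse <- leaf_contour(cbind(10 + 20 * cos(th2), -5 + 20 * sin(th2)))
  expect_equal(contour_centroid(sparse), contour_centroid(circ),
               tolerance = 0.1)
  expect_error(contour_centroid(leaf_contour(cbind(c(0, 1, 2), c(0, 1, 2) * 2))),
               "zero area")
})

test_that("radial profile matches closed forms", {
  circ <- ellipse_contour(a = 50, b = 50)
  pr <- radial_profile(circ, 360)
  expect_equal(pr$radius, rep(50, 360), tolerance = 1e-4)
  expect_equal(pr$angle[1], -pi)
  expect_equal(diff(pr$angle)[1], 2 * pi / 360)

  ell <- ellipse_contour(a = 60, b = 40)
  pr <- radial_profile(ell, 360)
  truth <- 60 * 40 / sqrt(60^2 * cos(pr$angle)^2 + 40^2 * sin(pr$angle)^2)
  expect_lt(max(abs(pr$radius - truth) / truth), 0.005)

  sq <- leaf_contour(cbind(c(.5, .5, -.5, -.5), c(-.5, .5, .5, -.5)),
                     normalized = TRUE)
  expect_equal(radial_profile(sq, 4)$radius, rep(0.5, 4))
})

test_that("rays are measured to the farthest crossing on lobed outlines", {
  # U-shaped outline with a shallow notch: tilted rays from the centroid
  # cross the notch floor, a notch wall, and the top face (3 crossings)
  u <- rbind(c(-50, 0), c(50, 0), c(50, 60), c(10, 60), c(10, 35),
             c(-10, 35), c(-10, 60), c(-50, 60))
  ctr <- leafgwas:::poly_centroid(u)
  ct <- leaf_contour(sweep(u, 2, ctr), normalized = TRUE)
  pr <- radial_profile(ct, 360)
  expect_true("non_star_convex" %in% attr(pr, "flags"))
  expect_true(all(pr$radius > 0))
  # farthest-intersection rule: a ray through a notch shoulder reaches the
  # top face (y = 60), beyond the notch floor (y = 35)
  shoulder <- atan2(60 - ctr[2], 11)
  j <- which.min(abs(pr$angle - shoulder))
  expect_gt(pr$radius[j] * sin(pr$angle[j]) + ctr[2], 50)
})

test_that("classic traits match rectangle and ellipse closed forms", {
  tr <- classic_traits(rect_contour(120, 80))
  expect_equal(tr$L, 120)
  expect_equal(tr$W, 80)
  expect_equal(tr$W13, 80)
  expect_equal(tr$W12, 80)
  expect_equal(tr$W23, 80)
  expect_equal(tr$A, 9600)
  expect_equal(tr$LW, 1.5)

  tr <- classic_traits(ellipse_contour(60, 40, n = 4000))
  expect_equal(tr$L, 120, tolerance = 1e-4)
  expect_equal(tr$W, 80, tolerance = 1e-4)
  expect_equal(tr$W12, 80, tolerance = 1e-4)
  expect_equal(tr$W13, 2 * 40 * sqrt(1 - (1 / 3)^2), tolerance = 1e-4)
  expect_equal(tr$W23, tr$W13, tolerance = 1e-4)
  expect_equal(tr$A, pi * 60 * 40, tolerance = 1e-4)
  expect_error(classic_traits(ellipse_contour(normalized = FALSE)),
               "normalized")
})

test_that("W is never smaller than any fractional width", {
  for (s in 1:5) {
    p <- random_leaf_params(1, seed = s)[[1]]
    tr <- leafgwas:::truth_traits(p, leafgwas:::shape_polygon(p))
    expect_gte(tr$W + 1e-9, max(tr$W13, tr$W12, tr$W23))
  }
})

test_that("reduced radius sets use the exact angle grids", {
  circ <- ellipse_contour(50, 50)
  pr <- radial_profile(circ, 360)
  r11 <- reduce_radii(pr, 11)
  expect_equal(r11$angle, seq(-pi / 2, pi / 2, by = pi / 10))
  expect_equal(r11$radius, rep(50, 11), tolerance = 1e-4)
  expect_equal(attr(r11, "kind"), "RD11")
  r61 <- reduce_radii(pr, 61)
  expect_equal(diff(r61$angle)[1] * 180 / pi, 3)
  r9 <- reduce_radii(pr, 9)
  expect_equal(diff(r9$angle)[1] * 180 / pi, 22.5)
  expect_error(reduce_radii(pr, 7), "must be one of")

  # interpolation at exact angles, not nearest 1-degree grid point
  ell <- ellipse_contour(60, 40, n = 8000)
  r9e <- reduce_radii(radial_profile(ell, 360), 9)
  truth <- 60 * 40 / sqrt(60^2 * cos(r9e$angle)^2 + 40^2 * sin(r9e$angle)^2)
  expect_lt(max(abs(r9e$radius - truth) / truth), 0.002)
})

test_that("traits are scale-equivariant and rotation-invariant", {
  p1 <- leaf_shape_params("parametric-leaf", a = 50, b = 35, taper_tip = 0.3,
                          taper_base = 0.1, pixels_per_mm = 8)
  m1 <- measure_leaf(render_leaf(p1), pixels_per_mm = 8, radii = "RD11")

  # scale: same leaf at double resolution
  p2 <- leaf_shape_params("parametric-leaf", a = 50, b = 35, taper_tip = 0.3,
                          taper_base = 0.1, pixels_per_mm = 16)
  m2 <- measure_leaf(render_leaf(p2), pixels_per_mm = 16, radii = "RD11")
  expect_equal(m1$traits$L, m2$traits$L, tolerance = 0.01)
  expect_equal(m1$traits$W, m2$traits$W, tolerance = 0.01)
  expect_equal(m1$traits$A, m2$traits$A, tolerance = 0.01)

  # rotation: rotate the analytic outline, re-rasterize, re-measure
  poly <- leafgwas:::shape_polygon(leaf_shape_params(
    "parametric-leaf", a = 50, b = 35, taper_tip = 0.3, taper_base = 0.1))
  th <- 25 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  rot <- poly %*% t(R)
  ppmm <- 8
  xr <- range(rot[, 1]); yr <- range(rot[, 2])
  nx <- ceiling(diff(xr) * ppmm) + 8; ny <- ceiling(diff(yr) * ppmm) + 8
  px <- xr[1] + ((seq_len(nx)) - 4.5) / ppmm
  py <- yr[1] + ((seq_len(ny)) - 4.5) / ppmm
  ctr0 <- leafgwas:::poly_centroid(rot)
  ang <- atan2(outer(rep(1, nx), py - ctr0[2]),
               outer(px - ctr0[1], rep(1, ny)))
  # inside test via ray radii of the rotated polygon
  shifted <- sweep(rot, 2, ctr0)
  rad <- leafgwas:::poly_radii(shifted, as.vector(ang))$radius
  dist <- sqrt(outer((px - ctr0[1])^2, rep(1, ny)) +
                 outer(rep(1, nx), (py - ctr0[2])^2))
  img <- matrix(as.integer(as.vector(dist) <= rad), nx, ny)
  m3 <- measure_leaf(img, pixels_per_mm = ppmm, radii = "RD11")
  expect_equal(m3$traits$L, m1$traits$L, tolerance = 0.01)
  expect_equal(m3$traits$W, m1$traits$W, tolerance = 0.01)
  expect_equal(m3$traits$A, m1$traits$A, tolerance = 0.01)
})

test_that("bilateral symmetry: right-side radii mirror the left side", {
  r <- render_leaf(leaf_shape_params("parametric-leaf", a = 50, b = 35,
                                     taper_tip = 0.3, taper_base = 0.1))
  pr <- measure_leaf(r, radii = "RD360")$radii$RD360
  ang <- pr$angle
  for (th in c(0.3, 0.8, 1.2)) {
    r_right <- pr$radius[which.min(abs(ang - th))]
    r_left <- pr$radius[which.min(abs(ang - (pi - th)))]
    expect_equal(r_right, r_left, tolerance = 0.01)
  }
})
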