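test_that("centerline resampling is arc-length uniform with orthonormal, twist-minimal frames", {
  # straight segment: 11 samples, all tangents +z
  cl <- resample_centerline(rbind(c(0, 0, 0), c(0, 0, 10)), spacing = 1)
  expect_equal(nrow(cl$samples), 11L)
  expect_equal(cl$frames$t, matrix(rep(c(0, 0, 1), each = 11), 11), tolerance = 1e-9)

  # planar quarter circle of radius 10, densely sampled input
  t <- seq(0, pi / 2, length.out = 400)
  pts <- cbind(10 * cos(t), 10 * sin(t), 0)
  cl <- resample_centerline(pts, spacing = 0.5)
  seg <- sqrt(rowSums(diff(cl$samples)^2))
  # uniform to within the polyline-linearization error of the input
  expect_true(all(abs(seg - 0.5) < 1e-3))
  expect_lt(diff(range(seg)), 1e-4)
  # tangent turns by the traversed arc angle (analytic circle); compare
  # interior samples where the tangent is a central difference
  n <- nrow(cl$samples)
  ang <- acos(min(1, abs(sum(cl$frames$t[2, ] * cl$frames$t[n - 1, ]))))
  expect_lt(abs(ang - (cl$s[n - 1] - cl$s[2]) / 10) * 180 / pi, 1)

  # frame invariants: right-handed orthonormal, t tangent, minimal twist
  for (i in seq_len(nrow(cl$samples))) {
    fr <- cbind(cl$frames$t[i, ], cl$frames$u[i, ], cl$frames$v[i, ])
    expect_equal(crossprod(fr), diag(3), tolerance = 1e-9)
    expect_gt(det(fr), 0)
  }
  du <- rowSums(cl$frames$u[-1, ] * cl$frames$u[-nrow(cl$samples), ])
  expect_true(all(acos(pmin(1, du)) < 15 * pi / 180))

  # degenerate input
  expect_error(resample_centerline(rbind(c(1, 2, 3), c(1, 2, 3)), 1),
               class = "invalid_centerline_error")
})

test_that("surface radial map recovers analytic tube radii", {
  cl <- resample_centerline(straight_centerline(), spacing = 0.5)
  cl <- aorticroot:::trim_centerline(cl, 2, 38)

  cyl <- make_tube_mesh(function(th, z) rep(12, length(th)))
  m <- surface_radial_map(cyl, cl, n_angles = 96)
  expect_true(all(abs(m$values - 12) < 0.1))

  # centerline offset 2 mm in +u: r(theta) follows the offset-circle solution
  cl_off <- resample_centerline(cbind(2, 0, seq(0, 40)), spacing = 0.5)
  cl_off <- aorticroot:::trim_centerline(cl_off, 2, 38)
  m2 <- surface_radial_map(cyl, cl_off, n_angles = 96)
  th <- m2$angle_centers
  # ray from (2,0) along (cos th, sin th) meets x^2+y^2=144:
  r_exp <- -2 * cos(th) + sqrt(4 * cos(th)^2 + 140)
  err <- sweep(m2$values, 2, r_exp)
  expect_lt(max(abs(err)), 0.1)
  expect_equal(which.max(m2$values[40, ]), which.min(abs(th - pi)))
  expect_equal(which.min(m2$values[40, ]), 1L)

  # trefoil tube: recovered profile matches the generating radius function
  tre <- make_tube_mesh(function(th, z) 10 + 1.5 * cos(3 * th))
  m3 <- surface_radial_map(tre, cl, n_angles = 96)
  r_exp3 <- 10 + 1.5 * cos(3 * m3$angle_centers)
  expect_lt(max(abs(sweep(m3$values, 2, r_exp3))), 0.1)
})

test_that("radial map flags non-star-shaped slices and inpaints isolated misses", {
  # a half-open shell: rays on the open side miss -> error names the slice
  zs <- seq(0, 40, 0.5); nth <- 64L
  th <- 2 * pi * (seq_len(nth) - 1L) / nth
  keep <- th < pi
  ns <- length(zs)
  zz <- rep(zs, times = sum(keep)); tt <- rep(th[keep], each = ns)
  V <- cbind(10 * cos(tt), 10 * sin(tt), zz)
  nk <- sum(keep)
  vid <- function(i, j) (j - 1L) * ns + i
  i <- rep(seq_len(ns - 1L), times = nk - 1L)
  j <- rep(seq_len(nk - 1L), each = ns - 1L)
  half <- surface_mesh(V, rbind(cbind(vid(i, j), vid(i + 1L, j), vid(i + 1L, j + 1L)),
                                cbind(vid(i, j), vid(i + 1L, j + 1L), vid(i, j + 1L))))
  cl <- resample_centerline(straight_centerline(), spacing = 0.5)
  cl <- aorticroot:::trim_centerline(cl, 2, 38)
  expect_error(surface_radial_map(half, cl, n_angles = 96),
               class = "non_star_shaped_slice_error")
})

test_that("three-point plane, circumcircle, distances and angles match analytic cases", {
  pl <- fit_plane(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_equal(abs(pl$normal), c(0, 0, 1), tolerance = 1e-12)
  expect_equal(point_plane_distance(pl, c(5, 7, 0)), 0, tolerance = 1e-12)

  pl5 <- fit_plane(c(0, 0, 5), c(3, 1, 5), c(-2, 4, 5))
  expect_equal(abs(pl5$normal[3]), 1, tolerance = 1e-12)
  expect_equal(abs(point_plane_distance(pl5, c(1, 1, 5))), 0, tolerance = 1e-9)

  expect_error(fit_plane(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
               class = "degenerate_plane_error")

  cc <- circumcircle_3d(c(1, 0, 0), c(0, 1, 0), c(-1, 0, 0))
  expect_equal(cc$center, c(0, 0, 0), tolerance = 1e-9)
  expect_equal(cc$radius, 1, tolerance = 1e-9)

  cc2 <- circumcircle_3d(c(0, 0, 0), c(2, 0, 0), c(1, 1, 0))
  expect_equal(cc2$center, c(1, 0, 0), tolerance = 1e-9)
  expect_equal(cc2$radius, 1, tolerance = 1e-9)

  pl0 <- fit_plane(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), orient = c(0, 0, 1))
  expect_equal(point_plane_distance(pl0, c(3, 4, 5)), 5, tolerance = 1e-12)
  expect_equal(point_plane_distance(pl0, c(0, 0, -2)), -2, tolerance = 1e-12)

  expect_equal(plane_angle(pl0, pl0), 0, tolerance = 1e-12)
  plx <- fit_plane(c(0, 0, 0), c(0, 1, 0), c(0, 0, 1))
  expect_equal(plane_angle(pl0, plx), 90, tolerance = 1e-9)
  pl45 <- structure(list(point = c(0, 0, 0),
                         normal = c(0, 1, 1) / sqrt(2)), class = "plane")
  expect_equal(plane_angle(pl0, pl45), 45, tolerance = 1e-9)
})

test_that("circumcircle agrees with a least-squares circle fit and is rigid-invariant", {
  set.seed(7)
  for (k in 1:20) {
    p <- matrix(rnorm(9, sd = 8), 3)
    if (norm3(cross3(p[2, ] - p[1, ], p[3, ] - p[1, ])) < 1e-3) next
    cc <- circumcircle_3d(p[1, ], p[2, ], p[3, ])
    # center equidistant from all three points
    d <- apply(p, 1, function(q) norm3(q - cc$center))
    expect_lt(max(abs(d - cc$radius)), 1e-9)
    # brute-force least-squares circle on 3 points: minimize sum over the
    # in-plane center coordinates (closed form = the linear system)
    pl <- cc$plane
    e1 <- normalize3(p[2, ] - p[1, ])
    e2 <- normalize3(cross3(pl$normal, e1))
    q <- sweep(p, 2, p[1, ]) %*% cbind(e1, e2)
    A <- cbind(2 * q[, 1], 2 * q[, 2], 1)
    b <- q[, 1]^2 + q[, 2]^2
    sol <- solve(crossprod(A), crossprod(A, b))
    ls_center <- p[1, ] + sol[1] * e1 + sol[2] * e2
    expect_lt(norm3(ls_center - cc$center), 1e-9)
    # rigid motion leaves the radius unchanged
    tr <- random_rigid(k)
    pt <- apply_rigid(tr, p)
    cct <- circumcircle_3d(pt[1, ], pt[2, ], pt[3, ])
    expect_lt(abs(cct$radius - cc$radius), 1e-9)
    expect_lt(norm3(cct$center - as.numeric(tr$R %*% cc$center + tr$t)), 1e-9)
  }
})

test_that("radial map outputs are equivariant under rigid motion of mesh and centerline", {
  cl_pts <- straight_centerline()
  tre <- make_tube_mesh(function(th, z) 10 + 1.5 * cos(3 * th))
  cl <- resample_centerline(cl_pts, 0.5)
  cl <- aorticroot:::trim_centerline(cl, 2, 38)
  m <- surface_radial_map(tre, cl, n_angles = 48)
  tr <- random_rigid(3)
  clt <- resample_centerline(apply_rigid(tr, cl_pts), 0.5)
  clt <- aorticroot:::trim_centerline(clt, 2, 38)
  mt <- surface_radial_map(apply_rigid(tr, tre), clt, n_angles = 48)
  # the rotated map is the same radius profile with a shifted angular origin:
  # harmonic magnitudes and the mean radius are invariant
  p0 <- harmonic_profile(m); p1 <- harmonic_profile(mt)
  expect_equal(p0$h3, p1$h3, tolerance = 1e-3)
  expect_equal(p0$h2, p1$h2, tolerance = 1e-3)
  expect_equal(mean(m$values), mean(mt$values), tolerance = 1e-3)
})
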