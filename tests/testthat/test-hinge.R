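test_that("Gaussian curvature matches analytic values on sphere, cylinder and saddle", {
  sph <- make_icosphere(4, r = 10)
  K <- mesh_gaussian_curvature(sph)
  expect_true(all(abs(K - 0.01) / 0.01 < 0.10))   # K = 1/r^2 within 10 %

  cyl <- make_tube_mesh(function(th, z) rep(10, length(th)),
                        z_hi = 30, dz = 0.5, n_theta = 96)
  Kc <- mesh_gaussian_curvature(cyl)
  bnd <- aorticroot:::boundary_vertices(cyl)
  expect_lt(max(abs(Kc[-bnd])), 0.002)

  sad <- make_saddle_mesh()
  Ks <- mesh_gaussian_curvature(sad)
  origin <- which.min(rowSums(sad$vertices[, 1:2]^2))
  expect_lt(Ks[origin], 0)                        # analytic K = -1/100 < 0
})

test_that("inward extremum maps respect uniform volumes and min <= max", {
  vol <- image_volume(array(100, c(40, 40, 40)), origin = c(-20, -20, 0))
  cyl <- make_tube_mesh(function(th, z) rep(12, length(th)), z_hi = 38)
  cl <- resample_centerline(straight_centerline(0, 38), 0.5)
  cl <- aorticroot:::trim_centerline(cl, 3, 35)
  rm <- surface_radial_map(cyl, cl, 48)
  mi <- inward_extremum_map(vol, rm, cl, mode = "min")
  mx <- inward_extremum_map(vol, rm, cl, mode = "max")
  expect_true(all(abs(mi$values - 100) < 1e-6))
  expect_true(all(abs(mx$values - 100) < 1e-6))

  ph <- default_phantom()
  fit <- default_fit()
  expect_true(all(fit$maps$miiam$values <= fit$maps$mxiam$values + 1e-9))
  # MIIAM is dark (leaflet) at the hinge, bright (lumen) at the sinus belly
  miiam <- fit$maps$miiam
  hinge_row <- which.min(abs(miiam$slice_positions - 13.5))
  belly_row <- which.min(abs(miiam$slice_positions - 25))
  sinus_col <- which.min(abs(miiam$angle_centers - 100 * pi / 180))
  expect_lt(miiam$values[hinge_row, sinus_col], 150)
  expect_gt(miiam$values[belly_row, sinus_col], 180)
})

test_that("combine_maps produces a [0,1] product with absorbing/identity behavior", {
  sp <- 1:10; th <- 2 * pi * (0:15) / 16
  mk <- function(v) cylindrical_map(matrix(v, 10, 16), sp, th)
  # all-constant factors are replaced by all-ones (with warnings): identity
  z <- suppressWarnings(combine_maps(mk(0.5), mk(7), mk(3)))
  expect_true(all(z$values == 1))
  expect_warning(expect_warning(expect_warning(
    combine_maps(mk(0), mk(7), mk(3)),
    "no positive"), "MIIAM"), "MXIAM")

  set.seed(2)
  a <- cylindrical_map(matrix(rnorm(160), 10), sp, th)
  b <- cylindrical_map(matrix(runif(160, 10, 40), 10), sp, th)
  cc <- cylindrical_map(matrix(runif(160, 100, 400), 10), sp, th)
  comb <- combine_maps(a, b, cc)
  expect_true(all(comb$values >= 0 & comb$values <= 1))
  # any all-zero factor (after rescale) absorbs: minimum cell of b is where
  # the inverted MIIAM factor is exactly 1, the maximum is exactly 0
  expect_equal(comb$values[which.max(b$values)], 0)
  # invariance to affine intensity rescaling of the inputs
  b2 <- cylindrical_map(3 * b$values + 100, sp, th)
  c2 <- cylindrical_map(0.5 * cc$values - 20, sp, th)
  comb2 <- combine_maps(a, b2, c2)
  expect_equal(comb$values, comb2$values, tolerance = 1e-12)
})

test_that("sinus tiling finds the three sinus sectors and falls back gracefully", {
  # analytic trefoil: peaks at 0/120/240, boundaries at 60/180/300
  cl <- resample_centerline(straight_centerline(0, 40), 0.5)
  cl <- aorticroot:::trim_centerline(cl, 2, 38)
  tre <- make_tube_mesh(function(th, z) 10 + 1.5 * cos(3 * th))
  rm <- surface_radial_map(tre, cl, 96)
  prof <- harmonic_profile(rm)
  ext <- structure(list(proximal_index = 10L, distal_index = 60L,
                        proximal_mm = rm$slice_positions[10],
                        distal_mm = rm$slice_positions[60],
                        stj_point = NA, stj_plane = NULL),
                   class = "root_extents")
  comb <- cylindrical_map(matrix(runif(length(rm$values)), nrow(rm$values)),
                          rm$slice_positions, rm$angle_centers)
  tiles <- split_sinus_tiles(comb, rm, ext, prof)
  peaks <- sort(vapply(tiles, function(t) t$peak_angle, 0)) * 180 / pi
  expect_equal(peaks, c(0, 120, 240), tolerance = 2)
  bounds <- sort(vapply(tiles, function(t) t$sector[1], 0)) * 180 / pi
  expect_equal(bounds, c(60, 180, 300), tolerance = 4)
  # every angular bin belongs to exactly one tile
  cover <- integer(96)
  for (t in tiles) {
    cols <- vapply(t$angles, function(a)
      which.min(abs(aorticroot:::circ_diff(rm$angle_centers, a))), 1L)
    cover[cols] <- cover[cols] + 1L
  }
  expect_true(all(cover == 1L))

  # rotated sinuses move the peaks by the same rotation
  tre30 <- make_tube_mesh(function(th, z) 10 + 1.5 * cos(3 * (th - pi / 6)))
  rm30 <- surface_radial_map(tre30, cl, 96)
  tiles30 <- split_sinus_tiles(comb, rm30, ext, harmonic_profile(rm30))
  peaks30 <- sort(vapply(tiles30, function(t) t$peak_angle, 0)) * 180 / pi
  expect_equal(peaks30, c(30, 150, 270), tolerance = 4)

  # circular slices: fallback uniform tiling with a warning
  circ <- make_tube_mesh(function(th, z) rep(10, length(th)))
  rmc <- surface_radial_map(circ, cl, 96)
  expect_warning(
    tiles_fb <- split_sinus_tiles(comb, rmc, ext, harmonic_profile(rmc)),
    "fall")
  widths <- vapply(tiles_fb, function(t)
    ((t$sector[2] - t$sector[1]) %% (2 * pi)) * 180 / pi, 0)
  expect_equal(widths, rep(120, 3), tolerance = 1e-6)
})

test_that("tile principal direction follows stripes and breaks ties proximally", {
  mk_tile <- function(vals, ds = 1, r = 10) {
    n <- nrow(vals); m <- ncol(vals)
    structure(list(values = vals, slice_positions = (1:n) * ds,
                   angles = (1:m) / r,     # so mm arc == column index
                   sector = c(0, pi), peak_angle = 0, mean_radius = r),
              class = "sinus_tile")
  }
  # diagonal stripe
  d <- diag(20)
  dir_diag <- tile_principal_direction(mk_tile(d), 0.5)
  expect_equal(abs(dir_diag), rep(1 / sqrt(2), 2), tolerance = 1e-6)
  # horizontal stripe (pure angular)
  h <- matrix(0, 20, 20); h[10, ] <- 1
  dir_h <- tile_principal_direction(mk_tile(h), 0.5)
  expect_equal(abs(dir_h), c(0, 1), tolerance = 1e-6)
  # isotropic disc: tie-break to the proximal axis
  g <- outer(1:21, 1:21, function(i, j) as.numeric((i - 11)^2 + (j - 11)^2 <= 25))
  dir_iso <- tile_principal_direction(mk_tile(g), 0.5)
  expect_equal(dir_iso, c(-1, 0))
  # sign convention points proximally (non-positive slice component)
  expect_lte(dir_diag[1], 0)
  # degenerate: < 3 above-threshold pixels
  few <- matrix(0, 20, 20); few[3, 3] <- 1
  expect_warning(dir_few <- tile_principal_direction(mk_tile(few), 0.5),
                 "fewer than 3")
  expect_equal(dir_few, c(-1, 0))
})

test_that("phantom hinges are located within tolerance and labeled consistently", {
  fit <- default_fit()
  ph <- default_phantom()
  for (lbl in c("hinge_RC", "hinge_LC", "hinge_NC"))
    expect_lt(norm3(fit$landmarks[[lbl]] - ph$landmarks[[lbl]]), 3)
  # combined map global maximum lies within 3 mm (map metric) of a true hinge
  cm <- fit$maps$combined
  ij <- which(cm$values == max(cm$values), arr.ind = TRUE)[1, ]
  smax <- cm$slice_positions[ij[1]]
  thmax <- cm$angle_centers[ij[2]]
  truth <- as.matrix(ph$landmarks)[c("hinge_RC", "hinge_LC", "hinge_NC"), ]
  s_true <- truth[, 3]
  th_true <- atan2(truth[, 2], truth[, 1])
  r_true <- sqrt(truth[, 1]^2 + truth[, 2]^2)
  dmap <- sqrt((smax - s_true)^2 +
               (aorticroot:::circ_diff(thmax, th_true) * r_true)^2)
  expect_lt(min(dmap), 3)
  # RC hinge sits in the sinus containing the right ostium (cross-check of
  # the anterior/posterior rule against the constructed anatomy)
  sec <- fit$hinges$RC$tile_sector * pi / 180
  ang_R <- atan2(ph$landmarks$ostium_R[2], ph$landmarks$ostium_R[1])
  inside <- ((ang_R - sec[1]) %% (2 * pi)) <= ((sec[2] - sec[1]) %% (2 * pi))
  expect_true(inside)
  sec_L <- fit$hinges$LC$tile_sector * pi / 180
  ang_L <- atan2(ph$landmarks$ostium_L[2], ph$landmarks$ostium_L[1])
  inside_L <- ((ang_L - sec_L[1]) %% (2 * pi)) <= ((sec_L[2] - sec_L[1]) %% (2 * pi))
  expect_true(inside_L)
})

test_that("hinge labeling applies the anterior / posterior-left rule", {
  mk <- function(p) structure(list(point = p, label = NA_character_,
                                   tile_sector = c(0, 120),
                                   combined_score = 1),
                              class = "hinge_detection")
  lab <- label_hinges(mk(c(0, -10, 0)), mk(c(5, 10, 0)), mk(c(-5, 0, 0)))
  expect_equal(lab$RC$point, c(0, -10, 0))
  expect_equal(lab$LC$point, c(5, 10, 0))
  expect_equal(lab$NC$point, c(-5, 0, 0))
  expect_error(label_hinges(mk(c(1, 1, 1)), mk(c(1, 1, 1)), mk(c(0, 0, 0))),
               class = "labeling_error")
})

test_that("an isolated Gaussian blob on a tile is located at its center", {
  sp <- seq(10, 30, 0.5)
  th <- 2 * pi * (0:95) / 96
  blob <- outer(sp, th, function(s, a)
    exp(-((s - 18)^2 / 8 + (aorticroot:::circ_diff(a, 1.0) * 10)^2 / 2)))
  comb <- cylindrical_map(blob, sp, th)
  tile <- structure(list(values = blob[, th >= 0.5 & th < 1.5],
                         slice_positions = sp,
                         angles = th[th >= 0.5 & th < 1.5],
                         sector = c(0.5, 1.5), peak_angle = 1.0,
                         mean_radius = 10),
                    class = "sinus_tile")
  cl <- resample_centerline(straight_centerline(0, 40), 0.5)
  mesh <- make_tube_mesh(function(a, z) rep(10, length(a)))
  rm <- surface_radial_map(mesh, aorticroot:::trim_centerline(cl, 10, 30), 96)
  det <- locate_hinge_on_tile(tile, mesh, comb, rm,
                              aorticroot:::trim_centerline(cl, 10, 30))
  expect_lt(abs(det$point[3] - 18), 0.3)
  expect_lt(abs(atan2(det$point[2], det$point[1]) - 1.0), 0.07)

  # an all-zero tile fails
  tile0 <- tile; tile0$values[] <- 0
  expect_error(locate_hinge_on_tile(tile0, mesh, comb, rm,
                                    aorticroot:::trim_centerline(cl, 10, 30)),
               class = "hinge_detection_failure")
})
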