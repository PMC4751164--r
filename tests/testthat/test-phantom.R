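test_that("phantom generation is bit-reproducible for a fixed seed", {
  sp <- phantom_spec(voxel_spacing = c(0.8, 0.8, 0.8))
  p1 <- generate_phantom(sp)
  p2 <- generate_phantom(sp)
  expect_identical(p1$volume$data, p2$volume$data)
  expect_identical(p1$mesh$vertices, p2$mesh$vertices)
  expect_identical(as.matrix(p1$landmarks), as.matrix(p2$landmarks))
})

test_that("the mesh reproduces the analytic radius function (fidelity check)", {
  ph <- default_phantom()
  cl <- resample_centerline(ph$centerline, 0.5)
  cl <- aorticroot:::trim_centerline(cl, 3, 47)
  rm <- surface_radial_map(ph$mesh, cl, 96)
  r_true <- outer(rm$slice_positions, rm$angle_centers, ph$r_fun)
  rms <- sqrt(mean((rm$values - r_true)^2))
  expect_lt(rms, 0.15)
})

test_that("ground-truth geometry is self-consistent", {
  ph <- default_phantom()
  # hinge circumradius equals the requested annulus radius by construction
  expect_equal(ph$sizing_true$annulus_radius, 12, tolerance = 1e-6)
  # hinges lie on the analytic surface
  hm <- as.matrix(ph$landmarks)[c("hinge_RC", "hinge_LC", "hinge_NC"), ]
  rho <- sqrt(hm[, 1]^2 + hm[, 2]^2)
  r_at <- ph$r_fun(hm[, 3], atan2(hm[, 2], hm[, 1]))
  expect_lt(max(abs(rho - r_at)), 1e-6)
  # ostium heights above the annulus plane match the requested values
  expect_equal(ph$sizing_true$dist_annulus_to_right_ostium, 14,
               tolerance = 0.05)
  expect_equal(ph$sizing_true$dist_annulus_to_left_ostium, 16,
               tolerance = 0.05)
  # STJ at the upper sinus-band edge
  expect_equal(ph$landmarks$STJ, c(0, 0, 35), tolerance = 1e-9)
})

test_that("sinus band carries a much stronger third/second harmonic ratio than the LVOT", {
  ph <- default_phantom()
  cl <- resample_centerline(ph$centerline, 0.5)
  cl <- aorticroot:::trim_centerline(cl, 3, 47)
  rm <- surface_radial_map(ph$mesh, cl, 96)
  prof <- harmonic_profile(rm)
  band <- prof$slice_positions > 18 & prof$slice_positions < 32
  lvot <- prof$slice_positions < 8
  expect_gt(mean(prof$ratio[band]) / max(mean(prof$ratio[lvot]), 1e-6), 10)
})

test_that("phantom suite jitter is deterministic, distinct, and collapses at zero jitter", {
  s1 <- phantom_suite(20, phantom_spec(), seed = 7)
  s2 <- phantom_suite(20, phantom_spec(), seed = 7)
  expect_identical(s1, s2)
  radii <- vapply(s1, function(s) s$annulus_radius, 0)
  expect_gt(length(unique(radii)), 15)
  expect_true(all(radii >= 12 * 0.85 - 1e-9 & radii <= 12 * 1.15 + 1e-9))

  s3 <- phantom_suite(1, phantom_spec(), seed = 3)
  expect_length(s3, 1)

  s0 <- phantom_suite(4, phantom_spec(), seed = 1, jitter_radius = 0,
                      jitter_depth = 0, jitter_angle = 0, jitter_height = 0,
                      jitter_phase = FALSE)
  base <- phantom_spec()
  for (s in s0) {
    s_cmp <- s; s_cmp$seed <- base$seed
    expect_equal(s_cmp, base)
  }
})

test_that("inconsistent phantom specs are rejected", {
  expect_error(phantom_spec(sinus_band = c(30, 20)), class = "phantom_spec_error")
  expect_error(phantom_spec(ostium_specs = list(
    list(angle_deg = 60, height_mm = 35, radius_mm = 1.5, intensity = 350))),
    class = "phantom_spec_error")
  # hinge override must lie on the surface
  sp <- phantom_spec(hinge_points = rbind(c(30, 0, 13.5), c(0, 30, 13.5),
                                          c(-30, 0, 13.5)))
  expect_error(generate_phantom(sp), class = "phantom_spec_error")
})

test_that("calcification near a hinge degrades that hinge by less than 2x", {
  ph0 <- default_phantom()
  fit0 <- default_fit()
  truth <- ph0$landmarks
  # blob just inward of the RC hinge
  rc <- truth$hinge_RC
  blob_center <- rc * c(0.85, 0.85, 1)
  spc <- phantom_spec(calcification_blobs = list(
    list(center = blob_center, radius = 2, intensity = 1200)))
  phc <- generate_phantom(spc)
  fitc <- detect_root_landmarks(phc$volume, phc$mesh, phc$centerline)
  e0 <- norm3(fit0$landmarks$hinge_RC - truth$hinge_RC)
  ec <- norm3(fitc$landmarks$hinge_RC - phc$landmarks$hinge_RC)
  expect_lt(ec, max(2 * e0, 1.0))   # floor for a near-exact baseline
})

test_that("a bent-centerline phantom is still recovered end to end", {
  sp <- phantom_spec(centerline_curvature = 0.004, noise_sd = 10)
  ph <- generate_phantom(sp)
  fit <- detect_root_landmarks(ph$volume, ph$mesh, ph$centerline)
  e <- landmark_errors(fit$landmarks, ph$landmarks)
  expect_lt(e$table$mean[e$table$landmark == "overall"], 3)
})
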