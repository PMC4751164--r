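test_that("outward projection of a uniform volume is the uniform value", {
  vol <- image_volume(array(100, c(40, 40, 40)), spacing = c(1, 1, 1),
                      origin = c(-20, -20, 0))
  cyl <- make_tube_mesh(function(th, z) rep(12, length(th)), z_hi = 38)
  cl <- resample_centerline(straight_centerline(0, 38), 0.5)
  cl <- aorticroot:::trim_centerline(cl, 3, 35)
  rm <- surface_radial_map(cyl, cl, 48)
  m <- outward_projection_map(vol, rm, cl)
  expect_true(all(abs(m$values - 100) < 1e-6))

  # probe_length -> 0 limit equals surface-intensity sampling
  m0 <- outward_projection_map(vol, rm, cl,
                               ostia_config(probe_length = 1e-9))
  expect_true(all(abs(m0$values - 100) < 1e-6))
})

test_that("distal Gaussian weighting matches the analytic factor and the wide limit", {
  sp <- seq(0, 40, 0.5)
  th <- 2 * pi * (0:47) / 48
  m <- cylindrical_map(matrix(7, length(sp), 48), sp, th)
  w <- weight_by_distal_gaussian(m, distal_mm = 30, sd = 4)
  i30 <- which(sp == 30)
  expect_equal(w$values[i30, 1], 7, tolerance = 1e-12)
  expect_equal(w$values[which(sp == 34), 1], 7 * exp(-0.5), tolerance = 1e-12)
  expect_equal(w$values[which(sp == 26), 1], 7 * exp(-0.5), tolerance = 1e-12)
  w_inf <- weight_by_distal_gaussian(m, 30, sd = 1e9)
  expect_equal(w_inf$values, m$values, tolerance = 1e-9)
  # weighting preserves per-column ordering of cells at equal axial position
  set.seed(1)
  mv <- matrix(runif(length(sp) * 48), length(sp), 48)
  mr <- cylindrical_map(mv, sp, th)
  wr <- weight_by_distal_gaussian(mr, 30, 4)
  for (i in c(1, 25, 60)) {
    expect_identical(order(mv[i, ]), order(wr$values[i, ]))
  }
})

test_that("phantom coronary tubes are detected at their angles and heights", {
  fit <- default_fit()
  ph <- default_phantom()
  bin <- 2 * pi / 96
  # true angles in the map frame equal the phantom angles (u = +x, v = +y)
  ang_err_L <- abs(aorticroot:::circ_diff(fit$ostia$left$angle, 60 * pi / 180))
  ang_err_R <- abs(aorticroot:::circ_diff(fit$ostia$right$angle, 200 * pi / 180))
  expect_lt(ang_err_L, bin + 1e-9)
  expect_lt(ang_err_R, bin + 1e-9)
  # per-ostium axial refinement: each detection near its own tube height
  expect_lt(abs(fit$ostia$left$slice_position - 29.5), 1.5)
  expect_lt(abs(fit$ostia$right$slice_position - 27.5), 1.5)
  expect_lt(norm3(fit$landmarks$ostium_R - ph$landmarks$ostium_R), 2.5)
  expect_lt(norm3(fit$landmarks$ostium_L - ph$landmarks$ostium_L), 2.5)
  # detections lie on the mesh (snapped to vertices)
  vi <- aorticroot:::cpp_nearest_point(ph$mesh$vertices,
                                       rbind(fit$landmarks$ostium_R))
  expect_equal(as.numeric(ph$mesh$vertices[vi, ]),
               as.numeric(fit$landmarks$ostium_R))
})

test_that("tube brightness changes move the detected angle by at most one bin", {
  base <- phantom_spec(noise_sd = 0)
  bright <- base
  bright$ostium_specs[[1]]$intensity <- 600
  f1 <- local({
    ph <- generate_phantom(base)
    detect_root_landmarks(ph$volume, ph$mesh, ph$centerline)
  })
  f2 <- local({
    ph <- generate_phantom(bright)
    detect_root_landmarks(ph$volume, ph$mesh, ph$centerline)
  })
  bin <- 2 * pi / 96
  expect_lt(abs(aorticroot:::circ_diff(f1$ostia$left$angle,
                                       f2$ostia$left$angle)), bin + 1e-9)
})

test_that("a uniform-intensity volume fails ostia detection with the named stage", {
  ph <- default_phantom()
  vol <- ph$volume
  vol$data[] <- 100
  err <- tryCatch(detect_root_landmarks(vol, ph$mesh, ph$centerline),
                  error = identity)
  expect_s3_class(err, "ostia_detection_failure")
  expect_identical(err$stage, "ostia_detector")
})

test_that("ostium labeling follows the anterior rule with a leftward tie-break", {
  mk <- function(p) structure(list(angle = 0, slice_index = 1L,
                                   slice_position = 0, point = p,
                                   side = NA, peak_value = 1),
                              class = "ostium_detection")
  lab <- label_ostia(mk(c(0, -10, 0)), mk(c(0, 10, 0)))
  expect_equal(lab$right$point, c(0, -10, 0))
  lab2 <- label_ostia(mk(c(8, 0, 0)), mk(c(-8, 0, 0)))
  expect_equal(lab2$left$point, c(8, 0, 0))
  expect_error(label_ostia(mk(c(1, 2, 3)), mk(c(1, 2, 3))),
               class = "labeling_error")
})
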