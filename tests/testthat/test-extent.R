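mk_map <- function(r_by_slice_fun, n_s = 60, n_a = 96, ds = 0.5) {
  sp <- (seq_len(n_s) - 1) * ds
  th <- 2 * pi * (seq_len(n_a) - 1) / n_a
  vals <- t(vapply(sp, function(s) r_by_slice_fun(s, th), numeric(n_a)))
  cylindrical_map(vals, sp, th)
}

test_that("harmonic magnitudes are exact for pure cosine profiles", {
  m2 <- mk_map(function(s, th) 10 + 2 * cos(2 * th))
  p2 <- harmonic_profile(m2, epsilon = 0.01)
  expect_equal(p2$h2, rep(2, 60), tolerance = 1e-9)
  expect_equal(p2$h3, rep(0, 60), tolerance = 1e-9)
  expect_lt(max(p2$ratio), 1e-6)

  m3 <- mk_map(function(s, th) 10 + 1.5 * cos(3 * th))
  p3 <- harmonic_profile(m3, epsilon = 0.01)
  expect_equal(p3$h3, rep(1.5, 60), tolerance = 1e-9)
  expect_equal(p3$h2, rep(0, 60), tolerance = 1e-9)
  expect_equal(p3$ratio, rep(150, 60), tolerance = 1e-9)

  mc <- mk_map(function(s, th) rep(10, length(th)))
  pc <- harmonic_profile(mc, epsilon = 0.01)
  expect_equal(pc$h2 + pc$h3 + pc$ratio, rep(0, 60), tolerance = 1e-12)
})

test_that("harmonic ratio is scale- and rotation-invariant (phase ignored)", {
  f <- function(s, th) 10 + 1.2 * cos(2 * th) + 0.8 * cos(3 * (th - 0.7))
  p <- harmonic_profile(mk_map(f), epsilon = 0.01)
  # uniform scale with epsilon scaled likewise
  p_sc <- harmonic_profile(mk_map(function(s, th) 3 * f(s, th)),
                           epsilon = 0.03)
  expect_equal(p$ratio, p_sc$ratio, tolerance = 1e-9)
  # angular origin rotation leaves magnitudes unchanged
  p_rot <- harmonic_profile(mk_map(function(s, th) f(s, th + 1.234)),
                            epsilon = 0.01)
  expect_equal(p$h2, p_rot$h2, tolerance = 1e-9)
  expect_equal(p$h3, p_rot$h3, tolerance = 1e-9)
})

test_that("extents bracket a Gaussian ratio bump at its curvature shoulders", {
  # ratio profile: Gaussian bump at 20 mm, half-width 8 mm, flat background.
  n_s <- 81; ds <- 0.5
  sp <- (seq_len(n_s) - 1) * ds
  sigma <- 8 / (2 * sqrt(2 * log(2)))          # half-width -> SD
  ratio <- 30 * exp(-(sp - 20)^2 / (2 * sigma^2))
  th <- 2 * pi * (seq_len(96) - 1) / 96
  # build a radial map realizing that ratio: h3 = ratio * eps (h2 = 0)
  vals <- 10 + outer(ratio * 0.01, cos(3 * th))
  prof <- harmonic_profile(cylindrical_map(vals, sp, th), epsilon = 0.01)
  expect_equal(prof$ratio, ratio, tolerance = 1e-6)
  ext <- locate_extents(prof, smoothing_sigma = 2)
  # independent oracle: numerically locate the |second difference| maxima of
  # the smoothed ratio on each side of the bump
  sm <- aorticroot:::gaussian_smooth_1d(ratio, 2)
  lap <- abs(diff(diff(sm)))
  peak <- which.max(sm)
  below <- which(diff(sign(diff(lap[1:(peak - 1)]))) < 0) + 1
  oracle_prox <- below[which.max(lap[below])]
  expect_lt(abs(ext$proximal_index - (oracle_prox + 1)), 2.5)
  # shoulders are symmetric about the bump center
  expect_equal(ext$proximal_mm + ext$distal_mm, 2 * 20, tolerance = 1.1)
  expect_lt(ext$proximal_mm, 20)
  expect_gt(ext$distal_mm, 20)
})

test_that("phantom sinus band extents and STJ are recovered within tolerance", {
  fit <- default_fit()
  ph <- default_phantom()
  expect_gte(fit$extents$proximal_mm, 12)
  expect_lte(fit$extents$proximal_mm, 18)
  expect_gte(fit$extents$distal_mm, 32)
  expect_lte(fit$extents$distal_mm, 38)
  # STJ within 3 mm of the ground-truth band edge
  expect_lt(norm3(fit$landmarks$STJ - ph$landmarks$STJ), 3)
  # ordering: proximal extent below the slice of maximal h3
  expect_lt(fit$extents$proximal_index, which.max(fit$profile$h3))
  # STJ plane normal equals the centerline tangent at the distal extent
  expect_equal(abs(sum(fit$extents$stj_plane$normal * c(0, 0, 1))), 1,
               tolerance = 1e-6)
})

test_that("a sinus-free cylinder yields an extent-detection failure", {
  m <- mk_map(function(s, th) 10 + 0.5 * cos(2 * th))   # elliptical only
  p <- harmonic_profile(m, epsilon = 0.01)
  expect_error(locate_extents(p), class = "extent_detection_failure")
  err <- tryCatch(locate_extents(p), error = identity)
  expect_identical(err$stage, "extent_detector")
})
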