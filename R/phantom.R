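#' Parametric aortic-root phantom specification
#'
#' Describes a synthetic aortic root: an elliptical LVOT cross-section
#' (strong second harmonic) blending into a three-sinus bulge region (strong
#' third harmonic) and then a circular tubular ascending aorta, with two
#' contrast-bright coronary arteries leaving the surface in the distal sinus
#' region, thin low-intensity leaflet sheets meeting the wall at three hinge
#' points, an annular waist at the basal attachment level (the annulus is the
#' narrowest part of the root) with a small convex attachment nub at each
#' hinge, optional calcification blobs, and additive Gaussian noise.
#' Intensities loosely mimic contrast CTA (lumen about 350, wall 80, leaflet
#' 100, calcification 1200, background -50); no Hounsfield calibration is
#' claimed -- only the relative contrast matters to the detectors.
#'
#' The hinge nub crest radius is `annulus_radius` by construction, so the
#' ground-truth hinge circumradius equals `annulus_radius` exactly.
#'
#' @param lvot_radii ellipse semi-axes (a, b) of the LVOT cross-section, mm.
#' @param tube_radius radius of the tubular ascending aorta, mm.
#' @param sinus_depth third-harmonic bulge amplitude, mm.
#' @param sinus_band (lo, hi) extent of the sinus region along the
#'   centerline, mm; the ground-truth STJ is the upper edge.
#' @param sinus_phase angular position of the first sinus peak, degrees.
#' @param annulus_radius ground-truth hinge circumradius, mm.
#' @param waist_depth depth of the annular narrowing at the hinge level, mm.
#' @param annulus_level position of the hinge points along the centerline,
#'   mm; default 1.5 mm below the sinus band.
#' @param ostium_specs list of two lists `(angle_deg, height_mm, radius_mm,
#'   intensity)`: ostium angle, height above the annulus level, coronary tube
#'   radius and intensity.
#' @param leaflet_intensity,lumen_intensity,wall_intensity,background_intensity
#'   phantom intensities (HU-like).
#' @param calcification_blobs list of lists `(center, radius, intensity)`
#'   (center in world mm).
#' @param noise_sd additive Gaussian noise SD (intensity units).
#' @param voxel_spacing voxel spacing, mm (length 3).
#' @param centerline_curvature curvature (1/mm) of the centerline, bending it
#'   into a circular arc in the x-z plane; 0 = straight.
#' @param centerline_length centerline length, mm.
#' @param wall_thickness thickness of the wall shell outside the lumen
#'   surface, mm.
#' @param commissure_rise rise of the leaflet attachment crown from hinge
#'   nadir to commissures, mm.
#' @param hinge_points optional 3 x 3 matrix overriding the ground-truth
#'   hinge points (must lie on the surface to within 0.5 mm).
#' @param seed RNG seed for the noise.
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(lvot_radii = c(13, 10), tube_radius = 12,
                         sinus_depth = 2.5, sinus_band = c(15, 35),
                         sinus_phase = 100, annulus_radius = 12,
                         waist_depth = 1, annulus_level = NULL,
                         ostium_specs = list(
                           list(angle_deg = 60, height_mm = 16,
                                radius_mm = 2.0, intensity = 350),
                           list(angle_deg = 200, height_mm = 14,
                                radius_mm = 1.5, intensity = 350)),
                         leaflet_intensity = 100, lumen_intensity = 350,
                         wall_intensity = 80, background_intensity = -50,
                         calcification_blobs = list(), noise_sd = 20,
                         voxel_spacing = c(0.6, 0.6, 0.6),
                         centerline_curvature = 0, centerline_length = 50,
                         wall_thickness = 1.5, commissure_rise = 9,
                         leaflets = TRUE, hinge_points = NULL, seed = 1L) {
  spec <- structure(as.list(environment()), class = "phantom_spec")
  if (is.null(spec$annulus_level)) spec$annulus_level <- sinus_band[1] - 1.5
  if (sinus_band[1] >= sinus_band[2] ||
      sinus_band[1] < 0 || sinus_band[2] > centerline_length)
    abort("sinus_band must lie inside the centerline extent",
          "phantom_spec_error")
  for (o in ostium_specs) {
    s_o <- spec$annulus_level + o$height_mm
    if (s_o < sinus_band[1] - 5 || s_o > sinus_band[2] + 5)
      abort("ostium heights must fall inside the sinus band +/- 5 mm",
            "phantom_spec_error")
  }
  spec
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(paste0("<phantom_spec> tube %.1f mm, annulus %.1f mm, sinus depth ",
                     "%.1f mm, band [%.0f, %.0f] mm, noise SD %.0f, seed %d\n"),
              x$tube_radius, x$annulus_radius, x$sinus_depth,
              x$sinus_band[1], x$sinus_band[2], x$noise_sd, x$seed))
  invisible(x)
}

smoothstep <- function(x, lo, hi) {
  t <- pmin(1, pmax(0, (x - lo) / (hi - lo)))
  t * t * (3 - 2 * t)
}

# Analytic surface radius r(s, theta) of the phantom (vectorized).
phantom_radius_fun <- function(spec) {
  a <- spec$lvot_radii[1]; b <- spec$lvot_radii[2]
  tube <- spec$tube_radius
  lo <- spec$sinus_band[1]; hi <- spec$sinus_band[2]
  phase <- spec$sinus_phase * pi / 180
  s_h <- spec$annulus_level
  waist <- spec$waist_depth
  nub_amp <- spec$annulus_radius - (tube - waist)
  theta_k <- phase + c(0, 2, 4) * pi / 3
  sigma_s <- 2; sigma_th <- 0.15; waist_sigma <- 3
  function(s, theta) {
    e2 <- 1 - smoothstep(s, lo - 11, lo - 5)
    r_ell <- a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
    w <- ifelse(s > lo & s < hi, sin(pi * (s - lo) / (hi - lo))^2, 0)
    r <- tube + e2 * (r_ell - tube) +
      spec$sinus_depth * cos(3 * (theta - phase)) * w -
      waist * exp(-(s - s_h)^2 / (2 * waist_sigma^2))
    if (abs(nub_amp) > 1e-12) {
      gs <- exp(-(s - s_h)^2 / (2 * sigma_s^2))
      for (tk in theta_k) {
        dth <- circ_diff(theta, tk)
        r <- r + nub_amp * gs * exp(-dth^2 / (2 * sigma_th^2))
      }
    }
    r
  }
}

# Centerline geometry: world point and (t, u, v) frame at arc length s.
# Straight along +z, or a circular arc in the x-z plane for curvature > 0.
phantom_frame_fun <- function(spec) {
  kappa <- spec$centerline_curvature
  if (kappa <= 1e-9) {
    list(
      point = function(s) cbind(0 * s, 0 * s, s),
      frame = function(s) list(t = cbind(0 * s, 0 * s, 1 + 0 * s),
                               u = cbind(1 + 0 * s, 0 * s, 0 * s),
                               v = cbind(0 * s, 1 + 0 * s, 0 * s)),
      # world -> (s, a, b): a along u, b along v
      local = function(p) list(s = p[, 3], a = p[, 1], b = p[, 2]))
  } else {
    Rc <- 1 / kappa
    list(
      point = function(s) cbind(Rc * (1 - cos(s / Rc)), 0 * s, Rc * sin(s / Rc)),
      frame = function(s) {
        phi <- s / Rc
        list(t = cbind(sin(phi), 0 * s, cos(phi)),
             u = cbind(-cos(phi), 0 * s, sin(phi)),
             v = cbind(0 * s, -1 + 0 * s, 0 * s))
      },
      local = function(p) {
        phi <- atan2(p[, 3], Rc - p[, 1])
        d <- sqrt((p[, 1] - Rc)^2 + p[, 3]^2)
        list(s = Rc * phi, a = Rc - d, b = -p[, 2])
      })
  }
}

#' Generate a synthetic aortic-root phantom
#'
#' Rasterizes the phantom described by a [phantom_spec()] into an image
#' volume, triangulates its analytic surface into a mesh, and returns the
#' centerline polyline and the ground-truth [landmark_set()] (STJ at the
#' upper edge of the sinus band, ostia at the coronary tube origins, hinges
#' at the attachment nub crests). The noise is seeded from `spec$seed`, so a
#' given spec is bit-reproducible.
#'
#' @param spec a [phantom_spec()].
#' @return list of class `aortic_phantom` with elements `volume`, `mesh`,
#'   `centerline` (polyline matrix), `landmarks` (ground truth),
#'   `sizing_true` (ground-truth [compute_sizing()] report), `r_fun` (the
#'   analytic radius function), and `spec`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  r_fun <- phantom_radius_fun(spec)
  geo <- phantom_frame_fun(spec)
  L <- spec$centerline_length
  phase <- spec$sinus_phase * pi / 180
  s_h <- spec$annulus_level
  theta_k <- phase + c(0, 2, 4) * pi / 3

  # --- ground-truth landmarks ------------------------------------------------
  surf_point <- function(s, theta) {
    fr <- geo$frame(s)
    as.numeric(geo$point(s)) +
      r_fun(s, theta) * (cos(theta) * as.numeric(fr$u) +
                         sin(theta) * as.numeric(fr$v))
  }
  hinges <- lapply(theta_k, function(tk) surf_point(s_h, tk))
  if (!is.null(spec$hinge_points)) {
    hp <- as_point_matrix(spec$hinge_points, "hinge_points")
    loc <- geo$local(hp)
    rr <- r_fun(loc$s, atan2(loc$b, loc$a))
    if (any(abs(sqrt(loc$a^2 + loc$b^2) - rr) > 0.5))
      abort("supplied hinge points are more than 0.5 mm off the surface",
            "phantom_spec_error")
    hinges <- lapply(seq_len(3), function(i) hp[i, ])
  }
  ost <- lapply(spec$ostium_specs, function(o) {
    th <- o$angle_deg * pi / 180
    s_o <- s_h + o$height_mm
    fr <- geo$frame(s_o)
    dir <- cos(th) * as.numeric(fr$u) + sin(th) * as.numeric(fr$v)
    list(point = surf_point(s_o, th), dir = dir, s = s_o, theta = th,
         radius = o$radius_mm, intensity = o$intensity)
  })
  # anterior rule labels the ground truth exactly as the detector labels
  hy <- vapply(hinges, function(h) h[2], 0)
  rc_i <- which.min(hy)
  rest <- setdiff(1:3, rc_i)
  score <- vapply(rest, function(i) hinges[[i]][2] + hinges[[i]][1], 0)
  lc_i <- rest[which.max(score)]
  nc_i <- setdiff(rest, lc_i)
  lms <- list(STJ = as.numeric(geo$point(spec$sinus_band[2])))
  right <- left <- NULL
  if (length(ost) >= 2L) {
    oy <- vapply(ost, function(o) o$point[2], 0)
    right <- ost[[which.min(oy)]]; left <- ost[[which.max(oy)]]
    lms$ostium_R <- right$point
    lms$ostium_L <- left$point
  }
  lms$hinge_RC <- hinges[[rc_i]]
  lms$hinge_LC <- hinges[[lc_i]]
  lms$hinge_NC <- hinges[[nc_i]]
  landmarks <- landmark_set(lms,
    case_id = sprintf("phantom_seed%d", spec$seed),
    provenance = list(source = "synthetic ground truth"))

  # --- surface mesh ----------------------------------------------------------
  # vertex spacing below 0.5 mm in both directions: detections snap to mesh
  # vertices, so the mesh resolution bounds the detection quantization
  ms <- seq(2, L - 2, by = 0.35)
  nth <- 256L
  mth <- uniform_angles(nth)
  ns <- length(ms)
  frg <- geo$frame(rep(ms, times = nth))
  thg <- rep(mth, each = ns)
  sg <- rep(ms, times = nth)
  rg <- r_fun(sg, thg)
  Vm <- geo$point(sg) + rg * (cos(thg) * frg$u + sin(thg) * frg$v)
  vid <- function(i, j) (j - 1L) * ns + i     # slice i, angle j
  i <- rep(seq_len(ns - 1L), times = nth)
  j <- rep(seq_len(nth), each = ns - 1L)
  jn <- (j %% nth) + 1L
  f1 <- cbind(vid(i, j), vid(i + 1L, j), vid(i + 1L, jn))
  f2 <- cbind(vid(i, j), vid(i + 1L, jn), vid(i, jn))
  mesh <- surface_mesh(Vm, rbind(f1, f2))

  # --- volume rasterization --------------------------------------------------
  vs <- spec$voxel_spacing
  cor_len <- 10
  pad_xy <- cor_len + 3
  rng <- apply(Vm, 2L, range)
  lo_w <- rng[1, ] - c(pad_xy, pad_xy, 3)
  hi_w <- rng[2, ] + c(pad_xy, pad_xy, 3)
  dims <- pmax(8L, as.integer(ceiling((hi_w - lo_w) / vs)) + 1L)
  origin <- lo_w
  xg <- origin[1] + (seq_len(dims[1]) - 1L) * vs[1]
  yg <- origin[2] + (seq_len(dims[2]) - 1L) * vs[2]
  zg <- origin[3] + (seq_len(dims[3]) - 1L) * vs[3]
  P <- cbind(rep(xg, times = dims[2] * dims[3]),
             rep(rep(yg, each = dims[1]), times = dims[3]),
             rep(zg, each = dims[1] * dims[2]))
  loc <- geo$local(P)
  rho <- sqrt(loc$a^2 + loc$b^2)
  theta <- atan2(loc$b, loc$a)
  rw <- r_fun(loc$s, theta)
  img <- rep(spec$background_intensity, nrow(P))
  img[rho > rw & rho <= rw + spec$wall_thickness] <- spec$wall_intensity
  lumen <- rho <= rw
  img[lumen] <- spec$lumen_intensity
  if (isTRUE(spec$leaflets)) {
    # leaflet sheets: from the attachment crown on the wall to a coaptation
    # level on the axis, 0.9 mm thick (about one slice thickness)
    s_att <- s_h + spec$commissure_rise * (1 - cos(3 * (theta - phase))) / 2
    s_coapt <- s_h + 7
    lam <- pmin(rho / pmax(rw, 1e-6), 1)
    S_leaf <- lam * s_att + (1 - lam) * s_coapt
    leaf <- lumen & abs(loc$s - S_leaf) <= 0.45
    img[leaf] <- spec$leaflet_intensity
  }
  # contrast-bright coronary tubes leaving the surface
  for (o in ost) {
    p0 <- o$point - 1.0 * o$dir          # start slightly inside the wall
    seg <- (cor_len + 1.0) * o$dir
    w <- P - matrix(p0, nrow(P), 3L, byrow = TRUE)
    tpar <- pmin(1, pmax(0, as.numeric(w %*% o$dir) / (cor_len + 1.0)))
    dvec <- w - cbind(tpar * seg[1], tpar * seg[2], tpar * seg[3])
    d2 <- rowSums(dvec^2)
    img[d2 <= o$radius^2] <- o$intensity
  }
  for (blob in spec$calcification_blobs) {
    ctr <- as.numeric(blob$center)
    d2 <- (P[, 1] - ctr[1])^2 + (P[, 2] - ctr[2])^2 + (P[, 3] - ctr[3])^2
    img[d2 <= blob$radius^2] <- blob$intensity
  }
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    img <- img + rnorm(length(img), sd = spec$noise_sd)
  }
  volume <- image_volume(array(img, dims), spacing = vs, origin = origin)

  # --- centerline polyline ---------------------------------------------------
  scl <- seq(0, L, by = 1)
  centerline <- geo$point(scl)

  sizing_true <- if (length(ost) >= 2L) compute_sizing(landmarks) else NULL
  structure(list(volume = volume, mesh = mesh, centerline = centerline,
                 landmarks = landmarks, sizing_true = sizing_true,
                 r_fun = r_fun, spec = spec),
            class = "aortic_phantom")
}

#' @export
print.aortic_phantom <- function(x, ...) {
  print(x$spec)
  print(x$volume)
  print(x$mesh)
  invisible(x)
}

#' Randomized phantom suite
#'
#' Jitters a base spec `n` times: annulus (and tube and LVOT) radius by
#' +/- `jitter_radius` (relative), sinus depth by +/- `jitter_depth`
#' (relative), ostium angles by +/- `jitter_angle` degrees, ostium heights by
#' +/- `jitter_height` mm, sinus phase uniform over 120 degrees; the noise SD
#' is kept fixed. Deterministic given `seed`; each spec receives its own
#' derived noise seed.
#'
#' @param n number of specs (>= 1).
#' @param base_spec the base [phantom_spec()].
#' @param seed suite RNG seed.
#' @param jitter_radius,jitter_depth relative jitter half-widths.
#' @param jitter_angle,jitter_height absolute jitter half-widths (deg, mm).
#' @param jitter_phase if `TRUE` (default) the sinus phase is drawn uniformly
#'   over its 120-degree period.
#' @return list of `n` [phantom_spec()]s.
#' @export
phantom_suite <- function(n, base_spec = phantom_spec(), seed = 1L,
                          jitter_radius = 0.15, jitter_depth = 0.4,
                          jitter_angle = 20, jitter_height = 3,
                          jitter_phase = TRUE) {
  stopifnot(n >= 1)
  set.seed(seed)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- base_spec
    f <- runif(1, 1 - jitter_radius, 1 + jitter_radius)
    sp$annulus_radius <- base_spec$annulus_radius * f
    sp$tube_radius <- base_spec$tube_radius * f
    sp$lvot_radii <- base_spec$lvot_radii * f
    sp$sinus_depth <- base_spec$sinus_depth *
      runif(1, 1 - jitter_depth, 1 + jitter_depth)
    sp$ostium_specs <- lapply(base_spec$ostium_specs, function(o) {
      o$angle_deg <- o$angle_deg + runif(1, -jitter_angle, jitter_angle)
      o$height_mm <- o$height_mm + runif(1, -jitter_height, jitter_height)
      o
    })
    if (jitter_phase)
      sp$sinus_phase <- runif(1, 0, 120)
    sp$seed <- as.integer((seed * 1000L + i) %% .Machine$integer.max)
    out[[i]] <- sp
  }
  out
}
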