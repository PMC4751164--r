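#' Detect the six aortic-root landmarks and compute TAVI sizing
#'
#' Runs the full detection pipeline on a CTA volume, a segmented aortic-root
#' surface and a centerline: (1) the centerline is resampled with
#' rotation-minimizing MPR frames and trimmed to the mesh's axial extent and
#' the surface is unwrapped into a wall-radius map; (2) the proximal and
#' distal root extents (the distal one defining the STJ) are located from the
#' third/second Fourier-harmonic ratio of the radius profiles; (3) the two
#' coronary ostia are detected on the distally-weighted outward
#' average-intensity projection map; (4) the three valvular hinge points are
#' detected on the product of the Gaussian-curvature map and the inward
#' minimum/maximum intensity maps, tiled per sinus with PCA-derived search
#' directions; (5) the sizing report (annulus plane/center/radius,
#' annulus-to-ostium distances) is derived from the landmarks.
#'
#' Any stage failure raises a classed condition whose `stage` field names the
#' failing stage (`extent_detector`, `ostia_detector`, `hinge_detector`,
#' `sizing`).
#'
#' @param volume an [image_volume()] (or a path readable by
#'   [read_volume()]).
#' @param mesh a [surface_mesh()] (or a path readable by [read_mesh()]).
#' @param centerline an n x 3 polyline matrix, LVOT to ascending aorta (or a
#'   path readable by [read_centerline()]).
#' @param control a [root_control()].
#' @return An object of class `root_landmarks` with elements `landmarks`
#'   (a [landmark_set()]), `sizing` (a [compute_sizing()] report), `extents`,
#'   `profile`, `ostia`, `hinges`, `control`, `timings` and -- with
#'   `control$debug = TRUE` -- the intermediate `maps`.
#' @seealso [generate_phantom()] to make synthetic inputs;
#'   [landmark_errors()] to score detections against a reference.
#' @export
detect_root_landmarks <- function(volume, mesh, centerline,
                                  control = root_control()) {
  if (is.character(volume)) volume <- read_volume(volume)
  if (is.character(mesh)) mesh <- read_mesh(mesh)
  if (is.character(centerline)) centerline <- read_centerline(centerline)
  stopifnot(inherits(volume, "image_volume"), inherits(mesh, "surface_mesh"),
            inherits(control, "root_control"))
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()

  cl <- resample_centerline(centerline, control$centerline_spacing)
  # keep only MPR slices inside the mesh's axial extent: probe each slice
  # with a cheap 8-ray cast and keep the largest contiguous run of slices
  # whose rays all hit the surface (slices beyond the open ends miss)
  probe <- radial_raycast(mesh, cl, 8L)
  ok <- rowSums(is.na(probe)) == 0L
  runs <- rle(ok)
  if (!any(runs$values))
    abort("centerline does not pass through the mesh",
          "invalid_centerline_error", stage = "geometry_core")
  ends <- cumsum(runs$lengths)
  best <- which(runs$values)[which.max(runs$lengths[runs$values])]
  lo <- ends[best] - runs$lengths[best] + 1L
  hi <- ends[best]
  # one extra sample of margin off each open end
  cl <- trim_centerline(cl, cl$s[min(lo + 1L, hi)], cl$s[max(hi - 1L, lo)])
  radial <- surface_radial_map(mesh, cl, control$n_angles)
  timings["geometry_core"] <- tic() - t0; t0 <- tic()

  profile <- harmonic_profile(radial, control$epsilon)
  extents <- locate_extents(profile, control$extent_sigma, centerline = cl,
                            mode = control$laplacian_mode,
                            min_ratio = control$min_ratio)
  timings["extent_detector"] <- tic() - t0; t0 <- tic()

  outward <- outward_projection_map(volume, radial, cl, control$ostia)
  weighted <- weight_by_distal_gaussian(subtract_row_background(outward),
                                        extents$distal_mm,
                                        control$ostia$gauss_sd)
  ost_pair <- detect_ostia(weighted, mesh, control$ostia, radial, cl)
  ostia <- label_ostia(ost_pair[[1]], ost_pair[[2]])
  timings["ostia_detector"] <- tic() - t0; t0 <- tic()

  curv <- gaussian_curvature_map(mesh, radial, cl)
  miiam <- inward_extremum_map(volume, radial, cl, control$hinge, "min")
  mxiam <- inward_extremum_map(volume, radial, cl, control$hinge, "max")
  combined <- smooth_map(combine_maps(curv, miiam, mxiam), sigma_cells = 1)
  tiles <- split_sinus_tiles(combined, radial, extents, profile)
  hs <- lapply(tiles, locate_hinge_on_tile, mesh = mesh, combined = combined,
               radial_map = radial, cl = cl, cfg = control$hinge,
               anchor_max_s = extents$proximal_mm + 3)
  hinges <- label_hinges(hs[[1]], hs[[2]], hs[[3]], ostia)
  timings["hinge_detector"] <- tic() - t0; t0 <- tic()

  landmarks <- landmark_set(
    STJ = extents$stj_point,
    ostium_R = ostia$right$point, ostium_L = ostia$left$point,
    hinge_RC = hinges$RC$point, hinge_LC = hinges$LC$point,
    hinge_NC = hinges$NC$point,
    provenance = list(
      STJ = "distal extent of the harmonic-ratio profile",
      ostia = "weighted outward projection map maxima",
      hinges = "combined curvature/MIIAM/MXIAM map per sinus tile"))
  sizing <- compute_sizing(landmarks, extents)
  timings["sizing"] <- tic() - t0

  structure(list(landmarks = landmarks, sizing = sizing, extents = extents,
                 profile = profile, ostia = ostia, hinges = hinges,
                 control = control, timings = timings,
                 maps = if (control$debug)
                   list(radial = radial, outward = outward,
                        weighted = weighted, curvature = curv, miiam = miiam,
                        mxiam = mxiam, combined = combined, tiles = tiles)
                 else NULL),
            class = "root_landmarks")
}

#' @export
print.root_landmarks <- function(x, ...) {
  cat("Aortic-root landmark detection\n")
  cat(sprintf("  extents: proximal %.1f mm, distal (STJ) %.1f mm\n",
              x$extents$proximal_mm, x$extents$distal_mm))
  print(x$landmarks)
  cat(sprintf("  annulus radius %.2f mm; annulus-to-ostium R %.2f mm, L %.2f mm\n",
              x$sizing$annulus_radius,
              x$sizing$dist_annulus_to_right_ostium,
              x$sizing$dist_annulus_to_left_ostium))
  invisible(x)
}

#' @export
summary.root_landmarks <- function(object, ...) {
  print(object)
  cat("\nDetection details\n")
  cat(sprintf("  ostium R: angle %.1f deg, s = %.1f mm, peak %.1f\n",
              object$ostia$right$angle * 180 / pi,
              object$ostia$right$slice_position, object$ostia$right$peak_value))
  cat(sprintf("  ostium L: angle %.1f deg, s = %.1f mm, peak %.1f\n",
              object$ostia$left$angle * 180 / pi,
              object$ostia$left$slice_position, object$ostia$left$peak_value))
  for (lbl in c("RC", "LC", "NC"))
    cat(sprintf("  hinge %s: sector [%.0f, %.0f) deg, score %.3f\n", lbl,
                object$hinges[[lbl]]$tile_sector[1],
                object$hinges[[lbl]]$tile_sector[2],
                object$hinges[[lbl]]$combined_score))
  cat("\nStage timings (s):\n")
  print(round(object$timings, 2))
  invisible(object)
}

#' @export
coef.root_landmarks <- function(object, ...) {
  c(annulus_radius_mm = object$sizing$annulus_radius,
    dist_annulus_to_right_ostium_mm = object$sizing$dist_annulus_to_right_ostium,
    dist_annulus_to_left_ostium_mm = object$sizing$dist_annulus_to_left_ostium,
    proximal_extent_mm = object$extents$proximal_mm,
    distal_extent_mm = object$extents$distal_mm)
}

#' @export
plot.root_landmarks <- function(x, ...) {
  op <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  sp <- x$profile$slice_positions
  plot(sp, x$profile$ratio, type = "l", xlab = "s along centerline (mm)",
       ylab = "h3 / (h2 + eps)", main = "Harmonic ratio and extents")
  abline(v = c(x$extents$proximal_mm, x$extents$distal_mm), lty = 2)
  ang <- seq_along(x$profile$h2)
  plot(sp, x$profile$h2, type = "l", col = "grey40",
       xlab = "s along centerline (mm)", ylab = "harmonic magnitude (mm)",
       main = "h2 (grey) and h3 (black)",
       ylim = range(c(x$profile$h2, x$profile$h3), na.rm = TRUE))
  lines(sp, x$profile$h3, col = "black")
  invisible(x)
}
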