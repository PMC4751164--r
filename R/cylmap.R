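#' Cylindrical (unwrapped) surface map
#'
#' A 2D scalar map indexed by MPR slice along the centerline (rows, proximal
#' to distal) and angle around the centerline (columns). This single
#' container carries the wall-radius map, the outward average-intensity
#' projection map, the inward minimum/maximum intensity maps (MIIAM/MXIAM),
#' the Gaussian-curvature map, and the combined hinge-detection map.
#'
#' @param values numeric matrix `n_slices x n_angles`.
#' @param slice_positions arc-length position (mm) of each row along the
#'   centerline.
#' @param angle_centers angular bin centers in radians in `[0, 2*pi)`;
#'   `angle_centers[1]` corresponds to the frame direction `u`.
#' @param valid logical matrix flagging cells with trustworthy values.
#' @return object of class `cylindrical_map`.
#' @export
cylindrical_map <- function(values, slice_positions, angle_centers,
                            valid = NULL) {
  values <- as.matrix(values)
  if (is.null(valid)) valid <- !is.na(values)
  stopifnot(nrow(values) == length(slice_positions),
            ncol(values) == length(angle_centers),
            all(dim(valid) == dim(values)))
  structure(list(values = values,
                 slice_positions = as.numeric(slice_positions),
                 angle_centers = as.numeric(angle_centers),
                 valid = valid),
            class = "cylindrical_map")
}

#' @export
print.cylindrical_map <- function(x, ...) {
  cat(sprintf("<cylindrical_map> %d slices x %d angles, s in [%.1f, %.1f] mm\n",
              nrow(x$values), ncol(x$values),
              min(x$slice_positions), max(x$slice_positions)))
  cat(sprintf("  values in [%.3g, %.3g], %d invalid cells\n",
              min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE),
              sum(!x$valid)))
  invisible(x)
}

#' @export
dim.cylindrical_map <- function(x) dim(x$values)

uniform_angles <- function(n_angles) 2 * pi * (seq_len(n_angles) - 1L) / n_angles

#' Unwrap a surface mesh into a wall-radius map
#'
#' Converts the 3D aortic-root surface into a 2D radial map: for every
#' centerline sample (MPR slice) and angular bin, the value is the distance
#' (mm) from the centerline to the first intersection of the in-plane ray
#' `cos(theta) * u + sin(theta) * v` with the mesh. Cells whose ray misses
#' the surface are marked invalid and inpainted by angular linear
#' interpolation; a slice with more than 25 percent misses raises a
#' non-star-shaped-slice error.
#'
#' @param mesh a [surface_mesh()].
#' @param cl a [resample_centerline()] result whose samples lie inside the
#'   mesh's axial extent.
#' @param n_angles number of angular bins (>= 8).
#' @param max_radius maximum ray length (mm).
#' @return a [cylindrical_map()] of radii.
#' @export
surface_radial_map <- function(mesh, cl, n_angles = 96L, max_radius = 60) {
  stopifnot(inherits(mesh, "surface_mesh"), inherits(cl, "centerline_curve"))
  if (n_angles < 8L)
    abort("'n_angles' must be at least 8", "io_error", stage = "geometry_core")
  values <- radial_raycast(mesh, cl, n_angles, max_radius)
  ns <- nrow(values)
  ang <- uniform_angles(n_angles)
  valid <- !is.na(values)
  bad_frac <- 1 - rowMeans(valid)
  if (any(bad_frac > 0.25)) {
    worst <- which.max(bad_frac)
    abort(sprintf(paste0("slice %d (s = %.1f mm) is not star-shaped around the ",
                         "centerline: %.0f%% of rays miss the surface"),
                  worst, cl$s[worst], 100 * bad_frac[worst]),
          "non_star_shaped_slice_error", stage = "geometry_core")
  }
  values <- inpaint_angular(values, valid)
  cylindrical_map(values, cl$s, ang, valid)
}

# Raw ray-cast radii (matrix, NA on miss) without validity policy.
radial_raycast <- function(mesh, cl, n_angles, max_radius = 60) {
  ns <- nrow(cl$samples)
  ang <- uniform_angles(n_angles)
  ca <- cos(ang); sa <- sin(ang)
  O <- cl$samples[rep(seq_len(ns), times = n_angles), , drop = FALSE]
  ia <- rep(seq_len(n_angles), each = ns)
  is <- rep(seq_len(ns), times = n_angles)
  D <- cl$frames$u[is, , drop = FALSE] * ca[ia] +
       cl$frames$v[is, , drop = FALSE] * sa[ia]
  axis_dir <- normalize3(cl$samples[ns, ] - cl$samples[1, ])
  slack <- max(4, 3 * cl$spacing)
  tvals <- cpp_ray_mesh_first_hit(mesh$vertices, mesh$faces, O, D,
                                  axis_dir, slack, max_radius)
  matrix(tvals, nrow = ns, ncol = n_angles)
}

# Fill invalid cells by circular linear interpolation along the angle axis.
inpaint_angular <- function(values, valid) {
  for (i in which(rowSums(!valid) > 0L)) {
    v <- values[i, ]
    ok <- valid[i, ]
    n <- length(v)
    if (!any(ok)) next
    idx <- which(ok)
    # wrap-extend for circular interpolation
    xo <- c(idx - n, idx, idx + n)
    yo <- rep(v[idx], 3L)
    values[i, !ok] <- approx(xo, yo, xout = which(!ok))$y
  }
  values
}

# Bilinear interpolation on a cylindrical map (circular in angle, clamped in
# slice). s in mm, theta in radians.
map_interp <- function(map, s, theta) {
  sp <- map$slice_positions
  na <- length(map$angle_centers)
  dth <- 2 * pi / na
  si <- findInterval(s, sp, all.inside = TRUE)
  ws <- (s - sp[si]) / (sp[si + 1L] - sp[si])
  ws <- pmin(1, pmax(0, ws))
  af <- wrap_angle(theta) / dth           # 0-based fractional bin
  a0 <- floor(af)
  wa <- af - a0
  a0 <- (a0 %% na) + 1L
  a1 <- (a0 %% na) + 1L
  v <- map$values
  (1 - ws) * ((1 - wa) * v[cbind(si, a0)] + wa * v[cbind(si, a1)]) +
    ws * ((1 - wa) * v[cbind(si + 1L, a0)] + wa * v[cbind(si + 1L, a1)])
}

# 3D surface point for map coordinates (s mm, theta rad) using the radial map.
map_surface_point <- function(radial_map, cl, s, theta) {
  r <- map_interp(radial_map, s, theta)
  fr <- centerline_at(cl, s)
  fr$point + r * (cos(theta) * fr$u + sin(theta) * fr$v)
}
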