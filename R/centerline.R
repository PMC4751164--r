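#' Resample a centerline polyline to arc-length-uniform samples with MPR frames
#'
#' Resamples the LVOT-to-ascending-aorta centerline at a uniform arc-length
#' step and attaches a right-handed orthonormal frame `(t, u, v)` to every
#' sample: `t` is the local tangent, and `(u, v)` span the multiplanar
#' reconstruction (MPR) plane perpendicular to the centerline. Frames are
#' propagated with the double-reflection rotation-minimizing-frame method, so
#' consecutive frames carry no spurious twist and the angular origin of all
#' cylindrical maps is seam-free.
#'
#' The initial in-plane axis `u[1]` is the projection of patient +x (left)
#' onto the first normal plane (falling back to +y when the tangent is nearly
#' parallel to +x); this fixes a reproducible angular origin.
#'
#' @param points polyline as an n x 3 matrix of mm positions, ordered
#'   proximal (LVOT) to distal (ascending aorta).
#' @param spacing arc-length step between samples (mm), > 0.
#' @return An object of class `centerline_curve` with elements `samples`
#'   (n x 3), `s` (arc-length positions, mm, starting at 0), `spacing`, and
#'   `frames` = list of n x 3 matrices `t`, `u`, `v`.
#' @export
resample_centerline <- function(points, spacing = 0.5) {
  pts <- as_point_matrix(points)
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0)
    abort("'spacing' must be a positive mm step", "invalid_centerline_error",
          stage = "geometry_core")
  keep <- c(TRUE, rowSums((pts[-1, , drop = FALSE] -
                           pts[-nrow(pts), , drop = FALSE])^2) > 1e-16)
  pts <- pts[keep, , drop = FALSE]
  if (nrow(pts) < 2L)
    abort("centerline needs at least 2 distinct points",
          "invalid_centerline_error", stage = "geometry_core")
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  arc <- c(0, cumsum(seg))
  total <- arc[length(arc)]
  n <- floor(total / spacing + 1e-9) + 1L
  s <- (seq_len(n) - 1L) * spacing
  # rule = 2 clamps the last sample when rounding puts it epsilon past the end
  samples <- cbind(approx(arc, pts[, 1], xout = s, rule = 2)$y,
                   approx(arc, pts[, 2], xout = s, rule = 2)$y,
                   approx(arc, pts[, 3], xout = s, rule = 2)$y)
  centerline_from_samples(samples, spacing, s)
}

# Build frames for already arc-length-uniform samples.
centerline_from_samples <- function(samples, spacing, s = NULL) {
  n <- nrow(samples)
  if (is.null(s)) s <- (seq_len(n) - 1L) * spacing
  tang <- matrix(0, n, 3L)
  if (n >= 3L) {
    tang[2:(n - 1), ] <- samples[3:n, , drop = FALSE] - samples[1:(n - 2), , drop = FALSE]
  }
  tang[1, ] <- samples[2, ] - samples[1, ]
  tang[n, ] <- samples[n, ] - samples[n - 1, ]
  tang <- tang / sqrt(rowSums(tang^2))

  u <- matrix(0, n, 3L)
  v <- matrix(0, n, 3L)
  t0 <- tang[1, ]
  u0 <- c(1, 0, 0) - sum(c(1, 0, 0) * t0) * t0
  if (norm3(u0) < 1e-6) u0 <- c(0, 1, 0) - sum(c(0, 1, 0) * t0) * t0
  u[1, ] <- u0 / norm3(u0)
  v[1, ] <- cross3(t0, u[1, ])
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      # double-reflection rotation-minimizing transport
      v1 <- samples[i + 1L, ] - samples[i, ]
      c1 <- sum(v1 * v1)
      if (c1 < 1e-18) { u[i + 1L, ] <- u[i, ]; v[i + 1L, ] <- v[i, ]; next }
      rL <- u[i, ] - (2 / c1) * sum(v1 * u[i, ]) * v1
      tL <- tang[i, ] - (2 / c1) * sum(v1 * tang[i, ]) * v1
      v2 <- tang[i + 1L, ] - tL
      c2 <- sum(v2 * v2)
      ui <- if (c2 < 1e-18) rL else rL - (2 / c2) * sum(v2 * rL) * v2
      ui <- ui - sum(ui * tang[i + 1L, ]) * tang[i + 1L, ]
      u[i + 1L, ] <- ui / norm3(ui)
      v[i + 1L, ] <- cross3(tang[i + 1L, ], u[i + 1L, ])
    }
  }
  structure(list(samples = samples, s = s, spacing = spacing,
                 frames = list(t = tang, u = u, v = v)),
            class = "centerline_curve")
}

#' @export
print.centerline_curve <- function(x, ...) {
  cat(sprintf("<centerline_curve> %d samples, spacing %.3g mm, length %.1f mm\n",
              nrow(x$samples), x$spacing, x$s[length(x$s)] - x$s[1]))
  invisible(x)
}

#' @export
length.centerline_curve <- function(x) nrow(x$samples)

# Restrict a centerline to samples with s in [smin, smax]; arc-length
# positions are preserved (not re-zeroed) so map rows stay comparable.
trim_centerline <- function(cl, smin, smax) {
  keep <- which(cl$s >= smin - 1e-9 & cl$s <= smax + 1e-9)
  if (length(keep) < 7L)
    abort("fewer than 7 centerline samples remain inside the mesh extent",
          "invalid_centerline_error", stage = "geometry_core")
  structure(list(samples = cl$samples[keep, , drop = FALSE], s = cl$s[keep],
                 spacing = cl$spacing,
                 frames = list(t = cl$frames$t[keep, , drop = FALSE],
                               u = cl$frames$u[keep, , drop = FALSE],
                               v = cl$frames$v[keep, , drop = FALSE])),
            class = "centerline_curve")
}

# Interpolated frame and position at an arbitrary arc-length position.
centerline_at <- function(cl, s) {
  s <- max(cl$s[1], min(cl$s[length(cl$s)], s))
  i <- max(1L, min(length(cl$s) - 1L, findInterval(s, cl$s)))
  w <- (s - cl$s[i]) / (cl$s[i + 1L] - cl$s[i])
  lerp <- function(m) (1 - w) * m[i, ] + w * m[i + 1L, ]
  tt <- normalize3(lerp(cl$frames$t))
  uu <- lerp(cl$frames$u)
  uu <- normalize3(uu - sum(uu * tt) * tt)
  list(point = lerp(cl$samples), t = tt, u = uu, v = cross3(tt, uu))
}

#' Read / write centerlines (CSV with x_mm,y_mm,z_mm header, or JSON)
#'
#' @param path file ending in `.csv` (header `x_mm,y_mm,z_mm`, one point per
#'   row) or `.json` (object with a `points` array of `[x, y, z]` mm triples).
#' @return `read_centerline` returns an n x 3 matrix of points;
#'   `write_centerline` returns `path` invisibly.
#' @export
read_centerline <- function(path) {
  if (!file.exists(path))
    abort(sprintf("centerline file not found: %s", path), "io_error")
  if (grepl("\\.json$", tolower(path))) {
    obj <- jsonlite::fromJSON(path)
    pts <- as_point_matrix(obj$points, "points")
  } else {
    df <- read.csv(path)
    need <- c("x_mm", "y_mm", "z_mm")
    if (!all(need %in% names(df)))
      abort(sprintf("centerline CSV %s must have header x_mm,y_mm,z_mm", path),
            "io_error")
    pts <- as.matrix(df[, need])
  }
  unname(pts)
}

#' @rdname read_centerline
#' @param points n x 3 matrix of centerline points (mm).
#' @export
write_centerline <- function(points, path) {
  pts <- as_point_matrix(points)
  if (grepl("\\.json$", tolower(path))) {
    jsonlite::write_json(list(points = pts), path, digits = NA, auto_unbox = TRUE)
  } else {
    df <- data.frame(x_mm = pts[, 1], y_mm = pts[, 2], z_mm = pts[, 3])
    write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}
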