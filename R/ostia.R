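#' Configuration for coronary-ostia detection
#'
#' Defaults follow the published protocol: a probing cylinder of length
#' 2.5 mm and radius 0.75 mm directed outward from the aortic surface, and a
#' Gaussian axial weighting of SD 4 mm centered at the distal extent (the
#' ostia lie close to the sinotubular junction). The minimum angular peak
#' separation (default 45 degrees) prevents one wide bright region from
#' producing both "ostia"; the true ostia sit in different sinuses, more than
#' 90 degrees apart.
#'
#' @param probe_length outward cylinder length, mm.
#' @param probe_radius cylinder radius, mm.
#' @param gauss_sd axial Gaussian weighting SD, mm.
#' @param min_peak_separation minimum angular separation of the two ostium
#'   peaks, degrees.
#' @param global_axial if `TRUE`, use a single global axial maximum shared by
#'   both ostia (the literal published reading) instead of the default
#'   per-ostium axial refinement in a narrow angular window.
#' @return list of class `ostia_config`.
#' @export
ostia_config <- function(probe_length = 2.5, probe_radius = 0.75,
                         gauss_sd = 4, min_peak_separation = 45,
                         global_axial = FALSE) {
  stopifnot(probe_length > 0, probe_radius > 0, gauss_sd > 0,
            min_peak_separation > 0)
  structure(list(probe_length = probe_length, probe_radius = probe_radius,
                 gauss_sd = gauss_sd,
                 min_peak_separation = min_peak_separation,
                 global_axial = isTRUE(global_axial)),
            class = "ostia_config")
}

# Shared sampler: statistic of trilinearly interpolated intensities inside a
# cylindrical probe planted on every surface cell, directed along +/- the
# surface ray. The probe is a bundle of parallel sub-rays (1 axial + 4 ring
# rays at 0.6 radius), each starting on the wall surface ALONG ITS OWN ray
# (surface position looked up in the radial map), so the probe samples the
# shell between the segmented surface and its dilated/eroded offset and never
# leaks across a sloping wall into the lumen of a neighboring slice.
# Sampling grid: n_axial stations x 5 sub-rays >= 20 points, enough to
# resolve a 0.75 mm radius at sub-mm voxels.
cylinder_stat_map <- function(volume, radial_map, cl, length_mm, radius_mm,
                              direction = c("outward", "inward"),
                              stat = c("mean", "min", "max"),
                              n_axial = 6L, fill = c("min", "median")) {
  direction <- match.arg(direction)
  stat <- match.arg(stat)
  fill <- match.arg(fill)
  ns <- nrow(radial_map$values)
  na <- ncol(radial_map$values)
  ang <- radial_map$angle_centers
  is <- rep(seq_len(ns), times = na)
  ia <- rep(seq_len(na), each = ns)
  s_cell <- radial_map$slice_positions[is]
  th_cell <- ang[ia]
  r_cell <- radial_map$values[cbind(is, ia)]
  u <- cl$frames$u[is, , drop = FALSE]
  v <- cl$frames$v[is, , drop = FALSE]
  tng <- cl$frames$t[is, , drop = FALSE]
  C <- cl$samples[is, , drop = FALSE]
  dirs <- u * cos(th_cell) + v * sin(th_cell)
  axis <- if (direction == "outward") dirs else -dirs
  n_cells <- ns * na
  lj <- seq(0, length_mm, length.out = n_axial)
  disc <- rbind(c(0, 0),
                0.6 * radius_mm * cbind(cos(c(0, .5, 1, 1.5) * pi),
                                        sin(c(0, .5, 1, 1.5) * pi)))
  npts <- n_axial * nrow(disc)
  vals <- matrix(NA_real_, n_cells, npts)
  smin <- min(radial_map$slice_positions)
  smax <- max(radial_map$slice_positions)
  p <- 0L
  for (d in seq_len(nrow(disc))) {
    # sub-ray anchored on the surface at its own (s', theta')
    s_off <- disc[d, 1]                     # along the centerline tangent
    s_sub <- pmin(smax, pmax(smin, s_cell + s_off))
    th_sub <- th_cell + disc[d, 2] / pmax(r_cell, 1e-6)
    r_sub <- map_interp(radial_map, s_sub, th_sub)
    dir_sub <- u * cos(th_sub) + v * sin(th_sub)
    anchor <- C + s_off * tng + r_sub * dir_sub
    ax_sub <- if (direction == "outward") dir_sub else -dir_sub
    for (j in seq_len(n_axial)) {
      p <- p + 1L
      vals[, p] <- sample_volume(volume, anchor + lj[j] * ax_sub)
    }
  }
  bad <- rowSums(is.na(vals)) > 0L
  m <- switch(stat,
    mean = rowMeans(vals),
    min  = do.call(pmin, c(as.data.frame(vals), na.rm = FALSE)),
    max  = do.call(pmax, c(as.data.frame(vals), na.rm = FALSE)))
  m[bad] <- NA_real_
  fill_val <- if (fill == "min") min(m, na.rm = TRUE) else median(m, na.rm = TRUE)
  m[bad] <- fill_val
  values <- matrix(m, ns, na)
  valid <- matrix(!bad, ns, na) & radial_map$valid
  cylindrical_map(values, radial_map$slice_positions, ang, valid)
}

#' Outward average-intensity projection map
#'
#' For every surface cell, the mean intensity of the volume inside a cylinder
#' of radius `probe_radius` and length `probe_length` starting on the surface
#' and directed along the outward surface ray -- the image of the shell
#' between the segmented surface and a dilated surface. Contrast-filled
#' coronary arteries leaving the root produce bright spots in this map.
#' Cells whose cylinder exits the volume are marked invalid and filled with
#' the map minimum (so they can never win a maximum projection).
#'
#' @param volume an [image_volume()].
#' @param radial_map wall-radius map from [surface_radial_map()].
#' @param cl the matching [resample_centerline()] result.
#' @param cfg an [ostia_config()].
#' @return a [cylindrical_map()] of mean outward intensities.
#' @export
outward_projection_map <- function(volume, radial_map, cl,
                                   cfg = ostia_config()) {
  cylinder_stat_map(volume, radial_map, cl, cfg$probe_length,
                    cfg$probe_radius, "outward", "mean", fill = "min")
}

#' Subtract the per-slice angular median from a cylindrical map
#'
#' Partial-volume averaging at the lumen boundary gives the outward
#' projection map a bright baseline ring that varies with the slice (it is
#' strongest where the wall is steep, near the sinotubular junction) but is
#' nearly constant around the circumference. Subtracting each row's median
#' cancels this ring while leaving angularly localized bright structures --
#' the coronary ostia -- untouched, so a genuinely bright but distally
#' down-weighted ostium cannot be outranked by the baseline.
#'
#' @param map a [cylindrical_map()].
#' @return the row-centered [cylindrical_map()].
#' @export
subtract_row_background <- function(map) {
  stopifnot(inherits(map, "cylindrical_map"))
  v <- map$values - apply(map$values, 1L, median)
  cylindrical_map(v, map$slice_positions, map$angle_centers, map$valid)
}

#' Weight a cylindrical map axially toward the distal extent
#'
#' Multiplies every cell by a Gaussian in the slice position centered at the
#' distal extent (weight exactly 1 there); with `sd = 4` mm this focuses the
#' ostium search near the sinotubular junction.
#'
#' @param map a [cylindrical_map()].
#' @param distal_mm slice position (mm) of the distal extent.
#' @param sd Gaussian SD in mm (> 0).
#' @return the weighted [cylindrical_map()].
#' @export
weight_by_distal_gaussian <- function(map, distal_mm, sd = 4) {
  stopifnot(inherits(map, "cylindrical_map"), sd > 0)
  w <- exp(-(map$slice_positions - distal_mm)^2 / (2 * sd^2))
  out <- cylindrical_map(map$values * w, map$slice_positions,
                         map$angle_centers, map$valid)
  attr(out, "axial_weight") <- w
  out
}

# circular local maxima of a 1D profile (value strictly above both wrapped
# neighbours, ties broken to the first)
circular_local_maxima <- function(y) {
  n <- length(y)
  left <- y[c(n, 1:(n - 1))]
  right <- y[c(2:n, 1)]
  which(y > left & y >= right)
}

#' Detect the two coronary ostia on the weighted projection map
#'
#' An angular profile (per-column maximum over slices) is searched for its
#' two strongest local maxima separated by at least
#' `cfg$min_peak_separation`; these give the two ostium angles. For each
#' angle, the axial location is the argmax over slices within a +/- 2-bin
#' angular window (per-ostium refinement; set `cfg$global_axial = TRUE` for a
#' single shared axial maximum). Both peaks are refined to sub-bin precision
#' by 3-point quadratic interpolation and each detection is snapped to the
#' nearest mesh vertex.
#'
#' @param weighted the distal-weighted [outward_projection_map()].
#' @param mesh the [surface_mesh()] the detections are snapped to.
#' @param cfg an [ostia_config()].
#' @param radial_map the wall-radius map (for the surface position).
#' @param cl the matching centerline.
#' @return unnamed list of two `ostium_detection` objects (unlabeled), each
#'   with `angle` (rad), `slice_position` (mm), `point` (3D mm), `peak_value`.
#' @export
detect_ostia <- function(weighted, mesh, cfg = ostia_config(),
                         radial_map, cl) {
  stopifnot(inherits(weighted, "cylindrical_map"))
  v <- weighted$values
  na <- ncol(v)
  dth <- 2 * pi / na
  prof <- apply(v, 2L, max)
  cand <- circular_local_maxima(prof)
  if (length(cand) < 2L)
    abort("fewer than two angular intensity maxima: cannot locate two ostia",
          "ostia_detection_failure", stage = "ostia_detector")
  cand <- cand[order(prof[cand], decreasing = TRUE)]
  sep <- cfg$min_peak_separation * pi / 180
  first <- cand[1L]
  rest <- cand[-1L]
  ok <- abs(circ_diff(weighted$angle_centers[rest],
                      weighted$angle_centers[first])) >= sep
  if (!any(ok))
    abort(sprintf("no second angular maximum at least %.0f degrees from the first",
                  cfg$min_peak_separation),
          "ostia_detection_failure", stage = "ostia_detector")
  second <- rest[which(ok)[1L]]

  global_si <- NULL
  if (cfg$global_axial) {
    axial_prof <- apply(v, 1L, max)
    global_si <- which.max(axial_prof)
  }

  one <- function(ai) {
    # sub-bin angular refinement on the angular profile
    am1 <- prof[((ai - 2L) %% na) + 1L]
    ap1 <- prof[(ai %% na) + 1L]
    doff <- quad_refine(am1, prof[ai], ap1)
    theta <- wrap_angle(weighted$angle_centers[ai] + doff * dth)
    cols <- ((ai - 1L + (-2:2)) %% na) + 1L
    axial <- apply(v[, cols, drop = FALSE], 1L, max)
    # the distal Gaussian picks WHICH bright structure wins; for the precise
    # axial position we undo it (otherwise the weight tilts a bright-tube
    # plateau and biases the height distally)
    aw <- attr(weighted, "axial_weight")
    if (!is.null(aw) && is.null(global_si)) axial <- axial / aw
    si <- if (is.null(global_si)) which.max(axial) else global_si
    ns <- length(axial)
    soff <- if (si > 1L && si < ns)
      quad_refine(axial[si - 1L], axial[si], axial[si + 1L]) else 0
    ds <- if (ns > 1L) weighted$slice_positions[2L] - weighted$slice_positions[1L] else 0
    s_mm <- weighted$slice_positions[si] + soff * ds
    p <- map_surface_point(radial_map, cl, s_mm, theta)
    vi <- cpp_nearest_point(mesh$vertices, matrix(p, 1L, 3L))[1L]
    structure(list(angle = theta, slice_index = si, slice_position = s_mm,
                   point = mesh$vertices[vi, ], side = NA_character_,
                   peak_value = v[si, ai]),
              class = "ostium_detection")
  }
  list(one(first), one(second))
}

#' @export
print.ostium_detection <- function(x, ...) {
  cat(sprintf("<ostium_detection> side %s, angle %.1f deg, s = %.1f mm, point (%.1f, %.1f, %.1f)\n",
              x$side, x$angle * 180 / pi, x$slice_position,
              x$point[1], x$point[2], x$point[3]))
  invisible(x)
}

#' Label two ostium detections as right and left
#'
#' In the left(+x)/posterior(+y)/superior(+z) patient convention the right
#' coronary ostium is the more anterior point (smaller +y); ties are broken
#' by taking the more leftward (larger +x) point as left.
#'
#' @param a,b `ostium_detection` objects.
#' @return named list with elements `right` and `left`.
#' @export
label_ostia <- function(a, b) {
  if (norm3(a$point - b$point) < 1e-9)
    abort("the two ostium detections coincide", "labeling_error",
          stage = "ostia_detector")
  if (abs(a$point[2] - b$point[2]) > 1e-12) {
    right <- if (a$point[2] < b$point[2]) a else b
    left <- if (a$point[2] < b$point[2]) b else a
  } else {
    left <- if (a$point[1] > b$point[1]) a else b
    right <- if (a$point[1] > b$point[1]) b else a
  }
  right$side <- "right"
  left$side <- "left"
  list(right = right, left = left)
}
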