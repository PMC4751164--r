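#' TAVI sizing report from the six landmarks
#'
#' The annulus plane, center and radius are the circumscribed circle of the
#' three hinge points (the virtual annulus ring); the annulus-to-ostium
#' distances are the perpendicular distances from the annulus plane to the
#' right and left coronary ostia (reported as absolute values -- the clinical
#' convention -- with the signed values retained for diagnostics). The STJ
#' plane is the MPR plane at the detected distal extent, the only orientation
#' the automated STJ detection provides.
#'
#' @param landmarks a [landmark_set()] with the six standard names.
#' @param extents optional [locate_extents()] result (fills the STJ plane;
#'   when absent the STJ plane is taken perpendicular to the annulus normal
#'   through the STJ landmark).
#' @return object of class `sizing_report`: `annulus_plane`,
#'   `annulus_center`, `annulus_radius`, `dist_annulus_to_right_ostium`,
#'   `dist_annulus_to_left_ostium`, signed variants, `stj_plane`,
#'   `stj_center`.
#' @export
compute_sizing <- function(landmarks, extents = NULL) {
  stopifnot(inherits(landmarks, "landmark_set"))
  missing <- setdiff(landmark_names, names(landmarks))
  if (length(missing) > 0L)
    abort(sprintf("landmarks missing: %s", paste(missing, collapse = ", ")),
          "degenerate_annulus_error", stage = "sizing")
  h <- lapply(landmarks[c("hinge_RC", "hinge_LC", "hinge_NC")], as.numeric)
  orient <- as.numeric(landmarks$STJ) - Reduce(`+`, h) / 3  # distal direction
  fit <- tryCatch(
    circumcircle_3d(h[[1]], h[[2]], h[[3]], orient = orient),
    aorticroot_error = function(e)
      abort("the three hinge points are collinear: degenerate annulus",
            "degenerate_annulus_error", stage = "sizing"))
  dr <- point_plane_distance(fit$plane, landmarks$ostium_R)
  dl <- point_plane_distance(fit$plane, landmarks$ostium_L)
  if (!is.null(extents) && !is.null(extents$stj_plane)) {
    stj_plane <- extents$stj_plane
    stj_center <- extents$stj_point
  } else {
    stj_center <- as.numeric(landmarks$STJ)
    stj_plane <- structure(list(point = stj_center, normal = fit$plane$normal),
                           class = "plane")
  }
  structure(list(annulus_plane = fit$plane, annulus_center = fit$center,
                 annulus_radius = fit$radius,
                 dist_annulus_to_right_ostium = abs(dr),
                 dist_annulus_to_left_ostium = abs(dl),
                 signed_dist_right = dr, signed_dist_left = dl,
                 stj_plane = stj_plane, stj_center = stj_center),
            class = "sizing_report")
}

#' @export
print.sizing_report <- function(x, ...) {
  cat("<sizing_report>\n")
  cat(sprintf("  annulus radius           %6.2f mm\n", x$annulus_radius))
  cat(sprintf("  annulus center           (%.2f, %.2f, %.2f) mm\n",
              x$annulus_center[1], x$annulus_center[2], x$annulus_center[3]))
  cat(sprintf("  annulus to right ostium  %6.2f mm\n",
              x$dist_annulus_to_right_ostium))
  cat(sprintf("  annulus to left ostium   %6.2f mm\n",
              x$dist_annulus_to_left_ostium))
  cat(sprintf("  STJ center               (%.2f, %.2f, %.2f) mm\n",
              x$stj_center[1], x$stj_center[2], x$stj_center[3]))
  invisible(x)
}

#' Paired differences between two sizing reports
#'
#' Plane accuracy is summarized as the Euclidean center shift and the planar
#' angle between the two annulus (and STJ) planes; scalar measures as paired
#' differences `auto - ref`.
#'
#' @param auto,ref [compute_sizing()] reports.
#' @return list of class `sizing_comparison`.
#' @export
compare_reports <- function(auto, ref) {
  stopifnot(inherits(auto, "sizing_report"), inherits(ref, "sizing_report"))
  structure(list(
    annulus_center_shift = norm3(auto$annulus_center - ref$annulus_center),
    annulus_plane_angle = plane_angle(auto$annulus_plane, ref$annulus_plane),
    stj_center_shift = norm3(auto$stj_center - ref$stj_center),
    stj_plane_angle = plane_angle(auto$stj_plane, ref$stj_plane),
    d_annulus_radius = auto$annulus_radius - ref$annulus_radius,
    d_dist_right_ostium = auto$dist_annulus_to_right_ostium -
      ref$dist_annulus_to_right_ostium,
    d_dist_left_ostium = auto$dist_annulus_to_left_ostium -
      ref$dist_annulus_to_left_ostium),
    class = "sizing_comparison")
}

#' @export
print.sizing_comparison <- function(x, ...) {
  cat("<sizing_comparison> (auto - ref)\n")
  cat(sprintf("  annulus center shift %.2f mm, plane angle %.2f deg\n",
              x$annulus_center_shift, x$annulus_plane_angle))
  cat(sprintf("  STJ center shift %.2f mm, plane angle %.2f deg\n",
              x$stj_center_shift, x$stj_plane_angle))
  cat(sprintf("  d radius %+0.2f mm, d right %+0.2f mm, d left %+0.2f mm\n",
              x$d_annulus_radius, x$d_dist_right_ostium, x$d_dist_left_ostium))
  invisible(x)
}

#' Write a sizing report to JSON or flat CSV
#'
#' @param report a [compute_sizing()] report.
#' @param path output path ending in `.json` or `.csv`.
#' @export
write_sizing <- function(report, path) {
  stopifnot(inherits(report, "sizing_report"))
  flat <- list(
    annulus_center_x_mm = report$annulus_center[1],
    annulus_center_y_mm = report$annulus_center[2],
    annulus_center_z_mm = report$annulus_center[3],
    annulus_normal_x = report$annulus_plane$normal[1],
    annulus_normal_y = report$annulus_plane$normal[2],
    annulus_normal_z = report$annulus_plane$normal[3],
    annulus_radius_mm = report$annulus_radius,
    dist_annulus_to_right_ostium_mm = report$dist_annulus_to_right_ostium,
    dist_annulus_to_left_ostium_mm = report$dist_annulus_to_left_ostium,
    signed_dist_right_mm = report$signed_dist_right,
    signed_dist_left_mm = report$signed_dist_left,
    stj_center_x_mm = report$stj_center[1],
    stj_center_y_mm = report$stj_center[2],
    stj_center_z_mm = report$stj_center[3])
  flat <- lapply(flat, function(v) round(as.numeric(v), 6))
  if (grepl("\\.json$", tolower(path))) {
    writeLines(jsonlite::toJSON(flat, digits = NA, auto_unbox = TRUE,
                                pretty = TRUE), path)
  } else {
    write.csv(as.data.frame(flat), path, row.names = FALSE)
  }
  invisible(path)
}
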