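#' Plane through three points
#'
#' Fits the (exact) plane through three non-collinear points; the annulus
#' plane is defined this way from the three hinge points.
#'
#' @param p1,p2,p3 3D points (mm).
#' @param orient optional direction (3-vector): the normal is flipped, if
#'   necessary, to have a positive dot product with it. The sizing code passes
#'   the distal centerline direction so annulus-to-ostium distances come out
#'   positive on the distal side.
#' @return An object of class `plane`: list with unit `normal` and `point`.
#' @export
fit_plane <- function(p1, p2, p3, orient = NULL) {
  p1 <- as.numeric(p1); p2 <- as.numeric(p2); p3 <- as.numeric(p3)
  n <- cross3(p2 - p1, p3 - p1)
  area2 <- norm3(n)             # twice the triangle area
  if (area2 / 2 <= 1e-6)
    abort("the three points are (near-)collinear: degenerate plane",
          "degenerate_plane_error", stage = "sizing")
  n <- n / area2
  if (!is.null(orient) && sum(n * orient) < 0) n <- -n
  structure(list(point = p1, normal = n), class = "plane")
}

#' @export
print.plane <- function(x, ...) {
  cat(sprintf("<plane> point (%.2f, %.2f, %.2f), normal (%.4f, %.4f, %.4f)\n",
              x$point[1], x$point[2], x$point[3],
              x$normal[1], x$normal[2], x$normal[3]))
  invisible(x)
}

#' Circumscribed circle of three points in 3D
#'
#' Center and radius of the unique circle through three non-collinear 3D
#' points -- the annulus circle fitted to the three hinge points.
#'
#' @inheritParams fit_plane
#' @return An object of class `circle_fit`: `center` (mm), `radius` (mm) and
#'   the supporting `plane`.
#' @export
circumcircle_3d <- function(p1, p2, p3, orient = NULL) {
  p1 <- as.numeric(p1); p2 <- as.numeric(p2); p3 <- as.numeric(p3)
  pl <- fit_plane(p1, p2, p3, orient = orient)
  v1 <- p2 - p1
  v2 <- p3 - p1
  g <- rbind(c(sum(v1 * v1), sum(v1 * v2)),
             c(sum(v1 * v2), sum(v2 * v2)))
  ab <- solve(g, c(sum(v1 * v1) / 2, sum(v2 * v2) / 2))
  center <- p1 + ab[1] * v1 + ab[2] * v2
  structure(list(center = center, radius = norm3(center - p1), plane = pl),
            class = "circle_fit")
}

#' @export
print.circle_fit <- function(x, ...) {
  cat(sprintf("<circle_fit> center (%.2f, %.2f, %.2f) mm, radius %.2f mm\n",
              x$center[1], x$center[2], x$center[3], x$radius))
  invisible(x)
}

#' Signed perpendicular distance from a plane to a point
#'
#' Positive on the side of the plane normal (for the annulus plane oriented
#' distally, the ostia sit at positive distance in plausible anatomy).
#'
#' @param plane a [fit_plane()] result.
#' @param p 3D point (mm).
#' @return signed distance in mm.
#' @export
point_plane_distance <- function(plane, p) {
  stopifnot(inherits(plane, "plane"))
  sum((as.numeric(p) - plane$point) * plane$normal)
}

#' Angle between two planes
#'
#' The planar angle between the normals, folded to `[0, 90]` degrees (used to
#' compare automatically detected and reference annulus / STJ planes).
#'
#' @param a,b planes from [fit_plane()].
#' @return angle in degrees.
#' @export
plane_angle <- function(a, b) {
  stopifnot(inherits(a, "plane"), inherits(b, "plane"))
  ca <- abs(sum(a$normal * b$normal))
  acos(min(1, ca)) * 180 / pi
}
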