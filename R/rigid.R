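#' Rigid (rotation + translation) transforms of the pipeline inputs
#'
#' `rigid_transform` builds a transform from a 3x3 rotation matrix and a
#' translation; `apply_rigid` applies it to point matrices, meshes,
#' centerlines, image volumes (by composing the volume's affine -- no
#' resampling) and landmark sets. The detection pipeline is equivariant under
#' such transforms, which the test-suite exercises.
#'
#' @param rotation 3x3 rotation matrix (orthonormal, det +1).
#' @param translation length-3 translation (mm).
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- unname(as.matrix(rotation))
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8 || det(rotation) < 0)
    abort("'rotation' must be a proper rotation matrix", "io_error")
  structure(list(R = rotation, t = as.numeric(translation)),
            class = "rigid_transform")
}

#' Rotation about an axis
#'
#' @param axis rotation axis (3-vector, need not be unit).
#' @param angle_deg rotation angle in degrees.
#' @rdname rigid_transform
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  k <- normalize3(as.numeric(axis))
  th <- angle_deg * pi / 180
  K <- rbind(c(0, -k[3], k[2]), c(k[3], 0, -k[1]), c(-k[2], k[1], 0))
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' @param transform a `rigid_transform`.
#' @param x object to transform.
#' @param ... unused.
#' @rdname rigid_transform
#' @export
apply_rigid <- function(transform, x, ...) UseMethod("apply_rigid", x)

#' @export
apply_rigid.default <- function(transform, x, ...) {
  pts <- as_point_matrix(x)
  sweep(pts %*% t(transform$R), 2L, transform$t, "+")
}

#' @export
apply_rigid.surface_mesh <- function(transform, x, ...) {
  surface_mesh(apply_rigid.default(transform, x$vertices), x$faces)
}

#' @export
apply_rigid.image_volume <- function(transform, x, ...) {
  image_volume(x$data, spacing = x$spacing,
               origin = as.numeric(transform$R %*% x$origin + transform$t),
               direction = transform$R %*% x$direction)
}

#' @export
apply_rigid.centerline_curve <- function(transform, x, ...) {
  rot <- function(m) m %*% t(transform$R)
  structure(list(samples = sweep(rot(x$samples), 2L, transform$t, "+"),
                 s = x$s, spacing = x$spacing,
                 frames = list(t = rot(x$frames$t), u = rot(x$frames$u),
                               v = rot(x$frames$v))),
            class = "centerline_curve")
}

#' @export
apply_rigid.landmark_set <- function(transform, x, ...) {
  out <- lapply(x, function(p) as.numeric(transform$R %*% p + transform$t))
  attributes(out) <- attributes(x)
  out
}
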