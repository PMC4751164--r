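#' Named landmark set
#'
#' The six aortic-root landmarks as named 3D points (mm): `STJ`, `ostium_R`,
#' `ostium_L`, `hinge_RC`, `hinge_LC`, `hinge_NC`. Extra names are allowed;
#' a detection-provenance record can be attached.
#'
#' @param ... named 3D points, or a single named list of them.
#' @param case_id optional case identifier.
#' @param provenance optional list describing how each landmark was obtained.
#' @return object of class `landmark_set` (a named list of numeric
#'   3-vectors).
#' @export
landmark_set <- function(..., case_id = NULL, provenance = NULL) {
  pts <- list(...)
  if (length(pts) == 1L && is.list(pts[[1]]) && is.null(names(pts)[1]))
    pts <- pts[[1]]
  if (is.null(names(pts)) || any(names(pts) == ""))
    abort("all landmarks must be named", "io_error")
  pts <- lapply(pts, function(p) {
    p <- as.numeric(p)
    if (length(p) != 3L || any(!is.finite(p)))
      abort("each landmark must be a finite 3D point (mm)", "io_error")
    p
  })
  structure(pts, class = "landmark_set", case_id = case_id,
            provenance = provenance)
}

landmark_names <- c("STJ", "ostium_R", "ostium_L",
                    "hinge_RC", "hinge_LC", "hinge_NC")

#' @export
print.landmark_set <- function(x, ...) {
  cid <- attr(x, "case_id")
  cat(sprintf("<landmark_set>%s %d landmarks\n",
              if (is.null(cid)) "" else paste0(" case ", cid), length(x)))
  for (nm in names(x))
    cat(sprintf("  %-9s (%7.2f, %7.2f, %7.2f) mm\n",
                nm, x[[nm]][1], x[[nm]][2], x[[nm]][3]))
  invisible(x)
}

#' @export
as.matrix.landmark_set <- function(x, ...) {
  m <- do.call(rbind, x)
  rownames(m) <- names(x)
  colnames(m) <- c("x_mm", "y_mm", "z_mm")
  m
}

#' Read / write landmark sets as JSON
#'
#' File format: `{"case_id": ..., "landmarks": {"STJ": [x, y, z], ...}}`
#' with coordinates in mm.
#'
#' @param path JSON file path.
#' @return `read_landmarks` returns a [landmark_set()]; `write_landmarks`
#'   returns `path` invisibly.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path))
    abort(sprintf("landmark file not found: %s", path), "io_error")
  obj <- jsonlite::fromJSON(path)
  if (is.null(obj$landmarks))
    abort(sprintf("%s has no 'landmarks' field", path), "io_error")
  landmark_set(lapply(obj$landmarks, as.numeric),
               case_id = obj$case_id)
}

#' @rdname read_landmarks
#' @param landmarks a [landmark_set()].
#' @export
write_landmarks <- function(landmarks, path) {
  stopifnot(inherits(landmarks, "landmark_set"))
  obj <- list(case_id = attr(landmarks, "case_id"),
              landmarks = lapply(landmarks, function(p) round(p, 6)))
  if (is.null(obj$case_id)) obj$case_id <- NA
  json <- jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}
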