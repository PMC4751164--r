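#' Pipeline configuration
#'
#' Collects every tunable parameter of the detection pipeline. The defaults
#' reproduce the published protocol parameters: outward probe 2.5 mm x
#' 0.75 mm, distal Gaussian SD 4 mm, inward probe 1.5 mm x 0.75 mm, tile
#' threshold at half maximum.
#'
#' @param n_angles angular bins of the cylindrical maps.
#' @param centerline_spacing MPR slice spacing along the centerline, mm.
#' @param epsilon denominator floor of the harmonic ratio, mm.
#' @param extent_sigma Gaussian pre-smoothing SD (slices) before the extent
#'   Laplacian.
#' @param laplacian_mode `"magnitude"` or `"signed"` extent peak search.
#' @param min_ratio minimum peak harmonic ratio accepted as a sinus
#'   signature.
#' @param ostia an [ostia_config()].
#' @param hinge a [hinge_config()].
#' @param debug keep intermediate maps on the result object.
#' @param seed seed recorded with results (the detection itself is
#'   deterministic).
#' @return list of class `root_control`.
#' @export
root_control <- function(n_angles = 96L, centerline_spacing = 0.5,
                         epsilon = 0.01, extent_sigma = 2,
                         laplacian_mode = "magnitude", min_ratio = 2,
                         ostia = ostia_config(), hinge = hinge_config(),
                         debug = FALSE, seed = 1L) {
  stopifnot(n_angles >= 8, centerline_spacing > 0, epsilon > 0,
            extent_sigma >= 0)
  structure(list(n_angles = as.integer(n_angles),
                 centerline_spacing = centerline_spacing, epsilon = epsilon,
                 extent_sigma = extent_sigma,
                 laplacian_mode = match.arg(laplacian_mode,
                                            c("magnitude", "signed")),
                 min_ratio = min_ratio, ostia = ostia, hinge = hinge,
                 debug = isTRUE(debug), seed = as.integer(seed)),
            class = "root_control")
}

#' Read / write a pipeline configuration as YAML
#'
#' A flat YAML file with the [root_control()] fields; nested `ostia` and
#' `hinge` sections carry the module configs. Write-then-read yields an
#' equal configuration.
#'
#' @param path YAML file path.
#' @return `read_control` returns a [root_control()]; `write_control`
#'   returns `path` invisibly.
#' @export
read_control <- function(path) {
  if (!file.exists(path))
    abort(sprintf("config file not found: %s", path), "io_error")
  obj <- yaml::read_yaml(path)
  oc <- do.call(ostia_config, obj$ostia %||% list())
  hc <- do.call(hinge_config, obj$hinge %||% list())
  obj$ostia <- NULL; obj$hinge <- NULL
  do.call(root_control, c(obj, list(ostia = oc, hinge = hc)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_control
#' @param control a [root_control()].
#' @export
write_control <- function(control, path) {
  stopifnot(inherits(control, "root_control"))
  obj <- unclass(control)
  obj$ostia <- unclass(obj$ostia)
  obj$hinge <- unclass(obj$hinge)
  yaml::write_yaml(obj, path)
  invisible(path)
}
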