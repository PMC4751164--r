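#' Fourier-harmonic profile of the wall-radius map
#'
#' For every MPR slice, computes the discrete Fourier transform of the
#' wall-radius function r(theta) and extracts the magnitudes of the second
#' and third harmonics. The elliptical LVOT cross-section drives the second
#' harmonic; the three sinuses of Valsalva drive the third. The per-slice
#' ratio `h3 / (h2 + epsilon)` therefore highlights the sinus region while
#' suppressing the elliptical LVOT signature; `epsilon` is a small floor that
#' keeps the ratio finite on circular slices.
#'
#' Magnitudes are normalized so that a pure `A * cos(k * theta)` profile
#' yields `h_k = A`.
#'
#' @param radial_map wall-radius [cylindrical_map()] from
#'   [surface_radial_map()].
#' @param epsilon denominator floor in mm (default 0.01).
#' @return object of class `harmonic_profile`: `slice_positions`, `h2`, `h3`,
#'   `ratio`, `ratio_laplacian` (second difference of the raw ratio) and
#'   `phase3` (third-harmonic phase, radians, used as a tiling fallback).
#' @export
harmonic_profile <- function(radial_map, epsilon = 0.01) {
  stopifnot(inherits(radial_map, "cylindrical_map"))
  n_angles <- ncol(radial_map$values)
  if (n_angles < 8L)
    abort("at least 8 angular bins are needed to resolve harmonics 2 and 3",
          "extent_detection_failure", stage = "extent_detector")
  ns <- nrow(radial_map$values)
  h2 <- h3 <- phase3 <- rep(NA_real_, ns)
  for (i in seq_len(ns)) {
    r <- radial_map$values[i, ]
    if (anyNA(r)) next                      # all-invalid slice propagates NA
    X <- fft(r)
    h2[i] <- 2 * Mod(X[3L]) / n_angles
    h3[i] <- 2 * Mod(X[4L]) / n_angles
    phase3[i] <- -Arg(X[4L])                # r ~ cos(3*(theta - phase3/3))
  }
  ratio <- h3 / (h2 + epsilon)
  lap <- rep(NA_real_, ns)
  if (ns >= 3L)
    lap[2:(ns - 1)] <- ratio[1:(ns - 2)] - 2 * ratio[2:(ns - 1)] + ratio[3:ns]
  structure(list(slice_positions = radial_map$slice_positions,
                 h2 = h2, h3 = h3, ratio = ratio, ratio_laplacian = lap,
                 phase3 = phase3, epsilon = epsilon),
            class = "harmonic_profile")
}

#' @export
print.harmonic_profile <- function(x, ...) {
  cat(sprintf("<harmonic_profile> %d slices, max h3/h2 ratio %.2f at s = %.1f mm\n",
              length(x$ratio), max(x$ratio, na.rm = TRUE),
              x$slice_positions[which.max(x$ratio)]))
  invisible(x)
}

# indices of strict local maxima of a vector (interior points only)
local_maxima <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
}

gaussian_smooth_1d <- function(y, sigma) {
  if (sigma <= 0) return(y)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  k <- k / sum(k)
  n <- length(y)
  ypad <- c(rev(y[seq_len(min(half, n))]), y,
            rev(y[seq.int(n, by = -1, length.out = min(half, n))]))
  out <- stats::filter(ypad, k, sides = 2)
  as.numeric(out[(half + 1):(half + n)])
}

#' Locate the proximal and distal extents of the aortic root
#'
#' The third/second-harmonic ratio forms a single broad bump over the sinus
#' region. After Gaussian smoothing, the discrete Laplacian (`[1, -2, 1]`
#' second difference) of the ratio has strong extrema at the shoulders of the
#' bump; among local maxima of the Laplacian magnitude flanking the global
#' ratio maximum, the strongest below is the proximal extent and the
#' strongest above is the distal extent. The sinotubular junction (STJ) is
#' defined as the distal extent.
#'
#' @param profile a [harmonic_profile()].
#' @param smoothing_sigma Gaussian pre-smoothing SD in slices (default 2).
#' @param centerline optional [resample_centerline()] result; when supplied,
#'   the STJ point and STJ plane (MPR plane at the distal extent) are filled.
#' @param mode `"magnitude"` (default) searches maxima of `|Laplacian|`;
#'   `"signed"` searches maxima of the signed Laplacian.
#' @param min_ratio minimum peak `h3/(h2 + eps)` ratio required to accept a
#'   sinus signature; below it the slice stack is considered sinus-free and an
#'   extent-detection-failure error is raised.
#' @return object of class `root_extents`: `proximal_index`, `distal_index`,
#'   `proximal_mm`, `distal_mm`, `stj_point`, `stj_plane`.
#' @export
locate_extents <- function(profile, smoothing_sigma = 2, centerline = NULL,
                           mode = c("magnitude", "signed"), min_ratio = 2) {
  stopifnot(inherits(profile, "harmonic_profile"))
  mode <- match.arg(mode)
  ratio <- profile$ratio
  ok <- is.finite(ratio)
  if (sum(ok) < 7L)
    abort("fewer than 7 usable slices", "extent_detection_failure",
          stage = "extent_detector", profile = profile)
  ratio[!ok] <- 0
  sm <- gaussian_smooth_1d(ratio, smoothing_sigma)
  n <- length(sm)
  lap <- rep(NA_real_, n)
  lap[2:(n - 1)] <- sm[1:(n - 2)] - 2 * sm[2:(n - 1)] + sm[3:n]
  lap[c(1, n)] <- 0
  sig <- if (mode == "magnitude") abs(lap) else lap
  peak <- which.max(sm)
  if (sm[peak] < min_ratio)
    abort(sprintf(paste0("no sinus signature: peak third/second harmonic ",
                         "ratio %.3g is below %.3g"), sm[peak], min_ratio),
          "extent_detection_failure", stage = "extent_detector",
          profile = profile)
  cand <- local_maxima(sig)
  below <- cand[cand < peak - 1L]
  above <- cand[cand > peak + 1L]
  if (length(below) == 0L || length(above) == 0L)
    abort("could not find curvature maxima flanking the sinus region",
          "extent_detection_failure", stage = "extent_detector",
          profile = profile)
  pi_ <- below[which.max(sig[below])]
  di <- above[which.max(sig[above])]
  sp <- profile$slice_positions
  # sub-slice refinement of the Laplacian peaks: an integer slice index would
  # let the STJ jump a whole slice under a rigid motion of the inputs
  refine_mm <- function(i) {
    off <- if (i > 1L && i < n) quad_refine(sig[i - 1L], sig[i], sig[i + 1L])
           else 0
    sp[i] + off * (sp[2L] - sp[1L])
  }
  prox_mm <- refine_mm(pi_)
  dist_mm <- refine_mm(di)
  stj_point <- rep(NA_real_, 3)
  stj_plane <- NULL
  if (!is.null(centerline)) {
    fr <- centerline_at(centerline, dist_mm)
    stj_point <- fr$point
    stj_plane <- structure(list(point = fr$point, normal = fr$t),
                           class = "plane")
  }
  structure(list(proximal_index = pi_, distal_index = di,
                 proximal_mm = prox_mm, distal_mm = dist_mm,
                 stj_point = stj_point, stj_plane = stj_plane),
            class = "root_extents")
}

#' @export
print.root_extents <- function(x, ...) {
  cat(sprintf("<root_extents> proximal %.1f mm (slice %d), distal/STJ %.1f mm (slice %d)\n",
              x$proximal_mm, x$proximal_index, x$distal_mm, x$distal_index))
  invisible(x)
}

#' Write the per-slice harmonic diagnostics to CSV
#'
#' @param profile a [harmonic_profile()].
#' @param path output CSV path.
#' @export
write_harmonic_profile <- function(profile, path) {
  df <- data.frame(position_mm = profile$slice_positions, h2 = profile$h2,
                   h3 = profile$h3, ratio = profile$ratio,
                   laplacian = profile$ratio_laplacian)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
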