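#' Configuration for hinge-point detection
#'
#' Defaults follow the published protocol: inward probing cylinders of
#' length 1.5 mm and radius 0.75 mm, and sinus tiles thresholded at half of
#' their maximum before the principal-component search. `profile_step` is the
#' sampling step (mm) of the 1D search profile along the tile eigenvector.
#'
#' @param inward_length inward cylinder length, mm.
#' @param inward_radius inward cylinder radius, mm.
#' @param tile_threshold_fraction threshold as a fraction of the tile
#'   maximum, in (0, 1).
#' @param profile_step 1D profile sampling step, mm.
#' @return list of class `hinge_config`.
#' @export
hinge_config <- function(inward_length = 1.5, inward_radius = 0.75,
                         tile_threshold_fraction = 0.5, profile_step = 0.25) {
  stopifnot(inward_length > 0, inward_radius > 0, profile_step > 0,
            tile_threshold_fraction > 0, tile_threshold_fraction < 1)
  structure(list(inward_length = inward_length, inward_radius = inward_radius,
                 tile_threshold_fraction = tile_threshold_fraction,
                 profile_step = profile_step),
            class = "hinge_config")
}

#' Per-vertex Gaussian curvature of a triangle mesh
#'
#' Estimates the Gaussian curvature K = kappa1 * kappa2 at every vertex by
#' the angle-deficit method normalized by the mixed Voronoi area (the
#' standard convergent discrete estimator). Vertices on the two open
#' boundaries inherit the value of their nearest interior neighbor.
#' Degenerate triangles (area < 1e-9) are skipped; their count is reported as
#' a warning.
#'
#' @param mesh a [surface_mesh()].
#' @return numeric vector of per-vertex K (1/mm^2).
#' @export
mesh_gaussian_curvature <- function(mesh) {
  V <- mesh$vertices
  f <- mesh$faces
  p1 <- V[f[, 1], , drop = FALSE]
  p2 <- V[f[, 2], , drop = FALSE]
  p3 <- V[f[, 3], , drop = FALSE]
  e12 <- p2 - p1; e13 <- p3 - p1; e23 <- p3 - p2
  cr <- cbind(e12[, 2] * e13[, 3] - e12[, 3] * e13[, 2],
              e12[, 3] * e13[, 1] - e12[, 1] * e13[, 3],
              e12[, 1] * e13[, 2] - e12[, 2] * e13[, 1])
  area2 <- sqrt(rowSums(cr^2))           # twice the triangle area
  degen <- area2 / 2 < 1e-9
  if (any(degen))
    warning(sprintf("%d degenerate triangles skipped in curvature estimation",
                    sum(degen)))
  l12 <- rowSums(e12^2); l13 <- rowSums(e13^2); l23 <- rowSums(e23^2)
  # corner angles via the dot products
  ang1 <- acos(pmin(1, pmax(-1, rowSums(e12 * e13) / sqrt(l12 * l13))))
  ang2 <- acos(pmin(1, pmax(-1, rowSums(-e12 * e23) / sqrt(l12 * l23))))
  ang3 <- pi - ang1 - ang2
  cot <- function(a) cos(a) / sin(a)
  tri_area <- area2 / 2
  # Meyer mixed area per corner
  mixed_corner <- function(angA, angB, angC, lB, lC) {
    # corner with angle angA; opposite squared edge lengths lB (edge facing B),
    # lC (edge facing C): Voronoi formula uses the two edges incident at A.
    vor <- (lB * cot(angB) + lC * cot(angC)) / 8
    out <- vor
    obtuseA <- angA > pi / 2
    obtuseOther <- (angB > pi / 2) | (angC > pi / 2)
    out[obtuseA] <- tri_area[obtuseA] / 2
    out[!obtuseA & obtuseOther] <- tri_area[!obtuseA & obtuseOther] / 4
    out
  }
  a1 <- mixed_corner(ang1, ang2, ang3, l13, l12)
  a2 <- mixed_corner(ang2, ang3, ang1, l12, l23)
  a3 <- mixed_corner(ang3, ang1, ang2, l23, l13)
  keep <- !degen
  nv <- nrow(V)
  idx <- c(f[keep, 1], f[keep, 2], f[keep, 3])
  angsum <- as.numeric(rowsum(c(ang1[keep], ang2[keep], ang3[keep]), idx,
                              reorder = FALSE))
  areasum <- as.numeric(rowsum(c(a1[keep], a2[keep], a3[keep]), idx,
                               reorder = FALSE))
  vids <- as.integer(rownames(rowsum(matrix(1, length(idx)), idx,
                                     reorder = FALSE)))
  angle_at <- rep(0, nv); area_at <- rep(0, nv)
  angle_at[vids] <- angsum
  area_at[vids] <- areasum
  K <- rep(NA_real_, nv)
  used <- area_at > 1e-12
  K[used] <- (2 * pi - angle_at[used]) / area_at[used]
  bnd <- boundary_vertices(mesh)
  interior <- setdiff(which(used), bnd)
  if (length(interior) == 0L)
    abort("mesh has no interior vertices", "io_error", stage = "hinge_detector")
  fixv <- union(bnd, which(!used))
  if (length(fixv) > 0L) {
    ni <- cpp_nearest_point(V[interior, , drop = FALSE],
                            V[fixv, , drop = FALSE])
    K[fixv] <- K[interior[ni]]
  }
  K
}

#' Gaussian-curvature map on the cylindrical grid
#'
#' Resamples per-vertex Gaussian curvature onto the (slice, angle) grid by
#' nearest-surface-point lookup: each map cell takes the curvature of the
#' mesh vertex closest to its surface position.
#'
#' @param mesh a [surface_mesh()].
#' @param radial_map wall-radius map (defines the grid and surface points).
#' @param cl the matching centerline.
#' @return a [cylindrical_map()] of Gaussian curvature (1/mm^2).
#' @export
gaussian_curvature_map <- function(mesh, radial_map, cl) {
  K <- mesh_gaussian_curvature(mesh)
  ns <- nrow(radial_map$values); na <- ncol(radial_map$values)
  ang <- radial_map$angle_centers
  is <- rep(seq_len(ns), times = na)
  ia <- rep(seq_len(na), each = ns)
  dirs <- cl$frames$u[is, , drop = FALSE] * cos(ang[ia]) +
          cl$frames$v[is, , drop = FALSE] * sin(ang[ia])
  pts <- cl$samples[is, , drop = FALSE] + radial_map$values[cbind(is, ia)] * dirs
  vi <- cpp_nearest_point(mesh$vertices, pts)
  cylindrical_map(matrix(K[vi], ns, na), radial_map$slice_positions, ang,
                  radial_map$valid)
}

#' Minimum / maximum intensity inward-the-wall maps (MIIAM / MXIAM)
#'
#' For every surface cell, the minimum (or maximum) of trilinearly sampled
#' intensities inside a cylinder directed inward from the surface. The
#' low-intensity valve leaflets meeting the wall make the MIIAM dark along
#' the leaflet attachment, while the MXIAM captures bright lumen and
#' calcifications. Out-of-volume cells are invalid and filled with the map
#' median.
#'
#' @param volume an [image_volume()].
#' @param radial_map wall-radius map.
#' @param cl the matching centerline.
#' @param cfg a [hinge_config()].
#' @param mode `"min"` (MIIAM) or `"max"` (MXIAM).
#' @return a [cylindrical_map()].
#' @export
inward_extremum_map <- function(volume, radial_map, cl, cfg = hinge_config(),
                                mode = c("min", "max")) {
  mode <- match.arg(mode)
  cylinder_stat_map(volume, radial_map, cl, cfg$inward_length,
                    cfg$inward_radius, "inward", mode, fill = "median")
}

rescale01 <- function(v, what) {
  rng <- range(v)
  if (diff(rng) < 1e-12) {
    warning(sprintf("%s map is constant; its factor is set to all ones", what))
    return(array(1, dim(v)))
  }
  (v - rng[1]) / diff(rng)
}

#' Combine curvature, MIIAM and MXIAM into a single hinge-evidence map
#'
#' Each factor is first rescaled to `[0, 1]`: curvature has negatives clamped
#' to zero then is divided by its maximum (only convex surface patches count
#' as hinge evidence); the MIIAM is inverted, `(max - v) / (max - min)`, so
#' dark leaflet attachments score high; the MXIAM is min-max rescaled. The
#' combined map is the element-wise product, a `[0, 1]` co-occurrence score
#' of convex geometry and leaflet contact. A constant factor is replaced by
#' all-ones with a warning.
#'
#' @param curv,miiam,mxiam [cylindrical_map()]s on the same grid.
#' @return the combined [cylindrical_map()].
#' @export
combine_maps <- function(curv, miiam, mxiam) {
  stopifnot(all(dim(curv$values) == dim(miiam$values)),
            all(dim(curv$values) == dim(mxiam$values)))
  cv <- pmax(curv$values, 0)
  mx <- max(cv)
  if (mx < 1e-12) {
    warning("curvature map has no positive values; its factor is set to all ones")
    cfac <- array(1, dim(cv))
  } else cfac <- cv / mx
  # rescale the inverted MIIAM directly so the constant-map guard yields an
  # all-ones factor (not an all-zero one)
  mi <- rescale01(max(miiam$values) - miiam$values, "minimum-intensity (MIIAM)")
  ma <- rescale01(mxiam$values, "maximum-intensity (MXIAM)")
  cylindrical_map(cfac * mi * ma, curv$slice_positions, curv$angle_centers,
                  curv$valid & miiam$valid & mxiam$valid)
}

#' Smooth a cylindrical map with a small separable Gaussian
#'
#' Separable Gaussian smoothing, circular along the angle axis and reflected
#' at the proximal/distal ends. Applied to the combined hinge-evidence map
#' before the peak search: the intensity factors carry voxel noise, and an
#' unsmoothed argmax wanders with that noise (and with how the angular bins
#' happen to sample it), while the blurred peak is determined by a
#' neighborhood average.
#'
#' @param map a [cylindrical_map()].
#' @param sigma_cells Gaussian SD in cells (same for both axes).
#' @return the smoothed [cylindrical_map()].
#' @export
smooth_map <- function(map, sigma_cells = 1) {
  stopifnot(inherits(map, "cylindrical_map"))
  v <- map$values
  if (sigma_cells > 0) {
    half <- max(1L, ceiling(3 * sigma_cells))
    k <- exp(-(seq(-half, half))^2 / (2 * sigma_cells^2))
    k <- k / sum(k)
    v <- apply(v, 2L, gaussian_smooth_1d, sigma = sigma_cells)   # along s
    na <- ncol(v)
    idx <- outer(seq_len(na), seq(-half, half), function(a, o) ((a + o - 1L) %% na) + 1L)
    v <- t(vapply(seq_len(nrow(v)), function(i)
      as.numeric(matrix(v[i, idx], nrow = na) %*% k), numeric(na)))
  }
  cylindrical_map(v, map$slice_positions, map$angle_centers, map$valid)
}

#' Split the combined map into three sinus tiles
#'
#' The sinus peak angles are the three maxima of the mean wall-radius profile
#' averaged over slices between the proximal and distal extents; tile
#' boundaries are the angular midpoints between adjacent peaks. Rows are
#' restricted to `[proximal extent - 5 mm, distal extent]` (the hinge points
#' sit at or slightly below the proximal extent). If fewer than three radial
#' maxima are found, tiling falls back to uniform 120-degree sectors anchored
#' at the third-harmonic phase, with a warning.
#'
#' @param combined the [combine_maps()] result.
#' @param radial_map the wall-radius map (for the angular sinus profile).
#' @param extents a [locate_extents()] result.
#' @param profile optional [harmonic_profile()]; used for the fallback
#'   anchor phase.
#' @param proximal_margin extra rows below the proximal extent, mm.
#' @return list of three `sinus_tile` objects, each with `values` (sub-map),
#'   `slice_positions`, `angles` (bin centers, possibly wrapped),
#'   `sector` = c(lo, hi) radians, `peak_angle`, `mean_radius`.
#' @export
split_sinus_tiles <- function(combined, radial_map, extents, profile = NULL,
                              proximal_margin = 5) {
  stopifnot(inherits(combined, "cylindrical_map"),
            inherits(extents, "root_extents"))
  sp <- radial_map$slice_positions
  band <- which(sp >= extents$proximal_mm & sp <= extents$distal_mm)
  rbar <- colMeans(radial_map$values[band, , drop = FALSE])
  na <- length(rbar)
  # light circular smoothing before peak picking
  sm <- (rbar[c(na, 1:(na - 1))] + 2 * rbar + rbar[c(2:na, 1)]) / 4
  cand <- circular_local_maxima(sm)
  ang <- radial_map$angle_centers
  # peaks must be real sinus bulges, not numerical ripple on a circular slice
  if (diff(range(sm)) < 0.1) cand <- integer(0)
  if (length(cand) >= 3L) {
    cand <- cand[order(sm[cand], decreasing = TRUE)][1:3]
    peaks <- sort(wrap_angle(ang[cand]))
  } else {
    warning("fewer than 3 sinus radial maxima; falling back to uniform 120-degree tiles")
    anchor <- 0
    if (!is.null(profile)) {
      ph <- profile$phase3[band]
      ph <- ph[is.finite(ph)]
      if (length(ph) > 0L) {
        # mean direction of the 3-fold phase
        anchor <- wrap_angle(atan2(mean(sin(ph)), mean(cos(ph))) / 3)
      }
    }
    peaks <- sort(wrap_angle(anchor + c(0, 2 * pi / 3, 4 * pi / 3)))
  }
  # boundaries at circular midpoints between adjacent peaks
  bounds <- numeric(3)
  for (k in 1:3) {
    a <- peaks[k]; b <- peaks[(k %% 3) + 1]
    gap <- (b - a) %% (2 * pi)
    bounds[k] <- wrap_angle(a + gap / 2)
  }
  bounds <- sort(bounds)
  rows <- which(sp >= extents$proximal_mm - proximal_margin &
                sp <= extents$distal_mm)
  mk_tile <- function(lo, hi) {
    inside <- if (lo < hi) ang >= lo & ang < hi else ang >= lo | ang < hi
    cols <- which(inside)
    # order columns circularly starting from the sector lower bound
    off <- (ang[cols] - lo) %% (2 * pi)
    cols <- cols[order(off)]
    pk <- peaks[sapply(peaks, function(p) {
      d <- (p - lo) %% (2 * pi); d < ((hi - lo) %% (2 * pi) + (hi == lo) * 2 * pi)
    })]
    structure(list(values = combined$values[rows, cols, drop = FALSE],
                   slice_positions = sp[rows],
                   angles = lo + (ang[cols] - lo) %% (2 * pi),
                   sector = c(lo, hi),
                   peak_angle = if (length(pk)) pk[1] else wrap_angle(lo),
                   mean_radius = mean(radial_map$values[band, cols])),
              class = "sinus_tile")
  }
  tiles <- list(mk_tile(bounds[1], bounds[2]),
                mk_tile(bounds[2], bounds[3]),
                mk_tile(bounds[3], bounds[1]))
  tiles
}

#' @export
print.sinus_tile <- function(x, ...) {
  cat(sprintf("<sinus_tile> sector [%.0f, %.0f) deg, peak %.0f deg, %d x %d cells\n",
              x$sector[1] * 180 / pi, x$sector[2] * 180 / pi,
              x$peak_angle * 180 / pi, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Principal search direction of a sinus tile
#'
#' The tile is binarized at `threshold_fraction` of its maximum; the leading
#' eigenvector of the covariance of above-threshold pixel coordinates (in mm:
#' slice positions along the centerline, angles scaled by the mean sinus
#' radius) is the search direction, with its sign chosen to point proximally.
#' With fewer than 3 above-threshold pixels, or perfectly isotropic pixels,
#' the direction defaults to the proximal axis (with a warning in the former
#' case).
#'
#' @param tile a `sinus_tile`.
#' @param threshold_fraction fraction of the tile maximum, in (0, 1).
#' @return unit 2-vector `(d_slice, d_angle)` in mm-scaled map coordinates.
#' @export
tile_principal_direction <- function(tile, threshold_fraction = 0.5) {
  v <- tile$values
  thr <- threshold_fraction * max(v)
  sel <- which(v >= thr, arr.ind = TRUE)
  if (nrow(sel) < 3L) {
    warning("fewer than 3 above-threshold pixels in sinus tile; using the proximal axis")
    return(c(-1, 0))
  }
  xs <- tile$slice_positions[sel[, 1]]
  ya <- tile$angles[sel[, 2]] * tile$mean_radius
  cc <- cbind(xs, ya)
  cv <- stats::cov(cc)
  eg <- eigen(cv, symmetric = TRUE)
  if (abs(eg$values[1] - eg$values[2]) < 1e-9 * max(eg$values[1], 1e-12))
    return(c(-1, 0))                      # isotropic: documented tie-break
  d <- eg$vectors[, 1]
  if (d[1] > 0) d <- -d                   # proximal = decreasing slice position
  d / sqrt(sum(d^2))
}

#' Locate the hinge point within one sinus tile
#'
#' A line along the tile's principal direction, anchored at the tile's
#' maximum cell, is sampled at `profile_step` (bilinear interpolation of the
#' combined map); the profile's global maximum, refined by 3-point quadratic
#' interpolation, gives the (slice, angle) hinge location, which is mapped
#' back to the 3D surface and snapped to the nearest mesh vertex. (Anchoring
#' at the maximum rather than the thresholded centroid keeps the search line
#' on the hinge when the whole leaflet-attachment crown, whose commissure
#' arms can carry substantial combined score, exceeds the threshold.)
#'
#' @param tile a `sinus_tile`.
#' @param mesh the [surface_mesh()].
#' @param combined the full combined [cylindrical_map()].
#' @param radial_map the wall-radius map.
#' @param cl the matching centerline.
#' @param cfg a [hinge_config()].
#' @param direction optional principal direction; computed from the tile when
#'   missing.
#' @param anchor_max_s optional upper bound (mm) on the slice position of the
#'   anchor cell. The hinge is the basal (proximal) end of the leaflet
#'   attachment, so the pipeline bounds the anchor a few mm above the
#'   proximal extent; without the bound, bright distal structures (the
#'   commissural crown, the sinus belly) can capture the anchor.
#' @return a `hinge_detection`: `point` (3D mm), `label` (NA until
#'   [label_hinges()]), `tile_sector` (deg), `combined_score`.
#' @export
locate_hinge_on_tile <- function(tile, mesh, combined, radial_map, cl,
                                 cfg = hinge_config(), direction = NULL,
                                 anchor_max_s = NULL) {
  v <- tile$values
  if (max(v) - min(v) < 1e-9)
    abort(sprintf("combined map is flat on sinus tile [%.0f, %.0f) deg",
                  tile$sector[1] * 180 / pi, tile$sector[2] * 180 / pi),
          "hinge_detection_failure", stage = "hinge_detector")
  if (is.null(direction))
    direction <- tile_principal_direction(tile, cfg$tile_threshold_fraction)
  v_anchor <- v
  if (!is.null(anchor_max_s) && any(tile$slice_positions <= anchor_max_s))
    v_anchor[tile$slice_positions > anchor_max_s, ] <- -Inf
  amax <- which(v_anchor == max(v_anchor), arr.ind = TRUE)[1, , drop = TRUE]
  cs <- tile$slice_positions[amax[1]]
  ctheta <- tile$angles[amax[2]]
  # sub-bin anchor refinement: a bin-quantized anchor would displace the
  # search line by up to half a bin under a rigid motion of the inputs
  if (amax[1] > 1L && amax[1] < nrow(v)) {
    ds <- quad_refine(v[amax[1] - 1L, amax[2]], v[amax[1], amax[2]],
                      v[amax[1] + 1L, amax[2]])
    cs <- cs + ds * (tile$slice_positions[2L] - tile$slice_positions[1L])
  }
  if (amax[2] > 1L && amax[2] < ncol(v)) {
    da <- quad_refine(v[amax[1], amax[2] - 1L], v[amax[1], amax[2]],
                      v[amax[1], amax[2] + 1L])
    ctheta <- ctheta + da * (tile$angles[2L] - tile$angles[1L])
  }
  r <- tile$mean_radius
  srange <- range(tile$slice_positions)
  span <- sqrt(diff(srange)^2 + (diff(range(tile$angles)) * r)^2)
  tgrid <- seq(-span, span, by = cfg$profile_step)
  ss <- cs + tgrid * direction[1]
  th <- ctheta + tgrid * direction[2] / r
  lo <- tile$sector[1]
  width <- (tile$sector[2] - tile$sector[1]) %% (2 * pi)
  inside <- ss >= srange[1] & ss <= srange[2] &
            ((th - lo) %% (2 * pi)) < width
  if (!any(inside))
    abort("hinge search line leaves the sinus tile", "hinge_detection_failure",
          stage = "hinge_detector")
  prof <- rep(NA_real_, length(tgrid))
  prof[inside] <- map_interp(combined, ss[inside], th[inside])
  if (max(prof, na.rm = TRUE) - min(prof, na.rm = TRUE) < 1e-9)
    abort("flat 1D hinge profile", "hinge_detection_failure",
          stage = "hinge_detector")
  pi_ <- which.max(prof)
  doff <- if (pi_ > 1L && pi_ < length(prof) &&
              is.finite(prof[pi_ - 1L]) && is.finite(prof[pi_ + 1L]))
    quad_refine(prof[pi_ - 1L], prof[pi_], prof[pi_ + 1L]) else 0
  s_hat <- ss[pi_] + doff * cfg$profile_step * direction[1]
  th_hat <- th[pi_] + doff * cfg$profile_step * direction[2] / r
  p <- map_surface_point(radial_map, cl, s_hat, wrap_angle(th_hat))
  vi <- cpp_nearest_point(mesh$vertices, matrix(p, 1L, 3L))[1L]
  structure(list(point = mesh$vertices[vi, ], label = NA_character_,
                 tile_sector = tile$sector * 180 / pi,
                 combined_score = max(prof, na.rm = TRUE)),
            class = "hinge_detection")
}

#' @export
print.hinge_detection <- function(x, ...) {
  cat(sprintf("<hinge_detection> %s, point (%.1f, %.1f, %.1f) mm, score %.3f\n",
              ifelse(is.na(x$label), "unlabeled", x$label),
              x$point[1], x$point[2], x$point[3], x$combined_score))
  invisible(x)
}

#' Label three hinge detections as RC, LC and NC
#'
#' The right-coronary (RC) hinge point is the most anterior (smallest +y in
#' the left/posterior/superior convention); of the remaining two, the
#' left-coronary (LC) is the more posterior-and-left one (largest y + x);
#' the last is non-coronary (NC).
#'
#' @param h1,h2,h3 `hinge_detection` objects.
#' @param ostia optional labeled ostia (unused by the rule, accepted for
#'   interface symmetry / provenance).
#' @return named list with elements `RC`, `LC`, `NC`.
#' @export
label_hinges <- function(h1, h2, h3, ostia = NULL) {
  hs <- list(h1, h2, h3)
  pts <- do.call(rbind, lapply(hs, `[[`, "point"))
  if (min(dist(pts)) < 1e-9)
    abort("coincident hinge detections", "labeling_error",
          stage = "hinge_detector")
  rc_i <- which.min(pts[, 2])
  rest <- setdiff(1:3, rc_i)
  lc_i <- rest[which.max(pts[rest, 2] + pts[rest, 1])]
  nc_i <- setdiff(rest, lc_i)
  hs[[rc_i]]$label <- "RC"; hs[[lc_i]]$label <- "LC"; hs[[nc_i]]$label <- "NC"
  list(RC = hs[[rc_i]], LC = hs[[lc_i]], NC = hs[[nc_i]])
}
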