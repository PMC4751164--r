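#' Run the detection pipeline on files and write its outputs
#'
#' Reads the volume, mesh and centerline, runs [detect_root_landmarks()],
#' and writes `landmarks.json`, `sizing.json` and `sizing.csv` into
#' `out_dir`. Stage failures propagate as classed conditions naming the
#' failing stage (the CLI turns them into a nonzero exit status).
#'
#' @param volume_path volume file (`.nii`, `.nii.gz`, `.mha`, `.mhd`).
#' @param mesh_path mesh file (`.ply`, `.stl`).
#' @param centerline_path centerline file (`.csv`, `.json`).
#' @param out_dir output directory (created if missing).
#' @param control a [root_control()].
#' @param case_id case identifier stored in the landmark JSON.
#' @return the `root_landmarks` object, invisibly.
#' @export
run_detect <- function(volume_path, mesh_path, centerline_path,
                       out_dir = ".", control = root_control(),
                       case_id = NULL) {
  volume <- read_volume(volume_path)
  mesh <- read_mesh(mesh_path)
  centerline <- read_centerline(centerline_path)
  fit <- detect_root_landmarks(volume, mesh, centerline, control)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  lm <- fit$landmarks
  attr(lm, "case_id") <- case_id %||%
    sub("\\.(nii(\\.gz)?|mh[ad])$", "", basename(volume_path))
  write_landmarks(lm, file.path(out_dir, "landmarks.json"))
  write_sizing(fit$sizing, file.path(out_dir, "sizing.json"))
  write_sizing(fit$sizing, file.path(out_dir, "sizing.csv"))
  if (control$debug) {
    write_harmonic_profile(fit$profile,
                           file.path(out_dir, "harmonic_profile.csv"))
    for (nm in setdiff(names(fit$maps), "tiles"))
      write.csv(fit$maps[[nm]]$values,
                file.path(out_dir, sprintf("map_%s.csv", nm)),
                row.names = FALSE)
  }
  invisible(fit)
}

#' Generate and write a phantom bundle (or suite)
#'
#' Writes, for each phantom, `volume.nii.gz`, `mesh.ply`, `centerline.csv`,
#' `landmarks_truth.json` and a `manifest.json` recording the spec and seed.
#' With `n > 1` the phantoms go into subdirectories `phantom_01`, ... and the
#' specs are jittered with [phantom_suite()].
#'
#' @param out_dir output directory.
#' @param spec base [phantom_spec()].
#' @param seed suite seed (also the noise seed for `n = 1`).
#' @param n number of phantoms.
#' @return character vector of phantom directories, invisibly.
#' @export
run_phantom <- function(out_dir, spec = phantom_spec(), seed = 1L, n = 1L) {
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    abort(sprintf("cannot create output directory: %s", out_dir), "io_error")
  specs <- if (n > 1L) phantom_suite(n, spec, seed) else {
    spec$seed <- as.integer(seed); list(spec)
  }
  dirs <- character(n)
  for (i in seq_len(n)) {
    d <- if (n > 1L) file.path(out_dir, sprintf("phantom_%02d", i)) else out_dir
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    ph <- generate_phantom(specs[[i]])
    write_volume(ph$volume, file.path(d, "volume.nii.gz"))
    write_mesh(ph$mesh, file.path(d, "mesh.ply"))
    write_centerline(ph$centerline, file.path(d, "centerline.csv"))
    write_landmarks(ph$landmarks, file.path(d, "landmarks_truth.json"))
    manifest <- specs[[i]]
    manifest$hinge_points <- NULL
    writeLines(jsonlite::toJSON(
      list(spec = unclass(manifest), suite_seed = seed),
      digits = NA, auto_unbox = TRUE, pretty = TRUE, null = "null"),
      file.path(d, "manifest.json"))
    dirs[i] <- d
  }
  invisible(dirs)
}

#' Evaluate predicted landmark files against reference files
#'
#' Pairs prediction and reference landmark JSON files by case id, computes
#' the paired landmark error table, and writes `landmark_errors.csv`
#' (summary), `landmark_errors_long.csv` (per case and landmark, box-whisker
#' ready). When per-case sizing values can be derived (all six landmarks
#' present), Bland-Altman and ICC(2,1) agreement statistics for the annulus
#' radius and the pooled annulus-to-ostium distances are written to
#' `agreement.csv` (>= 3 cases required for the ICC).
#'
#' @param pred_paths character vector of predicted landmark JSON files.
#' @param ref_paths character vector of reference landmark JSON files.
#' @param out_dir output directory.
#' @return the [landmark_errors()] object, invisibly.
#' @export
run_evaluate <- function(pred_paths, ref_paths, out_dir = ".") {
  preds <- lapply(pred_paths, read_landmarks)
  refs <- lapply(ref_paths, read_landmarks)
  id_of <- function(l, i) attr(l, "case_id") %||% sprintf("case_%d", i)
  pids <- vapply(seq_along(preds), function(i) id_of(preds[[i]], i), "")
  rids <- vapply(seq_along(refs), function(i) id_of(refs[[i]], i), "")
  if (!setequal(pids, rids) || anyDuplicated(pids) || anyDuplicated(rids)) {
    unmatched <- union(setdiff(pids, rids), setdiff(rids, pids))
    abort(sprintf("case ids do not pair up; unmatched: %s",
                  paste(unmatched, collapse = ", ")),
          "pairing_error", stage = "evaluation")
  }
  refs <- refs[match(pids, rids)]
  errs <- landmark_errors(preds, refs)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(errs$table, file.path(out_dir, "landmark_errors.csv"),
            row.names = FALSE)
  write.csv(errs$distances, file.path(out_dir, "landmark_errors_long.csv"),
            row.names = FALSE)

  sizing_of <- function(l) tryCatch(compute_sizing(l), error = function(e) NULL)
  sp <- lapply(preds, sizing_of)
  sr <- lapply(refs, sizing_of)
  ok <- !vapply(sp, is.null, TRUE) & !vapply(sr, is.null, TRUE)
  if (sum(ok) >= 2L) {
    get <- function(lst, f) vapply(lst[ok], function(x) x[[f]], 0)
    rows <- list()
    add <- function(measure, x, y) {
      ba <- bland_altman(x, y)
      rows[[length(rows) + 1L]] <<- data.frame(
        measure = measure, n = ba$n, mean_diff = ba$mean_diff,
        sd_diff = ba$sd_diff, loa_lower = ba$loa_lower,
        loa_upper = ba$loa_upper,
        icc = if (length(x) >= 3L && sd(c(x, y)) > 1e-12) icc(x, y)
              else NA_real_)
    }
    add("annulus_radius", get(sp, "annulus_radius"), get(sr, "annulus_radius"))
    add("annulus_to_ostium_pooled",
        c(get(sp, "dist_annulus_to_right_ostium"),
          get(sp, "dist_annulus_to_left_ostium")),
        c(get(sr, "dist_annulus_to_right_ostium"),
          get(sr, "dist_annulus_to_left_ostium")))
    add("annulus_to_right_ostium", get(sp, "dist_annulus_to_right_ostium"),
        get(sr, "dist_annulus_to_right_ostium"))
    add("annulus_to_left_ostium", get(sp, "dist_annulus_to_left_ostium"),
        get(sr, "dist_annulus_to_left_ostium"))
    write.csv(do.call(rbind, rows), file.path(out_dir, "agreement.csv"),
              row.names = FALSE)
  }
  invisible(errs)
}
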