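#' Triangulated surface mesh
#'
#' Container for the segmented aortic-root wall: a triangle mesh, open at the
#' proximal (LVOT) and distal (ascending aorta) ends, vertices in patient
#' millimeters.
#'
#' @param vertices n x 3 numeric matrix of vertex positions (mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- as_point_matrix(vertices, "vertices")
  faces <- as.matrix(faces)
  if (ncol(faces) != 3L) abort("'faces' must be an m x 3 index matrix", "io_error")
  storage.mode(faces) <- "integer"
  if (min(faces) < 1L || max(faces) > nrow(vertices))
    abort("face indices out of range", "io_error")
  structure(list(vertices = vertices, faces = unname(faces)),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$faces)))
  rng <- apply(x$vertices, 2L, range)
  cat(sprintf("  bounds x [%.1f, %.1f]  y [%.1f, %.1f]  z [%.1f, %.1f] mm\n",
              rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  invisible(x)
}

# Indices of vertices lying on an open boundary (edges used by one face only).
boundary_vertices <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  once <- names(which(table(key) == 1L))
  if (length(once) == 0L) return(integer(0))
  unique(as.integer(unlist(strsplit(once, " "))))
}

#' Read / write triangle meshes (ASCII PLY and STL)
#'
#' @param path file path ending in `.ply` or `.stl` (ASCII variants).
#' @return `read_mesh` returns a [surface_mesh()]; `write_mesh` returns
#'   `path` invisibly. STL stores no connectivity, so `read_mesh` on STL
#'   merges coincident vertices.
#' @export
read_mesh <- function(path) {
  if (!file.exists(path))
    abort(sprintf("mesh file not found: %s", path), "io_error")
  lp <- tolower(path)
  if (grepl("\\.ply$", lp)) read_ply(path)
  else if (grepl("\\.stl$", lp)) read_stl(path)
  else abort(sprintf("unsupported mesh format: %s (expected .ply/.stl)", path),
             "io_error")
}

#' @rdname read_mesh
#' @param mesh a [surface_mesh()].
#' @export
write_mesh <- function(mesh, path) {
  stopifnot(inherits(mesh, "surface_mesh"))
  lp <- tolower(path)
  if (grepl("\\.ply$", lp)) write_ply(mesh, path)
  else if (grepl("\\.stl$", lp)) write_stl(mesh, path)
  else abort(sprintf("unsupported mesh format: %s", path), "io_error")
  invisible(path)
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L || trimws(lines[1]) != "ply" ||
      !grepl("^format\\s+ascii", lines[2]))
    abort(sprintf("not an ASCII PLY file: %s", path), "io_error")
  endh <- match("end_header", trimws(lines))
  if (is.na(endh)) abort(sprintf("PLY header not terminated: %s", path), "io_error")
  nv <- as.integer(sub("^element vertex\\s+", "",
                       grep("^element vertex", lines[1:endh], value = TRUE)[1]))
  nf <- as.integer(sub("^element face\\s+", "",
                       grep("^element face", lines[1:endh], value = TRUE)[1]))
  vl <- lines[(endh + 1):(endh + nv)]
  v <- matrix(scan(text = vl, quiet = TRUE), nrow = nv, byrow = TRUE)[, 1:3, drop = FALSE]
  fl <- lines[(endh + nv + 1):(endh + nv + nf)]
  f <- matrix(scan(text = fl, quiet = TRUE), nrow = nf, byrow = TRUE)
  if (any(f[, 1] != 3)) abort("PLY contains non-triangle faces", "io_error")
  surface_mesh(v, f[, 2:4, drop = FALSE] + 1L)
}

write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(mesh$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(apply(format(mesh$vertices, digits = 10, trim = TRUE,
                          scientific = FALSE), 1L, paste, collapse = " "), con)
  writeLines(paste(3L, mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                   mesh$faces[, 3] - 1L), con)
  invisible(path)
}

read_stl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!grepl("^\\s*solid", lines[1]))
    abort(sprintf("not an ASCII STL file: %s", path), "io_error")
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  v <- matrix(scan(text = sub("^\\s*vertex\\s+", "", vl), quiet = TRUE),
              ncol = 3L, byrow = TRUE)
  if (nrow(v) %% 3L != 0L) abort("malformed STL vertex list", "io_error")
  key <- apply(round(v, 6L), 1L, paste, collapse = ",")
  uk <- !duplicated(key)
  idx <- match(key, key[uk])
  verts <- v[uk, , drop = FALSE]
  faces <- matrix(idx, ncol = 3L, byrow = TRUE)
  surface_mesh(verts, faces)
}

write_stl <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid aorticroot", con)
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  e1 <- p2 - p1; e2 <- p3 - p1
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2)); len[len < 1e-12] <- 1
  n <- n / len
  fmt <- function(m) apply(format(m, digits = 10, trim = TRUE, scientific = FALSE),
                           1L, paste, collapse = " ")
  writeLines(paste0("  facet normal ", fmt(n), "\n    outer loop\n      vertex ",
                    fmt(p1), "\n      vertex ", fmt(p2), "\n      vertex ",
                    fmt(p3), "\n    endloop\n  endfacet"), con)
  writeLines("endsolid aorticroot", con)
  invisible(path)
}
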