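#' 3D scalar image volume in patient coordinates
#'
#' A thin container for a 3D scalar grid (Hounsfield-unit-like intensities)
#' with voxel spacing, origin and axis orientation. The world position of
#' 0-based voxel index `(i, j, k)` is
#' `origin + direction %*% (spacing * c(i, j, k))`, so anisotropic and
#' obliquely oriented volumes are supported without resampling.
#'
#' @param data numeric 3D array of intensities.
#' @param spacing voxel spacing in mm, length 3, all positive.
#' @param origin world position (mm) of voxel `(0, 0, 0)`.
#' @param direction 3x3 orthonormal direction matrix (columns = world
#'   directions of the voxel axes).
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         direction = diag(3)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    abort("'data' must be a 3D array", "io_error")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    abort("'spacing' must be 3 positive mm values", "io_error")
  direction <- unname(as.matrix(direction))
  if (!all(dim(direction) == c(3L, 3L)) ||
      max(abs(crossprod(direction) - diag(3))) > 1e-6)
    abort("'direction' must be a 3x3 orthonormal matrix", "io_error")
  storage.mode(data) <- "double"
  structure(list(data = data, spacing = spacing,
                 origin = as.numeric(origin), direction = direction),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (%.2f, %.2f, %.2f) mm, intensity range [%.1f, %.1f]\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$data)

#' Trilinear interpolation of a volume at world points
#'
#' Samples the volume at arbitrary world positions (mm) by trilinear
#' interpolation. Points outside the voxel lattice return `NA`.
#'
#' @param volume an [image_volume()].
#' @param points n x 3 matrix of world positions (mm).
#' @return numeric vector of length n (NA outside the volume).
#' @export
sample_volume <- function(volume, points) {
  pts <- as_point_matrix(points)
  dm <- dim(volume$data)
  # world -> continuous 0-based voxel index
  q <- sweep(pts, 2L, volume$origin) %*% volume$direction  # direction orthonormal: t(D)^-1 = D
  q <- sweep(q, 2L, volume$spacing, "/")
  out <- rep(NA_real_, nrow(q))
  eps <- 1e-9
  ok <- q[, 1] >= -eps & q[, 1] <= dm[1] - 1 + eps &
        q[, 2] >= -eps & q[, 2] <= dm[2] - 1 + eps &
        q[, 3] >= -eps & q[, 3] <= dm[3] - 1 + eps
  if (!any(ok)) return(out)
  q <- q[ok, , drop = FALSE]
  i0 <- pmin(pmax(floor(q[, 1]), 0), dm[1] - 2)
  j0 <- pmin(pmax(floor(q[, 2]), 0), dm[2] - 2)
  k0 <- pmin(pmax(floor(q[, 3]), 0), dm[3] - 2)
  fx <- q[, 1] - i0; fy <- q[, 2] - j0; fz <- q[, 3] - k0
  nx <- dm[1]; nxy <- dm[1] * dm[2]
  base <- 1 + i0 + nx * j0 + nxy * k0
  v <- volume$data
  v000 <- v[base];            v100 <- v[base + 1]
  v010 <- v[base + nx];       v110 <- v[base + nx + 1]
  v001 <- v[base + nxy];      v101 <- v[base + nxy + 1]
  v011 <- v[base + nx + nxy]; v111 <- v[base + nx + nxy + 1]
  out[ok] <-
    v000 * (1 - fx) * (1 - fy) * (1 - fz) + v100 * fx * (1 - fy) * (1 - fz) +
    v010 * (1 - fx) * fy * (1 - fz)       + v110 * fx * fy * (1 - fz) +
    v001 * (1 - fx) * (1 - fy) * fz       + v101 * fx * (1 - fy) * fz +
    v011 * (1 - fx) * fy * fz             + v111 * fx * fy * fz
  out
}

#' Read / write image volumes (NIfTI and MetaImage)
#'
#' Dispatches on the file extension: `.nii` / `.nii.gz` are handled with the
#' RNifti package (the full sform affine is preserved), `.mha` / `.mhd` with a
#' minimal built-in uncompressed MetaImage reader/writer.
#'
#' @param path file path.
#' @return [image_volume()] for `read_volume`; `write_volume` returns `path`
#'   invisibly.
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    abort(sprintf("volume file not found: %s", path), "io_error")
  lp <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lp)) {
    img <- RNifti::readNifti(path)
    aff <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
    m <- aff[1:3, 1:3]
    spacing <- sqrt(colSums(m^2))
    arr <- as.array(img)
    attributes(arr) <- list(dim = dim(arr))     # drop RNifti metadata
    image_volume(arr, spacing = spacing, origin = aff[1:3, 4],
                 direction = sweep(m, 2L, spacing, "/"))
  } else if (grepl("\\.mh[ad]$", lp)) {
    read_metaimage(path)
  } else {
    abort(sprintf("unsupported volume format: %s (expected .nii/.nii.gz/.mha/.mhd)",
                  path), "io_error")
  }
}

#' @rdname read_volume
#' @param volume an [image_volume()].
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "image_volume"))
  lp <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lp)) {
    img <- RNifti::asNifti(volume$data)
    aff <- rbind(cbind(volume$direction %*% diag(volume$spacing), volume$origin),
                 c(0, 0, 0, 1))
    RNifti::`sform<-`(img, structure(aff, code = 2L)) -> img
    RNifti::writeNifti(img, path)
  } else if (grepl("\\.mh[ad]$", lp)) {
    write_metaimage(volume, path)
  } else {
    abort(sprintf("unsupported volume format: %s", path), "io_error")
  }
  invisible(path)
}

# Minimal uncompressed MetaImage (.mha, local-data .mhd) support.
read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L)
      abort(sprintf("truncated MetaImage header: %s", path), "io_error")
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    hdr[[key]] <- trimws(paste(kv[-1], collapse = "="))
    if (key == "ElementDataFile") break
  }
  if (!identical(hdr[["ElementDataFile"]], "LOCAL"))
    abort("only LOCAL ElementDataFile MetaImage is supported", "io_error")
  if (isTRUE(toupper(hdr[["CompressedData"]]) == "TRUE"))
    abort("compressed MetaImage is not supported", "io_error")
  dims <- as.integer(strsplit(hdr[["DimSize"]], "\\s+")[[1]])
  spacing <- if (!is.null(hdr[["ElementSpacing"]]))
    as.numeric(strsplit(hdr[["ElementSpacing"]], "\\s+")[[1]]) else rep(1, 3)
  origin <- if (!is.null(hdr[["Offset"]]))
    as.numeric(strsplit(hdr[["Offset"]], "\\s+")[[1]]) else rep(0, 3)
  direction <- if (!is.null(hdr[["TransformMatrix"]]))
    matrix(as.numeric(strsplit(hdr[["TransformMatrix"]], "\\s+")[[1]]), 3, 3)
  else diag(3)
  type <- hdr[["ElementType"]]
  n <- prod(dims)
  raw_data <- switch(type,
    "MET_FLOAT"  = readBin(con, "numeric", n = n, size = 4L, endian = "little"),
    "MET_DOUBLE" = readBin(con, "numeric", n = n, size = 8L, endian = "little"),
    "MET_SHORT"  = readBin(con, "integer", n = n, size = 2L, signed = TRUE,
                           endian = "little"),
    "MET_UCHAR"  = readBin(con, "integer", n = n, size = 1L, signed = FALSE,
                           endian = "little"),
    abort(sprintf("unsupported MetaImage ElementType: %s", type), "io_error"))
  image_volume(array(as.double(raw_data), dims), spacing = spacing,
               origin = origin, direction = direction)
}

write_metaimage <- function(volume, path) {
  dims <- dim(volume$data)
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    sprintf("TransformMatrix = %s",
            paste(format(as.vector(volume$direction), digits = 17), collapse = " ")),
    sprintf("Offset = %s",
            paste(format(volume$origin, digits = 17), collapse = " ")),
    sprintf("ElementSpacing = %s",
            paste(format(volume$spacing, digits = 17), collapse = " ")),
    sprintf("DimSize = %d %d %d", dims[1], dims[2], dims[3]),
    "ElementType = MET_FLOAT",
    "ElementDataFile = LOCAL")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  writeBin(as.numeric(volume$data), con, size = 4L, endian = "little")
  invisible(path)
}
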