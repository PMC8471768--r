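#' 3D scalar volume with physical spacing and origin
#'
#' Container for a CT-like image: a 3D intensity array plus the voxel spacing
#' (mm) and the world position of the first voxel (mm). All tracking and
#' evaluation code works in world millimetres; voxel indices appear only
#' inside interpolation.
#'
#' @param data 3D numeric array of intensities (HU-like).
#' @param spacing numeric length-3, mm per voxel along each axis; all > 0.
#' @param origin numeric length-3, world coordinates (mm) of voxel (1,1,1).
#' @return A `volume_image` object (list with `data`, `spacing`, `origin`).
#' @examples
#' v <- volume_image(array(0, c(8, 8, 8)), spacing = c(0.5, 0.5, 0.5))
#' dim(v$data)
#' @export
volume_image <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3D array", call. = FALSE)
  }
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be 3 positive values (mm/voxel)", call. = FALSE)
  }
  if (length(origin) != 3L || any(!is.finite(origin))) {
    stop("`origin` must be 3 finite values (mm)", call. = FALSE)
  }
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<volume_image> %d x %d x %d voxels, spacing (%g, %g, %g) mm, origin (%g, %g, %g) mm\n",
    d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
    x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  intensity range [%g, %g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' Convert between world (mm) and voxel coordinates
#'
#' Voxel coordinates are 1-based continuous indices: voxel (1,1,1) sits at
#' the world origin. The two transforms are exact inverses.
#'
#' @param vol a [volume_image()].
#' @param pts numeric matrix (n x 3) or length-3 vector of coordinates.
#' @return An n x 3 matrix of transformed coordinates.
#' @export
world_to_voxel <- function(vol, pts) {
  pts <- as_point_matrix(pts)
  sweep(sweep(pts, 2, vol$origin, "-"), 2, vol$spacing, "/") + 1
}

#' @rdname world_to_voxel
#' @export
voxel_to_world <- function(vol, pts) {
  pts <- as_point_matrix(pts)
  sweep(sweep(pts - 1, 2, vol$spacing, "*"), 2, vol$origin, "+")
}

as_point_matrix <- function(pts) {
  if (is.null(dim(pts))) {
    if (length(pts) != 3L) stop("points must have 3 coordinates", call. = FALSE)
    pts <- matrix(as.numeric(pts), nrow = 1L)
  }
  storage.mode(pts) <- "double"
  if (ncol(pts) != 3L) stop("points must be n x 3", call. = FALSE)
  pts
}

#' World-coordinate extent of a volume
#'
#' @param vol a [volume_image()].
#' @return 2 x 3 matrix: first row the minimum corner, second the maximum
#'   corner (voxel centres), in mm.
#' @export
volume_bounds <- function(vol) {
  d <- dim(vol$data)
  rbind(vol$origin, vol$origin + (d - 1) * vol$spacing)
}

#' Test whether world points fall inside a volume
#'
#' @inheritParams world_to_voxel
#' @return logical vector, one per point.
#' @export
in_volume <- function(vol, pts) {
  vx <- world_to_voxel(vol, pts)
  d <- dim(vol$data)
  vx[, 1] >= 1 & vx[, 1] <= d[1] &
    vx[, 2] >= 1 & vx[, 2] <= d[2] &
    vx[, 3] >= 1 & vx[, 3] <= d[3]
}

#' Trilinear interpolation of a volume at world points
#'
#' Points outside the voxel-centre grid take `fill` (by default the volume
#' minimum, an air-like value), so sampling near borders degrades gracefully
#' instead of failing.
#'
#' @inheritParams world_to_voxel
#' @param fill intensity for out-of-volume samples; defaults to `min(vol$data)`.
#' @return numeric vector of interpolated intensities, one per point.
#' @export
interp_volume <- function(vol, pts, fill = NULL) {
  if (is.null(fill)) fill <- min(vol$data)
  vx <- world_to_voxel(vol, pts)
  d <- dim(vol$data)
  n <- nrow(vx)

  inside <- vx[, 1] >= 1 & vx[, 1] <= d[1] &
    vx[, 2] >= 1 & vx[, 2] <= d[2] &
    vx[, 3] >= 1 & vx[, 3] <= d[3]
  out <- rep(fill, n)
  if (!any(inside)) return(out)

  v <- vx[inside, , drop = FALSE]
  i0 <- pmin(pmax(floor(v[, 1]), 1), d[1] - 1L)
  j0 <- pmin(pmax(floor(v[, 2]), 1), d[2] - 1L)
  k0 <- pmin(pmax(floor(v[, 3]), 1), d[3] - 1L)
  fx <- v[, 1] - i0; fy <- v[, 2] - j0; fz <- v[, 3] - k0

  # flat indices of the 8 cell corners
  base <- (i0 - 1) + d[1] * (j0 - 1) + d[1] * d[2] * (k0 - 1) + 1
  dx <- 1; dy <- d[1]; dz <- d[1] * d[2]
  a <- vol$data
  c000 <- a[base];               c100 <- a[base + dx]
  c010 <- a[base + dy];          c110 <- a[base + dx + dy]
  c001 <- a[base + dz];          c101 <- a[base + dx + dz]
  c011 <- a[base + dy + dz];     c111 <- a[base + dx + dy + dz]

  c00 <- c000 * (1 - fx) + c100 * fx
  c10 <- c010 * (1 - fx) + c110 * fx
  c01 <- c001 * (1 - fx) + c101 * fx
  c11 <- c011 * (1 - fx) + c111 * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  out[inside] <- c0 * (1 - fz) + c1 * fz
  out
}

# ---- MetaImage (.mhd/.raw) -------------------------------------------------
# Minimal MetaImage support: plain-text key = value header plus a raw binary
# payload in a sidecar file (or LOCAL). Little-endian only on write.

mhd_types <- c(
  MET_UCHAR = 1L, MET_CHAR = 1L, MET_SHORT = 2L, MET_USHORT = 2L,
  MET_INT = 4L, MET_UINT = 4L, MET_FLOAT = 4L, MET_DOUBLE = 8L
)

read_mhd_header <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  kv <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  if (any(lengths(kv) != 2L)) {
    stop("malformed MetaImage header: ", path, call. = FALSE)
  }
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, `[`, "", 2L))
  stats::setNames(as.list(vals), keys)
}

read_volume_mhd <- function(path) {
  h <- read_mhd_header(path)
  need <- c("NDims", "DimSize", "ElementType", "ElementDataFile")
  if (!all(need %in% names(h))) {
    stop("MetaImage header missing required fields: ", path, call. = FALSE)
  }
  if (as.integer(h$NDims) != 3L) {
    stop("only 3D MetaImage volumes are supported: ", path, call. = FALSE)
  }
  dims <- as.integer(strsplit(h$DimSize, "\\s+")[[1]])
  spacing <- if (!is.null(h$ElementSpacing)) {
    as.numeric(strsplit(h$ElementSpacing, "\\s+")[[1]])
  } else c(1, 1, 1)
  origin <- if (!is.null(h$Offset)) {
    as.numeric(strsplit(h$Offset, "\\s+")[[1]])
  } else c(0, 0, 0)
  type <- h$ElementType
  if (!type %in% names(mhd_types)) {
    stop("unsupported MetaImage ElementType '", type, "': ", path, call. = FALSE)
  }
  msb <- identical(h$BinaryDataByteOrderMSB, "True") ||
    identical(h$ElementByteOrderMSB, "True")
  endian <- if (msb) "big" else "little"

  datafile <- h$ElementDataFile
  raw_path <- if (identical(datafile, "LOCAL")) path else {
    file.path(dirname(path), datafile)
  }
  if (!file.exists(raw_path)) {
    stop("MetaImage payload not found: ", raw_path, call. = FALSE)
  }
  n <- prod(dims)
  size <- mhd_types[[type]]
  what <- switch(type,
    MET_FLOAT = "numeric", MET_DOUBLE = "numeric", "integer")
  signed <- !type %in% c("MET_UCHAR", "MET_USHORT", "MET_UINT")
  con <- file(raw_path, "rb")
  on.exit(close(con))
  if (identical(datafile, "LOCAL")) {
    # header and payload share the file; payload is the trailing n*size bytes
    sz <- file.info(raw_path)$size
    seek(con, where = sz - n * size)
  }
  vals <- readBin(con, what = what, n = n, size = size,
                  signed = signed, endian = endian)
  if (length(vals) < n) {
    stop("truncated MetaImage payload (expected ", n, " values, got ",
         length(vals), "): ", raw_path, call. = FALSE)
  }
  volume_image(array(as.double(vals), dims), spacing, origin)
}

write_volume_mhd <- function(vol, path) {
  stopifnot(inherits(vol, "volume_image"))
  raw_name <- paste0(sub("\\.mhd$", "", basename(path)), ".raw")
  d <- dim(vol$data)
  header <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    sprintf("DimSize = %d %d %d", d[1], d[2], d[3]),
    sprintf("ElementSpacing = %.9g %.9g %.9g",
            vol$spacing[1], vol$spacing[2], vol$spacing[3]),
    sprintf("Offset = %.9g %.9g %.9g",
            vol$origin[1], vol$origin[2], vol$origin[3]),
    "ElementType = MET_FLOAT",
    sprintf("ElementDataFile = %s", raw_name)
  )
  writeLines(header, path)
  con <- file(file.path(dirname(path), raw_name), "wb")
  on.exit(close(con))
  writeBin(as.numeric(vol$data), con, size = 4L, endian = "little")
  invisible(NULL)
}

# ---- NIfTI -----------------------------------------------------------------

read_volume_nii <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) {
    stop("only 3D NIfTI volumes are supported: ", path, call. = FALSE)
  }
  spacing <- abs(as.numeric(attr(img, "pixdim")[seq_len(3)]))
  origin <- as.numeric(RNifti::xform(img)[1:3, 4])
  volume_image(array(as.double(arr), dim(arr)), spacing, origin)
}

write_volume_nii <- function(vol, path) {
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  mat <- diag(4)
  diag(mat)[1:3] <- vol$spacing
  mat[1:3, 4] <- vol$origin
  img <- RNifti::`qform<-`(img, structure(mat, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(NULL)
}

#' Read a 3D volume from MetaImage or NIfTI
#'
#' Spacing and origin come from the file header; intensities are returned
#' unmodified as doubles.
#'
#' @param path path to a `.mhd` (MetaImage) or `.nii`/`.nii.gz` (NIfTI) file.
#' @return A [volume_image()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (grepl("\\.mhd$", path, ignore.case = TRUE)) {
    read_volume_mhd(path)
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    read_volume_nii(path)
  } else {
    stop("unsupported volume format (expect .mhd or .nii[.gz]): ", path,
         call. = FALSE)
  }
}

#' Write a 3D volume as MetaImage or NIfTI
#'
#' MetaImage output is a `.mhd` text header plus a little-endian `.raw`
#' float payload; NIfTI output stores spacing in `pixdim` and origin in the
#' qform. Both round-trip through [read_volume()].
#'
#' @param vol a [volume_image()].
#' @param path destination; format chosen by extension.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume_image"))
  if (grepl("\\.mhd$", path, ignore.case = TRUE)) {
    write_volume_mhd(vol, path)
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    write_volume_nii(vol, path)
  } else {
    stop("unsupported volume format (expect .mhd or .nii[.gz]): ", path,
         call. = FALSE)
  }
}
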