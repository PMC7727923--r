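#' 3-D image volume with grid geometry
#'
#' The basic spatial container of the package: a 3-D numeric array (HU,
#' density, ventilation, counts or a binary mask) together with its voxel
#' spacing and world-space origin. World coordinates are voxel centers:
#' the voxel with 0-based index `(i, j, k)` is centered at
#' `origin + c(i, j, k) * spacing` (millimetres).
#'
#' @param data numeric or logical 3-D array.
#' @param spacing positive numeric triple, voxel edge lengths in mm.
#' @param origin numeric triple, world coordinate of the first voxel center.
#' @return an object of class `image_volume` (a list with elements `data`,
#'   `spacing`, `origin`).
#' @export
image_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L)
    stop("'data' must be a 3-D array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be a positive numeric triple")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("'origin' must be a finite numeric triple")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "image_volume")
}

#' Displacement field on the target grid
#'
#' Stores the inverse transformation phi^-1 sampled at target voxel centers,
#' as world-mm offsets `u`: `phi^-1(x) = x + u(x)`. The data array has a
#' trailing dimension of length 3 (x, y, z components).
#'
#' @param data numeric 4-D array, dims `c(nx, ny, nz, 3)`.
#' @inheritParams image_volume
#' @return an object of class `displacement_field`.
#' @export
displacement_field <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  d <- dim(data)
  if (length(d) != 4L || d[4] != 3L)
    stop("'data' must be a 4-D array with 3 components in the last dimension")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("'spacing' must be a positive numeric triple")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "displacement_field")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_volume> %d x %d x %d, spacing %s mm, origin %s mm\n",
              d[1], d[2], d[3],
              paste(signif(x$spacing, 4), collapse = " x "),
              paste(signif(x$origin, 4), collapse = ", ")))
  v <- x$data[is.finite(x$data)]
  if (length(v))
    cat(sprintf("  range [%.4g, %.4g]\n", min(v), max(v)))
  invisible(x)
}

#' @export
print.displacement_field <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<displacement_field> %d x %d x %d (3 components), spacing %s mm\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x ")))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$data)

grid_geometry <- function(vol) {
  list(dims = dim(vol$data)[1:3], spacing = vol$spacing, origin = vol$origin)
}

same_grid <- function(a, b, tol = 1e-6) {
  all(dim(a$data)[1:3] == dim(b$data)[1:3]) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol
}

stopifnot_same_grid <- function(a, b, what = "volumes") {
  if (!same_grid(a, b))
    stop(sprintf("grid geometry mismatch between %s", what))
  invisible(TRUE)
}

#' Per-axis voxel-center coordinates
#'
#' @param vol an `image_volume` or `displacement_field`.
#' @param axis 1, 2 or 3.
#' @return numeric vector of world coordinates of voxel centers along `axis`.
#' @export
voxel_centers <- function(vol, axis) {
  n <- dim(vol$data)[axis]
  vol$origin[axis] + (seq_len(n) - 1) * vol$spacing[axis]
}

# world coordinates of every voxel center as an n x 3 matrix (column-major
# voxel order, matching which() on the data array)
world_coordinate_matrix <- function(geom, lin = NULL) {
  d <- geom$dims
  if (is.null(lin)) lin <- seq_len(prod(d))
  lin0 <- lin - 1L
  i <- lin0 %% d[1]
  j <- (lin0 %/% d[1]) %% d[2]
  k <- lin0 %/% (d[1] * d[2])
  cbind(geom$origin[1] + i * geom$spacing[1],
        geom$origin[2] + j * geom$spacing[2],
        geom$origin[3] + k * geom$spacing[3])
}

# nearest-voxel 1-based linear index for world points; NA when the point
# falls outside the grid
world_to_nearest_linear <- function(geom, xyz) {
  d <- geom$dims
  i <- as.integer(round((xyz[, 1] - geom$origin[1]) / geom$spacing[1]))
  j <- as.integer(round((xyz[, 2] - geom$origin[2]) / geom$spacing[2]))
  k <- as.integer(round((xyz[, 3] - geom$origin[3]) / geom$spacing[3]))
  ok <- i >= 0L & i < d[1] & j >= 0L & j < d[2] & k >= 0L & k < d[3]
  lin <- rep(NA_integer_, nrow(xyz))
  lin[ok] <- 1L + i[ok] + d[1] * (j[ok] + d[2] * k[ok])
  lin
}

# trilinear interpolation of a 3-D array at world points; NA outside the
# convex hull of voxel centers
trilinear_sample <- function(vol, xyz) {
  d <- dim(vol$data)
  fx <- (xyz[, 1] - vol$origin[1]) / vol$spacing[1]
  fy <- (xyz[, 2] - vol$origin[2]) / vol$spacing[2]
  fz <- (xyz[, 3] - vol$origin[3]) / vol$spacing[3]
  out <- rep(NA_real_, nrow(xyz))
  ok <- fx >= 0 & fx <= d[1] - 1 & fy >= 0 & fy <= d[2] - 1 &
    fz >= 0 & fz <= d[3] - 1
  if (!any(ok)) return(out)
  fx <- fx[ok]; fy <- fy[ok]; fz <- fz[ok]
  i0 <- pmin(floor(fx), d[1] - 2); i0 <- pmax(i0, 0)
  j0 <- pmin(floor(fy), d[2] - 2); j0 <- pmax(j0, 0)
  k0 <- pmin(floor(fz), d[3] - 2); k0 <- pmax(k0, 0)
  tx <- fx - i0; ty <- fy - j0; tz <- fz - k0
  base <- 1L + i0 + d[1] * (j0 + d[2] * k0)
  sx <- 1L; sy <- d[1]; sz <- d[1] * d[2]
  a <- vol$data
  v000 <- a[base];                 v100 <- a[base + sx]
  v010 <- a[base + sy];            v110 <- a[base + sx + sy]
  v001 <- a[base + sz];            v101 <- a[base + sx + sz]
  v011 <- a[base + sy + sz];       v111 <- a[base + sx + sy + sz]
  out[ok] <-
    v000 * (1 - tx) * (1 - ty) * (1 - tz) + v100 * tx * (1 - ty) * (1 - tz) +
    v010 * (1 - tx) * ty * (1 - tz)       + v110 * tx * ty * (1 - tz) +
    v001 * (1 - tx) * (1 - ty) * tz       + v101 * tx * (1 - ty) * tz +
    v011 * (1 - tx) * ty * tz             + v111 * tx * ty * tz
  out
}

#' Read an image or displacement volume from disk
#'
#' Supports NIfTI-1 (`.nii`, `.nii.gz`) and MetaImage (`.mhd` with a raw data
#' file). 3-D volumes are returned as [image_volume()]; 4-D volumes with a
#' trailing dimension of 3 are returned as [displacement_field()].
#'
#' @param path file path.
#' @return an `image_volume` or `displacement_field`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (grepl("\\.mhd$", path, ignore.case = TRUE)) return(read_metaimage(path))
  img <- RNifti::readNifti(path)
  sp <- attr(img, "pixdim")[1:3]
  or <- as.numeric(RNifti::xform(img)[1:3, 4])
  a <- unclass(img)
  attributes(a) <- list(dim = dim(img))
  d <- dim(a)
  if (length(d) == 3L) {
    image_volume(a, spacing = sp, origin = or)
  } else if (length(d) == 4L && d[4] == 3L) {
    displacement_field(a, spacing = sp, origin = or)
  } else stop(sprintf("unsupported volume dimensionality: %s",
                      paste(d, collapse = "x")))
}

#' Write an image or displacement volume to disk
#'
#' Round-trips values, spacing and origin (sub-micrometre precision).
#' The format is chosen from the file extension: `.nii`/`.nii.gz` for
#' NIfTI-1, `.mhd` for MetaImage.
#'
#' @param vol an `image_volume` or `displacement_field`.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  if (grepl("\\.mhd$", path, ignore.case = TRUE)) return(write_metaimage(vol, path))
  a <- vol$data
  storage.mode(a) <- "double"
  img <- RNifti::asNifti(a)
  RNifti::pixdim(img) <- if (length(dim(a)) == 4L) c(vol$spacing, 1)
  else vol$spacing
  m <- diag(4)
  m[1, 1] <- vol$spacing[1]; m[2, 2] <- vol$spacing[2]; m[3, 3] <- vol$spacing[3]
  m[1:3, 4] <- vol$origin
  RNifti::qform(img) <- structure(m, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

# --- MetaImage dialect ------------------------------------------------------
# Minimal MET_DOUBLE/MET_FLOAT support: plain-text .mhd header plus a raw
# little-endian data file. Displacement fields use ElementNumberOfChannels = 3
# with the component index fastest (MetaImage convention).

read_metaimage <- function(path) {
  lines <- readLines(path, warn = FALSE)
  kv <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) >= 2)
      kv[[trimws(parts[1])]] <- trimws(paste(parts[-1], collapse = "="))
  }
  dims <- as.integer(strsplit(kv$DimSize, "\\s+")[[1]])
  sp <- if (!is.null(kv$ElementSpacing))
    as.numeric(strsplit(kv$ElementSpacing, "\\s+")[[1]]) else rep(1, 3)
  or <- if (!is.null(kv$Offset))
    as.numeric(strsplit(kv$Offset, "\\s+")[[1]]) else rep(0, 3)
  nchan <- if (!is.null(kv$ElementNumberOfChannels))
    as.integer(kv$ElementNumberOfChannels) else 1L
  type <- kv$ElementType
  size <- switch(type, MET_DOUBLE = 8L, MET_FLOAT = 4L, MET_UCHAR = 1L,
                 stop(sprintf("unsupported MetaImage element type: %s", type)))
  datafile <- kv$ElementDataFile
  if (is.null(datafile) || identical(datafile, "LOCAL"))
    stop("MetaImage headers with LOCAL data are not supported")
  dpath <- file.path(dirname(path), datafile)
  n <- prod(dims) * nchan
  con <- file(dpath, "rb")
  on.exit(close(con))
  raw <- if (size == 1L) as.numeric(readBin(con, "integer", n, size = 1L, signed = FALSE))
  else readBin(con, "numeric", n, size = size, endian = "little")
  if (length(raw) != n) stop("MetaImage data file shorter than header promises")
  if (nchan == 1L) {
    image_volume(array(raw, dims), spacing = sp, origin = or)
  } else {
    # component-fastest on disk -> (x,y,z,comp) array
    a <- aperm(array(raw, c(nchan, dims)), c(2, 3, 4, 1))
    displacement_field(a, spacing = sp, origin = or)
  }
}

write_metaimage <- function(vol, path) {
  is_disp <- inherits(vol, "displacement_field")
  dims <- dim(vol$data)[1:3]
  rawfile <- sub("\\.mhd$", ".raw", basename(path), ignore.case = TRUE)
  hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           "CompressedData = False",
           sprintf("DimSize = %s", paste(dims, collapse = " ")),
           sprintf("ElementSpacing = %s", paste(vol$spacing, collapse = " ")),
           sprintf("Offset = %s", paste(vol$origin, collapse = " ")))
  if (is_disp)
    hdr <- c(hdr, "ElementNumberOfChannels = 3")
  hdr <- c(hdr, "ElementType = MET_DOUBLE",
           sprintf("ElementDataFile = %s", rawfile))
  writeLines(hdr, path)
  vals <- if (is_disp) as.numeric(aperm(vol$data, c(4, 1, 2, 3))) else as.numeric(vol$data)
  con <- file(file.path(dirname(path), rawfile), "wb")
  on.exit(close(con))
  writeBin(vals, con, size = 8L, endian = "little")
  invisible(path)
}

# --- seeded randomness ------------------------------------------------------

# run `expr` under a temporary RNG state seeded with `seed`; restores the
# caller's state afterwards so package functions never disturb the session RNG
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# deterministic substream seeds below 2^31, fanned out from one run seed
substream_seed <- function(seed, id) {
  as.integer((as.numeric(seed) * 48271 + id * 9973) %% 2147483629)
}
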