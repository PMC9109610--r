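#' Volumetric image with physical geometry
#'
#' A `ventimap_volume` is a 3-D scalar grid together with its physical
#' geometry: voxel spacing (mm per axis) and the physical position of the
#' first voxel (origin, mm). The coordinate convention used throughout the
#' package is: voxel indices are 0-based in physical terms, so the physical
#' position of voxel `(i, j, k)` (1-based R indices) is
#' `origin + (c(i, j, k) - 1) * spacing`. Axial slices are indexed by the
#' third axis (`z`); the axial plane is `(x, y)`.
#'
#' @param values numeric 3-D array of voxel values.
#' @param spacing numeric length-3, mm per axis; strictly positive.
#' @param origin numeric length-3, mm position of voxel (1,1,1).
#' @param intensity_kind one of `"HU"`, `"dimensionless"`, `"counts"`.
#' @return An object of class `ventimap_volume`.
#' @export
new_volume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                       intensity_kind = "dimensionless") {
  if (!is.array(values) || length(dim(values)) != 3L)
    vm_stop("values must be a 3-D array", "ventimap_format_error")
  if (any(dim(values) < 1L))
    vm_stop("all dimensions must be >= 1", "ventimap_format_error")
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    vm_stop("spacing must be 3 strictly positive numbers", "ventimap_format_error")
  if (length(origin) != 3L || any(!is.finite(origin)))
    vm_stop("origin must be 3 finite numbers", "ventimap_format_error")
  if (any(!is.finite(values)))
    vm_stop("voxel values must be finite", "ventimap_format_error")
  intensity_kind <- match.arg(intensity_kind, c("HU", "dimensionless", "counts"))
  structure(list(values = values, spacing = spacing, origin = origin,
                 intensity_kind = intensity_kind),
            class = "ventimap_volume")
}

#' Binary mask on a volume grid
#'
#' @param values logical 3-D array.
#' @inheritParams new_volume
#' @return An object of class `ventimap_mask`.
#' @export
new_mask <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    vm_stop("mask values must be a 3-D array", "ventimap_format_error")
  storage.mode(values) <- "logical"
  if (anyNA(values)) vm_stop("mask values must not contain NA", "ventimap_format_error")
  structure(list(values = values, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "ventimap_mask")
}

#' @export
print.ventimap_volume <- function(x, ...) {
  cat(sprintf("<ventimap_volume> %s voxels, spacing %s mm, origin %s mm, %s\n",
              paste(dim(x$values), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              paste(format(x$origin), collapse = ", "),
              x$intensity_kind))
  invisible(x)
}

#' @export
print.ventimap_mask <- function(x, ...) {
  cat(sprintf("<ventimap_mask> %s voxels, %d foreground\n",
              paste(dim(x$values), collapse = "x"), sum(x$values)))
  invisible(x)
}

# Geometry descriptor: shape + spacing + origin.
vol_geometry <- function(x) list(shape = dim(x$values), spacing = x$spacing,
                                 origin = x$origin)

same_geometry <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

check_same_geometry <- function(a, b, what = "volumes") {
  if (!same_geometry(a, b))
    vm_stop(paste0("geometry mismatch between ", what), "ventimap_geometry_error")
  invisible(TRUE)
}

# Physical coordinate vectors of the grid along each axis.
grid_axes <- function(geom) {
  lapply(1:3, function(a) geom$origin[a] + (seq_len(geom$shape[a]) - 1) * geom$spacing[a])
}

#' Read a volume from a NIfTI or MetaImage file
#'
#' NIfTI (`.nii`, `.nii.gz`) files are read through RNifti; spacing and origin
#' are taken from the stored transform. MetaImage (`.mhd`, `.mha`) files are
#' read with a built-in parser (ElementSpacing/Offset honoured). Only 3-D
#' images are accepted.
#'
#' @param path file path.
#' @param intensity_kind intensity kind to tag the volume with.
#' @return A [new_volume()] object.
#' @export
read_volume <- function(path, intensity_kind = "dimensionless") {
  if (!file.exists(path))
    vm_stop(paste0("file not found: ", path), "ventimap_io_error")
  if (grepl("\\.(mhd|mha)$", path, ignore.case = TRUE))
    return(read_metaimage(path, intensity_kind))
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    vm_stop(sprintf("expected a 3-D image, got %d-D", length(d)),
            "ventimap_format_error")
  xf <- RNifti::xform(img)
  spacing <- sqrt(colSums(xf[1:3, 1:3]^2))
  origin <- xf[1:3, 4]
  vals <- array(as.numeric(img), dim = d)
  new_volume(vals, spacing = spacing, origin = origin,
             intensity_kind = intensity_kind)
}

#' Write a volume to a NIfTI or MetaImage file
#'
#' @param volume a [new_volume()] object.
#' @param path output path ending in `.nii`, `.nii.gz`, `.mhd` or `.mha`.
#' @return Invisibly, `path`.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "ventimap_volume") || inherits(volume, "ventimap_mask"))
  if (!dir.exists(dirname(path)))
    vm_stop(paste0("directory does not exist: ", dirname(path)), "ventimap_io_error")
  vals <- volume$values
  storage.mode(vals) <- "double"
  if (grepl("\\.(mhd|mha)$", path, ignore.case = TRUE))
    return(write_metaimage(vals, volume$spacing, volume$origin, path))
  img <- RNifti::asNifti(vals)
  sf <- rbind(cbind(diag(volume$spacing), volume$origin), c(0, 0, 0, 1))
  attr(sf, "code") <- 2L
  img <- RNifti::`sform<-`(img, value = sf)
  RNifti::writeNifti(img, path)
  invisible(path)
}

# Minimal MetaImage (.mha single-file / .mhd + .raw) support: text header with
# `Key = value` lines followed by (or pointing at) a raw little-endian block.
read_metaimage <- function(path, intensity_kind = "dimensionless") {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) break
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) next
    key <- trimws(kv[1]); val <- trimws(kv[2])
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  ndims <- as.integer(hdr$NDims)
  if (is.null(ndims) || ndims != 3L)
    vm_stop(sprintf("expected a 3-D MetaImage, got NDims = %s",
                    as.character(hdr$NDims)), "ventimap_format_error")
  shape <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  spacing <- if (!is.null(hdr$ElementSpacing))
    as.numeric(strsplit(hdr$ElementSpacing, "\\s+")[[1]]) else c(1, 1, 1)
  origin <- if (!is.null(hdr$Offset))
    as.numeric(strsplit(hdr$Offset, "\\s+")[[1]]) else c(0, 0, 0)
  etype <- hdr$ElementType
  n <- prod(shape)
  read_block <- function(c2) switch(
    etype,
    MET_DOUBLE = readBin(c2, "double", n = n, size = 8, endian = "little"),
    MET_FLOAT  = readBin(c2, "double", n = n, size = 4, endian = "little"),
    MET_SHORT  = readBin(c2, "integer", n = n, size = 2, endian = "little"),
    MET_UCHAR  = readBin(c2, "integer", n = n, size = 1, signed = FALSE,
                         endian = "little"),
    vm_stop(paste0("unsupported ElementType: ", etype), "ventimap_format_error"))
  if (identical(hdr$ElementDataFile, "LOCAL")) {
    vals <- read_block(con)
  } else {
    raw_path <- file.path(dirname(path), hdr$ElementDataFile)
    if (!file.exists(raw_path))
      vm_stop(paste0("raw data file not found: ", raw_path), "ventimap_io_error")
    c2 <- file(raw_path, "rb"); on.exit(close(c2), add = TRUE)
    vals <- read_block(c2)
  }
  new_volume(array(as.numeric(vals), dim = shape), spacing = spacing,
             origin = origin, intensity_kind = intensity_kind)
}

write_metaimage <- function(vals, spacing, origin, path) {
  single <- grepl("\\.mha$", path, ignore.case = TRUE)
  hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           paste("DimSize =", paste(dim(vals), collapse = " ")),
           paste("ElementSpacing =", paste(format(spacing, digits = 15), collapse = " ")),
           paste("Offset =", paste(format(origin, digits = 15), collapse = " ")),
           "ElementType = MET_DOUBLE")
  if (single) {
    con <- file(path, "wb"); on.exit(close(con), add = TRUE)
    writeLines(c(hdr, "ElementDataFile = LOCAL"), con)
    writeBin(as.vector(vals), con, size = 8, endian = "little")
  } else {
    raw_name <- sub("\\.mhd$", ".raw", basename(path), ignore.case = TRUE)
    writeLines(c(hdr, paste("ElementDataFile =", raw_name)), path)
    con <- file(file.path(dirname(path), raw_name), "wb")
    on.exit(close(con), add = TRUE)
    writeBin(as.vector(vals), con, size = 8, endian = "little")
  }
  invisible(path)
}

# Trilinear sample of a 3-D array at fractional (1-based) voxel coordinates.
# ix/iy/iz are equal-length vectors; out-of-support points get `fill`.
trilinear_sample <- function(vals, ix, iy, iz, fill) {
  d <- dim(vals)
  inside <- ix >= 1 & ix <= d[1] & iy >= 1 & iy <= d[2] & iz >= 1 & iz <= d[3]
  clamp0 <- function(i, n) if (n == 1L) rep(1, length(i)) else pmin(pmax(floor(i), 1), n - 1L)
  x0 <- clamp0(ix, d[1]); y0 <- clamp0(iy, d[2]); z0 <- clamp0(iz, d[3])
  fx <- if (d[1] == 1L) numeric(length(ix)) else ix - x0
  fy <- if (d[2] == 1L) numeric(length(iy)) else iy - y0
  fz <- if (d[3] == 1L) numeric(length(iz)) else iz - z0
  x1 <- pmin(x0 + 1L, d[1]); y1 <- pmin(y0 + 1L, d[2]); z1 <- pmin(z0 + 1L, d[3])
  at <- function(a, b, c) vals[cbind(a, b, c)]
  out <- at(x0, y0, z0) * (1 - fx) * (1 - fy) * (1 - fz) +
         at(x1, y0, z0) * fx * (1 - fy) * (1 - fz) +
         at(x0, y1, z0) * (1 - fx) * fy * (1 - fz) +
         at(x1, y1, z0) * fx * fy * (1 - fz) +
         at(x0, y0, z1) * (1 - fx) * (1 - fy) * fz +
         at(x1, y0, z1) * fx * (1 - fy) * fz +
         at(x0, y1, z1) * (1 - fx) * fy * fz +
         at(x1, y1, z1) * fx * fy * fz
  out[!inside] <- fill
  out
}

nearest_sample <- function(vals, ix, iy, iz, fill) {
  d <- dim(vals)
  xr <- round(ix); yr <- round(iy); zr <- round(iz)
  inside <- xr >= 1 & xr <= d[1] & yr >= 1 & yr <= d[2] & zr >= 1 & zr <= d[3]
  out <- rep(fill, length(ix))
  out[inside] <- vals[cbind(xr[inside], yr[inside], zr[inside])]
  out
}

#' Resample a volume onto a target grid
#'
#' Samples the source volume at the physical voxel centres of a target
#' geometry, by nearest-neighbour or trilinear interpolation. Points falling
#' outside the source support take `fill` (default: the source minimum,
#' i.e. air-like background for CT).
#'
#' @param source a [new_volume()] object.
#' @param target_geometry list with `shape`, `spacing`, `origin`.
#' @param interpolation `"trilinear"` (default) or `"nearest"`.
#' @param fill fill value for out-of-support points.
#' @return A [new_volume()] on the target geometry.
#' @export
resample_to_grid <- function(source, target_geometry,
                             interpolation = c("trilinear", "nearest"),
                             fill = NULL) {
  interpolation <- match.arg(interpolation)
  stopifnot(inherits(source, "ventimap_volume"))
  tg <- target_geometry
  stopifnot(all(c("shape", "spacing", "origin") %in% names(tg)))
  # physical extents must overlap (voxel-centre bounding boxes)
  s_lo <- source$origin; s_hi <- source$origin + (dim(source$values) - 1) * source$spacing
  t_lo <- tg$origin; t_hi <- tg$origin + (tg$shape - 1) * tg$spacing
  if (any(pmax(s_lo, t_lo) > pmin(s_hi, t_hi)))
    vm_stop("source and target physical extents do not overlap",
            "ventimap_geometry_error")
  if (is.null(fill)) fill <- min(source$values)
  ax <- grid_axes(tg)
  ix <- (rep(ax[[1]], times = tg$shape[2] * tg$shape[3]) - source$origin[1]) /
    source$spacing[1] + 1
  iy <- (rep(rep(ax[[2]], each = tg$shape[1]), times = tg$shape[3]) -
           source$origin[2]) / source$spacing[2] + 1
  iz <- (rep(ax[[3]], each = tg$shape[1] * tg$shape[2]) - source$origin[3]) /
    source$spacing[3] + 1
  vals <- if (interpolation == "trilinear")
    trilinear_sample(source$values, ix, iy, iz, fill)
  else nearest_sample(source$values, ix, iy, iz, fill)
  new_volume(array(vals, dim = tg$shape), spacing = tg$spacing,
             origin = tg$origin, intensity_kind = source$intensity_kind)
}

#' Centre-crop a volume in the axial plane
#'
#' Keeps the central `in_plane_size` voxels along x and y (all of z). When the
#' margin is odd the extra voxel is dropped from the high-index side (the crop
#' window is shifted toward the low corner), and the origin is shifted so that
#' retained voxels keep their physical coordinates.
#'
#' @param volume a [new_volume()] or [new_mask()] object.
#' @param in_plane_size integer length-2 `(nx, ny)` (a scalar is recycled).
#' @return The cropped object, same class as the input.
#' @export
crop_center <- function(volume, in_plane_size) {
  in_plane_size <- as.integer(rep(in_plane_size, length.out = 2))
  d <- dim(volume$values)
  if (any(in_plane_size > d[1:2]) || any(in_plane_size < 1L))
    vm_stop("requested crop exceeds the volume's in-plane size",
            "ventimap_geometry_error")
  off <- (d[1:2] - in_plane_size) %/% 2L
  xi <- seq.int(off[1] + 1L, off[1] + in_plane_size[1])
  yi <- seq.int(off[2] + 1L, off[2] + in_plane_size[2])
  vals <- volume$values[xi, yi, , drop = FALSE]
  origin <- volume$origin + c(off * volume$spacing[1:2], 0)
  if (inherits(volume, "ventimap_mask"))
    new_mask(vals, spacing = volume$spacing, origin = origin)
  else new_volume(vals, spacing = volume$spacing, origin = origin,
                  intensity_kind = volume$intensity_kind)
}
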