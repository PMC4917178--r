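#' Voxel spacing in microns
#'
#' Physical size of one voxel along x, y and z. All pipeline geometry
#' (centroids, clustering, matching radii) is computed in micron space using
#' this spacing; it is always an explicit argument and never silently inferred
#' from file metadata.
#'
#' @param dx,dy,dz Microns per voxel along x, y and z. All strictly positive.
#' @return A `voxel_spacing` object (named numeric vector `dx`, `dy`, `dz`).
#' @seealso [reference_spacing()]
#' @export
voxel_spacing <- function(dx, dy, dz) {
  s <- c(dx = as.numeric(dx), dy = as.numeric(dy), dz = as.numeric(dz))
  if (any(!is.finite(s)) || any(s <= 0))
    stop("voxel spacing must be finite and strictly positive")
  structure(s, class = "voxel_spacing")
}

#' Reference confocal voxel spacing
#'
#' The anisotropic spacing of the reference acquisition setup:
#' 0.691 x 0.691 x 1.75 um per voxel. The z step is ~2.5x coarser than xy,
#' which is why nuclei touching along z are the dominant source of fused
#' objects.
#'
#' @return A [voxel_spacing()] of (0.691, 0.691, 1.75) um.
#' @export
reference_spacing <- function() voxel_spacing(0.691, 0.691, 1.75)

#' 3D image stack with physical spacing
#'
#' The universal carrier through the pipeline: a 3D array of non-negative
#' intensities stored `voxels[y, x, z]` (a z-slice is `voxels[, , z]` with
#' rows = y, columns = x), plus the voxel spacing in microns. Physical
#' coordinates are reported (x, y, z) in um with voxel centers at
#' `(i - 0.5) * spacing` for 1-based index `i` along each axis.
#'
#' @param voxels 3D numeric array, dimensions `(ny, nx, nz)`, finite and >= 0.
#'   A matrix is accepted as a single-slice stack.
#' @param spacing A [voxel_spacing()].
#' @param bit_depth 8 or 16 (informational; used when writing TIFFs).
#' @return An `image_stack` object.
#' @export
image_stack <- function(voxels, spacing, bit_depth = 16L) {
  if (is.matrix(voxels)) dim(voxels) <- c(dim(voxels), 1L)
  if (length(dim(voxels)) != 3L) stop("voxels must be a 3D array")
  if (!inherits(spacing, "voxel_spacing")) spacing <- do.call(voxel_spacing, as.list(spacing))
  storage.mode(voxels) <- "double"
  if (anyNA(voxels) || any(!is.finite(voxels)) || any(voxels < 0))
    stop("voxel intensities must be finite and non-negative")
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16")
  structure(list(voxels = voxels, spacing = spacing, bit_depth = as.integer(bit_depth)),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("image_stack: %d x %d x %d voxels (x * y * z), %d-bit\n",
              d[2], d[1], d[3], x$bit_depth))
  cat(sprintf("  spacing: %.4g x %.4g x %.4g um; intensity range [%g, %g]\n",
              x$spacing["dx"], x$spacing["dy"], x$spacing["dz"],
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$voxels)

## ---- minimal baseline TIFF (no TIFF package is available; uncompressed
## grayscale 8/16-bit multi-page is all the pipeline needs) ----

.tif_types <- c(BYTE = 1L, SHORT = 3L, LONG = 4L)
.tif_type_size <- c(1L, 0L, 2L, 4L)

.read_ifd_entries <- function(con, endian) {
  n <- readBin(con, "integer", 1, size = 2, signed = FALSE, endian = endian)
  entries <- vector("list", n)
  for (i in seq_len(n)) {
    tag   <- readBin(con, "integer", 1, size = 2, signed = FALSE, endian = endian)
    type  <- readBin(con, "integer", 1, size = 2, signed = FALSE, endian = endian)
    count <- readBin(con, "integer", 1, size = 4, endian = endian)
    raw4  <- readBin(con, "raw", 4)
    entries[[i]] <- list(tag = tag, type = type, count = count, raw = raw4)
  }
  nxt <- readBin(con, "integer", 1, size = 4, endian = endian)
  list(entries = entries, next_offset = nxt)
}

.ifd_values <- function(con, e, endian) {
  sz <- .tif_type_size[e$type]
  if (sz == 0L || is.na(sz)) return(NULL)
  total <- sz * e$count
  read_vals <- function(r) {
    readBin(r, "integer", e$count, size = sz, signed = sz > 2, endian = endian)
  }
  if (total <= 4L) {
    if (endian == "big") read_vals(e$raw[seq_len(total)]) else read_vals(e$raw)
  } else {
    off <- readBin(e$raw, "integer", 1, size = 4, endian = endian)
    seek(con, off)
    read_vals(con)
  }
}

#' Read a grayscale TIFF stack
#'
#' Reads a single- or multi-page uncompressed grayscale TIFF (8- or 16-bit)
#' into an [image_stack()]. The voxel spacing is an explicit argument: TIFF
#' files rarely carry trustworthy z-calibration, so it is never inferred.
#' RGB, paletted, floating-point or compressed TIFFs are rejected with an
#' explicit message rather than silently converted (silent channel mixing
#' would corrupt two-channel evaluation).
#'
#' @param path Path to the TIFF file.
#' @param spacing A [voxel_spacing()].
#' @return An [image_stack()] of dimensions pages x height x width.
#' @seealso [write_stack()]
#' @export
read_stack <- function(path, spacing = reference_spacing()) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  byte_order <- rawToChar(readBin(con, "raw", 2))
  endian <- switch(byte_order, II = "little", MM = "big",
                   stop("not a TIFF file: ", path))
  magic <- readBin(con, "integer", 1, size = 2, signed = FALSE, endian = endian)
  if (magic != 42L) stop("not a TIFF file (bad magic): ", path)
  ifd_off <- readBin(con, "integer", 1, size = 4, endian = endian)
  slices <- list()
  bd <- 8L
  while (ifd_off > 0L) {
    seek(con, ifd_off)
    ifd <- .read_ifd_entries(con, endian)
    tagval <- function(tag, default = NULL) {
      for (e in ifd$entries) if (e$tag == tag) return(.ifd_values(con, e, endian))
      default
    }
    width  <- tagval(256L); height <- tagval(257L)
    bits   <- tagval(258L, 8L)
    comp   <- tagval(259L, 1L)
    photo  <- tagval(262L, 1L)
    spp    <- tagval(277L, 1L)
    sfmt   <- tagval(339L, 1L)
    if (is.null(width) || is.null(height)) stop("TIFF page missing dimensions")
    if (any(comp != 1L)) stop("compressed TIFF not supported: ", path)
    if (any(spp > 1L) || any(photo > 1L))
      stop("RGB/paletted TIFF rejected (grayscale required, no conversion rule): ", path)
    if (any(sfmt == 3L)) stop("floating-point TIFF rejected (no conversion rule): ", path)
    bits <- bits[1]
    if (!bits %in% c(8L, 16L)) stop("only 8- and 16-bit TIFFs supported, got ", bits)
    if (bits == 16L) bd <- 16L
    offsets <- tagval(273L); counts <- tagval(279L)
    if (is.null(offsets)) stop("TIFF page missing strip offsets")
    if (is.null(counts)) counts <- rep((width * height * bits / 8) / length(offsets),
                                       length(offsets))
    vals <- integer(0)
    for (k in seq_along(offsets)) {
      seek(con, offsets[k])
      nv <- counts[k] / (bits / 8L)
      vals <- c(vals, readBin(con, "integer", nv, size = bits / 8L,
                              signed = FALSE, endian = endian))
    }
    slices[[length(slices) + 1L]] <- matrix(vals, nrow = height, ncol = width,
                                            byrow = TRUE)
    ifd_off <- ifd$next_offset
  }
  if (!length(slices)) stop("TIFF contains no pages: ", path)
  d1 <- dim(slices[[1]])
  if (!all(vapply(slices, function(m) identical(dim(m), d1), logical(1))))
    stop("TIFF pages differ in size")
  vox <- array(unlist(slices), dim = c(d1, length(slices)))
  image_stack(vox, spacing, bit_depth = bd)
}

.ifd_entry <- function(tag, type, count, value) {
  # value: integer vector already fitting the 4-byte field, or an offset
  raw4 <- raw(4)
  sz <- .tif_type_size[type]
  enc <- writeBin(as.integer(value), raw(), size = sz, endian = "little")
  raw4[seq_along(enc)] <- enc
  c(writeBin(as.integer(tag), raw(), size = 2, endian = "little"),
    writeBin(as.integer(type), raw(), size = 2, endian = "little"),
    writeBin(as.integer(count), raw(), size = 4, endian = "little"),
    raw4)
}

#' Write a grayscale TIFF stack
#'
#' Writes an [image_stack()] as an uncompressed little-endian multi-page
#' grayscale TIFF (one page per z-slice, one strip per page). Intensities are
#' rounded to integers; the round trip with [read_stack()] is voxel-exact for
#' integer-valued stacks within the bit depth. Integer label masks fit the
#' same path (write with `bit_depth = 16`).
#'
#' @param stack An [image_stack()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$voxels)
  ny <- d[1]; nx <- d[2]; nz <- d[3]
  bits <- stack$bit_depth
  maxval <- 2^bits - 1
  v <- round(stack$voxels)
  if (max(v) > maxval)
    stop("intensities exceed ", bits, "-bit range; increase bit_depth")
  bpp <- bits / 8L
  page_bytes <- ny * nx * bpp
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  data_start <- 8L
  ifd_start <- data_start + nz * page_bytes
  ifd_size <- 2L + 9L * 12L + 4L
  writeBin(as.integer(ifd_start), con, size = 4, endian = "little")
  for (z in seq_len(nz)) {
    rowmajor <- as.integer(t(v[, , z]))
    writeBin(rowmajor, con, size = bpp, endian = "little", useBytes = TRUE)
  }
  for (z in seq_len(nz)) {
    strip_off <- data_start + (z - 1L) * page_bytes
    entries <- c(
      .ifd_entry(256L, 4L, 1L, nx),
      .ifd_entry(257L, 4L, 1L, ny),
      .ifd_entry(258L, 3L, 1L, bits),
      .ifd_entry(259L, 3L, 1L, 1L),
      .ifd_entry(262L, 3L, 1L, 1L),
      .ifd_entry(273L, 4L, 1L, strip_off),
      .ifd_entry(277L, 3L, 1L, 1L),
      .ifd_entry(278L, 4L, 1L, ny),
      .ifd_entry(279L, 4L, 1L, page_bytes))
    writeBin(9L, con, size = 2, endian = "little")
    writeBin(entries, con)
    nxt <- if (z < nz) ifd_start + z * ifd_size else 0L
    writeBin(as.integer(nxt), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Write a centroid table as CSV
#'
#' Writes object centroids (micron coordinates) and volumes with the fixed
#' header `object_id,x_um,y_um,z_um,volume_voxels`, rows ordered by
#' `object_id`.
#'
#' @param table Data frame with columns `object_id`, `x_um`, `y_um`, `z_um`,
#'   `volume_voxels`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_centroids <- function(table, path) {
  cols <- c("object_id", "x_um", "y_um", "z_um", "volume_voxels")
  if (!all(cols %in% names(table))) stop("centroid table missing columns")
  if (anyDuplicated(table$object_id)) stop("object_id must be unique")
  table <- table[order(table$object_id), cols, drop = FALSE]
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a centroid table CSV written by [write_centroids()]
#' @param path CSV path.
#' @return Data frame with the standard centroid columns.
#' @export
read_centroids <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Centroid table of a segmentation result
#'
#' @param objects List of segmented objects (see [connected_components_3d()]).
#' @return Data frame with columns `object_id`, `x_um`, `y_um`, `z_um`,
#'   `volume_voxels`.
#' @export
centroid_table <- function(objects) {
  if (!length(objects))
    return(data.frame(object_id = integer(), x_um = numeric(), y_um = numeric(),
                      z_um = numeric(), volume_voxels = integer()))
  data.frame(
    object_id = vapply(objects, `[[`, integer(1), "object_id"),
    x_um = vapply(objects, function(o) o$centroid_um[1], numeric(1)),
    y_um = vapply(objects, function(o) o$centroid_um[2], numeric(1)),
    z_um = vapply(objects, function(o) o$centroid_um[3], numeric(1)),
    volume_voxels = vapply(objects, `[[`, integer(1), "volume"))
}
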