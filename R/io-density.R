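#' Voxel density map
#'
#' A 3-D grid of density values on an isotropic lattice, the in-memory form
#' of an MRC/CCP4 electron density map. Data are stored in canonical
#' (x, y, z) axis order with x fastest, regardless of the axis permutation
#' declared in a file header.
#'
#' @param data numeric 3-D array of densities, dims `(nx, ny, nz)`.
#' @param origin numeric length-3, position of the center of voxel
#'   `[1,1,1]` in Angstrom.
#' @param spacing voxel edge length in Angstrom (isotropic, > 0).
#' @param threshold display/contour level (informational).
#' @return An object of class `voxel_map`.
#' @export
voxel_map <- function(data, origin = c(0, 0, 0), spacing = 1, threshold = 0) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be a 3-D array")
  if (length(spacing) != 1L || !is.finite(spacing) || spacing <= 0)
    stop("'spacing' must be a single positive number")
  if (any(dim(data) < 1L)) stop("grid dimensions must all be >= 1")
  structure(list(data = data, origin = as.numeric(origin),
                 spacing = as.numeric(spacing),
                 threshold = as.numeric(threshold)),
            class = "voxel_map")
}

#' @export
print.voxel_map <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("voxel_map: %d x %d x %d voxels, spacing %.3f A, origin (%.1f, %.1f, %.1f)\n",
              d[1], d[2], d[3], x$spacing, x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Coordinates of all voxel centers
#' @param map a [voxel_map()].
#' @return matrix (n_voxels x 3), x fastest.
#' @export
voxel_centers <- function(map) {
  d <- dim(map$data)
  g <- as.matrix(expand.grid(x = seq_len(d[1]) - 1L,
                             y = seq_len(d[2]) - 1L,
                             z = seq_len(d[3]) - 1L))
  sweep(g * map$spacing, 2, map$origin, `+`)
}

# MRC2014 header words we use (all little-endian in our writer):
#   1-3 nx ny nz (columns, rows, sections); 4 mode (2 = float32);
#   5-7 nxstart nystart nzstart; 8-10 mx my mz; 11-13 cella (A);
#   14-16 cellb (deg); 17-19 mapc mapr maps (which axis is column/row/section);
#   20-22 dmin dmax dmean; 23 ispg; 24 nsymbt; 50-52 origin (A); 53 "MAP ".
.mrc_header_words <- 256L

#' Read an MRC/CCP4 density map
#'
#' Parses mode-2 (float32) maps. The file's axis permutation
#' (`mapc`/`mapr`/`maps` header words) is undone so that the returned grid is
#' always in canonical x-fastest (x, y, z) order. Only isotropic voxel
#' spacing is supported.
#'
#' @param path file path.
#' @return a [voxel_map()].
#' @export
read_density_map <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_i <- readBin(con, "integer", n = 256, size = 4, endian = "little")
  seek(con, 0)
  hdr_f <- readBin(con, "numeric", n = 256, size = 4, endian = "little")
  nc <- hdr_i[1]; nr <- hdr_i[2]; ns <- hdr_i[3]
  mode <- hdr_i[4]
  if (mode != 2L) stop("unsupported MRC mode ", mode, " (only mode 2, float32)")
  mx <- hdr_i[8]; my <- hdr_i[9]; mz <- hdr_i[10]
  cella <- hdr_f[11:13]
  mapc <- hdr_i[17]; mapr <- hdr_i[18]; maps <- hdr_i[19]
  if (any(sort(c(mapc, mapr, maps)) != 1:3))
    stop("invalid axis assignment in MRC header")
  nsymbt <- hdr_i[24]
  orig <- hdr_f[50:52]
  sp <- cella / c(mx, my, mz)
  sp <- sp[is.finite(sp) & sp > 0]
  if (length(sp) == 0L) sp <- 1
  if (diff(range(sp)) > 1e-4 * mean(sp))
    stop("anisotropic voxel spacing is not supported")
  spacing <- mean(sp)
  if (nsymbt > 0) seek(con, 1024 + nsymbt) else seek(con, 1024)
  n <- nc * nr * ns
  vals <- readBin(con, "numeric", n = n, size = 4, endian = "little")
  if (length(vals) != n) stop("truncated MRC data block")
  # file layout: column (axis mapc) fastest, then row (mapr), then section
  arr_file <- array(vals, dim = c(nc, nr, ns))
  # permute so that dimension k of the result is spatial axis k
  ax <- c(mapc, mapr, maps)        # spatial axis of file dims 1,2,3
  perm <- match(1:3, ax)           # file dim holding spatial axis 1,2,3
  arr <- aperm(arr_file, perm)
  voxel_map(arr, origin = orig, spacing = spacing)
}

#' Write a density map as MRC (mode 2, canonical axis order)
#'
#' @param map a [voxel_map()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_density_map <- function(map, path) {
  stopifnot(inherits(map, "voxel_map"))
  d <- dim(map$data)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(pos, v) { seek(con, (pos - 1) * 4, rw = "w"); writeBin(as.integer(v), con, size = 4, endian = "little") }
  wf <- function(pos, v) { seek(con, (pos - 1) * 4, rw = "w"); writeBin(as.numeric(v), con, size = 4, endian = "little") }
  writeBin(raw(1024), con)
  wi(1, d); wi(4, 2L)
  wi(5, c(0L, 0L, 0L))
  wi(8, d)
  wf(11, d * map$spacing)
  wf(14, c(90, 90, 90))
  wi(17, 1:3)
  wf(20, c(min(map$data), max(map$data), mean(map$data)))
  wi(23, 1L); wi(24, 0L)
  wf(50, map$origin)
  seek(con, (53 - 1) * 4, rw = "w")
  writeBin(charToRaw("MAP "), con)
  seek(con, 1024, rw = "w")
  writeBin(as.numeric(map$data), con, size = 4, endian = "little")
  invisible(path)
}
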