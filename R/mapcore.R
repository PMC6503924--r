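#' Cubic density map
#'
#' The universal volume currency of the package: a cubic 3D scalar grid with a
#' physical voxel size. All rotations and masks use the convention that the
#' box centre is the voxel with 0-based index `floor(N/2)` along each axis.
#'
#' @param grid Numeric 3D array with all three dimensions equal.
#' @param voxel_size Voxel edge length in Angstrom (> 0).
#' @param origin Physical origin in Angstrom, length-3 numeric.
#' @return An object of class `density_map` with fields `grid`, `voxel_size`,
#'   `origin`.
#' @export
density_map <- function(grid, voxel_size, origin = c(0, 0, 0)) {
  if (!is.array(grid) || length(dim(grid)) != 3L)
    stop("`grid` must be a 3D array")
  d <- dim(grid)
  if (d[1] != d[2] || d[2] != d[3])
    stop("non-cubic volume: dimensions ", paste(d, collapse = "x"))
  if (!all(is.finite(grid))) stop("grid contains non-finite values")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    stop("`voxel_size` must be a single positive number")
  structure(list(grid = grid, voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin)),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  N <- dim(x$grid)[1]
  cat(sprintf("<density_map> %d^3 voxels, %.4g A/voxel, range [%.4g, %.4g]\n",
              N, x$voxel_size, min(x$grid), max(x$grid)))
  invisible(x)
}

map_size <- function(map) dim(map$grid)[1]

stopifnot_same_shape <- function(a, b) {
  da <- if (inherits(a, "density_map") || inherits(a, "soft_mask")) dim(a$grid) else dim(a)
  db <- if (inherits(b, "density_map") || inherits(b, "soft_mask")) dim(b$grid) else dim(b)
  if (!identical(da, db))
    stop("shape mismatch: ", paste(da, collapse = "x"), " vs ",
         paste(db, collapse = "x"))
  invisible(TRUE)
}

## ---------------------------------------------------------------- MRC2014 I/O
## Hand-rolled MRC2014 container support (float32 mode 2 only, standard axis
## order mapc,mapr,maps = 1,2,3, little-endian). No R package on our dependency
## stack speaks MRC, and the format is a fixed 1024-byte header plus raw data.

.mrc_write_raw <- function(data, dims, voxel_size, origin, path, ispg) {
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  wi(c(nx, ny, nz))            # NX NY NZ
  wi(2L)                        # MODE 2 = float32
  wi(c(0L, 0L, 0L))             # NXSTART..
  wi(c(nx, ny, nz))             # MX MY MZ
  wf(c(nx, ny, nz) * voxel_size)  # CELLA
  wf(c(90, 90, 90))             # CELLB
  wi(c(1L, 2L, 3L))             # MAPC MAPR MAPS
  wf(c(min(data), max(data), mean(data)))  # DMIN DMAX DMEAN
  wi(ispg)                      # ISPG
  wi(0L)                        # NSYMBT
  wi(rep(0L, 25))               # EXTRA (words 25-49)
  wf(origin)                    # ORIGIN (words 50-52)
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # MACHST little-endian
  wf(sd(data))                  # RMS
  wi(1L)                        # NLABL
  lab <- sprintf("%-80s", "written by symref")
  writeChar(substr(lab, 1, 80), con, nchars = 80, eos = NULL)
  writeChar(paste(rep(" ", 80 * 9), collapse = ""), con, nchars = 720, eos = NULL)
  writeBin(as.numeric(data), con, size = 4, endian = "little")
  invisible(path)
}

.mrc_read_raw <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n = n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n = n, size = 4, endian = "little")
  dims <- ri(3)
  mode <- ri(1)
  if (mode != 2L)
    stop("unsupported MRC mode ", mode, " (only float32 mode 2 is handled)")
  ri(3)                      # nxstart
  m <- ri(3)                 # mx my mz
  cella <- rf(3)
  rf(3); ri(3); rf(3)        # cellb, axis order, dmin/dmax/dmean
  ri(1); ri(1); ri(25)       # ispg, nsymbt, extra
  origin <- rf(3)
  seek(con, 1024)
  n <- prod(dims)
  data <- readBin(con, "numeric", n = n, size = 4, endian = "little")
  if (length(data) != n) stop("truncated MRC data block in ", path)
  list(data = data, dims = dims, voxel_size = cella[1] / m[1], origin = origin)
}

#' Read / write MRC2014 volumes
#'
#' `read_mrc()` reads a cubic float32 MRC2014 volume; `write_mrc()` writes one.
#' Round trips preserve grid values bit-exactly at float32 precision and the
#' voxel size to better than 1e-4 Angstrom.
#'
#' @param path File path.
#' @return `read_mrc()` returns a [density_map]; `write_mrc()` returns `path`
#'   invisibly.
#' @export
read_mrc <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- .mrc_read_raw(path)
  d <- raw$dims
  if (d[1] != d[2] || d[2] != d[3])
    stop("non-cubic volume in ", path, ": ", paste(d, collapse = "x"))
  density_map(array(raw$data, dim = d), raw$voxel_size, raw$origin)
}

#' @rdname read_mrc
#' @param map A [density_map].
#' @export
write_mrc <- function(map, path) {
  if (!inherits(map, "density_map")) stop("`map` must be a density_map")
  .mrc_write_raw(map$grid, dim(map$grid), map$voxel_size, map$origin, path,
                 ispg = 1L)
  invisible(path)
}

## ------------------------------------------------------------------- masks

#' Soft cylindrical shell mask
#'
#' Builds a 0..1 mask supported on the cylindrical shell
#' `r_inner <= r <= r_outer`, `|z| <= z_half` (voxel units, axis = z through
#' the box centre). The mask equals 1 on the shell eroded by `edge_width` and
#' falls to 0 at the shell boundary with a raised-cosine profile;
#' `edge_width = 0` gives a hard binary mask.
#'
#' @param N Box size in voxels.
#' @param r_inner,r_outer Inner/outer radius in voxels, `0 <= r_inner < r_outer`.
#' @param z_half Axial half-height in voxels.
#' @param edge_width Raised-cosine falloff width in voxels.
#' @return An object of class `soft_mask` (fields `grid`, `edge_width`).
#' @export
cylindrical_mask <- function(N, r_inner, r_outer, z_half, edge_width = 3) {
  if (r_inner < 0 || r_inner >= r_outer) stop("need 0 <= r_inner < r_outer")
  if (z_half <= 0) stop("z_half must be positive")
  if (r_outer > N / 2) stop("r_outer (", r_outer, ") exceeds N/2 = ", N / 2)
  cc <- N %/% 2
  x <- (seq_len(N) - 1) - cc
  r <- sqrt(outer(x^2, x^2, "+"))            # N x N radial distance
  ramp <- function(t) {                       # 0 at t<=0, 1 at t>=1, cosine between
    t <- pmin(pmax(t, 0), 1)
    0.5 * (1 - cos(pi * t))
  }
  if (edge_width > 0) {
    p_in <- if (r_inner > 0) ramp((r - r_inner) / edge_width) else 1
    p_out <- ramp((r_outer - r) / edge_width)
    prof_xy <- pmin(p_in, p_out)
    prof_z <- ramp((z_half - abs(x)) / edge_width)
  } else {
    prof_xy <- as.numeric(r >= r_inner & r <= r_outer)
    prof_z <- as.numeric(abs(x) <= z_half)
  }
  grid <- array(0, dim = c(N, N, N))
  for (k in seq_len(N)) grid[, , k] <- pmin(prof_xy, prof_z[k])
  structure(list(grid = grid, edge_width = edge_width), class = "soft_mask")
}

#' @export
print.soft_mask <- function(x, ...) {
  cat(sprintf("<soft_mask> %d^3, edge %g vox, support %d voxels\n",
              dim(x$grid)[1], x$edge_width, sum(x$grid > 0)))
  invisible(x)
}

#' Scale a masked region of a map
#'
#' Multiplies density inside the mask by `factor`, leaving unmasked voxels
#' untouched: `out = map * (1 + (factor - 1) * mask)`. With the collar mask and
#' the default factor 1.5 this realizes the up-weighting of the asymmetric
#' collar region used during reference adjustment.
#'
#' @param map A [density_map].
#' @param mask A `soft_mask` or plain array of the same shape.
#' @param factor Positive scale factor.
#' @return A [density_map].
#' @export
scale_region <- function(map, mask, factor) {
  if (factor <= 0) stop("factor must be positive")
  stopifnot_same_shape(map, mask)
  m <- if (inherits(mask, "soft_mask")) mask$grid else mask
  density_map(map$grid * (1 + (factor - 1) * m), map$voxel_size, map$origin)
}

#' Combine wall and collar regions into one masked volume
#'
#' `out = (wall_map * wall_mask + collar_map * collar_mask) * outer_mask`.
#' With disjoint wall/collar masks this reassembles a reference volume from the
#' symmetrized wall and the weighted collar, removing background outside the
#' outer mask.
#'
#' @param wall_map,collar_map [density_map]s of identical shape.
#' @param wall_mask,collar_mask,outer_mask `soft_mask`s of the same shape.
#' @return A [density_map].
#' @export
combine_regions <- function(wall_map, collar_map, wall_mask, collar_mask,
                            outer_mask) {
  stopifnot_same_shape(wall_map, collar_map)
  stopifnot_same_shape(wall_map, wall_mask)
  stopifnot_same_shape(wall_map, collar_mask)
  stopifnot_same_shape(wall_map, outer_mask)
  g <- (wall_map$grid * wall_mask$grid + collar_map$grid * collar_mask$grid) *
    outer_mask$grid
  density_map(g, wall_map$voxel_size, wall_map$origin)
}

## --------------------------------------------------------------- sharpening

.freq_sq_grid <- function(N, voxel_size) {
  f <- 0:(N - 1)
  f[f > N / 2] <- f[f > N / 2] - N      # DFT frequency indices
  f <- f / (N * voxel_size)
  f2 <- f^2
  outer3 <- array(0, dim = c(N, N, N))
  for (k in seq_len(N)) outer3[, , k] <- outer(f2, f2, "+") + f2[k]
  outer3
}

#' B-factor sharpening
#'
#' Multiplies Fourier amplitudes by `exp(-bfactor * s^2 / 4)` with `s` the
#' spatial frequency in 1/Angstrom. A negative B factor (e.g. the -190 A^2
#' used for the hemocyanin map) boosts high-resolution amplitudes;
#' `bfactor = 0` is the identity and `sharpen(sharpen(V, b), -b) = V`.
#'
#' @param map A [density_map].
#' @param bfactor B factor in Angstrom^2.
#' @return A [density_map].
#' @export
sharpen <- function(map, bfactor) {
  N <- map_size(map)
  s2 <- .freq_sq_grid(N, map$voxel_size)
  F <- fft(map$grid) * exp(-bfactor * s2 / 4)
  density_map(Re(fft(F, inverse = TRUE)) / N^3, map$voxel_size, map$origin)
}

#' Low-pass filter a map to a target resolution
#'
#' Gaussian low-pass with half-amplitude at the target resolution, the usual
#' way an ab-initio reference is band-limited before refinement.
#'
#' @param map A [density_map].
#' @param resolution_A Target resolution in Angstrom (> 2 * voxel size).
#' @return A [density_map].
#' @export
lowpass <- function(map, resolution_A) {
  if (resolution_A <= 2 * map$voxel_size)
    stop("resolution must be coarser than Nyquist (", 2 * map$voxel_size,
         " A)")
  N <- map_size(map)
  s2 <- .freq_sq_grid(N, map$voxel_size)
  filt <- exp(-log(2) * s2 * resolution_A^2)
  density_map(Re(fft(fft(map$grid) * filt, inverse = TRUE)) / N^3,
              map$voxel_size, map$origin)
}
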