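#' Phantom specification for the synthetic decamer
#'
#' Parametric geometry of the synthetic hemocyanin-like decamer: a D5
#' cylindrical wall (30 Gaussian blobs, the D5 orbit of a 3-blob asymmetric
#' unit) enclosing an asymmetric inner collar of 20 blobs (10 FU-g, 10 FU-d*).
#' The five FU-g dimers sit at azimuths 72k degrees and occupy the northern or
#' southern hemisphere of the lumen according to `hemisphere_pattern`; a
#' southern dimer is the two-fold image of a northern one (local azimuth
#' offset and z both negated), so hemisphere flips are proper two-fold
#' rotations about the dimer's radial axis. Each dimer has one polar and one
#' equatorial FU-g; the two FU-d* of its protomers fill the void on the
#' opposite hemisphere, azimuthally between dimers. The numeric defaults are
#' schematic (chosen so that all 40 symmetry-expanded collar sites are
#' distinct at 1-voxel tolerance), not fitted to any deposited map.
#'
#' @param N Box size in voxels.
#' @param voxel_size Angstrom per voxel.
#' @param r_wall Wall radius, voxels.
#' @param wall_z_half Wall half-height, voxels.
#' @param r_collar Collar radius, voxels.
#' @param z_polar,z_equatorial FU-g polar/equatorial |z| levels, voxels.
#' @param z_polar_d,z_equatorial_d FU-d* polar/equatorial |z| levels, voxels.
#' @param blob_sigma Gaussian blob sigma, voxels.
#' @param amplitudes Named numeric: peak amplitude per role
#'   (`wall`, `fu_g`, `fu_dstar`).
#' @param hemisphere_pattern Character vector of length 5 over `"N"`/`"S"`:
#'   hemisphere of each FU-g dimer, in azimuthal order.
#' @param seed Integer seed recorded with the spec.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(N = 64, voxel_size = 3.0, r_wall = 22,
                         wall_z_half = 18, r_collar = 10,
                         z_polar = 10, z_equatorial = 4,
                         z_polar_d = 13, z_equatorial_d = 7,
                         blob_sigma = 2.5,
                         amplitudes = c(wall = 1, fu_g = 1, fu_dstar = 1),
                         hemisphere_pattern = c("N", "S", "N", "S", "N"),
                         seed = 1L) {
  if (length(hemisphere_pattern) != 5L)
    stop("hemisphere_pattern must have length 5")
  if (!all(hemisphere_pattern %in% c("N", "S")))
    stop("hemisphere_pattern labels must be \"N\" or \"S\"")
  if (r_collar >= r_wall) stop("need r_collar < r_wall")
  if (r_wall > N / 2 - 4) stop("need r_wall <= N/2 - 4")
  zs <- c(z_polar, z_equatorial, z_polar_d, z_equatorial_d)
  if (anyDuplicated(zs)) stop("z levels must be distinct across roles")
  if (!all(c("wall", "fu_g", "fu_dstar") %in% names(amplitudes)))
    stop("amplitudes must name wall, fu_g and fu_dstar")
  structure(list(N = as.integer(N), voxel_size = voxel_size, r_wall = r_wall,
                 wall_z_half = wall_z_half, r_collar = r_collar,
                 z_polar = z_polar, z_equatorial = z_equatorial,
                 z_polar_d = z_polar_d, z_equatorial_d = z_equatorial_d,
                 blob_sigma = blob_sigma, amplitudes = amplitudes,
                 hemisphere_pattern = hemisphere_pattern,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Ground-truth blob centroids of the decamer phantom
#'
#' Returns the labelled centroid table of the phantom: 30 wall blobs (the D5
#' orbit of a 3-blob asymmetric unit) plus exactly 10 FU-g and 10 FU-d*
#' collar blobs. Coordinates are voxels relative to the box centre. The wall
#' centroid set is exactly closed under D5; the collar set is not (that
#' asymmetry is the point of the model).
#'
#' @param spec A [phantom_spec].
#' @return A data frame with columns `x`, `y`, `z`, `role`
#'   (`wall`/`FU-g`/`FU-dstar`), `protomer` (1-10), `hemisphere` (`N`/`S`),
#'   `site_class` (`polar`/`equatorial`/`wall`).
#' @export
build_decamer_truth <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  deg <- pi / 180
  row_of <- function(r, az_deg, z, role, protomer, site_class) {
    data.frame(x = r * cos(az_deg * deg), y = r * sin(az_deg * deg), z = z,
               role = role, protomer = as.integer(protomer),
               hemisphere = if (z >= 0) "N" else "S",
               site_class = site_class, stringsAsFactors = FALSE)
  }
  ## wall: D5 orbit of a 3-blob asymmetric unit (generic positions, away from
  ## the two-fold axes at azimuth multiples of 36 deg)
  d5 <- point_group("D", 5)
  seed_az <- c(10, 34, 58)
  seed_z <- c(0.45, 0, -0.45) * spec$wall_z_half
  seed_pts <- cbind(spec$r_wall * cos(seed_az * deg),
                    spec$r_wall * sin(seed_az * deg), seed_z)
  wall_pts <- orbit_points(seed_pts, d5)
  az <- (atan2(wall_pts[, 2], wall_pts[, 1]) / deg) %% 360
  wall <- data.frame(x = wall_pts[, 1], y = wall_pts[, 2], z = wall_pts[, 3],
                     role = "wall",
                     protomer = as.integer(floor(az / 36) + 1),
                     hemisphere = ifelse(wall_pts[, 3] >= 0, "N", "S"),
                     site_class = "wall", stringsAsFactors = FALSE)
  ## collar: five FU-g dimers plus the FU-d* pair opposite each dimer
  collar <- list()
  for (k in 0:4) {
    s <- if (spec$hemisphere_pattern[k + 1] == "N") 1 else -1
    A <- 72 * k
    collar[[length(collar) + 1]] <-
      row_of(spec$r_collar, A, s * spec$z_polar, "FU-g", 2 * k + 1, "polar")
    collar[[length(collar) + 1]] <-
      row_of(spec$r_collar, A + 20 * s, s * spec$z_equatorial, "FU-g",
             2 * k + 2, "equatorial")
    collar[[length(collar) + 1]] <-
      row_of(spec$r_collar, A + 30 * s, -s * spec$z_polar_d, "FU-dstar",
             2 * k + 1, "polar")
    collar[[length(collar) + 1]] <-
      row_of(spec$r_collar, A + 42 * s, -s * spec$z_equatorial_d, "FU-dstar",
             2 * k + 2, "equatorial")
  }
  rbind(wall, do.call(rbind, collar))
}

#' Collar centroids of a ground-truth table
#' @param truth Output of [build_decamer_truth()].
#' @return Matrix (20 x 3) of FU-g and FU-d* centroids.
#' @export
collar_centroids <- function(truth) {
  as.matrix(truth[truth$role != "wall", c("x", "y", "z")])
}

#' Render a ground-truth table as a density map
#'
#' Sum of isotropic Gaussian blobs, peak amplitude per role taken from the
#' spec. Warns if a centroid lies within 3 sigma of the box edge.
#'
#' @param truth Output of [build_decamer_truth()].
#' @param spec The [phantom_spec] used to build it.
#' @return A [density_map].
#' @export
render_map <- function(truth, spec) {
  N <- spec$N
  cc <- N %/% 2
  sg <- spec$blob_sigma
  amp <- c(wall = unname(spec$amplitudes["wall"]),
           "FU-g" = unname(spec$amplitudes["fu_g"]),
           "FU-dstar" = unname(spec$amplitudes["fu_dstar"]))
  grid <- array(0, dim = c(N, N, N))
  ext <- ceiling(4 * sg)
  for (i in seq_len(nrow(truth))) {
    p <- c(truth$x[i], truth$y[i], truth$z[i]) + cc       # 0-based voxel coords
    if (any(p < 3 * sg - 1) || any(p > N - 1 - 3 * sg + 1))
      warning("centroid within 3 sigma of box edge (row ", i, ")")
    a <- amp[[truth$role[i]]]
    ix <- max(0, floor(p[1] - ext)):min(N - 1, ceiling(p[1] + ext))
    iy <- max(0, floor(p[2] - ext)):min(N - 1, ceiling(p[2] + ext))
    iz <- max(0, floor(p[3] - ext)):min(N - 1, ceiling(p[3] + ext))
    gx <- exp(-(ix - p[1])^2 / (2 * sg^2))
    gy <- exp(-(iy - p[2])^2 / (2 * sg^2))
    gz <- exp(-(iz - p[3])^2 / (2 * sg^2))
    grid[ix + 1, iy + 1, iz + 1] <- grid[ix + 1, iy + 1, iz + 1] +
      a * outer(outer(gx, gy), gz)
  }
  density_map(grid, spec$voxel_size)
}

#' Default wall/collar/outer masks for a phantom geometry
#'
#' Splits the box at the mid-radius between collar and wall with a
#' raised-cosine transition: collar + wall = outer exactly (a partition of
#' unity), so recombining the two regions conserves density and repeated
#' reference adjustment does not erode mask edges. The outer
#' background mask is binary for the same reason (masking twice must equal
#' masking once).
#'
#' @param spec A [phantom_spec].
#' @param edge_width Raised-cosine width of the wall/collar transition,
#'   voxels.
#' @return List with `wall`, `collar`, `outer` `soft_mask`s.
#' @export
default_masks <- function(spec, edge_width = 3) {
  N <- spec$N
  r_split <- (spec$r_collar + spec$r_wall) / 2
  r_out <- min(spec$r_wall + 8, N / 2)
  z_out <- min(spec$wall_z_half + 8, N / 2 - 1)
  outer <- cylindrical_mask(N, 0, r_out, z_out, edge_width = 0)
  cc <- N %/% 2
  x <- (seq_len(N) - 1) - cc
  r <- sqrt(outer(x^2, x^2, "+"))
  ## radial collar weight: 1 inside r_split - edge, 0 beyond r_split
  q <- pmin(pmax((r_split - r) / max(edge_width, 1e-9), 0), 1)
  q <- 0.5 * (1 - cos(pi * q))
  q3 <- array(q, dim = c(N, N, N))
  collar <- structure(list(grid = outer$grid * q3, edge_width = edge_width),
                      class = "soft_mask")
  wall <- structure(list(grid = outer$grid * (1 - q3),
                         edge_width = edge_width),
                    class = "soft_mask")
  list(wall = wall, collar = collar, outer = outer)
}

#' Shift an image by (dx, dy)
#'
#' Fourier phase-ramp shift (periodic); `out(x) = img(x - d)`. Exact for any
#' real-valued shift.
#' @param img Square numeric matrix.
#' @param dx,dy Shift in pixels.
#' @return Matrix of the same size.
#' @export
shift_image <- function(img, dx, dy) {
  N <- nrow(img)
  f <- 0:(N - 1)
  f[f > N / 2] <- f[f > N / 2] - N
  ph <- exp(-2i * pi * outer(f * dx, f * dy, "+") / N)
  Re(fft(fft(img) * ph, inverse = TRUE)) / N^2
}

.ctf_curve <- function(s2, defocus_A, voltage_kV = 300, cs_mm = 2.7,
                       amp_contrast = 0.07) {
  ## standard phase-contrast CTF; s2 = spatial frequency squared (1/A^2)
  lambda <- 12.2639 / sqrt(voltage_kV * 1e3 + 0.97845 * voltage_kV^2)
  chi <- pi * lambda * defocus_A * s2 -
    pi / 2 * (cs_mm * 1e7) * lambda^3 * s2^2
  -(sqrt(1 - amp_contrast^2) * sin(chi) + amp_contrast * cos(chi))
}

#' Simulate a particle stack from a map
#'
#' Projects the map at orientations drawn uniformly over SO(3) (or a
#' side-view-rich distribution), applies a uniform random in-plane shift in
#' -shift_max..shift_max, optionally modulates by a phase-contrast CTF,
#' and adds white Gaussian noise with variance = (per-image signal variance) /
#' `snr`. Fully reproducible from `seed`; the particle parity (even/odd index)
#' defines the gold-standard half-set split.
#'
#' @param map A [density_map].
#' @param n Number of particles (>= 1).
#' @param snr Signal-to-noise ratio (> 0; variance ratio).
#' @param shift_max Maximum |shift| in voxels (must be < N/4).
#' @param seed Integer seed.
#' @param ctf `NULL` (default, no CTF) or a list with `defocus_A` and
#'   optionally `voltage_kV`, `cs_mm`, `amp_contrast`.
#' @param view_dist `"uniform"` or `"side"` (side-view-rich: theta ~
#'   N(90, 15 deg), clamped).
#' @return An object of class `particle_stack`: `images` (N x N x n array),
#'   `pixel_size`, and `meta` (data frame with true `phi`, `theta`, `psi`,
#'   `dx`, `dy`, `half_set`, and empty assignment columns).
#' @export
simulate_particles <- function(map, n, snr, shift_max = 2, seed = 1,
                               ctf = NULL, view_dist = c("uniform", "side")) {
  view_dist <- match.arg(view_dist)
  N <- map_size(map)
  if (n < 1) stop("n must be >= 1")
  if (snr <= 0) stop("snr must be positive")
  if (shift_max >= N / 4) stop("shift_max must be < N/4")
  set.seed(seed)
  phi <- runif(n, 0, 360)
  psi <- runif(n, 0, 360)
  theta <- if (view_dist == "uniform") acos(runif(n, -1, 1)) * 180 / pi
           else pmin(pmax(rnorm(n, 90, 15), 0), 180)
  dx <- runif(n, -shift_max, shift_max)
  dy <- runif(n, -shift_max, shift_max)
  ctf_mat <- NULL
  if (!is.null(ctf)) {
    f <- 0:(N - 1)
    f[f > N / 2] <- f[f > N / 2] - N
    f <- f / (N * map$voxel_size)
    s2 <- outer(f^2, f^2, "+")
    ctf_mat <- do.call(.ctf_curve, c(list(s2 = s2), ctf))
  }
  images <- array(0, dim = c(N, N, n))
  for (i in seq_len(n)) {
    img <- project_cpp(map$grid, euler_to_matrix(phi[i], theta[i], psi[i]))
    if (!is.null(ctf_mat))
      img <- Re(fft(fft(img) * ctf_mat, inverse = TRUE)) / N^2
    img <- shift_image(img, dx[i], dy[i])
    sd_noise <- sqrt(stats::var(as.vector(img)) / snr)
    images[, , i] <- img + rnorm(N * N, 0, sd_noise)
  }
  meta <- data.frame(phi = phi, theta = theta, psi = psi, dx = dx, dy = dy,
                     half_set = (seq_len(n) - 1L) %% 2L,
                     score = NA_real_)
  structure(list(images = images, pixel_size = map$voxel_size, meta = meta),
            class = "particle_stack")
}

#' @export
print.particle_stack <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("<particle_stack> %d images of %dx%d px, %.4g A/px\n",
              d[3], d[1], d[2], x$pixel_size))
  invisible(x)
}

#' Write / read a particle stack (MRC stack + CSV metadata)
#'
#' Images go to an MRC2014 stack (float32); per-particle metadata (columns in
#' the order phi, theta, psi, dx, dy, half_set, score) to a CSV next to it.
#'
#' @param stack A `particle_stack`.
#' @param path Path to the `.mrcs` stack; metadata CSV uses the same path with
#'   extension `.csv`.
#' @return `write_particle_stack()` the path, invisibly;
#'   `read_particle_stack()` a `particle_stack`.
#' @export
write_particle_stack <- function(stack, path) {
  d <- dim(stack$images)
  .mrc_write_raw(stack$images, d, stack$pixel_size, c(0, 0, 0), path, ispg = 0L)
  write.csv(stack$meta, paste0(tools::file_path_sans_ext(path), ".csv"),
            row.names = FALSE)
  invisible(path)
}

#' @rdname write_particle_stack
#' @export
read_particle_stack <- function(path) {
  raw <- .mrc_read_raw(path)
  d <- raw$dims
  if (d[1] != d[2]) stop("stack images must be square")
  meta_path <- paste0(tools::file_path_sans_ext(path), ".csv")
  meta <- if (file.exists(meta_path)) read.csv(meta_path)
          else data.frame(phi = rep(NA_real_, d[3]), theta = NA_real_,
                          psi = NA_real_, dx = NA_real_, dy = NA_real_,
                          half_set = (seq_len(d[3]) - 1L) %% 2L,
                          score = NA_real_)
  structure(list(images = array(raw$data, dim = d),
                 pixel_size = raw$voxel_size, meta = meta),
            class = "particle_stack")
}
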