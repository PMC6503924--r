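#' Fourier shell correlation between two maps
#'
#' Per-shell normalized correlation of complex Fourier coefficients, shell
#' width one Fourier voxel, up to Nyquist. Optional soft pre-masking.
#'
#' @param mapA,mapB [density_map]s of identical shape and voxel size.
#' @param mask Optional `soft_mask` applied to both maps first.
#' @return An object of class `fsc_curve`: data frame with `shell_freq`
#'   (1/Angstrom, strictly increasing) and `fsc`.
#' @export
fsc <- function(mapA, mapB, mask = NULL) {
  stopifnot_same_shape(mapA, mapB)
  if (abs(mapA$voxel_size - mapB$voxel_size) > 1e-6)
    stop("voxel sizes differ")
  ga <- mapA$grid
  gb <- mapB$grid
  if (!is.null(mask)) {
    stopifnot_same_shape(mapA, mask)
    ga <- ga * mask$grid
    gb <- gb * mask$grid
  }
  N <- dim(ga)[1]
  Fa <- fft(ga)
  Fb <- fft(gb)
  f <- 0:(N - 1)
  f[f > N / 2] <- f[f > N / 2] - N
  shell <- round(sqrt(outer(outer(f^2, f^2, "+"),
                            f^2, "+")))  # N^3 array of shell indices
  nshell <- N %/% 2
  keep <- shell <= nshell
  sh <- as.vector(shell[keep]) + 1L
  ab <- Re(Fa[keep] * Conj(Fb[keep]))
  aa <- Mod(Fa[keep])^2
  bb <- Mod(Fb[keep])^2
  num <- as.vector(rowsum(ab, sh))
  den <- sqrt(as.vector(rowsum(aa, sh)) * as.vector(rowsum(bb, sh)))
  vals <- ifelse(den > 0, num / den, 0)
  curve <- data.frame(shell_freq = (0:nshell) / (N * mapA$voxel_size),
                      fsc = vals)
  class(curve) <- c("fsc_curve", "data.frame")
  curve
}

#' Resolution at an FSC threshold
#'
#' Reciprocal of the first frequency at which the curve falls below the
#' threshold, linearly interpolated between shells; returns the Nyquist
#' resolution if the curve never crosses.
#'
#' @param curve An [fsc()] result.
#' @param threshold FSC threshold (0.143 for the gold-standard criterion).
#' @return Resolution in Angstrom.
#' @export
resolution_at <- function(curve, threshold = 0.143) {
  if (nrow(curve) == 0) stop("empty FSC curve")
  below <- which(curve$fsc < threshold)
  below <- below[below > 1]             # ignore the DC shell
  if (length(below) == 0)
    return(1 / max(curve$shell_freq))
  i <- below[1]
  f0 <- curve$shell_freq[i - 1]; f1 <- curve$shell_freq[i]
  v0 <- curve$fsc[i - 1]; v1 <- curve$fsc[i]
  fc <- if (v0 <= threshold) f0 else f0 + (v0 - threshold) / (v0 - v1) * (f1 - f0)
  1 / fc
}

#' Masked Pearson correlation between two maps
#'
#' @param mapA,mapB [density_map]s of identical shape.
#' @param mask A `soft_mask`; only voxels with mask > 0.5 enter.
#' @return Pearson correlation coefficient.
#' @export
map_correlation <- function(mapA, mapB, mask) {
  stopifnot_same_shape(mapA, mapB)
  stopifnot_same_shape(mapA, mask)
  sel <- mask$grid > 0.5
  if (!any(sel)) stop("empty mask: no voxels with mask > 0.5")
  cor(mapA$grid[sel], mapB$grid[sel])
}

#' Register a map onto a reference over a point group
#'
#' The refined map may legitimately sit in any wall-equivalent frame; this
#' searches all group operators for the one maximizing the masked correlation
#' with the reference.
#'
#' @param map,reference [density_map]s.
#' @param mask `soft_mask` defining the comparison region (the collar).
#' @param group A [point_group].
#' @return List with `map` (the best-registered rotated map),
#'   `operator_index`, `correlation`.
#' @export
register_map <- function(map, reference, mask, group) {
  best <- NULL
  for (i in seq_along(group$operators)) {
    rot <- rotate_map(map, group$operators[[i]])
    cc <- map_correlation(rot, reference, mask)
    if (is.null(best) || cc > best$correlation)
      best <- list(map = rot, operator_index = i, correlation = cc)
  }
  best
}

#' Combine two half-maps after symmetry registration
#'
#' The wall-equivalent frame of each independently refined half-set is a
#' gauge freedom, and frames related by certain flips share most collar
#' sites, so plain masked correlation can mis-register by exactly such a
#' flip and average the break region away. When a `spec` is supplied, each
#' half is therefore brought to the canonical frame defined by its own
#' collar hemisphere readout (the symmetry break is the fiducial); masked
#' correlation over the group is the fallback when a readout is
#' undetermined (e.g. for symmetrized controls).
#'
#' @param half0,half1 [density_map]s.
#' @param mask Collar `soft_mask` used for correlation registration.
#' @param group A [point_group].
#' @param spec Optional [phantom_spec] enabling canonical (readout-based)
#'   registration.
#' @return List with `map` (the combined [density_map]), `operator_index`
#'   (the operator applied to `half1` relative to `half0`), `correlation`
#'   (half-map agreement in the mask after registration), and `method`
#'   (`"canonical"` or `"correlation"`).
#' @export
combine_half_maps <- function(half0, half1, mask, group, spec = NULL) {
  canonical <- c("N", "S", "N", "S", "N")
  if (!is.null(spec)) {
    r0 <- collar_readout(half0, spec, group)
    r1 <- collar_readout(half1, spec, group)
    if (identical(r0$pattern, canonical) && identical(r1$pattern, canonical)) {
      m0 <- rotate_map(half0, r0$operator)
      m1 <- rotate_map(half1, r1$operator)
      return(list(map = density_map((m0$grid + m1$grid) / 2,
                                    half0$voxel_size, half0$origin),
                  operator_index = r1$operator_index,
                  correlation = map_correlation(m0, m1, mask),
                  method = "canonical"))
    }
  }
  reg <- register_map(half1, half0, mask, group)
  list(map = density_map((half0$grid + reg$map$grid) / 2, half0$voxel_size,
                         half0$origin),
       operator_index = reg$operator_index,
       correlation = reg$correlation,
       method = "correlation")
}

.readout_windows <- function(spec) {
  ## canonical N/S integration windows at the five dimer loci; rows of the
  ## returned matrices are window centres (voxel coords relative to centre)
  deg <- pi / 180
  pol <- function(r, az, z) c(r * cos(az * deg), r * sin(az * deg), z)
  lapply(0:4, function(k) {
    A <- 72 * k
    list(N = rbind(pol(spec$r_collar, A, spec$z_polar),
                   pol(spec$r_collar, A + 20, spec$z_equatorial)),
         S = rbind(pol(spec$r_collar, A, -spec$z_polar),
                   pol(spec$r_collar, A - 20, -spec$z_equatorial)))
  })
}

.window_sum <- function(grid, centers, radius, cc) {
  N <- dim(grid)[1]
  tot <- 0
  for (i in seq_len(nrow(centers))) {
    p <- centers[i, ] + cc
    ix <- max(0, floor(p[1] - radius)):min(N - 1, ceiling(p[1] + radius))
    iy <- max(0, floor(p[2] - radius)):min(N - 1, ceiling(p[2] + radius))
    iz <- max(0, floor(p[3] - radius)):min(N - 1, ceiling(p[3] + radius))
    if (length(ix) == 0 || length(iy) == 0 || length(iz) == 0) next
    d2 <- outer(outer((ix - p[1])^2, (iy - p[2])^2, "+"), (iz - p[3])^2, "+")
    sub <- grid[ix + 1, iy + 1, iz + 1]
    tot <- tot + sum(sub[d2 <= radius^2])
  }
  tot
}

#' Read out the collar hemisphere pattern of a map
#'
#' Integrates density in northern vs southern windows at the five FU-g dimer
#' loci of the phantom geometry, for each of the 10 D5 registration operators
#' (the refined frame is only defined up to a wall symmetry). Each locus is
#' labelled by its dominant hemisphere, or `"U"` (undetermined) when the
#' N/S contrast falls below `contrast_floor` -- a fully symmetrized collar is
#' undetermined at every locus by construction. Among the operators, one
#' yielding the canonical fully-determined alternating pattern
#' `N,S,N,S,N` is preferred; otherwise the operator with the highest mean
#' contrast is reported.
#'
#' @param map A [density_map] on the spec's grid.
#' @param spec The [phantom_spec] describing the geometry.
#' @param group Registration group (default D5).
#' @param window_radius Integration window radius, voxels.
#' @param contrast_floor Minimum `|N - S| / (N + S)` to call a hemisphere.
#' @return List with `pattern` (5 labels over N/S/U), `contrast` (per-locus),
#'   `mean_contrast`, `operator_index`, `operator`.
#' @export
collar_readout <- function(map, spec, group = point_group("D", 5),
                           window_radius = 3, contrast_floor = 0.05) {
  if (map_size(map) != spec$N)
    stop("map grid (", map_size(map), ") does not match spec N = ", spec$N)
  windows <- .readout_windows(spec)
  cc <- spec$N %/% 2
  grid <- pmax(map$grid, 0)             # robust to negative background
  canonical <- c("N", "S", "N", "S", "N")
  evals <- lapply(seq_along(group$operators), function(oi) {
    g <- group$operators[[oi]]
    lab <- character(5)
    con <- numeric(5)
    for (k in 1:5) {
      ## window integral of (g.map) = integral of map over g^-1-moved windows
      cN <- windows[[k]]$N %*% g
      cS <- windows[[k]]$S %*% g
      iN <- .window_sum(grid, cN, window_radius, cc)
      iS <- .window_sum(grid, cS, window_radius, cc)
      tot <- iN + iS
      con[k] <- if (tot > 0) abs(iN - iS) / tot else 0
      lab[k] <- if (con[k] < contrast_floor) "U"
                else if (iN > iS) "N" else "S"
    }
    list(pattern = lab, contrast = con, mean_contrast = mean(con),
         operator_index = oi)
  })
  valid <- vapply(evals, function(e) identical(e$pattern, canonical), logical(1))
  pick <- if (any(valid)) which(valid)[1]
          else which.max(vapply(evals, `[[`, numeric(1), "mean_contrast"))
  out <- evals[[pick]]
  out$operator <- group$operators[[out$operator_index]]
  out
}

#' Write an FSC curve as a two-column CSV
#' @param curve An [fsc()] result.
#' @param path Output path.
#' @export
write_fsc_csv <- function(curve, path) {
  write.csv(as.data.frame(curve)[, c("shell_freq", "fsc")], path,
            row.names = FALSE)
  invisible(path)
}
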