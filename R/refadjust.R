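#' Configuration for per-iteration reference adjustment
#'
#' Bundles everything the reference-adjustment step needs: the wall point
#' group, the collar weighting factor, the three region masks and the number
#' of refinement rounds during which the adjustment is active.
#'
#' @param group [point_group] of the wall (D5 for the decamer).
#' @param wall_mask,collar_mask,outer_mask `soft_mask`s sharing one shape.
#' @param collar_scale Collar up-weighting factor (> 0; 1.5 reproduces the
#'   weighting found optimal for the hemocyanin refinement).
#' @param active_rounds Number of initial refinement rounds with the
#'   adjustment applied (>= 0); later rounds are plain local refinements.
#' @return An object of class `adjust_config`.
#' @export
adjust_config <- function(group, wall_mask, collar_mask, outer_mask,
                          collar_scale = 1.5, active_rounds = 3) {
  if (!inherits(group, "point_group")) stop("`group` must be a point_group")
  if (collar_scale <= 0) stop("collar_scale must be positive")
  if (active_rounds < 0) stop("active_rounds must be >= 0")
  stopifnot_same_shape(wall_mask, collar_mask)
  stopifnot_same_shape(wall_mask, outer_mask)
  structure(list(group = group, collar_scale = collar_scale,
                 wall_mask = wall_mask, collar_mask = collar_mask,
                 outer_mask = outer_mask,
                 active_rounds = as.integer(active_rounds)),
            class = "adjust_config")
}

#' Adjust a refinement reference between iterations
#'
#' The "user function" applied to each half-volume after a refinement
#' iteration: the wall region is replaced by its point-group-symmetrized
#' version, the collar region is multiplied by `collar_scale` (preserving its
#' asymmetry exactly -- collar voxel ratios are unchanged), and the two are
#' recombined and background-masked. The output is the reference for the next
#' iteration of the same half-set.
#'
#' @param map A [density_map] (a half-set reconstruction).
#' @param cfg An [adjust_config].
#' @return A [density_map].
#' @export
adjust_reference <- function(map, cfg) {
  if (!inherits(cfg, "adjust_config")) stop("`cfg` must be an adjust_config")
  stopifnot_same_shape(map, cfg$wall_mask)
  sym <- symmetrize_map(map, cfg$group)
  collar <- density_map(map$grid * cfg$collar_scale, map$voxel_size,
                        map$origin)
  combine_regions(sym, collar, cfg$wall_mask, cfg$collar_mask, cfg$outer_mask)
}
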