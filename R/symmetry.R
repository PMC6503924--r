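#' Point-group operator sets (Cn, Dn)
#'
#' Builds the explicit rotation-operator set of a cyclic (`Cn`) or dihedral
#' (`Dn`) point group. The n-fold axis is z; for `Dn` the first two-fold axis
#' lies along +x, so the two-fold axes sit at azimuths `k * 180/n` degrees.
#' `Cn` has `n` operators, `Dn` has `2n`; the identity is always included and
#' the set is closed under composition.
#'
#' @param family `"C"` or `"D"`.
#' @param n Fold, integer >= 1.
#' @return An object of class `point_group` with fields `family`, `n`,
#'   `operators` (list of 3x3 rotation matrices).
#' @export
point_group <- function(family = c("C", "D"), n) {
  family <- match.arg(family)
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop("`n` must be an integer >= 1")
  n <- as.integer(n)
  rz <- function(a) {
    ca <- cos(a); sa <- sin(a)
    matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3)
  }
  c2x <- diag(c(1, -1, -1))  # two-fold about +x
  ops <- lapply(2 * pi * (0:(n - 1)) / n, rz)
  if (family == "D")
    ops <- c(ops, lapply(ops, function(R) c2x %*% R))
  structure(list(family = family, n = n, operators = ops),
            class = "point_group")
}

#' @rdname point_group
#' @export
group_operators <- function(family = c("C", "D"), n) point_group(family, n)

#' @export
print.point_group <- function(x, ...) {
  cat(sprintf("<point_group> %s%d (order %d)\n", x$family, x$n,
              length(x$operators)))
  invisible(x)
}

#' Parse a symmetry string like "C5" or "D5"
#' @param sym Character scalar, e.g. `"D5"`.
#' @return A [point_group].
#' @export
parse_symmetry <- function(sym) {
  if (!is.character(sym) || length(sym) != 1L ||
      !grepl("^[CD][0-9]+$", toupper(sym)))
    stop("invalid symmetry string: ", sym,
         " (expected Cn or Dn, e.g. \"D5\")")
  sym <- toupper(sym)
  point_group(substr(sym, 1, 1), as.integer(substring(sym, 2)))
}

#' Rotate a density map by a rotation operator
#'
#' Applies `(R.V)(v) = V(R^-1 v)` about the box centre with trilinear
#' interpolation; samples falling outside the box read as 0.
#'
#' @param map A [density_map].
#' @param R 3x3 rotation matrix.
#' @return A [density_map].
#' @export
rotate_map <- function(map, R) {
  density_map(rotate_map_cpp(map$grid, R), map$voxel_size, map$origin)
}

#' Symmetrize a map over a point group
#'
#' Returns the mean over all group operators of the rotated copies of the map.
#' The result is invariant under any group operator up to interpolation error,
#' and the grid sum (total mass) is conserved up to interpolation/edge loss.
#'
#' @param map A [density_map].
#' @param group A [point_group].
#' @return A [density_map].
#' @export
symmetrize_map <- function(map, group) {
  if (!inherits(group, "point_group")) stop("`group` must be a point_group")
  acc <- array(0, dim = dim(map$grid))
  for (R in group$operators) {
    acc <- acc + if (isTRUE(all.equal(R, diag(3), tolerance = 1e-12)))
      map$grid else rotate_map_cpp(map$grid, R)
  }
  density_map(acc / length(group$operators), map$voxel_size, map$origin)
}

#' Orbit of points under a point group
#'
#' @param points Numeric matrix (n x 3) of voxel coordinates relative to the
#'   box centre (or anything coercible to one; a length-3 vector is a single
#'   point).
#' @param group A [point_group].
#' @return A matrix with `nrow(points) * order(group)` rows: the images of
#'   every point under every operator, operator-major.
#' @export
orbit_points <- function(points, group) {
  points <- .as_point_matrix(points)
  if (nrow(points) == 0)
    return(matrix(numeric(0), ncol = 3))
  do.call(rbind, lapply(group$operators, function(R) points %*% t(R)))
}

.as_point_matrix <- function(points) {
  if (is.null(dim(points))) {
    if (length(points) == 0) return(matrix(numeric(0), ncol = 3))
    points <- matrix(points, ncol = 3)
  }
  storage.mode(points) <- "double"
  if (ncol(points) != 3) stop("points must have 3 columns")
  points
}

#' Single-linkage clustering of points
#'
#' Groups points whose single-linkage (minimum chain) distance is at most
#' `tol` and returns cluster centroids with member counts. Used to count the
#' distinct density sites produced by symmetry expansion, e.g. the 40 apparent
#' collar sites arising when the 20 true collar positions are spread over the
#' D5 orbit.
#'
#' @param points Numeric matrix (n x 3).
#' @param tol Linkage distance threshold (> 0), voxels.
#' @return List with `centroids` (k x 3 matrix) and `multiplicities`
#'   (integer k); multiplicities sum to `nrow(points)`.
#' @export
cluster_points <- function(points, tol = 1.0) {
  if (tol <= 0) stop("tol must be positive")
  points <- .as_point_matrix(points)
  n <- nrow(points)
  if (n == 0)
    return(list(centroids = matrix(numeric(0), ncol = 3),
                multiplicities = integer(0)))
  if (n == 1)
    return(list(centroids = points, multiplicities = 1L))
  cl <- cutree(hclust(dist(points), method = "single"), h = tol)
  k <- max(cl)
  cent <- matrix(0, k, 3)
  for (g in seq_len(k))
    cent[g, ] <- colMeans(points[cl == g, , drop = FALSE])
  list(centroids = cent, multiplicities = as.integer(tabulate(cl, k)))
}
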