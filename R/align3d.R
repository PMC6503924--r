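#' Euler angles (ZYZ intrinsic) to rotation matrix
#'
#' `R = Rz(phi) Ry(theta) Rz(psi)`, angles in degrees (SPIDER-style
#' convention, projection along +z). This is the single orientation
#' convention used throughout the package.
#'
#' @param phi,theta,psi Euler angles in degrees.
#' @return 3x3 rotation matrix.
#' @export
euler_to_matrix <- function(phi, theta, psi) {
  d <- pi / 180
  rz <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1),
                           3, 3)
  ry <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)),
                           3, 3)
  rz(phi * d) %*% ry(theta * d) %*% rz(psi * d)
}

.orient_rots <- function(phi, theta, psi) {
  ## vectorized Rz(phi) Ry(theta) Rz(psi) for many orientations
  d <- pi / 180
  c1 <- cos(phi * d); s1 <- sin(phi * d)
  c2 <- cos(theta * d); s2 <- sin(theta * d)
  c3 <- cos(psi * d); s3 <- sin(psi * d)
  rots <- array(0, dim = c(3, 3, length(phi)))
  rots[1, 1, ] <- c1 * c2 * c3 - s1 * s3
  rots[2, 1, ] <- s1 * c2 * c3 + c1 * s3
  rots[3, 1, ] <- -s2 * c3
  rots[1, 2, ] <- -c1 * c2 * s3 - s1 * c3
  rots[2, 2, ] <- -s1 * c2 * s3 + c1 * c3
  rots[3, 2, ] <- s2 * s3
  rots[1, 3, ] <- c1 * s2
  rots[2, 3, ] <- s1 * s2
  rots[3, 3, ] <- c2
  rots
}

.trilinear_complex <- function(arr, pts) {
  ## vectorized trilinear interpolation on a complex 3D array;
  ## pts: m x 3 in 0-based array coordinates; out-of-range -> 0
  N <- dim(arr)[1]
  m <- nrow(pts)
  out <- complex(m)
  ok <- pts[, 1] >= 0 & pts[, 1] <= N - 1 &
        pts[, 2] >= 0 & pts[, 2] <= N - 1 &
        pts[, 3] >= 0 & pts[, 3] <= N - 1
  if (!any(ok)) return(out)
  p <- pts[ok, , drop = FALSE]
  p0 <- pmin(floor(p), N - 2)
  f <- p - p0
  acc <- complex(nrow(p))
  for (oz in 0:1) for (oy in 0:1) for (ox in 0:1) {
    w <- (if (ox) f[, 1] else 1 - f[, 1]) *
         (if (oy) f[, 2] else 1 - f[, 2]) *
         (if (oz) f[, 3] else 1 - f[, 3])
    idx <- cbind(p0[, 1] + ox, p0[, 2] + oy, p0[, 3] + oz) + 1
    acc <- acc + w * arr[idx]
  }
  out[ok] <- acc
  out
}

#' Project a map along an orientation
#'
#' Computes the 2D projection of the map at Euler angles (phi, theta, psi):
#' the line integral along z after rotating the map (restricted to the
#' inscribed sphere of the box, the standard spherical support of a
#' single-particle box), then shifted by
#' (dx, dy). Two implementations are provided: direct real-space integration
#' (default) and extraction of the central Fourier slice; they agree to high
#' correlation on smooth maps (the Fourier slice theorem).
#'
#' @param map A [density_map].
#' @param orientation Named list/vector with `phi`, `theta`, `psi` (degrees)
#'   and optionally `dx`, `dy` (voxels).
#' @param method `"real"` or `"fourier"`.
#' @return N x N numeric matrix.
#' @export
project_map <- function(map, orientation, method = c("real", "fourier")) {
  method <- match.arg(method)
  o <- as.list(orientation)
  dx <- if (is.null(o$dx)) 0 else o$dx
  dy <- if (is.null(o$dy)) 0 else o$dy
  R <- euler_to_matrix(o$phi, o$theta, o$psi)
  if (method == "real") {
    img <- project_cpp(map$grid, R)
  } else {
    N <- map_size(map)
    cc <- N %/% 2
    ## 2x zero-padded (oversampled) volume transform for accurate
    ## interpolation between Fourier samples
    M <- 2L * N
    cm <- M %/% 2
    pad <- array(0, dim = c(M, M, M))
    off <- cm - cc
    pad[off + (1:N), off + (1:N), off + (1:N)] <- map$grid
    qm <- 0:(M - 1)
    phm <- exp(-2i * pi * (qm - cm) * cm / M)      # DFT -> centred spectrum
    Fc <- fft(pad)[((qm + cm) %% M) + 1, ((qm + cm) %% M) + 1,
                   ((qm + cm) %% M) + 1] /
      outer(outer(phm, phm), phm)
    q <- 0:(N - 1)
    h <- as.matrix(expand.grid(h1 = q - cc, h2 = q - cc))
    p3 <- cbind(2 * h, 0) %*% t(R)                 # slice at R h; padded 2h
    vals <- .trilinear_complex(Fc, p3 + cm)
    F2c <- matrix(vals, N, N)
    ## back to DFT ordering with the centring phase removed
    ph2 <- exp(-2i * pi * (q - cc) * cc / N)
    F2 <- (F2c * outer(ph2, ph2))[((q + cc) %% N) + 1, ((q + cc) %% N) + 1]
    img <- Re(fft(F2, inverse = TRUE)) / N^2
  }
  if (dx != 0 || dy != 0) img <- shift_image(img, dx, dy)
  img
}

#' Build an exhaustive projection-template bank
#'
#' Quasi-uniform grid over projection directions: theta sampled every
#' `angular_step` degrees, phi sampled area-weighted (about
#' `360 sin(theta) / angular_step` values per theta ring), psi uniform every
#' `psi_step`. Every template is mean-zero and unit-norm.
#'
#' @param reference A [density_map].
#' @param angular_step Out-of-plane step in degrees (>= 2).
#' @param psi_step In-plane step in degrees (defaults to `angular_step`).
#' @param subset Optional integer indices into the orientation grid; only
#'   these templates are rendered (used by the local search, which knows in
#'   advance which orientations are reachable).
#' @return An object of class `template_bank`: `templates` (N x N x n array),
#'   `orientations` (data frame phi/theta/psi), `rots` (3 x 3 x n array).
#' @export
make_template_bank <- function(reference, angular_step,
                               psi_step = angular_step, subset = NULL) {
  if (angular_step < 2) stop("angular_step must be >= 2 degrees")
  grid <- bank_orientation_grid(angular_step, psi_step)
  if (!is.null(subset)) grid <- grid[subset, , drop = FALSE]
  N <- map_size(reference)
  n <- nrow(grid)
  templates <- array(0, dim = c(N, N, n))
  rots <- .orient_rots(grid$phi, grid$theta, grid$psi)
  for (i in seq_len(n)) {
    img <- project_cpp(reference$grid, rots[, , i])
    img <- img - mean(img)
    nrm <- sqrt(sum(img^2))
    if (nrm > 0) img <- img / nrm
    templates[, , i] <- img
  }
  structure(list(templates = templates, orientations = grid, rots = rots),
            class = "template_bank")
}

## Fast bank builder used inside refine(): one exact projection per viewing
## direction, in-plane rotations for the psi copies (exact in the continuum;
## bilinear in practice). make_template_bank() stays the exact reference
## implementation.
.fast_template_bank <- function(reference, angular_step,
                                psi_step = angular_step, subset = NULL) {
  grid <- bank_orientation_grid(angular_step, psi_step)
  if (!is.null(subset)) grid <- grid[subset, , drop = FALSE]
  N <- map_size(reference)
  n <- nrow(grid)
  templates <- array(0, dim = c(N, N, n))
  base_imgs <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    key <- paste(grid$phi[i], grid$theta[i])
    img0 <- base_imgs[[key]]
    if (is.null(img0)) {
      img0 <- project_cpp(reference$grid,
                          euler_to_matrix(grid$phi[i], grid$theta[i], 0))
      base_imgs[[key]] <- img0
    }
    img <- if (grid$psi[i] == 0) img0 else rotate_image_cpp(img0, grid$psi[i])
    img <- img - mean(img)
    nrm <- sqrt(sum(img^2))
    if (nrm > 0) img <- img / nrm
    templates[, , i] <- img
  }
  structure(list(templates = templates, orientations = grid,
                 rots = .orient_rots(grid$phi, grid$theta, grid$psi)),
            class = "template_bank")
}

#' Orientation grid of a template bank (closed-form enumeration)
#' @rdname make_template_bank
#' @export
bank_orientation_grid <- function(angular_step, psi_step = angular_step) {
  thetas <- seq(0, 180, by = angular_step)
  psis <- seq(0, 360 - psi_step, by = psi_step)
  rows <- lapply(thetas, function(th) {
    n_phi <- max(1, round(360 * sin(th * pi / 180) / angular_step))
    phis <- seq(0, 360, length.out = n_phi + 1)[seq_len(n_phi)]
    expand.grid(phi = phis, theta = th, psi = psis)
  })
  do.call(rbind, rows)
}

#' Assign orientations by exhaustive projection matching
#'
#' For every particle, finds the template and integer in-plane shift
#' maximizing the normalized cross-correlation (scores between -1 and 1; ties
#' resolved to the lowest bank index). Optionally restricts each particle to
#' a candidate subset of the bank (local / symmetry-relaxed search).
#'
#' @param stack A `particle_stack` (or plain N x N x n array).
#' @param bank A [make_template_bank()] result.
#' @param shift_range Maximum |integer shift| searched, voxels.
#' @param candidates Optional list (one integer vector of 1-based bank
#'   indices per particle).
#' @param freq_cut Fourier band limit of the matched filter in Fourier
#'   voxels; defaults to N/4 (half-Nyquist), which covers the full power of
#'   the Gaussian-blob references.
#' @return Data frame with `phi`, `theta`, `psi`, `dx`, `dy`, `score`,
#'   `template` per particle.
#' @export
assign_orientations <- function(stack, bank, shift_range = 2,
                                candidates = NULL, freq_cut = NULL) {
  images <- if (inherits(stack, "particle_stack")) stack$images else stack
  if (length(dim(images)) != 3 || dim(images)[3] < 1) stop("empty stack")
  if (!inherits(bank, "template_bank") || dim(bank$templates)[3] < 1)
    stop("empty template bank")
  if (is.null(freq_cut)) freq_cut <- dim(images)[1] %/% 4
  res <- assign_cpp(images, bank$templates, as.integer(shift_range),
                    if (is.null(candidates)) list() else candidates,
                    as.integer(freq_cut))
  o <- bank$orientations[res$template, ]
  data.frame(phi = o$phi, theta = o$theta, psi = o$psi,
             dx = res$dx, dy = res$dy, score = res$score,
             template = res$template, row.names = NULL)
}

#' Reconstruct a map from oriented particles
#'
#' Direct Fourier inversion: each image's 2D transform is inserted as a
#' central slice at its assigned orientation with trilinear gridding, the
#' accumulated transform is divided by the accumulated weights (plus an
#' epsilon of 1e-3 of the maximum weight), and inverse-transformed.
#'
#' @param stack A `particle_stack` or N x N x n array.
#' @param orientations Data frame with `phi`, `theta`, `psi`, `dx`, `dy` per
#'   particle (defaults to the stack's true metadata).
#' @param subset Optional integer indices of particles to use.
#' @return A [density_map].
#' @export
reconstruct <- function(stack, orientations = NULL, subset = NULL) {
  images <- if (inherits(stack, "particle_stack")) stack$images else stack
  px <- if (inherits(stack, "particle_stack")) stack$pixel_size else 1
  if (is.null(orientations) && inherits(stack, "particle_stack"))
    orientations <- stack$meta
  if (is.null(orientations)) stop("orientations required")
  if (!is.null(subset)) {
    images <- images[, , subset, drop = FALSE]
    orientations <- orientations[subset, , drop = FALSE]
  }
  n <- dim(images)[3]
  if (n < 1) stop("empty stack")
  if (nrow(orientations) != n)
    stop("orientations rows (", nrow(orientations),
         ") do not match particle count (", n, ")")
  rots <- .orient_rots(orientations$phi, orientations$theta,
                       orientations$psi)
  shifts <- cbind(orientations$dx, orientations$dy)
  acc <- insert_slices_cpp(images, rots, shifts)
  N <- dim(images)[1]
  cc <- N %/% 2
  eps <- 1e-3 * max(acc$W)
  Vc <- acc$A / (acc$W + eps)
  q <- 0:(N - 1)
  ord <- ((q + cc) %% N) + 1
  ph <- exp(-2i * pi * (q - cc) * cc / N)           # remove centring phase
  B <- Vc[ord, ord, ord] * outer(outer(ph[ord], ph[ord]), ph[ord])
  v <- Re(fft(B, inverse = TRUE)) / N^3
  density_map(v, px)
}

#' Refinement configuration
#'
#' @param iterations Total refinement iterations (>= 1).
#' @param angular_step Strictly decreasing schedule of angular steps in
#'   degrees, one per iteration (coarse to fine).
#' @param shift_range Integer shift search range, voxels.
#' @param adjust An [adjust_config]; its `active_rounds` K controls how many
#'   initial iterations apply the reference adjustment. Iterations 2..K use a
#'   symmetry-relaxed local search (candidates within 2x the current step of
#'   any wall-symmetry-equivalent of the previous assignment); iterations
#'   after K are strictly local.
#' @param seed Integer seed recorded with the run.
#' @param frame_relax Allow the symmetry-relaxed local search while the
#'   adjustment is active (default TRUE); FALSE restricts every post-global
#'   search to the plain neighbourhood of the previous assignment.
#' @return An object of class `refine_config`.
#' @export
refine_config <- function(iterations = 6,
                          angular_step = c(30, 25, 20, 15, 12, 10),
                          shift_range = 2, adjust, seed = 1L,
                          frame_relax = TRUE) {
  if (iterations < 1) stop("iterations must be >= 1")
  if (length(angular_step) != iterations)
    stop("angular_step schedule must have one entry per iteration")
  if (any(diff(angular_step) >= 0))
    stop("angular_step schedule must be strictly decreasing")
  if (!inherits(adjust, "adjust_config"))
    stop("`adjust` must be an adjust_config")
  structure(list(iterations = as.integer(iterations),
                 angular_step = angular_step,
                 shift_range = as.integer(shift_range), adjust = adjust,
                 seed = as.integer(seed),
                 frame_relax = isTRUE(frame_relax)),
            class = "refine_config")
}

#' Gold-standard projection-matching refinement with reference adjustment
#'
#' Splits the stack into half-sets by particle parity and refines each
#' independently: per iteration, orientations are assigned against the
#' half-set's own reference, a new map is reconstructed, and -- during the
#' first `active_rounds` iterations -- the reference-adjustment step
#' (wall symmetrization + collar weighting) is applied before the next
#' round. Later iterations are local refinements without adjustment. The two
#' half-set references never mix. Deterministic given the stack.
#'
#' @param stack A `particle_stack`.
#' @param initial_reference A [density_map] used to seed both half-sets.
#' @param cfg A [refine_config].
#' @param verbose Log per-iteration timing to stderr.
#' @return List with `half_maps` (two [density_map]s), `orientations` (final
#'   assignment for the full stack), `history` (per iteration/half-set mean
#'   score and timing), `trace` (per-iteration assignment tables) and `cfg`.
#' @export
refine <- function(stack, initial_reference, cfg, verbose = FALSE) {
  stopifnot(inherits(stack, "particle_stack"),
            inherits(cfg, "refine_config"))
  K <- cfg$adjust$active_rounds
  sym_ops <- cfg$adjust$group$operators
  sym_cube <- array(unlist(sym_ops), dim = c(3, 3, length(sym_ops)))
  id_cube <- array(diag(3), dim = c(3, 3, 1))
  n <- dim(stack$images)[3]
  halves <- lapply(0:1, function(h) which(stack$meta$half_set == h))
  refs <- list(initial_reference, initial_reference)
  prev <- list(NULL, NULL)
  prev_score <- c(NA_real_, NA_real_)
  history <- list()
  trace <- list()
  final_orient <- data.frame(phi = numeric(n), theta = numeric(n),
                             psi = numeric(n), dx = integer(n),
                             dy = integer(n), score = numeric(n),
                             template = integer(n))
  for (it in seq_len(cfg$iterations)) {
    step <- cfg$angular_step[it]
    for (h in 1:2) {
      t0 <- proc.time()[3]
      idx <- halves[[h]]
      if (it == 1) {
        ## exhaustive global search over the full bank
        bank <- .fast_template_bank(refs[[h]], step)
        cand <- NULL
      } else {
        ## local (it > K) or symmetry-relaxed local (it <= K) search:
        ## determine the reachable orientations first, render only those
        grid <- bank_orientation_grid(step)
        rots_full <- .orient_rots(grid$phi, grid$theta, grid$psi)
        prev_rots <- .orient_rots(prev[[h]]$phi, prev[[h]]$theta,
                                  prev[[h]]$psi)
        cand_full <- candidates_cpp(rots_full, prev_rots,
                                    if (it <= K && cfg$frame_relax) sym_cube
                                    else id_cube,
                                    2 * step)
        used <- sort(unique(unlist(cand_full)))
        bank <- .fast_template_bank(refs[[h]], step, subset = used)
        cand <- lapply(cand_full, function(v) match(v, used))
      }
      asn <- assign_orientations(stack$images[, , idx, drop = FALSE], bank,
                                 cfg$shift_range, cand)
      ms <- mean(asn$score)
      if (!is.na(prev_score[h]) && ms < 0.5 * prev_score[h])
        stop(sprintf(paste0("refinement diverged: half-set %d mean score ",
                            "dropped from %.4f to %.4f at iteration %d"),
                     h - 1, prev_score[h], ms, it))
      prev_score[h] <- ms
      recon <- reconstruct(stack$images[, , idx, drop = FALSE], asn)
      recon$voxel_size <- stack$pixel_size
      refs[[h]] <- if (it <= K) adjust_reference(recon, cfg$adjust) else recon
      prev[[h]] <- asn
      el <- proc.time()[3] - t0
      history[[length(history) + 1]] <-
        data.frame(iteration = it, half_set = h - 1, angular_step = step,
                   templates = nrow(bank$orientations), mean_score = ms,
                   adjusted = it <= K, seconds = el)
      trace[[paste0("it", it, "_h", h - 1)]] <- asn
      if (verbose)
        message(sprintf("iter %d half %d: step %g, %d templates, score %.4f, %.1fs",
                        it, h - 1, step, nrow(bank$orientations), ms, el))
    }
  }
  for (h in 1:2) final_orient[halves[[h]], ] <- prev[[h]]
  list(half_maps = refs, orientations = final_orient,
       history = do.call(rbind, history), trace = trace, cfg = cfg)
}

#' Geodesic orientation error after symmetry registration
#'
#' Rotation angle (degrees) between assigned and true orientations, minimized
#' over the operators of `group` (orientations that differ by a symmetry of
#' the reference are equivalent).
#'
#' @param assigned,truth Data frames with `phi`, `theta`, `psi`.
#' @param group Optional [point_group]; `NULL` compares directly.
#' @return Numeric vector of angles, degrees.
#' @export
orientation_error <- function(assigned, truth, group = NULL) {
  n <- nrow(assigned)
  Ra <- .orient_rots(assigned$phi, assigned$theta, assigned$psi)
  Rt <- .orient_rots(truth$phi, truth$theta, truth$psi)
  ops <- if (is.null(group)) list(diag(3)) else group$operators
  err <- numeric(n)
  for (i in seq_len(n)) {
    cmax <- -1
    for (S in ops) {
      Req <- S %*% Rt[, , i]
      ctr <- (sum(Ra[, , i] * Req) - 1) / 2
      if (ctr > cmax) cmax <- ctr
    }
    err[i] <- acos(pmin(pmax(cmax, -1), 1)) * 180 / pi
  }
  err
}
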