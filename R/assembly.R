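#' Minimum number of adjacent equal pairs on a labelled ring
#'
#' Exhaustively enumerates all 2^n binary labelings of a circular ring of
#' length n and returns the minimum count of adjacent equal pairs. Even rings
#' can alternate perfectly (0); odd rings are forced into at least one equal
#' adjacency -- the combinatorial origin of the collar symmetry break in a
#' five-dimer ring.
#'
#' @param ring_length Ring size, integer >= 3 (kept small; enumeration is
#'   exact).
#' @return Integer minimum count of adjacent equal pairs.
#' @export
min_adjacent_equal <- function(ring_length) {
  if (ring_length < 3) stop("ring_length must be >= 3")
  n <- as.integer(ring_length)
  best <- n
  for (m in 0:(2^n - 1)) {
    bits <- bitwAnd(bitwShiftR(m, 0:(n - 1)), 1L)
    eq <- sum(bits == bits[c(2:n, 1)])
    if (eq < best) best <- eq
  }
  best
}

#' Assemble the decamer from a ring arrangement
#'
#' Maps a hemisphere pattern of the five FU-g dimers (a length-5 ring over
#' N/S with exactly one adjacent equal pair -- a "squid-type" arrangement)
#' onto the ten-protomer conformer labelling: the four dimers after the break
#' are alternately conformer-1 and conformer-2 homodimers, and the dimer
#' closing the ring at the break is the conformer-3/4 heterodimer. Protomer
#' numbering starts at the first dimer after the break (protomers 01, 02) and
#' proceeds around the ring, so the heterodimer is always protomers 09
#' (conformer 3) and 10 (conformer 4).
#'
#' @param pattern Character vector of length 5 over `"N"`/`"S"` (circular).
#' @return An object of class `decamer_assembly`: `conformer` (integer
#'   vector of length 10 indexed by protomer), `dimers` (5 x 2 matrix of
#'   protomer pairs, heterodimer last), `break_dimer` (index of the
#'   ring-closing dimer in the input pattern), `census` (named counts).
#' @export
assemble_decamer <- function(pattern) {
  if (length(pattern) != 5L || !all(pattern %in% c("N", "S")))
    stop("pattern must be 5 labels over N/S")
  eq <- which(pattern == pattern[c(2:5, 1)])  # i: pattern[i] == pattern[i+1]
  if (length(eq) != 1L)
    stop("not a squid-type arrangement: ", length(eq),
         " adjacent equal pairs (need exactly 1)")
  brk <- eq                                    # heterodimer closes the ring
  ring_order <- ((brk + 0:3) %% 5) + 1         # the four homodimers, in ring order
  conformer <- integer(10)
  dimers <- matrix(0L, 5, 2)
  for (m in 0:3) {
    conf <- if (m %% 2 == 0) 1L else 2L
    prot <- c(2L * m + 1L, 2L * m + 2L)
    conformer[prot] <- conf
    dimers[m + 1, ] <- prot
  }
  conformer[9L] <- 3L
  conformer[10L] <- 4L
  dimers[5, ] <- c(9L, 10L)
  structure(list(conformer = conformer, dimers = dimers,
                 break_dimer = as.integer(brk),
                 ring_order = c(ring_order, brk),
                 census = table(factor(conformer, levels = 1:4))),
            class = "decamer_assembly")
}

#' @export
print.decamer_assembly <- function(x, ...) {
  cat("<decamer_assembly> conformers by protomer 01-10:",
      paste(x$conformer, collapse = " "), "\n")
  cat("  census:", paste(sprintf("conf%d x%d", 1:4, as.integer(x$census)),
                         collapse = ", "), "\n")
  invisible(x)
}

## ------------------------------------------------------- coordinate models

#' Labelled coordinate model
#'
#' Per-chain, per-functional-unit ordered 3D coordinates (Angstrom) of
#' representative atoms (alpha-carbons when read from a structure file).
#'
#' @param chains Named list; each element a named list mapping FU name to an
#'   n x 3 numeric matrix.
#' @return An object of class `coord_model`.
#' @export
coord_model <- function(chains) {
  if (length(chains) == 0 || is.null(names(chains)))
    stop("chains must be a non-empty named list")
  for (ch in names(chains)) {
    if (length(chains[[ch]]) == 0 || is.null(names(chains[[ch]])))
      stop("chain ", ch, " has no named FU selections")
    for (fu in names(chains[[ch]])) {
      m <- chains[[ch]][[fu]]
      if (!is.matrix(m) || ncol(m) != 3 || nrow(m) == 0)
        stop("selection ", ch, "/", fu, " must be a non-empty n x 3 matrix")
    }
  }
  structure(list(chains = chains), class = "coord_model")
}

#' Read a coordinate model from PDB/mmCIF with an FU-range mapping
#'
#' Reads alpha-carbon coordinates via bio3d and groups them into functional
#' units according to a user-supplied residue-range mapping (the FU
#' boundaries are not encoded in deposited files), e.g. from YAML:
#' `chain -> FU -> c(start, end)`.
#'
#' @param path PDB (`.pdb`) or mmCIF (`.cif`) file.
#' @param fu_map Named list: chain id -> named list of FU -> integer
#'   `c(start, end)` residue interval, or a YAML file path with the same
#'   structure.
#' @return A [coord_model].
#' @export
read_coord_model <- function(path, fu_map) {
  if (is.character(fu_map) && length(fu_map) == 1L)
    fu_map <- yaml::read_yaml(fu_map)
  ext <- tolower(tools::file_ext(path))
  pdb <- if (ext == "cif") bio3d::read.cif(path) else bio3d::read.pdb(path)
  ca <- pdb$atom[pdb$atom$elety == "CA", ]
  chains <- lapply(names(fu_map), function(ch) {
    sub <- ca[ca$chain == ch, ]
    fus <- lapply(names(fu_map[[ch]]), function(fu) {
      rng <- as.integer(unlist(fu_map[[ch]][[fu]]))
      sel <- sub[sub$resno >= rng[1] & sub$resno <= rng[2], ]
      as.matrix(sel[, c("x", "y", "z")])
    })
    names(fus) <- names(fu_map[[ch]])
    fus
  })
  names(chains) <- names(fu_map)
  coord_model(chains)
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Optimal rotation + translation (no scaling) mapping point set `P` onto
#' `Q` (rows are points), returned as a function of row matrices.
#'
#' @param P,Q n x 3 matrices with matching rows.
#' @return List with `R` (3x3), `transform` (function mapping an m x 3
#'   matrix), and `rmsd` of the fit on P/Q.
#' @export
kabsch <- function(P, Q) {
  if (!all(dim(P) == dim(Q))) stop("point sets must have equal dimensions")
  cp <- colMeans(P)
  cq <- colMeans(Q)
  H <- t(sweep(P, 2, cp)) %*% sweep(Q, 2, cq)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  transform <- function(x) sweep(sweep(x, 2, cp) %*% t(R), 2, cq, "+")
  fitted <- transform(P)
  list(R = R, transform = transform,
       rmsd = sqrt(mean(rowSums((fitted - Q)^2))))
}

#' Wall-aligned RMSD of a functional unit between two chains
#'
#' Superposes chain A onto chain B using only the wall selections (rigid
#' Kabsch fit, no scaling), applies the resulting transform to chain A's
#' target FU, and returns the RMSD against chain B's target FU. This is the
#' conformer-comparison measurement: how far a collar FU moves between two
#' protomer conformations once their invariant wall segments are aligned.
#'
#' @param model A [coord_model].
#' @param chainA,chainB Chain names in the model.
#' @param wall_selection Character vector of FU names forming the wall.
#' @param target_fu Name of the FU to compare (e.g. the FU-d* segment).
#' @return RMSD in Angstrom.
#' @export
superpose_rmsd <- function(model, chainA, chainB, wall_selection, target_fu) {
  stopifnot(inherits(model, "coord_model"))
  get <- function(ch, fu) {
    m <- model$chains[[ch]][[fu]]
    if (is.null(m)) stop("no selection for chain ", ch, ", FU ", fu)
    m
  }
  wa <- do.call(rbind, lapply(wall_selection, get, ch = chainA))
  wb <- do.call(rbind, lapply(wall_selection, get, ch = chainB))
  if (nrow(wa) != nrow(wb))
    stop("wall selection count mismatch: chain ", chainA, " has ", nrow(wa),
         " atoms, chain ", chainB, " has ", nrow(wb))
  ta <- get(chainA, target_fu)
  tb <- get(chainB, target_fu)
  if (nrow(ta) != nrow(tb))
    stop("target FU count mismatch: chain ", chainA, " has ", nrow(ta),
         " atoms, chain ", chainB, " has ", nrow(tb))
  fit <- kabsch(wa, wb)
  moved <- fit$transform(ta)
  sqrt(mean(rowSums((moved - tb)^2)))
}
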