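test_that("minimum adjacent-equal pairs: exhaustive values, parity law", {
  expect_equal(min_adjacent_equal(5), 1)     # the forced symmetry break
  expect_equal(min_adjacent_equal(4), 0)     # even rings alternate perfectly
  expect_equal(min_adjacent_equal(3), 1)
  for (n in 3:15)
    expect_equal(min_adjacent_equal(n), n %% 2)
  expect_error(min_adjacent_equal(2), ">= 3")
})

test_that("decamer assembly: census, heterodimer placement, invariance", {
  a <- assemble_decamer(c("N", "S", "N", "S", "N"))
  expect_equal(as.integer(a$census), c(4L, 4L, 1L, 1L))
  expect_equal(a$conformer[9], 3L)
  expect_equal(a$conformer[10], 4L)
  expect_equal(a$conformer[c(1, 2, 5, 6)], rep(1L, 4))
  expect_equal(a$conformer[c(3, 4, 7, 8)], rep(2L, 4))
  ## every protomer in exactly one dimer; heterodimer closes the ring
  expect_setequal(as.integer(a$dimers), 1:10)
  expect_equal(a$dimers[5, ], c(9L, 10L))
  ## rotation invariance of the census; one heterodimer for all 10 valid
  ## patterns (5 rotations x 2 complement/reflection classes)
  base <- c("N", "S", "N", "S", "N")
  patterns <- list()
  for (r in 0:4) {
    rot <- base[((0:4 + r) %% 5) + 1]
    patterns <- c(patterns, list(rot, chartr("NS", "SN", rot)))
  }
  for (p in patterns) {
    ap <- assemble_decamer(p)
    expect_equal(as.integer(ap$census), c(4L, 4L, 1L, 1L))
    expect_equal(sum(ap$conformer %in% c(3, 4)), 2)
    expect_equal(ap$conformer[9:10], c(3L, 4L))
  }
  expect_error(assemble_decamer(c("N", "N", "S", "S", "N")),
               "not a squid-type")
  expect_error(assemble_decamer(rep("N", 5)), "not a squid-type")
  expect_error(assemble_decamer(c("N", "S")), "5 labels")
})

make_toy_model <- function() {
  ## two chains; chain B is chain A under a rigid motion, except its target
  ## FU is offset by a known vector in the wall-aligned frame
  wallA <- matrix(c(0, 0, 0,  4, 0, 0,  0, 4, 0,  0, 0, 4), 4, 3,
                  byrow = TRUE)
  fuA <- matrix(c(2, 2, 2,  3, 1, 2), 2, 3, byrow = TRUE)
  th <- 0.9
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  t0 <- c(10, -3, 7)
  move <- function(x) sweep(x %*% t(R), 2, t0, "+")
  offset <- c(1.5, -2, 0.5)
  coord_model(list(
    A = list(wall = wallA, d = fuA),
    B = list(wall = move(wallA), d = move(sweep(fuA, 2, offset, "+")))))
}

test_that("wall-aligned RMSD: self, rigid invariance, closed-form offset", {
  m <- make_toy_model()
  expect_equal(superpose_rmsd(m, "A", "A", "wall", "d"), 0)
  ## chain B = rigid motion of chain A with a pure FU offset: the wall fit
  ## removes the global motion and the RMSD equals the offset norm
  offset_norm <- sqrt(sum(c(1.5, -2, 0.5)^2))
  expect_equal(superpose_rmsd(m, "A", "B", "wall", "d"), offset_norm,
               tolerance = 1e-6)
  ## symmetric in chain order
  expect_equal(superpose_rmsd(m, "A", "B", "wall", "d"),
               superpose_rmsd(m, "B", "A", "wall", "d"), tolerance = 1e-9)
  ## a pure rigid copy gives zero
  m0 <- m
  m0$chains$B$d <- m$chains$B$wall %*% diag(3)   # any matched selection
  m0$chains$A$d <- m$chains$A$wall
  expect_lt(superpose_rmsd(m0, "A", "B", "wall", "d"), 1e-6)
  m2 <- m
  m2$chains$B$d <- rbind(m$chains$B$d, c(0, 0, 0))
  expect_error(superpose_rmsd(m2, "A", "B", "wall", "d"), "mismatch")
})

test_that("Kabsch agrees with a brute-force rotation-grid search", {
  m <- make_toy_model()
  P <- m$chains$A$wall
  Q <- m$chains$B$wall
  fit <- kabsch(P, Q)
  expect_lt(fit$rmsd, 1e-9)
  ## brute force over a dense z-rotation grid (the toy motion is about z)
  best <- Inf
  cp <- colMeans(P); cq <- colMeans(Q)
  for (th in seq(0, 2 * pi, length.out = 7200)) {
    R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
    fitted <- sweep(sweep(P, 2, cp) %*% t(R), 2, cq, "+")
    best <- min(best, sqrt(mean(rowSums((fitted - Q)^2))))
  }
  expect_lt(abs(best - fit$rmsd), 1e-3)
  ## random rigid motions are recovered exactly
  set.seed(8)
  X <- matrix(rnorm(45), 15, 3)
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2)); ang <- 1.1
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K
  Y <- sweep(X %*% t(R), 2, c(1, 2, 3), "+")
  expect_lt(kabsch(X, Y)$rmsd, 1e-9)
})

test_that("coordinate models round-trip through PDB with an FU mapping", {
  skip_if_not_installed("bio3d")
  m <- make_toy_model()
  xyz <- rbind(m$chains$A$wall, m$chains$A$d,
               m$chains$B$wall, m$chains$B$d)
  tmp <- withr::local_tempfile(fileext = ".pdb")
  n_at <- nrow(xyz)
  bio3d::write.pdb(file = tmp, xyz = as.vector(t(xyz)),
                   resno = c(1:6, 1:6), chain = rep(c("A", "B"), each = 6),
                   resid = rep("ALA", n_at), elety = rep("CA", n_at),
                   o = rep(1, n_at), b = rep(0, n_at))
  fu_map <- list(A = list(wall = c(1, 4), d = c(5, 6)),
                 B = list(wall = c(1, 4), d = c(5, 6)))
  model <- read_coord_model(tmp, fu_map)
  expect_equal(model$chains$A$wall, m$chains$A$wall, ignore_attr = TRUE)
  expect_equal(superpose_rmsd(model, "A", "B", "wall", "d"),
               superpose_rmsd(m, "A", "B", "wall", "d"), tolerance = 1e-3)
  expect_error(coord_model(list()), "non-empty")
})
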