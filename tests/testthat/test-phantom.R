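test_that("ground truth has the canonical census and symmetry properties", {
  truth <- default_truth
  expect_equal(sum(truth$role == "FU-g"), 10)
  expect_equal(sum(truth$role == "FU-dstar"), 10)
  expect_equal(sum(truth$role != "wall"), 20)     # 20 collar FUs
  expect_equal(sum(truth$role == "wall"), 30)
  expect_setequal(truth$protomer[truth$role != "wall"], 1:10)
  ## five FU-g dimer pairs: pairs of FU-g centroids within the contact cutoff
  g <- as.matrix(truth[truth$role == "FU-g", c("x", "y", "z")])
  d <- as.matrix(dist(g))
  diag(d) <- Inf
  expect_equal(sum(d < 8) / 2, 5)                 # 5 disjoint close pairs
  expect_true(all(rowSums(d < 8) == 1))           # each FU-g in exactly one
  ## wall centroid set is exactly closed under D5
  wall <- as.matrix(truth[truth$role == "wall", c("x", "y", "z")])
  for (O in d5$operators) {
    img <- wall %*% t(O)
    nn <- apply(img, 1, function(p)
      min(sqrt(colSums((t(wall) - p)^2))))
    expect_lt(max(nn), 1e-6)
  }
  ## collar set is NOT closed under C5 or D5 (the asymmetry exists)
  col <- collar_centroids(truth)
  for (grp in list(c5, d5)) {
    img <- col %*% t(grp$operators[[2]])
    nn <- apply(img, 1, function(p) min(sqrt(colSums((t(col) - p)^2))))
    expect_gt(max(nn), 1)
  }
  expect_error(build_decamer_truth(
    phantom_spec(hemisphere_pattern = c("N", "S", "N"))), "length 5")
})

test_that("odd alternating rings have exactly one same-hemisphere adjacency", {
  ## exhaustive scan: a length-5 N/S ring has >= 1 adjacent equal pair, and
  ## exactly 10 of the 32 labelings achieve the minimum of one
  n_valid <- 0
  for (m in 0:31) {
    bits <- bitwAnd(bitwShiftR(m, 0:4), 1L)
    eq <- sum(bits == bits[c(2:5, 1)])
    expect_gte(eq, 1)
    if (eq == 1) n_valid <- n_valid + 1
  }
  expect_equal(n_valid, 10)
})

test_that("rendering matches the Gaussian closed form and wall symmetry", {
  spec <- default_spec
  one <- render_map(blob_truth(0, 0, 0), spec)
  expect_equal(sum(one$grid), (2 * pi * spec$blob_sigma^2)^1.5,
               tolerance = 0.01)
  ## peak value at an isolated centroid equals its amplitude
  cc <- spec$N %/% 2 + 1
  expect_equal(one$grid[cc, cc, cc], 1, tolerance = 0.02)
  expect_equal(render_map(default_truth[0, ], spec)$grid,
               array(0, rep(spec$N, 3)))
  expect_warning(render_map(blob_truth(spec$N / 2 - 2, 0, 0), spec), "edge")
})

test_that("particle simulation is reproducible with the requested SNR", {
  tm <- default_map
  a <- simulate_particles(tm, 20, snr = 0.5, shift_max = 2, seed = 42)
  b <- simulate_particles(tm, 20, snr = 0.5, shift_max = 2, seed = 42)
  expect_identical(a$images, b$images)            # bit-identical from seed
  expect_identical(a$meta, b$meta)
  ## noiseless limit reproduces clean projections
  cl <- simulate_particles(tm, 10, snr = 1e9, shift_max = 1, seed = 7)
  img1 <- project_map(tm, cl$meta[1, c("phi", "theta", "psi", "dx", "dy")])
  expect_lt(sqrt(mean((cl$images[, , 1] - img1)^2)) / sd(img1), 1e-3)
  ## measured SNR over 500 particles within 10% of the request
  st <- simulate_particles(tm, 500, snr = 0.7, shift_max = 2, seed = 3)
  clean <- simulate_particles(tm, 500, snr = 1e12, shift_max = 2, seed = 3)
  snr_hat <- mean(vapply(seq_len(500), function(i) {
    s <- var(as.vector(clean$images[, , i]))
    nv <- var(as.vector(st$images[, , i] - clean$images[, , i]))
    s / nv
  }, numeric(1)))
  expect_equal(snr_hat, 0.7, tolerance = 0.1)
  expect_error(simulate_particles(tm, 10, 1, shift_max = 16), "shift_max")
  expect_error(simulate_particles(tm, 0, 1), "n must")
  ## half-set split is by parity
  expect_equal(st$meta$half_set, (seq_len(500) - 1L) %% 2L)
})

test_that("masks derived from the spec partition wall and collar", {
  masks <- default_mask_set
  ## partition of unity: wall + collar = outer exactly
  expect_equal(masks$wall$grid + masks$collar$grid, masks$outer$grid,
               tolerance = 1e-12)
  expect_true(all(masks$outer$grid %in% c(0, 1)))
  ## the collar centroids are inside the collar mask, wall inside wall mask
  ## nearest-voxel mask values at the centroids (rounding can move a point
  ## ~0.7 voxels, so full-weight minus a little)
  cc <- default_spec$N %/% 2 + 1
  col <- round(collar_centroids(default_truth)) + cc
  for (i in seq_len(nrow(col)))
    expect_gt(masks$collar$grid[col[i, 1], col[i, 2], col[i, 3]], 0.8)
  wall <- round(as.matrix(
    default_truth[default_truth$role == "wall", c("x", "y", "z")])) + cc
  for (i in seq_len(nrow(wall)))
    expect_gt(masks$wall$grid[wall[i, 1], wall[i, 2], wall[i, 3]], 0.8)
})
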