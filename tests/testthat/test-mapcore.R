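test_that("MRC round trip is bit-exact at float32 and keeps the voxel size", {
  path <- withr::local_tempfile(fileext = ".mrc")
  m <- random_map(32, seed = 11, voxel = 1.14)
  write_mrc(m, path)
  r1 <- read_mrc(path)
  expect_equal(r1$voxel_size, 1.14, tolerance = 1e-4 / 1.14)
  ## values are float32-rounded on the first pass; a second pass is exact
  write_mrc(r1, path)
  r2 <- read_mrc(path)
  expect_identical(r2$grid, r1$grid)
  expect_equal(max(abs(r1$grid - m$grid)), 0, tolerance = 1e-6)
})

test_that("non-cubic volumes are rejected with an explicit message", {
  path <- withr::local_tempfile(fileext = ".mrcs")
  st <- structure(list(images = array(rnorm(16 * 16 * 8), c(16, 16, 8)),
                       pixel_size = 1,
                       meta = data.frame(phi = rep(0, 8), theta = 0, psi = 0,
                                         dx = 0, dy = 0, half_set = 0,
                                         score = NA_real_)),
                  class = "particle_stack")
  write_particle_stack(st, path)
  expect_error(read_mrc(path), "non-cubic")
  expect_error(density_map(array(0, c(16, 16, 8)), 1), "non-cubic")
  rt <- read_particle_stack(path)
  expect_equal(dim(rt$images), c(16L, 16L, 8L))
})

test_that("cylindrical masks: hard edges, disjoint wall/collar, voxel count", {
  N <- 32
  hard <- cylindrical_mask(N, 0, 10, 8, edge_width = 0)
  expect_true(all(hard$grid %in% c(0, 1)))
  ## brute-force count of voxels satisfying the inequalities
  cc <- N %/% 2
  cnt <- 0
  for (i in 0:(N - 1)) for (j in 0:(N - 1)) for (k in 0:(N - 1)) {
    r <- sqrt((i - cc)^2 + (j - cc)^2)
    if (r <= 10 && abs(k - cc) <= 8) cnt <- cnt + 1
  }
  expect_equal(sum(hard$grid), cnt)
  ## wall mask starting at r_w and collar ending at r_w - edge never overlap
  r_w <- 11
  wall <- cylindrical_mask(N, r_w, 15, 10, edge_width = 2)
  collar <- cylindrical_mask(N, 0, r_w - 2, 10, edge_width = 2)
  expect_lt(max(wall$grid * collar$grid), 1e-6)
  expect_true(all(wall$grid >= 0 & wall$grid <= 1))
  expect_error(cylindrical_mask(N, 0, 20, 8), "exceeds")
  expect_error(cylindrical_mask(N, 5, 4, 8), "r_inner")
})

test_that("scale_region matches its definition and a triple-loop oracle", {
  m <- random_map(16, seed = 21)
  mask <- cylindrical_mask(16, 0, 5, 4, edge_width = 2)
  expect_equal(scale_region(m, mask, 1)$grid, m$grid)
  z <- density_map(array(0, c(16, 16, 16)), 1)
  expect_equal(scale_region(z, mask, 7)$grid, z$grid)
  ## binary region scales exactly by the factor
  bin <- cylindrical_mask(16, 0, 5, 4, edge_width = 0)
  out <- scale_region(m, bin, 1.5)
  expect_equal(out$grid[bin$grid == 1], 1.5 * m$grid[bin$grid == 1])
  expect_equal(out$grid[bin$grid == 0], m$grid[bin$grid == 0])
  ## voxelwise loop oracle
  oracle <- array(0, c(16, 16, 16))
  for (i in 1:16) for (j in 1:16) for (k in 1:16)
    oracle[i, j, k] <- m$grid[i, j, k] * (1 + 0.5 * mask$grid[i, j, k])
  expect_equal(scale_region(m, mask, 1.5)$grid, oracle, tolerance = 1e-10)
  expect_error(scale_region(m, cylindrical_mask(8, 0, 3, 2), 2), "mismatch")
})

test_that("combine_regions follows the voxelwise formula", {
  w <- random_map(16, seed = 31)
  co <- random_map(16, seed = 32)
  wm <- cylindrical_mask(16, 4, 7, 6, edge_width = 1)
  cm <- cylindrical_mask(16, 0, 3, 6, edge_width = 1)
  om <- cylindrical_mask(16, 0, 7, 7, edge_width = 1)
  out <- combine_regions(w, co, wm, cm, om)
  oracle <- array(0, c(16, 16, 16))
  for (i in 1:16) for (j in 1:16) for (k in 1:16)
    oracle[i, j, k] <- (w$grid[i, j, k] * wm$grid[i, j, k] +
                          co$grid[i, j, k] * cm$grid[i, j, k]) *
      om$grid[i, j, k]
  expect_equal(out$grid, oracle, tolerance = 1e-10)
  ## complementary binary masks reproduce the original inside the outer mask
  a <- cylindrical_mask(16, 0, 3, 6, edge_width = 0)
  b <- cylindrical_mask(16, 0, 7, 7, edge_width = 0)
  bc <- b; bc$grid <- b$grid * (1 - a$grid)             # complement within b
  back <- combine_regions(w, w, bc, a, b)
  expect_equal(back$grid, w$grid * b$grid, tolerance = 1e-12)
  ## zero collar contributes nothing
  z <- density_map(array(0, c(16, 16, 16)), 1)
  expect_equal(combine_regions(w, z, wm, cm, om)$grid,
               w$grid * wm$grid * om$grid, tolerance = 1e-12)
})

test_that("sharpening is the exact exponential filter and inverts", {
  spec <- default_spec
  g <- render_map(blob_truth(0, 0, 0), spec)
  expect_equal(sharpen(g, 0)$grid, g$grid, tolerance = 1e-12)
  sh <- sharpen(g, -190)
  inv <- sharpen(sh, 190)
  expect_lt(max(abs(inv$grid - g$grid)) / max(abs(g$grid)), 1e-6)
  ## per-shell amplitude ratio equals exp(190 s^2 / 4)
  N <- spec$N
  f <- 0:(N - 1); f[f > N / 2] <- f[f > N / 2] - N
  shell <- round(sqrt(outer(outer(f^2, f^2, "+"), f^2, "+")))
  F0 <- abs(fft(g$grid)); F1 <- abs(fft(sh$grid))
  for (s in c(5, 8, 12, 15)) {
    ratio <- mean(F1[shell == s]) / mean(F0[shell == s])
    s_inv_A <- s / (N * spec$voxel_size)
    expect_equal(ratio, exp(190 * s_inv_A^2 / 4), tolerance = 0.01)
  }
  ## negative b: radially averaged power ratio is nondecreasing with shell
  ratios <- sapply(1:20, function(s) mean(F1[shell == s]^2) /
                     mean(F0[shell == s]^2))
  expect_true(all(diff(ratios) > -1e-9))
})
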