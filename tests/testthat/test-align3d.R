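test_that("projection: identity axis sum, slice theorem, wall periodicity", {
  ## identity orientation is the plain z sum (up to the spherical support)
  img0 <- project_map(default_map, list(phi = 0, theta = 0, psi = 0))
  expect_lt(nrms(img0, apply(default_map$grid, c(1, 2), sum)), 1e-3)
  ## real-space vs Fourier-central-slice implementations agree
  for (o in list(list(phi = 33, theta = 61, psi = 107),
                 list(phi = 290, theta = 140, psi = 12))) {
    pr <- project_map(default_map, o, method = "real")
    pf <- project_map(default_map, o, method = "fourier")
    expect_gt(cor(as.vector(pr), as.vector(pf)), 0.99)
  }
  ## D5 wall-only map: projections at phi and phi + 72 are identical
  p1 <- project_map(wall_only_map, list(phi = 15, theta = 70, psi = 0))
  p2 <- project_map(wall_only_map, list(phi = 87, theta = 70, psi = 0))
  expect_lt(nrms(p1, p2), 0.02)
})

test_that("template banks enumerate the closed-form grid and are normalized", {
  grid <- bank_orientation_grid(90, 90)
  ## theta in {0,90,180}; phi count per ring max(1, round(4 sin theta)); psi 4
  expect_equal(nrow(grid), (1 + 4 + 1) * 4)
  bank <- make_template_bank(default_map, 90, 90)
  expect_equal(dim(bank$templates)[3], nrow(grid))
  norms <- apply(bank$templates, 3, function(m) sqrt(sum(m^2)))
  expect_equal(norms, rep(1, length(norms)), tolerance = 1e-9)
  means <- apply(bank$templates, 3, mean)
  expect_lt(max(abs(means)), 1e-12)
  ## spherically symmetric map: all templates identical up to interpolation
  ball <- render_map(blob_truth(0, 0, 0), default_spec)
  bb <- make_template_bank(ball, 60)
  ref <- bb$templates[, , 1]
  devs <- apply(bb$templates, 3, function(m) max(abs(m - ref)))
  expect_lt(max(devs), 0.01)
  expect_error(make_template_bank(default_map, 1), ">= 2")
})

test_that("orientation assignment recovers bank orientations and shifts", {
  bank <- make_template_bank(default_map, 30)
  set.seed(77)
  sel <- sample(nrow(bank$orientations), 30)
  imgs <- array(0, c(64, 64, 30))
  for (i in seq_len(30))
    imgs[, , i] <- shift_image(project_map(default_map,
                                           bank$orientations[sel[i], ]),
                               2, -1)
  asn <- assign_orientations(imgs, bank, shift_range = 2)
  expect_equal(asn$template, sel)             # 100% exact recovery
  expect_true(all(asn$dx == 2 & asn$dy == -1))
  expect_true(all(asn$score <= 1 + 1e-9))     # Cauchy-Schwarz
  expect_gt(min(asn$score), 0.98)
  expect_error(assign_orientations(array(0, c(64, 64, 0)), bank), "empty")
})

test_that("a symmetric-collar reference leaves phi determined only mod 72", {
  ## particles come from the asymmetric truth, but the reference has a
  ## D5-symmetrized collar: the wall dominates and the azimuth is degenerate
  symref <- collar_symmetrized_reference(default_map, d5, default_mask_set)
  bank <- symref:::.fast_template_bank(symref, 12)
  st <- simulate_particles(default_map, 60, snr = 1e6, shift_max = 0,
                           seed = 19)
  asn <- assign_orientations(st, bank, shift_range = 0)
  side <- st$meta$theta > 30 & st$meta$theta < 150
  dphi <- abs(asn$phi[side] - st$meta$phi[side]) %% 72
  dphi <- pmin(dphi, 72 - dphi)               # distance to nearest multiple
  ## concentration at multiples of 72 deg, up to the 12-deg grid quantization
  expect_gt(mean(dphi < 12), 0.75)
  expect_lt(median(dphi), 8)
  ## and the D5-registered orientation error is small even so
  err_d5 <- orientation_error(asn, st$meta, d5)
  expect_lt(median(err_d5), 12)
})

test_that("reconstruction: weight normalization and single-slice smear", {
  st <- simulate_particles(default_map, 40, snr = 1e9, shift_max = 0,
                           seed = 23)
  r1 <- reconstruct(st)
  dup <- st
  dup$images <- array(c(st$images, st$images), c(64, 64, 80))
  dup$meta <- rbind(st$meta, st$meta)
  r2 <- reconstruct(dup)
  expect_equal(r1$grid, r2$grid, tolerance = 1e-10)
  ## a single identity-orientation projection back-projects to a volume
  ## constant along z
  single <- reconstruct(st$images[, , 1, drop = FALSE],
                        data.frame(phi = 0, theta = 0, psi = 0,
                                   dx = 0, dy = 0))
  along_z <- apply(single$grid, c(1, 2), sd)
  expect_lt(max(along_z), 1e-8)
  expect_error(reconstruct(st$images[, , 0, drop = FALSE],
                           st$meta[0, ]), "empty")
})

test_that("refinement is deterministic and guards against divergence", {
  st <- simulate_particles(default_map, 60, snr = 1, shift_max = 1, seed = 31)
  adj <- adjust_config(d5, default_mask_set$wall, default_mask_set$collar,
                       default_mask_set$outer, 1.5, active_rounds = 1)
  cfg <- refine_config(2, c(30, 15), shift_range = 1, adjust = adj, seed = 1)
  ra <- refine(st, default_map, cfg)
  rb <- refine(st, default_map, cfg)
  expect_identical(ra$half_maps[[1]]$grid, rb$half_maps[[1]]$grid)
  expect_identical(ra$half_maps[[2]]$grid, rb$half_maps[[2]]$grid)
  expect_identical(ra$orientations, rb$orientations)
  expect_equal(nrow(ra$history), 4)           # 2 iterations x 2 half-sets
  ## config validation
  expect_error(refine_config(2, c(15, 30), adjust = adj), "decreasing")
  expect_error(refine_config(3, c(30, 15), adjust = adj), "one entry per")
  expect_error(refine_config(0, numeric(0), adjust = adj), ">= 1")
})
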