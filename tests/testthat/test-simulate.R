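# Calibration inversion and the phantom generator.

test_that("DEI-to-HU inversion solves the formula", {
  expect_equal(hu_low_for_dei(0, 8000), 8000)
  # algebraic check by substitution back into the DEI formula
  h1 <- hu_low_for_dei(0.212, 8000)
  expect_equal(h1, 12842.64, tolerance = 1e-6)
  expect_equal(dei_index(h1, 8000), 0.212, tolerance = 1e-12)
  for (d in c(-0.5, -0.01, 0.008, 0.3, 0.9)) {
    expect_equal(dei_index(hu_low_for_dei(d, 8000), 8000), d,
                 tolerance = 1e-12)
  }
  expect_error(hu_low_for_dei(1, 8000), "< 1")
  expect_error(build_calibration(data.frame(material = "x", dei_mean = 0.2,
                                            dei_sd = 0.01),
                                 hu_high_anchor = 1500), "2000")
})

test_that("zero-pellet noise-free block is constant gelatine", {
  spec <- phantom_spec(data.frame(center_x_mm = numeric(0),
                                  center_y_mm = numeric(0),
                                  center_z_mm = numeric(0),
                                  diameter_mm = numeric(0),
                                  material = character(0)),
                       block_size = c(20, 20, 20), noise_sd = 0, seed = 1)
  calib <- build_calibration(material_dei_reference("paper-100-140"))
  gen <- generate_block(spec, calib)
  expect_true(all(gen$volume$low_kv == 60))
  expect_true(all(gen$volume$high_kv == 50))
  expect_false(any(threshold_mask(gen$volume$high_kv)))
})

test_that("same spec and seed reproduce bit-identical volumes and truth", {
  a <- small_block(seed = 3, n_pellets = 2)
  b <- small_block(seed = 3, n_pellets = 2)
  expect_identical(a$volume$low_kv, b$volume$low_kv)
  expect_identical(a$volume$high_kv, b$volume$high_kv)
  expect_identical(a$truth, b$truth)
  c <- small_block(seed = 4, n_pellets = 2)
  expect_false(identical(a$volume$low_kv, c$volume$low_kv))
})

test_that("partial-volume fractions integrate to the sphere volume", {
  for (diam in c(3, 4)) {
    sf <- dectpellet:::sphere_fractions(dims = c(30, 30, 12),
                                        spacing = c(0.504, 0.504, 1),
                                        center = c(7.3, 7.9, 6.2),
                                        radius = diam / 2, supersample = 4)
    vol_est <- sum(sf$frac) * 0.504 * 0.504 * 1
    vol_true <- 4 / 3 * pi * (diam / 2)^3
    expect_lt(abs(vol_est - vol_true) / vol_true, 0.02)
  }
})

test_that("noise-free interiors reproduce the drawn DEI exactly", {
  blk <- small_block(seed = 9, n_pellets = 1, noise_sd = 0)
  interior <- blk$volume$high_kv == blk$truth$hu_high[1]  # f = 1 voxels
  expect_gt(sum(interior), 0)
  d <- dei_index(blk$volume$low_kv[interior], blk$volume$high_kv[interior])
  expect_equal(d, rep(blk$truth$dei_true[1], sum(interior)),
               tolerance = 1e-12)
})

test_that("boundary voxels are DEI-biased toward gelatine", {
  blk <- small_block(seed = 10, n_pellets = 1, noise_sd = 0)
  f <- (blk$volume$high_kv - 50) / (blk$truth$hu_high[1] - 50)
  boundary <- f > 0.05 & f < 0.95
  expect_gt(sum(boundary), 0)
  d_bnd <- dei_index(blk$volume$low_kv[boundary],
                     blk$volume$high_kv[boundary])
  d_gel <- dei_index(60, 50)
  expect_true(all(d_bnd < blk$truth$dei_true[1]))
  expect_true(all(d_bnd > d_gel - 1e-12))
})

test_that("pellets outside the block are rejected; overlaps warn", {
  out <- data.frame(center_x_mm = 1, center_y_mm = 10, center_z_mm = 10,
                    diameter_mm = 3, material = "Fe")
  expect_error(phantom_spec(out, block_size = c(20, 20, 20)),
               "inside the block")
  two <- data.frame(center_x_mm = c(10, 11), center_y_mm = 10,
                    center_z_mm = c(10, 10.5), diameter_mm = 3,
                    material = "Fe")
  spec <- phantom_spec(two, block_size = c(20, 20, 20), noise_sd = 0,
                       seed = 2)
  calib <- build_calibration(material_dei_reference("paper-100-140"))
  expect_warning(gen <- generate_block(spec, calib), "overlap")
  expect_true(all(gen$truth$overlaps))
})

test_that("default phantom layouts carry the reference pellet counts", {
  ph <- default_phantom("paper-100-140", seed = 1)
  counts <- vapply(ph$blocks, function(b) nrow(b$pellets), integer(1))
  expect_equal(counts, c(Fe = 5L, Pb = 4L, Cu = 13L, W = 6L, Bi = 8L))
  expect_equal(sum(counts), 36L)
  # pairwise separation and depth window hold in every block
  for (b in ph$blocks) {
    ctr <- as.matrix(b$pellets[, c("center_x_mm", "center_y_mm",
                                   "center_z_mm")])
    if (nrow(ctr) > 1) expect_gte(min(dist(ctr)), 10)
    expect_true(all(b$pellets$center_z_mm >= 20 &
                    b$pellets$center_z_mm <= 120))
  }
  ph2 <- default_phantom("paper-80-140-steel", seed = 1)
  expect_equal(vapply(ph2$blocks, function(b) nrow(b$pellets), integer(1)),
               c(`steel-3mm` = 20L, `steel-4mm` = 20L))
  expect_equal(vapply(ph2$blocks, function(b) b$pellets$diameter_mm[1],
                      numeric(1)),
               c(`steel-3mm` = 3, `steel-4mm` = 4))
  expect_error(default_phantom("no-such-profile"), "unknown")
})

test_that("generator draws are independent of the caller's RNG state", {
  set.seed(123); x1 <- small_block(seed = 6, n_pellets = 2)
  set.seed(456); x2 <- small_block(seed = 6, n_pellets = 2)
  expect_identical(x1$volume$low_kv, x2$volume$low_kv)
  # and the caller's stream is restored afterwards
  set.seed(77); before <- rnorm(1)
  set.seed(77); invisible(small_block(seed = 6, n_pellets = 1))
  expect_identical(rnorm(1), before)
})
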