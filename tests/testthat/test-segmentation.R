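# Thresholding, disk erosion, connected components, per-pellet summaries.

test_that("threshold is strict: exactly-2000 voxels are background", {
  cfg <- segmentation_config()
  g <- array(60, c(4, 4, 2))
  expect_false(any(threshold_mask(g, cfg)))
  g[1, 1, 1] <- 2000      # at the threshold: excluded
  g[2, 2, 1] <- 2000.001  # above: included
  m <- threshold_mask(g, cfg)
  expect_false(m[1, 1, 1])
  expect_true(m[2, 2, 1])
  expect_equal(sum(m), 1L)
})

test_that("thresholded voxel count equals the supersampled blend recount", {
  blk <- small_block(seed = 11, n_pellets = 1, noise_sd = 0)
  m <- threshold_mask(blk$volume$high_kv, segmentation_config())
  # independent recount: blended HU = f * hu_high + (1 - f) * 50 > 2000
  f <- (blk$volume$high_kv - 50) / (blk$truth$hu_high[1] - 50)
  expect_equal(sum(m), sum(f > (2000 - 50) / (blk$truth$hu_high[1] - 50)))
})

test_that("the diameter-4 disk footprint matches the shipped fixture", {
  fp <- disk_footprint(4)
  fixture <- as.matrix(read.table(
    system.file("extdata", "footprints", "disk-d4.txt",
                package = "dectpellet")))
  expect_equal(unname(fp * 1L), unname(fixture), ignore_attr = TRUE)
  expect_equal(sum(fp), 13L)  # Euclidean <= 2.0 keeps 13 of the 5x5 box
})

test_that("erosion removes small structures and matches the definition", {
  cfg <- segmentation_config()
  empty <- array(FALSE, c(8, 8, 2))
  expect_equal(erode_mask(empty, cfg), empty)
  single <- empty; single[4, 4, 1] <- TRUE
  expect_false(any(erode_mask(single, cfg)))
  # 10 x 10 filled square in one slice vs the brute-force oracle
  sq <- array(FALSE, c(14, 14, 1))
  sq[3:12, 3:12, 1] <- TRUE
  got <- erode_mask(sq, cfg)
  expect_equal(got[, , 1], erode_oracle_2d(sq[, , 1], disk_footprint(4)))
  expect_gt(sum(got), 0)
})

test_that("erosion equals the brute-force oracle on random masks and is
           anti-extensive", {
  cfg <- segmentation_config()
  set.seed(2024)
  for (case in 1:50) {
    m <- matrix(runif(20 * 18) < runif(1, 0.3, 0.8), 20, 18)
    got <- erode_mask(m, cfg)
    expect_equal(got, erode_oracle_2d(m, disk_footprint(4)))
    expect_true(all(m[got]))  # eroded mask is a subset of the input
  }
})

test_that("erosion is applied per axial slice, independently", {
  set.seed(7)
  m <- array(runif(16 * 16 * 3) < 0.6, c(16, 16, 3))
  got <- erode_mask(m, segmentation_config())
  for (k in 1:3) {
    expect_equal(got[, , k], erode_oracle_2d(m[, , k], disk_footprint(4)))
  }
})

test_that("labelling finds the right components", {
  cfg <- segmentation_config()
  empty <- array(FALSE, c(6, 6, 6))
  expect_equal(nrow(label_pellets(empty, cfg)$census), 0L)
  # two blobs separated by more than one voxel of background
  m <- array(FALSE, c(12, 12, 8))
  m[2:4, 2:4, 2:3] <- TRUE
  m[8:10, 8:10, 5:6] <- TRUE
  lab <- label_pellets(m, cfg)
  expect_equal(nrow(lab$census), 2L)
  expect_equal(sort(lab$census$voxel_count), c(18L, 18L))
  # touching blobs merge into one component
  m2 <- array(FALSE, c(12, 12, 8))
  m2[2:5, 2:5, 2:4] <- TRUE
  m2[5:8, 5:8, 4:6] <- TRUE  # corner contact at (5,5,4): 26-connected
  expect_equal(nrow(label_pellets(m2, cfg)$census), 1L)
})

test_that("labelling agrees with the flood-fill oracle on random masks", {
  set.seed(99)
  for (case in 1:50) {
    conn <- sample(c(6, 18, 26), 1)
    m <- array(runif(9 * 9 * 6) < runif(1, 0.2, 0.45), c(9, 9, 6))
    lab <- label_pellets(m, segmentation_config(connectivity = conn))
    oracle <- components_oracle(m, conn)
    expect_equal(nrow(lab$census), oracle$n)
    expect_equal(sort(lab$census$voxel_count), oracle$sizes)
  }
})

test_that("size-filter hooks drop components outside the voxel-count band", {
  m <- array(FALSE, c(10, 10, 4))
  m[2:3, 2:3, 2] <- TRUE          # 4 voxels
  m[6:9, 6:9, 2:3] <- TRUE        # 32 voxels
  cfg <- segmentation_config(min_voxel_count = 5)
  expect_equal(label_pellets(m, cfg)$census$voxel_count, 32L)
  cfg2 <- segmentation_config(max_voxel_count = 10)
  expect_equal(label_pellets(m, cfg2)$census$voxel_count, 4L)
})

test_that("pellet summaries: means, SDs, centroids, invalid handling", {
  labels <- array(0L, c(4, 4, 2))
  labels[1:2, 1, 1] <- 1L
  dei <- array(0.2, c(4, 4, 2))
  rec <- pellet_dei_stats(labels, dei, spacing = c(0.5, 0.5, 1))
  expect_equal(rec$mean_dei, 0.2)
  expect_equal(rec$sd_dei, 0)
  expect_equal(rec$voxel_count, 2L)
  expect_equal(rec$centroid_x_mm, mean(c(0.25, 0.75)))
  expect_equal(rec$centroid_y_mm, 0.25)

  dei[1, 1, 1] <- 0.1; dei[2, 1, 1] <- 0.3
  rec2 <- pellet_dei_stats(labels, dei)
  expect_equal(rec2$mean_dei, 0.2)
  expect_equal(rec2$sd_dei, sd(c(0.1, 0.3)))

  # a label whose voxels are all DEI-invalid is excluded with a warning
  dv <- structure(list(dei = dei, valid_mask = array(FALSE, dim(dei)),
                       spacing = c(1, 1, 1)), class = "dei_volume")
  expect_warning(out <- pellet_dei_stats(labels, dv), "no valid DEI")
  expect_equal(nrow(out), 0L)
})

test_that("full synthetic block: per-pellet means match the truth sidecar", {
  blk <- small_block(seed = 5, n_pellets = 4)
  res <- analyze_volume(blk$volume)
  expect_equal(nrow(res$records), 4L)
  # match recovered pellets to truth by centroid proximity
  for (i in seq_len(nrow(res$records))) {
    d <- sqrt((blk$truth$center_x_mm - res$records$centroid_x_mm[i])^2 +
              (blk$truth$center_y_mm - res$records$centroid_y_mm[i])^2 +
              (blk$truth$center_z_mm - res$records$centroid_z_mm[i])^2)
    j <- which.min(d)
    expect_lt(d[j], 1.5)
    expect_lt(abs(res$records$mean_dei[i] - blk$truth$dei_true[j]), 0.005)
  }
})
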