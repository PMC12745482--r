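test_that("region growing respects the window and connectivity", {
  full <- matrix(500, 10, 12)
  expect_true(all(grow_region(full, c(3, 3))))

  # two in-range blobs separated by sub-threshold pixels
  img <- matrix(40, 20, 20)
  img[3:8, 3:8] <- 600
  img[14:18, 14:18] <- 600
  mA <- grow_region(img, c(4, 4))
  expect_true(all(which(mA, arr.ind = TRUE)[, 1] <= 8))
  expect_equal(sum(mA), 36)

  # diagonal touch joins under 8- but not 4-connectivity
  img2 <- matrix(40, 6, 6)
  img2[2, 2] <- 600; img2[3, 3] <- 600
  expect_equal(sum(grow_region(img2, c(2, 2), connectivity = 8)), 2)
  expect_equal(sum(grow_region(img2, c(2, 2), connectivity = 4)), 1)

  expect_error(grow_region(img, c(1, 1)), "outside the growing range")
  expect_error(grow_region(img, c(0, 1)), "outside the image")

  # exclusion mask blocks growth
  excl <- matrix(FALSE, 20, 20); excl[3:8, 6] <- TRUE
  mE <- grow_region(img, c(4, 4), exclude = excl)
  expect_true(all(which(mE, arr.ind = TRUE)[, 2] <= 5))
})

test_that("region growing equals a breadth-first flood-fill oracle", {
  for (s in 1:10) {
    img <- random_bmd_slice(32, seed = 100 + s)
    in_range <- img >= 200 & img <= 2000
    idx <- which(in_range, arr.ind = TRUE)
    seed_px <- idx[((s * 37) %% nrow(idx)) + 1, ]
    for (conn in c(8, 4)) {
      expect_identical(grow_region(img, seed_px, connectivity = conn),
                       bfs_flood_oracle(img, seed_px, 200, 2000, conn))
    }
  }
})

test_that("region growing matches the EBImage component containing the seed", {
  img <- random_bmd_slice(48, seed = 77)
  in_range <- img >= 200 & img <= 2000
  labels <- EBImage::bwlabel(in_range)
  idx <- which(in_range, arr.ind = TRUE)
  seed_px <- idx[17, ]
  oracle <- labels == labels[seed_px[1], seed_px[2]]
  expect_equal(grow_region(img, seed_px, connectivity = 4), oracle)
})

test_that("seed selection ranks by density with a spacing constraint", {
  img <- matrix(40, 12, 12)
  img[4:9, 4:9] <- 600
  img[6, 7] <- 900  # unique maximum
  expect_equal(unname(pick_seed(img, 1)), c(6, 7))

  # uniform in-range slice: lexicographically smallest admissible pixels
  uni <- matrix(500, 8, 8)
  seeds <- pick_seeds(uni, n = 3)
  expect_equal(unname(seeds), rbind(c(1, 1), c(1, 4), c(1, 7)))

  # audit: seeds in range and pairwise >= 3 px apart
  img3 <- random_bmd_slice(32, seed = 9)
  s3 <- pick_seeds(img3, n = 3)
  for (k in 1:3) expect_true(img3[s3[k, 1], s3[k, 2]] >= 200 &&
                               img3[s3[k, 1], s3[k, 2]] <= 2000)
  d <- as.matrix(dist(s3))
  expect_true(all(d[upper.tri(d)] >= 3))

  expect_error(pick_seed(matrix(40, 5, 5), 1), "no in-range pixel")
})

test_that("segmentation statistics match direct summation", {
  mask <- matrix(FALSE, 4, 4); mask[1:2, 1:2] <- TRUE
  vals <- matrix(0, 4, 4); vals[1:2, 1:2] <- 700
  s <- m2_slice_stats(mask, vals, spacing = c(1, 0.25, 0.25))
  expect_equal(s$mean, 700); expect_equal(s$sd, 0)
  expect_equal(s$area_mm2, 0.25); expect_equal(s$volume_mm3, 0.25)

  vals[1, 1:2] <- c(600, 800)
  mask2 <- matrix(FALSE, 4, 4); mask2[1, 1:2] <- TRUE
  s2 <- m2_slice_stats(mask2, vals)
  expect_equal(s2$mean, 700); expect_equal(s2$min, 600); expect_equal(s2$max, 800)
  expect_equal(s2$sd, 100)  # population SD of {600, 800}

  set.seed(3)
  vals3 <- matrix(runif(400, 100, 1000), 20, 20)
  mask3 <- matrix(runif(400) < 0.3, 20, 20)
  s3 <- m2_slice_stats(mask3, vals3, spacing = c(2, 0.5, 0.5))
  v <- vals3[mask3]
  expect_equal(s3$mean, sum(v) / length(v))
  expect_equal(s3$sd, sqrt(sum((v - mean(v))^2) / length(v)))
  expect_equal(s3$min, min(v)); expect_equal(s3$max, max(v))
  expect_equal(s3$area_mm2, length(v) * 0.25)
  expect_equal(s3$volume_mm3, length(v) * 0.5)
})

test_that("grown masks are valid segmentations of the slice", {
  img <- random_bmd_slice(48, seed = 21)
  res <- m2_slice_bmd(img, replicate = 1)
  expect_true(all(img[res$mask] >= 200 & img[res$mask] <= 2000))
  expect_true(res$mask[res$seed[["row"]], res$seed[["col"]]])
  expect_lte(res$stats$min, res$stats$mean)
  expect_gte(res$stats$max, res$stats$mean)
  # one connected component
  expect_identical(res$mask,
                   bfs_flood_oracle(img, unname(res$seed), 200, 2000, 8))
})

test_that("replicates seeded in the same component grow identical masks", {
  spec <- tiny_spec()
  b <- make_tibia_volume(spec, seed = 6)
  model <- fit_calibration(read_phantom(b$volume, spec$layout))
  excl <- phantom_mask(spec$layout, dim(b$volume$voxels)[2:3])
  z <- region_slice_indices(dim(b$volume$voxels)[1])[["medial"]]
  bmd <- hu_to_bmd(b$volume$voxels[z, , ], model)
  masks <- lapply(1:3, function(r) m2_slice_bmd(bmd, r, exclude = excl)$mask)
  expect_identical(masks[[1]], masks[[2]])
  expect_identical(masks[[1]], masks[[3]])
})
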