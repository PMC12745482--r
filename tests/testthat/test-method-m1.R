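disk_mask <- function(n, center, r) {
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  (rows - center[1])^2 + (cols - center[2])^2 <= r^2
}

test_that("bone mask keeps the largest in-range component", {
  img <- matrix(40, 64, 64)
  d <- disk_mask(64, c(32, 32), 12)
  img[d] <- 800
  expect_equal(bone_mask(img), d)

  # two components: 500-ish px vs a small satellite
  img2 <- matrix(40, 64, 64)
  big <- disk_mask(64, c(25, 25), 12)
  small <- disk_mask(64, c(55, 55), 2)
  img2[big] <- 700; img2[small] <- 700
  m <- bone_mask(img2)
  expect_equal(m, big)

  # values above the window are excluded
  img2[big] <- 2500
  expect_equal(bone_mask(img2), small)
  expect_error(bone_mask(matrix(40, 8, 8)), "empty bone mask")
})

test_that("bone mask agrees with an independent connected-component oracle", {
  # EBImage::bwlabel labels 4-connected components
  for (s in 1:5) {
    img <- random_bmd_slice(48, seed = s)
    in_range <- img >= 200 & img <= 2000
    labels <- EBImage::bwlabel(in_range)
    sizes <- table(labels[labels > 0])
    oracle <- labels == as.integer(names(which.max(sizes)))
    m <- bone_mask(img, connectivity = 4)
    expect_equal(sum(m), as.integer(max(sizes)))
    expect_true(all(m == oracle) ||
                  sum(m) == max(sizes))  # ties: any largest component is valid
  }
})

test_that("geometric center is the unweighted centroid", {
  ann <- disk_mask(41, c(21, 21), 15) & !disk_mask(41, c(21, 21), 8)
  expect_equal(unname(geometric_center(ann)), c(21, 21))
  single <- matrix(FALSE, 30, 30); single[10, 20] <- TRUE
  expect_equal(unname(geometric_center(single)), c(10, 20))
  set.seed(5)
  rnd <- matrix(runif(900) < 0.3, 30, 30)
  idx <- which(rnd, arr.ind = TRUE)
  expect_equal(unname(geometric_center(rnd)),
               c(mean(idx[, 1]), mean(idx[, 2])))
  expect_error(geometric_center(matrix(FALSE, 3, 3)), "empty")
})

test_that("quadrant partition is a disjoint cover aligned to anatomy", {
  ann <- disk_mask(41, c(21, 21), 15) & !disk_mask(41, c(21, 21), 8)
  qs <- quadrant_partition(ann)
  areas <- vapply(qs$masks, sum, numeric(1))
  expect_lt(max(areas) - min(areas), 2)  # symmetric annulus: equal within a pixel
  total <- Reduce(`+`, lapply(qs$masks, function(m) m * 1L))
  expect_true(all(total[ann] == 1L))
  expect_true(all(total[!ann] == 0L))

  # a pixel directly above the center is anterior; below, posterior
  m <- matrix(FALSE, 21, 21); m[4, 11] <- TRUE; m[18, 11] <- TRUE
  qs2 <- quadrant_partition(m, center = c(11, 11))
  expect_true(qs2$masks$anterior[4, 11])
  expect_true(qs2$masks$posterior[18, 11])

  # random masks: every pixel in exactly one quadrant
  for (s in 1:3) {
    set.seed(s)
    rnd <- matrix(runif(1600) < 0.4, 40, 40)
    q <- quadrant_partition(rnd, center = c(20.3, 19.6))
    tot <- Reduce(`+`, lapply(q$masks, function(m) m * 1L))
    expect_true(all(tot[rnd] == 1L) && all(tot[!rnd] == 0L))
  }
})

test_that("ROI placement maximizes mean density with lexicographic ties", {
  # uniform density: every admissible center ties; smallest (row, col) wins
  q <- disk_mask(40, c(20, 20), 12)
  vals <- matrix(500, 40, 40)
  roi <- place_cortical_roi(q, vals)
  adm <- which(q, arr.ind = TRUE)
  fits <- vapply(seq_len(nrow(adm)), function(k) {
    offs <- tibiaqct:::disk_offsets(2)
    all(q[cbind(adm[k, 1] + offs[, 1], adm[k, 2] + offs[, 2])])
  }, logical(1))
  adm <- adm[fits, , drop = FALSE]
  adm <- adm[order(adm[, 1], adm[, 2]), , drop = FALSE]
  expect_equal(unname(roi$base_center), unname(adm[1, ]))
  expect_equal(roi$mean, 500)
  expect_equal(roi$sd, 0)

  # a dense blob larger than the ROI: the ROI lands inside it
  vals2 <- matrix(300, 40, 40)
  blob <- disk_mask(40, c(24, 16), 4)
  vals2[blob] <- 1200
  roi2 <- place_cortical_roi(q, vals2, homogeneity_limit = Inf)
  expect_true(blob[roi2$base_center[1], roi2$base_center[2]])
  expect_equal(roi2$mean, 1200)

  # exhaustive-search oracle: chosen mean equals the max over all candidates
  set.seed(42)
  vals3 <- matrix(runif(1600, 300, 900), 40, 40)
  roi3 <- place_cortical_roi(q, vals3, homogeneity_limit = Inf)
  offs <- tibiaqct:::disk_offsets(2)
  cand <- which(q, arr.ind = TRUE)
  means <- vapply(seq_len(nrow(cand)), function(k) {
    px <- cbind(cand[k, 1] + offs[, 1], cand[k, 2] + offs[, 2])
    if (any(px < 1) || any(px > 40) || !all(q[px])) return(NA_real_)
    mean(vals3[px])
  }, numeric(1))
  expect_equal(roi3$mean, max(means, na.rm = TRUE), tolerance = 1e-12)
})

test_that("homogeneity constraint steers the ROI away from heterogeneous spots", {
  q <- matrix(TRUE, 20, 20)
  vals <- matrix(500, 20, 20)
  vals[4:8, 4:8] <- rep(c(100, 2000), length.out = 25)  # hot but wildly mixed
  unconstrained <- place_cortical_roi(q, vals, homogeneity_limit = Inf)
  constrained <- place_cortical_roi(q, vals, homogeneity_limit = 0.15)
  expect_gt(unconstrained$mean, constrained$mean)
  expect_equal(constrained$mean, 500)
  expect_lte(constrained$sd, 0.15 * constrained$mean)
})

test_that("a quadrant too thin for the disk raises a measurement error", {
  thin <- matrix(FALSE, 20, 20)
  thin[10, 3:18] <- TRUE  # one-pixel-wide strip
  expect_error(place_cortical_roi(thin, matrix(500, 20, 20)), "too thin")
})

test_that("slice BMD is the mean of the four quadrant ROI means", {
  img <- matrix(40, 64, 64)
  img[disk_mask(64, c(32, 32), 14)] <- 800
  res <- m1_slice_bmd(img)
  means <- vapply(res$rois, function(r) r$mean, numeric(1))
  expect_equal(res$slice_bmd, mean(means))
  expect_equal(res$slice_bmd, 800)

  # every reported ROI disk lies inside the bone mask
  for (roi in res$rois) {
    offs <- tibiaqct:::disk_offsets(roi$radius, roi$center - roi$base_center)
    px <- cbind(roi$base_center[1] + offs[, 1], roi$base_center[2] + offs[, 2])
    expect_true(all(res$mask[px]))
  }
})

test_that("max-density ROI selection never undershoots the whole-mask mean", {
  # the structural source of the quadrant method's positive bias
  spec <- tiny_spec()
  for (s in 1:3) {
    b <- make_tibia_volume(spec, seed = s)
    model <- fit_calibration(read_phantom(b$volume, spec$layout))
    excl <- phantom_mask(spec$layout, dim(b$volume$voxels)[2:3])
    for (z in region_slice_indices(dim(b$volume$voxels)[1])) {
      bmd <- hu_to_bmd(b$volume$voxels[z, , ], model)
      res <- m1_slice_bmd(bmd, exclude = excl)
      expect_gte(res$slice_bmd, mean(bmd[res$mask]))
    }
  }
})
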