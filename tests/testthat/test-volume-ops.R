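test_that("mirror_msp is an index-reversing involution and intensity isometry", {
  v <- volume3d(array(c(1, 5, 4), c(3, 1, 1)))
  expect_equal(as.numeric(mirror_msp(v)$voxels), c(4, 5, 1))
  for (seed in 1:3) {
    v <- rand_volume(c(7, 6, 5), seed)
    m <- mirror_msp(v)
    expect_identical(mirror_msp(m)$voxels, v$voxels)
    expect_identical(sort(as.numeric(m$voxels)), sort(as.numeric(v$voxels)))
  }
  s <- symmetric_volume(c(8, 5, 4))
  expect_equal(mirror_msp(s)$voxels, s$voxels)
  expect_error(mirror_msp(array(0, c(3, 3, 3))), "metadata")
})

test_that("mirror_subtract is exactly anti-symmetric", {
  v <- volume3d(array(c(1, 5, 4), c(3, 1, 1)))
  expect_equal(as.numeric(mirror_subtract(v)$voxels), c(-3, 0, 3))
  expect_equal(max(abs(mirror_subtract(symmetric_volume(c(9, 4, 4)))$voxels)), 0)
  for (seed in 1:3) {
    out <- mirror_subtract(rand_volume(c(6, 5, 4), seed))
    expect_equal(mirror_msp(out)$voxels, -out$voxels)
  }
})

test_that("split_hemispheres aligns homologous voxels and drops odd midlines", {
  v4 <- volume3d(array(c(1, 2, 3, 4), c(4, 1, 1)))
  sp <- split_hemispheres(v4)
  expect_equal(as.numeric(sp$left$voxels), c(1, 2))
  expect_equal(as.numeric(sp$right$voxels), c(4, 3))
  expect_equal(sp$midline_policy, "none")

  v91 <- volume3d(array(0, c(91, 109, 91)), template = "mni-2mm")
  sp91 <- split_hemispheres(v91)
  expect_equal(sp91$left$shape, c(45L, 109L, 91L))
  expect_equal(sp91$right$shape, c(45L, 109L, 91L))
  expect_equal(sp91$midline_policy, "dropped-central-plane")

  s <- symmetric_volume(c(9, 6, 5))
  sps <- split_hemispheres(s)
  expect_equal(sps$left$voxels, sps$right$voxels)

  # reconstruction: left + midline + re-mirrored right reproduces the input
  v <- rand_volume(c(9, 4, 3), 7)
  spv <- split_hemispheres(v)
  h <- 4
  rebuilt <- array(0, c(9, 4, 3))
  rebuilt[1:h, , ] <- spv$left$voxels
  rebuilt[5, , ] <- v$voxels[5, , ]
  rebuilt[9:(9 - h + 1), , ] <- spv$right$voxels
  expect_equal(rebuilt, v$voxels)

  expect_error(split_hemispheres(volume3d(array(0, c(2, 3, 3)))), "at least 3")
})

test_that("mip_axial equals the per-pixel max oracle and honours defaults", {
  for (seed in 1:4) {
    v <- rand_volume(c(8, 8, 8), seed)
    zlo <- sample(0:3, 1); zhi <- sample(4:7, 1)
    got <- mip_axial(v, zlo, zhi)
    expect_equal(got$pixels, mip_bruteforce(v$voxels, zlo, zhi))
    expect_equal(got$shape, c(8L, 8L))
  }
  cv <- volume3d(array(3.5, c(4, 5, 6)))
  expect_true(all(mip_axial(cv, 0, 5)$pixels == 3.5))
  z <- array(0, c(4, 5, 120))
  z[2, 3, 71] <- 9  # z index 70 (0-based)
  got <- mip_axial(volume3d(z), 45, 100)
  expect_equal(got$pixels[3, 2], 9)
  expect_equal(sum(got$pixels), 9)
  expect_error(mip_axial(rand_volume(c(4, 4, 4)), 0, 4), "outside")
  expect_error(mip_axial(rand_volume(c(4, 4, 4))), "z_lo")
})

test_that("slice-bag extraction matches a per-slice counting oracle", {
  for (seed in 1:3) {
    set.seed(seed)
    v <- volume3d(array(stats::rnorm(12 * 11 * 9, 0, 20), c(12, 11, 9)))
    thr <- stats::runif(1, -5, 5)
    minfg <- sample(40:80, 1)
    counts <- apply(v$voxels > thr, 3, sum)
    keep <- which(counts >= minfg)
    if (length(keep) == 0) {
      expect_error(extract_slice_bag(v, minfg, thr), "empty")
    } else {
      bag <- extract_slice_bag(v, minfg, thr)
      expect_equal(bag$kept_indices, keep)
      expect_true(all(diff(bag$kept_indices) > 0))
      for (j in seq_along(keep))
        expect_equal(bag$instances[[j]]$pixels, t(v$voxels[, , keep[j]]))
    }
  }
})

test_that("slice filter boundary keeps a slice with exactly the minimum count", {
  v <- array(0, c(20, 20, 3))
  v[1:10, 1:10, 2] <- 30  # exactly 100 suprathreshold pixels in slice 2
  bag <- extract_slice_bag(volume3d(v), min_fg_pixels = 100, fg_hu_threshold = 0)
  expect_equal(bag$kept_indices, 2L)
  expect_error(extract_slice_bag(volume3d(array(0, c(5, 5, 4)))), "empty")
})

test_that("phantom slice-bag counts follow planted foreground", {
  v <- array(0, c(30, 30, 91))
  v[8:27, 8:27, 1:60] <- 25       # 400 foreground pixels
  v[11:17, 11:17, 61:91] <- 25    # 49 pixels: below the default threshold
  bag <- extract_slice_bag(volume3d(v))
  expect_equal(length(bag$instances), 60L)
  expect_equal(bag$kept_indices, 1:60)
})

test_that("augmentation is a seeded pure function with the stated transforms", {
  v <- rand_volume(c(16, 14, 12), 3)
  spec <- augmentation_spec(rotate = TRUE, elastic = TRUE, noise = TRUE, seed = 11)
  a1 <- augment(v, spec)
  a2 <- augment(v, spec)
  expect_identical(a1$voxels, a2$voxels)
  expect_identical(dim(a1$voxels), dim(v$voxels))

  expect_identical(augment(v, augmentation_spec(mirror = TRUE, seed = 1))$voxels,
                   mirror_msp(v)$voxels)

  big <- rand_volume(c(30, 30, 30), 4)
  noise_only <- augment(big, augmentation_spec(noise = TRUE, seed = 5))
  delta <- noise_only$voxels - big$voxels
  se <- 2 / sqrt(length(delta))
  expect_lt(abs(mean(delta) - 5), 3 * se)
  expect_lt(abs(stats::sd(delta) - 2), 0.05)

  expect_error(augmentation_spec(noise_std = -1), "non-negative")
})

test_that("fourfold augmentation yields 4x volumes with a provenance manifest", {
  vols <- lapply(1:3, function(i) rand_volume(c(10, 9, 8), i))
  out <- augment_fourfold(vols, labels = c(0, 1, 1), seed = 9)
  expect_length(out$volumes, 12L)
  expect_equal(out$labels, rep(c(0, 1, 1), each = 4))
  expect_equal(nrow(out$manifest), 12L)
  expect_equal(sum(out$manifest$transform == "none"), 3L)
  expect_true(all(out$manifest$transform[out$manifest$copy > 0] %in%
                    c("mirror", "rotate", "elastic", "noise")))
})

test_that("NIfTI round trip preserves voxels, spacing and template tag", {
  v <- volume3d(array(stats::rnorm(91 * 109 * 91), c(91, 109, 91)),
                template = "mni-2mm")
  path <- tempfile(fileext = ".nii.gz")
  write_volume(v, path)
  v2 <- read_volume(path)
  expect_equal(v2$voxels, v$voxels, tolerance = 1e-6)
  expect_equal(v2$template, "mni-2mm")
  expect_equal(v2$spacing, c(2, 2, 2))
  unlink(path)
})

test_that("volume invariants are enforced", {
  expect_error(volume3d(array(0, c(10, 10, 10)), template = "mni-2mm"), "shape")
  expect_error(volume3d(array(c(NA, 1), c(2, 1, 1))), "finite")
  d <- downscale_volume(volume3d(array(1, c(91, 109, 91)), template = "mni-2mm"), 2)
  expect_equal(d$shape, c(46L, 55L, 46L))
  expect_true(all(abs(d$voxels - 1) < 1e-12))
  expect_equal(d$spacing, c(4, 4, 4))
})
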