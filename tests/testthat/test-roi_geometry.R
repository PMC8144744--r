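sphere_mask <- function(dims, centre_vox, radius_mm, spacing) {
  cx <- (seq_len(dims[1]) - centre_vox[1]) * spacing[1]
  cy <- (seq_len(dims[2]) - centre_vox[2]) * spacing[2]
  cz <- (seq_len(dims[3]) - centre_vox[3]) * spacing[3]
  d2 <- outer(outer(cx^2, cy^2, "+"), cz^2, "+")
  d2 <= radius_mm^2
}

test_that("mask translation uses nearest-voxel rounding and preserves voxel count", {
  sp <- c(1.17, 1.17, 3)
  m <- binary_mask(sphere_mask(c(20, 20, 20), c(10, 10, 10), 6, sp), sp)
  expect_identical(translate_mask(m, c(0, 0, 0))$mask, m$mask)

  shifted <- translate_mask(m, c(1.17, 0, 0))
  expect_equal(sum(shifted$mask), sum(m$mask))
  expect_identical(which(shifted$mask, arr.ind = TRUE)[, 1],
                   which(m$mask, arr.ind = TRUE)[, 1] + 1L)

  # half-voxel shift rounds per axis; count always preserved
  half <- translate_mask(m, 0.5 * sp)
  expect_equal(sum(half$mask), sum(m$mask))
  cen <- function(x) colMeans(which(x$mask, arr.ind = TRUE))
  expect_true(all(abs(cen(half) - cen(m)) %in% c(0, 1)))

  expect_error(translate_mask(m, c(100, 0, 0)), "out-of-bounds")
})

test_that("motion amplitude is the norm of the per-axis translation ranges", {
  expect_equal(motion_amplitude(matrix(0, 10, 3)), 0)
  tr <- matrix(0, 10, 3); tr[, 3] <- seq(0, 3, length.out = 10)
  expect_equal(motion_amplitude(tr), 3)
  # sinusoidal z +/-5 mm with +/-1 mm x
  th <- 2 * pi * (0:9) / 10
  tr <- cbind(cos(th), 0, 5 * cos(th))
  expect_equal(motion_amplitude(tr), sqrt(2^2 + 10^2))
  expect_error(motion_amplitude(matrix(0, 1, 3)), "at least 2")
})

test_that("peritumoural band matches brute-force voxel-centre distances", {
  # sphere radius 9 mm on isotropic 1 mm voxels
  sp <- c(1, 1, 1)
  dims <- c(30, 30, 30)
  gtv <- binary_mask(sphere_mask(dims, c(15, 15, 15), 9, sp), sp)
  band <- peritumour_band(gtv, inner = 3, outer = 3)

  # brute force: distance from every voxel centre to nearest centre across
  # the surface
  inside <- which(gtv$mask, arr.ind = TRUE)
  outside <- which(!gtv$mask, arr.ind = TRUE)
  nn_dist <- function(from, to) {
    apply(from, 1, function(v) sqrt(min(colSums((t(to) - v)^2))))
  }
  d_in <- nn_dist(inside, outside)
  d_out <- nn_dist(outside, inside)
  expected <- array(FALSE, dims)
  expected[inside[d_in <= 3, , drop = FALSE]] <- TRUE
  expected[outside[d_out <= 3, , drop = FALSE]] <- TRUE
  expect_identical(band$mask, expected)

  # symmetric in the mask and its complement when inner == outer
  comp <- binary_mask(!gtv$mask, sp)
  expect_identical(peritumour_band(comp, 3, 3)$mask, band$mask)

  expect_error(peritumour_band(binary_mask(array(FALSE, dims), sp)), "empty")
})

test_that("band equals brute force on random anisotropic blobs", {
  set.seed(11)
  sp <- c(1.17, 1.17, 3)
  for (rep in 1:3) {
    dims <- c(14, 14, 10)
    seedpts <- cbind(sample(4:11, 3), sample(4:11, 3), sample(3:8, 3))
    blob <- array(FALSE, dims)
    idx <- which(!blob, arr.ind = TRUE)
    for (k in 1:3) {
      d2 <- colSums((t(sweep(idx, 2, seedpts[k, ])) * sp)^2)
      blob[idx[d2 <= runif(1, 9, 25), , drop = FALSE]] <- TRUE
    }
    if (!any(blob) || all(blob)) next
    gtv <- binary_mask(blob, sp)
    band <- peritumour_band(gtv, 3, 3)
    inside <- which(blob, arr.ind = TRUE); outside <- which(!blob, arr.ind = TRUE)
    d_in <- apply(inside, 1, function(v) sqrt(min(colSums(((t(outside) - v) * sp)^2))))
    d_out <- apply(outside, 1, function(v) sqrt(min(colSums(((t(inside) - v) * sp)^2))))
    expected <- array(FALSE, dims)
    expected[inside[d_in <= 3, , drop = FALSE]] <- TRUE
    expected[outside[d_out <= 3, , drop = FALSE]] <- TRUE
    expect_identical(band$mask, expected)
  }
})

test_that("high-density correction trims slab-attached band voxels, matching a direct oracle", {
  sp <- c(1, 1, 1)
  dims <- c(24, 24, 24)
  gtv <- binary_mask(sphere_mask(dims, c(14, 12, 12), 6, sp), sp)
  band <- peritumour_band(gtv, 3, 3)
  img_arr <- array(-750, dims)
  img_arr[21:24, , ] <- 300   # chest-wall slab intersecting the outer band
  img <- image_volume(img_arr, sp)
  expect_gt(sum(band$mask & img_arr > 0), 0)

  corrected <- correct_high_density(band, gtv, img, hu_threshold = 0)
  expect_true(all(band$mask[corrected$mask]))  # subset of band

  # independent voxel-by-voxel oracle of the stated removal rule:
  # high-density outside-band voxels plus their 26-neighbours in the band,
  # then erosion against anything not in (surviving band | gtv core)
  outside <- band$mask & !gtv$mask
  seeds <- outside & img_arr > 0
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  nbhd <- function(v) {
    w <- sweep(offs, 2, v, "+")
    w[!apply(w, 1, function(r) any(r < 1) || any(r > dims)), , drop = FALSE]
  }
  removed_oracle <- array(FALSE, dims)
  for (v_lin in which(outside)) {
    v <- arrayInd(v_lin, dims)[1, ]
    if (seeds[v_lin] || any(seeds[nbhd(v)])) removed_oracle[v_lin] <- TRUE
  }
  surviving <- band$mask & !removed_oracle
  keep_region <- surviving | gtv$mask
  expected <- array(FALSE, dims)
  for (v_lin in which(surviving)) {
    v <- arrayInd(v_lin, dims)[1, ]
    nb <- nbhd(v)
    full_nbhd <- nrow(nb) == 26 && all(keep_region[nb])
    expected[v_lin] <- full_nbhd
  }
  expect_identical(corrected$mask, expected)
  # the slab side of the band is gone, the far side survives
  expect_equal(sum(corrected$mask[20:24, , ]), 0)
  expect_gt(sum(corrected$mask[1:12, , ]), 0)

  # threshold above the CT range removes nothing before erosion: result is a
  # superset of the slab-corrected result
  lax <- correct_high_density(band, gtv, img, hu_threshold = 3000)
  expect_true(all(lax$mask[corrected$mask]))

  # lung-density band far from any slab: removal stage is a no-op, so the
  # band only erodes at its own exterior boundary
  img2 <- image_volume(array(-750, dims), sp)
  only_eroded <- correct_high_density(band, gtv, img2, hu_threshold = 0)
  expect_true(all(band$mask[only_eroded$mask]))
  expect_identical(only_eroded$mask,
                   correct_high_density(band, gtv, img2, hu_threshold = 3000)$mask)
})

test_that("minimum-volume rule is inclusive at 64 voxels", {
  sp <- c(1, 1, 1)
  cube <- array(FALSE, c(10, 10, 10)); cube[1:4, 1:4, 1:4] <- TRUE
  expect_true(min_volume_check(binary_mask(cube, sp)))
  cube[1, 1, 1] <- FALSE
  expect_false(min_volume_check(binary_mask(cube, sp)))
  expect_false(min_volume_check(binary_mask(array(FALSE, c(5, 5, 5)), sp)))
})

test_that("translation never changes voxel count on random blobs", {
  set.seed(21)
  sp <- c(1.17, 1.17, 3)
  blob <- array(runif(16^3) < 0.2, c(16, 16, 16))
  blob[c(1:4, 13:16), , ] <- FALSE; blob[, c(1:4, 13:16), ] <- FALSE
  blob[, , c(1:4, 13:16)] <- FALSE
  m <- binary_mask(blob, sp)
  for (k in 1:10) {
    t <- runif(3, -3, 3)
    expect_equal(sum(translate_mask(m, t)$mask), sum(m$mask))
  }
})
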