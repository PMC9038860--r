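test_that("mixture_hu is the volume-weighted combination of pure materials", {
  b <- material_basis()
  expect_equal(mixture_hu(c(1, 0, 0), b), -100)
  expect_equal(mixture_hu(c(0, 1, 0), b), 45)
  expect_equal(mixture_hu(c(0.5, 0.5, 0), b), -27.5)
  expect_equal(mixture_hu(c(0, 0, 1), b, "low"), 1400)
  # matrix input and linearity across random mixtures
  set.seed(4)
  m <- t(replicate(20, { x <- runif(3); x / sum(x) }))
  expect_equal(mixture_hu(m, b),
               m[, 1] * -100 + m[, 2] * 45 + m[, 3] * 1000)
  expect_error(mixture_hu(c(1, 0, 0), b, "mono"), "unknown energy")
})

test_that("compartment fractions are validated", {
  expect_error(compartment_fractions(0.5, 0.5, 0.5), "sum to 1")
  expect_error(compartment_fractions(-0.1, 1.1, 0), "\\[0, 1\\]")
  f <- compartment_fractions(0.85, 0.05, 0.10)
  expect_equal(unname(sum(f)), 1)
})

test_that("material basis rejects non-physical configurations", {
  expect_error(material_basis(hu_mineral_low = 700, hu_mineral_high = 800),
               "more at low energy")
  expect_error(material_basis(hu_fat_conv = 10), "fat HU must be negative")
})

test_that("full-suppression VNCa removes the mineral term on a noise-free grid", {
  dims <- c(10, 10, 10)
  fr <- random_fractions(dims, cap_mineral = 0.8, seed = 11)
  v <- forward_volume(fr)
  vn <- vnca_transform(v, suppression_index = 25)
  nonmin <- fr$fat + fr$soft
  oracle <- (fr$fat * material_basis()$hu_fat_conv +
             fr$soft * material_basis()$hu_soft_conv) / nonmin
  expect_lt(max(abs(vn$vnca - oracle)), 1e-6)
})

test_that("zero-mineral voxels pass through VNCa unchanged", {
  dims <- c(6, 6, 6)
  fr <- random_fractions(dims, cap_mineral = 0, seed = 2)
  v <- forward_volume(fr)
  vn <- vnca_transform(v)
  expect_lt(max(abs(vn$vnca - v$conventional)), 1e-9)
  # pure fat voxel is exactly the fat HU
  frf <- list(fat = array(1, dims), soft = array(0, dims), mineral = array(0, dims))
  expect_equal(unique(as.vector(vnca_transform(forward_volume(frf))$vnca)), -100)
})

test_that("dense cortical voxels land below -1000 HU after suppression", {
  dims <- c(4, 4, 4)
  fr <- list(fat = array(0, dims), soft = array(0, dims), mineral = array(1, dims))
  vn <- vnca_transform(forward_volume(fr))
  expect_true(all(vn$vnca < -1000))
})

test_that("VNCa is non-increasing in mineral fraction at fixed fat:soft ratio", {
  b <- material_basis()
  ms <- seq(0, 0.95, by = 0.05)
  vals <- vapply(ms, function(m) {
    fr <- list(fat = array(0.7 * (1 - m), c(2, 2, 2)),
               soft = array(0.3 * (1 - m), c(2, 2, 2)),
               mineral = array(m, c(2, 2, 2)))
    vnca_transform(forward_volume(fr), b)$vnca[1]
  }, 1.0)
  expect_true(all(diff(vals) <= 1e-9))
})

test_that("partial suppression interpolates between conventional and full removal", {
  fr <- list(fat = array(0.6, c(2, 2, 2)), soft = array(0.3, c(2, 2, 2)),
             mineral = array(0.1, c(2, 2, 2)))
  v <- forward_volume(fr)
  v0 <- vnca_transform(v, suppression_index = 1e-9)$vnca[1]
  vh <- vnca_transform(v, suppression_index = 12.5)$vnca[1]
  vf <- vnca_transform(v, suppression_index = 25)$vnca[1]
  expect_equal(v0, v$conventional[1], tolerance = 1e-6)
  expect_true(vf < vh && vh < v0)
  # indices above 25 clip to full suppression
  expect_equal(vnca_transform(v, suppression_index = 100)$vnca[1], vf)
})

test_that("mineral density map is linear and exact at the calibration point", {
  b <- material_basis()
  dims <- c(3, 3, 3)
  zero <- forward_volume(list(fat = array(0.6, dims), soft = array(0.4, dims),
                              mineral = array(0, dims)))
  expect_lt(max(abs(mineral_density_map(zero, b))), 1e-9)
  ref <- forward_volume(list(fat = array(0, dims), soft = array(0, dims),
                             mineral = array(1, dims)))
  expect_equal(unique(as.vector(mineral_density_map(ref, b))), 400)
  half <- forward_volume(list(fat = array(0.3, dims), soft = array(0.2, dims),
                              mineral = array(0.5, dims)))
  expect_equal(unique(as.vector(mineral_density_map(half, b))), 200)
})

test_that("a singular basis is rejected", {
  expect_error(
    vnca_transform(forward_volume(random_fractions(c(2, 2, 2)),
                                  basis = material_basis()),
                   basis = material_basis(hu_soft_low = -10, hu_soft_high = -26,
                                          hu_mineral_low = 1400, hu_mineral_high = 800)),
    NA)
  # construct mineral response parallel to the soft-fat direction:
  # soft-fat excess (140, 70), mineral-fat excess (1400, 700)
  bad <- material_basis(hu_soft_low = 30, hu_soft_high = -20,
                        hu_mineral_low = 1290, hu_mineral_high = 610)
  v <- forward_volume(random_fractions(c(2, 2, 2)))
  expect_error(vnca_transform(v, bad), "singular")
})
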