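test_that("rule-based labeling recovers the ground-truth bodies with Dice 1", {
  for (i in c(0, 0.5)) {
    sp <- small_spec(n_vertebrae = 4, infiltration = i, seed = 21)
    ph <- build_phantom(sp)
    ls <- label_vertebrae(ph$volume$conventional, sp$spacing_mm)
    expect_equal(length(ls$ordering), 4)
    voi <- select_bottom_k(ls, 3)
    tr <- ph$truth$label_map %in% 1:3
    dice <- 2 * sum(tr & voi$mask) / (sum(tr) + sum(voi$mask))
    expect_equal(dice, 1)
  }
})

test_that("an empty volume raises a no-spine error", {
  expect_error(label_vertebrae(array(-1000, c(8, 8, 8)), c(1, 1, 1)), "no spine found")
})

test_that("two bodies fused by a thin bridge are still split", {
  # two 9x9x6 cuboid shells of bone joined by a 1-voxel column
  arr <- array(-1000, c(15, 15, 20))
  arr[4:12, 4:12, 3:8] <- 1000
  arr[4:12, 4:12, 12:17] <- 1000
  arr[8, 8, 9:11] <- 1000  # bridge
  ls <- label_vertebrae(arr, c(1, 1, 1))
  expect_equal(length(ls$ordering), 2)
})

test_that("bottom-k selection keeps the most caudal labels and validates counts", {
  lab <- array(0L, c(6, 6, 30))
  for (v in 1:5) lab[2:5, 2:5, (v * 6 - 4):(v * 6 - 1)] <- v
  ls <- labeled_spine(lab, c(1, 1, 1))
  expect_equal(ls$ordering, 1:5)
  m <- select_bottom_k(ls, 3)
  expect_true(all(lab[m$mask] %in% 1:3))
  expect_equal(sum(m$mask), sum(lab %in% 1:3))
  m5 <- select_bottom_k(ls, 5)
  expect_equal(sum(m5$mask), sum(lab > 0))
  expect_error(select_bottom_k(ls, 17), "found 5 < 17")
  # ordering follows centroid, not label value
  lab2 <- lab
  lab2[lab == 1] <- 9L
  ls2 <- labeled_spine(lab2, c(1, 1, 1))
  expect_equal(ls2$ordering, c(9L, 2L, 3L, 4L, 5L))
  expect_true(9L %in% lab2[select_bottom_k(ls2, 2)$mask])
})

test_that("3-mm ball erosion of an 11-cube at 1 mm leaves the 5-cube (125 voxels)", {
  mask <- array(FALSE, c(15, 15, 15))
  mask[3:13, 3:13, 3:13] <- TRUE
  er <- erode_cortex(voi_mask(mask, c(1, 1, 1)), 3)
  expect_equal(sum(er$mask), 125)
  expect_true(all(which(er$mask, arr.ind = TRUE) >= 6) &&
                all(which(er$mask, arr.ind = TRUE) <= 10))
})

test_that("anisotropic erosion matches the brute-force ball-fit oracle", {
  set.seed(8)
  mask <- array(FALSE, c(14, 12, 10))
  mask[3:12, 3:10, 3:8] <- TRUE
  mask[sample(which(mask), 30)] <- FALSE  # roughen the shape
  sp <- c(1, 1, 2)
  er <- suppressWarnings(erode_cortex(voi_mask(mask, sp), 3))
  expect_identical(er$mask, erode_bruteforce(mask, 3, sp))
  # through-plane depth is 1 voxel, in-plane 3 voxels for a solid cube
  cube <- array(FALSE, c(11, 11, 11)); cube[2:10, 2:10, 2:10] <- TRUE
  erc <- erode_cortex(voi_mask(cube, sp), 3)
  kept <- which(erc$mask, arr.ind = TRUE)
  expect_equal(range(kept[, 1]), c(5, 7))
  expect_equal(range(kept[, 3]), c(3, 9))
})

test_that("erosion is conservative: subset, identity at 0, and composable bounds", {
  set.seed(9)
  mask <- array(runif(14 * 14 * 14) < 0.9, c(14, 14, 14))
  mask[c(1, 14), , ] <- FALSE; mask[, c(1, 14), ] <- FALSE; mask[, , c(1, 14)] <- FALSE
  m <- voi_mask(mask, c(1, 1, 1))
  expect_identical(erode_cortex(m, 0)$mask, mask)
  e1 <- suppressWarnings(erode_cortex(m, 2))
  expect_true(all(!e1$mask | mask))
  e12 <- suppressWarnings(erode_cortex(e1, 2))
  e3 <- suppressWarnings(erode_cortex(m, 4))
  expect_true(all(!e3$mask | e12$mask))          # erode(r+r') subset of twice-eroded
  expect_true(all(!e12$mask | e1$mask))
})

test_that("erosion that swallows the VOI warns and returns an empty mask", {
  mask <- array(FALSE, c(8, 8, 8)); mask[4:5, 4:5, 4:5] <- TRUE
  expect_warning(er <- erode_cortex(voi_mask(mask, c(1, 1, 1)), 3), "entire VOI")
  expect_equal(sum(er$mask), 0)
})

test_that("voxel extraction returns the masked multiset and physical volume", {
  arr <- array(-80, c(10, 10, 10))
  full <- voi_mask(array(TRUE, c(10, 10, 10)), c(1, 1, 1))
  s <- extract_voxels(arr, full)
  expect_equal(length(s$hu), 1000)
  expect_true(all(s$hu == -80))
  expect_equal(s$voi_volume_cm3, 1)  # 1000 voxels x 1 mm3
  empty <- voi_mask(array(FALSE, c(10, 10, 10)), c(1, 1, 1))
  se <- extract_voxels(arr, empty)
  expect_equal(length(se$hu), 0)
  expect_equal(se$voi_volume_cm3, 0)
  expect_error(extract_voxels(array(0, c(5, 5, 5)), full), "shape mismatch")
})

test_that("lesion voxels carved from vertebrae stay out of the VOI", {
  sp <- small_spec(n_vertebrae = 3, noise_sd_hu = 0,
                   lesions = list(list(center_mm = c(22, 22, 27), radius_mm = 5)))
  ph <- build_phantom(sp)
  res <- quantify_patient(ph$volume, label_map = ph$truth$label_map,
                          cfg = run_config(segmentation = list(vertebrae = 3)))
  expect_equal(sum(res$voi$mask & ph$truth$label_map == -1L), 0)
})
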