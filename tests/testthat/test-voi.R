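test_that("background-corrected activity evaluates the estimator", {
  m <- tumorMeasurement(A0 = 120, V0 = 100, Aspect = 100, Vspect = 30,
                        Vct = 20)
  expect_equal(backgroundCorrectedActivity(m), 100 - (20 / 70) * 10)
  # zero-background and Vspect == Vct degeneracies leave Aspect untouched
  m2 <- tumorMeasurement(100, 100, 100, 30, 20)
  expect_equal(backgroundCorrectedActivity(m2), 100)
  m3 <- tumorMeasurement(120, 100, 100, 20, 20)
  expect_equal(backgroundCorrectedActivity(m3), 100)
  # monotone non-increasing in A0
  a4 <- vapply(seq(100, 200, by = 20), function(A0)
    backgroundCorrectedActivity(tumorMeasurement(A0, 100, 100, 30, 20)), 0)
  expect_true(all(diff(a4) <= 0))
  # heavy background can push below zero: clipped with warning
  expect_warning(
    expect_equal(backgroundCorrectedActivity(
      tumorMeasurement(A0 = 1000, V0 = 40, Aspect = 10, Vspect = 30,
                       Vct = 5)), 0),
    "clipping")
  expect_error(tumorMeasurement(120, 30, 100, 30, 20), "V0 equals Vspect")
  expect_error(tumorMeasurement(120, 100, 100, 10, 20), "Vspect < Vct")
})

test_that("enclose/separate recover a hot sphere against warm background", {
  # 10:1 sphere-to-background contrast, noiseless
  sp <- makeTumorSpec(withBackground = FALSE)
  st <- generatePhantomStudy(sp)
  vol <- st$volumes[[4]]
  # paint a uniform warm background at 10% of tumor concentration
  tumorConc <- max(vol@voxels)
  bg <- vol@voxels == 0
  vol@voxels[bg] <- 0.1 * tumorConc
  seedVox <- tumorSeedVoxel()
  enc <- encloseTumor(vol, seedVox, dilationMm = 15)
  sep <- separateTumor(vol, enc)
  # nesting and ordering invariants
  expect_true(all(sep@indices %in% enc@indices) ||
              nrow(merge(as.data.frame(sep@indices),
                         as.data.frame(enc@indices))) == nrow(sep@indices))
  expect_lte(voiVolume(sep), voiVolume(enc))
  expect_lte(voiActivity(vol, sep), voiActivity(vol, enc))
  # V_spect within one voxel shell of the rasterized truth
  nTrue <- sum(st$masks$tumor)
  expect_lte(abs(nrow(sep@indices) - nTrue), 0.3 * nTrue)
  # determinism
  sep2 <- separateTumor(vol, encloseTumor(vol, seedVox, dilationMm = 15))
  expect_identical(sep@indices, sep2@indices)
})

test_that("degenerate VOI inputs error as contracted", {
  zero <- new("ActivityVolume", voxels = array(0, c(8, 8, 8)),
              voxelSize = 5, origin = c(0, 0, 0), timePostInjection = 72)
  expect_error(suppressWarnings(encloseTumor(zero, c(4, 4, 4), 10)),
               "zero-activity")
  # a uniform rod spanning the grid can never be separated from the
  # enclosing VOI boundary (the abutting-vessel failure mode)
  arr <- array(0, c(16, 16, 16))
  arr[, 8, 8] <- 100
  rod <- new("ActivityVolume", voxels = arr, voxelSize = 5,
             origin = c(0, 0, 0), timePostInjection = 72)
  enc <- encloseTumor(rod, c(8, 8, 8), dilationMm = 6)
  expect_error(separateTumor(rod, enc), "separation failure")
})

test_that("zero background separation returns the super-zero component", {
  sp <- makeTumorSpec(withBackground = FALSE)
  st <- generatePhantomStudy(sp)
  vol <- st$volumes[[4]]
  enc <- encloseTumor(vol, tumorSeedVoxel(), dilationMm = 15)
  sep <- separateTumor(vol, enc)
  expect_equal(nrow(sep@indices), sum(st$masks$tumor))
})

test_that("tacVoi grows a connected hottest-voxel set of ~3 ml", {
  sp <- makeTumorSpec(withBackground = FALSE)
  st <- generatePhantomStudy(sp)
  vol <- st$volumes[[1]]
  voi <- tacVoi(vol, tumorSeedVoxel(), targetVolumeMl = 3)
  # 5.08 mm voxels: 23 voxels = 3.015 ml is the nearest count to 3 ml
  expect_equal(nrow(voi@indices), 23)
  expect_equal(voiVolume(voi), 3.015, tolerance = 1e-3)
  # uniform image: mean equals the uniform value wherever the mask sits
  u <- new("ActivityVolume", voxels = array(7, c(12, 12, 12)),
           voxelSize = 5.08, origin = c(0, 0, 0), timePostInjection = 1)
  expect_equal(voiMeanConcentration(u, tacVoi(u, c(6, 6, 6), 3)), 7)
  # one-voxel target picks the hottest voxel
  voi1 <- tacVoi(vol, tumorSeedVoxel(), targetVolumeMl = 5.08^3 / 1000)
  expect_equal(nrow(voi1@indices), 1)
  expect_equal(vol@voxels[voi1@indices], max(vol@voxels))
  expect_error(tacVoi(u, c(6, 6, 6), targetVolumeMl = 1e-5), "smaller")
})
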