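test_that("regional voxel sums reproduce the closed-form kinetics", {
  # tumor holding 1e6 Bq at the 72 h reference, Te = 30 h, no degradation
  sp <- phantomSpec(gridShape = 24L, voxelSize = 5.08,
    regions = list(phantomRegion("tumor", center = rep(60, 3),
                                 semiAxes = 12, Aref = 1e6, Te = 30,
                                 tRef = 72)),
    psfFwhm = 0, noiseModel = "none", seed = 2L)
  st <- generatePhantomStudy(sp)
  voxMl <- 5.08^3 / 1000
  sums <- vapply(st$volumes,
                 function(v) sum(v@voxels[st$masks$tumor]) * voxMl, 0)
  expect_equal(sums[4], 1e6, tolerance = 0.005)
  expect_equal(sums[3], 1e6 * 2^((72 - 24) / 30), tolerance = 0.005)
  expect_equal(sums[1], 1e6 * 2^((72 - 1) / 30), tolerance = 0.005)
  # conservation without noise: total image activity = sum of regions
  tr <- st$truth
  for (i in seq_along(sp@acquisitionTimes)) {
    tt <- sp@acquisitionTimes[i]
    expect_equal(sum(st$volumes[[i]]@voxels) * voxMl,
                 sum(tr@activities$activity_Bq[tr@activities$time_h == tt]),
                 tolerance = 0.005)
  }
  # monotone washout of the truth for finite Te, instantaneous uptake
  a <- tr@activities$activity_Bq[tr@activities$region == "tumor"]
  expect_true(all(diff(a) < 0))
})

test_that("phantom generation is seed-deterministic and validates inputs", {
  sp <- makeTumorSpec(noiseModel = "poisson", psfFwhm = 10, seed = 9L,
                      grid = 20L)
  a <- generatePhantomStudy(sp)
  b <- generatePhantomStudy(sp)
  for (i in seq_along(a$volumes))
    expect_identical(a$volumes[[i]]@voxels, b$volumes[[i]]@voxels)

  overlap <- phantomSpec(gridShape = 16L, voxelSize = 5,
    regions = list(
      phantomRegion("tumor", center = rep(40, 3), semiAxes = 12,
                    Aref = 1e5, Te = 30),
      phantomRegion("background", center = rep(44, 3), semiAxes = 12,
                    Aref = 1e5, Te = 8)))
  expect_error(generatePhantomStudy(overlap), "overlap")
  expect_error(generatePhantomStudy(
    phantomSpec(regions = list())), "no regions")
})

test_that("PSF blur preserves interior activity and Poisson noise is
           applied on the counts scale", {
  sp <- makeTumorSpec(psfFwhm = 12, withBackground = FALSE, grid = 28L)
  st <- generatePhantomStudy(sp)
  voxMl <- 5.08^3 / 1000
  tr <- st$truth
  # blur moves activity out of the mask but keeps the image total
  # (tumor is far from the grid edge)
  expect_equal(sum(st$volumes[[4]]@voxels) * voxMl,
               tr@activities$activity_Bq[tr@activities$region == "tumor" &
                                         tr@activities$time_h == 72],
               tolerance = 0.005)
  spN <- makeTumorSpec(noiseModel = "poisson", withBackground = FALSE,
                       grid = 20L, seed = 5L)
  stN <- generatePhantomStudy(spN)
  v <- stN$volumes[[1]]@voxels
  counts <- v * voxMl * spN@countsPerBq
  expect_true(all(abs(counts - round(counts)) < 1e-6))
})

test_that("synthetic chromatograms integrate to their peak areas", {
  one <- generateChromatogram(data.frame(rt_min = 6, area = 1000,
                                         sd_min = 0.2))
  tz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  expect_equal(tz(one@rt, one@counts), 1000, tolerance = 1e-3)

  two <- generateChromatogram(data.frame(rt_min = c(5, 9),
                                         area = c(750, 250),
                                         sd_min = c(0.15, 0.15)))
  expect_equal(tz(two@rt, two@counts), 1000, tolerance = 1e-3)

  n1 <- generateChromatogram(data.frame(rt_min = 6, area = 100,
                                        sd_min = 0.2),
                             noiseSd = 2, seed = 42L)
  n2 <- generateChromatogram(data.frame(rt_min = 6, area = 100,
                                        sd_min = 0.2),
                             noiseSd = 2, seed = 42L)
  expect_identical(n1@counts, n2@counts)
  expect_error(generateChromatogram(
    data.frame(rt_min = 99, area = 1, sd_min = 0.1)), "within rtRange")
  # baseline-only trace is allowed
  empty <- generateChromatogram(baseline = 5)
  expect_true(all(empty@counts == 5))
})
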