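test_that("fixture report recomputes the summary rows with match flags", {
  rep <- buildReport("fixtures")
  ds <- rep$doseSummary
  row <- function(ep) ds[ds$endpoint == ep, ]
  expect_equal(roundHalfUp(row("ratio_marrow")$medianWith, 1), 19.1)
  expect_true(row("tumor_dose")$medianWithoutMatches)
  expect_true(row("tumor_dose")$medianWithMatches)
  expect_true(row("tumor_dose")$pMatches)
  # flagged, known non-reproducing printed cells stay flagged
  expect_false(row("marrow_dose")$medianWithMatches)
  expect_false(row("marrow_dose")$pMatches)
  # every printed per-lesion ratio is consistent with the printed dose
  # quotient within propagated rounding
  expect_true(all(rep$ratioConsistency$consistent))
  # stability: per-time-point and pooled exact tests are both reported;
  # the pooled test is far below 0.001
  expect_equal(nrow(rep$stabilityTests), 5)
  expect_lt(rep$stabilityTests$p[rep$stabilityTests$scope == "pooled"],
            0.001)
  expect_error(buildReport("fixtures",
    fixtures = list(stability = data.frame())), "empty")
})

test_that("phantom report puts the noiseless pipeline within 2% of truth", {
  sp <- makeTumorSpec()
  st <- generatePhantomStudy(sp)
  kernel <- mcVoxelEnergy(lu177DecayData(), 5.08, nDecays = 1e5, seed = 3L)
  rep <- buildReport("phantom",
    phantom = list(study = st, kernel = kernel,
                   seedPoint = tumorSeedVoxel()))
  expect_true(all(abs(rep$truthVsEstimate$relDev) < 0.02))
  expect_error(buildReport("phantom"), "missing")
})

test_that("report bundles export to CSV", {
  rep <- buildReport("fixtures")
  dir <- tempfile()
  exportReport(rep, dir)
  expect_true(file.exists(file.path(dir, "doseSummary.csv")))
  back <- read.csv(file.path(dir, "doseSummary.csv"))
  expect_equal(nrow(back), 7)
  unlink(dir, recursive = TRUE)
})

test_that("trapezoid fallback engages when the washout fit is unusable", {
  # a region with no effective clearance gives a flat TAC (slope 0):
  # the log-linear fit is flagged unusable and the pipeline must switch
  # to trapezoid integration with the physical-decay tail
  sp <- phantomSpec(gridShape = 24L, voxelSize = 5.08,
    regions = list(phantomRegion("tumor", center = rep(60, 3),
                                 semiAxes = 12, Aref = 1e6, Te = Inf)),
    psfFwhm = 0, noiseModel = "none", seed = 6L)
  st <- generatePhantomStudy(sp)
  fit <- fitEffectiveHalfLife(sampleTac(st$volumes, tumorSeedVoxel()))
  expect_false(fit@usable)
  kernel <- new("EnergyDepositionKernel", voxelSize = 5.08,
                ECenter = 2.37e-14, se = 0,
                neighborEnergy = array(2.37e-14, c(1, 1, 1)),
                nDecays = 1e6, seed = 1L)
  res <- tumorDosimetry(st$volumes, tumorSeedVoxel(),
                        VctMl = st$truth@vctMl[["tumor"]], kernel = kernel)
  expect_equal(res$N@method, "trapezoid_tail")
  expect_true(res$dose@D > 0 && is.finite(res$dose@D))
})
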