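test_that("log-linear fit recovers exact mono-exponential half-lives", {
  tac <- timeActivityCurve(c(1, 4, 24, 72), 100 * 2^(-c(1, 4, 24, 72) / 10))
  fit <- fitEffectiveHalfLife(tac)
  expect_true(fit@usable)
  expect_equal(effectiveHalfLife(fit), 10, tolerance = 1e-10)
  expect_equal(fit@rSquared, 1)

  flat <- fitEffectiveHalfLife(timeActivityCurve(c(1, 4, 24, 72),
                                                 rep(5, 4)))
  expect_false(flat@usable)
  expect_equal(flat@lambdaE, 0, tolerance = 1e-12)

  # non-positive values are excluded with a warning; too few points error
  expect_warning(
    f2 <- fitEffectiveHalfLife(timeActivityCurve(c(1, 4, 24, 72),
                                                 c(10, 5, 0, 1))),
    "excluded")
  expect_equal(f2@nPointsUsed, 3L)
  expect_error(suppressWarnings(fitEffectiveHalfLife(
    timeActivityCurve(c(1, 4), c(0, 0)))), "fewer than 2")
})

test_that("fit recovery under multiplicative lognormal noise (500 draws)", {
  TeTrue <- 30
  tt <- c(1, 4, 24, 72)
  te <- withr::with_seed(101, vapply(seq_len(500), function(i) {
    v <- 1e5 * 2^(-tt / TeTrue) * exp(rnorm(4, sd = 0.1))
    fitEffectiveHalfLife(timeActivityCurve(tt, v))@Te
  }, 0))
  expect_equal(median(te), TeTrue, tolerance = 0.03)
  # 5th-95th percentile of the recovered Te covers the truth
  q <- quantile(te, c(0.05, 0.95))
  expect_lt(q[1], TeTrue); expect_gt(q[2], TeTrue)
})

test_that("back-extrapolation A1 = A4 * exp(lambdaE dt)", {
  mkFit <- function(TeH) new("KineticFit", alpha = 0,
    lambdaE = log(2) / (TeH * 3600), Te = TeH, rSquared = 1,
    usable = TRUE, nPointsUsed = 4L)
  expect_equal(backExtrapolateA1(50e3, mkFit(24), 71), 50e3 * 2^(71 / 24))
  expect_equal(backExtrapolateA1(50e3, mkFit(24), 71) / 1e3, 388.6,
               tolerance = 1e-3)
  expect_equal(backExtrapolateA1(7, mkFit(24), 0), 7)
  zero <- new("KineticFit", alpha = 0, lambdaE = 0, Te = NA_real_,
              rSquared = 1, usable = TRUE, nPointsUsed = 4L)
  expect_equal(backExtrapolateA1(7, zero, 100), 7)
  bad <- mkFit(24); bad@usable <- FALSE
  expect_error(backExtrapolateA1(1, bad, 1), "trapezoid")
})

test_that("closed-form N matches the quadrature oracle to 0.1%", {
  for (TeH in c(10, 24, 30, 80, 160)) {
    lam <- log(2) / (TeH * 3600)
    fit <- new("KineticFit", alpha = 0, lambdaE = lam, Te = TeH,
               rSquared = 1, usable = TRUE, nPointsUsed = 4L)
    A1 <- 1e6
    t1s <- 3600
    n <- integrateDisintegrations(A1, fit, t1h = 1)
    oracle <- A1 * t1s / 2 +
      integrate(function(tp) A1 * exp(-lam * (tp - t1s)), t1s,
                t1s + 60 * TeH * 3600, rel.tol = 1e-10)$value
    expect_equal(n@N, oracle, tolerance = 1e-3)
  }
  # the worked example: A1 = 1e6 Bq, t1 = 1 h, Te = 10 h -> ~5.374e10
  fit10 <- new("KineticFit", alpha = 0, lambdaE = log(2) / 36000, Te = 10,
               rSquared = 1, usable = TRUE, nPointsUsed = 4L)
  expect_equal(integrateDisintegrations(1e6, fit10, 1)@N, 5.374e10,
               tolerance = 1e-3)
  # linearity and the zero case
  expect_equal(integrateDisintegrations(2e6, fit10, 1)@N,
               2 * integrateDisintegrations(1e6, fit10, 1)@N)
  expect_equal(integrateDisintegrations(0, fit10, 1)@N, 0)
  expect_error(integrateDisintegrations(1, fit10, 0), "t1h")
})

test_that("trapezoid + physical tail matches the piecewise oracle", {
  d <- lu177DecayData()
  tac <- timeActivityCurve(c(1, 4, 24, 72), c(1.0, 0.9, 0.8, 0.7) * 1e6)
  n <- integrateDisintegrationsTrapezoid(tac, d)
  lamPhys <- physicalDecayConstant(d)
  oracle <- 1e6 * 3600 / 2 +
    (10800 * 0.95e6 + 72000 * 0.85e6 + 172800 * 0.75e6) +
    0.7e6 / lamPhys
  expect_equal(n@N, oracle)
  expect_equal(n@N, 7.83e11, tolerance = 1e-2)
  expect_equal(n@method, "trapezoid_tail")

  zero <- integrateDisintegrationsTrapezoid(
    timeActivityCurve(c(1, 4, 24, 72), rep(0, 4)), d)
  expect_equal(zero@N, 0)
  # unit invariance: kBq inputs scale N by 1/1000
  kbq <- integrateDisintegrationsTrapezoid(
    timeActivityCurve(c(1, 4, 24, 72), c(1.0, 0.9, 0.8, 0.7) * 1e3), d)
  expect_equal(kbq@N * 1000, n@N)
  expect_error(integrateDisintegrationsTrapezoid(
    timeActivityCurve(1, 5), d), "fewer than 2")
})

test_that("trapezoid agrees with closed form when Te equals the physical
           half-life", {
  d <- lu177DecayData()
  TeH <- d@halfLifeS / 3600
  lam <- log(2) / (TeH * 3600)
  tt <- c(1, 4, 24, 72)
  A1 <- 1e6
  vals <- A1 * exp(-lam * 3600 * (tt - 1))
  fit <- new("KineticFit", alpha = 0, lambdaE = lam, Te = TeH,
             rSquared = 1, usable = TRUE, nPointsUsed = 4L)
  nClosed <- integrateDisintegrations(A1, fit, 1)@N
  nTrap <- integrateDisintegrationsTrapezoid(
    timeActivityCurve(tt, vals), d)@N
  expect_equal(nTrap, nClosed, tolerance = 0.02)
  # convexity: the trapezoid overestimates the exponential
  expect_gt(nTrap, nClosed)
})
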