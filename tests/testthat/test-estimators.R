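test_that("shape factor is the volume of the bounding cylinder filled", {
  expect_equal(shapeFactor(992000, 400, 4000), 0.62)
  expect_equal(shapeFactor(10000, 100, 100), 1)
  expect_error(shapeFactor(0, 100, 100), "positive")
  expect_error(shapeFactor(100, -1, 100), "positive")
  # invariant under uniform scaling of areas and of length
  expect_equal(shapeFactor(5 * 992000, 400, 5 * 4000),
               shapeFactor(992000, 400, 4000))
  expect_equal(shapeFactor(3 * 992000, 3 * 400, 4000),
               shapeFactor(992000, 400, 4000))
})

test_that("measured shape factors recover the geometric constants", {
  expect_equal(measuredShapeFactor(oracleCylinder()), 1, tolerance = 0.02)
  expect_equal(measuredShapeFactor(oracleCone()), 1 / 3, tolerance = 0.03)
  expect_equal(measuredShapeFactor(oracleSpindle()), 2 / 3,
               tolerance = 0.015)
})

test_that("model fitting summarizes per-subject shape factors", {
  ph <- oracleSpindle()
  m <- fitShapeFactorModel(c(ph$mv, ph$mv), list(ph$prof, ph$prof))
  expect_equal(m@pSd, 0)
  expect_equal(m@pAvg, measuredShapeFactor(ph))
  expect_equal(m@avgAcsaMaxLocation, acsaMaxLocation(ph$prof))
  expect_error(fitShapeFactorModel(ph$mv, list(ph$prof)), "at least 2")

  # cohort of cones of different sizes: p_avg near 1/3
  cones <- lapply(c(150, 200, 250), function(L)
    cachedPhantom(paste0("coneL", L),
                  PhantomSpec("cone", L, 700), c(1, 1, 2)))
  m2 <- fitShapeFactorModel(vapply(cones, `[[`, numeric(1), "mv"),
                            lapply(cones, `[[`, "prof"))
  expect_lt(abs(m2@pAvg - 1 / 3), 0.01)
  expect_true(all(shapeFactors(m2) > 0 & shapeFactors(m2) <= 1))
})

test_that("leave-one-out estimation uses only the other subjects", {
  a <- oracleCylinder(); b <- oracleSpindle()
  m <- fitShapeFactorModel(c(a$mv, b$mv), list(a$prof, b$prof),
                           subjects = c("A", "B"), leaveOneOut = TRUE)
  pA <- shapeFactors(m)[["A"]]; pB <- shapeFactors(m)[["B"]]
  # with n = 2, estimating A must apply B's shape factor, and vice versa
  expect_equal(estimateShapeFactor(m, a$prof, ideal = TRUE, subject = "A"),
               pB * muscleLength(a$prof) * acsaMax(a$prof))
  expect_equal(estimateShapeFactor(m, b$prof, ideal = TRUE, subject = "B"),
               pA * muscleLength(b$prof) * acsaMax(b$prof))
  expect_error(estimateShapeFactor(m, a$prof, subject = "Z"), "not part")
  expect_error(estimateShapeFactor(m, a$prof), "subject id")
})

test_that("ideal-variant estimate with the subject's own p inverts the definition", {
  phantoms <- list(oracleCylinder(), oracleCone(), oracleSpindle())
  m <- fitShapeFactorModel(vapply(phantoms, `[[`, numeric(1), "mv"),
                           lapply(phantoms, `[[`, "prof"))
  for (ph in phantoms) {
    own <- shapeFactor(ph$mv, muscleLength(ph$prof), acsaMax(ph$prof))
    expect_equal(
      estimateShapeFactor(m, ph$prof, ideal = TRUE, pOverride = own),
      ph$mv, tolerance = 1e-12)
  }
})

test_that("practice-variant estimate is exact for constant profiles", {
  # for a cylinder the area at any sampling location equals ACSA_max,
  # so the cohort estimate reproduces each reference volume
  cyls <- lapply(c(100, 200, 300), function(L)
    cachedPhantom(paste0("cylL", L), PhantomSpec("cylinder", L, 1200),
                  c(1, 1, 2)))
  m <- fitShapeFactorModel(vapply(cyls, `[[`, numeric(1), "mv"),
                           lapply(cyls, `[[`, "prof"))
  for (ph in cyls)
    expect_equal(estimateShapeFactor(m, ph$prof), ph$mv,
                 tolerance = 0.02)
})

test_that("five-slice positions bracket the average peak location", {
  expect_equal(samplingPositions(truncatedConePositions(0.5)),
               c(1, 0.75, 0.5, 0.255, 0.01))
  expect_equal(samplingPositions(truncatedConePositions(0.61)),
               c(1, 0.805, 0.61, 0.31, 0.01))
  expect_error(truncatedConePositions(0.01), "between")
  expect_error(truncatedConePositions(1), "between")

  s <- truncatedConePositions(0.37)
  d <- interSliceDistances(s, 250)
  expect_true(all(d > 0))
  expect_equal(sum(d), 0.99 * 250)
})

test_that("frustum sums reproduce closed-form volumes on analytic profiles", {
  # constant profile: every frustum degenerates to d * A
  flat <- AcsaProfile(rep(100, 101), 100)
  expect_equal(estimateTruncatedCone(flat, truncatedConePositions(0.5)),
               9900)
  expect_equal(estimateTruncatedCone(flat, truncatedConePositions(0.61)),
               0.99 * 100 * 100)

  # cone: area quadratic in x, frustum quadrature exact over [1%, 100%]
  cone <- analyticProfile(PhantomSpec("cone", 100, 300))
  for (loc in c(0.3, 0.5, 0.61))
    expect_equal(estimateTruncatedCone(cone, truncatedConePositions(loc)),
                 300 * 100 * (1 - 0.01^3) / 3, tolerance = 1e-4)
})

test_that("truncated-cone estimates never exceed the 99% bounding cylinder", {
  specs <- list(oracleCylinder(), oracleCone(), oracleSpindle(),
                cachedPhantom("tcspindle61",
                              PhantomSpec("beta_spindle", 300, 2000,
                                          peakLocation = 0.61,
                                          sharpness = 3)))
  for (ph in specs) {
    loc <- min(max(acsaMaxLocation(ph$prof), 0.02), 0.99)
    est <- estimateTruncatedCone(ph$prof, truncatedConePositions(loc))
    expect_lte(est, 0.99 * muscleLength(ph$prof) * acsaMax(ph$prof) + 1e-9)
  }
  # mass at the ends of a spindle is systematically missed
  sp <- oracleSpindle()
  est <- estimateTruncatedCone(sp$prof, truncatedConePositions(0.5))
  expect_lt(est, sp$mv)
})
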