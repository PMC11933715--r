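test_that("analytic ACSA profiles follow their closed forms", {
  cyl <- PhantomSpec("cylinder", 300, 100)
  expect_equal(analyticAcsa(cyl, c(0, 0.3, 1)), rep(100, 3))

  cone <- PhantomSpec("cone", 100, 300)
  expect_equal(analyticAcsa(cone, c(0, 0.5, 1)), c(0, 75, 300))

  fr <- PhantomSpec("frustum", 100, endRadiiMm = c(5, 10))
  expect_equal(analyticAcsa(fr, 0.5), pi * 7.5^2)

  # symmetric spindle with kappa = 2 is the parabolic kernel 4x(1-x)
  sp <- PhantomSpec("beta_spindle", 300, 100, peakLocation = 0.5,
                    sharpness = 2)
  expect_equal(analyticAcsa(sp, 0.5), 100)
  expect_equal(analyticAcsa(sp, 0.25), 100 * 4 * 0.25 * 0.75)
  expect_equal(analyticAcsa(sp, c(0, 1)), c(0, 0))

  expect_error(analyticAcsa(cyl, 1.2), "\\[0, 1\\]")
  expect_error(analyticAcsa(cyl, -0.1), "\\[0, 1\\]")
})

test_that("spindle profile peaks exactly at the requested location", {
  for (xm in c(0.29, 0.38, 0.48, 0.56, 0.61)) {
    for (kappa in c(2, 3, 5)) {
      sp <- PhantomSpec("beta_spindle", 300, 1000, peakLocation = xm,
                        sharpness = kappa)
      grid <- seq(0, 1, length.out = 10001)
      a <- analyticAcsa(sp, grid)
      expect_lt(abs(grid[which.max(a)] - xm), 1e-4)
      expect_equal(max(a), 1000, tolerance = 1e-8)
      expect_true(all(a >= 0))
    }
  }
})

test_that("closed-form volumes match adaptive quadrature of the profile", {
  specs <- list(
    PhantomSpec("cylinder", 123, 456),
    PhantomSpec("cone", 200, 300),
    PhantomSpec("frustum", 150, endRadiiMm = c(5, 12)),
    PhantomSpec("frustum", 150, endRadiiMm = c(12, 0)),
    PhantomSpec("beta_spindle", 300, 100, peakLocation = 0.5, sharpness = 2),
    PhantomSpec("beta_spindle", 250, 2000, peakLocation = 0.29, sharpness = 3),
    PhantomSpec("beta_spindle", 400, 3000, peakLocation = 0.61, sharpness = 6),
    PhantomSpec("beta_spindle", 100, 500, peakLocation = 0.5, sharpness = 0))
  for (s in specs) {
    quad <- stats::integrate(function(x) analyticAcsa(s, x), 0, 1,
                             rel.tol = 1e-10)$value * s@lengthMm
    expect_equal(analyticVolume(s), quad, tolerance = 1e-8)
  }
  # spot values
  expect_equal(analyticVolume(PhantomSpec("cylinder", 100, 100)), 10000)
  expect_equal(analyticVolume(PhantomSpec("cone", 100, 300)), 10000)
  expect_equal(
    analyticVolume(PhantomSpec("beta_spindle", 100, 100,
                               peakLocation = 0.5, sharpness = 2)),
    2 / 3 * 100 * 100, tolerance = 1e-12)
})

test_that("phantom specs reject invalid geometry", {
  expect_error(PhantomSpec("cylinder", -10, 100))
  expect_error(PhantomSpec("cylinder", 100, 0))
  expect_error(PhantomSpec("beta_spindle", 100, 100, peakLocation = 0))
  expect_error(PhantomSpec("beta_spindle", 100, 100, peakLocation = 1))
  expect_error(PhantomSpec("beta_spindle", 100, 100, sharpness = -1))
  expect_error(PhantomSpec("frustum", 100))
  expect_error(PhantomSpec("frustum", 100, endRadiiMm = c(0, 0)))
})

test_that("voxelization approximates the analytic volume and is deterministic", {
  cyl <- PhantomSpec("cylinder", 20, pi * 100, aspectRatio = 1)  # r = 10 mm
  vol <- voxelize(cyl, c(1, 1, 2))
  expect_equal(referenceVolume(vol, 1L), 2000 * pi, tolerance = 0.03)

  again <- voxelize(cyl, c(1, 1, 2))
  expect_identical(vol@voxels, again@voxels)

  expect_error(voxelize(cyl, c(0.01, 0.01, 0.01), maxVoxels = 1e6),
               "maxVoxels")
})

test_that("voxelized volume error shrinks monotonically under grid refinement", {
  r1 <- sqrt(473 / pi)
  specs <- list(
    cylinder = PhantomSpec("cylinder", 57, 473),
    cone = PhantomSpec("cone", 57, 473),
    frustum = PhantomSpec("frustum", 57, endRadiiMm = c(r1 / 2, r1)),
    spindle = PhantomSpec("beta_spindle", 57, 473, peakLocation = 0.4,
                          sharpness = 3))
  spacings <- list(c(2, 2, 4), c(1, 1, 2), c(0.5, 0.5, 1))
  for (nm in names(specs)) {
    truth <- analyticVolume(specs[[nm]])
    err <- vapply(spacings, function(sp)
      abs(referenceVolume(voxelize(specs[[nm]], sp), 1L) - truth) / truth,
      numeric(1))
    expect_true(all(diff(err) < 0), info = nm)
    expect_lt(err[3], 0.01)
  }
})

test_that("cohort generation is seed-reproducible and honors truncation", {
  cs <- CohortSpec(3, c(120, 10), c(700, 60), c(0.5, 0.05),
                   voxelSpacingMm = c(2, 2, 4), seed = 7)
  tmpl <- PhantomSpec("beta_spindle", 1, 1)
  a <- generateCohort(cs, tmpl)
  b <- generateCohort(cs, tmpl)
  expect_identical(a$truth, b$truth)
  expect_identical(lapply(a$volumes, slot, "voxels"),
                   lapply(b$volumes, slot, "voxels"))
  expect_true(all(a$truth$peak_location >= 0.05 &
                  a$truth$peak_location <= 0.95))

  # degenerate location SD pins every subject to the mean
  cs0 <- CohortSpec(3, c(120, 10), c(700, 60), c(0.37, 0),
                    voxelSpacingMm = c(2, 2, 4), seed = 7)
  z <- generateCohort(cs0, tmpl)
  expect_equal(z$truth$peak_location, rep(0.37, 3))

  expect_error(CohortSpec(3, c(120, -5), c(700, 60), c(0.5, 0.05)),
               "SD")
  # location draws truncated to [0.05, 0.95] hug the generating mean
  csBig <- CohortSpec(39, c(80, 0), c(400, 0), c(0.61, 0.10),
                      voxelSpacingMm = c(2, 2, 4), seed = 11)
  g <- generateCohort(csBig, tmpl)
  se <- 0.10 / sqrt(39)
  expect_lt(abs(mean(g$truth$peak_location) - 0.61), 4 * se)
})

test_that("cohort generation leaves the caller's RNG state untouched", {
  set.seed(99)
  before <- .Random.seed
  cs <- CohortSpec(2, c(60, 5), c(300, 20), c(0.5, 0.05),
                   voxelSpacingMm = c(2, 2, 4), seed = 1)
  generateCohort(cs, PhantomSpec("beta_spindle", 1, 1))
  expect_identical(.Random.seed, before)
})
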