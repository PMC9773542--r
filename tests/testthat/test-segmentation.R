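test_that("segmentation recovers annulus areas within 2% of pi R^2", {
  for (noise in c(0, 5)) {
    a <- simulateAnnulusFrame(100, 50, noiseSd = noise, seed = 1)
    m <- segmentOrganoid(a$frame)
    expect_false(m$failed)
    expect_lt(abs(sum(m$outerMask) - a$outerArea) / a$outerArea, 0.02)
    expect_lt(abs(sum(m$innerMask) - a$innerArea) / a$innerArea, 0.02)
    expect_true(all(m$outerMask[m$innerMask]))  # inner contained in outer
  }
})

test_that("solid disks segment with an empty chamber; blanks are flagged", {
  d <- simulateAnnulusFrame(80, 0, noiseSd = 3, seed = 2)
  m <- segmentOrganoid(d$frame)
  expect_false(m$failed)
  expect_identical(sum(m$innerMask), 0L)
  expect_lt(abs(sum(m$outerMask) - d$outerArea) / d$outerArea, 0.02)
  blank <- segmentOrganoid(matrix(100, 64, 64))
  expect_true(blank$failed)
  expect_match(blank$reason, "no contrast")
})

test_that("inverted-contrast chambers segment with the inversion flag", {
  ## chamber darker than wall (the opposite of the brightfield default)
  a <- simulateAnnulusFrame(80, 40, wallIntensity = 180,
                            chamberIntensity = 90,
                            backgroundIntensity = 30, noiseSd = 0)
  m <- segmentOrganoid(a$frame, invertChamber = TRUE)
  expect_false(m$failed)
  expect_lt(abs(sum(m$outerMask) - a$outerArea) / a$outerArea, 0.02)
  expect_lt(abs(sum(m$innerMask) - a$innerArea) / a$innerArea, 0.02)
})

test_that("equivalent-circle wall thickness has its closed form", {
  expect_equal(wallThicknessFromAreas(pi * 100^2, pi * 50^2), 50)
  expect_equal(wallThicknessFromAreas(pi * 80^2, 0), 80)
  expect_equal(wallThicknessFromAreas(c(pi * 4, pi * 9), c(pi, pi * 4)),
               c(1, 1))
  expect_error(wallThicknessFromAreas(10, 20), "outerArea >= innerArea")
  expect_error(wallThicknessFromAreas(10, -1), "outerArea >= innerArea")
})

test_that("segmentStack produces a full AreaTrace with valid invariants", {
  sim <- simulateOrganoidVideo(smallVideoParams(duration = 5, seed = 4))
  at <- segmentStack(sim$stack)
  s <- as.data.frame(at)
  expect_identical(nrow(s), length(sim$stack))
  expect_false(any(s$interpolated))
  expect_true(all(s$wall_area_px2 == s$outer_area_px2 - s$inner_area_px2))
  expect_true(all(s$wall_fraction >= 0 & s$wall_fraction <= 1))
  expect_true(all(s$wall_thickness_px >= 0))
  ## thickness oscillates between the programmed diastolic and systolic
  ## values (wall thickens at systole when coupling < 1)
  expect_lt(abs(min(s$wall_thickness_px) - sim$truth$wallThicknessDia), 2)
  expect_lt(abs(max(s$wall_thickness_px) - sim$truth$wallThicknessSys), 2)
})

test_that("isolated failed frames are interpolated and flagged", {
  sim <- simulateOrganoidVideo(smallVideoParams(duration = 5, noiseSd = 0,
                                                seed = 5))
  stack <- sim$stack
  stack@frames[[25]] <- matrix(0, 160, 160)  # one blank frame in 50
  at <- segmentStack(stack)
  s <- as.data.frame(at)
  expect_identical(which(s$interpolated), 25L)
  expect_identical(attr(at, "failedFrames"), 25L)
  neigh <- mean(s$outer_area_px2[c(24, 26)])
  expect_equal(s$outer_area_px2[25], neigh, tolerance = 1e-9)
  ## too many failures: quality error with a per-frame report
  blankStack <- FrameStack(rep(list(matrix(7, 32, 32)), 10), 0.1)
  expect_error(segmentStack(blankStack), "segmentation failed on 10/10")
})

test_that("measured areas scale with the square of the spatial scale", {
  a1 <- simulateAnnulusFrame(50, 25, imageSize = 128, noiseSd = 0)
  up <- as.matrix(EBImage::resize(a1$frame, w = 256, h = 256))
  m1 <- segmentOrganoid(a1$frame)
  m2 <- segmentOrganoid(up)
  expect_equal(sum(m2$outerMask) / sum(m1$outerMask), 4, tolerance = 0.02)
  expect_equal(sum(m2$innerMask) / sum(m1$innerMask), 4, tolerance = 0.02)
  t1 <- wallThicknessFromAreas(sum(m1$outerMask), sum(m1$innerMask))
  t2 <- wallThicknessFromAreas(sum(m2$outerMask), sum(m2$innerMask))
  expect_equal(t2 / t1, 2, tolerance = 0.02)
})

test_that("inner-area excursion grows monotonically with programmed pulsation", {
  exc <- vapply(c(0.05, 0.15, 0.3), function(pf) {
    sim <- simulateOrganoidVideo(smallVideoParams(
      duration = 3, pulsationFraction = pf, noiseSd = 0,
      beatIntervalSd = 0, seed = 6))
    s <- as.data.frame(segmentStack(sim$stack))
    max(s$inner_area_px2) - min(s$inner_area_px2)
  }, numeric(1))
  expect_true(all(diff(exc) > 0))
})

test_that("distance-map thickness variant tracks the annulus wall", {
  sim <- simulateOrganoidVideo(smallVideoParams(duration = 1, noiseSd = 0,
                                                pulsationFraction = 0,
                                                seed = 1))
  at <- segmentStack(sim$stack, thicknessMethod = "distmap")
  ## 30 px programmed wall; distance-map estimate within ~10%
  expect_lt(abs(mean(as.data.frame(at)$wall_thickness_px) - 30), 3)
})
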