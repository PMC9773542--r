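test_that("annulus frames obey the analytic area identities", {
  a <- simulateAnnulusFrame(100, 50, noiseSd = 0)
  expect_equal(a$outerArea, pi * 100^2)
  expect_equal(a$innerArea, pi * 50^2)
  expect_equal((a$outerArea - a$innerArea) / a$outerArea, 0.75)
  ## solid disk: inner radius zero
  d <- simulateAnnulusFrame(100, 0, noiseSd = 0)
  expect_equal(d$innerArea, 0)
  ## rendered pixel mass approximates the analytic area directly
  thr <- (120 + 40) / 2
  expect_lt(abs(sum(a$frame > thr) - a$outerArea) / a$outerArea, 0.02)
  ## harmonic boundary perturbation carries its exact area correction
  h <- simulateAnnulusFrame(80, 40, noiseSd = 0, harmonicAmp = 0.1)
  expect_equal(h$outerArea, pi * 80^2 * (1 + 0.1^2 / 2))
})

test_that("annulus geometry preconditions are enforced", {
  expect_error(simulateAnnulusFrame(50, 60), "radii")
  expect_error(simulateAnnulusFrame(200, 50, imageSize = 256), "radii")
  expect_error(simulateAnnulusFrame(100, -1), "radii")
})

test_that("video, trace and matrix generators are bit-reproducible under a seed", {
  p <- smallVideoParams(duration = 2, seed = 42)
  s1 <- simulateOrganoidVideo(p)
  s2 <- simulateOrganoidVideo(p)
  expect_identical(s1$stack@frames, s2$stack@frames)
  expect_identical(s1$truth, s2$truth)
  c1 <- simulateCalciumTrace(calciumSimParams(duration = 3, seed = 9))
  c2 <- simulateCalciumTrace(calciumSimParams(duration = 3, seed = 9))
  expect_identical(c1$trace@fluorescence, c2$trace@fluorescence)
  m1 <- simulateCountMatrix(20, 200, featuresPerCell = 50, seed = 4)
  m2 <- simulateCountMatrix(20, 200, featuresPerCell = 50, seed = 4)
  expect_identical(as.matrix(m1$counts), as.matrix(m2$counts))
  ## a different seed changes the noise realization
  s3 <- simulateOrganoidVideo(smallVideoParams(duration = 2, seed = 43))
  expect_false(identical(s1$stack@frames, s3$stack@frames))
})

test_that("programmed beat schedule matches its closed-form cases", {
  ## zero-variability 1 s rhythm over 30 s: exactly 30 programmed beats
  p <- smallVideoParams(beatIntervalMean = 1.0, beatIntervalSd = 0,
                        duration = 30, noiseSd = 0, seed = 1)
  sim <- simulateOrganoidVideo(p)
  expect_identical(length(sim$truth$beatTimes), 30L)
  expect_true(all(abs(sim$truth$intervals - 1.0) < 1e-12))
  expect_equal(length(sim$stack), 300L)
  ## beat times strictly increasing
  expect_true(all(diff(sim$truth$beatTimes) > 0))
  ## too short for one beat: warning and zero-beat truth
  expect_warning(
    short <- simulateOrganoidVideo(smallVideoParams(duration = 0.3,
                                                    seed = 1)),
    "zero beats")
  expect_length(short$truth$beatTimes, 0)
})

test_that("programmed truth obeys the pipeline's own FS formula exactly", {
  p <- smallVideoParams(duration = 2, pulsationFraction = 0.25,
                        outerCoupling = 0.4, seed = 3)
  tr <- simulateOrganoidVideo(p)$truth
  tDia <- tr$outerRadiusDia - tr$innerRadiusDia
  tSys <- tr$outerRadiusSys - tr$innerRadiusSys
  expect_equal(tr$wallThicknessDia, tDia)
  expect_equal(tr$wallThicknessSys, tSys)
  expect_equal(tr$fractionalShortening, 100 * (tSys - tDia) / tDia)
  ## no pulsation: FS truth is exactly zero and frames are static
  p0 <- smallVideoParams(duration = 2, pulsationFraction = 0, noiseSd = 0,
                         seed = 3)
  sim0 <- simulateOrganoidVideo(p0)
  expect_equal(sim0$truth$fractionalShortening, 0)
  expect_true(all(vapply(sim0$stack@frames, identical,
                         logical(1), sim0$stack@frames[[1]])))
})

test_that("transient truth reduces to the closed form for a pure exponential decay", {
  tt <- transientTruth(0, 0.5)
  expect_equal(tt$repol30, 0.5 * log(1 / 0.7), tolerance = 1e-9)
  expect_equal(tt$repol60, 0.5 * log(1 / 0.4), tolerance = 1e-9)
  expect_equal(tt$repol90, 0.5 * log(10), tolerance = 1e-9)
  for (tau in c(0.1, 0.25, 1, 2)) {
    tt <- transientTruth(0, tau)
    expect_equal(tt$repol90, tau * log(10), tolerance = 1e-9)
  }
  ## with a finite upstroke the ordering still holds
  tt2 <- transientTruth(0.06, 0.18)
  expect_lt(tt2$repol30, tt2$repol60)
  expect_lt(tt2$repol60, tt2$repol90)
  expect_equal(tt2$ctd, tt2$end - tt2$onset)
})

test_that("calcium generator: flat at zero amplitude, floor count for a fixed train", {
  flat <- simulateCalciumTrace(calciumSimParams(amplitude = 0, noiseSd = 0,
                                                driftSlope = 0, seed = 1))
  expect_true(all(flat$trace@fluorescence == 100))
  expect_length(flat$truth$onsetTimes, 0)
  expect_identical(nrow(detectTransients(flat$trace,
                                         baseline = rep(100, length(flat$trace@time)))),
                   0L)
  ## 0.8 s train over 30 s: floor(30 / 0.8) = 37 programmed transients
  train <- simulateCalciumTrace(calciumSimParams(beatIntervalMean = 0.8,
                                                 beatIntervalSd = 0,
                                                 noiseSd = 0, seed = 1))
  expect_identical(length(train$truth$onsetTimes), 37L)
  expect_true(all(abs(diff(train$truth$onsetTimes) - 0.8) < 1e-9))
})

test_that("count-matrix generator programs feature counts exactly", {
  sim <- simulateCountMatrix(50, 1000, featuresPerCell = c(rep(30L, 40),
                                                           rep(200L, 10)),
                             mitoFraction = c(rep(0, 25), rep(0.05, 25)),
                             seed = 7)
  nf <- Matrix::colSums(sim$counts > 0)
  expect_equal(unname(nf), as.double(sim$truth$n_features))
  expect_equal(unname(nf[1:40]), rep(30, 40))
  ## zero-mito cells have no mitochondrial counts at all
  mito <- grepl("^MT-", rownames(sim$counts))
  expect_true(all(Matrix::colSums(sim$counts[mito, 1:25]) == 0))
  ## programmed mito fractions achieved to within rounding
  expect_true(all(abs(sim$truth$mito_fraction[26:50] - 0.05) < 0.01))
})

test_that("cohort generator applies effects and matches noise by seed offset", {
  base <- smallVideoParams(duration = 3, noiseSd = 0)
  ## identical seeds in both groups + null effects: identical recordings
  spec <- cohortSpec(groups = list(a = list(seed = 1), b = list(seed = 1)),
                     weeks = 0L, nPerGroup = 1, base = base, seed = 5)
  coh <- simulateCohort(spec)
  expect_identical(coh$recordings[[1]]$stack@frames,
                   coh$recordings[[2]]$stack@frames)
  ## distinct seeds: distinct realizations
  spec2 <- cohortSpec(groups = list(a = NULL, b = NULL), weeks = 0L,
                      nPerGroup = 1, base = base, seed = 5,
                      organoidJitter = 0.05)
  coh2 <- simulateCohort(spec2)
  expect_false(identical(coh2$recordings[[1]]$stack@frames,
                         coh2$recordings[[2]]$stack@frames))
  ## thickness and rate multipliers land in the programmed truth
  spec3 <- cohortSpec(groups = list(ctrl = NULL,
                                    tx = list(thickness = c(1, 1.35),
                                              rate = c(1, 2))),
                      weeks = c(0L, 3L), nPerGroup = 1, base = base,
                      organoidJitter = 0, seed = 5)
  man <- simulateCohort(spec3)$manifest
  tx3 <- man[man$group == "tx" & man$week == 3, ]
  tx0 <- man[man$group == "tx" & man$week == 0, ]
  expect_equal(tx3$true_thickness_dia_px / tx0$true_thickness_dia_px, 1.35)
  expect_equal(tx3$true_interval_mean_s, tx0$true_interval_mean_s / 2)
  expect_error(cohortSpec(groups = list()), "non-empty")
})

test_that("truncated-normal interval sampler respects its floor and moments", {
  set.seed(1)
  iv <- sampleBeatIntervals(5000, 1.0, 0.1)
  expect_true(all(iv >= 0.2))
  expect_equal(mean(iv), 1.0, tolerance = 0.01)
  expect_equal(sd(iv), 0.1, tolerance = 0.05)
  expect_identical(sampleBeatIntervals(3, 0.8, 0), rep(0.8, 3))
})
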