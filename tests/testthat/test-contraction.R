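test_that("a sin^2 area waveform yields its closed-form systoles", {
  t <- seq(0, 29.9, by = 0.1)
  tr <- data.frame(time_s = t, area = 1000 - 100 * sin(pi * t)^2)
  beats <- detectBeats(tr)
  expect_identical(length(beats), 30L)
  ## minima of the waveform sit at 0.5 + k, intervals exactly 1 s
  expect_equal(systoleTimes(beats), 0.5 + 0:29, tolerance = 1e-6)
  expect_equal(beatIntervals(beats), rep(1, 29), tolerance = 1e-6)
  ## without sub-frame refinement times land on the sampling grid
  coarse <- detectBeats(tr, refine = FALSE)
  expect_true(all(abs(systoleTimes(coarse) - (0.5 + 0:29)) <= 0.1 + 1e-9))
  ## diastoles precede their systoles
  expect_true(all(diastoleTimes(beats) < systoleTimes(beats)))
})

test_that("degenerate traces are handled: constant, too short, non-uniform", {
  t <- seq(0, 5, by = 0.1)
  expect_length(detectBeats(data.frame(time_s = t, v = rep(7, length(t)))), 0)
  expect_error(detectBeats(data.frame(time_s = c(0, 0.1), v = c(1, 2))),
               "at least 3")
  expect_error(detectBeats(data.frame(time_s = c(0, 0.1, 0.3),
                                      v = c(1, 2, 1))), "uniform")
})

test_that("interval statistics match hand-computed values", {
  b <- BeatSeries(c(0, 1, 2, 3), c(-0.5, 0.5, 1.5, 2.5))
  s <- beatStatistics(b)
  expect_equal(s$interval_mean_s, 1)
  expect_equal(s$interval_sd_s, 0)
  expect_equal(s$frequency_bpm, 60)
  b2 <- BeatSeries(c(0, 0.8, 1.8, 3.0), c(-0.5, 0.4, 1.3, 2.4))
  s2 <- beatStatistics(b2)
  expect_equal(s2$interval_mean_s, 1)       # mean of {0.8, 1.0, 1.2}
  expect_equal(s2$interval_sd_s, 0.2)       # sample SD, n-1 denominator
  ## fewer than two systoles: explicit NA, never zero
  s3 <- beatStatistics(BeatSeries(1, 0.5))
  expect_true(is.na(s3$interval_mean_s) && is.na(s3$frequency_bpm))
})

test_that("detected beats match the programmed truth on a synthetic video", {
  sim <- simulateOrganoidVideo(smallVideoParams(duration = 20, seed = 7))
  at <- segmentStack(sim$stack)
  beats <- detectBeats(at)
  expect_identical(length(beats), length(sim$truth$beatTimes))
  expect_true(all(abs(systoleTimes(beats) - sim$truth$beatTimes) <= 0.1))
  ## detector vs brute-force oracle: per programmed cycle, the global
  ## area minimum within that cycle must coincide with the detected
  ## systole to one frame
  coarse <- detectBeats(at, refine = FALSE)
  s <- as.data.frame(at)
  oracle <- vapply(sim$truth$beatTimes, function(bt) {
    win <- which(abs(s$time_s - bt) <= 0.3)
    s$time_s[win[which.min(s$outer_area_px2[win])]]
  }, numeric(1))
  expect_true(all(abs(systoleTimes(coarse) - oracle) <= 0.1 + 1e-9))
})

test_that("beat metrics are invariant to uniform intensity rescaling", {
  sim <- simulateOrganoidVideo(smallVideoParams(duration = 8, seed = 8))
  at1 <- segmentStack(sim$stack)
  dimmed <- FrameStack(lapply(sim$stack@frames, function(f) round(f / 2)),
                       frameInterval(sim$stack))
  at2 <- segmentStack(dimmed)
  b1 <- detectBeats(at1); b2 <- detectBeats(at2)
  expect_identical(length(b1), length(b2))
  expect_equal(beatStatistics(b1)$interval_mean_s,
               beatStatistics(b2)$interval_mean_s, tolerance = 0.01)
})

test_that("fractional shortening has its closed form on paired thickness", {
  n <- 11
  samples <- data.frame(
    time_s = (0:(n - 1)) * 0.1,
    outer_area_px2 = rep(1e4, n), inner_area_px2 = rep(100, n),
    wall_area_px2 = rep(9900, n), wall_fraction = rep(0.99, n),
    wall_thickness_px = c(50, 50, 50, 55, 60, 65, 60, 55, 50, 50, 50),
    interpolated = FALSE)
  at <- CCOmetrics:::AreaTrace(samples, 0.1)
  beats <- BeatSeries(0.5, 0.1)
  beats@meta <- list(systoleIdx = 6L, diastoleIdx = 2L)
  fs <- fractionalShortening(at, beats)
  expect_equal(fs$meanFS, 100 * (65 - 50) / 50)  # 30%
  expect_false(any(fs$perBeat$excluded))
})

test_that("measured FS tracks the programmed truth and is scale invariant", {
  base <- smallVideoParams(duration = 8, noiseSd = 0, seed = 9)
  sim <- simulateOrganoidVideo(base)
  at <- segmentStack(sim$stack)
  fs <- fractionalShortening(at, detectBeats(at))
  expect_lt(abs(fs$meanFS - sim$truth$fractionalShortening), 3)
  ## same organoid rendered 1.5x larger: FS within 1 percentage point
  big <- organoidSimParams(imageSize = 240, outerRadius = 90,
                           innerRadius = 45, duration = 8, noiseSd = 0,
                           seed = 9)
  simB <- simulateOrganoidVideo(big)
  atB <- segmentStack(simB$stack)
  fsB <- fractionalShortening(atB, detectBeats(atB))
  expect_lt(abs(fsB$meanFS - fs$meanFS), 1)
})

test_that("a non-pulsating organoid yields no beats and undefined FS", {
  sim <- simulateOrganoidVideo(smallVideoParams(duration = 4,
                                                pulsationFraction = 0,
                                                noiseSd = 0, seed = 10))
  at <- segmentStack(sim$stack)
  beats <- detectBeats(at)
  expect_length(beats, 0)
  fs <- fractionalShortening(at, beats)
  expect_true(is.na(fs$meanFS))
  expect_identical(nrow(fs$perBeat), 0L)
})

test_that("week-0 normalization gives unit folds and excludes orphans", {
  m <- data.frame(organoid = rep(c("a", "b"), each = 2),
                  week = c(0, 3, 0, 3),
                  thickness_dia_px = c(30, 39, 28, 28))
  out <- weeklyNormalize(m)
  expect_equal(out$thickness_fold[out$week == 0], c(1, 1))
  expect_equal(out$thickness_fold[out$organoid == "a" & out$week == 3], 1.3)
  m2 <- rbind(m, data.frame(organoid = "c", week = 3,
                            thickness_dia_px = 35))
  expect_warning(out2 <- weeklyNormalize(m2), "week-0")
  expect_false("c" %in% out2$organoid)
})
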