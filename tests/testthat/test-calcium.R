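test_that("baseline estimation: flat traces, drift tracking, window fallback", {
  flat <- CalciumTrace(0.05, rep(100, 200))
  expect_true(all(estimateBaseline(flat) == 100))
  ## linear drift under sparse transients: slope recovered within 10%
  sim <- simulateCalciumTrace(calciumSimParams(driftSlope = 2,
                                               beatIntervalMean = 2,
                                               beatIntervalSd = 0,
                                               noiseSd = 0, seed = 1))
  bl <- estimateBaseline(sim$trace)
  mid <- sim$trace@time > 3 & sim$trace@time < 27  # away from clipped edges
  fit <- stats::lm(bl[mid] ~ sim$trace@time[mid])
  expect_lt(abs(coef(fit)[2] - 2) / 2, 0.10)
  ## window longer than the trace: global percentile with a warning
  short <- CalciumTrace(0.05, c(rep(10, 30), rep(20, 10)))
  expect_warning(b <- estimateBaseline(short, windowS = 10), "global")
  expect_true(all(b == b[1]))
})

test_that("transient detection counts programmed trains and merges close peaks", {
  train <- simulateCalciumTrace(calciumSimParams(beatIntervalMean = 0.8,
                                                 beatIntervalSd = 0,
                                                 noiseSd = 0, seed = 1))
  pk <- detectTransients(train$trace)
  expect_lte(abs(nrow(pk) - length(train$truth$onsetTimes)), 1)
  ## two pulses 0.05 s apart with a 0.2 s spacing rule merge to one event
  t <- seq(0, 3, by = 0.01)
  pulse <- function(t0) ifelse(t >= t0, 50 * exp(-(t - t0) / 0.15), 0)
  y <- pulse(1.0) + pulse(1.05)
  two <- CalciumTrace(t, y)
  pk2 <- detectTransients(two, baseline = rep(0, length(t)),
                          minIntervalS = 0.2)
  expect_identical(nrow(pk2), 1L)
  ## flat trace: no transients, and that is not an error
  expect_identical(nrow(detectTransients(CalciumTrace(0.01, rep(5, 300)),
                                         baseline = rep(5, 300))), 0L)
})

test_that("exponential-decay repolarization matches tau*log(1/(1-x)) to one frame", {
  dt <- 0.01
  for (tau in c(0.1, 0.5, 1, 2)) {
    tr <- expDecayTrace(100, tau, t0 = 1, dt = dt)
    n <- length(tr@time)
    ev <- transientEvents(transientMetrics(tr, baseline = rep(0, n),
                                           peaks = which(tr@time == 1),
                                           smoothWindow = 1))
    expect_equal(nrow(ev), 1L)
    expect_lte(abs(ev$repol30_s - tau * log(1 / 0.7)), dt)
    expect_lte(abs(ev$repol60_s - tau * log(1 / 0.4)), dt)
    expect_lte(abs(ev$repol90_s - tau * log(10)), dt)
  }
})

test_that("triangular transients give exact linear-geometry metrics", {
  tr <- triangleTrace(amplitude = 50, base = 1.0, t0 = 1.0, dt = 0.05)
  n <- length(tr@time)
  ev <- transientEvents(transientMetrics(tr, baseline = rep(0, n),
                                         peaks = which.max(tr@fluorescence),
                                         onsetFrac = 0, endFrac = 0,
                                         smoothWindow = 1))
  expect_equal(ev$amplitude_au, 50)
  expect_equal(ev$depol_s, 0.5, tolerance = 1e-9)
  expect_equal(ev$ctd_s, 1.0, tolerance = 1e-9)
  expect_equal(ev$repol60_s, 0.3, tolerance = 1e-9)
  expect_equal(ev$depol_speed_au_per_s, 100, tolerance = 1e-9)
})

test_that("repolarization ordering holds on every event of a noisy fixture", {
  for (seed in 1:3) {
    sim <- simulateCalciumTrace(calciumSimParams(noiseSd = 5, seed = seed))
    ev <- transientEvents(calciumKinetics(sim$trace)$events)
    ok <- !is.na(ev$repol30_s) & !is.na(ev$repol60_s) & !is.na(ev$repol90_s)
    expect_gt(sum(ok), 0)
    expect_true(all(ev$repol30_s[ok] <= ev$repol60_s[ok] + 1e-12))
    expect_true(all(ev$repol60_s[ok] <= ev$repol90_s[ok] + 1e-12))
    expect_true(all(ev$onset_s < ev$peak_s, na.rm = TRUE))
    expect_true(all(ev$peak_s < ev$end_s, na.rm = TRUE))
  }
})

test_that("duration metrics are invariant under amplitude rescaling", {
  sim <- simulateCalciumTrace(calciumSimParams(noiseSd = 0,
                                               beatIntervalSd = 0, seed = 4))
  s1 <- calciumKinetics(sim$trace)$summary
  scaled <- CalciumTrace(sim$trace@time, sim$trace@fluorescence * 3)
  s3 <- calciumKinetics(scaled)$summary
  for (col in c("ctd_M_s", "depol_M_s", "repol30_M_s", "repol60_M_s",
                "repol90_M_s", "b2b_M_s"))
    expect_equal(s3[[col]], s1[[col]], tolerance = 1e-9)
  expect_equal(s3$amplitude_M_au, 3 * s1$amplitude_M_au, tolerance = 1e-9)
  expect_equal(s3$depol_speed_M_au_per_s, 3 * s1$depol_speed_M_au_per_s,
               tolerance = 1e-9)
})

test_that("noisy recordings recover the noiseless kinetic truth within 10%", {
  truth <- simulateCalciumTrace(calciumSimParams(noiseSd = 0,
                                                 beatIntervalSd = 0,
                                                 seed = 1))$truth
  for (seed in 1:3) {
    sim <- simulateCalciumTrace(calciumSimParams(noiseSd = 5, seed = seed))
    s <- calciumKinetics(sim$trace)$summary
    expect_lt(abs(s$ctd_M_s - truth$ctd) / truth$ctd, 0.10)
    expect_lt(abs(s$depol_M_s - truth$depol) / truth$depol, 0.10)
    expect_lt(abs(s$repol30_M_s - truth$repol30) / truth$repol30, 0.10)
    expect_lt(abs(s$repol60_M_s - truth$repol60) / truth$repol60, 0.10)
    expect_lt(abs(s$repol90_M_s - truth$repol90) / truth$repol90, 0.10)
    expect_lt(abs(s$amplitude_M_au - 100) / 100, 0.10)
    ## programmed interval mean recovered within 2% at this SNR
    expect_lt(abs(s$b2b_M_s - 1.0), 0.02)
  }
})

test_that("a decay truncated by the trace end leaves repol values missing", {
  dt <- 0.01
  t <- seq(0, 1.25, by = dt)  # peak at 1.0, only 0.25 s of decay sampled
  y <- ifelse(t >= 1, 100 * exp(-(t - 1) / 0.5), 0)
  tr <- CalciumTrace(t, y)
  ev <- transientEvents(transientMetrics(tr, baseline = rep(0, length(t)),
                                         peaks = which(t == 1),
                                         smoothWindow = 1))
  expect_false(is.na(ev$repol30_s))       # 0.18 s: reached
  expect_true(is.na(ev$repol90_s))        # 1.15 s: truncated
  expect_true(is.na(ev$ctd_s))
})

test_that("summaries average per-event metrics and flag empty sets", {
  sim <- simulateCalciumTrace(calciumSimParams(noiseSd = 0,
                                               beatIntervalSd = 0, seed = 2))
  res <- calciumKinetics(sim$trace)
  ev <- transientEvents(res$events)
  one <- summarizeTransients(TransientSet(ev[1, , drop = FALSE]),
                             windowS = NULL)
  expect_equal(one$ctd_M_s, ev$ctd_s[1])
  expect_equal(one$amplitude_M_au, ev$amplitude_au[1])
  two <- ev[1:2, ]; two$ctd_s <- c(0.4, 0.6)
  expect_equal(summarizeTransients(TransientSet(two),
                                   windowS = NULL)$ctd_M_s, 0.5)
  none <- summarizeTransients(TransientSet(ev[0, , drop = FALSE]))
  expect_identical(none$n_transients, 0L)
  expect_true(is.na(none$ctd_M_s))
  ## the 30 s summary window restricts events
  expect_true(all(transientEvents(res$events)$peak_s <=
                    max(sim$trace@time)))
})
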