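## Synthetic beating-organoid generator.
##
## Geometry is a concentric annulus: a bright chamber core inside a darker
## wall on a dark background, matching the brightfield appearance of a
## chambered organoid (hollow core of a lighter shade). The circular
## geometry is deliberate: every area has a closed form (pi R^2), so the
## generator doubles as an analytic oracle for the segmentation and
## kinetics stages. An optional low-order harmonic boundary perturbation is
## available for robustness experiments only.

.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## derive a reproducible 32-bit sub-seed from a base seed and indices
.subSeed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483647
  for (k in idx) s <- (s * 69069 + as.double(k) * 10007 + 1) %% 2147483647
  as.integer(s)
}

#' Parameters for the synthetic beating-organoid video generator
#'
#' Defaults describe a plausible mid-size chambered organoid recorded at
#' 10 frames per second for 30 s: a 100 px outer radius, a 50 px chamber,
#' beating at roughly 75 bpm (0.8 s mean interval) with a 10% rhythm
#' variability, contracting the chamber by 20% at peak systole with half of
#' that excursion transmitted to the outer boundary.
#'
#' @param imageSize square frame size in pixels.
#' @param center length-2 pixel coordinates of the organoid center
#'   (row, col); default frame center.
#' @param outerRadius diastolic outer equivalent radius, px.
#' @param innerRadius diastolic inner-chamber radius, px (< outerRadius).
#' @param pulsationFraction fractional reduction of the inner radius at
#'   peak systole, in [0, 1).
#' @param outerCoupling fraction of the inner-radius excursion transmitted
#'   to the outer radius, in [0, 1]. Values < 1 make the wall thicken at
#'   systole.
#' @param beatIntervalMean,beatIntervalSd mean and SD of the programmed
#'   beat-to-beat interval, seconds. Intervals are drawn from a normal
#'   truncated below at `0.2 * beatIntervalMean` so beats never overlap.
#' @param contractionRiseFraction fraction of each cycle spent contracting
#'   (the fall into systole); the remainder is the recovery, in (0, 1).
#' @param duration recording length, seconds.
#' @param frameInterval seconds per frame.
#' @param wallIntensity,chamberIntensity,backgroundIntensity grayscale
#'   levels (0-255); the chamber must be brighter than the wall, the wall
#'   brighter than the background.
#' @param noiseSd Gaussian pixel noise SD in grayscale units.
#' @param boundaryHarmonicAmp,boundaryHarmonicOrder optional boundary
#'   perturbation: radii become \eqn{R(1 + a\cos(m\theta))}. Default off.
#' @param seed integer seed for interval draws and pixel noise.
#' @return A validated list of class `OrganoidSimParams`.
#' @examples
#' p <- organoidSimParams(duration = 5, noiseSd = 0)
#' @export
organoidSimParams <- function(imageSize = 256L,
                              center = NULL,
                              outerRadius = 100,
                              innerRadius = 50,
                              pulsationFraction = 0.2,
                              outerCoupling = 0.5,
                              beatIntervalMean = 0.8,
                              beatIntervalSd = 0.08,
                              contractionRiseFraction = 0.3,
                              duration = 30,
                              frameInterval = 0.1,
                              wallIntensity = 120,
                              chamberIntensity = 200,
                              backgroundIntensity = 40,
                              noiseSd = 5,
                              boundaryHarmonicAmp = 0,
                              boundaryHarmonicOrder = 3L,
                              seed = 1L) {
  if (is.null(center)) center <- c((imageSize + 1) / 2, (imageSize + 1) / 2)
  p <- list(imageSize = as.integer(imageSize), center = center,
            outerRadius = outerRadius, innerRadius = innerRadius,
            pulsationFraction = pulsationFraction,
            outerCoupling = outerCoupling,
            beatIntervalMean = beatIntervalMean,
            beatIntervalSd = beatIntervalSd,
            contractionRiseFraction = contractionRiseFraction,
            duration = duration, frameInterval = frameInterval,
            wallIntensity = wallIntensity,
            chamberIntensity = chamberIntensity,
            backgroundIntensity = backgroundIntensity,
            noiseSd = noiseSd,
            boundaryHarmonicAmp = boundaryHarmonicAmp,
            boundaryHarmonicOrder = as.integer(boundaryHarmonicOrder),
            seed = as.integer(seed))
  stopifnot(
    "innerRadius must be positive" = p$innerRadius > 0,
    "innerRadius must be smaller than outerRadius" =
      p$innerRadius < p$outerRadius,
    "organoid must fit inside the frame" =
      p$outerRadius < p$imageSize / 2,
    "pulsationFraction must be in [0, 1)" =
      p$pulsationFraction >= 0 && p$pulsationFraction < 1,
    "outerCoupling must be in [0, 1]" =
      p$outerCoupling >= 0 && p$outerCoupling <= 1,
    "contractionRiseFraction must be in (0, 1)" =
      p$contractionRiseFraction > 0 && p$contractionRiseFraction < 1,
    "frameInterval must be positive" = p$frameInterval > 0,
    "duration must cover at least one frame" =
      p$duration >= p$frameInterval,
    "beatIntervalMean must be positive" = p$beatIntervalMean > 0,
    "beatIntervalSd must be non-negative" = p$beatIntervalSd >= 0,
    "intensities must satisfy chamber > wall > background" =
      p$chamberIntensity > p$wallIntensity &&
      p$wallIntensity > p$backgroundIntensity,
    "noiseSd must be non-negative" = p$noiseSd >= 0
  )
  class(p) <- "OrganoidSimParams"
  p
}

#' Parameters for the synthetic GCaMP calcium-trace generator
#'
#' Each transient is the classic double-exponential pulse
#' \eqn{(1 - e^{-t/\tau_{up}}) e^{-t/\tau_{down}}}, rescaled so its peak
#' equals `amplitude`, superposed on a baseline with optional linear drift
#' and Gaussian noise. Defaults emulate GCaMP6s kinetics in a spontaneously
#' beating organoid: ~0.06 s upstroke, ~0.18 s decay, 1 s beat interval,
#' recorded at 100 Hz for 30 s.
#'
#' @param baseline resting fluorescence, a.u.
#' @param amplitude peak transient height above baseline, a.u.
#' @param tauUp upstroke time constant, s. `tauUp = 0` gives an
#'   instantaneous upstroke (pure exponential decay).
#' @param tauDown decay time constant, s (must exceed tauUp).
#' @param beatIntervalMean,beatIntervalSd programmed transient-interval
#'   mean/SD, s (normal truncated below at 0.2 x mean).
#' @param duration recording length, s.
#' @param frameInterval sampling interval, s.
#' @param driftSlope linear baseline drift, a.u. per second.
#' @param noiseSd Gaussian noise SD, a.u.
#' @param seed integer seed.
#' @return A validated list of class `CalciumSimParams`.
#' @export
calciumSimParams <- function(baseline = 100,
                             amplitude = 100,
                             tauUp = 0.06,
                             tauDown = 0.18,
                             beatIntervalMean = 1.0,
                             beatIntervalSd = 0.05,
                             duration = 30,
                             frameInterval = 0.01,
                             driftSlope = 0,
                             noiseSd = 2,
                             seed = 1L) {
  p <- list(baseline = baseline, amplitude = amplitude, tauUp = tauUp,
            tauDown = tauDown, beatIntervalMean = beatIntervalMean,
            beatIntervalSd = beatIntervalSd, duration = duration,
            frameInterval = frameInterval, driftSlope = driftSlope,
            noiseSd = noiseSd, seed = as.integer(seed))
  stopifnot(
    "amplitude must be non-negative" = p$amplitude >= 0,
    "tauUp must be non-negative" = p$tauUp >= 0,
    "tauUp must be smaller than tauDown" = p$tauUp < p$tauDown,
    "frameInterval must be positive" = p$frameInterval > 0,
    "duration must cover at least one sample" =
      p$duration >= p$frameInterval,
    "beatIntervalMean must be positive" = p$beatIntervalMean > 0,
    "beatIntervalSd must be non-negative" = p$beatIntervalSd >= 0,
    "noiseSd must be non-negative" = p$noiseSd >= 0
  )
  class(p) <- "CalciumSimParams"
  p
}

#' Render one annulus frame with analytic areas
#'
#' Pixels strictly inside `innerRadius` take the chamber intensity, pixels
#' between the radii the wall intensity, pixels outside the background
#' intensity, with a 1 px linear edge ramp (sub-pixel coverage) so measured
#' areas converge on the analytic \eqn{\pi R^2}. Frames are quantized to
#' integer gray levels in [0, 255], as a camera would deliver.
#'
#' @param outerRadius,innerRadius annulus radii in px,
#'   `0 <= innerRadius < outerRadius < imageSize/2`.
#' @param imageSize square frame size, px.
#' @param center length-2 (row, col) center; default frame center.
#' @param wallIntensity,chamberIntensity,backgroundIntensity gray levels.
#' @param noiseSd Gaussian pixel noise SD (gray levels); 0 disables noise.
#' @param harmonicAmp,harmonicOrder optional boundary perturbation
#'   \eqn{R(\theta) = R(1 + a\cos(m\theta))}; analytic areas then include
#'   the exact \eqn{(1 + a^2/2)} correction.
#' @param seed optional integer seed for the noise.
#' @return list with `frame` (integer-valued matrix), `outerArea` and
#'   `innerArea` (analytic areas, px^2).
#' @examples
#' a <- simulateAnnulusFrame(100, 50, noiseSd = 0)
#' a$outerArea / (pi * 100^2)  # exactly 1
#' @export
simulateAnnulusFrame <- function(outerRadius, innerRadius,
                                 imageSize = 256L, center = NULL,
                                 wallIntensity = 120,
                                 chamberIntensity = 200,
                                 backgroundIntensity = 40,
                                 noiseSd = 0,
                                 harmonicAmp = 0, harmonicOrder = 3L,
                                 seed = NULL) {
  if (innerRadius < 0 || innerRadius >= outerRadius ||
      outerRadius >= imageSize / 2)
    stop("radii must satisfy 0 <= innerRadius < outerRadius < imageSize/2")
  if (is.null(center)) center <- c((imageSize + 1) / 2, (imageSize + 1) / 2)
  n <- as.integer(imageSize)
  rr <- matrix(seq_len(n) - center[1L], n, n)
  cc <- matrix(seq_len(n) - center[2L], n, n, byrow = TRUE)
  d <- sqrt(rr * rr + cc * cc)
  if (harmonicAmp != 0) {
    theta <- atan2(cc, rr)
    mod <- 1 + harmonicAmp * cos(harmonicOrder * theta)
    rOut <- outerRadius * mod
    rIn <- innerRadius * mod
  } else {
    rOut <- outerRadius
    rIn <- innerRadius
  }
  covOut <- pmin(pmax(rOut - d + 0.5, 0), 1)   # 1 px anti-aliasing ramp
  covIn <- if (innerRadius > 0) pmin(pmax(rIn - d + 0.5, 0), 1) else 0
  img <- backgroundIntensity +
    (wallIntensity - backgroundIntensity) * covOut +
    (chamberIntensity - wallIntensity) * covIn
  if (noiseSd > 0)
    img <- img + .withSeed(seed, matrix(stats::rnorm(n * n, 0, noiseSd), n, n))
  img <- matrix(pmin(pmax(round(img), 0), 255), n, n)
  corr <- 1 + harmonicAmp^2 / 2
  list(frame = img,
       outerArea = pi * outerRadius^2 * corr,
       innerArea = pi * innerRadius^2 * corr)
}

## truncated-normal beat intervals; floor at 0.2 * mean prevents
## non-physical overlap of consecutive contractions
#' Draw beat-to-beat intervals from the generator's interval model
#'
#' Intervals are normal with the given mean and SD, truncated below at
#' `0.2 * mean` (rejection sampling). This is the interval model used by
#' both the video and calcium generators; it is exported so null-cohort
#' simulations can draw per-organoid rhythm metrics without rendering.
#'
#' @param n number of intervals.
#' @param mean,sd interval mean and SD in seconds.
#' @return numeric vector of n positive intervals.
#' @export
sampleBeatIntervals <- function(n, mean, sd) {
  if (n <= 0) return(numeric())
  if (sd == 0) return(rep(mean, n))
  lo <- 0.2 * mean
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n, mean, sd)
    out <- c(out, x[x >= lo])
  }
  out[seq_len(n)]
}

## programmed systole times covering `duration`; recording starts at the
## onset of the first contraction. A trailing beat is only kept in the
## truth when enough of its recovery is sampled to localize the minimum.
.beatSchedule <- function(meanI, sdI, riseFrac, duration, frameInterval) {
  tMax <- duration - frameInterval
  margin <- function(i) frameInterval + 0.35 * (1 - riseFrac) * i
  times <- numeric(0)
  iv <- numeric(0)
  t <- 0
  first <- TRUE
  repeat {
    i <- sampleBeatIntervals(1L, meanI, sdI)
    tNext <- if (first) riseFrac * i else t + i
    if (tNext > tMax - margin(i)) break
    times <- c(times, tNext)
    iv <- c(iv, i)
    t <- tNext
    first <- FALSE
  }
  list(systoleTimes = times, intervals = iv)
}

## asymmetric contraction waveform: w(t) in [0, 1], 1 at systole.
## Between systoles: cosine recovery over (1 - riseFrac) of the gap, then
## cosine fall over riseFrac of the gap. Before the first systole: the
## fall only; after the last: recovery over (1 - riseFrac) * meanI.
.contractionWave <- function(t, systoles, riseFrac, meanI) {
  w <- numeric(length(t))
  if (!length(systoles)) return(w)
  ns <- length(systoles)
  ## segment before first systole: fall from rest starting at
  ## s1 - riseFrac * gap1 (== 0 by construction of .beatSchedule)
  fall0 <- systoles[1L] # duration of first fall == riseFrac * i1
  sel <- t <= systoles[1L]
  u <- pmin(pmax((t[sel] - (systoles[1L] - fall0)) / fall0, 0), 1)
  w[sel] <- (1 - cos(pi * u)) / 2
  if (ns >= 2L) {
    for (k in seq_len(ns - 1L)) {
      a <- systoles[k]; b <- systoles[k + 1L]
      gap <- b - a
      rec <- (1 - riseFrac) * gap
      sel <- t > a & t <= b
      tt <- t[sel] - a
      wk <- ifelse(tt <= rec,
                   (1 + cos(pi * tt / rec)) / 2,
                   (1 - cos(pi * (tt - rec) / (gap - rec))) / 2)
      w[sel] <- wk
    }
  }
  ## after last systole: recovery only
  rec <- (1 - riseFrac) * meanI
  sel <- t > systoles[ns]
  tt <- pmin((t[sel] - systoles[ns]) / rec, 1)
  w[sel] <- (1 + cos(pi * tt)) / 2
  w
}

#' Simulate a beating-organoid brightfield video with ground truth
#'
#' Draws a beat schedule from the truncated-normal interval model, drives
#' the inner-chamber radius through an asymmetric contract/recover cosine
#' waveform (contraction over `contractionRiseFraction` of each cycle),
#' co-varies the outer radius by `outerCoupling`, and renders every frame
#' as an annulus via [simulateAnnulusFrame()]. Deterministic under a fixed
#' seed.
#'
#' The attached truth records the programmed systole times, the programmed
#' interval mean/SD (of the realized draws), diastolic and systolic radii
#' and wall thickness, and the programmed fractional shortening
#' \eqn{100 (T_{sys} - T_{dia}) / T_{dia}} implied by the geometry.
#'
#' @param params an [organoidSimParams()] list.
#' @return list with `stack` (a [FrameStack-class]) and `truth` (list:
#'   beatTimes, intervals, intervalMean, intervalSd, outerRadiusDia,
#'   innerRadiusDia, outerRadiusSys, innerRadiusSys, wallThicknessDia,
#'   wallThicknessSys, fractionalShortening).
#' @examples
#' sim <- simulateOrganoidVideo(organoidSimParams(duration = 3, seed = 1))
#' sim$truth$fractionalShortening
#' @export
simulateOrganoidVideo <- function(params = organoidSimParams()) {
  stopifnot(inherits(params, "OrganoidSimParams"))
  p <- params
  .withSeed(p$seed, {
    sched <- .beatSchedule(p$beatIntervalMean, p$beatIntervalSd,
                           p$contractionRiseFraction, p$duration,
                           p$frameInterval)
    nf <- floor(p$duration / p$frameInterval)
    t <- (seq_len(nf) - 1) * p$frameInterval
    if (!length(sched$systoleTimes))
      warning("duration too short for a single beat; truth has zero beats")
    w <- .contractionWave(t, sched$systoleTimes,
                          p$contractionRiseFraction, p$beatIntervalMean)
    dR <- p$pulsationFraction * p$innerRadius
    rIn <- p$innerRadius - dR * w
    rOut <- p$outerRadius - p$outerCoupling * dR * w
    frames <- vector("list", nf)
    for (k in seq_len(nf)) {
      frames[[k]] <- simulateAnnulusFrame(
        rOut[k], rIn[k], imageSize = p$imageSize, center = p$center,
        wallIntensity = p$wallIntensity,
        chamberIntensity = p$chamberIntensity,
        backgroundIntensity = p$backgroundIntensity,
        noiseSd = p$noiseSd,
        harmonicAmp = p$boundaryHarmonicAmp,
        harmonicOrder = p$boundaryHarmonicOrder)$frame
    }
    tDia <- p$outerRadius - p$innerRadius
    tSys <- (p$outerRadius - p$outerCoupling * dR) - (p$innerRadius - dR)
    truth <- list(
      beatTimes = sched$systoleTimes,
      intervals = if (length(sched$systoleTimes) >= 2L)
        diff(sched$systoleTimes) else numeric(),
      intervalMean = p$beatIntervalMean,
      intervalSd = p$beatIntervalSd,
      outerRadiusDia = p$outerRadius, innerRadiusDia = p$innerRadius,
      outerRadiusSys = p$outerRadius - p$outerCoupling * dR,
      innerRadiusSys = p$innerRadius - dR,
      wallThicknessDia = tDia, wallThicknessSys = tSys,
      fractionalShortening = 100 * (tSys - tDia) / tDia)
    list(stack = FrameStack(frames, p$frameInterval,
                            origin = sprintf("synthetic-organoid-seed%d",
                                             p$seed)),
         truth = truth)
  })
}

## normalized transient pulse and its kinetic truth -----------------------

.pulseShape <- function(t, tauUp, tauDown) {
  h <- ifelse(t < 0, 0,
              if (tauUp > 0) (1 - exp(-t / tauUp)) * exp(-t / tauDown)
              else exp(-t / tauDown))
  h
}

#' Closed-form kinetics of the generator's transient pulse
#'
#' For the noiseless pulse \eqn{(1 - e^{-t/\tau_{up}}) e^{-t/\tau_{down}}}
#' (instantaneous upstroke when `tauUp = 0`), computes the peak time, and
#' by root finding to 1e-12: the onset and end crossings at the given
#' amplitude fractions, the transient duration, and the repolarization
#' 30/60/90 times (time from peak until the pulse has decayed by 30/60/90%
#' of its peak). For `tauUp = 0` the repolarization times reduce to the
#' closed form \eqn{\tau_{down} \ln(1/(1-x))}.
#'
#' @param tauUp,tauDown pulse time constants, s.
#' @param onsetFrac,endFrac amplitude fractions defining onset and end.
#' @return list: peakTime, peakValue (of the unnormalized pulse), onset,
#'   end, ctd, depol, repol30, repol60, repol90 (all seconds; onset/end
#'   relative to pulse start).
#' @export
transientTruth <- function(tauUp, tauDown, onsetFrac = 0.1, endFrac = 0.1) {
  stopifnot(tauUp >= 0, tauDown > tauUp)
  if (tauUp > 0) {
    tPeak <- tauUp * log((tauUp + tauDown) / tauUp)
  } else tPeak <- 0
  hPeak <- .pulseShape(tPeak, tauUp, tauDown)
  f <- function(t) .pulseShape(t, tauUp, tauDown) / hPeak
  cross <- function(level, lower, upper) {
    stats::uniroot(function(t) f(t) - level, c(lower, upper),
                   tol = 1e-12)$root
  }
  far <- tPeak + tauDown * 60 # decay to ~1e-26 of peak
  onset <- if (tauUp > 0) cross(onsetFrac, 0, tPeak) else 0
  end <- cross(endFrac, tPeak, far)
  rep30 <- cross(0.7, tPeak, far) - tPeak
  rep60 <- cross(0.4, tPeak, far) - tPeak
  rep90 <- cross(0.1, tPeak, far) - tPeak
  list(peakTime = tPeak, peakValue = hPeak, onset = onset, end = end,
       ctd = end - onset, depol = tPeak - onset,
       repol30 = rep30, repol60 = rep60, repol90 = rep90)
}

#' Simulate a GCaMP calcium trace with ground truth
#'
#' A train of double-exponential transients on a drifting baseline with
#' Gaussian noise. Transient onsets follow the truncated-normal interval
#' model; the first onset falls one interval into the recording, and a
#' trailing transient is only programmed when its peak and the first 40%
#' of its decay are sampled. Deterministic under a fixed seed.
#'
#' @param params a [calciumSimParams()] list.
#' @return list with `trace` (a [CalciumTrace-class]) and `truth` (list:
#'   onsetTimes, peakTimes, intervals, intervalMean, intervalSd, amplitude,
#'   and the noiseless single-pulse kinetics from [transientTruth()]:
#'   ctd, depol, repol30, repol60, repol90).
#' @examples
#' sim <- simulateCalciumTrace(calciumSimParams(duration = 5, seed = 2))
#' sim$truth$repol90
#' @export
simulateCalciumTrace <- function(params = calciumSimParams()) {
  stopifnot(inherits(params, "CalciumSimParams"))
  p <- params
  .withSeed(p$seed, {
    nf <- floor(p$duration / p$frameInterval)
    t <- (seq_len(nf) - 1) * p$frameInterval
    kin <- if (p$amplitude > 0) transientTruth(p$tauUp, p$tauDown) else NULL
    onsets <- numeric(0)
    if (p$amplitude > 0) {
      tMax <- (nf - 1) * p$frameInterval
      margin <- p$frameInterval + 0.4 * p$tauDown
      tt <- 0
      repeat {
        i <- sampleBeatIntervals(1L, p$beatIntervalMean, p$beatIntervalSd)
        tNext <- tt + i
        if (tNext + kin$peakTime > tMax - margin) break
        onsets <- c(onsets, tNext)
        tt <- tNext
      }
    }
    y <- p$baseline + p$driftSlope * t
    if (length(onsets)) {
      for (o in onsets)
        y <- y + p$amplitude * .pulseShape(t - o, p$tauUp, p$tauDown) /
          kin$peakValue
    }
    if (p$noiseSd > 0) y <- y + stats::rnorm(nf, 0, p$noiseSd)
    truth <- list(
      onsetTimes = onsets,
      peakTimes = if (length(onsets)) onsets + kin$peakTime else numeric(),
      intervals = if (length(onsets) >= 2L) diff(onsets) else numeric(),
      intervalMean = p$beatIntervalMean, intervalSd = p$beatIntervalSd,
      amplitude = p$amplitude,
      ctd = if (!is.null(kin)) kin$ctd else NA_real_,
      depol = if (!is.null(kin)) kin$depol else NA_real_,
      repol30 = if (!is.null(kin)) kin$repol30 else NA_real_,
      repol60 = if (!is.null(kin)) kin$repol60 else NA_real_,
      repol90 = if (!is.null(kin)) kin$repol90 else NA_real_)
    list(trace = CalciumTrace((seq_len(nf) - 1) * p$frameInterval, y),
         truth = truth)
  })
}

#' Describe a simulated treatment cohort
#'
#' Emulates a longitudinal hypertrophy-induction design: groups of
#' organoids imaged weekly, with per-week multiplicative effects on wall
#' thickness, beat rate, interval SD and pulsation. Effects default to 1
#' (null). Each organoid keeps its identity (its jittered base geometry)
#' across weeks, as a re-imaged organoid would.
#'
#' @param groups named list; each element is either NULL (null effects) or
#'   a list with optional numeric vectors `thickness`, `rate`,
#'   `intervalSd`, `pulsation`, one value per week, and an optional scalar
#'   `seed` offset. Distinct offsets (the default: the group index) give
#'   independent organoids; identical offsets give exactly noise-matched
#'   groups, so two null groups with the same offset produce identical
#'   recordings.
#' @param weeks integer vector of week labels, ordered; week 0 should be
#'   present for fold-change normalization downstream.
#' @param nPerGroup organoids per group (>= 1).
#' @param base an [organoidSimParams()] list used as the week-0 template.
#' @param organoidJitter per-organoid uniform jitter (+/- fraction) applied
#'   to both radii, fixed per organoid across weeks.
#' @param seed integer master seed; expands to per-organoid sub-seeds.
#' @return list of class `CohortSpec`.
#' @export
cohortSpec <- function(groups = list(control = NULL),
                       weeks = c(0L, 3L),
                       nPerGroup = 5L,
                       base = organoidSimParams(duration = 15),
                       organoidJitter = 0.05,
                       seed = 1L) {
  stopifnot(
    "groups must be a non-empty named list" =
      length(groups) >= 1L && !is.null(names(groups)) &&
      all(nzchar(names(groups))),
    "weeks must be ordered" = !is.unsorted(weeks),
    "nPerGroup must be >= 1" = nPerGroup >= 1L
  )
  for (g in names(groups)) {
    eff <- groups[[g]]
    if (is.null(eff)) next
    for (nm in setdiff(names(eff), "seed"))
      if (length(eff[[nm]]) != length(weeks))
        stop("effect vector '", nm, "' in group '", g,
             "' must have one value per week")
  }
  structure(list(groups = groups, weeks = as.integer(weeks),
                 nPerGroup = as.integer(nPerGroup), base = base,
                 organoidJitter = organoidJitter, seed = as.integer(seed)),
            class = "CohortSpec")
}

.effectAt <- function(eff, name, wIdx) {
  if (is.null(eff) || is.null(eff[[name]])) 1 else eff[[name]][wIdx]
}

#' Simulate a longitudinal organoid cohort
#'
#' For every group x organoid x week, derives per-recording parameters from
#' the cohort template (thickness multiplier applied to the diastolic wall
#' by moving the inner radius; rate multiplier dividing the beat interval;
#' SD and pulsation multipliers applied directly), simulates the video,
#' and returns all recordings with their truths plus a manifest table.
#'
#' @param spec a [cohortSpec()].
#' @return list with `manifest` (data.frame: group, organoid, week, seed
#'   and programmed truth columns) and `recordings` (list parallel to the
#'   manifest rows; each element has stack, truth, params).
#' @export
simulateCohort <- function(spec = cohortSpec()) {
  stopifnot(inherits(spec, "CohortSpec"))
  base <- spec$base
  rows <- list()
  recs <- list()
  idx <- 0L
  for (gi in seq_along(spec$groups)) {
    gname <- names(spec$groups)[gi]
    eff <- spec$groups[[gi]]
    gSeed <- if (!is.null(eff$seed)) eff$seed else gi
    for (o in seq_len(spec$nPerGroup)) {
      jit <- .withSeed(.subSeed(spec$seed, gSeed, o, 0L),
                       stats::runif(1, -spec$organoidJitter,
                                    spec$organoidJitter))
      rOut <- base$outerRadius * (1 + jit)
      tDia0 <- (base$outerRadius - base$innerRadius) * (1 + jit)
      for (wi in seq_along(spec$weeks)) {
        w <- spec$weeks[wi]
        mT <- .effectAt(eff, "thickness", wi)
        mR <- .effectAt(eff, "rate", wi)
        mS <- .effectAt(eff, "intervalSd", wi)
        mP <- .effectAt(eff, "pulsation", wi)
        subSeed <- .subSeed(spec$seed, gSeed, o, wi)
        p <- base
        p$outerRadius <- rOut
        p$innerRadius <- rOut - mT * tDia0
        if (p$innerRadius <= 0)
          stop("thickness multiplier leaves no chamber")
        p$beatIntervalMean <- base$beatIntervalMean / mR
        p$beatIntervalSd <- base$beatIntervalSd * mS
        p$pulsationFraction <- min(base$pulsationFraction * mP, 0.95)
        p$seed <- subSeed
        class(p) <- "OrganoidSimParams"
        sim <- simulateOrganoidVideo(p)
        idx <- idx + 1L
        rows[[idx]] <- data.frame(
          group = gname, organoid = sprintf("%s_%02d", gname, o),
          week = w, seed = subSeed,
          true_thickness_dia_px = p$outerRadius - p$innerRadius,
          true_interval_mean_s = p$beatIntervalMean,
          true_interval_sd_s = p$beatIntervalSd,
          true_fs_percent = sim$truth$fractionalShortening,
          n_true_beats = length(sim$truth$beatTimes),
          stringsAsFactors = FALSE)
        recs[[idx]] <- list(group = gname,
                            organoid = rows[[idx]]$organoid,
                            week = w, stack = sim$stack,
                            truth = sim$truth, params = p)
      }
    }
  }
  list(manifest = do.call(rbind, rows), recordings = recs)
}

#' Simulate a sparse single-cell count matrix with QC ground truth
#'
#' Builds a genes x cells MatrixMarket-style sparse count matrix whose
#' per-cell detected-feature counts and mitochondrial fractions are
#' programmed, so QC filtering rules can be checked against known labels.
#' Thirteen mitochondrial genes named `MT-*` (the human mtDNA
#' protein-coding set) head the gene list.
#'
#' @param nCells number of cells.
#' @param nGenes total genes including the 13 `MT-` genes.
#' @param featuresPerCell integer vector (length nCells or 1) of detected
#'   features programmed per cell.
#' @param mitoFraction numeric vector (length nCells or 1) of target
#'   mitochondrial count fractions; 0 means no mitochondrial counts.
#' @param seed integer seed.
#' @return list: `counts` (dgCMatrix genes x cells with gene/barcode
#'   names), `truth` (data.frame: barcode, n_features, mito_fraction —
#'   achieved values, exact for features, near-target for mito fraction).
#' @export
simulateCountMatrix <- function(nCells = 100L, nGenes = 8000L,
                                featuresPerCell = 3000L,
                                mitoFraction = 0,
                                seed = 1L) {
  stopifnot(nCells >= 1L, nGenes >= 20L)
  mitoNames <- paste0("MT-", c("ND1", "ND2", "CO1", "CO2", "ATP8", "ATP6",
                               "CO3", "ND3", "ND4L", "ND4", "ND5", "ND6",
                               "CYB"))
  nMito <- length(mitoNames)
  genes <- c(mitoNames, sprintf("GENE%05d", seq_len(nGenes - nMito)))
  barcodes <- sprintf("CELL%04d-1", seq_len(nCells))
  featuresPerCell <- rep_len(as.integer(featuresPerCell), nCells)
  mitoFraction <- rep_len(as.numeric(mitoFraction), nCells)
  featuresPerCell <- pmin(featuresPerCell, nGenes)
  .withSeed(seed, {
    ii <- integer(0); jj <- integer(0); xx <- integer(0)
    truth <- data.frame(barcode = barcodes,
                        n_features = featuresPerCell,
                        mito_fraction = NA_real_)
    for (j in seq_len(nCells)) {
      fj <- featuresPerCell[j]
      mj <- mitoFraction[j]
      ## number of mito genes used scales with the mito mass so tiny
      ## target fractions are not floored up by the one-count-per-gene rule
      nMitoUsed <- if (mj > 0)
        max(1L, min(nMito, as.integer(ceiling(mj * fj)), fj - 1L)) else 0L
      nNon <- min(fj - nMitoUsed, nGenes - nMito)
      gNon <- if (nNon > 0)
        sample.int(nGenes - nMito, nNon) + nMito else integer(0)
      cNon <- if (nNon > 0) 1L + stats::rpois(nNon, 2) else integer(0)
      C <- sum(cNon)
      if (nMitoUsed > 0) {
        M <- max(nMitoUsed, round(mj / (1 - mj) * C))
        extra <- M - nMitoUsed
        add <- if (extra > 0)
          as.integer(stats::rmultinom(1, extra, rep(1, nMitoUsed))) else 0L
        cMito <- 1L + add
        gMito <- seq_len(nMitoUsed)
      } else {
        M <- 0L; cMito <- integer(0); gMito <- integer(0)
      }
      ii <- c(ii, gNon, gMito)
      jj <- c(jj, rep.int(j, nNon + nMitoUsed))
      xx <- c(xx, cNon, cMito)
      truth$mito_fraction[j] <- if (C + M > 0) M / (C + M) else 0
    }
    counts <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                                   dims = c(nGenes, nCells),
                                   dimnames = list(genes, barcodes))
    list(counts = methods::as(counts, "CsparseMatrix"), truth = truth)
  })
}
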