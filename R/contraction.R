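## Contraction kinetics from area/thickness time series.
##
## "Contraction peaks" are located from the first-order difference of the
## (smoothed) organoid-area trace: peak systole = projected-area minimum,
## found at negative-to-positive zero crossings of the first difference.
## Interval statistics are invariant to choosing minima vs maxima for a
## periodic trace; the minimum is used because contraction reduces the
## projected area, and the choice is recorded in the result metadata.

## centered moving average; edge windows shrink symmetrically
.movingAverage <- function(v, window) {
  window <- as.integer(window)
  if (window <= 1L) return(v)
  if (window %% 2L == 0L) window <- window + 1L
  half <- (window - 1L) %/% 2L
  n <- length(v)
  out <- as.numeric(stats::filter(v, rep(1 / window, window), sides = 2))
  for (i in seq_len(min(half, n))) {
    h <- i - 1L
    out[i] <- mean(v[max(1L, i - h):min(n, i + h)])
    j <- n - i + 1L
    h <- n - j
    out[j] <- mean(v[max(1L, j - h):min(n, j + h)])
  }
  out
}

## candidate local minima of v: negative-to-positive sign changes of
## diff(v), zero runs carried forward so plateaus yield one candidate
.signChangeMinima <- function(v) {
  d <- diff(v)
  s <- sign(d)
  for (i in seq_along(s)[-1L]) if (s[i] == 0) s[i] <- s[i - 1L]
  idx <- which(s[-length(s)] < 0 & s[-1L] > 0) + 1L
  idx[v[idx] < Inf]
}

## topographic prominence of minima of v: on each side, walk to the
## nearest point lower than the candidate (or the trace end) and take the
## highest value in between; prominence = the lower of the two cols minus
## the candidate. Noise dips riding a slope get the tiny near-side col and
## are rejected; genuine minima get the full excursion.
.candidateProminence <- function(v, cand) {
  n <- length(v)
  vapply(cand, function(i) {
    j <- i - 1L
    leftCol <- v[i]
    while (j >= 1L && v[j] >= v[i]) {
      if (v[j] > leftCol) leftCol <- v[j]
      j <- j - 1L
    }
    j <- i + 1L
    rightCol <- v[i]
    while (j <= n && v[j] >= v[i]) {
      if (v[j] > rightCol) rightCol <- v[j]
      j <- j + 1L
    }
    min(leftCol, rightCol) - v[i]
  }, numeric(1))
}

## sub-frame refinement of an extremum by parabolic interpolation
.refineExtremum <- function(v, i, t0, dt) {
  n <- length(v)
  if (i <= 1L || i >= n) return(t0 + (i - 1L) * dt)
  denom <- v[i - 1L] - 2 * v[i] + v[i + 1L]
  off <- if (abs(denom) < 1e-12) 0 else 0.5 * (v[i - 1L] - v[i + 1L]) / denom
  off <- min(max(off, -0.5), 0.5)
  t0 + (i - 1L + off) * dt
}

.checkUniform <- function(time) {
  if (length(time) < 3L) stop("need at least 3 samples")
  dt <- diff(time)
  if (diff(range(dt)) > 1e-6 * mean(dt))
    stop("time grid must be uniform")
  mean(dt)
}

#' Detect contraction events in an area trace
#'
#' Smooths the trace with a centered moving average, takes the first-order
#' difference, and calls a systole at every negative-to-positive zero
#' crossing (area minimum) whose prominence reaches
#' `minProminenceFrac x (max - min)` of the smoothed trace and whose
#' spacing from an already accepted (deeper) event is at least
#' `minIntervalS`. Each systole is paired with the preceding diastole, the
#' area maximum since the previous systole. Event times are optionally
#' refined to sub-frame resolution by parabolic interpolation.
#'
#' @param trace an [AreaTrace-class] (the outer area is analysed) or a
#'   data.frame with a time column (`time_s` or `time`) and one value
#'   column.
#' @param smoothWindow moving-average width in frames (default 3).
#' @param minProminenceFrac prominence threshold as a fraction of the
#'   trace range (default 0.2).
#' @param minIntervalS minimum spacing between systoles, s (default 0.2).
#' @param refine logical; parabolic sub-frame refinement of event times.
#' @return a [BeatSeries-class]; a constant trace yields an empty series.
#'   `meta` records the settings, the systole/diastole frame indices and
#'   the extremum convention.
#' @export
detectBeats <- function(trace, smoothWindow = 3, minProminenceFrac = 0.2,
                        minIntervalS = 0.2, refine = TRUE) {
  if (is(trace, "AreaTrace")) {
    time <- trace@samples$time_s
    value <- trace@samples$outer_area_px2
  } else if (is.data.frame(trace)) {
    tc <- intersect(c("time_s", "time"), names(trace))[1L]
    if (is.na(tc)) stop("trace needs a time_s or time column")
    vc <- setdiff(names(trace), tc)[1L]
    time <- trace[[tc]]
    value <- trace[[vc]]
  } else stop("trace must be an AreaTrace or a data.frame")
  dt <- .checkUniform(time)
  meta <- list(smoothWindow = smoothWindow,
               minProminenceFrac = minProminenceFrac,
               minIntervalS = minIntervalS, refine = refine,
               convention = "systole = area minimum")
  v <- .movingAverage(value, smoothWindow)
  rng <- max(v) - min(v)
  ## a constant trace (up to floating-point residue) has no beats
  if (rng <= 1e-9 * max(abs(v), 1))
    return(BeatSeries(meta = meta))
  cand <- .signChangeMinima(v)
  if (!length(cand)) return(BeatSeries(meta = meta))
  prom <- .candidateProminence(v, cand)
  keepIdx <- cand[prom >= minProminenceFrac * rng]
  if (!length(keepIdx)) return(BeatSeries(meta = meta))
  ## enforce minimum spacing, deepest first
  ord <- keepIdx[order(v[keepIdx])]
  accepted <- integer(0)
  for (i in ord) {
    if (!length(accepted) ||
        all(abs(time[accepted] - time[i]) >= minIntervalS))
      accepted <- c(accepted, i)
  }
  sysIdx <- sort(accepted)
  ## paired diastole: maximum since the previous systole (or trace start)
  diaIdx <- integer(length(sysIdx))
  for (j in seq_along(sysIdx)) {
    lo <- if (j > 1L) sysIdx[j - 1L] else 1L
    seg <- lo:sysIdx[j]
    diaIdx[j] <- seg[which.max(v[seg])]
  }
  ## a systole needs a genuine preceding relaxation; drop a first event
  ## whose "diastole" coincides with it (trace started mid-fall at peak)
  ok <- diaIdx < sysIdx
  sysIdx <- sysIdx[ok]; diaIdx <- diaIdx[ok]
  if (!length(sysIdx)) return(BeatSeries(meta = meta))
  t0 <- time[1L]
  sysT <- if (refine)
    vapply(sysIdx, function(i) .refineExtremum(v, i, t0, dt), numeric(1))
  else time[sysIdx]
  diaT <- if (refine)
    vapply(diaIdx, function(i) .refineExtremum(-v, i, t0, dt), numeric(1))
  else time[diaIdx]
  diaT <- pmin(diaT, sysT - 1e-9)
  meta$systoleIdx <- sysIdx
  meta$diastoleIdx <- diaIdx
  BeatSeries(sysT, diaT, meta = meta)
}

#' Interval statistics of a beat series
#'
#' @param beats a [BeatSeries-class].
#' @return one-row data.frame: n_beats, interval_mean_s, interval_sd_s
#'   (sample SD, n-1 denominator), frequency_bpm (60 / mean interval) and
#'   frequency_hz. With fewer than two systoles the interval metrics are
#'   explicit NA, never zero.
#' @examples
#' beatStatistics(BeatSeries(c(0, 1, 2, 3), c(-0.5, 0.5, 1.5, 2.5)))
#' @export
beatStatistics <- function(beats) {
  stopifnot(is(beats, "BeatSeries"))
  iv <- beats@intervals
  if (length(iv) < 1L) {
    return(data.frame(n_beats = length(beats@systoleTimes),
                      interval_mean_s = NA_real_, interval_sd_s = NA_real_,
                      frequency_bpm = NA_real_, frequency_hz = NA_real_))
  }
  m <- mean(iv)
  data.frame(n_beats = length(beats@systoleTimes),
             interval_mean_s = m,
             interval_sd_s = if (length(iv) >= 2L) stats::sd(iv) else NA_real_,
             frequency_bpm = 60 / m,
             frequency_hz = 1 / m)
}

#' Fractional shortening from wall thickness at paired beat extremes
#'
#' For every beat, fractional shortening is the percentage change of the
#' wall thickness between the paired diastole (maximum relaxation) and
#' systole (maximum contraction):
#' \eqn{FS = 100 (T_{sys} - T_{dia}) / T_{dia}}, positive when the wall
#' thickens at systole. The alternative echocardiographic convention based
#' on the chamber equivalent diameter,
#' \eqn{100 (D_{dia} - D_{sys}) / D_{dia}}, is available via
#' `convention = "chamber"`.
#'
#' @param areaTrace an [AreaTrace-class] from [segmentStack()].
#' @param beats a [BeatSeries-class] from [detectBeats()] on that trace.
#' @param convention "wall" (default) or "chamber".
#' @return list: `perBeat` (data.frame systole_s, diastole_s,
#'   thickness_sys_px, thickness_dia_px, fs_percent, excluded) and
#'   `meanFS` (mean over non-excluded beats; NA when no beats). Beats with
#'   non-positive diastolic thickness are excluded and flagged.
#' @export
fractionalShortening <- function(areaTrace, beats,
                                 convention = c("wall", "chamber")) {
  stopifnot(is(areaTrace, "AreaTrace"), is(beats, "BeatSeries"))
  convention <- match.arg(convention)
  sysIdx <- beats@meta$systoleIdx
  diaIdx <- beats@meta$diastoleIdx
  if (is.null(sysIdx) || !length(sysIdx)) {
    return(list(perBeat = data.frame(systole_s = numeric(),
                                     diastole_s = numeric(),
                                     thickness_sys_px = numeric(),
                                     thickness_dia_px = numeric(),
                                     fs_percent = numeric(),
                                     excluded = logical()),
                meanFS = NA_real_, convention = convention))
  }
  s <- areaTrace@samples
  if (convention == "wall") {
    tSys <- s$wall_thickness_px[sysIdx]
    tDia <- s$wall_thickness_px[diaIdx]
    fs <- 100 * (tSys - tDia) / tDia
  } else {
    dSys <- 2 * sqrt(s$inner_area_px2[sysIdx] / pi)
    dDia <- 2 * sqrt(s$inner_area_px2[diaIdx] / pi)
    tSys <- dSys; tDia <- dDia
    fs <- 100 * (dDia - dSys) / dDia
  }
  excluded <- !(tDia > 0)
  fs[excluded] <- NA_real_
  perBeat <- data.frame(systole_s = beats@systoleTimes,
                        diastole_s = beats@diastoleTimes,
                        thickness_sys_px = tSys,
                        thickness_dia_px = tDia,
                        fs_percent = fs,
                        excluded = excluded)
  list(perBeat = perBeat,
       meanFS = if (all(excluded)) NA_real_ else mean(fs[!excluded]),
       convention = convention)
}

#' One-row contraction phenotype summary for a recording
#'
#' Convenience wrapper chaining [detectBeats()], [beatStatistics()] and
#' [fractionalShortening()] on a segmented recording.
#'
#' @param areaTrace an [AreaTrace-class].
#' @param ... passed to [detectBeats()].
#' @return one-row data.frame: n_beats, interval_mean_s, interval_sd_s,
#'   frequency_bpm, frequency_hz, fs_percent, thickness_dia_px,
#'   thickness_sys_px.
#' @export
summarizeContraction <- function(areaTrace, ...) {
  beats <- detectBeats(areaTrace, ...)
  stats <- beatStatistics(beats)
  fs <- fractionalShortening(areaTrace, beats)
  ok <- !fs$perBeat$excluded
  cbind(stats,
        data.frame(
          fs_percent = fs$meanFS,
          thickness_dia_px = if (any(ok))
            mean(fs$perBeat$thickness_dia_px[ok]) else NA_real_,
          thickness_sys_px = if (any(ok))
            mean(fs$perBeat$thickness_sys_px[ok]) else NA_real_))
}

#' Normalize longitudinal metrics to week 0
#'
#' Adds a `thickness_fold` column: each organoid/week wall thickness
#' divided by the same organoid's week-0 value. Organoids without a
#' week-0 record are excluded with a warning.
#'
#' @param metrics data.frame with columns `organoid`, `week` and
#'   `thickness_dia_px` (plus any others, carried through).
#' @param thicknessCol name of the thickness column to normalize.
#' @return the table restricted to organoids with a week-0 record, with
#'   `thickness_fold` appended (exactly 1 at week 0).
#' @export
weeklyNormalize <- function(metrics, thicknessCol = "thickness_dia_px") {
  stopifnot(all(c("organoid", "week", thicknessCol) %in% names(metrics)))
  w0 <- metrics[metrics$week == 0, c("organoid", thicknessCol)]
  names(w0)[2L] <- ".t0"
  missing <- setdiff(unique(metrics$organoid), w0$organoid)
  if (length(missing)) {
    warning("excluding organoids without a week-0 record: ",
            paste(missing, collapse = ", "))
    metrics <- metrics[!metrics$organoid %in% missing, , drop = FALSE]
  }
  out <- merge(metrics, w0, by = "organoid", sort = FALSE)
  out$thickness_fold <- out[[thicknessCol]] / out$.t0
  out$.t0 <- NULL
  out[order(out$organoid, out$week), , drop = FALSE]
}
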