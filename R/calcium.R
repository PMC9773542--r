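## Calcium-transient kinetics from GCaMP fluorescence traces.
##
## Per transient: onset and end at a configurable fraction (default 10%)
## of the baseline-subtracted peak amplitude; calcium transient duration
## (CTD) = end - onset; depolarization duration = onset to peak and
## depolarization speed = amplitude over that duration (the mean rate of
## fluorescence rise during the upstroke); repolarization 30/60/90 = time
## from the peak until the signal has decayed by 30/60/90% of the
## amplitude, with linear interpolation between samples for sub-frame
## resolution (the APD-style convention: decay measured from the peak).

#' Rolling-percentile baseline of a fluorescence trace
#'
#' A rolling low percentile (default the 10th) over a window much longer
#' than a transient tracks the diastolic baseline, including slow drift,
#' while ignoring the transients themselves. Windows are clipped at the
#' trace edges. A window longer than the trace falls back to the global
#' percentile with a warning.
#'
#' @param trace a [CalciumTrace-class].
#' @param windowS window length in seconds; should be at least ~5x the
#'   typical transient duration.
#' @param percentile percentile tracked, in (0, 1); default 0.1.
#' @return numeric baseline, one value per sample.
#' @export
estimateBaseline <- function(trace, windowS = 5, percentile = 0.1) {
  stopifnot(is(trace, "CalciumTrace"))
  y <- trace@fluorescence
  n <- length(y)
  dt <- frameInterval(trace)
  if (is.na(dt)) return(y)
  winN <- round(windowS / dt)
  if (winN >= n) {
    warning("baseline window exceeds the trace; using the global percentile")
    return(rep(stats::quantile(y, percentile, names = FALSE), n))
  }
  half <- max(1L, winN %/% 2L)
  vapply(seq_len(n), function(i) {
    stats::quantile(y[max(1L, i - half):min(n, i + half)], percentile,
                    names = FALSE)
  }, numeric(1))
}

## local maxima with prominence and spacing rules (mirror of the systole
## detector: maxima of y found via sign changes of the first difference)
.findPeaks <- function(y, time, minProminenceFrac, minIntervalS) {
  cand <- .signChangeMinima(-y)
  if (!length(cand)) return(integer(0))
  prom <- .candidateProminence(-y, cand)
  keep <- cand[prom >= minProminenceFrac * max(y)]
  if (!length(keep)) return(integer(0))
  ord <- keep[order(-y[keep])]
  accepted <- integer(0)
  for (i in ord) {
    if (!length(accepted) ||
        all(abs(time[accepted] - time[i]) >= minIntervalS))
      accepted <- c(accepted, i)
  }
  sort(accepted)
}

#' Detect calcium-transient peaks
#'
#' Peaks are local maxima of the baseline-subtracted trace with
#' prominence at least `minProminenceFrac` of the largest amplitude and
#' spacing at least `minIntervalS`. An empty result is valid (a flat
#' trace has no transients).
#'
#' @param trace a [CalciumTrace-class].
#' @param baseline numeric baseline per sample (see [estimateBaseline()]);
#'   NULL computes it with defaults.
#' @param minProminenceFrac prominence threshold, fraction of the maximum
#'   baseline-subtracted amplitude (default 0.2).
#' @param minIntervalS minimum peak spacing, s (default 0.2).
#' @param smoothWindow moving-average width (frames) applied to the
#'   subtracted trace before peak search (default 3; 1 disables).
#' @return data.frame with `index` and `time_s` of each peak.
#' @export
detectTransients <- function(trace, baseline = NULL,
                             minProminenceFrac = 0.2, minIntervalS = 0.2,
                             smoothWindow = 3) {
  stopifnot(is(trace, "CalciumTrace"))
  if (is.null(baseline)) baseline <- estimateBaseline(trace)
  y <- .movingAverage(trace@fluorescence - baseline, smoothWindow)
  if (max(y) <= 0 || diff(range(y)) <= 0)
    return(data.frame(index = integer(), time_s = numeric()))
  idx <- .findPeaks(y, trace@time, minProminenceFrac, minIntervalS)
  data.frame(index = idx, time_s = trace@time[idx])
}

## linearly interpolated time at which y crosses `level`, searching from
## index `from` in direction `dir` (+1/-1), bounded by `bound`
.crossingTime <- function(y, time, from, dir, level, bound) {
  i <- from
  repeat {
    j <- i + dir
    if ((dir > 0 && j > bound) || (dir < 0 && j < bound)) return(NA_real_)
    if ((y[i] - level) * (y[j] - level) <= 0) {
      if (y[i] == y[j]) return(time[j])
      f <- (level - y[i]) / (y[j] - y[i])
      return(time[i] + f * (time[j] - time[i]))
    }
    i <- j
  }
}

#' Per-transient kinetic metrics
#'
#' For each supplied peak, measures the baseline-subtracted amplitude and
#' locates the onset (last pre-peak crossing of `onsetFrac x amplitude`),
#' the end (first post-peak crossing down to `endFrac x amplitude`) and
#' the repolarization 30/60/90 times (first post-peak decay through 70%,
#' 40% and 10% of the amplitude), all linearly interpolated between
#' samples. Searches are bounded by the neighbouring peaks; a decay
#' truncated by the end of the recording (or masked by the next transient)
#' leaves the affected values as explicit NA.
#'
#' @param trace a [CalciumTrace-class].
#' @param baseline numeric baseline per sample; NULL computes defaults.
#' @param peaks data.frame from [detectTransients()] (or integer indices).
#' @param onsetFrac,endFrac amplitude fractions defining onset/end
#'   (default 0.1, making CTD a CTD90-style measure).
#' @param smoothWindow moving-average width (frames) applied to the
#'   subtracted trace before measurement (default 3; set 1 to disable).
#' @return a [TransientSet-class].
#' @export
transientMetrics <- function(trace, baseline = NULL, peaks = NULL,
                             onsetFrac = 0.1, endFrac = 0.1,
                             smoothWindow = 3) {
  stopifnot(is(trace, "CalciumTrace"))
  if (is.null(baseline)) baseline <- estimateBaseline(trace)
  if (is.null(peaks)) peaks <- detectTransients(trace, baseline)
  idx <- if (is.data.frame(peaks)) peaks$index else as.integer(peaks)
  meta <- list(onsetFrac = onsetFrac, endFrac = endFrac,
               smoothWindow = smoothWindow)
  empty <- data.frame(onset_s = numeric(), peak_s = numeric(),
                      end_s = numeric(), amplitude_au = numeric(),
                      depol_s = numeric(),
                      depol_speed_au_per_s = numeric(), ctd_s = numeric(),
                      repol30_s = numeric(), repol60_s = numeric(),
                      repol90_s = numeric(), b2b_s = numeric())
  if (!length(idx)) return(TransientSet(empty, meta))
  yRaw <- trace@fluorescence - baseline
  y <- .movingAverage(yRaw, smoothWindow)
  time <- trace@time
  n <- length(y)
  rows <- vector("list", length(idx))
  dt <- time[2L] - time[1L]
  for (j in seq_along(idx)) {
    pk <- idx[j]
    amp <- y[pk]
    if (!(amp > 0)) next
    ## sub-frame peak time: noise on the flat-topped pulse biases the raw
    ## argmax toward the slow (decay) side; a parabolic vertex does not
    peakT <- .refineExtremum(-y, pk, time[1L], dt)
    loBound <- if (j > 1L) {
      seg <- idx[j - 1L]:pk
      seg[which.min(y[seg])]
    } else 1L
    hiBound <- if (j < length(idx)) {
      seg <- pk:idx[j + 1L]
      seg[which.min(y[seg])]
    } else n
    ## the upstroke is steep, so its crossing is located on the raw trace
    ## (noise jitter is tiny there and smoothing would bias it early)
    onset <- .crossingTime(yRaw, time, pk, -1L, onsetFrac * amp, loBound)
    end <- .crossingTime(y, time, pk, +1L, endFrac * amp, hiBound)
    r30 <- .crossingTime(y, time, pk, +1L, 0.7 * amp, hiBound)
    r60 <- .crossingTime(y, time, pk, +1L, 0.4 * amp, hiBound)
    r90 <- .crossingTime(y, time, pk, +1L, 0.1 * amp, hiBound)
    depol <- if (is.na(onset)) NA_real_ else peakT - onset
    rows[[j]] <- data.frame(
      onset_s = onset, peak_s = peakT, end_s = end,
      amplitude_au = amp,
      depol_s = depol,
      depol_speed_au_per_s = if (!is.na(depol) && depol > 0)
        amp / depol else NA_real_,
      ctd_s = if (is.na(onset) || is.na(end)) NA_real_ else end - onset,
      repol30_s = if (is.na(r30)) NA_real_ else r30 - peakT,
      repol60_s = if (is.na(r60)) NA_real_ else r60 - peakT,
      repol90_s = if (is.na(r90)) NA_real_ else r90 - peakT,
      b2b_s = if (j < length(idx)) time[idx[j + 1L]] - time[pk]
              else NA_real_)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  events <- if (length(rows)) do.call(rbind, rows) else empty
  TransientSet(events, meta)
}

#' Summarize transient kinetics per recording
#'
#' Means of every per-transient metric over valid (non-NA) events — the
#' per-organoid "_M" variables — plus the mean beat-to-beat duration.
#'
#' @param transients a [TransientSet-class].
#' @param windowS restrict to transients peaking within the first
#'   `windowS` seconds (default 30; NULL for the full recording).
#' @return one-row data.frame: n_transients, ctd_M_s, amplitude_M_au,
#'   depol_M_s, depol_speed_M_au_per_s, repol30_M_s, repol60_M_s,
#'   repol90_M_s, b2b_M_s. All NA with zero events.
#' @export
summarizeTransients <- function(transients, windowS = 30) {
  stopifnot(is(transients, "TransientSet"))
  e <- transients@events
  if (!is.null(windowS) && nrow(e)) e <- e[e$peak_s <= windowS, , drop = FALSE]
  mn <- function(x) if (any(!is.na(x))) mean(x, na.rm = TRUE) else NA_real_
  data.frame(
    n_transients = nrow(e),
    ctd_M_s = mn(e$ctd_s),
    amplitude_M_au = mn(e$amplitude_au),
    depol_M_s = mn(e$depol_s),
    depol_speed_M_au_per_s = mn(e$depol_speed_au_per_s),
    repol30_M_s = mn(e$repol30_s),
    repol60_M_s = mn(e$repol60_s),
    repol90_M_s = mn(e$repol90_s),
    b2b_M_s = mn(e$b2b_s))
}

#' Full calcium-kinetics analysis of one trace
#'
#' Chains [estimateBaseline()], [detectTransients()],
#' [transientMetrics()] and [summarizeTransients()].
#'
#' @param trace a [CalciumTrace-class].
#' @param windowS baseline window, s.
#' @param percentile baseline percentile.
#' @param minProminenceFrac,minIntervalS peak-detection settings.
#' @param onsetFrac,endFrac,smoothWindow metric settings.
#' @param summaryWindowS measurement window for the summary, s.
#' @return list: baseline, peaks, events ([TransientSet-class]), summary
#'   (one-row data.frame).
#' @export
calciumKinetics <- function(trace, windowS = 5, percentile = 0.1,
                            minProminenceFrac = 0.2, minIntervalS = 0.2,
                            onsetFrac = 0.1, endFrac = 0.1,
                            smoothWindow = 3, summaryWindowS = 30) {
  bl <- estimateBaseline(trace, windowS, percentile)
  pk <- detectTransients(trace, bl, minProminenceFrac, minIntervalS,
                         smoothWindow = smoothWindow)
  ev <- transientMetrics(trace, bl, pk, onsetFrac, endFrac, smoothWindow)
  list(baseline = bl, peaks = pk, events = ev,
       summary = summarizeTransients(ev, summaryWindowS))
}
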