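#' @import methods
NULL

#' FrameStack: an ordered grayscale time-lapse recording
#'
#' Container for the raw unit of video analysis: a list of equally shaped
#' grayscale frames acquired at a fixed frame interval. Frame \eqn{k}
#' (1-based) is assigned timestamp \eqn{(k-1)\cdot\Delta t}; timestamps are
#' always derived from the index and the interval, never from container
#' metadata.
#'
#' @slot frames list of numeric matrices, all of identical dimension.
#' @slot frameInterval numeric(1), seconds between consecutive frames.
#' @slot origin character(1), free-text recording identifier.
#'
#' @seealso [FrameStack()], [frameTimes()], [readFrameStack()]
#' @export
setClass("FrameStack",
  representation(
    frames = "list",
    frameInterval = "numeric",
    origin = "character"
  )
)

setValidity("FrameStack", function(object) {
  msg <- NULL
  if (length(object@frames) < 1L)
    msg <- c(msg, "a FrameStack needs at least one frame")
  if (!all(vapply(object@frames, is.matrix, logical(1))))
    msg <- c(msg, "all frames must be numeric matrices")
  if (length(object@frames) >= 1L) {
    d <- dim(object@frames[[1L]])
    same <- vapply(object@frames, function(f) identical(dim(f), d), logical(1))
    if (!all(same)) msg <- c(msg, "all frames must share the same dimensions")
  }
  if (length(object@frameInterval) != 1L || !is.finite(object@frameInterval) ||
      object@frameInterval <= 0)
    msg <- c(msg, "frameInterval must be a single positive number")
  if (is.null(msg)) TRUE else msg
})

#' Construct a FrameStack
#'
#' @param frames list of numeric matrices (grayscale frames, equal shape).
#' @param frameInterval seconds between frames (> 0).
#' @param origin recording identifier stored with the object.
#' @return A [FrameStack-class] object.
#' @examples
#' fs <- FrameStack(list(matrix(0, 4, 4), matrix(1, 4, 4)), frameInterval = 0.1)
#' frameTimes(fs)
#' @export
FrameStack <- function(frames, frameInterval, origin = "in-memory") {
  new("FrameStack", frames = frames, frameInterval = as.numeric(frameInterval),
      origin = as.character(origin)[1L])
}

#' CalciumTrace: fluorescence intensity on a uniform time grid
#'
#' A single-channel GCaMP fluorescence recording reduced to mean region
#' intensity versus time. The grid must be uniform; all transient kinetics
#' assume a constant sampling interval.
#'
#' @slot time numeric, seconds, strictly increasing and uniform.
#' @slot fluorescence numeric, arbitrary fluorescence units, same length.
#'
#' @seealso [CalciumTrace()], [detectTransients()], [transientMetrics()]
#' @export
setClass("CalciumTrace",
  representation(time = "numeric", fluorescence = "numeric")
)

setValidity("CalciumTrace", function(object) {
  msg <- NULL
  if (length(object@time) != length(object@fluorescence))
    msg <- c(msg, "time and fluorescence must have equal length")
  if (length(object@time) >= 2L) {
    dt <- diff(object@time)
    if (any(dt <= 0)) msg <- c(msg, "time must be strictly increasing")
    else if (diff(range(dt)) > 1e-9)
      msg <- c(msg, "time grid must be uniform (to 1e-9)")
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a CalciumTrace
#'
#' @param time numeric vector of seconds (uniform grid) or a single frame
#'   interval when `fluorescence` is given and `time` has length 1.
#' @param fluorescence numeric fluorescence values.
#' @return A [CalciumTrace-class] object.
#' @export
CalciumTrace <- function(time, fluorescence) {
  if (length(time) == 1L && length(fluorescence) > 1L)
    time <- (seq_along(fluorescence) - 1) * time
  new("CalciumTrace", time = as.numeric(time),
      fluorescence = as.numeric(fluorescence))
}

#' AreaTrace: per-frame organoid geometry
#'
#' One row per frame: outer (whole-organoid) area, inner-chamber area, wall
#' area, wall fraction and equivalent-circle wall thickness, plus a flag for
#' frames whose segmentation failed and was interpolated from neighbours.
#' Areas are in px^2 and thickness in px unless a physical calibration is
#' applied upstream.
#'
#' @slot samples data.frame with columns time_s, outer_area_px2,
#'   inner_area_px2, wall_area_px2, wall_fraction, wall_thickness_px,
#'   interpolated (logical).
#' @slot frameInterval numeric(1), seconds.
#' @export
setClass("AreaTrace",
  representation(samples = "data.frame", frameInterval = "numeric")
)

.areaTraceCols <- c("time_s", "outer_area_px2", "inner_area_px2",
                    "wall_area_px2", "wall_fraction", "wall_thickness_px",
                    "interpolated")

setValidity("AreaTrace", function(object) {
  msg <- NULL
  if (!all(.areaTraceCols %in% names(object@samples)))
    msg <- c(msg, paste("samples must contain columns:",
                        paste(.areaTraceCols, collapse = ", ")))
  else {
    s <- object@samples
    if (any(s$wall_area_px2 < -1e-9, na.rm = TRUE))
      msg <- c(msg, "wall_area_px2 must be non-negative")
    if (any(s$wall_fraction < -1e-9 | s$wall_fraction > 1 + 1e-9, na.rm = TRUE))
      msg <- c(msg, "wall_fraction must lie in [0, 1]")
  }
  if (is.null(msg)) TRUE else msg
})

AreaTrace <- function(samples, frameInterval) {
  new("AreaTrace", samples = samples, frameInterval = as.numeric(frameInterval))
}

#' BeatSeries: detected contraction events
#'
#' Systole times are the times of maximal contraction (minimum projected
#' outer area); each systole is paired with the preceding diastole (maximum
#' area since the previous systole). Intervals are successive
#' systole-to-systole differences.
#'
#' @slot systoleTimes numeric, seconds, strictly increasing.
#' @slot diastoleTimes numeric, one per systole, each before its systole.
#' @slot intervals numeric, length = number of systoles - 1 (or 0).
#' @slot meta list of detector settings recorded with the result.
#' @export
setClass("BeatSeries",
  representation(systoleTimes = "numeric", diastoleTimes = "numeric",
                 intervals = "numeric", meta = "list")
)

setValidity("BeatSeries", function(object) {
  msg <- NULL
  st <- object@systoleTimes
  if (length(st) >= 2L && any(diff(st) <= 0))
    msg <- c(msg, "systoleTimes must be strictly increasing")
  if (length(object@diastoleTimes) != length(st))
    msg <- c(msg, "one diastole per systole required")
  if (length(st) >= 1L && any(object@diastoleTimes >= st))
    msg <- c(msg, "each diastole must precede its systole")
  if (length(object@intervals) && any(object@intervals <= 0))
    msg <- c(msg, "intervals must be positive")
  if (is.null(msg)) TRUE else msg
})

BeatSeries <- function(systoleTimes = numeric(), diastoleTimes = numeric(),
                       meta = list()) {
  new("BeatSeries", systoleTimes = as.numeric(systoleTimes),
      diastoleTimes = as.numeric(diastoleTimes),
      intervals = if (length(systoleTimes) >= 2L) diff(systoleTimes)
                  else numeric(),
      meta = meta)
}

#' TransientSet: per-transient calcium kinetics
#'
#' One row per detected calcium transient with onset/peak/end times,
#' baseline-subtracted peak amplitude, depolarization duration and speed,
#' calcium transient duration (CTD) and repolarization 30/60/90 times.
#' Values that could not be measured (decay truncated by the end of the
#' recording) are explicit NA, never zero.
#'
#' @slot events data.frame with columns onset_s, peak_s, end_s, amplitude_au,
#'   depol_s, depol_speed_au_per_s, ctd_s, repol30_s, repol60_s, repol90_s,
#'   b2b_s.
#' @slot meta list of analysis settings.
#' @export
setClass("TransientSet",
  representation(events = "data.frame", meta = "list")
)

.transientCols <- c("onset_s", "peak_s", "end_s", "amplitude_au", "depol_s",
                    "depol_speed_au_per_s", "ctd_s", "repol30_s", "repol60_s",
                    "repol90_s", "b2b_s")

setValidity("TransientSet", function(object) {
  msg <- NULL
  if (!all(.transientCols %in% names(object@events)))
    msg <- c(msg, paste("events must contain columns:",
                        paste(.transientCols, collapse = ", ")))
  else if (nrow(object@events)) {
    e <- object@events
    bad <- with(e, !is.na(repol30_s) & !is.na(repol60_s) & repol30_s > repol60_s + 1e-9) |
           with(e, !is.na(repol60_s) & !is.na(repol90_s) & repol60_s > repol90_s + 1e-9)
    if (any(bad)) msg <- c(msg, "repolarization times must be ordered 30 <= 60 <= 90")
  }
  if (is.null(msg)) TRUE else msg
})

TransientSet <- function(events, meta = list()) {
  new("TransientSet", events = events, meta = meta)
}

#' QCReport: record of a single-cell QC filtering run
#'
#' @slot perCell data.frame with barcode, n_features, mito_fraction,
#'   retained (logical).
#' @slot perGene data.frame with gene, n_cells_expressing (over retained
#'   cells), retained (logical).
#' @slot thresholds list of the thresholds applied.
#' @export
setClass("QCReport",
  representation(perCell = "data.frame", perGene = "data.frame",
                 thresholds = "list")
)

QCReport <- function(perCell, perGene, thresholds) {
  new("QCReport", perCell = perCell, perGene = perGene,
      thresholds = thresholds)
}
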