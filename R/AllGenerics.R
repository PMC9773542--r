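#' Frame interval accessor
#' @param x an object with a fixed sampling interval.
#' @return numeric(1), seconds per frame.
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))

#' Frame timestamps
#' @param x a [FrameStack-class].
#' @return numeric vector of seconds, `(k-1) * frameInterval`.
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))

#' Number of frames
#' @param x a [FrameStack-class].
#' @return integer frame count.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Extract a single frame
#' @param x a [FrameStack-class].
#' @param i frame index (1-based).
#' @return numeric matrix.
#' @export
setGeneric("getFrame", function(x, i) standardGeneric("getFrame"))

#' Systole times accessor
#' @param x a [BeatSeries-class].
#' @return numeric vector of seconds.
#' @export
setGeneric("systoleTimes", function(x) standardGeneric("systoleTimes"))

#' Diastole times accessor
#' @param x a [BeatSeries-class].
#' @return numeric vector of seconds.
#' @export
setGeneric("diastoleTimes", function(x) standardGeneric("diastoleTimes"))

#' Beat-to-beat interval accessor
#' @param x a [BeatSeries-class].
#' @return numeric vector of seconds (length = systoles - 1).
#' @export
setGeneric("beatIntervals", function(x) standardGeneric("beatIntervals"))

#' Transient event table accessor
#' @param x a [TransientSet-class].
#' @return data.frame of per-transient metrics.
#' @export
setGeneric("transientEvents", function(x) standardGeneric("transientEvents"))

## ---- methods -----------------------------------------------------------

#' @describeIn FrameStack seconds between frames
#' @export
setMethod("frameInterval", "FrameStack", function(x) x@frameInterval)

#' @describeIn CalciumTrace sampling interval of the uniform grid
#' @export
setMethod("frameInterval", "CalciumTrace", function(x) {
  if (length(x@time) < 2L) NA_real_ else x@time[2L] - x@time[1L]
})

#' @describeIn AreaTrace seconds between frames
#' @export
setMethod("frameInterval", "AreaTrace", function(x) x@frameInterval)

#' @describeIn FrameStack timestamps derived from index and interval
#' @export
setMethod("frameTimes", "FrameStack", function(x)
  (seq_along(x@frames) - 1) * x@frameInterval)

#' @describeIn FrameStack number of frames
#' @export
setMethod("nFrames", "FrameStack", function(x) length(x@frames))

#' @describeIn FrameStack extract frame i as a matrix
#' @export
setMethod("getFrame", "FrameStack", function(x, i) x@frames[[i]])

#' @describeIn FrameStack number of frames (length method)
#' @param x a FrameStack
#' @export
setMethod("length", "FrameStack", function(x) length(x@frames))

#' Subset a FrameStack by frame index
#' @param x a [FrameStack-class].
#' @param i integer indices of frames to keep (order preserved as given).
#' @param j,...,drop ignored.
#' @return a [FrameStack-class] with the selected frames. Note the frame
#'   interval is kept as-is; non-contiguous subsets are the caller's
#'   responsibility (see [extractFrames()] for resampling).
#' @export
setMethod("[", "FrameStack", function(x, i, j, ..., drop = TRUE) {
  FrameStack(x@frames[i], x@frameInterval, x@origin)
})

#' @describeIn BeatSeries systole (maximal contraction) times
#' @export
setMethod("systoleTimes", "BeatSeries", function(x) x@systoleTimes)

#' @describeIn BeatSeries paired diastole times
#' @export
setMethod("diastoleTimes", "BeatSeries", function(x) x@diastoleTimes)

#' @describeIn BeatSeries successive systole-to-systole intervals
#' @export
setMethod("beatIntervals", "BeatSeries", function(x) x@intervals)

#' @describeIn BeatSeries number of detected systoles
#' @export
setMethod("length", "BeatSeries", function(x) length(x@systoleTimes))

#' @describeIn TransientSet the per-event metric table
#' @export
setMethod("transientEvents", "TransientSet", function(x) x@events)

#' @describeIn TransientSet number of transients
#' @export
setMethod("length", "TransientSet", function(x) nrow(x@events))

#' Coerce a CalciumTrace to a data.frame
#' @param x a [CalciumTrace-class].
#' @param ... ignored.
#' @export
setMethod("as.data.frame", "CalciumTrace", function(x, ...)
  data.frame(time_s = x@time, fluorescence_au = x@fluorescence))

#' Coerce an AreaTrace to a data.frame
#' @param x an [AreaTrace-class].
#' @param ... ignored.
#' @export
setMethod("as.data.frame", "AreaTrace", function(x, ...) x@samples)

setMethod("show", "FrameStack", function(object) {
  d <- dim(object@frames[[1L]])
  cat("FrameStack:", length(object@frames), "frames of", d[1L], "x", d[2L],
      "px,", object@frameInterval, "s/frame (",
      sprintf("%.1f", (length(object@frames) - 1) * object@frameInterval),
      "s )\n  origin:", object@origin, "\n")
})

setMethod("show", "CalciumTrace", function(object) {
  cat("CalciumTrace:", length(object@time), "samples at",
      frameInterval(object), "s; fluorescence range [",
      sprintf("%.3g", min(object@fluorescence)), ",",
      sprintf("%.3g", max(object@fluorescence)), "]\n")
})

setMethod("show", "AreaTrace", function(object) {
  s <- object@samples
  cat("AreaTrace:", nrow(s), "frames;",
      sum(s$interpolated), "interpolated\n")
  cat(sprintf("  outer area %.0f-%.0f px2, wall thickness %.2f-%.2f px\n",
              min(s$outer_area_px2), max(s$outer_area_px2),
              min(s$wall_thickness_px), max(s$wall_thickness_px)))
})

setMethod("show", "BeatSeries", function(object) {
  cat("BeatSeries:", length(object@systoleTimes), "systoles")
  if (length(object@intervals))
    cat(sprintf("; interval mean %.3f s, sd %.3f s",
                mean(object@intervals), stats::sd(object@intervals)))
  cat("\n")
})

setMethod("show", "TransientSet", function(object) {
  cat("TransientSet:", nrow(object@events), "calcium transients\n")
  if (nrow(object@events))
    cat(sprintf("  mean CTD %.3f s, mean amplitude %.3g au\n",
                mean(object@events$ctd_s, na.rm = TRUE),
                mean(object@events$amplitude_au, na.rm = TRUE)))
})

setMethod("show", "QCReport", function(object) {
  cat("QCReport:", sum(object@perCell$retained), "/",
      nrow(object@perCell), "cells retained;",
      sum(object@perGene$retained), "/", nrow(object@perGene),
      "genes retained\n")
})
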