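## Reading and writing recordings, traces and derived tables.
##
## Timestamps always derive from frame index x frame interval; container
## metadata is never consulted. Image values are kept in their stored
## integer gray levels: multi-page TIFF round-trips are exact for integer
## imagery in [0, 65535].

.GRAY_MAX <- 65535

#' Write a FrameStack as a multi-page grayscale TIFF
#'
#' Gray levels are stored on the 16-bit grid (`value / 65535`), so any
#' integer-valued imagery in [0, 65535] round-trips exactly through
#' [readFrameStack()].
#'
#' @param stack a [FrameStack-class].
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
writeFrameStack <- function(stack, path) {
  stopifnot(is(stack, "FrameStack"))
  pages <- lapply(stack@frames, function(f) f / .GRAY_MAX)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

.readOneImage <- function(path) {
  lower <- tolower(path)
  img <- if (grepl("\\.tiff?$", lower)) {
    tiff::readTIFF(path)
  } else {
    as.array(EBImage::readImage(path))
  }
  if (length(dim(img)) == 3L) {
    ## color input: unweighted channel mean
    img <- apply(img, c(1L, 2L), mean)
  }
  img * .GRAY_MAX
}

#' Load a frame stack from a multi-page TIFF or a frame directory
#'
#' Directories are read in lexicographic filename order; TIFF stacks in
#' page order. Color frames are converted to grayscale by the unweighted
#' channel mean. All frames must share one shape.
#'
#' @param path a `.tif` stack or a directory of single-frame images
#'   (tif/png/jpg).
#' @param frameInterval seconds per frame (> 0); stored with the stack.
#' @return a [FrameStack-class].
#' @export
readFrameStack <- function(path, frameInterval) {
  if (frameInterval <= 0) stop("frameInterval must be positive")
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(tif|tiff|png|jpg|jpeg)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (!length(files)) stop("no image frames found in directory: ", path)
    frames <- lapply(files, .readOneImage)
  } else {
    if (!file.exists(path)) stop("cannot read: ", path)
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    frames <- lapply(pages, function(pg) {
      if (length(dim(pg)) == 3L) pg <- apply(pg, c(1L, 2L), mean)
      pg * .GRAY_MAX
    })
  }
  shapes <- vapply(frames, function(f) paste(dim(f), collapse = "x"),
                   character(1))
  if (length(unique(shapes)) != 1L)
    stop("frames have inconsistent shapes: ",
         paste(unique(shapes), collapse = ", "))
  FrameStack(frames, frameInterval, origin = path)
}

#' Resample a recording at a fixed frame interval
#'
#' Emulates frame extraction from a video at a requested sampling
#' frequency. The output holds `floor(duration / frameInterval)` frames
#' (duration = native frame count x native interval); sample `m`
#' (0-based time `m * frameInterval`) takes the latest native frame at or
#' before that time.
#'
#' @param source a [FrameStack-class], or a path accepted by
#'   [readFrameStack()] together with `nativeInterval`.
#' @param frameInterval requested sampling interval, s (> 0).
#' @param nativeInterval native interval of `source` when it is a path.
#' @return a [FrameStack-class] at the requested interval.
#' @examples
#' sim <- simulateOrganoidVideo(organoidSimParams(duration = 2, seed = 1))
#' length(extractFrames(sim$stack, 0.5))  # floor(2 / 0.5) = 4
#' @export
extractFrames <- function(source, frameInterval, nativeInterval = NULL) {
  if (!is(source, "FrameStack")) {
    if (is.null(nativeInterval))
      stop("nativeInterval is required when source is a path")
    source <- readFrameStack(source, nativeInterval)
  }
  if (!is.numeric(frameInterval) || length(frameInterval) != 1L ||
      frameInterval <= 0)
    stop("frameInterval must be a single positive number")
  dtNative <- frameInterval(source)
  duration <- length(source) * dtNative
  n <- floor(duration / frameInterval + 1e-9)
  if (n < 1L) stop("requested interval exceeds the recording duration")
  idx <- pmin(floor((seq_len(n) - 1) * frameInterval / dtNative + 1e-9) + 1L,
              length(source))
  FrameStack(source@frames[idx], frameInterval, origin = source@origin)
}

#' Mean region fluorescence over time
#'
#' Reduces a (fluorescence) frame stack to a [CalciumTrace-class] by
#' averaging intensity over a region of interest on every frame.
#'
#' @param stack a [FrameStack-class].
#' @param mask logical/0-1 matrix matching the frame shape, or NULL for
#'   the whole frame.
#' @return a [CalciumTrace-class]; time from frame index x interval.
#' @export
meanRoiFluorescence <- function(stack, mask = NULL) {
  stopifnot(is(stack, "FrameStack"))
  if (!is.null(mask)) {
    mask <- mask > 0
    if (!identical(dim(mask), dim(stack@frames[[1L]])))
      stop("mask shape must match the frame shape")
    if (!any(mask)) stop("mask is empty")
    vals <- vapply(stack@frames, function(f) mean(f[mask]), numeric(1))
  } else {
    vals <- vapply(stack@frames, mean, numeric(1))
  }
  CalciumTrace(frameTimes(stack), vals)
}

## ---- CSV helpers -------------------------------------------------------

#' Write a table as CSV with provenance comment lines
#'
#' All derived tables are written with a small `#`-prefixed header
#' recording the package version and, when run through the pipeline
#' driver, the configuration hash and seed; [readCsv()] skips it.
#'
#' @param df data.frame.
#' @param path output path.
#' @param provenance character vector of extra header fields
#'   (`name: value` strings), or NULL.
#' @return `path`, invisibly.
#' @export
writeCsv <- function(df, path, provenance = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("# ", c(paste0("package: CCOmetrics ",
                                   as.character(utils::packageVersion("CCOmetrics"))),
                            provenance)), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a CSV written by this package
#' @param path CSV path (provenance comment lines are skipped).
#' @return data.frame.
#' @export
readCsv <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

#' Write a CalciumTrace to a two-column CSV
#' @param trace a [CalciumTrace-class].
#' @param path output path.
#' @param provenance optional header fields, see [writeCsv()].
#' @return `path`, invisibly.
#' @export
writeCalciumTrace <- function(trace, path, provenance = NULL) {
  writeCsv(as.data.frame(trace), path, provenance)
}

#' Read a CalciumTrace from a two-column CSV
#'
#' Expects columns `time_s` and `fluorescence_au` (any second column name
#' is accepted if there are exactly two columns).
#'
#' @param path CSV path.
#' @return a [CalciumTrace-class].
#' @export
readCalciumTrace <- function(path) {
  df <- readCsv(path)
  if (!"time_s" %in% names(df))
    stop("trace CSV must have a time_s column")
  vcol <- setdiff(names(df), "time_s")[1L]
  CalciumTrace(df$time_s, df[[vcol]])
}

#' Write an AreaTrace to CSV
#' @param areaTrace an [AreaTrace-class].
#' @param path output path.
#' @param provenance optional header fields.
#' @return `path`, invisibly.
#' @export
writeAreaTrace <- function(areaTrace, path, provenance = NULL) {
  writeCsv(as.data.frame(areaTrace), path, provenance)
}
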