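## Configuration-driven pipeline stages.
##
## One YAML config drives all stages; every derived CSV embeds the
## package version, the config hash and the seed, so identical config +
## seed reproduces byte-identical outputs. A thin command-line wrapper
## over these functions ships in inst/scripts/cco_pipeline.R.

#' Default pipeline configuration
#'
#' @param seed master seed.
#' @return nested list (serializable to/from YAML via [readRunConfig()]).
#' @export
defaultRunConfig <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    frame_interval = 0.1,
    simulate = list(duration = 15, noise_sd = 5, image_size = 256,
                    outer_radius = 100, inner_radius = 50,
                    beat_interval_mean = 0.8, beat_interval_sd = 0.08,
                    pulsation_fraction = 0.2, outer_coupling = 0.5),
    segmentation = list(smoothing_sigma = 2, min_object_px = 64,
                        invert_chamber = FALSE, max_fail_fraction = 0.05),
    beats = list(smooth_window = 3, min_prominence_frac = 0.2,
                 min_interval_s = 0.2),
    calcium = list(baseline_window_s = 5, baseline_percentile = 0.1,
                   min_prominence_frac = 0.2, min_interval_s = 0.2,
                   onset_frac = 0.1, end_frac = 0.1, smooth_window = 3,
                   summary_window_s = 30),
    stats = list(small_n_cutoff = 8, test = "auto"),
    scqc = list(min_features = 2000, max_features = 7500,
                max_mito_fraction = 0.10, min_cells_per_gene = 10)
  )
}

#' Read (or write) a pipeline config
#'
#' @param path YAML file.
#' @return nested config list.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  utils::modifyList(defaultRunConfig(), cfg)
}

#' @rdname readRunConfig
#' @param config config list.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Hash of a configuration
#'
#' MD5 of the canonical YAML serialization; embedded in every output so
#' results can be traced to the exact settings that produced them.
#'
#' @param config config list.
#' @return character(1) md5 hex digest.
#' @export
configHash <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(config, tf)
  unname(tools::md5sum(tf))
}

.provenance <- function(config) {
  c(paste0("config_md5: ", configHash(config)),
    paste0("seed: ", config$seed))
}

#' Generate the synthetic fixture set for a pipeline run
#'
#' Writes a beating-organoid video (multi-page TIFF), a calcium trace
#' (CSV), a toy count-matrix triplet, the programmed truths and a
#' manifest, all under `outDir`. Deterministic under config seed.
#'
#' @param config config list (see [defaultRunConfig()]).
#' @param outDir output directory.
#' @return named list of written paths, invisibly.
#' @export
runSimulate <- function(config = defaultRunConfig(), outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  pv <- .provenance(config)
  sm <- config$simulate
  vp <- organoidSimParams(
    imageSize = sm$image_size, outerRadius = sm$outer_radius,
    innerRadius = sm$inner_radius,
    pulsationFraction = sm$pulsation_fraction,
    outerCoupling = sm$outer_coupling,
    beatIntervalMean = sm$beat_interval_mean,
    beatIntervalSd = sm$beat_interval_sd,
    duration = sm$duration, frameInterval = config$frame_interval,
    noiseSd = sm$noise_sd, seed = config$seed)
  vid <- simulateOrganoidVideo(vp)
  videoPath <- file.path(outDir, "organoid_video.tif")
  writeFrameStack(vid$stack, videoPath)
  writeCsv(data.frame(beat_time_s = vid$truth$beatTimes),
           file.path(outDir, "video_truth_beats.csv"), pv)
  ca <- simulateCalciumTrace(calciumSimParams(seed = config$seed))
  tracePath <- file.path(outDir, "calcium_trace.csv")
  writeCalciumTrace(ca$trace, tracePath, pv)
  mx <- simulateCountMatrix(seed = config$seed)
  mtxDir <- file.path(outDir, "counts")
  writeTenxMatrix(mx$counts, mtxDir)
  writeCsv(mx$truth, file.path(outDir, "counts_truth.csv"), pv)
  manifest <- data.frame(
    artifact = c("video", "calcium_trace", "count_matrix"),
    path = c(basename(videoPath), basename(tracePath), "counts"),
    seed = config$seed,
    n_true_beats = c(length(vid$truth$beatTimes),
                     length(ca$truth$onsetTimes), NA))
  writeCsv(manifest, file.path(outDir, "manifest.csv"), pv)
  invisible(list(video = videoPath, trace = tracePath, counts = mtxDir,
                 manifest = file.path(outDir, "manifest.csv")))
}

#' Contraction analysis of one recording
#'
#' Segments the video, detects beats and writes the area trace, per-beat
#' table and one-row contraction summary as CSV.
#'
#' @param input path to a TIFF stack or frame directory.
#' @param config config list.
#' @param outDir output directory.
#' @return the summary data.frame, invisibly; CSVs under `outDir`.
#' @export
runContraction <- function(input, config = defaultRunConfig(), outDir) {
  if (!file.exists(input) && !dir.exists(input))
    stop("input not found: ", input)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  pv <- .provenance(config)
  sg <- config$segmentation; bt <- config$beats
  stack <- readFrameStack(input, config$frame_interval)
  at <- segmentStack(stack, smoothingSigma = sg$smoothing_sigma,
                     minObjectPx = sg$min_object_px,
                     invertChamber = isTRUE(sg$invert_chamber),
                     maxFailFraction = sg$max_fail_fraction)
  writeAreaTrace(at, file.path(outDir, "area_trace.csv"), pv)
  beats <- detectBeats(at, smoothWindow = bt$smooth_window,
                       minProminenceFrac = bt$min_prominence_frac,
                       minIntervalS = bt$min_interval_s)
  fs <- fractionalShortening(at, beats)
  perBeat <- fs$perBeat
  perBeat$interval_s <- c(NA, beatIntervals(beats))[seq_len(nrow(perBeat))]
  writeCsv(perBeat, file.path(outDir, "beats.csv"), pv)
  summary <- summarizeContraction(at, smoothWindow = bt$smooth_window,
                                  minProminenceFrac = bt$min_prominence_frac,
                                  minIntervalS = bt$min_interval_s)
  writeCsv(summary, file.path(outDir, "contraction_summary.csv"), pv)
  invisible(summary)
}

#' Calcium-kinetics analysis of one trace
#'
#' @param input path to a two-column trace CSV (time_s, fluorescence_au).
#' @param config config list.
#' @param outDir output directory.
#' @return the summary data.frame, invisibly; CSVs under `outDir`.
#' @export
runCalcium <- function(input, config = defaultRunConfig(), outDir) {
  if (!file.exists(input)) stop("input not found: ", input)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  pv <- .provenance(config)
  cc <- config$calcium
  trace <- readCalciumTrace(input)
  res <- calciumKinetics(trace, windowS = cc$baseline_window_s,
                         percentile = cc$baseline_percentile,
                         minProminenceFrac = cc$min_prominence_frac,
                         minIntervalS = cc$min_interval_s,
                         onsetFrac = cc$onset_frac, endFrac = cc$end_frac,
                         smoothWindow = cc$smooth_window,
                         summaryWindowS = cc$summary_window_s)
  writeCsv(transientEvents(res$events),
           file.path(outDir, "transients.csv"), pv)
  writeCsv(res$summary, file.path(outDir, "calcium_summary.csv"), pv)
  invisible(res$summary)
}

#' Cohort comparison from a long metrics table
#'
#' @param input path to a CSV of per-organoid metrics with a group column
#'   (and optionally a week column, used as stratum when present).
#' @param metrics metric column names to compare.
#' @param config config list.
#' @param outDir output directory.
#' @return the comparison table, invisibly; CSV under `outDir`.
#' @export
runCohort <- function(input, metrics, config = defaultRunConfig(), outDir) {
  if (!file.exists(input)) stop("input not found: ", input)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  data <- readCsv(input)
  by <- if ("week" %in% names(data)) "week" else NULL
  tab <- compareCohort(data, metrics, by = by,
                       smallNCutoff = config$stats$small_n_cutoff,
                       test = config$stats$test)
  writeCsv(tab, file.path(outDir, "comparisons.csv"), .provenance(config))
  invisible(tab)
}

#' QC-filter a count matrix directory
#'
#' @param input 10x-style matrix directory (see [readTenxMatrix()]).
#' @param config config list.
#' @param outDir output directory; receives the filtered triplet and the
#'   per-cell/per-gene QC report CSVs.
#' @return the [QCReport-class], invisibly.
#' @export
runScqc <- function(input, config = defaultRunConfig(), outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  pv <- .provenance(config)
  qc <- config$scqc
  counts <- readTenxMatrix(input)
  res <- qcFilter(counts, minFeatures = qc$min_features,
                  maxFeatures = qc$max_features,
                  maxMitoFraction = qc$max_mito_fraction,
                  minCellsPerGene = qc$min_cells_per_gene)
  writeTenxMatrix(res$counts, file.path(outDir, "filtered"))
  writeCsv(res$report@perCell, file.path(outDir, "qc_cells.csv"), pv)
  writeCsv(res$report@perGene, file.path(outDir, "qc_genes.csv"), pv)
  invisible(res$report)
}
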