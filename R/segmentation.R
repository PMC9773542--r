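## Per-frame segmentation of the organoid boundary and inner chamber.
##
## The outer boundary is the largest connected foreground component after
## Gaussian smoothing and automatic (Otsu) organoid/background
## thresholding, with holes filled. The chamber is the largest bright
## region strictly inside it, found by a second Otsu threshold restricted
## to interior pixels (the chamber core is a lighter shade than the wall
## in brightfield; set `invertChamber` for the opposite contrast).

## Otsu threshold on a numeric sample (histogram, between-class variance)
.otsuThreshold <- function(vals, levels = 256L) {
  r <- range(vals)
  if (diff(r) <= 0) return(r[1L])
  br <- seq(r[1L], r[2L], length.out = levels + 1L)
  h <- tabulate(findInterval(vals, br, rightmost.closed = TRUE),
                nbins = levels)
  mids <- (br[-1L] + br[-length(br)]) / 2
  w <- cumsum(h)
  mu <- cumsum(h * mids)
  tot <- w[levels]
  muT <- mu[levels]
  w1 <- w[-levels]; mu1 <- mu[-levels]
  w2 <- tot - w1
  valid <- w1 > 0 & w2 > 0
  sigma <- rep(-Inf, levels - 1L)
  sigma[valid] <- (muT * w1[valid] - tot * mu1[valid])^2 /
    (w1[valid] * w2[valid])
  mids[which.max(sigma)]
}

## largest connected component; ties broken by lowest centroid row then
## column. Returns NULL when no component reaches minPx.
.largestComponent <- function(mask, minPx) {
  lab <- EBImage::bwlabel(mask)
  if (max(lab) == 0L) return(NULL)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes == max(sizes))
  if (max(sizes) < minPx) return(NULL)
  if (length(keep) > 1L) {
    cent <- t(vapply(keep, function(k) {
      idx <- which(lab == k, arr.ind = TRUE)
      colMeans(idx)
    }, numeric(2)))
    keep <- keep[order(cent[, 1L], cent[, 2L])][1L]
  }
  lab == keep
}

.removeSmall <- function(mask, minPx) {
  lab <- EBImage::bwlabel(mask)
  if (max(lab) == 0L) return(mask)
  sizes <- tabulate(lab[lab > 0L])
  drop <- which(sizes < minPx)
  if (length(drop)) mask[lab %in% drop] <- FALSE
  mask
}

#' Segment one frame into outer-boundary and inner-chamber masks
#'
#' @param frame grayscale numeric matrix.
#' @param smoothingSigma Gaussian smoothing sigma in px before
#'   thresholding (0 disables).
#' @param minObjectPx components smaller than this are discarded.
#' @param invertChamber set TRUE when the chamber is darker than the wall.
#' @return list of class `OrganoidMasks`: `outerMask`, `innerMask`
#'   (logical matrices, inner contained in outer), `failed` (logical),
#'   `reason` (character, when failed). A frame with no foreground
#'   component of at least `minObjectPx` is flagged failed, never silently
#'   zero; a solid organoid without a resolvable chamber yields a valid
#'   result with an empty inner mask.
#' @examples
#' fr <- simulateAnnulusFrame(100, 50, noiseSd = 0)$frame
#' m <- segmentOrganoid(fr)
#' sum(m$outerMask) / (pi * 100^2)  # ~1
#' @export
segmentOrganoid <- function(frame, smoothingSigma = 2, minObjectPx = 64,
                            invertChamber = FALSE) {
  stopifnot(is.matrix(frame))
  fail <- function(reason)
    structure(list(outerMask = NULL, innerMask = NULL, failed = TRUE,
                   reason = reason), class = "OrganoidMasks")
  rng <- diff(range(frame))
  if (!is.finite(rng) || rng <= 0)
    return(fail("uniform frame: no contrast"))
  g <- (frame - min(frame)) / rng
  if (smoothingSigma > 0) g <- EBImage::gblur(g, sigma = smoothingSigma)
  ## boundary threshold: initial Otsu split, then refined to the midpoint
  ## between the background mean and the darker foreground class (the
  ## wall). A raw Otsu threshold drifts upward with the bright-chamber
  ## mass and shaves the outer boundary; the refined midpoint cuts the
  ## background-to-wall edge ramp at half height, which is unbiased.
  t0 <- .otsuThreshold(as.vector(g))
  fgVals <- g[g > t0]
  bgMean <- mean(g[g <= t0])
  tIn0 <- .otsuThreshold(fgVals)
  lowFrac <- mean(fgVals <= tIn0)
  ## the wall is the dominant dark foreground mode; when the "dark class"
  ## is only a sliver (edge-ramp pixels of a chamberless organoid), the
  ## bright class is the wall instead
  wallMean <- if (lowFrac >= 0.25) mean(fgVals[fgVals <= tIn0])
              else mean(fgVals[fgVals > tIn0])
  if (!is.finite(wallMean)) wallMean <- mean(fgVals)
  thr <- (bgMean + wallMean) / 2
  fg <- g > thr
  outer <- .largestComponent(fg, minObjectPx)
  if (is.null(outer))
    return(fail(sprintf("no foreground component >= %d px", minObjectPx)))
  outer <- EBImage::fillHull(outer) > 0
  ## chamber: second threshold restricted to interior pixels
  interior <- g[outer]
  thrIn <- .otsuThreshold(interior)
  cand <- if (invertChamber) (g < thrIn) & outer else (g > thrIn) & outer
  inner <- .largestComponent(cand, minObjectPx)
  if (!is.null(inner)) {
    inner <- EBImage::fillHull(inner) > 0
    inner <- inner & outer
    ## reject pseudo-chambers carved out of noise: a genuine chamber is
    ## strictly interior, clear of the smoothed boundary ramp (margin of
    ## a few smoothing lengths), and separated from the wall by a real
    ## intensity step
    marginPx <- max(3L, as.integer(ceiling(2 * smoothingSigma)) + 1L)
    core <- EBImage::erode(outer,
                           EBImage::makeBrush(2L * marginPx + 1L,
                                              "disc")) > 0
    step <- abs(mean(g[inner]) - mean(g[outer & !inner]))
    if (any(inner & !core) || !is.finite(step) || step < 0.1 ||
        sum(inner) < minObjectPx)
      inner <- NULL
  }
  if (is.null(inner))
    inner <- matrix(FALSE, nrow(frame), ncol(frame))
  structure(list(outerMask = outer, innerMask = inner, failed = FALSE,
                 reason = NA_character_), class = "OrganoidMasks")
}

#' Equivalent-circle wall thickness from areas
#'
#' Thickness is the difference of the radii of circles with the same areas
#' as the outer boundary and the inner chamber:
#' \eqn{\sqrt{A_{outer}/\pi} - \sqrt{A_{inner}/\pi}}. This area-based
#' construction is robust to irregular outlines and consistent with the
#' pipeline's other area metrics.
#'
#' @param outerArea,innerArea areas in px^2, `outerArea >= innerArea >= 0`.
#' @return thickness in px (vectorized).
#' @examples
#' wallThicknessFromAreas(pi * 100^2, pi * 50^2)  # exactly 50
#' @export
wallThicknessFromAreas <- function(outerArea, innerArea) {
  if (any(innerArea < 0) || any(outerArea < innerArea))
    stop("areas must satisfy outerArea >= innerArea >= 0")
  sqrt(outerArea / pi) - sqrt(innerArea / pi)
}

## distance-transform mean thickness (sensitivity variant): twice the mean
## distance-to-edge over the wall ridge approximates local wall thickness
.wallThicknessDistmap <- function(outerMask, innerMask) {
  wall <- outerMask & !innerMask
  if (!any(wall)) return(0)
  d <- EBImage::distmap(wall)
  2 * max(d)
}

#' Segment every frame of a recording into an AreaTrace
#'
#' Frames whose segmentation fails are linearly interpolated from their
#' neighbours (and flagged) when they make up less than `maxFailFraction`
#' of the stack; otherwise the whole recording is rejected with a
#' per-frame report in the error condition.
#'
#' @param stack a [FrameStack-class].
#' @param smoothingSigma,minObjectPx,invertChamber see [segmentOrganoid()].
#' @param maxFailFraction failed-frame fraction above which the recording
#'   errors out (default 0.05).
#' @param thicknessMethod "equivalent" (equivalent-circle radii
#'   difference, the default) or "distmap" (distance-transform variant,
#'   for sensitivity analysis).
#' @return an [AreaTrace-class]; attribute `failedFrames` lists the
#'   interpolated frame indices.
#' @export
segmentStack <- function(stack, smoothingSigma = 2, minObjectPx = 64,
                         invertChamber = FALSE, maxFailFraction = 0.05,
                         thicknessMethod = c("equivalent", "distmap")) {
  stopifnot(is(stack, "FrameStack"))
  thicknessMethod <- match.arg(thicknessMethod)
  n <- length(stack)
  outer <- inner <- thickDm <- rep(NA_real_, n)
  failed <- logical(n)
  reasons <- character(n)
  for (k in seq_len(n)) {
    m <- segmentOrganoid(stack@frames[[k]], smoothingSigma, minObjectPx,
                         invertChamber)
    if (m$failed) {
      failed[k] <- TRUE
      reasons[k] <- m$reason
    } else {
      outer[k] <- sum(m$outerMask)
      inner[k] <- sum(m$innerMask)
      if (thicknessMethod == "distmap")
        thickDm[k] <- .wallThicknessDistmap(m$outerMask, m$innerMask)
    }
  }
  if (all(failed) || mean(failed) >= maxFailFraction) {
    bad <- which(failed)
    stop(sprintf(
      "segmentation failed on %d/%d frames (>= %.0f%%): frames %s [%s]",
      length(bad), n, 100 * maxFailFraction,
      paste(utils::head(bad, 10L), collapse = ", "),
      paste(unique(reasons[bad]), collapse = "; ")))
  }
  if (any(failed)) {
    t <- seq_len(n)
    ok <- !failed
    outer[failed] <- stats::approx(t[ok], outer[ok], t[failed],
                                   rule = 2)$y
    inner[failed] <- stats::approx(t[ok], inner[ok], t[failed],
                                   rule = 2)$y
    if (thicknessMethod == "distmap")
      thickDm[failed] <- stats::approx(t[ok], thickDm[ok], t[failed],
                                       rule = 2)$y
  }
  inner <- pmin(inner, outer)
  thick <- if (thicknessMethod == "distmap") thickDm
           else wallThicknessFromAreas(outer, inner)
  samples <- data.frame(
    time_s = frameTimes(stack),
    outer_area_px2 = outer,
    inner_area_px2 = inner,
    wall_area_px2 = outer - inner,
    wall_fraction = (outer - inner) / outer,
    wall_thickness_px = thick,
    interpolated = failed)
  at <- AreaTrace(samples, frameInterval(stack))
  attr(at, "failedFrames") <- which(failed)
  at
}
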