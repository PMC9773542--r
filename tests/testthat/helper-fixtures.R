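## Shared fixtures and independent oracles.

## small, fast video parameterization used across tests (geometry scaled
## down from the defaults; radii stay >= 20 px where area accuracy holds)
smallVideoParams <- function(...) {
  organoidSimParams(imageSize = 160L, outerRadius = 60, innerRadius = 30,
                    ...)
}

## independent exact Mann-Whitney oracle: enumerate all assignments of the
## pooled ranks to group 1, build the exact null distribution of U, and
## compute the two-sided p as the probability of a U at least as far from
## its null mean nm/2 as the observed one
mwExactOracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled)) # tie-free fixtures only
  r <- rank(pooled)
  uStat <- function(ix) sum(r[ix]) - nx * (nx + 1) / 2
  obs <- uStat(seq_len(nx))
  combos <- utils::combn(nx + ny, nx)
  uAll <- apply(combos, 2L, uStat)
  center <- nx * ny / 2
  mean(abs(uAll - center) >= abs(obs - center) - 1e-9)
}

## brute-force QC oracle: per-cell and per-gene loops, no matrix algebra
qcOracle <- function(counts, minFeatures = 2000, maxFeatures = 7500,
                     maxMitoFraction = 0.10, minCellsPerGene = 10) {
  m <- as.matrix(counts)
  mito <- grepl("^MT-", rownames(m), ignore.case = TRUE)
  keepCell <- logical(ncol(m))
  for (j in seq_len(ncol(m))) {
    nf <- sum(m[, j] > 0)
    tot <- sum(m[, j])
    mf <- if (tot > 0) sum(m[mito, j]) / tot else 0
    keepCell[j] <- nf >= minFeatures && nf <= maxFeatures &&
      mf < maxMitoFraction
  }
  keepGene <- logical(nrow(m))
  for (i in seq_len(nrow(m))) {
    keepGene[i] <- sum(m[i, keepCell] > 0) >= minCellsPerGene
  }
  list(cells = keepCell, genes = keepGene)
}

## a single triangular transient on a uniform grid: baseline 0, linear
## rise over [t0, t0+base/2], linear fall back over [t0+base/2, t0+base]
triangleTrace <- function(amplitude = 50, base = 1.0, t0 = 1.0,
                          duration = 4, dt = 0.05) {
  t <- seq(0, duration, by = dt)
  apex <- t0 + base / 2
  y <- ifelse(t >= t0 & t <= apex, amplitude * (t - t0) / (base / 2),
       ifelse(t > apex & t <= t0 + base,
              amplitude * (t0 + base - t) / (base / 2), 0))
  CalciumTrace(t, y)
}

## exponential-decay transient with instantaneous upstroke at t0
expDecayTrace <- function(amplitude = 100, tau = 0.5, t0 = 1.0,
                          duration = NULL, dt = 0.01) {
  if (is.null(duration)) duration <- t0 + 6 * tau
  t <- seq(0, duration, by = dt)
  y <- ifelse(t >= t0, amplitude * exp(-(t - t0) / tau), 0)
  CalciumTrace(t, y)
}
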