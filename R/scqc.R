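## Single-cell RNA-seq quality-control filtering.
##
## Cells are retained when their detected-feature count lies within an
## inclusive [minFeatures, maxFeatures] band and their mitochondrial
## count fraction is strictly below maxMitoFraction; genes are then
## retained when expressed (count > 0) in at least minCellsPerGene of the
## retained cells. The cell filter is applied before the gene filter; the
## gene filter counts retained cells only, so the order matters and is
## fixed. Mitochondrial genes are recognized by a case-insensitive "MT-"
## name prefix (human nomenclature).

#' Read a 10x-style sparse count matrix directory
#'
#' Expects the MatrixMarket triplet: `matrix.mtx`, `barcodes.tsv` and
#' `features.tsv` (or `genes.tsv`), plain or gzipped. Gene names come
#' from the second column of the features file when present (symbols),
#' else the first. Orientation is normalized to genes x cells,
#' auto-detected from the name counts when the matrix arrives transposed.
#'
#' @param dir directory containing the triplet.
#' @return a `dgCMatrix`, genes in rows (rownames), barcodes in columns.
#' @export
readTenxMatrix <- function(dir) {
  findFile <- function(stem) {
    for (f in c(file.path(dir, stem), file.path(dir, paste0(stem, ".gz"))))
      if (file.exists(f)) return(f)
    NULL
  }
  mtx <- findFile("matrix.mtx")
  bc <- findFile("barcodes.tsv")
  ft <- findFile("features.tsv")
  if (is.null(ft)) ft <- findFile("genes.tsv")
  if (is.null(mtx)) stop("matrix.mtx(.gz) not found in ", dir)
  if (is.null(bc)) stop("barcodes.tsv(.gz) not found in ", dir)
  if (is.null(ft)) stop("features.tsv(.gz)/genes.tsv(.gz) not found in ", dir)
  m <- Matrix::readMM(mtx)
  barcodes <- utils::read.table(bc, sep = "\t",
                                stringsAsFactors = FALSE)[[1L]]
  feat <- utils::read.table(ft, sep = "\t", stringsAsFactors = FALSE)
  genes <- if (ncol(feat) >= 2L) feat[[2L]] else feat[[1L]]
  if (nrow(m) == length(genes) && ncol(m) == length(barcodes)) {
    ## genes x cells, as deposited by cellranger
  } else if (nrow(m) == length(barcodes) && ncol(m) == length(genes)) {
    m <- Matrix::t(m)
  } else {
    stop(sprintf(
      "matrix is %d x %d but there are %d features and %d barcodes",
      nrow(m), ncol(m), length(genes), length(barcodes)))
  }
  dimnames(m) <- list(genes, barcodes)
  methods::as(m, "CsparseMatrix")
}

#' Write a count matrix as a MatrixMarket triplet
#'
#' @param counts genes x cells sparse matrix with dimnames.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeTenxMatrix <- function(counts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(counts, "CsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  utils::write.table(
    data.frame(id = rownames(counts), name = rownames(counts),
               type = "Gene Expression"),
    file.path(dir, "features.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' Per-cell and per-gene QC filtering of a count matrix
#'
#' @param counts genes x cells sparse (or dense) non-negative integer
#'   matrix with gene rownames and barcode colnames.
#' @param minFeatures,maxFeatures inclusive detected-feature band
#'   (defaults 2000 and 7500).
#' @param maxMitoFraction strict upper bound on the mitochondrial count
#'   fraction (default 0.10).
#' @param minCellsPerGene a gene is kept when expressed in at least this
#'   many retained cells (default 10).
#' @param mitoPattern regex identifying mitochondrial genes
#'   (case-insensitive; default `^MT-`).
#' @return list: `counts` (the filtered matrix) and `report` (a
#'   [QCReport-class] with per-cell and per-gene detail and the
#'   thresholds used). Errors when every cell is removed.
#' @examples
#' sim <- simulateCountMatrix(20, 100, featuresPerCell = 60, seed = 1)
#' qcFilter(sim$counts, minFeatures = 10, maxFeatures = 100,
#'          minCellsPerGene = 1)$report
#' @export
qcFilter <- function(counts, minFeatures = 2000, maxFeatures = 7500,
                     maxMitoFraction = 0.10, minCellsPerGene = 10,
                     mitoPattern = "^MT-") {
  stopifnot(!is.null(rownames(counts)), !is.null(colnames(counts)))
  counts <- methods::as(counts, "CsparseMatrix")
  nFeatures <- Matrix::colSums(counts > 0)
  total <- Matrix::colSums(counts)
  mito <- grepl(mitoPattern, rownames(counts), ignore.case = TRUE)
  mitoCounts <- if (any(mito))
    Matrix::colSums(counts[mito, , drop = FALSE]) else rep(0, ncol(counts))
  mitoFrac <- ifelse(total > 0, mitoCounts / total, 0)
  keepCell <- nFeatures >= minFeatures & nFeatures <= maxFeatures &
    mitoFrac < maxMitoFraction
  perCell <- data.frame(barcode = colnames(counts),
                        n_features = as.integer(nFeatures),
                        mito_fraction = as.numeric(mitoFrac),
                        retained = keepCell,
                        stringsAsFactors = FALSE)
  if (!any(keepCell))
    stop("QC filtering removed every cell")
  kept <- counts[, keepCell, drop = FALSE]
  cellsPerGene <- Matrix::rowSums(kept > 0)
  keepGene <- cellsPerGene >= minCellsPerGene
  perGene <- data.frame(gene = rownames(counts),
                        n_cells_expressing = as.integer(cellsPerGene),
                        retained = as.logical(keepGene),
                        stringsAsFactors = FALSE)
  thresholds <- list(minFeatures = minFeatures, maxFeatures = maxFeatures,
                     maxMitoFraction = maxMitoFraction,
                     minCellsPerGene = minCellsPerGene,
                     mitoPattern = mitoPattern)
  list(counts = kept[keepGene, , drop = FALSE],
       report = QCReport(perCell, perGene, thresholds))
}
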