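#' QC thresholds for single-cell filtering
#'
#' Defaults follow the standard filters for protoplast-derived Arabidopsis
#' inflorescence cells: a cell is kept when it detects more than `min_genes`
#' but fewer than `max_genes` genes, with mitochondrial transcripts below
#' `max_mito_pct` percent and chloroplast transcripts below `max_chloro_pct`
#' percent. All four comparisons are strict.
#'
#' @param min_genes minimum detected-gene count (exclusive), default 600.
#' @param max_genes maximum detected-gene count (exclusive), default 6000.
#' @param max_mito_pct mitochondrial transcript percentage cap, default 10.
#' @param max_chloro_pct chloroplast transcript percentage cap, default 20.
#' @return a list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_genes = 600, max_genes = 6000,
                          max_mito_pct = 10, max_chloro_pct = 20) {
  stopifnot(min_genes < max_genes,
            max_mito_pct >= 0, max_mito_pct <= 100,
            max_chloro_pct >= 0, max_chloro_pct <= 100)
  structure(list(min_genes = min_genes, max_genes = max_genes,
                 max_mito_pct = max_mito_pct, max_chloro_pct = max_chloro_pct),
            class = "qc_thresholds")
}

# Resolve gene-set ids against the matrix; unknown ids warn, never error,
# so published set lists with absent genes still run.
resolve_genes <- function(gene_set, gene_ids) {
  hit <- gene_set %in% gene_ids
  if (any(!hit))
    warning(sprintf("%d of %d gene-set ids not found in matrix; ignored",
                    sum(!hit), length(gene_set)))
  gene_set[hit]
}

#' Percentage of a cell's transcripts coming from a gene set
#'
#' The pipeline's core primitive: for each cell (column),
#' `100 * sum(counts over set genes) / sum(all counts)`. Computed on raw
#' counts; no normalization.
#'
#' @param sce SingleCellExperiment (or a genes x cells matrix with dimnames).
#' @param gene_set character vector of gene ids; unknown ids are ignored with
#'   a warning.
#' @return named numeric vector, one percentage in \[0, 100\] per cell.
#' @export
transcript_fraction <- function(sce, gene_set) {
  m <- if (methods::is(sce, "SummarizedExperiment")) counts_of(sce) else sce
  totals <- Matrix::colSums(m)
  if (any(totals == 0))
    stop("cell(s) with zero total transcripts: ",
         paste(colnames(m)[totals == 0], collapse = ", "))
  set <- resolve_genes(unique(gene_set), rownames(m))
  if (length(set) == 0) return(stats::setNames(numeric(ncol(m)), colnames(m)))
  hits <- if (length(set) == 1) m[set, , drop = FALSE] else m[set, , drop = FALSE]
  100 * Matrix::colSums(hits) / totals
}

#' Transcript fraction for a single cell's count vector
#'
#' Scalar form of [transcript_fraction()]; convenient for spelled-out
#' examples and spot-level use.
#'
#' @param cell_counts named per-gene counts for one cell.
#' @param gene_set gene ids.
#' @return percentage in \[0, 100\].
#' @export
compute_fraction <- function(cell_counts, gene_set) {
  total <- sum(cell_counts)
  if (total == 0) stop("cell has zero total transcripts")
  set <- intersect(unique(gene_set), names(cell_counts))
  100 * sum(cell_counts[set]) / total
}

#' Apply the single-cell QC filters
#'
#' Retains cells whose detected-gene count (genes with count > 0) lies
#' strictly between `min_genes` and `max_genes`, and whose mitochondrial and
#' chloroplast transcript percentages are strictly below their caps.
#'
#' @param sce SingleCellExperiment with `mito`/`chloro` flags in rowData.
#' @param thresholds a [qc_thresholds()] object.
#' @return list with `sce` (filtered), `kept` (barcodes), and `removed`
#'   (named per-rule removal counts; a cell failing several rules counts in
#'   each).
#' @export
filter_cells <- function(sce, thresholds = qc_thresholds()) {
  m <- counts_of(sce)
  rd <- SummarizedExperiment::rowData(sce)
  detected <- Matrix::colSums(m > 0)
  totals <- Matrix::colSums(m)
  if (any(totals == 0))
    stop("cell(s) with zero total transcripts: ",
         paste(colnames(m)[totals == 0], collapse = ", "))
  mito_pct <- 100 * Matrix::colSums(m[rd$mito, , drop = FALSE]) / totals
  chloro_pct <- 100 * Matrix::colSums(m[rd$chloro, , drop = FALSE]) / totals
  fail_low <- detected <= thresholds$min_genes
  fail_high <- detected >= thresholds$max_genes
  fail_mito <- mito_pct >= thresholds$max_mito_pct
  fail_chloro <- chloro_pct >= thresholds$max_chloro_pct
  keep <- !(fail_low | fail_high | fail_mito | fail_chloro)
  if (!any(keep)) message("filter_cells: no cells retained")
  list(sce = sce[, keep],
       kept = colnames(m)[keep],
       removed = c(low_genes = sum(fail_low), high_genes = sum(fail_high),
                   mito = sum(fail_mito), chloro = sum(fail_chloro)),
       qc = data.frame(barcode = colnames(m), detected = as.numeric(detected),
                       mito_pct = as.numeric(mito_pct),
                       chloro_pct = as.numeric(chloro_pct),
                       kept = keep, row.names = NULL))
}

#' Candidate protoplasting-artifact genes
#'
#' Genes detected in the single-cell data (count > 0 in at least `min_cells`
#' cells) but absent from a bulk reference: the set difference flags genes
#' plausibly induced by protoplast generation rather than biology.
#'
#' @param sce SingleCellExperiment (or character vector of detected genes).
#' @param bulk_expressed character vector of genes expressed in the bulk
#'   reference.
#' @param min_cells minimum number of cells a gene must be detected in,
#'   default 1.
#' @return character vector of single-cell-only gene ids.
#' @export
protoplast_artifact_genes <- function(sce, bulk_expressed, min_cells = 1) {
  sc_detected <- if (is.character(sce)) sce else {
    m <- counts_of(sce)
    rownames(m)[Matrix::rowSums(m > 0) >= min_cells]
  }
  if (is.null(sc_detected) || is.null(bulk_expressed))
    stop("both gene sets must be non-null")
  setdiff(sc_detected, bulk_expressed)
}
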