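#' Best-mapping cluster per spot
#'
#' Argmax over a spots x clusters prediction-score matrix (reference-based
#' deconvolution output). Ties go to the lowest cluster label in sort order
#' (logged); a spot whose scores are all zero is labeled `"unassigned"`.
#'
#' @param scores spots x clusters numeric matrix with dimnames; entries
#'   non-negative.
#' @return named character vector of cluster labels, one per spot.
#' @export
best_cluster <- function(scores) {
  stopifnot(is.matrix(scores) || is.data.frame(scores))
  scores <- as.matrix(scores)
  if (any(!is.finite(scores))) stop("scores must be finite")
  if (any(scores < 0)) stop("scores must be non-negative")
  cl_order <- order(colnames(scores))
  ordered <- scores[, cl_order, drop = FALSE]
  n_ties <- 0L
  labs <- apply(ordered, 1, function(r) {
    if (all(r == 0)) return("unassigned")
    top <- which(r == max(r))
    if (length(top) > 1) n_ties <<- n_ties + 1L
    colnames(ordered)[top[1]]
  })
  if (n_ties > 0)
    message(sprintf("best_cluster: %d tie(s) resolved to lowest label", n_ties))
  stats::setNames(labs, rownames(scores))
}

#' Per-genotype spot proportions by best cluster
#'
#' For each genotype, the fraction of its spots best-mapped to each cluster.
#' Clusters with fewer than `min_spots` spots in either genotype are omitted
#' from the output table, but their spots still count in the denominators,
#' so reported proportions are fractions of all spots.
#'
#' @param labels per-spot best-cluster labels.
#' @param genotype per-spot genotype labels (two levels).
#' @param min_spots omission threshold, default 10.
#' @return data.frame `cluster`, one proportion column per genotype, and
#'   per-genotype spot counts as attribute `n_spots`.
#' @export
cluster_spot_proportions <- function(labels, genotype, min_spots = 10) {
  stopifnot(length(labels) == length(genotype))
  genos <- sort(unique(as.character(genotype)))
  if (length(genos) < 2) stop("two genotypes required")
  tab <- table(cluster = labels, genotype = genotype)
  totals <- table(genotype)[colnames(tab)]
  keep <- apply(tab, 1, function(r) all(r >= min_spots))
  prop <- sweep(tab, 2, as.numeric(totals), "/")
  out <- data.frame(cluster = rownames(tab), stringsAsFactors = FALSE)
  for (g in genos) out[[g]] <- as.numeric(prop[, g])
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_spots") <- as.numeric(totals)
  names(attr(out, "n_spots")) <- colnames(tab)
  out
}

#' Capture-area mitochondrial QC
#'
#' Flags capture areas whose spots carry abnormally high mitochondrial
#' transcript fractions: an area is flagged when its median spot mito
#' percentage exceeds `area_flag_factor` times the median of the other
#' areas' medians.
#'
#' @param sce spots SingleCellExperiment with `mito` rowData flags and a
#'   `capture_area` column in colData.
#' @param area_flag_factor multiplier on the cross-area median, default 2.
#' @return data.frame `capture_area`, `median_mito_pct`, `flagged`.
#' @export
spot_qc <- function(sce, area_flag_factor = 2.0) {
  area <- SummarizedExperiment::colData(sce)$capture_area
  if (is.null(area)) stop("colData must contain capture_area")
  if (length(unique(area)) < 2) stop("need at least 2 capture areas")
  m <- counts_of(sce)
  mito <- SummarizedExperiment::rowData(sce)$mito
  totals <- Matrix::colSums(m)
  pct <- 100 * Matrix::colSums(m[mito, , drop = FALSE]) / totals
  med <- tapply(pct, area, stats::median)
  flagged <- vapply(names(med), function(a) {
    others <- med[names(med) != a]
    med[[a]] > area_flag_factor * stats::median(others)
  }, logical(1))
  data.frame(capture_area = names(med), median_mito_pct = as.numeric(med),
             flagged = as.logical(flagged), row.names = NULL)
}

#' Spot-level gene-set fractions and group contrasts
#'
#' The spot analogue of the per-cell analysis: per-spot transcript fractions
#' for every hormone set, then genotype contrasts per best-cluster group via
#' [contrast_clusters()] (Bonferroni family = n_groups x n_sets, counted
#' from the inputs).
#'
#' @param sce spots SingleCellExperiment (flagged capture areas already
#'   excluded).
#' @param sets gene-set table.
#' @param best_labels per-spot best-cluster labels (e.g. [best_cluster()]).
#' @param genotype per-spot genotype labels.
#' @param alpha family-wise error target, default 0.05.
#' @return list with `scores` (spots x sets matrix) and `contrasts`
#'   (`contrast_table`).
#' @export
score_spots <- function(sce, sets, best_labels, genotype, alpha = 0.05) {
  scores <- score_cells(sce, sets)
  contrasts <- contrast_clusters(scores, best_labels, genotype, alpha = alpha)
  list(scores = scores, contrasts = contrasts)
}
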