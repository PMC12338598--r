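#' Log-normalize raw counts
#'
#' `log(1 + 1e4 * count / cell_total)` (natural log), the scale on which
#' module scores and variance-explained are computed.
#'
#' @param m genes x cells count matrix (sparse or dense).
#' @param scale_factor library-size target, default 1e4.
#' @return dense genes x cells matrix of log-normalized values.
#' @export
lognorm_counts <- function(m, scale_factor = 1e4) {
  if (methods::is(m, "SummarizedExperiment")) m <- counts_of(m)
  totals <- Matrix::colSums(m)
  if (any(totals == 0)) stop("cell(s) with zero total transcripts")
  out <- as.matrix(m %*% Matrix::Diagonal(x = scale_factor / totals))
  dimnames(out) <- dimnames(m)
  log1p(out)
}

#' Gene-module score with binned expression-matched controls
#'
#' For each cell, the mean log-normalized expression of the target genes
#' minus the mean over control genes drawn from the same average-expression
#' bins. Genes are ranked by their mean expression across cells and cut into
#' `n_bins` equal-frequency bins; each target gene contributes `n_ctrl`
#' control genes sampled uniformly from its bin (excluding targets; with
#' replacement when the bin is small). Positive scores mean the module is
#' expressed above its expression-matched background.
#'
#' @param m genes x cells raw counts (SingleCellExperiment or matrix);
#'   log-normalization is applied internally.
#' @param target_set character vector of target gene ids.
#' @param n_bins number of expression bins, default 24.
#' @param n_ctrl control genes per target gene, default 100.
#' @param seed integer seed for the control draw.
#' @return named per-cell numeric score.
#' @export
module_score <- function(m, target_set, n_bins = 24, n_ctrl = 100, seed = 1) {
  log_expr <- lognorm_counts(m)
  targets <- resolve_genes(unique(target_set), rownames(log_expr))
  if (length(targets) == 0) stop("target set resolves to zero genes")
  avg <- rowMeans(log_expr)
  # equal-frequency bins on mean expression; ties broken by rank order
  r <- rank(avg, ties.method = "first")
  bins <- ceiling(r / length(r) * min(n_bins, length(r)))
  names(bins) <- names(avg)
  set.seed(seed)
  ctrl <- unlist(lapply(targets, function(g) {
    pool <- names(bins)[bins == bins[g]]
    pool <- setdiff(pool, targets)
    if (length(pool) == 0) return(character(0))
    sample(pool, n_ctrl, replace = length(pool) < n_ctrl)
  }))
  target_mean <- colMeans(log_expr[targets, , drop = FALSE])
  ctrl_mean <- if (length(ctrl) == 0) 0 else
    colMeans(log_expr[ctrl, , drop = FALSE])  # multiplicity kept
  target_mean - ctrl_mean
}

#' Phase call from S and G2M scores
#'
#' G1 when both scores are non-positive; otherwise the phase of the larger
#' score, with a positive tie resolved to S (deterministic; ties are
#' measure-zero on real data).
#'
#' @param s_score,g2m_score numeric vectors (recycled to common length).
#' @return character vector of `"G1"`, `"S"`, `"G2M"`.
#' @export
assign_phase <- function(s_score, g2m_score) {
  n <- max(length(s_score), length(g2m_score))
  s <- rep_len(s_score, n); g <- rep_len(g2m_score, n)
  out <- rep("G1", n)
  out[s > 0 & s >= g] <- "S"
  out[g > 0 & g > s] <- "G2M"
  out
}

#' Score cell-cycle phase per cell
#'
#' Computes S and G2M module scores from a two-column phase gene list and
#' calls the phase.
#'
#' @param sce SingleCellExperiment of raw counts.
#' @param cc_genes data.frame with columns `gene` and `phase` (`"S"` or
#'   `"G2M"`), as read from a two-column TSV.
#' @param n_bins,n_ctrl,seed passed to [module_score()].
#' @return data.frame with `barcode`, `s_score`, `g2m_score`, `phase`.
#' @export
score_cell_cycle <- function(sce, cc_genes, n_bins = 24, n_ctrl = 100, seed = 1) {
  stopifnot(all(c("gene", "phase") %in% names(cc_genes)))
  s_set <- cc_genes$gene[toupper(cc_genes$phase) == "S"]
  g_set <- cc_genes$gene[toupper(cc_genes$phase) == "G2M"]
  s <- module_score(sce, s_set, n_bins, n_ctrl, seed = seed)
  g <- module_score(sce, g_set, n_bins, n_ctrl, seed = seed + 1L)
  data.frame(barcode = colnames(sce), s_score = as.numeric(s),
             g2m_score = as.numeric(g), phase = assign_phase(s, g),
             row.names = NULL)
}

#' Fraction of a gene's variance explained by phase
#'
#' One-way ANOVA R-squared: `SS_between / SS_total` of the per-cell values
#' grouped by phase label. Returns 0 for a constant gene (SS_total = 0).
#'
#' @param gene_values per-cell numeric values (log-normalized expression).
#' @param phase_labels per-cell group labels.
#' @return R-squared in \[0, 1\].
#' @export
variance_explained <- function(gene_values, phase_labels) {
  stopifnot(length(gene_values) == length(phase_labels))
  if (length(gene_values) < 3) stop("need at least 3 cells")
  if (length(unique(phase_labels)) < 2)
    stop("need at least 2 distinct phase labels")
  gm <- mean(gene_values)
  sst <- sum((gene_values - gm)^2)
  if (sst == 0) return(0)
  means <- tapply(gene_values, phase_labels, mean)
  n_k <- tapply(gene_values, phase_labels, length)
  ssb <- sum(n_k * (means - gm)^2)
  ssb / sst
}

# Vectorized over genes (rows of a dense log-expression matrix).
variance_explained_matrix <- function(log_expr, phase_labels) {
  stopifnot(ncol(log_expr) == length(phase_labels))
  f <- factor(phase_labels)
  if (nlevels(f) < 2) stop("need at least 2 distinct phase labels")
  ind <- stats::model.matrix(~ f - 1)           # cells x groups
  n_k <- colSums(ind)
  gm <- rowMeans(log_expr)
  sst <- rowSums((log_expr - gm)^2)
  group_means <- (log_expr %*% ind) %*% diag(1 / n_k)
  ssb <- as.numeric(((group_means - gm)^2) %*% n_k)
  r2 <- ifelse(sst == 0, 0, ssb / sst)
  pmin(pmax(r2, 0), 1)
}

#' Remove cell-cycle-driven and mitochondrial genes
#'
#' Drops every gene whose phase-explained variance (one-way ANOVA R-squared
#' on log-normalized expression) exceeds `threshold` (strictly), plus all
#' mitochondrial-flagged genes, and reports every gene's R-squared with its
#' removal reason.
#'
#' @param sce SingleCellExperiment with `mito` flags in rowData.
#' @param phase_labels per-cell phase labels (e.g. from
#'   [score_cell_cycle()]).
#' @param threshold variance-explained cutoff, default 0.03 (3%).
#' @return list with `sce` (reduced) and `report` (data.frame: gene,
#'   r_squared, mito, removed, reason).
#' @export
remove_cc_genes <- function(sce, phase_labels, threshold = 0.03) {
  log_expr <- lognorm_counts(sce)
  r2 <- variance_explained_matrix(log_expr, phase_labels)
  mito <- SummarizedExperiment::rowData(sce)$mito
  over <- r2 > threshold
  removed <- over | mito
  reason <- ifelse(mito & over, "mito+cell_cycle",
            ifelse(mito, "mito", ifelse(over, "cell_cycle", "")))
  report <- data.frame(gene = rownames(sce), r_squared = r2,
                       mito = mito, removed = removed, reason = reason,
                       row.names = NULL)
  list(sce = sce[!removed, ], report = report)
}
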