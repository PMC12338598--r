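#' Per-cell hormone-response gene-set fractions
#'
#' For every (hormone, direction) gene set, the percentage of each cell's
#' transcripts that originate from the set's genes. Computed on raw counts
#' via [transcript_fraction()]. With a high hormone-signaling level, the
#' hormone's up-regulated set is expected to take a larger share of the
#' cell's transcripts and the down-regulated set a smaller one; discordant
#' shifts of the two sets between genotypes are read as a signaling change.
#'
#' @param sce QC-filtered SingleCellExperiment (cells or spots).
#' @param sets gene-set table (`hormone`, `direction`, `gene`), see
#'   [read_gene_sets()].
#' @return matrix cells x sets of percentages; column names
#'   `"hormone_direction"`.
#' @export
score_cells <- function(sce, sets) {
  sets <- validate_gene_sets(sets)
  sl <- set_list(sets)
  out <- vapply(sl, function(genes) transcript_fraction(sce, genes),
                numeric(ncol(sce)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1, dimnames = list(colnames(sce), names(sl)))
  rownames(out) <- colnames(sce)
  out
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact null enumeration when the combined sample size is at most 20 and
#' there are no ties; otherwise the normal approximation with tie-corrected
#' variance and continuity correction. Degenerate inputs where every rank is
#' tied (zero rank variance) return p = 1. P-values are never clipped.
#'
#' @param x,y numeric samples (both non-empty).
#' @return two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  if (length(unique(c(x, y))) == 1) return(1)
  exact <- (length(x) + length(y) <= 20) && !ties
  res <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = exact, correct = TRUE))
  unname(res$p.value)
}

#' Per-cluster genotype contrasts of gene-set fractions
#'
#' For each (cluster, gene set): the two genotype means, their difference
#' (mutant minus reference), a two-sided Wilcoxon rank-sum p-value on the
#' per-cell fractions, the dot-plot size statistic `log10(1/p)`, a
#' Bonferroni significance call at `alpha / (n_clusters * n_sets)` (family
#' counted from the inputs), and a per-cluster star annotation. Rows failing
#' the family threshold are flagged for suppression in dot plots.
#'
#' Clusters where either genotype has fewer than 2 cells yield a row with
#' p = 1 and a warning.
#'
#' @param scores cells x sets matrix from [score_cells()].
#' @param cluster_labels per-cell cluster labels.
#' @param genotype_labels per-cell genotype labels (exactly two levels).
#' @param alpha family-wise error target, default 0.05.
#' @param reference reference genotype label; defaults to `"WT"` when
#'   present, else the first sorted label.
#' @return data.frame of class `contrast_table` with columns `cluster`,
#'   `hormone`, `direction`, `mean_ref`, `mean_mut`, `diff`, `p`,
#'   `dot_size`, `significant`, `stars`. Attributes `bonferroni_threshold`
#'   (alpha / (n_clusters * n_sets)) and `star_family` (n_clusters) record
#'   the two families used.
#' @export
contrast_clusters <- function(scores, cluster_labels, genotype_labels,
                              alpha = 0.05, reference = NULL) {
  stopifnot(nrow(scores) == length(cluster_labels),
            nrow(scores) == length(genotype_labels))
  genos <- sort(unique(as.character(genotype_labels)))
  if (length(genos) != 2) stop("exactly two genotype labels required")
  if (is.null(reference)) reference <- if ("WT" %in% genos) "WT" else genos[1]
  mutant <- setdiff(genos, reference)
  clusters <- sort(unique(as.character(cluster_labels)))
  sets <- colnames(scores)
  n_tests <- length(clusters) * length(sets)
  thr <- alpha / n_tests
  rows <- list()
  for (cl in clusters) {
    in_cl <- cluster_labels == cl
    idx_ref <- in_cl & genotype_labels == reference
    idx_mut <- in_cl & genotype_labels == mutant
    degenerate <- sum(idx_ref) < 2 || sum(idx_mut) < 2
    if (degenerate)
      warning(sprintf("cluster %s has < 2 cells in a genotype; p set to 1", cl))
    for (s in sets) {
      xr <- scores[idx_ref, s]
      xm <- scores[idx_mut, s]
      m_ref <- if (length(xr)) mean(xr) else NA_real_
      m_mut <- if (length(xm)) mean(xm) else NA_real_
      p <- if (degenerate) 1 else wilcoxon_rank_sum(xm, xr)
      horm <- sub("_[^_]*$", "", s)
      dir <- sub(".*_", "", s)
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = cl, hormone = horm, direction = dir,
        mean_ref = m_ref, mean_mut = m_mut, diff = m_mut - m_ref,
        p = p, dot_size = log10(1 / p), significant = p < thr,
        stars = star_annotation(p, length(clusters)),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "bonferroni_threshold") <- thr
  attr(out, "star_family") <- length(clusters)
  attr(out, "reference") <- reference
  attr(out, "mutant") <- mutant
  class(out) <- c("contrast_table", class(out))
  out
}

#' Bonferroni star annotation
#'
#' Number of base significance levels (default 0.05, 0.01, 0.001, 0.0001)
#' the p-value clears after dividing each by the number of groups tested.
#' With 17 clusters the thresholds are 0.00294, 0.00059, 0.000059 and
#' 0.0000059.
#'
#' @param p p-value(s).
#' @param n_groups Bonferroni family size (number of groups), >= 1.
#' @param base_alphas descending base levels.
#' @return integer star count(s) 0-4.
#' @export
star_annotation <- function(p, n_groups, base_alphas = c(0.05, 0.01, 0.001, 0.0001)) {
  stopifnot(n_groups >= 1)
  vapply(p, function(pv) sum(pv < base_alphas / n_groups), integer(1))
}

#' Infer hormone-signaling direction from an up/down row pair
#'
#' The inference logic for reading the contrast table: a hormone's signaling
#' is called higher in the mutant when the up-regulated set is significantly
#' higher there, or the down-regulated set significantly lower (and
#' symmetrically for lower). Concordant significance of both sets gives a
#' strong call; one set alone a weak call; conflicting or no evidence is
#' inconclusive.
#'
#' @param row_up,row_down single rows of a `contrast_table` for the same
#'   (cluster, hormone), directions `up` and `down`.
#' @return list with `call` in `higher_in_mutant`, `lower_in_mutant`,
#'   `inconclusive`, and `confidence` in `strong`, `weak`, `none`.
#' @export
infer_direction <- function(row_up, row_down) {
  if (row_up$cluster != row_down$cluster || row_up$hormone != row_down$hormone)
    stop("rows must refer to the same (cluster, hormone)")
  if (row_up$direction != "up" || row_down$direction != "down")
    stop("expected one 'up' and one 'down' row")
  up_hi <- isTRUE(row_up$significant) && row_up$diff > 0
  down_hi <- isTRUE(row_down$significant) && row_down$diff < 0
  up_lo <- isTRUE(row_up$significant) && row_up$diff < 0
  down_lo <- isTRUE(row_down$significant) && row_down$diff > 0
  higher <- up_hi || down_hi
  lower <- up_lo || down_lo
  if (higher && !lower)
    list(call = "higher_in_mutant",
         confidence = if (up_hi && down_hi) "strong" else "weak")
  else if (lower && !higher)
    list(call = "lower_in_mutant",
         confidence = if (up_lo && down_lo) "strong" else "weak")
  else list(call = "inconclusive", confidence = "none")
}

#' Directional calls for every (cluster, hormone) pair in a contrast table
#'
#' @param contrasts a `contrast_table` from [contrast_clusters()].
#' @return data.frame with `cluster`, `hormone`, `call`, `confidence`.
#' @export
infer_directions <- function(contrasts) {
  keys <- unique(contrasts[, c("cluster", "hormone")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    cl <- keys$cluster[i]; h <- keys$hormone[i]
    ru <- contrasts[contrasts$cluster == cl & contrasts$hormone == h &
                      contrasts$direction == "up", , drop = FALSE]
    rd <- contrasts[contrasts$cluster == cl & contrasts$hormone == h &
                      contrasts$direction == "down", , drop = FALSE]
    if (nrow(ru) != 1 || nrow(rd) != 1) return(NULL)
    res <- infer_direction(ru, rd)
    data.frame(cluster = cl, hormone = h, call = res$call,
               confidence = res$confidence, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
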