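# Fixture builders and independent oracles shared across the suite.

# Small dense count matrix with named genes/cells, wrapped as an SCE.
toy_sce <- function(counts, mito = NULL, chloro = NULL, cell_meta = NULL) {
  flags <- data.frame(
    mito = rownames(counts) %in% (mito %||% character(0)),
    chloro = rownames(counts) %in% (chloro %||% character(0)))
  make_sce(Matrix::Matrix(counts, sparse = TRUE), flags, cell_meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

named_matrix <- function(data, n_genes, n_cells, gene_prefix = "g",
                         cell_prefix = "cell") {
  m <- matrix(data, nrow = n_genes, ncol = n_cells)
  dimnames(m) <- list(paste0(gene_prefix, seq_len(n_genes)),
                      paste0(cell_prefix, seq_len(n_cells)))
  m
}

# Independent Wilcoxon oracle: full enumeration of all C(n, nx) rank
# assignments. Two-sided p = fraction of assignments whose rank-sum
# deviates from its mean by at least as much as the observed one.
# Tie-free inputs only.
wilcoxon_enum_oracle <- function(x, y) {
  n <- length(x) + length(y)
  r <- rank(c(x, y))
  obs <- sum(r[seq_along(x)])
  mu <- length(x) * (n + 1) / 2
  combos <- utils::combn(n, length(x))
  sums <- colSums(matrix(seq_len(n)[combos], nrow = length(x)))
  mean(abs(sums - mu) >= abs(obs - mu) - 1e-12)
}

# Independent one-way ANOVA R^2 oracle via lm().
anova_r2_oracle <- function(values, labels) {
  summary(stats::lm(values ~ factor(labels)))$r.squared
}
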