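#' Assemble a SingleCellExperiment from counts and annotations
#'
#' Thin constructor used throughout the package. Counts are genes x cells
#' (or genes x spots), stored sparse. Organelle membership travels as logical
#' columns `mito` and `chloro` in `rowData`.
#'
#' @param counts genes x cells matrix of non-negative integers (coerced to
#'   `dgCMatrix`); must carry rownames (gene ids) and colnames (barcodes).
#' @param gene_flags data.frame with logical columns `mito` and `chloro`,
#'   one row per gene (optional; defaults to all-FALSE).
#' @param cell_meta data.frame of per-cell labels (genotype, replicate,
#'   cluster, ...), one row per cell (optional).
#' @return a [SingleCellExperiment::SingleCellExperiment] with assay `counts`.
#' @export
make_sce <- function(counts, gene_flags = NULL, cell_meta = NULL) {
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have rownames (gene ids) and colnames (barcodes)")
  if (anyDuplicated(rownames(counts))) stop("gene ids must be unique")
  if (anyDuplicated(colnames(counts))) stop("barcodes must be unique")
  if (any(counts@x < 0)) stop("counts must be non-negative")
  if (is.null(gene_flags))
    gene_flags <- data.frame(mito = logical(nrow(counts)),
                             chloro = logical(nrow(counts)))
  stopifnot(nrow(gene_flags) == nrow(counts))
  rd <- S4Vectors::DataFrame(gene_flags, row.names = rownames(counts))
  cd <- if (is.null(cell_meta)) S4Vectors::DataFrame(row.names = colnames(counts))
        else S4Vectors::DataFrame(cell_meta, row.names = colnames(counts))
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts), rowData = rd, colData = cd)
}

counts_of <- function(sce) SummarizedExperiment::assay(sce, "counts")

#' Write a cellranger-style MatrixMarket triplet
#'
#' Writes `matrix.mtx`, `features.tsv` (id, name, mito flag, chloro flag) and
#' `barcodes.tsv` into `dir`, plus `metadata.csv` when the object carries
#' cell metadata.
#'
#' @param sce SingleCellExperiment from [make_sce()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_counts_triplet <- function(sce, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- counts_of(sce)
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  rd <- SummarizedExperiment::rowData(sce)
  feats <- data.frame(id = rownames(sce), name = rownames(sce),
                      mito = as.integer(rd$mito), chloro = as.integer(rd$chloro))
  utils::write.table(feats, file.path(dir, "features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(colnames(sce), file.path(dir, "barcodes.tsv"))
  cd <- SummarizedExperiment::colData(sce)
  if (ncol(cd) > 0) {
    meta <- cbind(data.frame(barcode = colnames(sce)), as.data.frame(cd))
    utils::write.csv(meta, file.path(dir, "metadata.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' Read a cellranger-style MatrixMarket triplet
#'
#' @param dir directory holding `matrix.mtx`, `features.tsv`, `barcodes.tsv`
#'   and optionally `metadata.csv`.
#' @return a SingleCellExperiment.
#' @export
read_counts_triplet <- function(dir) {
  m <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")), "CsparseMatrix")
  feats <- utils::read.table(file.path(dir, "features.tsv"), sep = "\t",
                             stringsAsFactors = FALSE)
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  rownames(m) <- feats[[1]]
  colnames(m) <- barcodes
  flags <- data.frame(
    mito = if (ncol(feats) >= 3) as.logical(feats[[3]]) else grepl("^ATM", feats[[1]]),
    chloro = if (ncol(feats) >= 4) as.logical(feats[[4]]) else grepl("^ATC", feats[[1]]))
  meta_path <- file.path(dir, "metadata.csv")
  meta <- NULL
  if (file.exists(meta_path)) {
    meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
    meta <- meta[match(barcodes, meta$barcode), setdiff(names(meta), "barcode"),
                 drop = FALSE]
  }
  make_sce(m, flags, meta)
}

#' Read hormone-response gene sets
#'
#' Accepts either GMT (set name encodes `hormone_direction`, e.g.
#' `auxin_up`) or a three-column TSV `hormone  direction  gene`.
#'
#' @param path file path.
#' @return data.frame with columns `hormone`, `direction`, `gene`;
#'   `direction` is `"up"` or `"down"`.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  first <- strsplit(lines[1], "\t")[[1]]
  if (length(first) >= 3 && tolower(first[2]) %in% c("up", "down")) {
    df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                            col.names = c("hormone", "direction", "gene"))
  } else {
    # GMT: name <tab> description <tab> gene1 <tab> gene2 ...
    parts <- strsplit(lines, "\t")
    df <- do.call(rbind, lapply(parts, function(p) {
      nm <- p[1]
      dir <- sub(".*_", "", nm)
      horm <- sub("_[^_]*$", "", nm)
      data.frame(hormone = horm, direction = tolower(dir),
                 gene = p[-(1:2)], stringsAsFactors = FALSE)
    }))
  }
  validate_gene_sets(df)
}

#' Validate a gene-set table
#'
#' @param df data.frame with columns `hormone`, `direction`, `gene`.
#' @return the validated data.frame (directions lower-cased).
#' @export
validate_gene_sets <- function(df) {
  stopifnot(all(c("hormone", "direction", "gene") %in% names(df)))
  df$direction <- tolower(df$direction)
  if (!all(df$direction %in% c("up", "down")))
    stop("direction must be 'up' or 'down'")
  sizes <- table(paste(df$hormone, df$direction, sep = "_"))
  if (any(sizes == 0)) stop("empty gene set")
  df
}

# Split a gene-set table into a named list of gene-id vectors, names
# "hormone_direction".
set_list <- function(sets) {
  split(sets$gene, paste(sets$hormone, sets$direction, sep = "_"))
}

#' Write a CSV with a provenance header comment
#'
#' Every pipeline output carries a `#`-prefixed header recording package
#' version, seed and a digest of the key parameters, so runs are auditable.
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param seed integer seed used for the run (NA if none).
#' @param params named list folded into the header.
#' @return `path`, invisibly.
#' @export
write_csv_stamped <- function(df, path, seed = NA, params = list()) {
  pd <- paste(names(params), unlist(lapply(params, paste, collapse = "|")),
              sep = "=", collapse = "; ")
  hdr <- sprintf("# sepalsig %s; seed=%s; %s",
                 as.character(utils::packageVersion("sepalsig")), seed, pd)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a CSV written by [write_csv_stamped()]
#' @param path file path.
#' @return data.frame (header comment skipped).
#' @export
read_csv_stamped <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
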