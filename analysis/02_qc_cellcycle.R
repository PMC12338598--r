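#!/usr/bin/env Rscript
# Cell-level QC and cell-cycle handling: apply the 600/6000 detected-gene and
# 10%/20% organelle filters, score S and G2M phases, and delete genes whose
# expression variance is substantially (>3%) explained by phase, plus all
# mitochondrial genes.

suppressMessages(library(sepalsig))
seed <- 1
data_dir <- "results/data"
out <- "results"

sce <- read_counts_triplet(file.path(data_dir, "sc"))
qc <- filter_cells(sce, qc_thresholds())
write_csv_stamped(qc$qc, file.path(out, "qc_summary.csv"), seed = seed,
                  params = list(min_genes = 600, max_genes = 6000,
                                max_mito_pct = 10, max_chloro_pct = 20))
message(sprintf("QC: %d of %d cells retained (removed: %s)",
                length(qc$kept), ncol(sce),
                paste(names(qc$removed), qc$removed, sep = "=", collapse = ", ")))

cc_genes <- read_csv_stamped(file.path(data_dir, "cc_genes.csv"))
phases <- score_cell_cycle(qc$sce, cc_genes, seed = seed)
write_csv_stamped(phases, file.path(out, "phase_scores.csv"), seed = seed)
truth <- read_csv_stamped(file.path(data_dir, "sc_truth.csv"))
acc <- mean(phases$phase == truth$phase_truth[match(phases$barcode, truth$barcode)])
message(sprintf("cell cycle: phase called for %d cells (%.1f%% agree with truth)",
                nrow(phases), 100 * acc))

res <- remove_cc_genes(qc$sce, phases$phase, threshold = 0.03)
write_csv_stamped(res$report, file.path(out, "variance_report.csv"), seed = seed,
                  params = list(threshold = 0.03, scale = "log-normalized"))
message(sprintf("variance filter: %d genes removed (%d cell-cycle, %d mito); %d genes remain",
                sum(res$report$removed),
                sum(res$report$reason %in% c("cell_cycle", "mito+cell_cycle")),
                sum(res$report$mito), nrow(res$sce)))
write_counts_triplet(res$sce, file.path(out, "sc_filtered"))
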