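#!/usr/bin/env Rscript
# Spot-level analysis: best-mapping cluster per spot from the prediction
# scores, per-genotype spot proportions with the <10-spot omission rule,
# capture-area mitochondrial QC, and spot-level hormone-set contrasts
# grouped by best cluster.

suppressMessages(library(sepalsig))
seed <- 1
data_dir <- "results/data"
out <- "results"

sce <- read_counts_triplet(file.path(data_dir, "spots"))
scores_df <- utils::read.csv(file.path(data_dir, "prediction_scores.csv"))
pred <- as.matrix(scores_df[, -1])
rownames(pred) <- scores_df$spot

labels <- best_cluster(pred)
meta <- SummarizedExperiment::colData(sce)
write_csv_stamped(data.frame(spot = names(labels), best_cluster = labels,
                             genotype = meta$genotype),
                  file.path(out, "spot_labels.csv"), seed = seed)

truth <- utils::read.csv(file.path(data_dir, "spot_truth_weights.csv"))
tw <- as.matrix(truth[, -1])
recovery <- mean(labels == colnames(tw)[max.col(tw)])
message(sprintf("best cluster: %.1f%% of %d spots match the true argmax",
                100 * recovery, length(labels)))

props <- cluster_spot_proportions(labels, meta$genotype, min_spots = 10)
write_csv_stamped(props, file.path(out, "spot_proportions.csv"), seed = seed,
                  params = list(min_spots = 10))
message(sprintf("proportions: %d clusters reported (omission rule applied): %s",
                nrow(props),
                paste(sprintf("%s WT=%.3f mut=%.3f", props$cluster, props$WT,
                              props$mutant), collapse = "; ")))

area_qc <- spot_qc(sce, area_flag_factor = 2)
write_csv_stamped(area_qc, file.path(out, "spot_area_qc.csv"), seed = seed)
keep <- meta$capture_area %in% area_qc$capture_area[!area_qc$flagged]
message(sprintf("area QC: %d/%d areas pass; %d spots retained",
                sum(!area_qc$flagged), nrow(area_qc), sum(keep)))

sets <- read_csv_stamped(file.path(data_dir, "hormone_sets.csv"))
res <- score_spots(sce[, keep], sets, labels[keep], meta$genotype[keep])
write_csv_stamped(as.data.frame(res$contrasts),
                  file.path(out, "spot_contrasts.csv"), seed = seed,
                  params = list(bonferroni = attr(res$contrasts,
                                                  "bonferroni_threshold")))
message(sprintf("spot contrasts: %d rows, %d significant",
                nrow(res$contrasts), sum(res$contrasts$significant)))
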