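#!/usr/bin/env Rscript
# Generate the synthetic study: a cluster-structured single-cell experiment
# with a brassinosteroid-signaling shift planted in one cluster of the
# mutant, matched spatial spots, reporter nucleus tables, and sepal growth
# series. All downstream scripts consume these files.

suppressMessages(library(sepalsig))
seed <- 1
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

lm <- matrix(0, 2, 3, dimnames = list(c("WT", "mutant"), c("c0", "c1", "c2")))
lm["mutant", "c1"] <- 1    # latent BR-signaling shift in cluster c1
cfg <- sc_sim_config(seed = seed,
                     beta = c(auxin = 0, cytokinin = 0, brassinosteroid = 0.2,
                              abscisic_acid = 0, gibberellin = 0, ethylene = 0),
                     latent_mean = lm)
sim <- simulate_sc(cfg)
write_counts_triplet(sim$sce, file.path(out, "sc"))
write_csv_stamped(sim$truth, file.path(out, "sc_truth.csv"), seed = seed)
write_csv_stamped(sim_gene_sets(cfg), file.path(out, "hormone_sets.csv"), seed = seed)
write_csv_stamped(sim_cc_genes(cfg), file.path(out, "cc_genes.csv"), seed = seed)
message(sprintf("single-cell: %d genes x %d cells, BR shift planted in c1",
                nrow(sim$sce), ncol(sim$sce)))

sp <- simulate_spots(cfg)
write_counts_triplet(sp$sce, file.path(out, "spots"))
utils::write.csv(data.frame(spot = rownames(sp$scores), sp$scores),
                 file.path(out, "prediction_scores.csv"), row.names = FALSE)
utils::write.csv(data.frame(spot = rownames(sp$truth$weights), sp$truth$weights),
                 file.path(out, "spot_truth_weights.csv"), row.names = FALSE)
message(sprintf("spots: %d spots across %d capture areas", ncol(sp$sce),
                length(unique(SummarizedExperiment::colData(sp$sce)$capture_area))))

nuc <- simulate_nuclei(seed = seed)    # WT mean 1.0 / CV 0.2 vs mutant 1.3 / 0.35
write_csv_stamped(nuc$nuclei, file.path(out, "nuclei.csv"), seed = seed)
write_csv_stamped(nuc$truth, file.path(out, "nuclei_truth.csv"), seed = seed)
message(sprintf("reporter: %d nuclei across %d sepals", nrow(nuc$nuclei),
                length(unique(nuc$nuclei$sepal_id))))

gr <- simulate_growth(n_buds = 20, noise_sd = 0.02, seed = seed)
write_csv_stamped(gr$series, file.path(out, "areas.csv"), seed = seed)
message(sprintf("growth: %d buds, %d timepoints, 2%% measurement noise",
                length(unique(gr$series$bud_id)),
                length(unique(gr$series$time_h))))
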