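#!/usr/bin/env Rscript
# The central analysis: per-cell hormone-response gene-set transcript
# fractions, per-cluster genotype contrasts with a Bonferroni family counted
# from the inputs, dot statistics, star annotations, and directional
# hormone-signaling calls.

suppressMessages(library(sepalsig))
seed <- 1
out <- "results"

sce <- read_counts_triplet(file.path(out, "sc_filtered"))
sets <- read_csv_stamped(file.path("results/data", "hormone_sets.csv"))
scores <- score_cells(sce, sets)
meta <- SummarizedExperiment::colData(sce)
contrasts <- contrast_clusters(scores, meta$cluster, meta$genotype, alpha = 0.05)
write_csv_stamped(as.data.frame(contrasts), file.path(out, "contrasts.csv"),
                  seed = seed,
                  params = list(alpha = 0.05,
                                bonferroni = attr(contrasts, "bonferroni_threshold"),
                                star_family = attr(contrasts, "star_family")))
message(sprintf("contrasts: %d (cluster x set) rows; Bonferroni threshold %.3g (%d tests)",
                nrow(contrasts), attr(contrasts, "bonferroni_threshold"),
                nrow(contrasts)))
sig <- contrasts[contrasts$significant, ]
message(sprintf("significant rows: %d -> %s", nrow(sig),
                paste(sprintf("%s %s_%s (diff %+.2f, p %.2g)", sig$cluster,
                              sig$hormone, sig$direction, sig$diff, sig$p),
                      collapse = "; ")))

calls <- infer_directions(contrasts)
write_csv_stamped(calls, file.path(out, "direction_calls.csv"), seed = seed)
hits <- calls[calls$call != "inconclusive", ]
message(sprintf("signaling calls: %s",
                paste(sprintf("%s/%s: %s (%s)", hits$cluster, hits$hormone,
                              hits$call, hits$confidence), collapse = "; ")))
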