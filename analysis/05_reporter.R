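#!/usr/bin/env Rscript
# Ratiometric reporter quantification: per-nucleus BES1/H2B ratios rolled up
# to per-sepal mean and CV, compared between groups overall and by sepal
# position.

suppressMessages(library(sepalsig))
seed <- 1
out <- "results"

nuclei <- read_csv_stamped(file.path("results/data", "nuclei.csv"))
summ <- sepal_summary(nuclei, min_nuclei = 5)
write_csv_stamped(summ, file.path(out, "sepal_summaries.csv"), seed = seed,
                  params = list(min_nuclei = 5, sd = "sample (n-1)"))
by_group <- split(summ, summ$group)
for (g in names(by_group))
  message(sprintf("%s: %d sepals, mean ratio %.3f, mean CV %.3f", g,
                  nrow(by_group[[g]]), mean(by_group[[g]]$mean_ratio),
                  mean(by_group[[g]]$cv_ratio)))

cmp <- group_compare(summ, by = "position")
write_csv_stamped(cmp, file.path(out, "reporter_comparisons.csv"), seed = seed)
for (i in seq_len(nrow(cmp)))
  message(sprintf("%s / %s: p = %.3g", cmp$stratum[i], cmp$metric[i], cmp$p[i]))
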