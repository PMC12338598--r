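#!/usr/bin/env Rscript
# Growth coordination: per-interval absolute growth, each sepal's
# contribution to total bud growth, and outer/inner (two inners merged) and
# outer/lateral area ratios, compared with the exponential closed form.

suppressMessages(library(sepalsig))
seed <- 1
out <- "results"

series <- read_csv_stamped(file.path("results/data", "areas.csv"))
rec <- growth_records(series)
write_csv_stamped(rec$contributions, file.path(out, "growth_contributions.csv"),
                  seed = seed)
write_csv_stamped(rec$ratios, file.path(out, "area_ratios.csv"), seed = seed)

rates <- c(outer = 0.06, inner = 0.02, lateral1 = 0.03, lateral2 = 0.03)
a0 <- stats::setNames(rep(100, 4), names(rates))
expected <- exp_growth_contributions(rates, a0, 0, 12)
outer <- rec$contributions[rec$contributions$position == "outer" &
                             rec$contributions$t0 == 0, ]
message(sprintf("outer-sepal contribution over 0-12 h: %.1f%% (closed form %.1f%%) across %d buds",
                100 * mean(outer$contribution), 100 * expected[["outer"]],
                nrow(outer)))
oi <- rec$ratios[rec$ratios$ratio == "outer_inner", ]
by_t <- tapply(oi$value, oi$time_h, mean)
message(sprintf("mean outer/inner area ratio by timepoint: %s",
                paste(sprintf("%sh=%.2f", names(by_t), by_t), collapse = ", ")))
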