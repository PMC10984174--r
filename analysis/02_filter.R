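#!/usr/bin/env Rscript
# Stage 2 -- clean the raw GPS fixes.
#
# Pass order: coordinate blocklist, iterative >100 m/min speed filter,
# 15 m/min + 165-180 degree spike filter, removal of fixes stranded
# between removed neighbours, stationary-run collapse. With the truth
# labels from stage 1 we also report recall on injected artifacts and the
# false-removal rate on clean fixes.
suppressMessages(library(catroam))

cfg <- roam_config(rng_seed = 20210601L)
fixes <- read_fixes("results/data/fixes_raw.csv", cfg)
truth <- read.csv("results/data/truth_labels.csv")

res <- run_filter_pipeline(fixes, cfg)
write_fixes(res$fixes, "results/data/fixes_clean.csv")
rep <- res$report
write_results(rep[, setdiff(names(rep), "reasons")],
              "results/filter_report.csv", cfg)

# align truth labels with the reader's (animal_id, t) ordering
key <- function(id, t) paste(id, t)
m <- match(key(fixes$animal_id, format(fixes$t, "%Y-%m-%d %H:%M:%S")),
           key(truth$animal_id, truth$timestamp))
stopifnot(!anyNA(m))
labels <- truth$label[m]
reasons <- unlist(rep$reasons)
art <- labels %in% c("outlier", "spike")
cat(sprintf("retained %d of %d fixes\n", sum(rep$retained), sum(rep$input)))
cat(sprintf("artifact recall: %.1f%% of %d injected outliers/spikes removed\n",
            100 * mean(reasons[art] != "retained"), sum(art)))
cat(sprintf("false removal: %.2f%% of clean fixes\n",
            100 * mean(reasons[labels == "clean"] != "retained")))
cat(sprintf("stationary duplicates collapsed: %d\n", sum(rep$stationary)))
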