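#!/usr/bin/env Rscript
# 01: generate the synthetic multi-cohort study and record what was planted.
#
# Every later script re-creates the same dataset from the same seed, so no
# large intermediates are written; this script documents the design: probe
# manifest composition, sample-sheet sizes, and the planted truth table.

library(methpanel)

seed <- as.integer(Sys.getenv("METHPANEL_SEED", "1"))
out <- "results"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(seed = seed)
d <- simulate_dataset(cfg)

write.table(d$truth, file.path(out, "01_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

class_tab <- as.data.frame(table(class = d$truth$class))
write.table(class_tab, file.path(out, "01_planted_classes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

sizes <- do.call(rbind, lapply(names(d$cohorts), function(nm) {
  s <- d$cohorts[[nm]]$sheet
  data.frame(cohort = nm, as.data.frame(table(group = s$group)))
}))
sizes <- rbind(sizes,
               data.frame(cohort = "blood_ref", group = "blood",
                          Freq = ncol(d$blood$beta)))
write.table(sizes, file.path(out, "01_cohort_sizes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("seed %d: %d probes (%d CGI), %d planted non-null probes\n",
            seed, nrow(d$manifest), sum(d$manifest$in_cgi),
            sum(d$truth$class != "null")))
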