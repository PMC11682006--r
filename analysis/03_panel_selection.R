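#!/usr/bin/env Rscript
# 03: run the full selection cascade (blood filter, clock filter, branches
# A/B, union panel, disease exclusion, validation tumor fraction) and write
# the per-candidate ledger, stage funnel and BED export.

library(methpanel)

seed <- as.integer(Sys.getenv("METHPANEL_SEED", "1"))
out <- "results"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

d <- simulate_dataset(sim_config(seed = seed))
run <- run_pipeline(d)
print(run)

write_report(run$panel_records, file.path(out, "03_panel_records.tsv"),
             summary = c(unclass(run$cfg), as.list(run$funnel)))
write_panel_bed(run$panel, d$manifest, file.path(out, "03_panel.bed"))

funnel <- data.frame(stage = names(run$funnel),
                     probes = unname(run$funnel))
write.table(funnel, file.path(out, "03_funnel.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

in_panel <- run$panel_records[run$panel_records$in_panel, ]
cat(sprintf("panel: %d probes; disease-flagged: %d; mean validation tumor fraction: %.3f\n",
            nrow(in_panel), sum(in_panel$disease_flag, na.rm = TRUE),
            mean(in_panel$tumor_fraction, na.rm = TRUE)))
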