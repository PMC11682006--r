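#!/usr/bin/env Rscript
# 04: classify the selected panel's specificity across the simulated
# pan-cancer cohorts and write the specificity table plus the deterministic
# heatmap row/column ordering.

library(methpanel)

seed <- as.integer(Sys.getenv("METHPANEL_SEED", "1"))
out <- "results"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

d <- simulate_dataset(sim_config(seed = seed))
run <- run_pipeline(d)

spec <- run$specificity
spec$hyper_tumors <- vapply(spec$hyper_tumors, paste, "", collapse = ",")
spec$meth_tumor_only <- vapply(spec$meth_tumor_only, paste, "", collapse = ",")
spec$nt_methylated_tissues <- vapply(spec$nt_methylated_tissues, paste, "",
                                     collapse = ",")
write.table(spec, file.path(out, "04_specificity.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

summaries <- lapply(d$pan, function(coh)
  summarize_cohort(coh$beta, coh$sheet, coh$tissue_code))
ord <- heatmap_order(spec, summaries)
write.table(data.frame(axis = rep(c("probe", "tissue"),
                                  c(length(ord$probe_order),
                                    length(ord$tissue_order))),
                       id = c(ord$probe_order, ord$tissue_order)),
            file.path(out, "04_heatmap_order.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("panel specificity classes:\n")
print(table(run$specificity$class))
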