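#!/usr/bin/env Rscript
# 02: merge the discovery cohorts, restrict to CpG-island probes, and test
# tumor vs pooled non-tumoral liver for differential methylation.

library(methpanel)

seed <- as.integer(Sys.getenv("METHPANEL_SEED", "1"))
out <- "results"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

d <- simulate_dataset(sim_config(seed = seed))
merged <- merge_cohorts(lapply(d$cohorts, `[[`, "beta"),
                        lapply(d$cohorts, `[[`, "sheet"))
cgi <- cgi_subset(merged$beta, d$manifest)
dmc <- dmc_test(cgi, merged$sheet, case = "tumor",
                control = c("healthy", "cirrhotic", "adjacent"))

write.table(dmc[dmc$status != "ns", ], file.path(out, "02_dmc.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

enr <- global_hyper_enrichment(dmc)
qc <- cluster_qc(cgi[dmc$probe_id[dmc$status != "ns"], , drop = FALSE],
                 merged$sheet)
summ <- data.frame(
  probes_universe = nrow(merged$beta), probes_cgi = nrow(cgi),
  n_hyper = enr$n_hyper, n_hypo = enr$n_hypo,
  enrichment_p = enr$p, cluster_agreement = qc$agreement)
write.table(summ, file.path(out, "02_dmc_summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("hyper %d / hypo %d (binomial p = %.3g); DMC cluster agreement %.3f\n",
            enr$n_hyper, enr$n_hypo, enr$p, qc$agreement))
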