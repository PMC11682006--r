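#!/usr/bin/env Rscript
# 05: relate panel CpG location (promoter / gene body / intergenic) to
# host-gene expression change and tissue-level repression.

library(methpanel)

seed <- as.integer(Sys.getenv("METHPANEL_SEED", "1"))
out <- "results"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

d <- simulate_dataset(sim_config(seed = seed))
run <- run_pipeline(d)

conc <- run$concordance
write.table(conc, file.path(out, "05_concordance.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

xtab <- location_expression_table(conc)
write.table(xtab, file.path(out, "05_location_expression.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

genes <- unique(conc$gene[!is.na(conc$gene) & conc$gene != ""])
rep_tab <- data.frame(
  gene = genes,
  tissue_status = vapply(genes, tissue_repression, "", tpm = d$tpm))
write.table(rep_tab, file.path(out, "05_tissue_repression.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("concordance rate among coupled genes: %.3f\n",
            mean(conc$concordant, na.rm = TRUE)))
print(xtab)
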