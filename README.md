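# methpanel

Discovery of tumor-hypermethylated CpG marker panels from methylation-array
β-value matrices, with pan-cancer specificity classification and
methylation–expression concordance analysis. The package contains all the
computation; the numbered scripts under `analysis/` are thin narrative
drivers that run it on a seeded synthetic study and write result tables.

## Scientific problem

Solid tumors acquire focal DNA hypermethylation at CpG-island (CGI) loci
that are unmethylated in normal tissue. CpGs that are (i) strongly
hypermethylated in tumor, (ii) unmethylated in all relevant non-tumoral
tissues and in blood leukocytes, and (iii) not part of age-associated
methylation drift are candidates for sensitive, specific detection of tumor
DNA. `methpanel` implements the full in-silico funnel that selects such a
panel from multi-cohort array data and then characterizes it:

1. **Cohort merge** — β matrices from independent studies are merged over
   the probes complete in every cohort; sample ids are namespaced
   `cohort:sample`.
2. **CGI restriction** — only probes annotated to CpG islands are tested.
3. **Differential methylation** — per-CpG two-sample t test of tumor vs
   pooled non-tumoral liver (healthy, cirrhotic, tumor-adjacent);
   Δβ = mean β(tumor) − mean β(control). A CpG is a DMC when |Δβ| > 0.2
   and the Benjamini–Hochberg q-value < 0.05. Hypermethylated DMCs
   (Δβ > 0.2) continue.
4. **Blood filter** — a candidate is excluded if *any* blood reference
   sample has β > 0.2 there.
5. **Clock filter** — candidates on a 353-CpG aging-clock list are removed
   (the overlap is reported, never assumed).
6. **Two selection branches**:
   - **Branch A** (tumor-exclusive): β < 0.2 in *every* non-tumoral liver
     sample and Δβ(tumor − non-tumoral) > 0.3.
   - **Branch B** (premalignant-field): β < 0.2 in all healthy and
     cirrhotic samples, group mean β > 0.2 in both adjacent and tumor
     tissue, and Δβ(tumor − healthy+cirrhotic) > 0.4.
   The panel is the union; the summary criterion mean β(tumor) > 0.3 is
   verified per probe and reported as a flag.
7. **Disease exclusion** — panel probes with Δβ > 0.2 in any non-hepatic
   disease cohort are flagged.
8. **Validation** — the fraction of independent validation tumors with
   β > 0.2 per panel probe (descriptive; no filtering).
9. **Pan-cancer specificity** — across many tumor-type cohorts, a probe is
   called hypermethylated in a tissue when that cohort has more than 5
   non-tumoral controls and mean Δβ > 0.2. Probes hyper in ≥ 10 tumor
   types are `pan`; probes hyper only in the index tissue are
   `index_exclusive`; the rest `shared_k`. Tumor-only cohorts (no
   controls) can corroborate methylation but never enter the exclusivity
   call.
10. **Expression integration** — each panel CpG is assigned to promoter
    (TSS−1500..TSS+300, strand-oriented, promoter takes precedence),
    gene body, or intergenic. Host-gene differential expression on
    log2(CPM + 0.5) uses a Student t test when both groups pass a
    D'Agostino–Pearson K² normality test (α = 0.05), otherwise
    Mann–Whitney; calls at α = 0.001. Concordance = promoter CpG with
    down-regulation, or gene-body CpG with up-regulation.

## Synthetic data generator

`sim_config()` / `simulate_dataset()` produce a seeded synthetic study with
Beta-distributed β values and negative-binomial RNA-seq counts, planting
probe classes (branch-A and branch-B markers, blood-methylated decoys,
clock overlaps, disease-only, hypomethylated, pan-cancer and
index-exclusive probes) and returning a ground-truth table, so every stage
of the funnel can be checked against known answers without any downloads.

## Worked example

```r
library(methpanel)
d   <- simulate_dataset(sim_config(seed = 1))
run <- run_pipeline(d)
print(run)
#> Marker-discovery run
#> Stage funnel (probes):
#>   universe    20000
#>   cgi         6000
#>   hyper_dmc   102
#>   blood_pass  52
#>   clock_pass  42
#>   branch_a    30
#>   branch_b    12
#>   panel       42
#> Hyper vs hypo: 102 vs 100 (binomial p = 0.944)
table(run$specificity$class)        # all 42 panel probes index_exclusive
mean(run$concordance$concordant, na.rm = TRUE)  # 1.0 at seed 1
```

File-based runs are available through `run_pipeline_files()` with a YAML
config of input paths and an optional `thresholds:` block.

## Analysis workflow

```sh
Rscript analysis/01_simulate.R                   # design + truth tables
Rscript analysis/02_differential_methylation.R   # DMC table, enrichment, cluster QC
Rscript analysis/03_panel_selection.R            # funnel, ledger, BED export
Rscript analysis/04_pan_cancer.R                 # specificity + heatmap ordering
Rscript analysis/05_expression.R                 # concordance + tissue repression
```

Each script writes TSV tables to `results/` and is seeded through the
`METHPANEL_SEED` environment variable (default 1).

## Package layout

- `R/io.R` — readers/writers and validation for β matrices, sample
  sheets, manifests, clock lists; cohort merging; BED and report export.
- `R/dmc.R` — Δβ, t tests (vectorized), BH adjustment, DMC
  classification, CGI subset, enrichment and clustering QC.
- `R/panel.R` — thresholds object, blood/clock filters, branches A/B,
  panel union, disease exclusion, validation fraction.
- `R/pancancer.R` — cohort summaries, hypermethylation calls,
  specificity classes, heatmap ordering.
- `R/expression.R` — region classification, log-CPM, D'Agostino–Pearson
  K², expression status, concordance, tissue repression.
- `R/simulate.R` — the seeded synthetic-study generator.
- `R/pipeline.R` — end-to-end orchestration and the YAML file interface.
- `vignettes/methylation-panel-discovery.Rmd` — methods vignette.
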