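---
title: "Methods: discovery of tumor-hypermethylated CpG marker panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discovery of tumor-hypermethylated CpG marker panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methpanel)
```

This vignette documents the statistical model and procedure implemented by
`methpanel`, the rationale for each threshold, and what the synthetic-data
generator does and does not emulate. Empirical performance claims are made
only by the test suite and `scripts/acceptance.R`, which compute them; this
document explains the method.

## Data model

The unit of measurement is the per-CpG methylation fraction
β ∈ [0, 1] from a methylation array, arranged as a probes × samples
matrix with a sample sheet assigning each sample a cohort and a group in
{tumor, adjacent, cirrhotic, healthy, blood, disease}. All effect sizes
are differences of group means, Δβ = mean β(case) − mean β(control).
Following the common array convention, a locus is read as *unmethylated*
when β < 0.2 and *methylated* when β > 0.2; these two cut points are
deliberately the same number used strictly on either side, so β = 0.2 is
neither.

## Cohort merging

`merge_cohorts()` intersects the probe sets of the input cohorts and keeps
only probes with complete data in every cohort (the default
`max_missing_frac = 0`). Probe order follows the first cohort. Sample ids
are namespaced `cohort:sample` to prevent collisions; the operation is
idempotent, so already-prefixed ids are not re-prefixed.

## Differential methylation

`dmc_test()` performs a per-probe two-sample t test of tumor against the
pooled non-tumoral livers (healthy, cirrhotic, tumor-adjacent). The
default is the equal-variance Student test; Welch is available via
`var_equal = FALSE`. Probes with zero variance in both groups get p = 1
when the means are equal and p = 0 otherwise, and are flagged
(`zero_var`). P values are adjusted by Benjamini–Hochberg step-up
(`bh_adjust()`, a thin exported wrapper over `stats::p.adjust` so the
surface is testable against an independent brute-force oracle). A probe is
a differentially methylated CpG (DMC) when |Δβ| > 0.2 and q < 0.05, split
into `hyper` (Δβ > 0.2) and `hypo`.

`global_hyper_enrichment()` asks whether hyper calls outnumber hypo calls
beyond chance with an exact two-sided binomial test against p = 1/2 —
i.e. under the null each DMC is equally likely to fall on either side.
`cluster_qc()` offers a descriptive check that Ward (ward.D2) hierarchical
clustering of samples over the DMCs separates tumor from non-tumor.

## Selection cascade

All thresholds live in a single validated object, `filter_config()`:

| threshold | default | role |
|---|---|---|
| `unmeth_thresh` | 0.2 | "unmethylated" read-out (strict `<`) |
| `meth_thresh` | 0.2 | "methylated" read-out (strict `>`) |
| `delta_thresh` | 0.2 | DMC and disease-exclusion effect size |
| `fdr_thresh` | 0.05 | BH q cut |
| `branch_a_delta` | 0.3 | branch-A effect size |
| `branch_b_delta` | 0.4 | branch-B effect size |
| `panel_tumor_beta` | 0.3 | panel summary criterion |

The funnel after the DMC stage:

- **Blood filter**: a candidate is excluded if *any* blood sample exceeds
  β = 0.2 at it. The per-sample maximum (not a group mean) is used because
  a single methylated leukocyte population would contaminate a blood-based
  assay.
- **Clock filter**: candidates appearing on a supplied 353-probe
  aging-clock list are removed. The overlap is computed from the list, not
  assumed.
- **Branch A** (tumor-exclusive markers): β < `unmeth_thresh` in **every**
  individual non-tumoral liver sample (healthy, cirrhotic and adjacent)
  and Δβ(tumor − non-tumoral) > 0.3.
- **Branch B** (premalignant-field markers): β < `unmeth_thresh` in all
  healthy and cirrhotic samples, adjacent and tumor groups methylated
  (group mean > `meth_thresh`; per-sample `all`/`fraction` variants are
  available via `branch_b_adjacent`), and Δβ(tumor − healthy+cirrhotic)
  > 0.4. Branch B deliberately reads adjacent-tissue methylation as a
  group mean by default: field-effect methylation is partial and
  heterogeneous, so requiring every adjacent sample to be methylated
  would empty the branch.
- **Panel**: the union of the branches. When `unmeth_thresh ≤
  meth_thresh` the branches are provably disjoint (branch A requires all
  adjacent samples unmethylated, branch B requires the adjacent mean
  methylated). `combine_panel()` additionally verifies the summary
  criterion mean β(tumor) > `panel_tumor_beta` per probe and reports it as
  a `summary_ok` flag rather than silently filtering, because the union
  definition and the summary criterion are distinct statements that can
  disagree.
- **Disease exclusion**: a panel probe is flagged when Δβ(disease −
  cohort-internal controls) > 0.2 in any non-hepatic disease cohort.
- **Validation**: the fraction of independent tumor samples with β >
  `meth_thresh` per panel probe, a descriptive penetrance estimate; no
  probe is removed at this stage.

## Pan-cancer specificity

`summarize_cohort()` reduces each tumor-type cohort to per-probe tumor and
non-tumoral means. A cohort supports hypermethylation *calls* only when it
has **more than 5** non-tumoral controls (strict). For such paired
cohorts, a probe is called hyper in that tissue when mean Δβ > 0.2 — an
effect-size rule, not a significance test, because cross-cohort sample
sizes vary wildly and the classification should not reward big cohorts.
Cohorts without controls can only *corroborate* tumor methylation (mean
β(tumor) > 0.2); they never enter the exclusivity call. Classes:
`pan` (hyper in ≥ 10 tumor types), `index_exclusive` (hyper **only** in
the index tissue), else `shared_k`. `heatmap_order()` gives the
deterministic display ordering: probes by descending number of hyper
tissues, tissues by descending probe support, lexicographic ties.

## Expression integration

`classify_region()` assigns each CpG to `promoter` (TSS−1500..TSS+300,
strand-oriented, closed interval), `gene_body`, or `intergenic`; promoter
takes precedence where the windows overlap. Expression uses
log2(CPM + 0.5). A gene is `not_expressed` when median CPM < 1 in both
groups. Otherwise differential expression is tested with a Student t test
when both groups pass a D'Agostino–Pearson K² normality check at α = 0.05,
falling back to Mann–Whitney; the differential call itself uses α = 0.001.
The K² statistic (D'Agostino's skewness z combined with the
Anscombe–Glynn kurtosis z, referred to χ²(2)) is implemented in the
package because no installed R package provides it; the implementation is
pinned in the tests against reference values from an independent
implementation. Groups smaller than 8 cannot support the kurtosis
approximation and fall back to Mann–Whitney with a warning.

Concordance is the classical repression logic: a promoter CpG is
concordant with *down*-regulation, a gene-body CpG with *up*-regulation;
intergenic CpGs and unchanged/not-expressed genes yield `NA`.
`tissue_repression()` classifies a gene across a normal-tissue TPM panel
as `broadly_silent` (median TPM < 1 everywhere), `repressed_in_index`
(index tissue < 1 TPM and < 0.25× the median of other tissues), else
`expressed_in_index`.

## Synthetic study generator

`simulate_dataset(sim_config(seed))` builds a complete study: two
discovery cohorts (one with healthy and cirrhotic controls, one with
adjacent tissue), a blood reference, a non-hepatic disease cohort, a
large validation tumor cohort, 27 pan-cancer cohorts (14 with paired
controls, 13 tumor-only), RNA-seq counts for tumor/adjacent pairs, and a
normal-tissue TPM panel — plus the ground-truth table of what was
planted.

β values are Beta-distributed: baseline Beta(2, 38) (mean 0.05),
methylated Beta(30, 10) (mean 0.75), branch-B adjacent tissue
Beta(14, 26) (mean 0.35). The unmethylated groups of *planted marker*
probes use the tighter Beta(8, 152) (same mean 0.05): under Beta(2, 38)
a single sample exceeds β = 0.2 with probability ≈ 0.0018, so across 50
non-tumoral samples roughly 8–9% of true markers would fail the strict
all-samples-unmethylated clause purely by baseline noise. Real marker
CpGs are selected precisely for tight, low baselines, so the tighter
shape is the realistic choice — and it is a property of the generator's
truth, not a tuning of the method. Counts are negative binomial
(mean 200, dispersion 0.1) with a two-fold coupling: promoter-marker
genes are halved in tumor, gene-body-marker genes doubled; a configured
fraction of genes is silent. Validation tumors methylate each panel probe
with penetrance 0.7. Planted pan-cancer probes are hypermethylated in 11
paired cohorts; index-exclusive probes only in the index tissue.

The generator emulates the *statistical structure* of such a study —
group separations, strict-threshold edge behavior, decoy classes
(blood-methylated, clock-overlap, disease-only, hypomethylated), coupling
of methylation location to expression direction. It does not emulate
genomic sequence context, probe cross-reactivity, batch effects, tumor
purity gradients, or within-gene correlation of CpGs.

## Problem sizes and determinism

Default sizes: 20,000 probes (30% CGI), 100 discovery tumors split
across the two cohorts, 30 adjacent, 10 cirrhotic, 10 healthy, 200 blood,
500 validation tumors, and 20 tumor / 8 control samples per pan-cancer
cohort. Everything is a deterministic function of `sim_config(seed)`;
cohort simulation and count simulation use derived seeds (`seed + 1`,
`seed + 2`) so each component is independently reproducible. All seeds
stay below 2^31.

## Limitations

- Significance in the DMC stage assumes approximately normal β within
  groups; for strongly bimodal probes the t test is conservative in the
  middle and anticonservative in the tails. M-value transformation is a
  standard alternative not implemented here.
- The binomial enrichment test treats DMCs as independent; neighboring
  CpGs are correlated in real arrays, so its p value is optimistic there.
- The pan-cancer hyper call is an effect-size rule without uncertainty;
  cohorts barely above the 5-control minimum yield noisy non-tumoral
  means.
- Expression concordance is association, not causality; the generator
  plants the causal direction by construction.
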