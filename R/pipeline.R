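# End-to-end orchestration: merge -> CGI restriction -> differential
# methylation -> blood filter -> clock filter -> selection branches ->
# panel -> disease check -> validation tumor fraction -> pan-cancer
# specificity -> expression concordance, with a stage-count funnel.

#' Run the complete marker-discovery pipeline
#'
#' Stage order is fixed: cohort merge, CGI restriction, differential
#' methylation (tumor vs pooled non-tumoral livers), exclusion of
#' blood-methylated and clock CpGs, the two selection branches and their
#' union, then (when inputs are present) the liver-disease specificity
#' check, the validation tumor-methylation fraction, pan-cancer
#' classification and expression concordance.
#'
#' @param data List with elements `cohorts` (list of `list(beta, sheet)`),
#'   `manifest`, `blood` (`list(beta, sheet)`), `clock` (probe ids), and
#'   optionally `disease`, `validation`, `pan`, `counts`, `counts_sheet`,
#'   `tpm` — the shape returned by [simulate_dataset()].
#' @param cfg [filter_config()].
#' @param index_tissue,pan_min Passed to [specificity_table()].
#' @param expr_alpha Significance level for [expression_status()] calls.
#' @return List of class `meth_panel_run`: `funnel` (named stage counts),
#'   `dmc` (full DMC table), `panel_records` (per-candidate ledger),
#'   `panel` (final probe ids), `specificity`, `concordance`,
#'   `enrichment`, `cfg`.
#' @export
run_pipeline <- function(data, cfg = filter_config(), index_tissue = "LIHC",
                         pan_min = 10, expr_alpha = 0.001) {
  merged <- merge_cohorts(lapply(data$cohorts, `[[`, "beta"),
                          lapply(data$cohorts, `[[`, "sheet"))
  beta <- merged$beta; sheet <- merged$sheet
  cgi <- cgi_subset(beta, data$manifest)
  dmc <- dmc_test(cgi, sheet, case = "tumor",
                  control = c("healthy", "cirrhotic", "adjacent"),
                  delta_thresh = cfg$delta_thresh,
                  fdr_thresh = cfg$fdr_thresh)
  enrichment <- tryCatch(global_hyper_enrichment(dmc), error = function(e) NULL)
  hyper <- dmc$probe_id[dmc$status == "hyper"]
  blood_pass <- blood_filter(hyper, data$blood$beta, cfg$meth_thresh)
  ck <- clock_filter(blood_pass, data$clock)
  a <- branch_a(ck$retained, beta, sheet, cfg)
  b <- branch_b(ck$retained, beta, sheet, cfg)
  panel_df <- combine_panel(a, b, beta, sheet, cfg)
  panel <- panel_df$probe_id

  disease_flag <- NULL
  if (!is.null(data$disease) && length(panel))
    disease_flag <- disease_exclusion_check(panel, data$disease, cfg)
  tumor_frac <- NULL
  if (!is.null(data$validation) && length(panel))
    tumor_frac <- tumor_methylation_fraction(panel, data$validation,
                                             cfg$meth_thresh)

  # per-candidate ledger over all significant hypermethylated CpGs
  max_blood <- if (length(hyper) == 0) numeric(0) else
    apply(data$blood$beta[hyper, , drop = FALSE], 1, max)
  delta_hcc <- dmc$delta[match(hyper, dmc$probe_id)]
  records <- data.frame(
    probe_id = hyper,
    pass_blood = hyper %in% blood_pass,
    pass_clock = hyper %in% ck$retained,
    branch_a = hyper %in% a,
    branch_b = hyper %in% b,
    in_panel = hyper %in% panel,
    max_blood_beta = max_blood,
    delta_hcc = delta_hcc,
    disease_flag = if (is.null(disease_flag)) rep(NA, length(hyper)) else
      unname(disease_flag[match(hyper, names(disease_flag))]),
    tumor_fraction = if (is.null(tumor_frac)) rep(NA_real_, length(hyper)) else
      unname(tumor_frac[match(hyper, names(tumor_frac))]),
    summary_ok = panel_df$summary_ok[match(hyper, panel_df$probe_id)],
    row.names = NULL, stringsAsFactors = FALSE)

  specificity <- NULL
  if (!is.null(data$pan) && length(panel)) {
    summaries <- lapply(data$pan, function(coh)
      summarize_cohort(coh$beta, coh$sheet, coh$tissue_code))
    specificity <- specificity_table(summaries, panel,
                                     index_tissue = index_tissue,
                                     pan_min = pan_min,
                                     delta_thresh = cfg$delta_thresh,
                                     meth_thresh = cfg$meth_thresh)
  }

  conc <- NULL
  if (!is.null(data$counts) && length(panel))
    conc <- concordance_table(panel, data$manifest, data$counts,
                              data$counts_sheet, alpha = expr_alpha)

  funnel <- c(universe = nrow(beta), cgi = nrow(cgi),
              hyper_dmc = length(hyper), blood_pass = length(blood_pass),
              clock_pass = length(ck$retained), branch_a = length(a),
              branch_b = length(b), panel = length(panel))
  structure(list(funnel = funnel, dmc = dmc, panel_records = records,
                 panel = panel, clock_overlap = ck$overlap,
                 specificity = specificity, concordance = conc,
                 enrichment = enrichment, cfg = cfg),
            class = "meth_panel_run")
}

#' @export
print.meth_panel_run <- function(x, ...) {
  cat("Marker-discovery run\n")
  cat("Stage funnel (probes):\n")
  for (s in names(x$funnel))
    cat(sprintf("  %-11s %d\n", s, x$funnel[[s]]))
  if (!is.null(x$enrichment))
    cat(sprintf("Hyper vs hypo: %d vs %d (binomial p = %.3g)\n",
                x$enrichment$n_hyper, x$enrichment$n_hypo, x$enrichment$p))
  invisible(x)
}

#' Read a pipeline run configuration from YAML
#'
#' The YAML holds input paths (`beta`/`sheet` pairs under `cohorts`, plus
#' `blood_beta`, `blood_sheet`, `clock`, `manifest`, ...) and an optional
#' `thresholds` block overriding [filter_config()] defaults.
#'
#' @param path YAML file.
#' @return List with `inputs` and `cfg`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  thr <- raw$thresholds
  cfg <- do.call(filter_config, if (is.null(thr)) list() else thr)
  list(inputs = raw, cfg = cfg)
}

#' Run the pipeline from a YAML configuration of file paths
#'
#' Thin file-based wrapper over [run_pipeline()]: loads each input named in
#' the YAML, executes the pipeline, and writes the panel ledger, BED export
#' and JSON funnel summary to `out_dir`.
#'
#' @param path YAML config (see [read_run_config()]).
#' @param out_dir Output directory.
#' @return The [run_pipeline()] result, invisibly.
#' @export
run_pipeline_files <- function(path, out_dir) {
  rc <- read_run_config(path)
  inp <- rc$inputs
  load_cohort <- function(x)
    list(beta = read_beta_matrix(x$beta), sheet = read_sample_sheet(x$sheet))
  data <- list(
    cohorts = lapply(inp$cohorts, load_cohort),
    manifest = read_manifest(inp$manifest),
    blood = load_cohort(list(beta = inp$blood_beta, sheet = inp$blood_sheet)),
    clock = read_clock_list(inp$clock),
    disease = if (!is.null(inp$disease)) lapply(inp$disease, load_cohort),
    validation = if (!is.null(inp$validation))
      lapply(inp$validation, load_cohort))
  run <- run_pipeline(data, rc$cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_report(run$panel_records, file.path(out_dir, "panel_records.tsv"),
               summary = c(unclass(run$cfg), as.list(run$funnel)))
  write_panel_bed(run$panel, data$manifest, file.path(out_dir, "panel.bed"))
  invisible(run)
}
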