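# Pan-cancer specificity: summarise each tumor-type cohort, count baseline
# non-tumoral methylation, call per-tissue hypermethylation, classify each
# probe as index-exclusive / shared / pan-cancer, and order heatmap axes.

#' Summarise one tumor-type cohort
#'
#' Computes per-probe tumor and non-tumor group means and records whether
#' the cohort carries enough non-tumoral (peritumoral) samples to support a
#' differential call: `has_controls` requires strictly more than
#' `min_controls` non-tumoral samples.
#'
#' @param beta Cohort beta matrix.
#' @param sheet Cohort sample sheet; non-tumor groups (adjacent, healthy,
#'   cirrhotic) form the control side.
#' @param tissue_code Tissue/tumor-type code (e.g. "LIHC", "CHOL").
#' @param min_controls Control-count threshold; cohorts with more than this
#'   many non-tumoral samples are control-bearing (default 5).
#' @return List of class `tumor_cohort_summary`: `tissue_code`,
#'   `has_controls`, `mean_beta_nt` (NULL when control-poor), `mean_beta_t`,
#'   `n_nt`, `n_t`.
#' @export
summarize_cohort <- function(beta, sheet, tissue_code, min_controls = 5) {
  t_ids <- sheet$sample_id[sheet$group == "tumor"]
  if (length(t_ids) == 0) stop("cohort ", tissue_code, " has no tumor samples")
  nt_ids <- sheet$sample_id[sheet$group %in% c("adjacent", "healthy", "cirrhotic")]
  has_controls <- length(nt_ids) > min_controls
  structure(list(
    tissue_code = tissue_code,
    has_controls = has_controls,
    mean_beta_nt = if (has_controls)
      rowMeans(beta[, nt_ids, drop = FALSE]) else NULL,
    mean_beta_t = rowMeans(beta[, t_ids, drop = FALSE]),
    n_nt = length(nt_ids),
    n_t = length(t_ids)), class = "tumor_cohort_summary")
}

#' Count tissues whose non-tumoral baseline is methylated at a probe
#'
#' Counted over control-bearing cohorts only.
#'
#' @param summaries List of [summarize_cohort()] results.
#' @param probe Probe id.
#' @param meth_thresh Methylation threshold on the NT mean (default 0.2).
#' @return Integer count.
#' @export
baseline_tissue_status <- function(summaries, probe, meth_thresh = 0.2) {
  paired <- Filter(function(s) s$has_controls, summaries)
  if (length(paired) == 0) stop("no control-bearing cohorts")
  sum(vapply(paired, function(s) s$mean_beta_nt[[probe]] > meth_thresh,
             logical(1)))
}

#' Per-probe hypermethylation calls across tumor-type cohorts
#'
#' Control-bearing cohorts contribute to `hyper_tumors` when the mean
#' tumor-minus-control difference exceeds `delta_thresh`; tumor-only cohorts
#' can only corroborate methylation (`meth_tumor_only`, tumor mean >
#' `meth_thresh`) and never enter exclusivity decisions.
#'
#' @param summaries List of [summarize_cohort()] results.
#' @param probe Probe id.
#' @param delta_thresh Mean-difference threshold for paired cohorts (0.2).
#' @param meth_thresh Methylation threshold for tumor-only cohorts (0.2).
#' @return List with character vectors `hyper_tumors` and `meth_tumor_only`.
#' @export
hyper_calls <- function(summaries, probe, delta_thresh = 0.2,
                        meth_thresh = 0.2) {
  hyper <- character(0); meth_only <- character(0)
  for (s in summaries) {
    if (s$has_controls) {
      if (s$mean_beta_t[[probe]] - s$mean_beta_nt[[probe]] > delta_thresh)
        hyper <- c(hyper, s$tissue_code)
    } else if (s$mean_beta_t[[probe]] > meth_thresh) {
      meth_only <- c(meth_only, s$tissue_code)
    }
  }
  list(hyper_tumors = hyper, meth_tumor_only = meth_only)
}

#' Classify a probe's tumor-type specificity
#'
#' @param hyper_tumors Tissue codes with a hypermethylation call (paired
#'   cohorts only).
#' @param index_tissue The index tumor type (default "LIHC").
#' @param pan_min Minimum number of hyper tumor types for the pan-cancer
#'   class (default 10).
#' @return "pan" when `length(hyper_tumors) >= pan_min`; "index_exclusive"
#'   when the only hyper call is the index tissue; otherwise
#'   `"shared_<k>"` with k the number of hyper tumor types.
#' @export
classify_specificity <- function(hyper_tumors, index_tissue = "LIHC",
                                 pan_min = 10) {
  k <- length(unique(hyper_tumors))
  if (k >= pan_min) return("pan")
  if (k == 1 && unique(hyper_tumors) == index_tissue) return("index_exclusive")
  paste0("shared_", k)
}

#' Specificity calls for a set of probes across tumor-type cohorts
#'
#' Convenience wrapper assembling [baseline_tissue_status()],
#' [hyper_calls()] and [classify_specificity()] into one table.
#'
#' @param summaries List of [summarize_cohort()] results; the index tissue
#'   must be among the control-bearing cohorts.
#' @param probes Probe ids.
#' @inheritParams classify_specificity
#' @inheritParams hyper_calls
#' @return data.frame: `probe_id`, `nt_methylated_tissues`, `n_hyper_tumors`,
#'   `hyper_tumors` / `meth_tumor_only` (comma-joined codes), `class`.
#' @export
specificity_table <- function(summaries, probes, index_tissue = "LIHC",
                              pan_min = 10, delta_thresh = 0.2,
                              meth_thresh = 0.2) {
  paired_codes <- vapply(Filter(function(s) s$has_controls, summaries),
                         function(s) s$tissue_code, character(1))
  if (!index_tissue %in% paired_codes)
    stop("index tissue ", index_tissue, " is not a control-bearing cohort")
  rows <- lapply(probes, function(p) {
    calls <- hyper_calls(summaries, p, delta_thresh, meth_thresh)
    data.frame(
      probe_id = p,
      nt_methylated_tissues = baseline_tissue_status(summaries, p, meth_thresh),
      n_hyper_tumors = length(calls$hyper_tumors),
      hyper_tumors = paste(sort(calls$hyper_tumors), collapse = ","),
      meth_tumor_only = paste(sort(calls$meth_tumor_only), collapse = ","),
      class = classify_specificity(calls$hyper_tumors, index_tissue, pan_min),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Deterministic heatmap ordering of probes and tissues
#'
#' Probes are ranked by the number of tumor types with a hypermethylation
#' call (most to least); control-bearing tissues by the number of
#' hypermethylated panel CpGs (most to least). Ties break lexicographically.
#'
#' @param calls data.frame from [specificity_table()].
#' @param summaries List of [summarize_cohort()] results.
#' @return List with `probe_order` and `tissue_order` character vectors.
#' @export
heatmap_order <- function(calls, summaries) {
  probe_order <- calls$probe_id[order(-calls$n_hyper_tumors, calls$probe_id)]
  paired <- Filter(function(s) s$has_controls, summaries)
  codes <- vapply(paired, function(s) s$tissue_code, character(1))
  hyper_sets <- strsplit(calls$hyper_tumors, ",", fixed = TRUE)
  counts <- vapply(codes, function(code)
    sum(vapply(hyper_sets, function(h) code %in% h, logical(1))), integer(1))
  list(probe_order = probe_order,
       tissue_order = codes[order(-counts, codes)])
}
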