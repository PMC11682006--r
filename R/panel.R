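# Panel selection: blood and clock exclusion filters, the two selection
# branches, their union with the summary-criterion verification, the
# liver-disease specificity check, and the validation tumor-fraction.

#' Threshold configuration for panel selection
#'
#' All beta thresholds are strict inequalities: a CpG is unmethylated when
#' beta < `unmeth_thresh` and methylated when beta > `meth_thresh`.
#'
#' @param unmeth_thresh Beta below which a CpG counts as unmethylated (0.2).
#' @param meth_thresh Beta above which a CpG counts as methylated (0.2).
#' @param branch_a_delta Minimum tumor-vs-all-non-tumoral delta for branch A (0.3).
#' @param branch_b_delta Minimum tumor-vs-tumor-free-liver delta for branch B (0.4).
#' @param panel_tumor_beta Tumor mean beta the final panel must exceed (0.3).
#' @param delta_thresh Differential-methylation delta threshold (0.2).
#' @param fdr_thresh BH FDR threshold (0.05).
#' @param branch_b_adjacent One of "mean", "all", "fraction": how "methylated
#'   in adjacent tissue" is judged in branch B (default group mean).
#' @param branch_b_adjacent_frac Fraction of adjacent samples that must be
#'   methylated when `branch_b_adjacent = "fraction"`.
#' @return List of class `filter_config`.
#' @export
filter_config <- function(unmeth_thresh = 0.2, meth_thresh = 0.2,
                          branch_a_delta = 0.3, branch_b_delta = 0.4,
                          panel_tumor_beta = 0.3, delta_thresh = 0.2,
                          fdr_thresh = 0.05,
                          branch_b_adjacent = c("mean", "all", "fraction"),
                          branch_b_adjacent_frac = 0.5) {
  vals <- c(unmeth_thresh, meth_thresh, branch_a_delta, branch_b_delta,
            panel_tumor_beta, delta_thresh)
  if (any(vals <= 0 | vals >= 1)) stop("all beta thresholds must lie in (0, 1)")
  if (fdr_thresh < 0 || fdr_thresh > 1) stop("fdr_thresh must lie in [0, 1]")
  structure(list(unmeth_thresh = unmeth_thresh, meth_thresh = meth_thresh,
                 branch_a_delta = branch_a_delta,
                 branch_b_delta = branch_b_delta,
                 panel_tumor_beta = panel_tumor_beta,
                 delta_thresh = delta_thresh, fdr_thresh = fdr_thresh,
                 branch_b_adjacent = match.arg(branch_b_adjacent),
                 branch_b_adjacent_frac = branch_b_adjacent_frac),
            class = "filter_config")
}

#' Exclude CpGs methylated in any blood sample
#'
#' A candidate is retained only if no blood sample exceeds `meth_thresh`
#' (strict: beta exactly at the threshold does not exclude).
#'
#' @param candidates Character vector of probe ids.
#' @param blood Beta matrix of whole-blood samples covering all candidates.
#' @param meth_thresh Methylation threshold (default 0.2).
#' @return Retained probe ids (original order).
#' @export
blood_filter <- function(candidates, blood, meth_thresh = 0.2) {
  missing <- setdiff(candidates, rownames(blood))
  if (length(missing))
    stop("candidates absent from blood matrix: ",
         paste(missing, collapse = ", "))
  if (length(candidates) == 0) return(character(0))
  maxb <- apply(blood[candidates, , drop = FALSE], 1, max, na.rm = TRUE)
  candidates[!(maxb > meth_thresh)]
}

#' Exclude epigenetic-clock CpGs
#'
#' @param candidates Character vector of probe ids.
#' @param clock Character vector of clock probe ids.
#' @return List with `retained` (candidates minus clock, order kept) and
#'   `overlap` (candidates that are clock probes) — the overlap is reported
#'   rather than assumed empty.
#' @export
clock_filter <- function(candidates, clock) {
  overlap <- candidates[candidates %in% clock]
  list(retained = candidates[!candidates %in% clock], overlap = overlap)
}

.branch_groups <- function(sheet, groups) {
  for (g in groups) {
    if (!any(sheet$group == g)) stop("required group missing: ", g)
  }
  invisible(TRUE)
}

#' Branch A: unmethylated in every non-tumoral sample, strongly gained in tumor
#'
#' Selects candidates with beta < `unmeth_thresh` in every healthy,
#' cirrhotic and adjacent sample and a tumor-minus-non-tumoral mean
#' difference > `branch_a_delta`.
#'
#' @param candidates Probe ids (already blood- and clock-filtered).
#' @param beta Merged beta matrix.
#' @param sheet Sample sheet with tumor, adjacent, cirrhotic, healthy groups.
#' @param cfg [filter_config()].
#' @return Selected probe ids.
#' @export
branch_a <- function(candidates, beta, sheet, cfg = filter_config()) {
  .branch_groups(sheet, c("tumor", "adjacent", "cirrhotic", "healthy"))
  if (length(candidates) == 0) return(character(0))
  nt_ids <- .samples_in_groups(sheet, c("healthy", "cirrhotic", "adjacent"))
  t_ids <- .samples_in_groups(sheet, "tumor")
  x <- beta[candidates, , drop = FALSE]
  all_unmeth <- apply(x[, nt_ids, drop = FALSE] < cfg$unmeth_thresh, 1, all)
  delta <- rowMeans(x[, t_ids, drop = FALSE]) -
    rowMeans(x[, nt_ids, drop = FALSE])
  candidates[all_unmeth & delta > cfg$branch_a_delta]
}

#' Branch B: unmethylated in tumor-free livers, methylated in adjacent tissue
#' and tumor
#'
#' Selects candidates with beta < `unmeth_thresh` in every healthy and
#' cirrhotic sample, methylated (by default: group mean > `meth_thresh`) in
#' both adjacent tissue and tumor, and a tumor-minus-tumor-free-liver mean
#' difference > `branch_b_delta`. These are field-effect markers: gained in
#' peritumoral tissue as well as in the tumor.
#'
#' @inheritParams branch_a
#' @return Selected probe ids.
#' @export
branch_b <- function(candidates, beta, sheet, cfg = filter_config()) {
  .branch_groups(sheet, c("tumor", "adjacent", "cirrhotic", "healthy"))
  if (length(candidates) == 0) return(character(0))
  free_ids <- .samples_in_groups(sheet, c("healthy", "cirrhotic"))
  adj_ids <- .samples_in_groups(sheet, "adjacent")
  t_ids <- .samples_in_groups(sheet, "tumor")
  x <- beta[candidates, , drop = FALSE]
  all_unmeth <- apply(x[, free_ids, drop = FALSE] < cfg$unmeth_thresh, 1, all)
  meth_in <- function(cols) {
    sub <- x[, cols, drop = FALSE]
    switch(cfg$branch_b_adjacent,
           mean = rowMeans(sub) > cfg$meth_thresh,
           all = apply(sub > cfg$meth_thresh, 1, all),
           fraction = rowMeans(sub > cfg$meth_thresh) >= cfg$branch_b_adjacent_frac)
  }
  delta <- rowMeans(x[, t_ids, drop = FALSE]) -
    rowMeans(x[, free_ids, drop = FALSE])
  candidates[all_unmeth & meth_in(adj_ids) & meth_in(t_ids) &
               delta > cfg$branch_b_delta]
}

#' Combine the two selection branches into the final panel
#'
#' The panel is the union of branch A and branch B. Each member is also
#' checked against the summary criterion (tumor group mean beta >
#' `panel_tumor_beta`; healthy and cirrhotic group means < `unmeth_thresh`);
#' failures are flagged (`summary_ok = FALSE`), not removed — the union and
#' the summary rule are both reported so discrepancies are visible.
#'
#' @param a,b Probe ids selected by [branch_a()] and [branch_b()].
#' @param beta Merged beta matrix.
#' @param sheet Sample sheet.
#' @param cfg [filter_config()].
#' @return data.frame with `probe_id`, `branch_a`, `branch_b`, `in_panel`,
#'   `summary_ok`.
#' @export
combine_panel <- function(a, b, beta, sheet, cfg = filter_config()) {
  both <- intersect(a, b)
  if (length(both))
    warning("probes selected by both branches (branches should be exclusive): ",
            paste(both, collapse = ", "))
  panel <- union(a, b)
  if (length(panel) == 0) {
    return(data.frame(probe_id = character(0), branch_a = logical(0),
                      branch_b = logical(0), in_panel = logical(0),
                      summary_ok = logical(0), stringsAsFactors = FALSE))
  }
  t_mean <- group_mean_beta(beta[panel, , drop = FALSE], sheet, "tumor")
  h_mean <- group_mean_beta(beta[panel, , drop = FALSE], sheet, "healthy")
  c_mean <- group_mean_beta(beta[panel, , drop = FALSE], sheet, "cirrhotic")
  data.frame(probe_id = panel,
             branch_a = panel %in% a,
             branch_b = panel %in% b,
             in_panel = TRUE,
             summary_ok = t_mean > cfg$panel_tumor_beta &
               h_mean < cfg$unmeth_thresh & c_mean < cfg$unmeth_thresh,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Flag panel CpGs hypermethylated in non-tumor liver disease
#'
#' For each disease cohort the per-probe delta (disease group mean minus
#' in-cohort control mean) is computed; a probe is flagged when the delta
#' exceeds `cfg$delta_thresh` in any cohort. Controls within a cohort are
#' its healthy / cirrhotic / adjacent samples.
#'
#' @param panel Probe ids.
#' @param disease_cohorts List of `list(beta = , sheet = )` cohorts, each
#'   containing a disease group and at least one control group.
#' @param cfg [filter_config()].
#' @return Named logical vector (TRUE = hypermethylated in some disease cohort).
#' @export
disease_exclusion_check <- function(panel, disease_cohorts,
                                    cfg = filter_config()) {
  flags <- stats::setNames(rep(FALSE, length(panel)), panel)
  for (cohort in disease_cohorts) {
    sheet <- cohort$sheet
    ctrl_groups <- intersect(c("healthy", "cirrhotic", "adjacent"),
                             unique(sheet$group))
    if (length(ctrl_groups) == 0)
      stop("disease cohort has no control group")
    d_mean <- group_mean_beta(cohort$beta[panel, , drop = FALSE], sheet,
                              "disease")
    c_mean <- group_mean_beta(cohort$beta[panel, , drop = FALSE], sheet,
                              ctrl_groups)
    flags <- flags | (d_mean - c_mean > cfg$delta_thresh)
  }
  flags
}

#' Fraction of validation tumors methylated at each panel CpG
#'
#' Descriptive validation (no threshold is applied as a filter): per probe,
#' the fraction of pooled tumor samples with beta > `meth_thresh`.
#'
#' @param panel Probe ids.
#' @param validation List of `list(beta = , sheet = )` validation cohorts.
#' @param meth_thresh Methylation threshold (default 0.2).
#' @return Named numeric vector of fractions in \[0, 1\].
#' @export
tumor_methylation_fraction <- function(panel, validation, meth_thresh = 0.2) {
  cols <- lapply(validation, function(cohort) {
    ids <- cohort$sheet$sample_id[cohort$sheet$group == "tumor"]
    cohort$beta[panel, ids, drop = FALSE]
  })
  pooled <- do.call(cbind, cols)
  if (is.null(pooled) || ncol(pooled) == 0)
    stop("validation cohorts contain no tumor samples")
  rowMeans(pooled > meth_thresh)
}
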