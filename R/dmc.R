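# Differential methylation: per-CpG group means, delta-beta, Student t with
# Benjamini-Hochberg correction, hyper/hypo classification, CGI restriction,
# global hypermethylation enrichment and a Ward-clustering QC check.

.samples_in_groups <- function(sheet, groups) {
  ids <- sheet$sample_id[sheet$group %in% groups]
  if (length(ids) == 0)
    stop("no samples in group(s): ", paste(groups, collapse = ", "))
  ids
}

#' Per-probe mean beta over one sample group
#'
#' @param beta Beta matrix.
#' @param sheet Sample sheet covering the matrix columns.
#' @param group Group label (or vector of labels pooled together).
#' @return Named numeric vector of per-probe arithmetic means.
#' @export
group_mean_beta <- function(beta, sheet, group) {
  ids <- .samples_in_groups(sheet, group)
  rowMeans(beta[, ids, drop = FALSE])
}

#' Classify a delta-beta as hyper-, hypo-methylated or not significant
#'
#' Strict thresholds: hypermethylated requires delta > `delta_thresh`,
#' hypomethylated delta < `-delta_thresh`; a boundary value is `ns`.
#'
#' @param delta Numeric vector of mean methylation differences in \[-1, 1\].
#' @param significant Logical vector (FDR call) recycled against `delta`.
#' @param delta_thresh Difference threshold (default 0.2).
#' @return Character vector: "hyper", "hypo" or "ns".
#' @export
classify_dmc <- function(delta, significant, delta_thresh = 0.2) {
  stopifnot(all(delta >= -1 & delta <= 1))
  out <- rep("ns", length(delta))
  out[significant & delta > delta_thresh] <- "hyper"
  out[significant & delta < -delta_thresh] <- "hypo"
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' The multiple-testing correction applied over all probes entering
#' [dmc_test()]. Adjusted values are monotone non-decreasing in p and never
#' smaller than the raw p-value.
#'
#' @param p Numeric vector of p-values.
#' @return Vector of BH-adjusted q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  stats::p.adjust(p, method = "BH")
}

# Vectorised two-sample t-test over matrix rows. Equal-variance Student t by
# default (Welch behind var_equal = FALSE). Degenerate rows: both groups
# constant and equal -> p = 1; constant but different -> p = 0.
.row_t_test <- function(x_case, x_ctrl, var_equal = TRUE) {
  n1 <- ncol(x_case); n2 <- ncol(x_ctrl)
  m1 <- rowMeans(x_case); m2 <- rowMeans(x_ctrl)
  v1 <- rowSums((x_case - m1)^2) / (n1 - 1)
  v2 <- rowSums((x_ctrl - m2)^2) / (n2 - 1)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(se))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tstat <- (m1 - m2) / se
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  zero <- se == 0
  p[zero & m1 == m2] <- 1
  p[zero & m1 != m2] <- 0
  list(mean_case = m1, mean_ctrl = m2, p = p, zero_var = zero)
}

#' Per-CpG differential methylation test
#'
#' For each probe: delta = mean beta(case) - mean beta(control), two-sided
#' Student t-test (equal variance; Welch available), Benjamini-Hochberg
#' correction over all tested probes, and hyper/hypo/ns classification with
#' strict thresholds (`delta > delta_thresh` and `q < fdr_thresh` for hyper).
#'
#' @param beta Beta matrix with no missing values.
#' @param sheet Sample sheet.
#' @param case Group label(s) forming the case set (default "tumor").
#' @param control Group label(s) pooled as the control set.
#' @param delta_thresh Methylation-difference threshold (default 0.2).
#' @param fdr_thresh FDR threshold (default 0.05).
#' @param var_equal Equal-variance Student t (default TRUE); FALSE for Welch.
#' @return data.frame with columns `probe_id`, `mean_beta_case`,
#'   `mean_beta_control`, `delta`, `p_value`, `q_value`, `status`,
#'   `zero_var`, ordered by ascending q, then descending delta, then probe id.
#' @export
dmc_test <- function(beta, sheet, case = "tumor", control,
                     delta_thresh = 0.2, fdr_thresh = 0.05,
                     var_equal = TRUE) {
  case_ids <- .samples_in_groups(sheet, case)
  ctrl_ids <- .samples_in_groups(sheet, control)
  if (length(case_ids) < 2 || length(ctrl_ids) < 2)
    stop("both groups need at least 2 samples")
  if (anyNA(beta[, c(case_ids, ctrl_ids)]))
    stop("beta matrix has missing values; merge cohorts first")
  tt <- .row_t_test(beta[, case_ids, drop = FALSE],
                    beta[, ctrl_ids, drop = FALSE], var_equal = var_equal)
  q <- bh_adjust(tt$p)
  delta <- tt$mean_case - tt$mean_ctrl
  res <- data.frame(probe_id = rownames(beta),
                    mean_beta_case = tt$mean_case,
                    mean_beta_control = tt$mean_ctrl,
                    delta = delta,
                    p_value = tt$p,
                    q_value = q,
                    status = classify_dmc(delta, q < fdr_thresh, delta_thresh),
                    zero_var = tt$zero_var,
                    row.names = NULL,
                    stringsAsFactors = FALSE)
  res[order(res$q_value, -res$delta, res$probe_id), , drop = FALSE]
}

#' Restrict a beta matrix to CpG-island probes
#'
#' @param beta Beta matrix.
#' @param manifest CpG manifest containing every probe of `beta`.
#' @return Beta matrix restricted to probes with `in_cgi == TRUE`, original
#'   row order preserved.
#' @export
cgi_subset <- function(beta, manifest) {
  missing <- setdiff(rownames(beta), manifest$probe_id)
  if (length(missing))
    stop("probes absent from manifest: ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) " ..." else "")
  in_cgi <- manifest$probe_id[manifest$in_cgi]
  beta[rownames(beta) %in% in_cgi, , drop = FALSE]
}

#' Global hypermethylation enrichment
#'
#' Exact two-sided binomial test of the number of significant
#' hypermethylated versus hypomethylated CpGs against a symmetric null
#' (proportion 0.5).
#'
#' @param records data.frame from [dmc_test()].
#' @return List with `n_hyper`, `n_hypo` and `p`.
#' @export
global_hyper_enrichment <- function(records) {
  n_hyper <- sum(records$status == "hyper")
  n_hypo <- sum(records$status == "hypo")
  if (n_hyper + n_hypo == 0)
    stop("no significant hyper- or hypomethylated CpGs")
  p <- stats::binom.test(n_hyper, n_hyper + n_hypo, p = 0.5)$p.value
  list(n_hyper = n_hyper, n_hypo = n_hypo, p = p)
}

#' Clustering QC: do beta profiles separate tumors from non-tumors?
#'
#' Agglomerative clustering with Ward linkage on Euclidean distances between
#' sample beta profiles, cut at two clusters. Agreement is the best fraction
#' (over the two label mappings) of samples whose cluster matches their
#' tumor / non-tumor status.
#'
#' @param beta Beta matrix without missing values (>= 2 probes, >= 2 samples).
#' @param sheet Sample sheet; blood samples are excluded from agreement.
#' @return List with `labels` (named cluster ids) and `agreement`.
#' @export
cluster_qc <- function(beta, sheet) {
  if (anyNA(beta)) stop("cluster_qc requires a complete beta matrix")
  if (nrow(beta) < 2 || ncol(beta) < 2)
    stop("need at least 2 probes and 2 samples")
  d <- stats::dist(t(beta))
  if (max(d) == 0) {
    # degenerate: all profiles identical, a single cluster
    labels <- stats::setNames(rep(1L, ncol(beta)), colnames(beta))
  } else {
    hc <- stats::hclust(d, method = "ward.D2")
    labels <- stats::cutree(hc, k = 2)
  }
  truth <- ifelse(sheet$group[match(names(labels), sheet$sample_id)] == "tumor",
                  1L, 2L)
  agreement <- max(mean(labels == truth), mean(labels == 3L - truth))
  list(labels = labels, agreement = agreement)
}
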