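# Methylation-expression integration: genomic-context classification of
# panel CpGs, log-CPM normalisation, normality-gated differential expression
# of host genes, location/expression concordance, and tissue-of-origin
# repression from a tissue-wide TPM table.

#' Classify a CpG's genomic context
#'
#' Promoter spans TSS-1500 to TSS+300 on the gene's strand-oriented axis
#' (upstream = 5' of the TSS), closed on both ends; a probe inside the gene
#' span but outside the promoter is gene body; probes without an assigned
#' gene are intergenic. Promoter takes precedence where the TSS+300 window
#' overlaps the first exon.
#'
#' @param manifest CpG manifest rows (one or more probes).
#' @return Character vector: "promoter", "gene_body" or "intergenic".
#' @export
classify_region <- function(manifest) {
  n <- nrow(manifest)
  out <- character(n)
  for (i in seq_len(n)) {
    row <- manifest[i, ]
    if (is.na(row$gene) || row$gene == "") {
      out[i] <- "intergenic"
      next
    }
    if (is.na(row$tss_pos))
      stop("probe ", row$probe_id, " has a gene but no TSS position")
    pos <- row$pos; tss <- row$tss_pos
    promoter <- if (row$strand == "-") {
      pos >= tss - 300 && pos <= tss + 1500
    } else {
      pos >= tss - 1500 && pos <= tss + 300
    }
    in_span <- !is.na(row$gene_start) && !is.na(row$gene_end) &&
      pos >= row$gene_start && pos <= row$gene_end
    out[i] <- if (promoter) "promoter"
      else if (in_span) "gene_body"
      else "intergenic"
  }
  out
}

#' Counts-per-million on the log2 scale
#'
#' CPM = count / library size x 1e6, then log2(CPM + pseudocount). Column
#' sums of the pre-log CPM matrix equal 1e6 by construction.
#'
#' @param counts Gene-by-sample matrix of non-negative raw counts.
#' @param pseudocount Added to CPM before the log (default 0.5).
#' @param log Return log2 values (default TRUE); FALSE returns plain CPM.
#' @return Matrix of the same shape.
#' @export
log_cpm <- function(counts, pseudocount = 0.5, log = TRUE) {
  totals <- colSums(counts)
  if (any(totals <= 0)) stop("sample with zero total count: ",
                             paste(colnames(counts)[totals <= 0], collapse = ", "))
  cpm <- sweep(counts, 2, totals, "/") * 1e6
  if (log) log2(cpm + pseudocount) else cpm
}

#' D'Agostino-Pearson K-squared omnibus normality test
#'
#' Combines the D'Agostino transformed-skewness statistic with the
#' Anscombe-Glynn transformed-kurtosis statistic into K2 = Z1^2 + Z2^2,
#' referred to a chi-squared distribution with 2 df. Requires n >= 8.
#'
#' @param x Numeric vector.
#' @return List with `statistic` (K2) and `p_value`.
#' @export
dagostino_test <- function(x) {
  n <- length(x)
  if (n < 8) stop("D'Agostino test requires at least 8 observations")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  if (m2 == 0) stop("zero variance")
  # skewness component (D'Agostino 1970)
  g1 <- m3 / m2^1.5
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))
  # kurtosis component (Anscombe & Glynn 1983)
  b2 <- m4 / m2^2
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - eb2) / sqrt(vb2)
  sqb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqb1 * (2 / sqb1 + sqrt(1 + 4 / sqb1^2))
  z2 <- ((1 - 2 / (9 * a)) -
           ((1 - 2 / a) / (1 + xk * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))
  k2 <- z1^2 + z2^2
  list(statistic = k2,
       p_value = stats::pchisq(k2, df = 2, lower.tail = FALSE))
}

#' Expression status of one gene between tumor and control samples
#'
#' A gene is `not_expressed` when its median CPM is below
#' `not_expressed_cpm` in both groups. Otherwise group log2-CPM values are
#' compared with a two-sided unpaired Student's t-test when both groups pass
#' the D'Agostino normality test (alpha 0.05), else a Mann-Whitney U-test;
#' `down` / `up` when p < `alpha` with the corresponding direction of the
#' group means, else `unchanged`. Groups smaller than 8 fall back to
#' Mann-Whitney with a warning.
#'
#' @param gene Gene id (row of `counts`).
#' @param counts Gene-by-sample raw count matrix.
#' @param sheet Sample sheet for the columns of `counts`.
#' @param case,control Group labels (defaults "tumor" vs "adjacent").
#' @param alpha Significance level for the differential call (default 0.001).
#' @param not_expressed_cpm Median-CPM floor for expression (default 1).
#' @param normality_alpha Per-group D'Agostino level (default 0.05).
#' @return List: `status` ("not_expressed", "unchanged", "down", "up"),
#'   `p_value`, `test` ("t", "mann_whitney" or "none"), `log_fc`
#'   (case minus control mean log2-CPM).
#' @export
expression_status <- function(gene, counts, sheet, case = "tumor",
                              control = "adjacent", alpha = 0.001,
                              not_expressed_cpm = 1.0,
                              normality_alpha = 0.05) {
  if (!gene %in% rownames(counts)) stop("gene absent from counts: ", gene)
  case_ids <- .samples_in_groups(sheet, case)
  ctrl_ids <- .samples_in_groups(sheet, control)
  cpm <- log_cpm(counts, log = FALSE)[gene, ]
  if (stats::median(cpm[case_ids]) < not_expressed_cpm &&
      stats::median(cpm[ctrl_ids]) < not_expressed_cpm) {
    return(list(status = "not_expressed", p_value = NA_real_,
                test = "none", log_fc = NA_real_))
  }
  lx <- log2(cpm + 0.5)
  x_case <- lx[case_ids]; x_ctrl <- lx[ctrl_ids]
  use_t <- FALSE
  if (length(x_case) >= 8 && length(x_ctrl) >= 8) {
    norm_ok <- function(v) {
      if (stats::var(v) == 0) return(FALSE)
      dagostino_test(v)$p_value > normality_alpha
    }
    use_t <- norm_ok(x_case) && norm_ok(x_ctrl)
  } else {
    warning("group smaller than 8 samples for gene ", gene,
            "; using Mann-Whitney without normality gating")
  }
  p <- if (use_t) {
    stats::t.test(x_case, x_ctrl, var.equal = TRUE)$p.value
  } else {
    stats::wilcox.test(x_case, x_ctrl, exact = FALSE)$p.value
  }
  log_fc <- mean(x_case) - mean(x_ctrl)
  status <- if (p < alpha && log_fc < 0) "down"
    else if (p < alpha && log_fc > 0) "up"
    else "unchanged"
  list(status = status, p_value = p,
       test = if (use_t) "t" else "mann_whitney", log_fc = log_fc)
}

#' Methylation-location / expression concordance
#'
#' Promoter CGI hypermethylation is expected to silence the gene, gene-body
#' CGI hypermethylation to activate it: concordant means (promoter AND down)
#' or (gene_body AND up). Statuses other than down/up, and intergenic
#' probes, are not applicable (NA).
#'
#' @param region "promoter", "gene_body" or "intergenic".
#' @param expr_status "down", "up", "unchanged" or "not_expressed".
#' @return TRUE / FALSE, or NA when not applicable.
#' @export
concordance <- function(region, expr_status) {
  mapply(function(r, e) {
    if (r == "intergenic" || !e %in% c("down", "up")) return(NA)
    (r == "promoter" && e == "down") || (r == "gene_body" && e == "up")
  }, region, expr_status, USE.NAMES = FALSE)
}

#' Tissue-of-origin repression status from a tissue-wide TPM table
#'
#' @param gene Gene id.
#' @param tpm Gene-by-tissue TPM matrix (>= 2 tissues).
#' @param index_tissue Column name of the index tissue (default "liver").
#' @param low_tpm TPM below which a tissue counts as not expressing (1.0).
#' @param ratio Index TPM must also fall below `ratio` x the median
#'   non-index TPM to call index-specific repression (0.25).
#' @return "broadly_silent" (median TPM across all tissues < `low_tpm`),
#'   "repressed_in_index", or "expressed_in_index".
#' @export
tissue_repression <- function(gene, tpm, index_tissue = "liver",
                              low_tpm = 1.0, ratio = 0.25) {
  if (!gene %in% rownames(tpm)) stop("gene absent from TPM table: ", gene)
  if (ncol(tpm) < 2) stop("need at least 2 tissues")
  v <- tpm[gene, ]
  if (stats::median(v) < low_tpm) return("broadly_silent")
  idx <- v[[index_tissue]]
  others <- v[setdiff(colnames(tpm), index_tissue)]
  if (idx < low_tpm && idx < ratio * stats::median(others))
    return("repressed_in_index")
  "expressed_in_index"
}

#' Concordance records for a CpG panel
#'
#' One record per panel probe: genomic context, host-gene expression status
#' and the location/expression concordance call.
#'
#' @param panel Probe ids.
#' @param manifest CpG manifest.
#' @param counts Gene-by-sample raw count matrix.
#' @param counts_sheet Sample sheet for `counts`.
#' @param ... Passed to [expression_status()].
#' @return data.frame: `probe_id`, `gene`, `region`, `expr_status`,
#'   `p_value`, `concordant`.
#' @export
concordance_table <- function(panel, manifest, counts, counts_sheet, ...) {
  rows <- manifest[match(panel, manifest$probe_id), ]
  region <- classify_region(rows)
  status <- character(length(panel)); pval <- rep(NA_real_, length(panel))
  for (i in seq_along(panel)) {
    if (region[i] == "intergenic" || !rows$gene[i] %in% rownames(counts)) {
      status[i] <- NA_character_
      next
    }
    es <- expression_status(rows$gene[i], counts, counts_sheet, ...)
    status[i] <- es$status
    pval[i] <- es$p_value
  }
  data.frame(probe_id = panel, gene = rows$gene, region = region,
             expr_status = status, p_value = pval,
             concordant = concordance(region,
                                      ifelse(is.na(status), "na", status)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Cross-tabulate CpG location against expression status
#'
#' Counts CpGs per (region x expression status) cell, and distinct genes per
#' cell, with row/column totals. A gene with several probes counts once in
#' the gene columns but once per probe in the CpG columns.
#'
#' @param records data.frame from [concordance_table()].
#' @return data.frame with one row per region plus a total row; columns
#'   `n_cpg`, `n_gene`, and per-status CpG and gene counts.
#' @export
location_expression_table <- function(records) {
  regions <- c("promoter", "gene_body", "intergenic")
  statuses <- c("not_expressed", "unchanged", "down", "up")
  make_row <- function(sub, label) {
    row <- data.frame(region = label,
                      n_cpg = nrow(sub),
                      n_gene = length(unique(sub$gene[!is.na(sub$gene) &
                                                        sub$gene != ""])),
                      stringsAsFactors = FALSE)
    for (s in statuses) {
      hit <- sub[!is.na(sub$expr_status) & sub$expr_status == s, , drop = FALSE]
      row[[paste0("cpg_", s)]] <- nrow(hit)
      row[[paste0("gene_", s)]] <- length(unique(hit$gene[hit$gene != ""]))
    }
    row
  }
  rows <- lapply(regions, function(r)
    make_row(records[records$region == r, , drop = FALSE], r))
  rows <- c(rows, list(make_row(records, "total")))
  do.call(rbind, rows)
}
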