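# Shared fixtures and independent oracles for the test suite.

# Independent Benjamini-Hochberg step-up: for each p_i, the smallest
# m * t / #{p <= t} over observed values t >= p_i, capped at 1. Written from
# the definition, not via p.adjust, so it can serve as an oracle.
bh_brute <- function(p) {
  m <- length(p)
  vapply(p, function(pi) {
    cand <- p[p >= pi]
    min(1, min(vapply(cand, function(t) m * t / sum(p <= t), numeric(1))))
  }, numeric(1))
}

# small beta matrix with named dims
make_beta <- function(values, probes, samples) {
  matrix(values, nrow = length(probes), ncol = length(samples),
         dimnames = list(probes, samples), byrow = TRUE)
}

make_sheet <- function(sample_id, group, cohort = "c1", tissue = "liver") {
  data.frame(sample_id = sample_id, cohort = cohort, group = group,
             tissue = tissue, stringsAsFactors = FALSE)
}

# liver contrast fixture: per-probe group means are set exactly (zero
# within-group noise) so branch logic can be checked against hand values
make_liver_fixture <- function(probe_means) {
  # probe_means: data.frame(probe_id, tumor, adjacent, cirrhotic, healthy)
  groups <- c(tumor = 6, adjacent = 4, cirrhotic = 3, healthy = 3)
  ids <- unlist(mapply(function(g, n) sprintf("%s_%d", g, seq_len(n)),
                       names(groups), groups, SIMPLIFY = FALSE))
  sheet <- make_sheet(ids, rep(names(groups), groups))
  beta <- matrix(NA_real_, nrow = nrow(probe_means), ncol = length(ids),
                 dimnames = list(probe_means$probe_id, ids))
  for (g in names(groups)) {
    cols <- sheet$sample_id[sheet$group == g]
    beta[, cols] <- matrix(rep(probe_means[[g]], length(cols)),
                           ncol = length(cols))
  }
  list(beta = beta, sheet = sheet)
}

# minimal manifest row(s)
make_manifest <- function(probe_id, chrom = "chr1", pos = 1000L,
                          strand = "+", in_cgi = TRUE, gene = "",
                          tss_pos = NA_integer_, gene_start = NA_integer_,
                          gene_end = NA_integer_) {
  data.frame(probe_id = probe_id, chrom = chrom, pos = pos, strand = strand,
             in_cgi = in_cgi, gene = gene, tss_pos = tss_pos,
             gene_start = gene_start, gene_end = gene_end,
             stringsAsFactors = FALSE)
}

# cohort summary stub for the pan-cancer module
make_summary <- function(tissue_code, mean_t, mean_nt = NULL,
                         n_nt = if (is.null(mean_nt)) 0L else 8L,
                         n_t = 20L) {
  structure(list(tissue_code = tissue_code,
                 has_controls = !is.null(mean_nt),
                 mean_beta_nt = mean_nt, mean_beta_t = mean_t,
                 n_nt = n_nt, n_t = n_t),
            class = "tumor_cohort_summary")
}
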