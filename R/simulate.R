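# Seeded synthetic-data generator. Emulates the statistical structure of
# multi-cohort methylation-array studies: Beta-distributed beta values with
# tissue-specific baselines, planted tumor-hypermethylation classes
# (clean panel markers, field-effect markers, blood-methylated probes,
# aging-clock overlaps, liver-disease-only probes, tumor-hypomethylated
# probes, pan-cancer and index-exclusive probes), a validation cohort with
# configurable per-sample penetrance, and negative-binomial expression
# counts coupled to methylation by CpG location class. Every draw is
# determined by the config seed; a ground-truth table accompanies the data.

#' Simulation configuration
#'
#' Defaults describe the emulated study: a discovery set of 100 tumors and
#' 50 non-tumoral livers split over two cohorts, a 200-sample whole-blood
#' reference, a 353-probe epigenetic clock, a 30-sample liver-disease
#' cohort, a 500-tumor validation set, and 14 paired plus 13 tumor-only
#' pan-cancer cohorts (20 tumors / 8 peritumoral each). Null probes draw
#' from Beta(2, 38) (mean 0.05); methylated states from Beta(30, 10)
#' (mean 0.75); planted marker probes use a tight unmethylated distribution
#' Beta(8, 152) in their unmethylated groups, emulating the confidently
#' unmethylated character of marker CpGs (which by definition stay below
#' beta 0.2 in every one of hundreds of control samples).
#'
#' @param seed Integer seed driving every draw.
#' @param n_probes Total probes (default 20000).
#' @param cgi_fraction Fraction of probes inside a CpG island (0.3); all
#'   planted classes are placed on CGI probes.
#' @param n_tumor,n_adjacent,n_cirrhotic,n_healthy Discovery cohort sizes.
#' @param n_blood Whole-blood reference samples (200).
#' @param n_disease,n_disease_controls Liver-disease cohort composition.
#' @param n_tumor_val Validation tumors (500).
#' @param val_penetrance Per-sample probability that a validation tumor is
#'   methylated at a panel CpG (0.7).
#' @param n_pan_paired,n_pan_tumor_only,n_pan_t,n_pan_nt Pan-cancer cohort
#'   layout.
#' @param n_branch_a,n_branch_b Planted clean-panel and field-effect marker
#'   counts (30, 12).
#' @param n_blood_meth,n_clock_overlap,n_disease_only,n_hypo Planted
#'   confounder classes (50, 10, 20, 100).
#' @param clock_size Total clock-list size (353).
#' @param n_pan_cancer,pan_hyper_k,n_index_exclusive Pan-cancer planted
#'   classes: 5 probes hyper in `pan_hyper_k` = 11 paired cohorts; 10
#'   probes hyper only in the index tissue.
#' @param base_shape,meth_shape,adjacent_shape,marker_low_shape Beta shape
#'   pairs for the baseline, methylated, adjacent field-effect and
#'   tight-unmethylated states.
#' @param nb_mean,nb_dispersion,coupling_fold Negative-binomial expression
#'   model: baseline mean 200, dispersion 0.1, methylation-coupled fold 2.
#' @param silent_fraction Fraction of panel genes silent in both groups (0.3).
#' @param region_ratio Promoter : gene-body : intergenic split of panel
#'   probes (21:16:2, scaled by largest remainder).
#' @param n_background_genes Unplanted genes added to the count matrix (120).
#' @param n_tissues Tissues in the TPM table, including "liver" (20).
#' @param index_tissue Index tumor-type code ("LIHC").
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1, n_probes = 20000, cgi_fraction = 0.3,
                       n_tumor = 100, n_adjacent = 30, n_cirrhotic = 10,
                       n_healthy = 10, n_blood = 200, n_disease = 30,
                       n_disease_controls = 10, n_tumor_val = 500,
                       val_penetrance = 0.7,
                       n_pan_paired = 14, n_pan_tumor_only = 13,
                       n_pan_t = 20, n_pan_nt = 8,
                       n_branch_a = 30, n_branch_b = 12,
                       n_blood_meth = 50, n_clock_overlap = 10,
                       clock_size = 353, n_disease_only = 20, n_hypo = 100,
                       n_pan_cancer = 5, pan_hyper_k = 11,
                       n_index_exclusive = 10,
                       base_shape = c(2, 38), meth_shape = c(30, 10),
                       adjacent_shape = c(14, 26),
                       marker_low_shape = c(8, 152),
                       nb_mean = 200, nb_dispersion = 0.1,
                       coupling_fold = 2.0, silent_fraction = 0.3,
                       region_ratio = c(21, 16, 2),
                       n_background_genes = 120, n_tissues = 20,
                       index_tissue = "LIHC") {
  cfg <- as.list(environment())
  n_planted <- n_branch_a + n_branch_b + n_blood_meth + n_clock_overlap +
    n_disease_only + n_hypo + n_pan_cancer + n_index_exclusive
  if (n_planted > floor(n_probes * cgi_fraction))
    stop("planted classes exceed the number of CGI probes")
  structure(cfg, class = "sim_config")
}

.paired_codes <- c("LIHC", "CHOL", "COADREAD", "BRCA", "PAAD", "BLCA",
                   "LUAD", "PRAD", "ESCA", "HNSC", "UCEC", "LUSC",
                   "KIRC", "THCA")
.tumor_only_codes <- c("STAD", "CESC", "SKCM", "GBM", "ACC", "MESO", "UCS",
                       "SARC", "OV", "LAML", "TGCT", "THYM", "LUNG")

# largest-remainder apportionment of n into parts proportional to ratio
.apportion <- function(n, ratio) {
  quota <- n * ratio / sum(ratio)
  base <- floor(quota)
  rem <- n - sum(base)
  if (rem > 0) {
    order_idx <- order(quota - base, decreasing = TRUE)
    base[order_idx[seq_len(rem)]] <- base[order_idx[seq_len(rem)]] + 1L
  }
  as.integer(base)
}

#' Simulate a CpG manifest with planted classes and gene assignments
#'
#' Probes are placed on 22 synthetic chromosomes; exactly
#' `round(cgi_fraction * n_probes)` probes are flagged in-CGI, and all
#' planted classes live on CGI probes. Planted panel probes are split
#' promoter : gene body : intergenic by `region_ratio`; promoter and
#' gene-body probes each receive a unique gene with a strand-consistent TSS
#' and span. Background genes are attached to random null probes.
#'
#' @param cfg [sim_config()].
#' @return List with `manifest` (data.frame) and `truth` (data.frame:
#'   probe_id, class, gene, region, expr_effect, tissue_profile,
#'   hyper_tissues).
#' @export
simulate_manifest <- function(cfg) {
  set.seed(cfg$seed)
  n <- cfg$n_probes
  probe_id <- sprintf("cg%08d", seq_len(n))
  chrom <- paste0("chr", sample.int(22, n, replace = TRUE))
  pos <- sample.int(2e8, n, replace = TRUE) + 1e4
  strand <- sample(c("+", "-"), n, replace = TRUE)
  n_cgi <- round(cfg$cgi_fraction * n)
  in_cgi <- rep(FALSE, n)
  cgi_idx <- sample.int(n, n_cgi)
  in_cgi[cgi_idx] <- TRUE

  classes <- c(branch_a = cfg$n_branch_a, branch_b = cfg$n_branch_b,
               blood_methylated = cfg$n_blood_meth,
               clock_overlap = cfg$n_clock_overlap,
               disease_only = cfg$n_disease_only,
               hypo_in_tumor = cfg$n_hypo,
               pan_cancer = cfg$n_pan_cancer,
               index_exclusive = cfg$n_index_exclusive)
  planted_idx <- sample(cgi_idx, sum(classes))
  class_vec <- rep("null", n)
  class_vec[planted_idx] <- rep(names(classes), classes)

  gene <- rep("", n)
  tss_pos <- rep(NA_integer_, n)
  gene_start <- rep(NA_integer_, n)
  gene_end <- rep(NA_integer_, n)
  region <- rep(NA_character_, n)

  assign_gene <- function(i, gid, want_region) {
    gene[i] <<- gid
    region[i] <<- want_region
    p <- pos[i]
    if (want_region == "promoter") {
      if (strand[i] == "+") {
        tss <- p + 500L          # probe sits 500 nt upstream of the TSS
        gs <- tss; ge <- tss + 5000L
      } else {
        tss <- p - 500L
        gs <- tss - 5000L; ge <- tss
      }
    } else {                      # gene body, clear of the promoter window
      if (strand[i] == "+") {
        tss <- p - 2000L
        gs <- tss; ge <- tss + 8000L
      } else {
        tss <- p + 2000L
        gs <- tss - 8000L; ge <- tss
      }
    }
    tss_pos[i] <<- tss; gene_start[i] <<- gs; gene_end[i] <<- ge
  }

  panel_idx <- planted_idx[class_vec[planted_idx] %in% c("branch_a", "branch_b")]
  counts3 <- .apportion(length(panel_idx), cfg$region_ratio)
  panel_regions <- rep(c("promoter", "gene_body", "intergenic"), counts3)
  gene_counter <- 0L
  for (j in seq_along(panel_idx)) {
    i <- panel_idx[j]
    if (panel_regions[j] == "intergenic") {
      region[i] <- "intergenic"
      next
    }
    gene_counter <- gene_counter + 1L
    assign_gene(i, sprintf("PGENE%03d", gene_counter), panel_regions[j])
  }
  # background genes on null probes, half promoter half gene body
  null_pool <- setdiff(which(class_vec == "null"), which(!in_cgi))
  bg_idx <- sample(null_pool, cfg$n_background_genes)
  for (j in seq_along(bg_idx)) {
    assign_gene(bg_idx[j], sprintf("BGENE%03d", j),
                if (j %% 2 == 0) "promoter" else "gene_body")
  }

  # expression effects for panel genes: a silent subset, then coupling by
  # location (promoter -> down, gene body -> up)
  panel_gene_idx <- panel_idx[gene[panel_idx] != ""]
  n_silent <- round(cfg$silent_fraction * length(panel_gene_idx))
  silent_idx <- sample(panel_gene_idx, n_silent)
  expr_effect <- rep(NA_character_, n)
  expr_effect[panel_gene_idx] <- ifelse(region[panel_gene_idx] == "promoter",
                                        "down", "up")
  expr_effect[silent_idx] <- "silent"
  expr_effect[bg_idx] <- "none"
  tissue_profile <- rep(NA_character_, n)
  tissue_profile[panel_gene_idx] <-
    ifelse(expr_effect[panel_gene_idx] == "silent", "broadly_silent",
           ifelse(expr_effect[panel_gene_idx] == "down",
                  "repressed_in_index", "expressed_in_index"))
  tissue_profile[bg_idx] <- "expressed_in_index"

  # pan-cancer planting layout (index tissue always included)
  hyper_tissues <- rep("", n)
  pan_set <- c(cfg$index_tissue,
               setdiff(.paired_codes[seq_len(cfg$n_pan_paired)],
                       cfg$index_tissue)[seq_len(cfg$pan_hyper_k - 1)])
  hyper_tissues[class_vec == "pan_cancer"] <- paste(sort(pan_set),
                                                    collapse = ",")
  hyper_tissues[class_vec == "index_exclusive"] <- cfg$index_tissue
  hyper_tissues[class_vec %in% c("branch_a", "branch_b", "blood_methylated",
                                 "clock_overlap")] <- cfg$index_tissue

  manifest <- data.frame(probe_id = probe_id, chrom = chrom, pos = pos,
                         strand = strand, in_cgi = in_cgi, gene = gene,
                         tss_pos = tss_pos, gene_start = gene_start,
                         gene_end = gene_end, stringsAsFactors = FALSE)
  truth <- data.frame(probe_id = probe_id, class = class_vec, gene = gene,
                      region = region, expr_effect = expr_effect,
                      tissue_profile = tissue_profile,
                      hyper_tissues = hyper_tissues,
                      stringsAsFactors = FALSE)
  list(manifest = manifest, truth = truth)
}

# one Beta-distributed block
.rbeta_mat <- function(n_probe, ids, shape) {
  m <- matrix(stats::rbeta(n_probe * length(ids), shape[1], shape[2]),
              nrow = n_probe)
  colnames(m) <- ids
  m
}

# build a cohort matrix: baseline everywhere, then per-class overrides by
# sample subset. overrides: list of list(rows = logical/index, cols = ids,
# shape = c(a, b))
.sim_cohort_beta <- function(cfg, probe_ids, sample_ids, overrides = list()) {
  m <- .rbeta_mat(length(probe_ids), sample_ids, cfg$base_shape)
  rownames(m) <- probe_ids
  for (ov in overrides) {
    rows <- ov$rows
    if (length(rows) == 0) next
    m[rows, ov$cols] <- stats::rbeta(length(rows) * length(ov$cols),
                                     ov$shape[1], ov$shape[2])
  }
  m
}

#' Simulate all beta-value cohorts plus the clock list
#'
#' Generates the two discovery cohorts (tumor / adjacent / cirrhotic /
#' healthy), the whole-blood reference, the liver-disease cohort, and —
#' when requested via `include` — the validation tumors and the pan-cancer
#' cohorts. All planted classes from the manifest truth are realised here.
#'
#' @param cfg [sim_config()].
#' @param manifest,truth From [simulate_manifest()].
#' @param include Character subset of `c("validation", "pan_cancer")`
#'   controlling the heavier optional cohorts.
#' @return List: `cohorts` (two discovery cohorts, each `list(beta, sheet)`),
#'   `blood`, `disease` (list of one cohort), `validation` (list of one, or
#'   NULL), `pan` (list of `list(beta, sheet, tissue_code)`, or NULL),
#'   `clock` (character vector of clock probe ids).
#' @export
simulate_beta_cohorts <- function(cfg, manifest, truth,
                                  include = c("validation", "pan_cancer")) {
  set.seed(cfg$seed + 1L)
  probes <- manifest$probe_id
  cls <- function(name) which(truth$class == name)
  idx_a <- cls("branch_a"); idx_b <- cls("branch_b")
  idx_blood <- cls("blood_methylated"); idx_clock <- cls("clock_overlap")
  idx_dis <- cls("disease_only"); idx_hypo <- cls("hypo_in_tumor")
  idx_pan <- cls("pan_cancer"); idx_excl <- cls("index_exclusive")
  panel_idx <- c(idx_a, idx_b)
  hyper_idx <- c(panel_idx, idx_blood, idx_clock)  # tumor-hyper in discovery

  mk_ids <- function(prefix, n) sprintf("%s_%03d", prefix, seq_len(n))
  mk_sheet <- function(ids, cohort, group, tissue = "liver")
    data.frame(sample_id = ids, cohort = cohort, group = group,
               tissue = tissue, stringsAsFactors = FALSE)

  n_t1 <- ceiling(0.6 * cfg$n_tumor)
  n_t2 <- cfg$n_tumor - n_t1

  # discovery cohort 1: tumors + cirrhotic + healthy
  t1 <- mk_ids("t1", n_t1); ci <- mk_ids("ci", cfg$n_cirrhotic)
  he <- mk_ids("he", cfg$n_healthy)
  beta1 <- .sim_cohort_beta(cfg, probes, c(t1, ci, he), list(
    list(rows = hyper_idx, cols = t1, shape = cfg$meth_shape),
    list(rows = idx_hypo, cols = t1, shape = cfg$base_shape),
    list(rows = idx_hypo, cols = c(ci, he), shape = cfg$meth_shape),
    list(rows = c(hyper_idx), cols = c(ci, he), shape = cfg$marker_low_shape)))
  sheet1 <- rbind(mk_sheet(t1, "study1", "tumor"),
                  mk_sheet(ci, "study1", "cirrhotic"),
                  mk_sheet(he, "study1", "healthy"))

  # discovery cohort 2: tumors + adjacent (field effect on branch-B probes)
  t2 <- mk_ids("t2", n_t2); ad <- mk_ids("ad", cfg$n_adjacent)
  beta2 <- .sim_cohort_beta(cfg, probes, c(t2, ad), list(
    list(rows = hyper_idx, cols = t2, shape = cfg$meth_shape),
    list(rows = idx_hypo, cols = t2, shape = cfg$base_shape),
    list(rows = idx_hypo, cols = ad, shape = cfg$meth_shape),
    list(rows = c(idx_a, idx_blood, idx_clock), cols = ad,
         shape = cfg$marker_low_shape),
    list(rows = idx_b, cols = ad, shape = cfg$adjacent_shape)))
  sheet2 <- rbind(mk_sheet(t2, "study2", "tumor"),
                  mk_sheet(ad, "study2", "adjacent"))

  # whole-blood reference
  bl <- mk_ids("bl", cfg$n_blood)
  blood_beta <- .sim_cohort_beta(cfg, probes, bl, list(
    list(rows = idx_blood, cols = bl, shape = cfg$meth_shape),
    list(rows = c(panel_idx, idx_clock), cols = bl,
         shape = cfg$marker_low_shape)))
  blood <- list(beta = blood_beta,
                sheet = mk_sheet(bl, "blood_ref", "blood", "blood"))

  # liver-disease cohort (disease + healthy controls)
  di <- mk_ids("di", cfg$n_disease); dh <- mk_ids("dh", cfg$n_disease_controls)
  disease_beta <- .sim_cohort_beta(cfg, probes, c(di, dh), list(
    list(rows = idx_dis, cols = di, shape = cfg$meth_shape),
    list(rows = panel_idx, cols = c(di, dh), shape = cfg$marker_low_shape)))
  disease <- list(list(beta = disease_beta,
                       sheet = rbind(mk_sheet(di, "liver_disease", "disease"),
                                     mk_sheet(dh, "liver_disease", "healthy"))))

  # clock list: the planted overlaps plus null probes padded to clock_size
  null_pool <- setdiff(which(truth$class == "null"), which(manifest$in_cgi))
  clock <- c(probes[idx_clock],
             probes[sample(null_pool, cfg$clock_size - length(idx_clock))])

  validation <- NULL
  if ("validation" %in% include) {
    vt <- mk_ids("vt", cfg$n_tumor_val)
    vbeta <- .sim_cohort_beta(cfg, probes, vt)
    # penetrance: each tumor independently methylated at each panel probe
    on <- matrix(stats::runif(length(panel_idx) * length(vt)) <
                   cfg$val_penetrance, nrow = length(panel_idx))
    meth_draws <- matrix(stats::rbeta(length(panel_idx) * length(vt),
                                      cfg$meth_shape[1], cfg$meth_shape[2]),
                         nrow = length(panel_idx))
    sub <- vbeta[panel_idx, , drop = FALSE]
    sub[on] <- meth_draws[on]
    vbeta[panel_idx, ] <- sub
    validation <- list(list(beta = vbeta,
                            sheet = mk_sheet(vt, "validation", "tumor")))
  }

  pan <- NULL
  if ("pan_cancer" %in% include) {
    paired <- .paired_codes[seq_len(cfg$n_pan_paired)]
    tumor_only <- .tumor_only_codes[seq_len(cfg$n_pan_tumor_only)]
    pan_set <- strsplit(truth$hyper_tissues[idx_pan[1]], ",")[[1]]
    pan <- list()
    for (code in paired) {
      pt <- mk_ids(paste0(tolower(code), "_t"), cfg$n_pan_t)
      pn <- mk_ids(paste0(tolower(code), "_n"), cfg$n_pan_nt)
      overrides <- list()
      if (code %in% pan_set)
        overrides <- c(overrides, list(list(rows = idx_pan, cols = pt,
                                            shape = cfg$meth_shape)))
      if (code == cfg$index_tissue)
        overrides <- c(overrides,
                       list(list(rows = c(idx_excl, panel_idx, idx_blood,
                                          idx_clock),
                                 cols = pt, shape = cfg$meth_shape)))
      b <- .sim_cohort_beta(cfg, probes, c(pt, pn), overrides)
      pan[[code]] <- list(beta = b,
                          sheet = rbind(mk_sheet(pt, code, "tumor", code),
                                        mk_sheet(pn, code, "adjacent", code)),
                          tissue_code = code)
    }
    for (code in tumor_only) {
      pt <- mk_ids(paste0(tolower(code), "_t"), cfg$n_pan_t)
      overrides <- list()
      if (code %in% c("STAD", "CESC", "SKCM"))  # corroborating methylation
        overrides <- list(list(rows = idx_pan, cols = pt,
                               shape = cfg$meth_shape))
      b <- .sim_cohort_beta(cfg, probes, pt, overrides)
      pan[[code]] <- list(beta = b,
                          sheet = mk_sheet(pt, code, "tumor", code),
                          tissue_code = code)
    }
  }

  list(cohorts = list(list(beta = beta1, sheet = sheet1),
                      list(beta = beta2, sheet = sheet2)),
       blood = blood, disease = disease, validation = validation,
       pan = pan, clock = clock)
}

#' Simulate expression counts and a tissue-wide TPM table
#'
#' Negative-binomial counts for all manifest genes over a tumor / adjacent
#' contrast; genes of promoter-hypermethylated panel probes are halved in
#' tumors, gene-body genes doubled (`coupling_fold`), silent genes kept at
#' mean 0.1 in both groups. The TPM table covers `n_tissues` tissues
#' including "liver": index-repressed genes are low in liver only, broadly
#' silent genes low everywhere.
#'
#' @param cfg [sim_config()].
#' @param truth Truth table from [simulate_manifest()].
#' @return List: `counts` (gene-by-sample integer matrix), `sheet`
#'   (expression sample sheet), `tpm` (gene-by-tissue matrix).
#' @export
simulate_counts <- function(cfg, truth) {
  set.seed(cfg$seed + 2L)
  gene_rows <- truth[truth$gene != "", ]
  genes <- gene_rows$gene
  effect <- gene_rows$expr_effect
  profile <- gene_rows$tissue_profile
  n_t <- cfg$n_tumor; n_c <- cfg$n_adjacent
  ids_t <- sprintf("rna_t_%03d", seq_len(n_t))
  ids_c <- sprintf("rna_c_%03d", seq_len(n_c))
  mu_ctrl <- rep(cfg$nb_mean, length(genes))
  mu_tum <- mu_ctrl
  mu_tum[effect == "down"] <- cfg$nb_mean / cfg$coupling_fold
  mu_tum[effect == "up"] <- cfg$nb_mean * cfg$coupling_fold
  mu_ctrl[effect == "silent"] <- 0.1
  mu_tum[effect == "silent"] <- 0.1
  size <- 1 / cfg$nb_dispersion
  draw <- function(mu, ids) {
    m <- matrix(stats::rnbinom(length(mu) * length(ids), mu = mu, size = size),
                nrow = length(mu))
    colnames(m) <- ids
    m
  }
  counts <- cbind(draw(mu_tum, ids_t), draw(mu_ctrl, ids_c))
  rownames(counts) <- genes
  sheet <- data.frame(
    sample_id = c(ids_t, ids_c), cohort = "rna",
    group = c(rep("tumor", n_t), rep("adjacent", n_c)),
    tissue = "liver", stringsAsFactors = FALSE)

  tissues <- c("liver", sprintf("tissue_%02d", seq_len(cfg$n_tissues - 1)))
  tpm <- matrix(stats::rlnorm(length(genes) * length(tissues),
                              meanlog = log(20), sdlog = 0.5),
                nrow = length(genes), dimnames = list(genes, tissues))
  tpm[profile == "broadly_silent", ] <-
    stats::runif(sum(profile == "broadly_silent") * length(tissues), 0, 0.5)
  tpm[profile == "repressed_in_index", "liver"] <-
    stats::runif(sum(profile == "repressed_in_index"), 0, 0.3)
  list(counts = counts, sheet = sheet, tpm = tpm)
}

#' Simulate a complete multi-cohort dataset
#'
#' Convenience wrapper over [simulate_manifest()],
#' [simulate_beta_cohorts()] and [simulate_counts()].
#'
#' @param cfg [sim_config()].
#' @param include Character subset of
#'   `c("validation", "pan_cancer", "expression")` selecting the optional
#'   heavier components (all included by default).
#' @return List: `cfg`, `manifest`, `truth`, `clock`, `cohorts`, `blood`,
#'   `disease`, `validation`, `pan`, `counts`, `counts_sheet`, `tpm`.
#' @export
simulate_dataset <- function(cfg = sim_config(),
                             include = c("validation", "pan_cancer",
                                         "expression")) {
  mf <- simulate_manifest(cfg)
  cohorts <- simulate_beta_cohorts(cfg, mf$manifest, mf$truth,
                                   include = include)
  expr <- if ("expression" %in% include) simulate_counts(cfg, mf$truth)
          else NULL
  list(cfg = cfg, manifest = mf$manifest, truth = mf$truth,
       clock = cohorts$clock, cohorts = cohorts$cohorts,
       blood = cohorts$blood, disease = cohorts$disease,
       validation = cohorts$validation, pan = cohorts$pan,
       counts = expr$counts, counts_sheet = expr$sheet, tpm = expr$tpm)
}

#' Write a simulated dataset to plain-text files
#'
#' Writes every cohort's beta TSV and sample-sheet CSV, the manifest CSV,
#' the clock list, the expression counts and TPM TSVs, and the truth table.
#'
#' @param data List from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  wr_cohort <- function(cohort, stem) {
    write_beta_matrix(cohort$beta, p(paste0(stem, "_beta.tsv")))
    data.table::fwrite(cohort$sheet, p(paste0(stem, "_sheet.csv")))
  }
  for (i in seq_along(data$cohorts))
    wr_cohort(data$cohorts[[i]], paste0("discovery", i))
  wr_cohort(data$blood, "blood")
  for (i in seq_along(data$disease)) wr_cohort(data$disease[[i]],
                                               paste0("disease", i))
  if (!is.null(data$validation))
    for (i in seq_along(data$validation))
      wr_cohort(data$validation[[i]], paste0("validation", i))
  if (!is.null(data$pan))
    for (code in names(data$pan)) wr_cohort(data$pan[[code]],
                                            paste0("pan_", code))
  data.table::fwrite(data$manifest, p("manifest.csv"))
  data.table::fwrite(data$truth, p("truth.tsv"), sep = "\t")
  writeLines(data$clock, p("clock.txt"))
  if (!is.null(data$counts)) {
    data.table::fwrite(data.table::data.table(gene = rownames(data$counts),
                                              data$counts),
                       p("counts.tsv"), sep = "\t")
    data.table::fwrite(data$counts_sheet, p("counts_sheet.csv"))
    data.table::fwrite(data.table::data.table(gene = rownames(data$tpm),
                                              data$tpm),
                       p("tpm.tsv"), sep = "\t")
  }
  invisible(dir)
}
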