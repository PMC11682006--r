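# Unit checks of the generator use a scaled-down configuration; the
# full-size default is exercised by the pipeline-level recovery tests.
small_cfg <- function(seed = 1, ...) {
  sim_config(seed = seed, n_probes = 2000, n_tumor = 30, n_adjacent = 12,
             n_cirrhotic = 5, n_healthy = 5, n_blood = 40, n_disease = 10,
             n_tumor_val = 60, n_pan_t = 10, n_pan_nt = 7,
             n_branch_a = 10, n_branch_b = 6, n_blood_meth = 10,
             n_clock_overlap = 5, n_disease_only = 8, n_hypo = 20,
             clock_size = 50, n_background_genes = 30, ...)
}

test_that("manifest has the exact CGI count and deterministic regeneration", {
  cfg <- sim_config(seed = 4, n_probes = 100, cgi_fraction = 0.5,
                    n_branch_a = 5, n_branch_b = 3, n_blood_meth = 5,
                    n_clock_overlap = 2, n_disease_only = 2, n_hypo = 5,
                    n_pan_cancer = 2, n_index_exclusive = 2,
                    n_background_genes = 5)
  mf <- simulate_manifest(cfg)
  expect_equal(sum(mf$manifest$in_cgi), 50)
  mf2 <- simulate_manifest(cfg)
  expect_identical(mf, mf2)
})

test_that("planted classes are disjoint, CGI-resident and conserve configured counts", {
  cfg <- small_cfg(seed = 2)
  mf <- simulate_manifest(cfg)
  counts <- table(mf$truth$class)
  expect_equal(unname(counts["branch_a"]), cfg$n_branch_a)
  expect_equal(unname(counts["branch_b"]), cfg$n_branch_b)
  expect_equal(unname(counts["blood_methylated"]), cfg$n_blood_meth)
  expect_equal(unname(counts["clock_overlap"]), cfg$n_clock_overlap)
  expect_equal(unname(counts["disease_only"]), cfg$n_disease_only)
  expect_equal(unname(counts["hypo_in_tumor"]), cfg$n_hypo)
  expect_equal(unname(counts["pan_cancer"]), cfg$n_pan_cancer)
  expect_equal(unname(counts["index_exclusive"]), cfg$n_index_exclusive)
  planted <- mf$truth$probe_id[mf$truth$class != "null"]
  expect_equal(anyDuplicated(planted), 0)
  expect_true(all(mf$manifest$in_cgi[match(planted,
                                           mf$manifest$probe_id)]))
})

test_that("panel-probe regions follow the configured promoter:body:intergenic split", {
  cfg <- small_cfg(seed = 3)
  mf <- simulate_manifest(cfg)
  panel <- mf$truth[mf$truth$class %in% c("branch_a", "branch_b"), ]
  got <- table(factor(panel$region,
                      c("promoter", "gene_body", "intergenic")))
  # largest-remainder apportionment of 16 probes at 21:16:2
  expect_equal(unname(c(got)), c(9, 6, 1))
  # region labels agree with the geometric classifier applied to the manifest
  rows <- mf$manifest[match(panel$probe_id, mf$manifest$probe_id), ]
  expect_identical(classify_region(rows), panel$region)
})

test_that("beta cohorts realise the planted effect structure", {
  cfg <- small_cfg(seed = 5)
  mf <- simulate_manifest(cfg)
  sim <- simulate_beta_cohorts(cfg, mf$manifest, mf$truth,
                               include = character(0))
  merged <- merge_cohorts(lapply(sim$cohorts, `[[`, "beta"),
                          lapply(sim$cohorts, `[[`, "sheet"))
  null_ids <- mf$truth$probe_id[mf$truth$class == "null"]
  null_mean <- mean(merged$beta[null_ids,
                                merged$sheet$sample_id[
                                  merged$sheet$group == "healthy"]])
  expect_equal(null_mean, 0.05, tolerance = 0.2)  # Beta(2,38) mean
  a_ids <- mf$truth$probe_id[mf$truth$class == "branch_a"]
  t_mean <- group_mean_beta(merged$beta[a_ids, ], merged$sheet, "tumor")
  h_mean <- group_mean_beta(merged$beta[a_ids, ], merged$sheet, "healthy")
  expect_true(all(t_mean - h_mean > 0.5))
  b_ids <- mf$truth$probe_id[mf$truth$class == "branch_b"]
  adj_mean <- group_mean_beta(merged$beta[b_ids, ], merged$sheet, "adjacent")
  expect_true(all(adj_mean > 0.2 & adj_mean < 0.55))
  # clock list holds all planted overlaps at the configured size
  ck_ids <- mf$truth$probe_id[mf$truth$class == "clock_overlap"]
  expect_length(sim$clock, cfg$clock_size)
  expect_true(all(ck_ids %in% sim$clock))
})

test_that("the generator is fully determined by its seed", {
  cfg <- small_cfg(seed = 7)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$cohorts[[1]]$beta, d2$cohorts[[1]]$beta)
  expect_identical(d1$blood$beta, d2$blood$beta)
  expect_identical(d1$pan$LIHC$beta, d2$pan$LIHC$beta)
  expect_identical(d1$counts, d2$counts)
  expect_identical(d1$tpm, d2$tpm)
  d3 <- simulate_dataset(small_cfg(seed = 8))
  expect_false(identical(d1$cohorts[[1]]$beta, d3$cohorts[[1]]$beta))
})

test_that("expression counts couple to methylation location and silence", {
  cfg <- small_cfg(seed = 9)
  mf <- simulate_manifest(cfg)
  expr <- simulate_counts(cfg, mf$truth)
  truth_genes <- mf$truth[mf$truth$gene != "", ]
  silent <- truth_genes$gene[truth_genes$expr_effect == "silent"]
  cpm <- log_cpm(expr$counts, log = FALSE)
  t_ids <- expr$sheet$sample_id[expr$sheet$group == "tumor"]
  c_ids <- expr$sheet$sample_id[expr$sheet$group == "adjacent"]
  expect_true(all(apply(cpm[silent, c_ids, drop = FALSE], 1, median) < 1))
  up_genes <- truth_genes$gene[truth_genes$expr_effect == "up"]
  down_genes <- truth_genes$gene[truth_genes$expr_effect == "down"]
  expect_true(all(rowMeans(expr$counts[up_genes, t_ids]) >
                    rowMeans(expr$counts[up_genes, c_ids])))
  expect_true(all(rowMeans(expr$counts[down_genes, t_ids]) <
                    rowMeans(expr$counts[down_genes, c_ids])))
  # tissue profiles realised in the TPM table
  rep_genes <- truth_genes$gene[truth_genes$tissue_profile ==
                                  "repressed_in_index"]
  for (g in rep_genes)
    expect_identical(tissue_repression(g, expr$tpm), "repressed_in_index")
})

test_that("a simulated dataset round-trips through the plain-text writers", {
  cfg <- small_cfg(seed = 10)
  d <- simulate_dataset(cfg, include = character(0))
  dir <- withr::local_tempdir()
  write_dataset(d, dir)
  beta_back <- read_beta_matrix(file.path(dir, "discovery1_beta.tsv"))
  expect_equal(beta_back, d$cohorts[[1]]$beta)
  man_back <- read_manifest(file.path(dir, "manifest.csv"))
  expect_equal(as.numeric(man_back$pos), as.numeric(d$manifest$pos))
  expect_identical(read_clock_list(file.path(dir, "clock.txt")), d$clock)
})
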