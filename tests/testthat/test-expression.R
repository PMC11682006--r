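test_that("genomic-context classification is strand-aware with promoter precedence", {
  # plus strand: promoter spans TSS-1500 .. TSS+300
  man <- rbind(
    make_manifest("up1000", pos = 9000L, gene = "G1", tss_pos = 10000L,
                  gene_start = 10000L, gene_end = 20000L),
    make_manifest("body", pos = 10301L, gene = "G1", tss_pos = 10000L,
                  gene_start = 10000L, gene_end = 20000L),
    make_manifest("edge300", pos = 10300L, gene = "G1", tss_pos = 10000L,
                  gene_start = 10000L, gene_end = 20000L),
    make_manifest("inter"))
  expect_identical(classify_region(man),
                   c("promoter", "gene_body", "promoter", "intergenic"))
  expect_error(classify_region(make_manifest("bad", gene = "G2")), "TSS")
})

test_that("region classes are invariant under mirroring about the TSS on the minus strand", {
  # mirror of up1000: minus-strand gene, probe 1000 nt 5' of the TSS
  plus <- make_manifest("p", pos = 9000L, gene = "G", tss_pos = 10000L,
                        gene_start = 10000L, gene_end = 20000L, strand = "+")
  minus <- make_manifest("m", pos = 11000L, gene = "G", tss_pos = 10000L,
                         gene_start = 1L, gene_end = 10000L, strand = "-")
  expect_identical(classify_region(plus), classify_region(minus))
  plus_body <- make_manifest("pb", pos = 15000L, gene = "G", tss_pos = 10000L,
                             gene_start = 10000L, gene_end = 20000L)
  minus_body <- make_manifest("mb", pos = 5000L, gene = "G", tss_pos = 10000L,
                              gene_start = 1L, gene_end = 10000L, strand = "-")
  expect_identical(classify_region(plus_body), classify_region(minus_body))
})

test_that("log-CPM normalisation conserves column sums and matches brute force", {
  counts <- matrix(c(10, 0, 0, 5, 3, 2), nrow = 3,
                   dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  cpm <- log_cpm(counts, log = FALSE)
  expect_equal(cpm["g1", "s1"], 1e6)
  expect_equal(unname(colSums(cpm)), c(1e6, 1e6))
  set.seed(71)
  rnd <- matrix(rpois(50, 100), nrow = 10,
                dimnames = list(sprintf("g%d", 1:10), sprintf("s%d", 1:5)))
  brute <- log2(t(t(rnd) / colSums(rnd)) * 1e6 + 0.5)
  expect_equal(log_cpm(rnd), brute)
  zero <- counts; zero[, 2] <- 0
  expect_error(log_cpm(zero), "zero total")
})

test_that("D'Agostino K2 omnibus statistic matches an independent implementation", {
  # expected values computed with scipy.stats.normaltest on fixed vectors
  x1 <- c(5.304717, 3.960016, 5.750451, 5.940565, 3.048965, 3.69782, 5.12784,
          4.683757, 4.983199, 4.146956, 5.879398, 5.777792, 5.066031,
          6.127241, 5.467509, 4.140708, 5.368751, 4.041117, 5.87845,
          4.950074, 4.815138, 4.31907, 6.222541, 4.845471, 4.571672,
          4.647866, 5.532309, 5.365444, 5.412733, 5.430821)
  r1 <- dagostino_test(x1)
  expect_equal(r1$statistic, 1.9577817476489023, tolerance = 1e-9)
  expect_equal(r1$p_value, 0.3757275971469938, tolerance = 1e-9)
  x2 <- c(0.38868, 1.264207, 0.708491, 0.23793, 0.461088, 0.641557, 0.343833,
          0.321911, 0.878915, 0.296947, 1.333702, 1.390864, 1.084083,
          0.073028, 1.134068, 1.354338, 1.12204, 0.280049, 0.320936,
          0.165736, 0.354364, 0.02114, 0.167356, 1.315057, 3.995756)
  r2 <- dagostino_test(x2)
  expect_equal(r2$statistic, 33.679839567772376, tolerance = 1e-9)
  expect_equal(r2$p_value, 4.858651644745354e-08, tolerance = 1e-6)
  x3 <- c(-0.319671, -0.470373, -0.638878, -0.275142, 1.494941, -0.865831,
          0.968278, -1.68287, -0.334885)
  r3 <- dagostino_test(x3)
  expect_equal(r3$statistic, 1.3289458840080386, tolerance = 1e-9)
  expect_error(dagostino_test(rnorm(5)), "at least 8")
})

test_that("expression status: silent, shifted and null genes classify correctly", {
  set.seed(81)
  n_t <- 30; n_c <- 30
  ids <- c(sprintf("t%02d", 1:n_t), sprintf("c%02d", 1:n_c))
  sheet <- make_sheet(ids, rep(c("tumor", "adjacent"), c(n_t, n_c)))
  lib <- 1e6  # one library-size anchor gene keeps totals comparable
  mk_counts <- function(t_counts, c_counts) {
    m <- rbind(gene = c(t_counts, c_counts), anchor = rep(lib, n_t + n_c))
    colnames(m) <- ids
    m
  }
  # silent: a handful of counts against a 1e6-count library -> CPM << 1
  silent <- mk_counts(rpois(n_t, 0.2), rpois(n_c, 0.1))
  expect_identical(expression_status("gene", silent, sheet)$status,
                   "not_expressed")
  # clearly shifted normal-ish groups -> up, p < 0.001
  up <- mk_counts(rnbinom(n_t, mu = 2000, size = 50),
                  rnbinom(n_c, mu = 250, size = 50))
  res_up <- expression_status("gene", up, sheet)
  expect_identical(res_up$status, "up")
  expect_lt(res_up$p_value, 0.001)
  # identical groups -> unchanged
  base <- rnbinom(n_t, mu = 500, size = 20)
  null <- mk_counts(base, base)
  expect_identical(expression_status("gene", null, sheet)$status, "unchanged")
})

test_that("expression status swaps down/up under group relabelling", {
  set.seed(83)
  ids <- c(sprintf("t%02d", 1:25), sprintf("c%02d", 1:25))
  sheet <- make_sheet(ids, rep(c("tumor", "adjacent"), each = 25))
  counts <- rbind(gene = c(rnbinom(25, mu = 100, size = 20),
                           rnbinom(25, mu = 800, size = 20)),
                  anchor = rep(1e5, 50))
  colnames(counts) <- ids
  fwd <- expression_status("gene", counts, sheet)
  rev <- expression_status("gene", counts, sheet,
                           case = "adjacent", control = "tumor")
  expect_identical(fwd$status, "down")
  expect_identical(rev$status, "up")
  expect_equal(fwd$p_value, rev$p_value)
  expect_equal(fwd$log_fc, -rev$log_fc)
})

test_that("concordance pairs promoter with down and gene body with up", {
  expect_true(concordance("promoter", "down"))
  expect_false(concordance("promoter", "up"))      # the SEPT9-like exception
  expect_false(concordance("gene_body", "down"))   # the AMN-like exception
  expect_true(concordance("gene_body", "up"))
  expect_true(is.na(concordance("intergenic", "down")))
  expect_true(is.na(concordance("promoter", "not_expressed")))
})

test_that("tissue repression distinguishes index-repressed from broadly silent genes", {
  tissues <- c("liver", sprintf("t%02d", 1:19))
  tpm <- matrix(20, nrow = 3, ncol = 20,
                dimnames = list(c("rep", "silent", "expr"), tissues))
  tpm["rep", "liver"] <- 0.1
  tpm["silent", ] <- 0.2
  tpm["expr", "liver"] <- 50
  expect_identical(tissue_repression("rep", tpm), "repressed_in_index")
  expect_identical(tissue_repression("silent", tpm), "broadly_silent")
  expect_identical(tissue_repression("expr", tpm), "expressed_in_index")
  expect_error(tissue_repression("missing", tpm), "absent")
})

test_that("location/expression cross-tabulation counts genes once and CpGs per probe", {
  recs <- data.frame(
    probe_id = c("cg1", "cg2", "cg3", "cg4"),
    gene = c("GA", "GA", "GB", ""),
    region = c("promoter", "promoter", "gene_body", "intergenic"),
    expr_status = c("down", "down", "up", NA),
    stringsAsFactors = FALSE)
  tab <- location_expression_table(recs)
  prom <- tab[tab$region == "promoter", ]
  expect_equal(prom$n_cpg, 2)
  expect_equal(prom$n_gene, 1)
  expect_equal(prom$cpg_down, 2)
  expect_equal(prom$gene_down, 1)
  expect_equal(tab[tab$region == "total", "n_cpg"], 4)
  empty <- location_expression_table(recs[0, ])
  expect_true(all(empty$n_cpg == 0))
})
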