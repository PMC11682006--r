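test_that("blood filter excludes on any sample strictly above the threshold", {
  blood <- make_beta(c(0.05, 0.19,   # retained: no sample > 0.2
                       0.05, 0.21,   # excluded: one sample above
                       0.05, 0.20),  # retained: boundary is not 'methylated'
                     c("cg1", "cg2", "cg3"), c("b1", "b2"))
  expect_identical(blood_filter(c("cg1", "cg2", "cg3"), blood),
                   c("cg1", "cg3"))
  expect_error(blood_filter("cgX", blood), "cgX")
})

test_that("clock filter reports the overlap instead of assuming it empty", {
  expect_identical(clock_filter(c("cg1", "cg2"), "cg3"),
                   list(retained = c("cg1", "cg2"), overlap = character(0)))
  expect_identical(clock_filter("cg1", "cg1"),
                   list(retained = character(0), overlap = "cg1"))
  set.seed(31)
  cands <- sprintf("cg%04d", sample(1:5000, 1061))
  clock <- sprintf("ck%03d", 1:353)
  res <- clock_filter(cands, clock)
  expect_identical(res$retained, cands)
  expect_length(res$overlap, 0)
})

test_that("branch A requires universal non-tumoral unmethylation and delta > 0.3", {
  fx <- make_liver_fixture(data.frame(
    probe_id = c("ok", "adj_meth", "weak_delta"),
    tumor = c(0.55, 0.55, 0.38),
    adjacent = c(0.10, 0.25, 0.10),
    cirrhotic = c(0.10, 0.10, 0.10),
    healthy = c(0.10, 0.10, 0.10)))
  sel <- branch_a(c("ok", "adj_meth", "weak_delta"), fx$beta, fx$sheet)
  expect_identical(sel, "ok")  # delta 0.45 and all non-tumoral at 0.10
  # weak_delta: non-tumoral mean 0.10, delta 0.28 < 0.3
  expect_false("weak_delta" %in% sel)
  no_adj <- fx$sheet[fx$sheet$group != "adjacent", ]
  expect_error(branch_a("ok", fx$beta, no_adj), "adjacent")
})

test_that("branch B requires field-effect methylation in adjacent tissue", {
  fx <- make_liver_fixture(data.frame(
    probe_id = c("ok", "adj_low", "weak_delta"),
    tumor = c(0.60, 0.60, 0.45),
    adjacent = c(0.35, 0.15, 0.35),
    cirrhotic = c(0.10, 0.10, 0.10),
    healthy = c(0.10, 0.10, 0.10)))
  sel <- branch_b(c("ok", "adj_low", "weak_delta"), fx$beta, fx$sheet)
  expect_identical(sel, "ok")   # delta vs tumor-free livers = 0.50 > 0.4
  # weak_delta: 0.45 - 0.10 = 0.35 < 0.4
})

test_that("combine_panel is the union with a summary-criterion verification", {
  fx <- make_liver_fixture(data.frame(
    probe_id = c("cg1", "cg2", "cg3", "lowbeta"),
    tumor = c(0.55, 0.55, 0.60, 0.28),
    adjacent = c(0.10, 0.10, 0.35, 0.10),
    cirrhotic = c(0.10, 0.10, 0.10, 0.10),
    healthy = c(0.10, 0.10, 0.10, 0.10)))
  panel <- combine_panel(c("cg1", "cg2"), "cg3", fx$beta, fx$sheet)
  expect_setequal(panel$probe_id, c("cg1", "cg2", "cg3"))
  expect_true(all(panel$in_panel))
  expect_true(all(panel$summary_ok))
  # a member whose tumor mean is below the panel criterion gets flagged
  panel2 <- combine_panel(c("cg1", "lowbeta"), character(0), fx$beta, fx$sheet)
  expect_false(panel2$summary_ok[panel2$probe_id == "lowbeta"])
  expect_warning(combine_panel("cg1", "cg1", fx$beta, fx$sheet), "exclusive")
})

test_that("branch selection is monotone in its thresholds", {
  set.seed(41)
  fx <- make_liver_fixture(data.frame(
    probe_id = sprintf("cg%02d", 1:40),
    tumor = runif(40, 0.2, 0.9),
    adjacent = runif(40, 0, 0.4),
    cirrhotic = runif(40, 0, 0.3),
    healthy = runif(40, 0, 0.3)))
  cands <- rownames(fx$beta)
  base <- branch_a(cands, fx$beta, fx$sheet, filter_config())
  looser <- branch_a(cands, fx$beta, fx$sheet,
                     filter_config(unmeth_thresh = 0.35))
  expect_true(all(base %in% looser))
  stricter <- branch_a(cands, fx$beta, fx$sheet,
                       filter_config(branch_a_delta = 0.5))
  expect_true(all(stricter %in% base))
})

test_that("branches are mutually exclusive whenever unmeth <= meth threshold", {
  set.seed(43)
  for (i in 1:50) {
    fx <- make_liver_fixture(data.frame(
      probe_id = sprintf("cg%02d", 1:20),
      tumor = runif(20), adjacent = runif(20, 0, 0.6),
      cirrhotic = runif(20, 0, 0.3), healthy = runif(20, 0, 0.3)))
    u <- runif(1, 0.05, 0.5)
    cfg <- filter_config(unmeth_thresh = u, meth_thresh = runif(1, u, 0.6),
                         branch_a_delta = runif(1, 0.1, 0.5),
                         branch_b_delta = runif(1, 0.1, 0.5))
    a <- branch_a(rownames(fx$beta), fx$beta, fx$sheet, cfg)
    b <- branch_b(rownames(fx$beta), fx$beta, fx$sheet, cfg)
    expect_length(intersect(a, b), 0)
  }
})

test_that("disease exclusion flags hypermethylation in any disease cohort", {
  mk <- function(d_mean, c_mean) {
    ids <- c(sprintf("d%d", 1:4), sprintf("h%d", 1:4))
    beta <- make_beta(rep(c(d_mean, c_mean), each = 4), "cg1", ids)
    list(beta = beta,
         sheet = make_sheet(ids, rep(c("disease", "healthy"), each = 4),
                            cohort = "dis"))
  }
  expect_false(disease_exclusion_check("cg1", list(mk(0.15, 0.10)))[["cg1"]])
  expect_true(disease_exclusion_check("cg1", list(mk(0.35, 0.10)))[["cg1"]])
  # flagged if hyper in ANY cohort
  expect_true(disease_exclusion_check(
    "cg1", list(mk(0.12, 0.10), mk(0.40, 0.10)))[["cg1"]])
  no_ctrl <- mk(0.35, 0.10)
  no_ctrl$sheet$group <- "disease"
  expect_error(disease_exclusion_check("cg1", list(no_ctrl)), "control")
})

test_that("tumor methylation fraction counts methylated validation tumors", {
  ids <- sprintf("v%d", 1:4)
  beta <- make_beta(c(0.5, 0.1, 0.6, 0.7, 0.1, 0.15, 0.18, 0.19),
                    c("cg1", "cg2"), ids)
  val <- list(list(beta = beta, sheet = make_sheet(ids, rep("tumor", 4),
                                                   cohort = "val")))
  frac <- tumor_methylation_fraction(c("cg1", "cg2"), val)
  expect_equal(unname(frac), c(0.75, 0))
  no_t <- val
  no_t[[1]]$sheet$group <- "healthy"
  expect_error(tumor_methylation_fraction("cg1", no_t), "tumor")
})
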