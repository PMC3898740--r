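test_that("a multi-variant homozygous carrier counts once dominant, by alleles additive", {
  # case 1 carries two qualifying variants, one homozygous: dominant
  # contribution 1, additive contribution 3
  m <- matrix(0L, 6, 2)
  m[1, 1] <- 2L; m[1, 2] <- 1L
  co <- toy_cohort(m, n_case = 3)
  qual <- c("v01", "v02")
  dom <- carrier_table(co, qual, "dominant")
  expect_identical(unname(dom[1:4]), c(1L, 2L, 0L, 3L))
  add <- carrier_table(co, qual, "additive")
  expect_identical(unname(add[1:4]), c(3L, 3L, 0L, 6L))
})

test_that("empty qualifying set yields the degenerate table", {
  co <- toy_cohort(matrix(0L, 8, 1), n_case = 3)
  tab <- carrier_table(co, character(0), "dominant")
  expect_identical(unname(tab[1:4]), c(0L, 3L, 0L, 5L))
})

test_that("carrier table matches an exhaustive manual tally on a toy cohort", {
  set.seed(14)
  m <- matrix(rbinom(10 * 4, 2, 0.25), 10, 4)
  co <- toy_cohort(m, n_case = 4)
  qual <- c("v01", "v03")
  tab <- carrier_table(co, qual, "dominant")
  manual_a <- sum(rowSums(m[1:4, c(1, 3)]) > 0)
  manual_c <- sum(rowSums(m[5:10, c(1, 3)]) > 0)
  expect_identical(unname(tab[1:4]),
                   c(manual_a, 4L - manual_a, manual_c, 6L - manual_c))
  add <- carrier_table(co, qual, "additive")
  expect_identical(add[["a"]], sum(m[1:4, c(1, 3)]))
})

test_that("dominant carrier count never exceeds additive allele count", {
  for (seed in 1:5) {
    co <- simulate_cohort(sim_config(n_cases = 100, n_controls = 100,
                                     n_sites = 15, seed = seed,
                                     maf_spectrum = maf_uniform(1e-3, 0.05)))
    qual <- co$variants$variant_id
    dom <- carrier_table(co, qual, "dominant")
    add <- carrier_table(co, qual, "additive")
    expect_lte(dom[["a"]], add[["a"]])
    expect_lte(dom[["c"]], add[["c"]])
  }
})

test_that("degenerate arms are rejected before testing", {
  co <- toy_cohort(matrix(0L, 4, 1), n_case = 4)
  expect_error(carrier_table(co, "v01", "dominant"), "degenerate")
  expect_error(vt_scan(co, burden_config()), "degenerate")
})

test_that("vt_scan: thresholds with identical qualifying sets share one p", {
  # every variant far below the strictest threshold
  m <- matrix(0L, 3000, 2)
  m[1:2, 1] <- 1L     # v01: two case hets, MAF 2/6000
  m[1501, 2] <- 1L    # v02: one control het, MAF 1/6000
  co <- toy_cohort(m, n_case = 1500)
  res <- vt_scan(co, burden_config(n_permutations = 1))
  expect_length(unique(res$per_threshold$fisher_p), 1L)
  expect_identical(res$min_p, res$per_threshold$fisher_p[1])
  # ties break toward the largest threshold
  expect_identical(res$min_p_threshold, 0.005)
})

test_that("vt_scan: a variant qualifying only at the loosest threshold moves the min", {
  # a balanced variant at pooled MAF 0.003 qualifies at 0.005 only and
  # dilutes the signal there; the rare case-enriched variant drives the
  # min at the stricter 0.001 threshold
  n <- 1000
  m <- matrix(0L, 2 * n, 2)
  m[c(4:9, (n + 4):(n + 9)), 1] <- 1L    # v01: 6 case + 6 control hets
  m[1:3, 2] <- 1L                        # v02: 3 case hets, MAF 0.00075
  co <- toy_cohort(m, n_case = n)
  res <- vt_scan(co, burden_config(n_permutations = 1))
  pt <- res$per_threshold
  expect_identical(pt$n_qualifying, c(2L, 1L, 0L))
  # manual per-threshold tables
  expect_identical(pt$a, c(9L, 3L, 0L))
  expect_identical(pt$c, c(6L, 0L, 0L))
  expect_equal(pt$fisher_p[1], fisher_oracle(9, 991, 6, 994),
               tolerance = 1e-12)
  expect_equal(pt$fisher_p[2], fisher_oracle(3, 997, 0, 1000),
               tolerance = 1e-12)
  expect_identical(pt$fisher_p[3], 1)
  expect_identical(res$min_p_threshold, 0.001)
  expect_identical(res$min_p, min(pt$fisher_p))
})

test_that("zero carriers everywhere gives min_p 1", {
  co <- toy_cohort(matrix(0L, 20, 2), n_case = 10)
  res <- vt_scan(co, burden_config())
  expect_identical(res$min_p, 1)
  expect_true(all(res$per_threshold$fisher_p == 1))
})

test_that("min_p equals the per-threshold minimum on random cohorts", {
  for (seed in 6:10) {
    co <- simulate_cohort(sim_config(n_cases = 150, n_controls = 150,
                                     n_sites = 20, odds_ratio = 3,
                                     seed = seed))
    res <- vt_scan(co, burden_config())
    expect_identical(res$min_p, min(res$per_threshold$fisher_p))
  }
})

test_that("normal-weight subset shrinks the control arm only", {
  m <- matrix(0L, 10, 1); m[1, 1] <- 1L
  bmi <- c(rep(45, 4), 22, 28, 31, 24, NA, 29)
  co <- toy_cohort(m, n_case = 4, bmi = bmi)
  sub <- normal_weight_controls(co)
  expect_identical(n_cases(sub), 4L)
  # controls kept: bmi 22, 28, 24, 29 (31 excluded, NA unverifiable)
  expect_identical(n_controls(sub), 4L)
  res <- vt_scan(co, burden_config(control_subset = "normal_weight"))
  expect_identical(res$n_controls, 4L)
})

test_that("weight classes follow the BMI cutpoints", {
  expect_identical(weight_class(c(20, 25, 30, 30.1, NA)),
                   c("normal", "overweight", "overweight", "obese", NA))
})

test_that("merging cohorts sums arms and reconciles variants", {
  a <- make_paper_fixture()
  b <- make_replication_fixture()
  m <- merge_cohorts(a, b)
  expect_identical(n_cases(m), 2339L)
  expect_identical(n_controls(m), 2653L)
  # identity under empty merge
  empty <- cohort(a$individuals[0, ], a$variants[0, ], a$genotypes[0, ])
  same <- merge_cohorts(a, empty)
  expect_equal(same$individuals, a$individuals)
  expect_equal(same$genotypes, a$genotypes)
  # id collision
  expect_error(merge_cohorts(a, a), "collision")
  # conflicting annotation
  b2 <- b
  b2$variants$protein_pos[b2$variants$variant_id == "V22"] <- 999L
  expect_error(merge_cohorts(a, b2), "conflicting annotation")
})

test_that("merged pooled MAF equals combined allele count over combined 2N", {
  # 20-individual arithmetic check for a variant carried in both cohorts
  m1 <- matrix(0L, 12, 1); m1[c(1, 7), 1] <- c(1L, 2L)
  m2 <- matrix(0L, 8, 1); m2[3, 1] <- 1L
  a <- toy_cohort(m1, n_case = 6)
  b <- toy_cohort(m2, n_case = 4)
  b$individuals$individual_id <- sprintf("j%03d", 1:8)
  b$individuals$cohort_label <- "replication"
  b$genotypes$individual_id <- "j003"
  b <- validate_cohort(b)
  mg <- merge_cohorts(a, b)
  expect_identical(compute_sample_maf(mg, "v01"), (1 + 2 + 1) / (2 * 20))
})

test_that("run_analysis executes plan cells with provenance", {
  co <- simulate_cohort(sim_config(n_cases = 120, n_controls = 150,
                                   n_sites = 12, odds_ratio = 3, seed = 8))
  regions <- data.frame(region_name = "kinase", start = 634L, end = 938L)
  plan <- analysis_plan(sample = "original",
                        control_set = c("all", "normal_weight"),
                        scope = c("whole_gene", "kinase"),
                        model = c("dominant", "additive"))
  rep <- run_analysis(co, plan, burden_config(n_permutations = 50, seed = 3),
                      regions = regions)
  expect_s3_class(rep, "burden_report")
  expect_length(rep, 2L)
  r1 <- rep[[1]]$result
  expect_true(r1$adjusted_p >= 1 / 51 && r1$adjusted_p <= 1)
  # normal-weight cell shrinks the control arm
  expect_lte(rep[[2]]$result$n_controls, r1$n_controls)
  expect_identical(rep[[2]]$config$region$region_name, "kinase")
  # unknown region or missing regions table is a config error
  bad <- analysis_plan(scope = "nope")
  expect_error(run_analysis(co, bad, burden_config(n_permutations = 5),
                            regions = regions), "unknown region")
  expect_error(run_analysis(co, bad, burden_config(n_permutations = 5)),
               "no regions table")
  # plan cell requesting a missing sample
  expect_error(run_analysis(co, analysis_plan(sample = "replication"),
                            burden_config(n_permutations = 5)),
               "replication")
})

test_that("config validation rejects malformed ladders", {
  expect_error(burden_config(thresholds = c(0.001, 0.005)),
               "strictly decreasing")
  expect_error(burden_config(thresholds = numeric(0)))
  expect_error(burden_config(thresholds = c(0.6)))
  expect_error(burden_config(n_permutations = 0))
  expect_error(analysis_plan(sample = "bogus"), "unknown plan sample")
})
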