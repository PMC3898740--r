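write_stanza_file <- function(ind, var, gt, path = tempfile(fileext = ".tsv")) {
  writeLines(c("#table: individuals",
               "individual_id\tstatus\tcohort_label\tbmi", ind,
               "#table: variants",
               "variant_id\tprotein_pos\tfunc_class", var,
               "#table: genotypes",
               "individual_id\tvariant_id\tallele_count", gt), path)
  path
}

test_that("smallest valid file parses: one carrier case, one non-carrier control", {
  f <- write_stanza_file(c("p1\tcase\toriginal\t",
                           "p2\tcontrol\toriginal\t24.5"),
                         "R684C\t684\tmissense",
                         "p1\tR684C\t1")
  co <- read_variant_table(f)
  expect_s3_class(co, "cohort")
  expect_identical(nrow(co$individuals), 2L)
  expect_identical(nrow(co$variants), 1L)
  expect_identical(nrow(co$genotypes), 1L)
  # empty bmi field means missing
  expect_true(is.na(co$individuals$bmi[1]))
  expect_equal(co$individuals$bmi[2], 24.5)
})

test_that("one individual may hold homozygous entries for several variants", {
  f <- write_stanza_file(c("p1\tcase\toriginal\t41", "p2\tcontrol\toriginal\t22"),
                         c("R253W\t253\tmissense", "D323E\t323\tmissense"),
                         c("p1\tR253W\t2", "p1\tD323E\t2"))
  co <- read_variant_table(f)
  expect_identical(sum(co$genotypes$individual_id == "p1"), 2L)
  expect_true(all(co$genotypes$allele_count == 2L))
})

test_that("invalid rows are rejected with informative errors", {
  # allele_count outside {1, 2}
  f <- write_stanza_file("p1\tcase\toriginal\t41",
                         "V1\t100\tmissense", "p1\tV1\t3")
  expect_error(read_variant_table(f), "allele_count")
  # wrong field count names the file line
  f2 <- write_stanza_file("p1\tcase\toriginal\t41\textra",
                          "V1\t100\tmissense", "p1\tV1\t1")
  expect_error(read_variant_table(f2), "line 3")
  # genotype referencing an unknown individual
  f3 <- write_stanza_file("p1\tcase\toriginal\t41",
                          "V1\t100\tmissense", "ghost\tV1\t1")
  expect_error(read_variant_table(f3), "unknown individual_id")
  # duplicate (individual, variant) pair
  f4 <- write_stanza_file("p1\tcase\toriginal\t41",
                          "V1\t100\tmissense",
                          c("p1\tV1\t1", "p1\tV1\t2"))
  expect_error(read_variant_table(f4), "duplicate")
  # missing stanza
  f5 <- tempfile(); writeLines("#table: individuals\nindividual_id", f5)
  expect_error(read_variant_table(f5), "missing stanza")
})

test_that("write/read round-trip is lossless in both layouts", {
  co <- simulate_cohort(sim_config(n_cases = 40, n_controls = 60,
                                   n_sites = 8, seed = 5))
  f <- tempfile(fileext = ".tsv")
  write_variant_table(co, f)
  back <- read_variant_table(f)
  expect_equal(back$individuals, co$individuals)
  expect_equal(back$variants[c("variant_id", "protein_pos", "func_class")],
               co$variants[c("variant_id", "protein_pos", "func_class")])
  expect_equal(back$genotypes, co$genotypes)
  d <- tempfile()
  write_variant_table(co, d, as_dir = TRUE)
  back2 <- read_variant_table(d)
  expect_equal(back2$genotypes, co$genotypes)
  expect_equal(back2$individuals, co$individuals)
})

test_that("regions file reads and validates", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("region_name\tstart\tend", "CA3\t330\t390",
               "kinase\t634\t938"), f)
  reg <- read_regions(f)
  expect_identical(reg$region_name, c("CA3", "kinase"))
  expect_identical(reg$start, c(330L, 634L))
  bad <- tempfile()
  writeLines(c("region_name\tstart\tend", "x\t10\t5"), bad)
  expect_error(read_regions(bad), "start <= end")
})

test_that("packaged example regions file covers the kinase-domain mutations", {
  reg <- read_regions(system.file("extdata", "ksr2_regions.tsv",
                                  package = "vtburden"))
  k <- reg[reg$region_name == "kinase", ]
  expect_identical(nrow(k), 1L)
  # the approximate interval must span the C-terminal missense cluster
  expect_true(k$start <= 662 && k$end >= 904)
})

test_that("minimal VCF ingestion maps GT and INFO to the cohort model", {
  skip_if_not_installed("vcfR")
  f <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=PPOS,Number=1,Type=Integer,Description=\"residue\">",
    "##INFO=<ID=FCLASS,Number=1,Type=String,Description=\"class\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", "s3", sep = "\t"),
    paste("12", "117890000", "R684C", "C", "T", ".", "PASS",
          "PPOS=684;FCLASS=missense", "GT", "0/1", "0/0", "1/1", sep = "\t"),
    paste("12", "117890500", "Y569X", "C", "A", ".", "PASS",
          "PPOS=569;FCLASS=nonsense", "GT", "0/0", "0/1", "0/0", sep = "\t")),
    f)
  ind <- data.frame(individual_id = c("s1", "s2", "s3"),
                    status = c("case", "case", "control"),
                    cohort_label = "original", bmi = NA_real_)
  co <- read_vcf_cohort(f, ind)
  expect_identical(nrow(co$variants), 2L)
  expect_identical(sort(co$variants$func_class), c("missense", "nonsense"))
  gt <- co$genotypes[order(co$genotypes$individual_id,
                           co$genotypes$variant_id), ]
  expect_identical(gt$allele_count,
                   c(1L, 1L, 2L))  # s1 het R684C, s2 het Y569X, s3 hom R684C
  expect_equal(compute_sample_maf(co, "R684C"), 3 / 6)
})

test_that("multi-allelic VCF sites are rejected", {
  skip_if_not_installed("vcfR")
  f <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", sep = "\t"),
    paste("12", "1000", "v", "C", "T,G", ".", "PASS", ".",
          "GT", "0/1", sep = "\t")), f)
  ind <- data.frame(individual_id = "s1", status = "case",
                    cohort_label = "original", bmi = NA_real_)
  expect_error(read_vcf_cohort(f, ind), "multi-allelic")
})
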