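test_that("fibrosis grades dichotomize at the G3 threshold", {
  expect_equal(grade_to_group(c(0, 1, 2)), rep("control", 3))
  expect_equal(grade_to_group(c(3, 4)), rep("case", 2))
  expect_error(grade_to_group(5, patient_id = "P9"), "P9")
  expect_error(grade_to_group(-1), "0..4")
  expect_error(grade_to_group(1.5), "integer")
})

test_that("the published grade histogram splits 107 controls / 48 cases", {
  grades <- rep(0:4, times = c(17, 54, 36, 38, 10))
  grp <- grade_to_group(grades)
  expect_equal(length(grades), 155)
  expect_equal(sum(grp == "control"), 107)
  expect_equal(sum(grp == "case"), 48)
})

test_that("cohort construction validates panel, patients and dosage", {
  coh <- make_tiny_cohort()
  expect_s3_class(coh, "cohort")
  expect_equal(dim(coh$dosage), c(6, 2))
  expect_equal(coh$patients$group,
               c("control", "control", "control", "case", "case", "case"))

  panel <- coh$panel
  bad_panel <- panel; bad_panel$allele2[1] <- bad_panel$allele1[1]
  expect_error(as_snp_panel(bad_panel), "allele1 must differ")
  dup_panel <- rbind(panel, panel[1, ])
  expect_error(as_snp_panel(dup_panel), "duplicate rs_id")

  pats <- coh$patients[c("patient_id", "fibrosis_grade")]
  pats$fibrosis_grade[2] <- NA
  expect_error(new_cohort(panel, pats, coh$dosage), "missing fibrosis_grade")

  bad_dos <- coh$dosage; bad_dos[1, 1] <- 3L
  expect_error(new_cohort(panel, coh$patients, bad_dos), "rs1")
})

test_that("genotype TSV round-trips, with errors naming the offending line", {
  dir <- withr::local_tempdir()
  coh <- make_tiny_cohort()
  paths <- write_cohort(coh, dir)
  back <- read_genotype_table(paths["genotype"], read_panel(paths["panel"]),
                              read_phenotype(paths["phenotype"]))
  expect_identical(back$dosage, coh$dosage)
  expect_identical(back$patients, coh$patients)

  # a cell outside {0,1,2,NA} is rejected with its line number
  lines <- readLines(paths["genotype"])
  lines[3] <- sub("\t1\t", "\t3\t", lines[3])
  bad <- file.path(dir, "bad.tsv")
  writeLines(lines, bad)
  expect_error(read_genotype_table(bad, coh$panel, coh$patients),
               "line 3")

  # duplicated patient row
  writeLines(c(readLines(paths["genotype"]), lines[2]),
             file.path(dir, "dup.tsv"))
  expect_error(read_genotype_table(file.path(dir, "dup.tsv"), coh$panel,
                                   coh$patients), "duplicate patient_id")

  # unknown rs column
  lines2 <- readLines(paths["genotype"])
  lines2[1] <- sub("rs2", "rs99", lines2[1])
  writeLines(lines2, file.path(dir, "unk.tsv"))
  expect_error(read_genotype_table(file.path(dir, "unk.tsv"), coh$panel,
                                   coh$patients), "rs99")

  # a genotyped patient without a grade is rejected, not dropped
  expect_error(read_genotype_table(paths["genotype"], coh$panel,
                                   coh$patients[-2, ]), "P2")
})

test_that("a simulated 155 x 45 cohort survives the TSV round trip intact", {
  cfg <- sim_config(reported_sim_panel("null"), seed = 11L)
  coh <- simulate_cohort(cfg)
  dir <- withr::local_tempdir()
  paths <- write_cohort(coh, dir)
  back <- read_genotype_table(paths["genotype"], read_panel(paths["panel"]),
                              read_phenotype(paths["phenotype"]))
  expect_identical(back$dosage, coh$dosage)
  expect_identical(back$panel, coh$panel)
})

test_that("allele counts follow the dosage algebra and a per-patient tally", {
  coh <- make_tiny_cohort()
  # cases: dosages (1,2,0) at rs1 -> b = 3, a = 2*3-3 = 3
  t1 <- count_alleles(coh, "rs1")
  expect_equal(c(t1$a, t1$b, t1$c, t1$d), c(3, 3, 3, 3))
  # rs2 has one missing control genotype: complete-case per marker
  t2 <- count_alleles(coh, "rs2")
  expect_equal(t2$c + t2$d, 2 * 2)

  # brute-force per-patient loop oracle on a simulated cohort
  coh2 <- simulate_cohort(sim_config(reported_sim_panel("null"), seed = 3L))
  all_counts <- count_alleles_all(coh2)
  for (j in c(1, 7, 22, 45)) {
    b <- 0L; n_case <- 0L; d <- 0L; n_ctrl <- 0L
    for (i in seq_len(nrow(coh2$patients))) {
      g <- coh2$dosage[i, j]
      if (is.na(g)) next
      if (coh2$patients$group[i] == "case") { b <- b + g; n_case <- n_case + 1L }
      else { d <- d + g; n_ctrl <- n_ctrl + 1L }
    }
    expect_equal(all_counts$b[j], b)
    expect_equal(all_counts$a[j], 2L * n_case - b)
    expect_equal(all_counts$d[j], d)
    expect_equal(all_counts$c[j], 2L * n_ctrl - d)
  }

  # permuting patient rows leaves every allele table unchanged
  set.seed(5)
  perm <- sample(nrow(coh2$patients))
  coh_p <- new_cohort(coh2$panel,
                      coh2$patients[perm, c("patient_id", "fibrosis_grade")],
                      coh2$dosage[perm, ])
  expect_equal(count_alleles_all(coh_p)[c("a", "b", "c", "d")],
               all_counts[c("a", "b", "c", "d")])
})

test_that("allele percentages use integer rounding with 0.5/99.5 edges", {
  expect_equal(unname(allele_percentages(allele_table(74, 22, 157, 57))),
               c(77, 23, 73, 27))
  expect_equal(unname(allele_percentages(allele_table(96, 0, 214, 0))),
               c(100, 0, 100, 0))
  expect_equal(unname(allele_percentages(allele_table(48, 48, 107, 107))),
               c(50, 50, 50, 50))
  # the rare-allele rendering: 1/214 -> 0.5, 213/214 -> 99.5, but 1/96 -> 1
  expect_equal(unname(allele_percentages(allele_table(95, 1, 213, 1))),
               c(99, 1, 99.5, 0.5))
  expect_true(all(is.na(allele_percentages(allele_table(0, 0, 10, 2)))[1:2]))
})

test_that("VCF genotypes map to dosage with NA for non-biallelic calls", {
  skip_if_not_installed("vcfR")
  dir <- withr::local_tempdir()
  vcf <- file.path(dir, "toy.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "P1", "P2", "P3", sep = "\t"),
    paste("1", "100", "rs1", "A", "G", ".", "PASS", ".", "GT",
          "0/0", "0/1", "1|1", sep = "\t"),
    paste("1", "200", "rs2", "C", "T", ".", "PASS", ".", "GT",
          "./.", "0/2", "0/1", sep = "\t")), vcf)
  panel <- data.frame(gene = c("G1", "G2"), rs_id = c("rs1", "rs2"),
                      allele1 = c("A", "C"), allele2 = c("G", "T"))
  pheno <- data.frame(patient_id = c("P1", "P2", "P3"),
                      fibrosis_grade = c(0, 3, 4))
  expect_warning(coh <- read_cohort_vcf(vcf, panel, pheno), "multi-allelic")
  expect_equal(unname(coh$dosage[, "rs1"]), c(0L, 1L, 2L))
  expect_equal(unname(coh$dosage[, "rs2"]), c(NA_integer_, NA_integer_, 1L))
  expect_equal(coh$patients$group, c("control", "case", "case"))
})
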