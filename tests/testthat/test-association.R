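test_that("Woolf odds ratios reproduce published 2x2 rows", {
  e <- odds_ratio_woolf(c(71, 25, 125, 89))
  expect_equal(round(e[["or"]], 2), 0.49)
  expect_equal(round(e[["ci_low"]], 2), 0.29)
  expect_equal(round(e[["ci_high"]], 2), 0.84)

  e2 <- odds_ratio_woolf(c(95, 1, 198, 16))
  expect_equal(round(e2[["or"]], 2), 0.13)
  expect_equal(e2[["ci_low"]], 0.01702, tolerance = 1e-3)
  expect_equal(e2[["ci_high"]], 0.99688, tolerance = 1e-3)

  expect_equal(odds_ratio_woolf(c(10, 10, 10, 10))[["or"]], 1)
  expect_error(odds_ratio_woolf(c(1, 0, 2, 3)), "cells")
})

test_that("swapping case and control rows inverts the OR and its CI", {
  set.seed(101)
  for (i in 1:25) {
    x <- random_table() + 1  # all cells positive
    e <- odds_ratio_woolf(x)
    es <- odds_ratio_woolf(x[c(3, 4, 1, 2)])
    expect_equal(es[["or"]], 1 / e[["or"]])
    expect_equal(es[["ci_low"]], 1 / e[["ci_high"]])
    expect_equal(es[["ci_high"]], 1 / e[["ci_low"]])
    # relabeling allele1 <-> allele2 does the same
    ea <- odds_ratio_woolf(x[c(2, 1, 4, 3)])
    expect_equal(ea[["or"]], 1 / e[["or"]])
  }
})

test_that("Katz risk ratio covers the zero-control-variant fallback", {
  e <- risk_ratio_katz(c(94, 2, 214, 0))
  expect_equal(e[["rr"]], 308 / 94)  # closed form by hand
  expect_equal(round(e[["rr"]], 2), 3.28)
  expect_equal(round(e[["ci_low"]], 2), 2.77)
  expect_equal(round(e[["ci_high"]], 2), 3.88)
  # closed form (b/(b+d)) / (a/(a+c)) = (10/10) / (10/20) = 2
  expect_equal(risk_ratio_katz(c(10, 10, 10, 0))[["rr"]], 2)
  expect_error(risk_ratio_katz(c(10, 0, 10, 0)), "positive")
})

test_that("Pearson chi-square matches the expected-count oracle and stats::chisq.test", {
  ct <- pearson_chi2(c(71, 25, 125, 89))
  expect_equal(ct[["statistic"]], 6.89, tolerance = 1e-3)
  expect_true(ct[["p_value"]] < 0.01 && ct[["p_value"]] > 0.008)
  expect_equal(pearson_chi2(c(10, 10, 10, 10)),
               c(statistic = 0, p_value = 1))
  set.seed(7)
  for (i in 1:20) {
    x <- random_table() + 1
    ct <- pearson_chi2(x)
    expect_equal(ct[["statistic"]], oracle_chi2(x[1], x[2], x[3], x[4]))
    ref <- suppressWarnings(stats::chisq.test(matrix(x, 2, byrow = TRUE),
                                              correct = FALSE))
    expect_equal(ct[["p_value"]], unname(ref$p.value))
    yates <- suppressWarnings(stats::chisq.test(matrix(x, 2, byrow = TRUE)))
    expect_equal(pearson_chi2(x, correct = TRUE)[["p_value"]],
                 unname(yates$p.value))
  }
  expect_true(is.na(pearson_chi2(c(0, 0, 5, 5))[["p_value"]]))
})

test_that("two-sided Fisher p matches enumeration, fisher.test and the doubling flag", {
  expect_equal(fisher_exact_two_sided(c(3, 0, 0, 3)), 0.10)
  expect_equal(fisher_exact_two_sided(c(5, 5, 5, 5)), 1)
  expect_equal(fisher_exact_two_sided(c(96, 0, 213, 1)), 1)
  expect_equal(round(fisher_exact_two_sided(c(94, 2, 214, 0)), 2), 0.10)
  set.seed(13)
  for (i in 1:50) {
    x <- random_table()
    p <- fisher_exact_two_sided(x)
    expect_equal(p, oracle_fisher(x[1], x[2], x[3], x[4]))
    expect_equal(p, stats::fisher.test(matrix(x, 2, byrow = TRUE))$p.value,
                 tolerance = 1e-10)
    pd <- fisher_exact_two_sided(x, convention = "doubling")
    expect_true(pd > 0 && pd <= 1)
  }
  # doubling convention: twice the smaller exact tail, capped at 1
  expect_equal(fisher_exact_two_sided(c(3, 0, 0, 3), convention = "doubling"),
               0.10)
  expect_equal(fisher_exact_two_sided(c(5, 5, 5, 5), convention = "doubling"),
               1)
})

test_that("test selection follows Cochran's rule and the zero-margin guard", {
  expect_equal(choose_test(c(71, 25, 125, 89)), "chi_square")
  expect_equal(choose_test(c(96, 0, 214, 0)), "fisher_exact")
  expect_equal(choose_test(c(94, 2, 214, 0)), "fisher_exact")
  # min expected cell = 96*17/310 = 5.26 >= 5, so chi-square applies -- and
  # indeed gives the published 0.02 for this row
  expect_equal(choose_test(c(95, 1, 198, 16)), "chi_square")
  expect_equal(round(pearson_chi2(c(95, 1, 198, 16))[["p_value"]], 2), 0.02)
})

test_that("chi-square and Fisher converge on large well-filled tables", {
  # the exact test is conservative relative to uncorrected chi-square at
  # moderate counts; the two-sided p-values coincide only asymptotically
  set.seed(23)
  for (i in 1:10) {
    x <- 2000 + stats::rpois(4, 500)
    pc <- pearson_chi2(x)[["p_value"]]
    pf <- fisher_exact_two_sided(x)
    expect_gte(pf, pc - 1e-3)   # Fisher never anticonservative here
    expect_lt(abs(pc - pf), 0.02)
  }
})

test_that("effect dispatch mirrors the published zero-cell reporting", {
  e <- estimate_effect(c(83, 13, 155, 59))
  expect_equal(e$effect_type, "OR")
  expect_equal(round(e$effect, 2), 0.41)
  expect_equal(round(e$ci_low, 2), 0.21)
  expect_equal(round(e$ci_high, 2), 0.79)

  z <- estimate_effect(c(96, 0, 213, 1))
  expect_equal(z$effect_type, "zero")
  expect_equal(z$effect, 0)
  expect_true(is.na(z$ci_low))

  u <- estimate_effect(c(96, 0, 214, 0))
  expect_equal(u$effect_type, "undefined")
  expect_true(is.na(u$effect))

  r <- estimate_effect(c(94, 2, 214, 0))
  expect_equal(r$effect_type, "RR")

  h <- estimate_effect(c(96, 0, 213, 1), zero_cell = "haldane")
  expect_equal(h$effect_type, "OR")
  expect_true(is.finite(h$effect) && h$effect > 0)
})

test_that("Bonferroni threshold is alpha over m", {
  expect_equal(bonferroni_threshold(0.05, 45), 0.05 / 45)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_true(0.0005 < bonferroni_threshold(0.05, 20))
  expect_error(bonferroni_threshold(0.05, 0), "m")
  expect_error(bonferroni_threshold(1.2, 10), "alpha")
})

test_that("exact HWE test matches the enumeration oracle", {
  expect_gte(hwe_exact_test(25, 50, 25), 0.5)
  expect_lt(hwe_exact_test(50, 0, 50), 1e-10)
  expect_equal(hwe_exact_test(100, 0, 0), 1)
  set.seed(31)
  for (i in 1:20) {
    g <- stats::rmultinom(1, size = sample(10:80, 1), prob = c(0.4, 0.4, 0.2))
    expect_equal(hwe_exact_test(g[1], g[2], g[3]),
                 oracle_hwe(g[1], g[2], g[3]))
  }
})

test_that("the Woolf CI excludes 1 exactly when the Wald z-test rejects", {
  set.seed(43)
  for (i in 1:30) {
    x <- random_table() + 1
    e <- odds_ratio_woolf(x)
    z <- abs(log(e[["or"]])) / sqrt(sum(1 / x))
    p_wald <- 2 * stats::pnorm(-z)
    excludes <- e[["ci_low"]] > 1 || e[["ci_high"]] < 1
    expect_equal(excludes, p_wald < 2 * stats::pnorm(-1.96))
  }
})

test_that("the published tables yield six significant SNPs with the printed directions", {
  res <- associate_tables(reported_allele_tables())
  expect_equal(nrow(res), 45)
  sig <- res[res$significant_nominal, ]
  expect_equal(nrow(sig), 6)
  # the deleterious/protective pattern: ATM variant is the lone risk variant
  expect_gt(sig$effect[sig$rs_id == "rs1801516"], 1)
  expect_true(all(sig$effect[sig$rs_id != "rs1801516"] < 1))
  # monomorphic rows: undefined effect, no test
  mono <- res[res$b + res$d == 0, ]
  expect_equal(nrow(mono), 16)
  expect_true(all(mono$effect_type == "undefined"))
  expect_true(all(mono$test_used == "none"))
  expect_false(any(mono$significant_nominal))
  # Bonferroni default divisor: SNPs with any variant allele observed
  expect_equal(attr(res, "bonferroni_m"), 29)
  expect_true(all(res$significant_nominal[res$significant_bonferroni]))
  # a monomorphic-only toy panel: nothing significant, nothing defined
  toy <- data.frame(rs_id = c("x1", "x2"), a = c(10, 8), b = 0,
                    c = c(20, 22), d = 0)
  rtoy <- associate_tables(toy)
  expect_true(all(rtoy$effect_type == "undefined"))
  expect_false(any(rtoy$significant_nominal))
})
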