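## Per-SNP 2x2 association statistics.
##
## Cell layout throughout (allele counts): a = case allele1, b = case allele2,
## c = control allele1, d = control allele2. The effect is the variant-allele
## (allele2) odds in cases over controls, OR = (b/a)/(d/c) = bc/ad, so OR > 1
## means the variant allele is enriched in the radiosensitive group.

z975 <- 1.96  # matches the published 95% interval convention

as_counts <- function(table) {
  # doubles, not integers: cell products overflow 32-bit at large n
  if (inherits(table, "allele_table") || is.list(table))
    out <- c(a = table$a, b = table$b, c = table$c, d = table$d)
  else if (is.numeric(table) && length(table) == 4L)
    out <- c(a = table[[1]], b = table[[2]], c = table[[3]], d = table[[4]])
  else
    out <- NULL
  if (!is.null(out)) {
    storage.mode(out) <- "double"
    return(out)
  }
  stop("expected an allele_table or a numeric vector (a, b, c, d)",
       call. = FALSE)
}

#' Odds ratio with Woolf 95% confidence interval
#'
#' OR = bc/ad (variant-allele odds in cases over controls); the interval is
#' the log-normal (Woolf) one, `exp(log(OR) +/- 1.96 * sqrt(1/a+1/b+1/c+1/d))`.
#'
#' @param table [allele_table()] or numeric `(a, b, c, d)`.
#' @return Named numeric vector `c(or=, ci_low=, ci_high=)`.
#' @export
odds_ratio_woolf <- function(table) {
  x <- as_counts(table)
  if (any(x == 0))
    stop("odds_ratio_woolf needs all four cells > 0; use estimate_effect() ",
         "for zero-cell dispatch", call. = FALSE)
  or <- (x["b"] * x["c"]) / (x["a"] * x["d"])
  se <- sqrt(sum(1 / x))
  ci <- exp(log(or) + c(-1, 1) * z975 * se)
  c(or = unname(or), ci_low = ci[1], ci_high = ci[2])
}

#' Haldane-Anscombe continuity-corrected odds ratio
#'
#' Adds 0.5 to every cell before the Woolf computation. Never used by the
#' default dispatch ([estimate_effect()] reports zero-cell tables as printed);
#' offered for users who want a finite estimate on sparse tables.
#'
#' @inheritParams odds_ratio_woolf
#' @return Named numeric vector `c(or=, ci_low=, ci_high=)`.
#' @export
odds_ratio_haldane <- function(table) {
  x <- as_counts(table) + 0.5
  or <- (x["b"] * x["c"]) / (x["a"] * x["d"])
  se <- sqrt(sum(1 / x))
  ci <- exp(log(or) + c(-1, 1) * z975 * se)
  c(or = unname(or), ci_low = ci[1], ci_high = ci[2])
}

#' Risk ratio (Katz) fallback for zero-control-variant tables
#'
#' When the variant allele is absent in controls (d = 0) the OR is infinite;
#' the reported effect is then the risk ratio of case status between carriers
#' of allele2 and allele1: RR = \[b/(b+d)\] / \[a/(a+c)\], with the Katz
#' log-normal interval `exp(log(RR) +/- 1.96 * sqrt(1/b - 1/(b+d) + 1/a -
#' 1/(a+c)))`.
#'
#' @inheritParams odds_ratio_woolf
#' @return Named numeric vector `c(rr=, ci_low=, ci_high=)`.
#' @export
risk_ratio_katz <- function(table) {
  x <- as_counts(table)
  if (x["b"] == 0)
    stop("risk_ratio_katz needs a positive case variant count b", call. = FALSE)
  if (x["a"] == 0 || x["a"] + x["c"] == 0)
    stop("risk_ratio_katz needs allele1 carriers in cases", call. = FALSE)
  rr <- (x["b"] / (x["b"] + x["d"])) / (x["a"] / (x["a"] + x["c"]))
  se <- sqrt(1 / x["b"] - 1 / (x["b"] + x["d"]) +
             1 / x["a"] - 1 / (x["a"] + x["c"]))
  ci <- exp(log(rr) + c(-1, 1) * z975 * se)
  c(rr = unname(rr), ci_low = ci[1], ci_high = ci[2])
}

#' Pearson chi-square test on a 2x2 table (1 df)
#'
#' Uncorrected by default: `N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`. The
#' Yates continuity correction is available behind `correct = TRUE` but is
#' never used by the default pipeline.
#'
#' @inheritParams odds_ratio_woolf
#' @param correct Apply the Yates continuity correction.
#' @return Named numeric vector `c(statistic=, p_value=)`; both `NA` when a
#'   margin is zero (the test is not applicable and callers fall through to
#'   Fisher).
#' @export
pearson_chi2 <- function(table, correct = FALSE) {
  x <- as_counts(table)
  n <- sum(x)
  r1 <- x["a"] + x["b"]; r2 <- x["c"] + x["d"]
  c1 <- x["a"] + x["c"]; c2 <- x["b"] + x["d"]
  if (n == 0 || r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0)
    return(c(statistic = NA_real_, p_value = NA_real_))
  dev <- abs(x["a"] * x["d"] - x["b"] * x["c"])
  if (correct) dev <- max(0, dev - n / 2)
  stat <- n * dev^2 / (r1 * r2 * c1 * c2)
  c(statistic = unname(stat),
    p_value = stats::pchisq(unname(stat), df = 1, lower.tail = FALSE))
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Conditional on both margins, sums hypergeometric point probabilities over
#' all tables. The default two-sided convention is minimum likelihood (sum of
#' probabilities no greater than the observed table's, the convention of
#' `stats::fisher.test`); `convention = "doubling"` doubles the smaller tail
#' instead.
#'
#' @inheritParams odds_ratio_woolf
#' @param convention `"min.likelihood"` (default) or `"doubling"`.
#' @return Two-sided p-value in (0, 1]; degenerate margins give 1.
#' @export
fisher_exact_two_sided <- function(table,
                                   convention = c("min.likelihood", "doubling")) {
  convention <- match.arg(convention)
  x <- as_counts(table)
  m1 <- x["a"] + x["b"]   # case alleles
  m2 <- x["c"] + x["d"]   # control alleles
  k  <- x["b"] + x["d"]   # variant alleles drawn
  if (m1 == 0 || m2 == 0 || k == 0 || k == m1 + m2) return(1)
  support <- max(0, k - m2):min(k, m1)
  pr <- stats::dhyper(support, m1, m2, k)
  p_obs <- pr[support == x["b"]]
  p <- switch(convention,
    min.likelihood = sum(pr[pr <= p_obs * (1 + 1e-7)]),
    doubling = 2 * min(sum(pr[support <= x["b"]]), sum(pr[support >= x["b"]])))
  min(p, 1)
}

#' Choose between chi-square and Fisher for a 2x2 table
#'
#' Cochran's criterion: the chi-square test is used iff no margin is zero and
#' every expected cell count is at least 5; otherwise the Fisher exact test.
#'
#' @inheritParams odds_ratio_woolf
#' @return `"chi_square"` or `"fisher_exact"`.
#' @export
choose_test <- function(table) {
  x <- as_counts(table)
  n <- sum(x)
  rows <- c(x["a"] + x["b"], x["c"] + x["d"])
  cols <- c(x["a"] + x["c"], x["b"] + x["d"])
  if (n == 0 || any(rows == 0) || any(cols == 0)) return("fisher_exact")
  expected <- outer(rows, cols) / n
  if (all(expected >= 5)) "chi_square" else "fisher_exact"
}

#' Effect estimate dispatch for one allele table
#'
#' Reproduces the published reporting rules:
#' all four cells positive -> OR with Woolf CI; variant present in cases but
#' absent in controls (b > 0, d = 0) -> Katz risk ratio; variant absent in
#' cases but present in controls (b = 0, d > 0) -> effect reported as the
#' literal 0 with no interval; variant absent everywhere -> undefined.
#'
#' @inheritParams odds_ratio_woolf
#' @param zero_cell `"as.printed"` (default; zero-cell tables give effect 0 or
#'   undefined) or `"haldane"` (0.5 added to every cell, Woolf OR).
#' @return List with `effect_type` (`"OR"`, `"RR"`, `"zero"`, `"undefined"`),
#'   `effect`, `ci_low`, `ci_high`.
#' @export
estimate_effect <- function(table, zero_cell = c("as.printed", "haldane")) {
  zero_cell <- match.arg(zero_cell)
  x <- as_counts(table)
  if (all(x > 0)) {
    e <- odds_ratio_woolf(x)
    return(list(effect_type = "OR", effect = e[["or"]],
                ci_low = e[["ci_low"]], ci_high = e[["ci_high"]]))
  }
  if (x["b"] > 0 && x["d"] == 0 && x["a"] > 0) {
    e <- risk_ratio_katz(x)
    return(list(effect_type = "RR", effect = e[["rr"]],
                ci_low = e[["ci_low"]], ci_high = e[["ci_high"]]))
  }
  if (zero_cell == "haldane" && any(x["b"] > 0, x["d"] > 0)) {
    e <- odds_ratio_haldane(x)
    return(list(effect_type = "OR", effect = e[["or"]],
                ci_low = e[["ci_low"]], ci_high = e[["ci_high"]]))
  }
  if (x["b"] == 0 && x["d"] > 0)
    return(list(effect_type = "zero", effect = 0,
                ci_low = NA_real_, ci_high = NA_real_))
  list(effect_type = "undefined", effect = NA_real_,
       ci_low = NA_real_, ci_high = NA_real_)
}

#' Bonferroni significance threshold
#'
#' @param alpha Family-wise type I error, in (0, 1).
#' @param m Number of comparisons, >= 1.
#' @return `alpha / m`; a result is Bonferroni-significant iff its p-value is
#'   strictly below this.
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)", call. = FALSE)
  if (!is.finite(m) || m < 1 || m != round(m))
    stop("m must be a positive integer", call. = FALSE)
  alpha / m
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact p-value conditional on the allele counts, enumerating all
#' heterozygote counts of the right parity and summing probabilities no
#' greater than the observed configuration's (Wigginton-style QC check).
#'
#' @param n_11 Homozygous allele1 genotype count.
#' @param n_12 Heterozygote count.
#' @param n_22 Homozygous allele2 genotype count.
#' @return Exact p-value; monomorphic samples give 1.
#' @export
hwe_exact_test <- function(n_11, n_12, n_22) {
  counts <- c(n_11, n_12, n_22)
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("genotype counts must be non-negative integers", call. = FALSE)
  n <- sum(counts)
  m <- min(2 * n_11 + n_12, 2 * n_22 + n_12)  # minor allele count
  if (n == 0 || m == 0) return(1)
  hets <- seq.int(m %% 2, min(m, 2 * n - m), by = 2)
  # P(h hets | n, m) = 2^h n! m! (2n-m)! / ( n_rare! n_common! h! (2n)! )
  logp <- hets * log(2) + lgamma(n + 1) + lgamma(m + 1) + lgamma(2 * n - m + 1) -
    lgamma((m - hets) / 2 + 1) - lgamma((2 * n - m - hets) / 2 + 1) -
    lgamma(hets + 1) - lgamma(2 * n + 1)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  p_obs <- pr[hets == n_12]
  min(sum(pr[pr <= p_obs * (1 + 1e-7)]), 1)
}

#' Associate every SNP from its 2x2 allele-count table
#'
#' The workhorse of the association stage, operating directly on counts so
#' that published allele tables can be re-analysed without individual
#' genotypes. Per SNP: effect dispatch ([estimate_effect()]), test selection
#' ([choose_test()]; monomorphic tables are untested), nominal significance at
#' `alpha`, and Bonferroni significance at `alpha / m`.
#'
#' @param tables Data frame with columns `rs_id`, `a`, `b`, `c`, `d`
#'   (optionally `gene`, `allele1`, `allele2`), one row per SNP.
#' @param alpha Nominal significance level (default 0.05).
#' @param bonferroni_m Bonferroni divisor; default is the number of SNPs with
#'   any variant allele observed (`b + d > 0`).
#' @param fisher_convention Two-sided Fisher convention, see
#'   [fisher_exact_two_sided()].
#' @param chi_correct Yates-correct the chi-square (default `FALSE`).
#' @param zero_cell Zero-cell effect policy, see [estimate_effect()].
#' @return Data frame, one row per SNP in input order, with counts,
#'   percentages, `effect_type`, `effect`, `ci_low`, `ci_high`, `test_used`,
#'   `statistic`, `p_value`, `significant_nominal`, `significant_bonferroni`.
#' @export
associate_tables <- function(tables, alpha = 0.05, bonferroni_m = NULL,
                             fisher_convention = "min.likelihood",
                             chi_correct = FALSE,
                             zero_cell = "as.printed") {
  need <- c("rs_id", "a", "b", "c", "d")
  miss <- setdiff(need, names(tables))
  if (length(miss))
    stop("tables is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  n_snp <- nrow(tables)
  if (is.null(bonferroni_m)) bonferroni_m <- sum(tables$b + tables$d > 0)
  bonf <- if (bonferroni_m >= 1) bonferroni_threshold(alpha, bonferroni_m) else NA_real_

  res <- vector("list", n_snp)
  for (i in seq_len(n_snp)) {
    x <- c(a = tables$a[i], b = tables$b[i], c = tables$c[i], d = tables$d[i])
    eff <- estimate_effect(x, zero_cell = zero_cell)
    variant_seen <- (x["b"] + x["d"]) > 0
    no_group <- (x["a"] + x["b"] == 0) || (x["c"] + x["d"] == 0)
    if (!variant_seen || no_group) {
      test <- "none"; stat <- NA_real_; p <- NA_real_
    } else {
      test <- choose_test(x)
      if (test == "chi_square") {
        ct <- pearson_chi2(x, correct = chi_correct)
        stat <- ct[["statistic"]]; p <- ct[["p_value"]]
      } else {
        stat <- NA_real_
        p <- fisher_exact_two_sided(x, convention = fisher_convention)
      }
    }
    pct <- allele_percentages(list(a = x[["a"]], b = x[["b"]],
                                   c = x[["c"]], d = x[["d"]]))
    res[[i]] <- data.frame(
      rs_id = tables$rs_id[i],
      a = x[["a"]], b = x[["b"]], c = x[["c"]], d = x[["d"]],
      pct_case_allele1 = pct[["a"]], pct_case_allele2 = pct[["b"]],
      pct_control_allele1 = pct[["c"]], pct_control_allele2 = pct[["d"]],
      effect_type = eff$effect_type, effect = eff$effect,
      ci_low = eff$ci_low, ci_high = eff$ci_high,
      test_used = test, statistic = stat, p_value = p,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out$significant_nominal <- !is.na(out$p_value) & out$p_value <= alpha
  out$significant_bonferroni <- !is.na(out$p_value) & !is.na(bonf) &
    out$p_value < bonf
  for (extra in c("gene", "allele1", "allele2"))
    if (extra %in% names(tables)) out[[extra]] <- tables[[extra]]
  front <- intersect(c("gene", "rs_id", "allele1", "allele2"), names(out))
  out <- out[c(front, setdiff(names(out), front))]
  attr(out, "alpha") <- alpha
  attr(out, "bonferroni_m") <- bonferroni_m
  attr(out, "bonferroni_threshold") <- bonf
  rownames(out) <- NULL
  out
}

#' Associate every panel SNP of a cohort
#'
#' Tallies per-SNP allele tables ([count_alleles_all()]) and runs
#' [associate_tables()]; one result row per panel SNP, in panel order. A
#' degenerate SNP never aborts the panel.
#'
#' @param cohort A cohort object.
#' @inheritParams associate_tables
#' @return See [associate_tables()].
#' @export
associate_all <- function(cohort, alpha = 0.05, bonferroni_m = NULL,
                          fisher_convention = "min.likelihood",
                          chi_correct = FALSE, zero_cell = "as.printed") {
  associate_tables(count_alleles_all(cohort), alpha = alpha,
                   bonferroni_m = bonferroni_m,
                   fisher_convention = fisher_convention,
                   chi_correct = chi_correct, zero_cell = zero_cell)
}
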