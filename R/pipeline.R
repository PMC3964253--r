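round_half_up <- function(x, digits = 2) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5 + 1e-9) / s
}

fmt2 <- function(x) sprintf("%.2f", round_half_up(x, 2))

fmt_pct <- function(p) {
  if (is.na(p)) return("")
  if (p == round(p)) sprintf("%d", as.integer(p)) else sprintf("%.1f", p)
}

#' Format association results as a publication-style allele-frequency table
#'
#' One row per SNP: allele counts with group percentages in parentheses, the
#' effect as `"X.XX (L-H)"` (risk ratios marked `**`, zero-variant-in-cases
#' tables as the literal `"0"`, monomorphic tables as `"-"`), and the
#' p-value at two decimals with `"<0.01"` for p < 0.01 and a `*` marker on
#' Fisher-tested rows.
#'
#' @param results Association results from [associate_tables()] /
#'   [associate_all()].
#' @return Data frame of display strings with columns `gene_snp`,
#'   `cases_allele1`, `controls_allele1`, `cases_allele2`, `controls_allele2`,
#'   `effect`, `p`.
#' @export
format_report_table <- function(results) {
  cell <- function(n, pct) {
    pc <- fmt_pct(pct)
    if (pc == "") sprintf("%d", n) else sprintf("%d (%s)", n, pc)
  }
  eff <- character(nrow(results))
  pv <- character(nrow(results))
  for (i in seq_len(nrow(results))) {
    r <- results[i, ]
    eff[i] <- switch(r$effect_type,
      OR = sprintf("%s (%s-%s)", fmt2(r$effect), fmt2(r$ci_low),
                   fmt2(r$ci_high)),
      RR = sprintf("%s** (%s-%s)", fmt2(r$effect), fmt2(r$ci_low),
                   fmt2(r$ci_high)),
      zero = "0",
      undefined = "-")
    pv[i] <- if (is.na(r$p_value)) "-"
      else paste0(if (r$p_value < 0.01) "<0.01" else fmt2(r$p_value),
                  if (r$test_used == "fisher_exact") "*" else "")
  }
  has_alleles <- all(c("allele1", "allele2") %in% names(results))
  gene <- if ("gene" %in% names(results)) results$gene else results$rs_id
  label <- if (has_alleles)
    sprintf("%s %s/%s %s", gene, results$allele1, results$allele2,
            results$rs_id) else paste(gene, results$rs_id)
  data.frame(
    gene_snp = label,
    cases_allele1 = mapply(cell, results$a, results$pct_case_allele1),
    controls_allele1 = mapply(cell, results$c, results$pct_control_allele1),
    cases_allele2 = mapply(cell, results$b, results$pct_case_allele2),
    controls_allele2 = mapply(cell, results$d, results$pct_control_allele2),
    effect = eff, p = pv,
    stringsAsFactors = FALSE)
}

#' Genotype-distribution report by fibrosis severity
#'
#' Per-SNP genotype histograms (allele1 homozygote / heterozygote / allele2
#' homozygote) split by group, restricted to SNPs carried by at least
#' `min_carriers` individuals with a minor (variant-carrying) genotype --
#' the usual "five or more carriers" display filter.
#'
#' @param cohort A cohort object.
#' @param min_carriers Minimum number of patients with dosage >= 1 for a SNP
#'   to be included (default 5).
#' @return Long data frame with `gene`, `rs_id`, `group`, `genotype`
#'   (`"11"`, `"12"`, `"22"`), `count`, plus a `carriers` column.
#' @export
genotype_distribution_report <- function(cohort, min_carriers = 5) {
  if (min_carriers < 0) stop("min_carriers must be >= 0", call. = FALSE)
  carriers <- colSums(cohort$dosage >= 1, na.rm = TRUE)
  keep <- which(carriers >= min_carriers)
  case <- cohort$patients$group == "case"
  rows <- list()
  for (j in keep) {
    for (grp in c("control", "case")) {
      dos <- cohort$dosage[if (grp == "case") case else !case, j]
      cnt <- tabulate(dos + 1L, nbins = 3L)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = cohort$panel$gene[j], rs_id = cohort$panel$rs_id[j],
        group = grp, genotype = c("11", "12", "22"), count = cnt,
        carriers = unname(carriers[j]), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(gene = character(), rs_id = character(),
                      group = character(), genotype = character(),
                      count = integer(), carriers = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full association -> risk model -> burden pipeline
#'
#' Orchestrates the stages on a cohort (or directly on published allele-count
#' tables), identical to calling the module functions in sequence:
#' association ([associate_all()] / [associate_tables()]), risk-allele
#' designation ([assign_risk_alleles()]) and, when the risk model is
#' non-empty and individual genotypes are available, the burden comparison
#' ([burden_compare()]). Optionally writes the report bundle as TSVs plus a
#' run log; identical inputs give byte-identical outputs.
#'
#' @param cohort A cohort object (individual-level path), or `NULL`.
#' @param tables Allele-count tables (counts-only path), or `NULL`. Exactly
#'   one of `cohort`/`tables` must be given.
#' @param alpha Nominal significance level.
#' @param bonferroni_m Bonferroni divisor (default: SNPs with any variant
#'   allele observed).
#' @param min_carriers Filter for the genotype-distribution report.
#' @param out_dir Output directory; `NULL` (default) writes nothing.
#' @param ... Passed to the association stage (e.g. `fisher_convention`,
#'   `chi_correct`).
#' @return List of class `"rad_pipeline"` with `association`, `report`,
#'   `risk_model`, `burden` (`NULL` when skipped), `genotypes` (`NULL` for
#'   the counts-only path), and `log` (character vector).
#' @export
run_pipeline <- function(cohort = NULL, tables = NULL, alpha = 0.05,
                         bonferroni_m = NULL, min_carriers = 5,
                         out_dir = NULL, ...) {
  if (is.null(cohort) == is.null(tables))
    stop("give exactly one of cohort or tables", call. = FALSE)
  log <- c(sprintf("alpha=%g", alpha))
  assoc <- if (is.null(cohort))
    associate_tables(tables, alpha = alpha, bonferroni_m = bonferroni_m, ...)
  else
    associate_all(cohort, alpha = alpha, bonferroni_m = bonferroni_m, ...)
  log <- c(log,
           sprintf("bonferroni_m=%d threshold=%g",
                   attr(assoc, "bonferroni_m"),
                   attr(assoc, "bonferroni_threshold")),
           sprintf("n_snps=%d n_significant=%d", nrow(assoc),
                   sum(assoc$significant_nominal)))
  model <- assign_risk_alleles(assoc)
  burden <- NULL
  genotypes <- NULL
  if (!is.null(cohort)) {
    genotypes <- genotype_distribution_report(cohort, min_carriers)
    if (nrow(model) > 0) {
      burden <- burden_compare(cohort, model)
      log <- c(log, sprintf("burden: U=%g p=%g (%d-SNP model)", burden$U,
                            burden$p_value, nrow(model)))
    } else {
      log <- c(log, "burden stage skipped: empty risk model")
    }
  } else if (nrow(model) == 0) {
    log <- c(log, "empty risk model")
  }
  out <- structure(list(association = assoc, report = format_report_table(assoc),
                        risk_model = model, burden = burden,
                        genotypes = genotypes, log = log),
                   class = "rad_pipeline")
  if (!is.null(out_dir)) write_pipeline(out, out_dir)
  out
}

#' Write a pipeline report bundle to disk
#'
#' Emits `association.tsv`, `report_table.tsv`, `risk_model.tsv`, and, when
#' available, `burden.tsv`, `burden_summary.tsv`, `genotype_distribution.tsv`,
#' plus `run_log.txt`.
#'
#' @param x A `"rad_pipeline"` result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_pipeline <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, f) utils::write.table(
    df, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  w(x$association, "association.tsv")
  w(x$report, "report_table.tsv")
  w(x$risk_model, "risk_model.tsv")
  if (!is.null(x$burden)) {
    w(x$burden$scores, "burden.tsv")
    w(x$burden$summary, "burden_summary.tsv")
  }
  if (!is.null(x$genotypes)) w(x$genotypes, "genotype_distribution.tsv")
  writeLines(x$log, file.path(dir, "run_log.txt"))
  invisible(dir)
}

#' @export
print.rad_pipeline <- function(x, ...) {
  cat("<rad_pipeline>\n")
  for (l in x$log) cat(" ", l, "\n")
  sig <- x$association[x$association$significant_nominal, , drop = FALSE]
  if (nrow(sig))
    cat("  significant SNPs:",
        paste(sig$rs_id, collapse = ", "), "\n")
  invisible(x)
}
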