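#' Designate risk alleles from association results
#'
#' Every SNP with a nominally significant (p <= alpha), defined, non-unit
#' effect contributes one risk allele: allele2 (the variant) when the effect
#' exceeds 1, allele1 (the wild type) when the variant is protective
#' (effect < 1). SNPs with effect exactly 1 are directionless and excluded.
#'
#' @param results Association results from [associate_tables()] /
#'   [associate_all()]; must carry `allele1`/`allele2` columns.
#' @return Data frame (the risk model) with `rs_id`, `gene`, `risk_allele`
#'   (the allele token), `risk_which` (`"allele1"` or `"allele2"`), `effect`,
#'   `p_value`.
#' @export
assign_risk_alleles <- function(results) {
  if (!all(c("allele1", "allele2") %in% names(results)))
    stop("results must carry allele1/allele2 columns", call. = FALSE)
  keep <- results$significant_nominal &
    results$effect_type %in% c("OR", "RR") &
    !is.na(results$effect) & results$effect != 1
  r <- results[keep, , drop = FALSE]
  which_allele <- ifelse(r$effect > 1, "allele2", "allele1")
  out <- data.frame(
    rs_id = r$rs_id,
    gene = if ("gene" %in% names(r)) r$gene else NA_character_,
    risk_allele = ifelse(which_allele == "allele2", r$allele2, r$allele1),
    risk_which = which_allele,
    effect = r$effect,
    p_value = r$p_value,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Per-patient cumulative risk-allele burden scores
#'
#' Each patient scores, at every model SNP, the number of risk-allele copies
#' carried: the variant dosage itself when the risk allele is allele2, and
#' `2 - dosage` when the wild-type allele is the risk allele. The burden is
#' the sum over model SNPs (homozygous risk = 2, heterozygous = 1, absent =
#' 0), so scores lie in `[0, 2 * nrow(model)]`. A patient missing a genotype
#' at any model SNP gets an `NA` score and is flagged.
#'
#' @param cohort A cohort object.
#' @param model Risk model from [assign_risk_alleles()] (needs `rs_id` and
#'   `risk_which`).
#' @return Data frame with `patient_id`, `group`, `score`, `complete`.
#' @export
burden_scores <- function(cohort, model) {
  if (nrow(model) == 0) stop("risk model is empty", call. = FALSE)
  if (anyDuplicated(model$rs_id))
    stop("risk model has duplicate rs_id", call. = FALSE)
  j <- match(model$rs_id, cohort$panel$rs_id)
  if (any(is.na(j)))
    stop("model SNP(s) not in cohort panel: ",
         paste(model$rs_id[is.na(j)], collapse = ", "), call. = FALSE)
  dos <- cohort$dosage[, j, drop = FALSE]
  flip <- model$risk_which == "allele1"
  copies <- dos
  copies[, flip] <- 2L - dos[, flip, drop = FALSE]
  score <- rowSums(copies)  # NA whenever any model genotype is missing
  data.frame(patient_id = cohort$patients$patient_id,
             group = cohort$patients$group,
             score = as.integer(score),
             complete = !is.na(score),
             stringsAsFactors = FALSE)
}

#' Mann-Whitney rank-sum comparison of two score vectors
#'
#' Exact two-sided p-value when the product of group sizes is at most 10^4
#' and there are no ties; otherwise the normal approximation with
#' tie-corrected variance and continuity correction (the behaviour of
#' `stats::wilcox.test`).
#'
#' @param case_scores,control_scores Non-empty numeric vectors.
#' @param exact Force (`TRUE`/`FALSE`) the exact computation; default `NULL`
#'   applies the rule above.
#' @return List with `U` (the Mann-Whitney U for the case sample), `p_value`,
#'   and `exact` (logical, whether the exact distribution was used).
#' @export
mann_whitney_test <- function(case_scores, control_scores, exact = NULL) {
  if (length(case_scores) == 0 || length(control_scores) == 0)
    stop("both groups must be non-empty", call. = FALSE)
  pooled <- c(case_scores, control_scores)
  if (all(pooled == pooled[1]))  # constant scores: no evidence either way
    return(list(U = length(case_scores) * length(control_scores) / 2,
                p_value = 1, exact = FALSE))
  ties <- anyDuplicated(pooled) > 0
  if (is.null(exact))
    exact <- !ties &&
      length(case_scores) * length(control_scores) <= 1e4
  wt <- suppressWarnings(
    stats::wilcox.test(case_scores, control_scores,
                       exact = exact, correct = TRUE))
  list(U = unname(wt$statistic), p_value = wt$p.value,
       exact = exact && !ties)
}

#' Compare risk-allele burden between cases and controls
#'
#' Computes all patient scores ([burden_scores()]), per-group box-plot
#' statistics (median, quartiles, 10th/90th percentiles, range) and the
#' two-sided Mann-Whitney comparison. Patients with incomplete model
#' genotypes are excluded from the comparison and counted in `n_excluded`.
#'
#' @inheritParams burden_scores
#' @return Object of class `"burden_result"`: list with `scores` (per-patient
#'   data frame), `summary` (per-group statistics), `U`, `p_value`, `exact`,
#'   `n_excluded`.
#' @export
burden_compare <- function(cohort, model) {
  sc <- burden_scores(cohort, model)
  ok <- sc$complete
  cs <- sc$score[ok & sc$group == "case"]
  ks <- sc$score[ok & sc$group == "control"]
  if (length(cs) == 0 || length(ks) == 0)
    stop("burden comparison needs scored patients in both groups",
         call. = FALSE)
  qs <- function(x) {
    q <- stats::quantile(x, c(0.1, 0.25, 0.5, 0.75, 0.9), type = 7)
    data.frame(n = length(x), min = min(x), p10 = q[[1]], q25 = q[[2]],
               median = q[[3]], q75 = q[[4]], p90 = q[[5]], max = max(x))
  }
  summ <- rbind(cbind(group = "control", qs(ks)),
                cbind(group = "case", qs(cs)))
  rownames(summ) <- NULL
  mw <- mann_whitney_test(cs, ks)
  structure(list(scores = sc, summary = summ, U = mw$U,
                 p_value = mw$p_value, exact = mw$exact,
                 n_excluded = sum(!ok), n_model_snps = nrow(model)),
            class = "burden_result")
}

#' @export
print.burden_result <- function(x, ...) {
  cat("<burden_result> ", x$n_model_snps, "-SNP risk model\n", sep = "")
  print(x$summary, row.names = FALSE)
  cat("Mann-Whitney U = ", x$U, " (",
      if (x$exact) "exact" else "normal approximation", "), two-sided P = ",
      format.pval(x$p_value, digits = 3), "\n", sep = "")
  if (x$n_excluded > 0)
    cat(x$n_excluded, "patient(s) excluded for missing model genotypes\n")
  invisible(x)
}

#' Box plot of burden scores by group
#'
#' Base-graphics rendering of the burden comparison: boxes span the
#' quartiles with the median marked, whiskers extend to the range.
#'
#' @param x A `"burden_result"`.
#' @param ... Passed to [graphics::boxplot()].
#' @export
plot.burden_result <- function(x, ...) {
  sc <- x$scores[x$scores$complete, ]
  graphics::boxplot(score ~ factor(group, c("control", "case")), data = sc,
                    range = 0, xlab = "", ylab = "Number of risk alleles",
                    names = c("Controls (G0-2)", "Cases (G3-4)"), ...)
  invisible(x)
}
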