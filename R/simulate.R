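#' Draw Hardy-Weinberg genotypes
#'
#' Variant-allele dosages are i.i.d. Binomial(2, maf), i.e. genotype
#' probabilities `(1-maf)^2`, `2 maf (1-maf)`, `maf^2` for 0/1/2 copies.
#' Uses the current RNG stream.
#'
#' @param maf Allele2 frequency in \[0, 1\].
#' @param n Number of individuals.
#' @return Integer vector of dosages in \{0, 1, 2\}.
#' @export
sample_genotypes_hwe <- function(maf, n) {
  if (!is.finite(maf) || maf < 0 || maf > 1)
    stop("maf must be in [0, 1]", call. = FALSE)
  stats::rbinom(n, 2L, maf)
}

#' Simulation configuration for a retrospective case-control cohort
#'
#' Defaults mirror the study design the analysis targets: 48 severe-fibrosis
#' cases versus 107 controls, and the published within-group grade mixture
#' (grades 0/1/2 at 17/54/36 of 107 controls; grades 3/4 at 38/10 of 48
#' cases).
#'
#' @param panel Data frame with `rs_id`, `maf` (control allele2 frequency)
#'   and optionally `gene`, `allele1`, `allele2`, `or` (per-allele odds
#'   ratio, default 1 = null).
#' @param n_cases,n_controls Group sizes.
#' @param grade_probs_controls Probabilities of grades 0, 1, 2 within
#'   controls (must sum to 1).
#' @param grade_probs_cases Probabilities of grades 3, 4 within cases.
#' @param seed Integer seed; the whole cohort draw is reproducible from it.
#' @return Object of class `"sim_config"`.
#' @export
sim_config <- function(panel, n_cases = 48, n_controls = 107,
                       grade_probs_controls = c(17, 54, 36) / 107,
                       grade_probs_cases = c(38, 10) / 48,
                       seed = 1L) {
  panel <- as.data.frame(panel)
  if (!all(c("rs_id", "maf") %in% names(panel)))
    stop("panel needs rs_id and maf columns", call. = FALSE)
  if (!"or" %in% names(panel)) panel$or <- 1
  if (!"gene" %in% names(panel)) panel$gene <- panel$rs_id
  if (!"allele1" %in% names(panel)) panel$allele1 <- "A"
  if (!"allele2" %in% names(panel)) panel$allele2 <- "B"
  if (any(!is.finite(panel$maf) | panel$maf < 0 | panel$maf > 1))
    stop("panel maf must be in [0, 1]", call. = FALSE)
  if (any(!is.finite(panel$or) | panel$or < 0))
    stop("per-allele odds ratios must be >= 0", call. = FALSE)
  if (abs(sum(grade_probs_controls) - 1) > 1e-8 ||
      abs(sum(grade_probs_cases) - 1) > 1e-8)
    stop("grade mixtures must each sum to 1", call. = FALSE)
  if (n_cases < 1 || n_controls < 1)
    stop("both groups must be non-empty", call. = FALSE)
  structure(list(panel = panel, n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 grade_probs_controls = grade_probs_controls,
                 grade_probs_cases = grade_probs_cases,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Case allele frequency implied by a per-allele odds ratio
#'
#' Retrospective construction: the case allele odds are `or` times the
#' control allele odds, so `q_case = or q / (1 - q + or q)`. This makes the
#' simulator's `or` exactly the estimand of the allele-level odds ratio.
#'
#' @param maf Control allele2 frequency.
#' @param or Per-allele odds ratio.
#' @return Case allele2 frequency.
#' @export
case_maf <- function(maf, or) {
  q <- or * maf / (1 - maf + or * maf)
  if (any(!is.finite(q) | q < 0 | q > 1))
    stop("implied case allele frequency outside [0, 1]", call. = FALSE)
  q
}

#' Simulate a case-control cohort under Hardy-Weinberg equilibrium
#'
#' Per SNP, control genotypes are drawn at the base minor-allele frequency
#' and case genotypes at the frequency implied by the per-allele odds ratio
#' ([case_maf()]); genotypes are in HWE within group and SNPs are
#' independent. Fibrosis grades are drawn from the group's grade mixture.
#' Fully seeded: identical configurations give bit-identical cohorts.
#'
#' @param config A [sim_config()].
#' @return A [new_cohort()] object; cases first, then controls.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  p <- config$panel
  n_ca <- config$n_cases; n_co <- config$n_controls
  q_case <- case_maf(p$maf, p$or)
  dos_ca <- vapply(q_case, sample_genotypes_hwe, integer(n_ca), n = n_ca)
  dos_co <- vapply(p$maf, sample_genotypes_hwe, integer(n_co), n = n_co)
  grades <- c(sample(3:4, n_ca, replace = TRUE,
                     prob = config$grade_probs_cases),
              sample(0:2, n_co, replace = TRUE,
                     prob = config$grade_probs_controls))
  patients <- data.frame(
    patient_id = sprintf("S%03d", seq_len(n_ca + n_co)),
    fibrosis_grade = grades, stringsAsFactors = FALSE)
  new_cohort(p[c("gene", "rs_id", "allele1", "allele2")], patients,
             rbind(matrix(dos_ca, nrow = n_ca),
                   matrix(dos_co, nrow = n_co)))
}

#' Type I error / power experiment over replicate cohorts
#'
#' Simulates `n_reps` cohorts (replicate r uses seed `config$seed + r - 1`),
#' runs the association stage on each, and tabulates per-SNP rejection
#' frequencies at level `alpha` with Monte-Carlo standard errors, split by
#' the test actually used (chi-square vs Fisher, which is conservative on
#' sparse tables).
#'
#' @param config A [sim_config()].
#' @param n_reps Number of replicate cohorts (>= 1).
#' @param alpha Rejection level (default 0.05).
#' @return List of class `"type1_power"`: `per_snp` (data frame with
#'   rejection counts/rates per SNP) and `pooled` (rates pooled over
#'   SNP x replicate, by test).
#' @export
type1_power_experiment <- function(config, n_reps, alpha = 0.05) {
  stopifnot(inherits(config, "sim_config"), n_reps >= 1)
  m <- nrow(config$panel)
  n_chi <- n_fis <- rej_chi <- rej_fis <- integer(m)
  for (r in seq_len(n_reps)) {
    cfg <- config
    cfg$seed <- config$seed + r - 1L
    res <- associate_all(simulate_cohort(cfg), alpha = alpha)
    rej <- !is.na(res$p_value) & res$p_value <= alpha
    is_chi <- res$test_used == "chi_square"
    is_fis <- res$test_used == "fisher_exact"
    n_chi <- n_chi + is_chi
    n_fis <- n_fis + is_fis
    rej_chi <- rej_chi + (rej & is_chi)
    rej_fis <- rej_fis + (rej & is_fis)
  }
  rate <- function(k, n) ifelse(n > 0, k / n, NA_real_)
  per_snp <- data.frame(
    rs_id = config$panel$rs_id, or = config$panel$or,
    maf = config$panel$maf,
    n_chi_square = n_chi, reject_chi_square = rate(rej_chi, n_chi),
    n_fisher = n_fis, reject_fisher = rate(rej_fis, n_fis),
    reject_any = (rej_chi + rej_fis) / n_reps,
    stringsAsFactors = FALSE)
  per_snp$mc_se <- sqrt(per_snp$reject_any * (1 - per_snp$reject_any) / n_reps)
  pooled <- list(
    chi_square = rate(sum(rej_chi), sum(n_chi)),
    fisher_exact = rate(sum(rej_fis), sum(n_fis)),
    n_chi_square = sum(n_chi), n_fisher = sum(n_fis),
    alpha = alpha, n_reps = n_reps)
  structure(list(per_snp = per_snp, pooled = pooled), class = "type1_power")
}

#' @export
print.type1_power <- function(x, ...) {
  cat("<type1_power> ", x$pooled$n_reps, " replicates, alpha = ",
      x$pooled$alpha, "\n", sep = "")
  cat("pooled rejection: chi-square ",
      format(x$pooled$chi_square, digits = 3), " (",
      x$pooled$n_chi_square, " tests), Fisher ",
      format(x$pooled$fisher_exact, digits = 3), " (",
      x$pooled$n_fisher, " tests)\n", sep = "")
  invisible(x)
}
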