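#' Published allele-count tables for the 45-SNP fibrosis panel
#'
#' The 2x2 allele counts (48 cases with grade 3--4 fibrosis, 96 alleles;
#' 107 controls with grade 0--2, 214 alleles) for all 45 SNPs in the 11
#' candidate genes, as published. These counts are the complete input to the
#' association stage, so the printed odds ratios, confidence intervals and
#' p-values can be recomputed without individual genotypes.
#'
#' @return Data frame with columns `gene`, `rs_id`, `allele1`, `allele2`,
#'   `a`, `b`, `c`, `d` (cases/controls x allele1/allele2 counts).
#' @export
reported_allele_tables <- function() {
  path <- system.file("extdata", "reported_allele_tables.tsv",
                      package = "radburden", mustWork = TRUE)
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  data.frame(gene = x$gene, rs_id = x$rs_id,
             allele1 = x$allele1, allele2 = x$allele2,
             a = as.integer(x$case_allele1), b = as.integer(x$case_allele2),
             c = as.integer(x$control_allele1),
             d = as.integer(x$control_allele2),
             stringsAsFactors = FALSE)
}

#' Simulation panel matching the published allele-frequency spectrum
#'
#' Builds a [sim_config()] panel whose control minor-allele frequencies are
#' the published control variant-allele frequencies `d / (c + d)` (monomorphic
#' through common). Per-allele odds ratios are 1 under `effects = "null"`;
#' under `effects = "significant"` the six nominally significant SNPs get
#' their observed allelic odds ratios (so case allele frequencies match the
#' published case columns in expectation) and all other SNPs stay null.
#'
#' @param effects `"null"` or `"significant"`.
#' @return Data frame with `gene`, `rs_id`, `allele1`, `allele2`, `maf`, `or`.
#' @export
reported_sim_panel <- function(effects = c("null", "significant")) {
  effects <- match.arg(effects)
  tab <- reported_allele_tables()
  panel <- tab[c("gene", "rs_id", "allele1", "allele2")]
  panel$maf <- tab$d / (tab$c + tab$d)
  panel$or <- 1
  if (effects == "significant") {
    res <- associate_tables(tab)
    sig <- res$significant_nominal & res$effect_type %in% c("OR", "RR") &
      tab$d > 0  # need a finite allelic odds in controls
    panel$or[sig] <- (tab$b[sig] / tab$a[sig]) / (tab$d[sig] / tab$c[sig])
  }
  panel
}
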