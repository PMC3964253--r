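#' Read a cohort from a VCF file (optional path; requires vcfR)
#'
#' Biallelic records are matched to the panel by the VCF ID field; GT fields
#' are mapped to allele2 dosage by counting ALT alleles. Genotypes involving
#' an allele index other than 0/1 (multi-allelic calls) or a half-missing
#' call become `NA` with a warning. Panel SNPs absent from the VCF are an
#' error, as are genotyped patients without a fibrosis grade.
#'
#' @param path Path to a VCF (plain or bgzipped).
#' @param panel SNP panel data frame (see [as_snp_panel()]).
#' @param phenotype Phenotype data frame (or TSV path) with `patient_id` and
#'   `fibrosis_grade`.
#' @return A [new_cohort()] object, samples in VCF column order.
#' @export
read_cohort_vcf <- function(path, panel, phenotype) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("read_cohort_vcf needs the vcfR package", call. = FALSE)
  panel <- as_snp_panel(panel)
  if (is.character(phenotype) && length(phenotype) == 1L)
    phenotype <- read_phenotype(phenotype)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ids <- vcfR::getID(v)
  hit <- match(panel$rs_id, ids)
  if (any(is.na(hit)))
    stop("panel SNP(s) missing from VCF: ",
         paste(panel$rs_id[is.na(hit)], collapse = ", "), call. = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")[hit, , drop = FALSE]
  to_dosage <- function(g) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_integer_)
    alleles <- strsplit(g, "[/|]")[[1]]
    if (length(alleles) != 2L || any(!alleles %in% c("0", "1")))
      return(NA_integer_)
    sum(alleles == "1")
  }
  dosage <- t(apply(gt, c(1, 2), to_dosage))  # patients x SNPs
  n_bad <- sum(is.na(dosage)) - sum(is.na(gt))
  if (n_bad > 0)
    warning(n_bad, " genotype call(s) were multi-allelic or half-missing; ",
            "set to NA", call. = FALSE)
  ph <- phenotype[match(colnames(gt), phenotype$patient_id), , drop = FALSE]
  if (any(is.na(ph$patient_id)))
    stop("no fibrosis grade for VCF sample(s): ",
         paste(colnames(gt)[is.na(ph$patient_id)], collapse = ", "),
         call. = FALSE)
  new_cohort(panel, ph, dosage)
}
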