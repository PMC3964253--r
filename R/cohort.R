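#' Dichotomize an RTOG/EORTC fibrosis grade into case/control
#'
#' Patients with severe late fibrosis (grade 3--4) form the radiosensitive
#' case group; grades 0--2 are controls.
#'
#' @param grade Integer vector of fibrosis grades, each in 0--4.
#' @param patient_id Optional character vector of the same length, used to
#'   name the offending patient in validation errors.
#' @return Character vector with elements `"case"` or `"control"`.
#' @examples
#' grade_to_group(c(0, 2, 3, 4))
#' @export
grade_to_group <- function(grade, patient_id = NULL) {
  if (length(grade) == 0L) return(character(0))
  bad <- !is.finite(grade) | grade != as.integer(grade) | grade < 0 | grade > 4
  if (any(bad)) {
    who <- if (!is.null(patient_id)) patient_id[bad] else which(bad)
    stop("fibrosis_grade must be an integer in 0..4; offending patient(s): ",
         paste(utils::head(who, 5L), collapse = ", "), call. = FALSE)
  }
  ifelse(grade >= 3, "case", "control")
}

#' Construct and validate a SNP panel
#'
#' A panel is a data frame with one row per SNP: `gene`, `rs_id`,
#' `allele1` (majority / wild-type) and `allele2` (minority / variant).
#'
#' @param panel Data frame with columns `gene`, `rs_id`, `allele1`, `allele2`.
#' @return The validated panel (character columns, row names dropped).
#' @export
as_snp_panel <- function(panel) {
  need <- c("gene", "rs_id", "allele1", "allele2")
  miss <- setdiff(need, names(panel))
  if (length(miss))
    stop("panel is missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  panel <- as.data.frame(panel)[need]
  for (cn in need) panel[[cn]] <- as.character(panel[[cn]])
  if (anyDuplicated(panel$rs_id))
    stop("duplicate rs_id in panel: ",
         paste(unique(panel$rs_id[duplicated(panel$rs_id)]), collapse = ", "),
         call. = FALSE)
  same <- panel$allele1 == panel$allele2
  if (any(same))
    stop("allele1 must differ from allele2 (rs_id: ",
         paste(panel$rs_id[same], collapse = ", "), ")", call. = FALSE)
  rownames(panel) <- NULL
  panel
}

#' Construct a validated case-control cohort
#'
#' Bundles a SNP panel, a patient table (with fibrosis grades and the derived
#' case/control label) and a patients x SNPs variant-allele dosage matrix.
#'
#' @param panel SNP panel (see [as_snp_panel()]).
#' @param patients Data frame with columns `patient_id` and `fibrosis_grade`.
#' @param dosage Numeric matrix, `nrow(patients)` x `nrow(panel)`, entries in
#'   \{0, 1, 2, NA\}: copies of `allele2` carried by each patient at each SNP.
#' @return An object of class `"cohort"`: a list with elements `panel`,
#'   `patients` (including the derived `group` column) and `dosage` (with
#'   patient / rs_id dimnames).
#' @export
new_cohort <- function(panel, patients, dosage) {
  panel <- as_snp_panel(panel)
  patients <- as.data.frame(patients)
  if (!all(c("patient_id", "fibrosis_grade") %in% names(patients)))
    stop("patients needs columns patient_id and fibrosis_grade", call. = FALSE)
  patients$patient_id <- as.character(patients$patient_id)
  if (anyDuplicated(patients$patient_id))
    stop("duplicate patient_id: ",
         paste(unique(patients$patient_id[duplicated(patients$patient_id)]),
               collapse = ", "), call. = FALSE)
  if (any(is.na(patients$fibrosis_grade)))
    stop("missing fibrosis_grade for patient(s): ",
         paste(patients$patient_id[is.na(patients$fibrosis_grade)],
               collapse = ", "), call. = FALSE)
  patients$fibrosis_grade <- as.integer(patients$fibrosis_grade)
  patients$group <- grade_to_group(patients$fibrosis_grade, patients$patient_id)

  dosage <- as.matrix(dosage)
  if (nrow(dosage) != nrow(patients) || ncol(dosage) != nrow(panel))
    stop("dosage must be ", nrow(patients), " x ", nrow(panel),
         " (patients x SNPs), got ", nrow(dosage), " x ", ncol(dosage),
         call. = FALSE)
  ok <- is.na(dosage) | dosage %in% c(0, 1, 2)
  if (!all(ok)) {
    idx <- which(!ok, arr.ind = TRUE)[1, ]
    stop("dosage must be 0, 1, 2 or NA; found ", dosage[idx[1], idx[2]],
         " at patient ", patients$patient_id[idx[1]],
         ", SNP ", panel$rs_id[idx[2]], call. = FALSE)
  }
  storage.mode(dosage) <- "integer"
  dimnames(dosage) <- list(patients$patient_id, panel$rs_id)
  rownames(patients) <- NULL
  structure(list(panel = panel, patients = patients, dosage = dosage),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  tab <- table(factor(x$patients$group, levels = c("control", "case")))
  cat("<cohort> ", nrow(x$patients), " patients (",
      tab[["case"]], " cases G3-4 / ", tab[["control"]], " controls G0-2), ",
      nrow(x$panel), " SNPs; ", sum(is.na(x$dosage)),
      " missing genotypes\n", sep = "")
  invisible(x)
}

## ---- TSV dialects -----------------------------------------------------------
## panel:     gene <TAB> rs_id <TAB> allele1 <TAB> allele2
## phenotype: patient_id <TAB> fibrosis_grade
## genotype:  patient_id <TAB> rs... <TAB> rs...   (cells 0|1|2|NA)

#' Read a SNP panel TSV
#' @param path Path to a tab-separated file with header
#'   `gene  rs_id  allele1  allele2`.
#' @return Validated panel data frame.
#' @export
read_panel <- function(path) {
  as_snp_panel(utils::read.delim(path, colClasses = "character"))
}

#' Read a phenotype TSV (`patient_id`, `fibrosis_grade`)
#' @param path Path to a tab-separated file.
#' @return Data frame with `patient_id` (character) and `fibrosis_grade`
#'   (integer).
#' @export
read_phenotype <- function(path) {
  ph <- utils::read.delim(path, colClasses = "character")
  if (!all(c("patient_id", "fibrosis_grade") %in% names(ph)))
    stop("phenotype file needs columns patient_id and fibrosis_grade",
         call. = FALSE)
  grade <- suppressWarnings(as.integer(ph$fibrosis_grade))
  if (any(is.na(grade)))
    stop("non-integer or missing fibrosis_grade at line(s) ",
         paste(which(is.na(grade)) + 1L, collapse = ", "), " of ", path,
         call. = FALSE)
  data.frame(patient_id = ph$patient_id, fibrosis_grade = grade,
             stringsAsFactors = FALSE)
}

#' Read a genotype dosage TSV and assemble a cohort
#'
#' The genotype table has one row per patient (`patient_id` column) and one
#' column per panel SNP, named by rs identifier; cells are the variant-allele
#' (allele2) copy number `0|1|2|NA`. Row order is preserved. Phenotype rows
#' must cover every genotyped patient: patients with no fibrosis grade are
#' rejected, not dropped, because grading is the case definition.
#'
#' @param path Path to the genotype TSV.
#' @param panel SNP panel data frame (see [as_snp_panel()]).
#' @param phenotype Phenotype data frame (or path to a phenotype TSV) with
#'   `patient_id` and `fibrosis_grade`.
#' @return A [new_cohort()] object.
#' @export
read_genotype_table <- function(path, panel, phenotype) {
  panel <- as_snp_panel(panel)
  if (is.character(phenotype) && length(phenotype) == 1L)
    phenotype <- read_phenotype(phenotype)
  gt <- utils::read.delim(path, colClasses = "character",
                          check.names = FALSE)
  if (!"patient_id" %in% names(gt))
    stop("genotype file must have a patient_id column: ", path, call. = FALSE)
  snp_cols <- setdiff(names(gt), "patient_id")
  unknown <- setdiff(snp_cols, panel$rs_id)
  if (length(unknown))
    stop("genotype column(s) not in panel: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  absent <- setdiff(panel$rs_id, snp_cols)
  if (length(absent))
    stop("panel SNP(s) missing from genotype file: ",
         paste(absent, collapse = ", "), call. = FALSE)
  if (anyDuplicated(gt$patient_id))
    stop("duplicate patient_id at line(s) ",
         paste(which(duplicated(gt$patient_id)) + 1L, collapse = ", "),
         " of ", path, call. = FALSE)

  dosage <- matrix(NA_integer_, nrow(gt), nrow(panel),
                   dimnames = list(gt$patient_id, panel$rs_id))
  for (rs in panel$rs_id) {
    cell <- gt[[rs]]
    cell[is.na(cell)] <- "NA"  # read.delim maps literal NA to missing
    val <- suppressWarnings(as.integer(cell))
    bad <- !(cell %in% c("NA", "")) & (is.na(val) | !(val %in% 0:2))
    if (any(bad))
      stop("invalid dosage '", cell[which(bad)[1]], "' for ", rs,
           " at line ", which(bad)[1] + 1L, " of ", path, call. = FALSE)
    val[cell %in% c("NA", "")] <- NA_integer_
    dosage[, rs] <- val
  }

  ph <- phenotype[match(gt$patient_id, phenotype$patient_id), , drop = FALSE]
  if (any(is.na(ph$patient_id)))
    stop("no fibrosis grade for patient(s): ",
         paste(gt$patient_id[is.na(ph$patient_id)], collapse = ", "),
         call. = FALSE)
  new_cohort(panel, ph, dosage)
}

#' Write a cohort to the genotype/phenotype/panel TSV dialects
#'
#' @param cohort A cohort object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named character vector of the three file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(panel = file.path(dir, "panel.tsv"),
             phenotype = file.path(dir, "phenotype.tsv"),
             genotype = file.path(dir, "genotype.tsv"))
  utils::write.table(cohort$panel, paths["panel"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$patients[c("patient_id", "fibrosis_grade")],
                     paths["phenotype"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  gt <- data.frame(patient_id = cohort$patients$patient_id,
                   cohort$dosage, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(gt, paths["genotype"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

## ---- allele counting --------------------------------------------------------

#' 2x2 allele-count table constructor
#'
#' Cell layout follows the published convention: `a` = case allele1 count,
#' `b` = case allele2 (variant) count, `c` = control allele1 count,
#' `d` = control allele2 count.
#'
#' @param a,b,c,d Non-negative integer counts.
#' @param rs_id Optional SNP identifier carried along for reporting.
#' @return An object of class `"allele_table"`.
#' @export
allele_table <- function(a, b, c, d, rs_id = NA_character_) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(cells)) || any(cells < 0) || any(cells != round(cells)))
    stop("allele counts must be non-negative integers", call. = FALSE)
  structure(list(a = as.integer(a), b = as.integer(b),
                 c = as.integer(c), d = as.integer(d),
                 rs_id = rs_id,
                 degenerate = (a + b == 0L) || (c + d == 0L)),
            class = "allele_table")
}

#' @export
print.allele_table <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2,
              dimnames = list(c("cases", "controls"), c("allele1", "allele2")))
  cat("<allele_table>", if (!is.na(x$rs_id)) x$rs_id, "\n")
  print(m)
  invisible(x)
}

#' Tally the 2x2 allele-count table for one SNP
#'
#' Per group, the allele2 count is the sum of dosages over patients with a
#' non-missing genotype; the allele1 count is twice the number of non-missing
#' patients minus that (complete-case per marker).
#'
#' @param cohort A cohort object.
#' @param snp SNP index or rs identifier.
#' @return An [allele_table()]; its `degenerate` flag is set when a group has
#'   no non-missing genotypes.
#' @export
count_alleles <- function(cohort, snp) {
  j <- if (is.character(snp)) match(snp, cohort$panel$rs_id) else as.integer(snp)
  if (is.na(j) || j < 1L || j > nrow(cohort$panel))
    stop("unknown SNP: ", snp, call. = FALSE)
  dos <- cohort$dosage[, j]
  case <- cohort$patients$group == "case"
  n_case <- sum(!is.na(dos[case]))
  n_ctrl <- sum(!is.na(dos[!case]))
  b <- sum(dos[case], na.rm = TRUE)
  d <- sum(dos[!case], na.rm = TRUE)
  allele_table(2L * n_case - b, b, 2L * n_ctrl - d, d,
               rs_id = cohort$panel$rs_id[j])
}

#' Allele-count tables for every panel SNP
#'
#' @param cohort A cohort object.
#' @return Data frame in panel order with `gene`, `rs_id`, `allele1`,
#'   `allele2` and the four counts `a`, `b`, `c`, `d`
#'   (cases/controls x allele1/allele2).
#' @export
count_alleles_all <- function(cohort) {
  case <- cohort$patients$group == "case"
  dc <- cohort$dosage[case, , drop = FALSE]
  dk <- cohort$dosage[!case, , drop = FALSE]
  b <- colSums(dc, na.rm = TRUE)
  d <- colSums(dk, na.rm = TRUE)
  a <- 2L * colSums(!is.na(dc)) - b
  c_ <- 2L * colSums(!is.na(dk)) - d
  out <- cbind(cohort$panel,
               data.frame(a = as.integer(a), b = as.integer(b),
                          c = as.integer(c_), d = as.integer(d)))
  rownames(out) <- NULL
  out
}

#' Render allele counts as group percentages
#'
#' Each count is expressed as a percentage of its group's allele total,
#' rounded half away from zero to the nearest integer. A non-zero count that
#' would round to 0 is reported as 0.5, and a below-total count that would
#' round to 100 as 99.5, matching the usual table rendering of rare alleles.
#'
#' @param table An [allele_table()] (or anything with fields `a`,`b`,`c`,`d`).
#' @return Named numeric vector `c(a=, b=, c=, d=)` of percentages; all `NA`
#'   when a group margin is zero.
#' @export
allele_percentages <- function(table) {
  one <- function(count, total) {
    if (total == 0L) return(NA_real_)
    r <- floor(100 * count / total + 0.5)
    if (r == 0 && count > 0) return(0.5)
    if (r == 100 && count < total) return(99.5)
    r
  }
  with(table, c(a = one(a, a + b), b = one(b, a + b),
                c = one(c, c + d), d = one(d, c + d)))
}
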