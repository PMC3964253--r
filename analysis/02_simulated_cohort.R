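#!/usr/bin/env Rscript
# End-to-end run on one synthetic cohort drawn at the study design: 48 cases
# / 107 controls, the published 45-SNP allele-frequency spectrum, and the six
# significant SNPs carrying their observed allelic odds ratios. Exercises the
# individual-level path (genotype TSVs -> association -> risk model ->
# burden) that the published counts alone cannot.

library(radburden)

seed <- 20130426 %% 1e6
cfg <- sim_config(reported_sim_panel("significant"), seed = seed)
coh <- simulate_cohort(cfg)
print(coh)

# round-trip through the TSV dialects, as an external dataset would arrive
tsv_dir <- "results/simulated/cohort_tsv"
paths <- write_cohort(coh, tsv_dir)
coh <- read_genotype_table(paths["genotype"], read_panel(paths["panel"]),
                           read_phenotype(paths["phenotype"]))

pl <- run_pipeline(cohort = coh, out_dir = "results/simulated")
print(pl)

if (!is.null(pl$burden)) {
  cat("\nBurden comparison under the recovered risk model:\n")
  print(pl$burden)
  cat("\nAt n = 48/107 the association stage has partial power, so the",
      "recovered model typically holds 2-6 of the 6 generating SNPs.\n")
}

cat("\nGenotype-distribution report covers",
    length(unique(pl$genotypes$rs_id)),
    "SNPs with >= 5 minor-allele carriers\n")
cat("Outputs written to results/simulated\n")
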