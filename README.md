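# radburden

Allele-level case-control association and cumulative risk-allele burden
scoring for radiation-induced fibrosis, built for candidate-gene
radiogenomic studies.

Patients treated with radiotherapy differ markedly in late normal-tissue
toxicity (fibrosis, graded 0–4 on the RTOG/EORTC scale), and part of that
difference is genetic. The standard study design genotypes a panel of SNPs
in DNA-repair / cell-cycle / cytokine genes, splits patients into severe
(grade 3–4, "cases") and minor (grade 0–2, "controls") reactors, and tests
each SNP's allele frequencies in a 2×2 table. `radburden` implements that
analysis end to end:

* **Cohort I/O** — genotype dosage / phenotype / panel TSV dialects (plus
  optional VCF via `vcfR`), strict validation, grade dichotomization at
  G ≥ 3, per-SNP allele-count tables.
* **Association** — variant-allele odds ratio `OR = bc/ad` with the Woolf
  interval `exp(ln OR ± 1.96·√(1/a+1/b+1/c+1/d))`; Katz risk-ratio fallback
  `RR = [b/(b+d)]/[a/(a+c)]` when the variant is absent in controls;
  uncorrected Pearson chi-square with a two-sided Fisher exact fallback
  under Cochran's rule (all expected cells ≥ 5); Bonferroni correction with
  a configurable divisor.
* **Risk-allele burden** — each SNP with p ≤ 0.05 contributes one risk
  allele (the variant if deleterious, the wild type if the variant is
  protective); per-patient burden = risk-allele copies summed over model
  SNPs (0–2 each); groups compared by the two-sided Mann–Whitney test.
* **Simulation** — Hardy–Weinberg case-control cohorts with configurable
  per-allele odds ratios (case allele odds = OR × control odds), used for
  type-I, power and parameter-recovery calibration.
* **Reporting** — publication-style allele-frequency tables, risk-model and
  burden TSVs, genotype-distribution summaries by fibrosis severity.

The package ships the complete published allele-count tables of a
155-patient, 45-SNP nasopharyngeal-carcinoma panel
(`reported_allele_tables()`), so the counts-only analysis can be reproduced
exactly.

## Worked example

```r
library(radburden)

res <- associate_tables(reported_allele_tables())
subset(res, significant_nominal,
       select = c(gene, rs_id, effect_type, effect, ci_low, ci_high, p_value))
#>    gene     rs_id effect_type    effect     ci_low   ci_high     p_value
#> 4   ATM rs1801516          OR 2.8739837 1.27402082 6.4828823 0.008387771
#> 7  HDM2 rs2279744          OR 0.4945403 0.29087821 0.8407989 0.008670515
#> 8  HDM2 rs1196333          OR 0.1302632 0.01702154 0.9968837 0.021393156
#> 13 TGFB1 rs1800469          OR 0.5740428 0.34351340 0.9593077 0.032917216
#> 22 XRCC1   rs25487          OR 0.4114764 0.21326184 0.7939676 0.006841931
#> 33 XRCC5 rs1051677          OR 0.3888889 0.16636690 0.9089607 0.024786451
```

Six SNPs are nominally associated with severe fibrosis: the ATM variant
allele raises risk (OR 2.87), the other five variant alleles are protective
(OR < 1), so their wild-type alleles are the risk alleles. The risk model
and a formatted report row:

```r
assign_risk_alleles(res)[, c("rs_id", "gene", "risk_allele", "risk_which")]
#>       rs_id  gene risk_allele risk_which
#> 1 rs1801516   ATM           A    allele2
#> 2 rs2279744  HDM2           T    allele1
#> 3 rs1196333  HDM2           T    allele1
#> 4 rs1800469 TGFB1           C    allele1
#> 5   rs25487 XRCC1           G    allele1
#> 6 rs1051677 XRCC5           T    allele1

format_report_table(res)[7, c("gene_snp", "effect", "p")]
#>             gene_snp           effect     p
#> 7 HDM2 T/G rs2279744 0.49 (0.29-0.84) <0.01
```

On the individual-level path, a synthetic cohort at the study design (48
cases / 107 controls, published frequency spectrum, observed effect sizes at
the six significant SNPs) runs the whole pipeline including the burden
comparison:

```r
coh <- simulate_cohort(sim_config(reported_sim_panel("significant"), seed = 1))
pl <- run_pipeline(cohort = coh)
pl$burden
#> <burden_result> 5-SNP risk model
#>    group   n min p10  q25 median  q75 p90 max
#>  control 107   3   4 5.00      6 6.00   7   9
#>     case  48   4   6 6.75      7 7.25   9   9
#> Mann-Whitney U = 4258.5 (normal approximation), two-sided P = 1.88e-11
```

(the recovered model holds 5 of the 6 generating SNPs at this seed —
power at n = 48/107 is partial by design).

The `analysis/` directory contains four numbered drivers that narrate the
full study: `01_reported_association.R` (counts-only reanalysis),
`02_simulated_cohort.R` (individual-level pipeline), `03_calibration.R`
(type-I error, power, parameter recovery) and `04_burden_separation.R`
(burden behaviour across seeds). Each writes its tables under `results/`.

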