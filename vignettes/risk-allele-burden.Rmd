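---
title: "Allele-level association and risk-allele burden: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allele-level association and risk-allele burden: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radburden)
```

## The problem

Late normal-tissue toxicity after radiotherapy — here subcutaneous and deep
tissue fibrosis graded 0–4 on the RTOG/EORTC scale — varies widely between
patients given identical treatment, and a large part of that variability is
believed to be inherited. Candidate-gene radiogenomic studies genotype a
panel of SNPs in DNA-damage-response and cytokine genes and ask, marker by
marker, whether an allele is over-represented among severely affected
patients. `radburden` implements that analysis as a tested, reusable
pipeline: dichotomization of the toxicity grade, per-SNP 2×2 allele-table
association, risk-allele designation, and a cumulative risk-allele burden
comparison — together with a cohort simulator so every stage can be
exercised and calibrated without access to individual-level data.

The package ships the complete published allele-count tables of a 155-patient
nasopharyngeal-carcinoma cohort (45 SNPs in 11 genes; 48 cases with grade
3–4 fibrosis contributing 96 alleles, 107 controls with grade 0–2
contributing 214) as `reported_allele_tables()`, so the counts-only path can
be re-run exactly.

## The model

### Case definition

A patient is a **case** iff the fibrosis grade is ≥ 3 (`grade_to_group()`).
This is a hard threshold on an ordinal scale; patients with a missing grade
are rejected at load rather than silently dropped, because the grade *is*
the case definition.

### Allele-level 2×2 tables

Each patient contributes two alleles, so a SNP with genotype dosage $g_i \in
\{0,1,2\}$ (copies of the minority allele, "allele2") yields the table

|            | allele1 | allele2 |
|------------|---------|---------|
| cases      | $a$     | $b$     |
| controls   | $c$     | $d$     |

with $b = \sum_{\text{cases}} g_i$ and $a = 2n_{\text{case}} - b$ over
non-missing genotypes (complete-case per marker). Percentages are rendered
per group with integer rounding, except that a non-zero count that would
round to 0 displays as 0.5 and its complement as 99.5 — the convention used
for rare alleles in published tables.

### Effect estimates

The effect is the variant-allele odds ratio in cases over controls,

$$\mathrm{OR} = \frac{b/a}{d/c} = \frac{bc}{ad},$$

with the Woolf log-normal interval
$\exp\!\left(\ln \mathrm{OR} \pm 1.96\sqrt{1/a + 1/b + 1/c + 1/d}\right)$.
When the variant is present in cases but absent in controls ($d = 0$) the OR
is infinite and the pipeline falls back to the Katz risk ratio of case
status between allele2 and allele1 carriers,

$$\mathrm{RR} = \frac{b/(b+d)}{a/(a+c)}, \qquad
\mathrm{SE}(\ln \mathrm{RR}) = \sqrt{\tfrac1b - \tfrac1{b+d} + \tfrac1a -
\tfrac1{a+c}}.$$

Both methods reproduce the published intervals on the rows where they can be
checked (e.g. OR 0.49, CI 0.29–0.84; RR 3.28, CI 2.77–3.88). Tables with the
variant absent in cases but present in controls report the literal effect 0
with no interval, and fully monomorphic tables are undefined — exactly the
rendering conventions of the source table. A Haldane–Anscombe
continuity-corrected OR is available behind `zero_cell = "haldane"` but is
never used by default, since the published zero rows show no correction.

### Test selection

Significance is tested by the uncorrected Pearson chi-square (1 df) when
Cochran's criterion holds — no zero margin and every expected cell count at
least 5 — and by the two-sided Fisher exact test otherwise. The Fisher
two-sided p-value uses the minimum-likelihood convention (sum of
hypergeometric point probabilities no larger than the observed table's, as
in `stats::fisher.test`); the tail-doubling convention is exposed behind
`fisher_convention = "doubling"`. The uncorrected chi-square with this
dispatch reproduces the published significance pattern, including the
borderline table (95, 1, 198, 16) whose minimum expected count is 5.26:
chi-square applies and gives the printed 0.02, where Fisher would give 0.03.
A Yates-corrected chi-square sits behind `chi_correct = TRUE`.

### Multiplicity

`bonferroni_threshold(alpha, m)` is `alpha/m` with strict inequality for
significance. Which SNPs should enter $m$ is genuinely ambiguous in studies
of this design (all 45 assessed markers? the 29 with any variant allele
observed? the 20 with enough carriers to display?), so the divisor is
configurable; the default is the number of SNPs with any variant allele
observed. With the shipped tables the smallest p-value is ≈ 0.007, so no SNP
survives any of those divisors — the package reports what the counts
support rather than any stricter published claim.

### Risk alleles and the burden score

Every SNP with $p \le 0.05$ and a defined, non-unit effect contributes one
risk allele: the variant when its effect exceeds 1, the wild-type allele when
the variant is protective (effect < 1). With the shipped tables this yields a
six-SNP model — the ATM variant plus five wild-type alleles. The
significance gate uses $p \le 0.05$ (not $<$), and an effect of exactly 1 at
a significant SNP — possible only under pathological rounding — is excluded
as directionless.

The burden of a patient is the number of risk-allele copies summed over
model SNPs: dosage $g$ where the risk allele is the variant, $2 - g$ where
it is the wild type (the complement formula the verbal "wild-type alleles
were the risk factors" rule implies). Scores therefore lie in $[0, 2K]$ for
a $K$-SNP model. Patients missing a genotype at any model SNP are flagged
and excluded from the comparison by default; mean imputation is deliberately
not a default anywhere.

Groups are compared with the two-sided Mann–Whitney rank-sum test via
`stats::wilcox.test`: exact when the product of group sizes is ≤ 10⁴ and
the scores are tie-free, otherwise the normal approximation with
tie-corrected variance and continuity correction (integer burden scores
essentially always tie). An all-constant score vector returns p = 1.

## The simulator

`simulate_cohort()` draws retrospective case-control data: per SNP, control
genotypes are Binomial(2, q) — Hardy–Weinberg at the control minor-allele
frequency q — and case genotypes are Binomial(2, q′) with case allele odds
equal to the per-allele odds ratio times the control odds,
$q' = \mathrm{OR}\,q / (1 - q + \mathrm{OR}\,q)$. This retrospective
allele-odds construction (rather than prospective logistic sampling) makes
the simulator's OR exactly the estimand of the allele-level odds ratio, so
parameter-recovery checks are sharp. SNPs are independent (the analysis is
marginal; linkage disequilibrium is out of scope), and fibrosis grades are
drawn from the within-group mixtures of the emulated study (grades 0/1/2 at
17/54/36 within 107 controls, 3/4 at 38/10 within 48 cases), so
grade-stratified displays look realistic. `reported_sim_panel()` builds
panels whose frequency spectrum is the published control column —
monomorphic through common — with either all-null effects or the observed
odds ratios at the six significant SNPs.

What the simulator does **not** emulate: linkage disequilibrium and
haplotype structure, population stratification, genotyping error and
missingness patterns, covariates (dose, chemotherapy), and any
grade-by-genotype interaction beyond the case/control shift. Passing
simulation-based checks therefore validates the statistical machinery at the
study's design point, not the biological claims of any particular cohort.

## Numerical and design choices

* All internal arithmetic is at full double precision; 32-bit integer
  overflow in cell products is avoided explicitly. Rounding to 2 decimals
  (half away from zero) happens only at the formatting layer.
* The p-value display mimics the published convention: `"<0.01"` for
  p < 0.01, two decimals otherwise, `*` marking Fisher-tested rows, `**`
  marking risk-ratio fallbacks, `-` for untestable rows.
* The exact HWE test enumerates heterozygote counts conditional on the
  allele counts in log-space; it is a QC utility, not part of the default
  association path.
* Degenerate inputs never abort a panel run: monomorphic SNPs carry
  undefined effects and no test, and an empty risk model skips the burden
  stage with a notice.
* Seeds: a `sim_config` seed fully determines a cohort; replicate
  experiments derive per-replicate seeds by small offsets, keeping every
  stream below 2³¹.

## Calibration results the test suite recomputes

The test suite and `scripts/acceptance.R` recompute, at fixed problem sizes
chosen to keep a full run in minutes on one CPU:

* exact agreement of the Fisher p-value with a brute-force hypergeometric
  enumeration over random tables with total ≤ 60 (1000 tables), and of the
  exact Mann–Whitney p-value with a full-permutation oracle for all group
  sizes with $n_A + n_B \le 12$;
* pooled type-I error of chi-square-tested SNPs within 0.05 ± 0.02 over
  1000 null cohorts at the 48/107 design (per-SNP rates at 1000 replicates
  carry Monte-Carlo SE ≈ 0.007, so the band is asserted on the pooled rate;
  Fisher-tested sparse SNPs are conservative, as exact conditional tests
  are);
* recovery of generating log odds ratios (OR ∈ {0.4, 1, 2.5}, MAF ∈
  {0.05, 0.3}) as the Monte-Carlo mean over 25 cohorts of 10⁴/10⁴ — a
  single cohort at that size has ln-OR standard error up to ≈ 0.06, so the
  mean, not a single draw, is the meaningful recovery summary; single-cohort
  recovery is additionally checked at 10⁵/10⁵ where the estimator is
  precise enough;
* burden behaviour: with the six significant SNPs at their observed odds
  ratios, the case median burden exceeds the control median in ≥ 95% of 200
  seeds, and on null cohorts the burden-test p-values are approximately
  uniform.

## Known limitations

* The allele-level test treats the two alleles of a patient as independent
  Bernoulli draws, which is standard for this design but assumes HWE;
  genotype-level (2×3) models, covariate-adjusted logistic regression and
  haplotype analyses are intentionally out of scope.
* Individual genotypes were never deposited for the emulated study, so its
  burden medians (7 vs 9), ranges and Bonferroni survivor set cannot be
  recomputed from the printed counts; the simulator-based checks above are
  the substitute, and one published row (the ATM OR printed as 2.86 where
  the counts give 2.87) is known not to be exactly recoverable.
* The Fisher exact test is conservative on sparse tables; its two-sided
  p-value differs from the chi-square p by more than a few percent even at
  cell counts of 30–40, converging only at counts in the thousands.
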