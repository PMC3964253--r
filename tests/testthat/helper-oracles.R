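# Independent brute-force oracles; deliberately distinct code paths from the
# package implementation (choose()/dmultinom/full enumeration, no dhyper, no
# wilcox.test).

# Two-sided Fisher p by enumerating every table with the observed margins and
# summing the probabilities of those no more likely than the observed table.
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; k <- b + d; n <- r1 + r2
  if (r1 == 0 || r2 == 0 || k == 0 || k == n) return(1)
  support <- max(0, k - r2):min(k, r1)
  pr <- vapply(support, function(bb)
    choose(r1, bb) * choose(r2, k - bb) / choose(n, k), numeric(1))
  min(sum(pr[pr <= pr[support == b] * (1 + 1e-7)]), 1)
}

# Pearson statistic recomputed from an explicit expected-count loop.
oracle_chi2 <- function(a, b, c, d) {
  obs <- matrix(c(a, b, c, d), 2, byrow = TRUE)
  n <- sum(obs)
  stat <- 0
  for (i in 1:2) for (j in 1:2) {
    e <- sum(obs[i, ]) * sum(obs[, j]) / n
    stat <- stat + (obs[i, j] - e)^2 / e
  }
  stat
}

# Exact two-sided Mann-Whitney p by full enumeration of group assignments
# (tie-free inputs), using the doubled-tail convention capped at 1.
oracle_mw <- function(x, y) {
  v <- c(x, y)
  stopifnot(!anyDuplicated(v))
  nx <- length(x)
  rk <- rank(v)
  sets <- utils::combn(length(v), nx)
  us <- apply(sets, 2, function(s) sum(rk[s]) - nx * (nx + 1) / 2)
  u_obs <- sum(rk[seq_len(nx)]) - nx * (nx + 1) / 2
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# Exact HWE p via dmultinom conditional probabilities (allele frequency 1/2
# cancels on renormalization).
oracle_hwe <- function(n11, n12, n22) {
  n <- n11 + n12 + n22
  m <- min(2 * n11 + n12, 2 * n22 + n12)
  if (n == 0 || m == 0) return(1)
  hets <- seq.int(m %% 2, min(m, 2 * n - m), by = 2)
  pr <- vapply(hets, function(h)
    stats::dmultinom(c((m - h) / 2, h, (2 * n - m - h) / 2),
                     prob = c(1, 2, 1) / 4), numeric(1))
  pr <- pr / sum(pr)
  min(sum(pr[pr <= pr[hets == n12] * (1 + 1e-7)]), 1)
}

# Small deterministic cohort: 6 patients, 2 SNPs, one missing genotype.
make_tiny_cohort <- function() {
  panel <- data.frame(gene = c("G1", "G2"), rs_id = c("rs1", "rs2"),
                      allele1 = c("A", "C"), allele2 = c("G", "T"))
  patients <- data.frame(patient_id = paste0("P", 1:6),
                         fibrosis_grade = c(0, 1, 2, 3, 4, 3))
  dosage <- matrix(c(0, 1, 2, 1, 2, 0,
                     0, 0, NA, 1, 2, 1), ncol = 2)
  new_cohort(panel, patients, dosage)
}

random_table <- function(max_n = 60) {
  repeat {
    x <- stats::rpois(4, sample(c(1, 3, 8), 4, replace = TRUE))
    if (sum(x) >= 2 && sum(x) <= max_n) return(x)
  }
}
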