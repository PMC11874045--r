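# Independent oracles, written as plain loops so they share no code with the
# implementation they check.

# DQ by explicit enumeration of all 27 diploid trio genotype configurations.
dq_oracle <- function(cpl, mpl, fpl, mu = 1e-8, p = 1e-4) {
  lik <- function(pl) 10^(-(pl - min(pl)) / 10)
  lc <- lik(cpl); lm <- lik(mpl); lf <- lik(fpl)
  pri <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  alleles <- list(c(1, 0), c(0.5, 0.5), c(0, 1))
  num <- mu * lm[1] * lf[1] * lc[2]
  den <- 0
  for (gm in 1:3) for (gf in 1:3) for (gc in 1:3) {
    tr <- 0
    for (am in 0:1) for (af in 0:1)
      if (am + af + 1 == gc)
        tr <- tr + alleles[[gm]][am + 1] * alleles[[gf]][af + 1]
    den <- den + pri[gm] * pri[gf] * tr * lm[gm] * lf[gf] * lc[gc]
  }
  max(min(log10(num) - log10(den), 20), -20)
}

# hemizygous variant: haploid child and father, maternal transmission only
dq_oracle_hemi <- function(cpl, mpl, fpl, mu = 1e-8, p = 1e-4) {
  lik <- function(pl) 10^(-(pl - min(pl)) / 10)
  lc <- lik(cpl); lm <- lik(mpl); lf <- lik(fpl)
  pri_m <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  pri_f <- c(1 - p, p)
  tr <- rbind(c(1, 0), c(0.5, 0.5), c(0, 1))
  num <- mu * lm[1] * lf[1] * lc[2]
  den <- 0
  for (gm in 1:3) for (gf in 1:2) for (gc in 1:2)
    den <- den + pri_m[gm] * pri_f[gf] * tr[gm, gc] * lm[gm] * lf[gf] * lc[gc]
  max(min(log10(num) - log10(den), 20), -20)
}

# two-sided Fisher exact p by hypergeometric tail enumeration
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  ks <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(ks, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# per-base scan: which genes have an exon base inside [start, end]
overlap_oracle <- function(chrom, start, end, exon_df) {
  hits <- character(0)
  for (k in seq_len(nrow(exon_df))) {
    if (exon_df$chrom[k] != chrom) next
    for (b in exon_df$start[k]:exon_df$end[k]) {
      if (b >= start && b <= end) { hits <- c(hits, exon_df$gene[k]); break }
    }
  }
  sort(unique(hits))
}

# leave-one-out z of element i
loo_z_oracle <- function(x, i) {
  others <- x[-i]
  (x[i] - mean(others)) / stats::sd(others)
}

# compound-het clause logic, written as a direct truth table
comphet_oracle_qualifies <- function(class_m, mpc_m, class_p, mpc_p) {
  eligible <- function(cl) cl %in% c("ptv", "qualifying_splice", "missense")
  if (!eligible(class_m) || !eligible(class_p)) return(FALSE)
  ptvish <- function(cl) cl %in% c("ptv", "qualifying_splice")
  one_strong <-
    (ptvish(class_m) || (class_m == "missense" && !is.na(mpc_m) && mpc_m > 2)) ||
    (ptvish(class_p) || (class_p == "missense" && !is.na(mpc_p) && mpc_p > 2))
  both_weak <-
    (ptvish(class_m) || (class_m == "missense" && !is.na(mpc_m) && mpc_m > 1)) &&
    (ptvish(class_p) || (class_p == "missense" && !is.na(mpc_p) && mpc_p > 1))
  one_strong || both_weak
}
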