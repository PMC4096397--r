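# Independent oracles used across test files.

# Two-sided Fisher p by direct hypergeometric enumeration over all tables
# with the observed margins (point-probability rule, the same floating-point
# tie tolerance as the tested route).
oracle_fisher <- function(a, b, c, d) {
  m <- a + b
  n2 <- c + d
  k <- a + c
  lo <- max(0, k - n2)
  hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n2, k)
  p_obs <- stats::dhyper(a, m, n2, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Exact HWE p via the recurrence relation on the heterozygote count
# (numerically independent of the closed-form log-gamma route in hwe_test).
oracle_hwe <- function(nAA, nAB, nBB) {
  nA <- 2 * nAA + nAB
  nB <- 2 * nBB + nAB
  if (nA == 0 || nB == 0) return(1)
  hets <- seq(nA %% 2, min(nA, nB), by = 2)
  u <- numeric(length(hets))
  u[1] <- 1
  if (length(hets) > 1) {
    for (i in 2:length(hets)) {
      h <- hets[i - 1]
      u[i] <- u[i - 1] * 4 * ((nA - h) / 2) * ((nB - h) / 2) /
        ((h + 2) * (h + 1))
    }
  }
  p <- u / sum(u)
  p_obs <- p[match(nAB, hets)]
  min(1, sum(p[p <= p_obs * (1 + 1e-9)]))
}

# Small methylation matrix straight from a beta matrix (depth constant).
make_meth <- function(beta, depth = 50, chrom = "chr1",
                      pos = NULL, samples = NULL) {
  beta <- as.matrix(beta)
  if (is.null(pos)) pos <- seq_len(nrow(beta)) * 1000 + 1
  if (is.null(samples)) samples <- sprintf("S%03d", seq_len(ncol(beta)))
  meth_matrix(data.frame(chrom = rep(chrom, nrow(beta)), pos = pos,
                         strand = rep("+", nrow(beta))),
              samples,
              beta,
              matrix(depth, nrow(beta), ncol(beta)))
}

# Genotype matrix from a dosage matrix.
make_geno <- function(dosage, pos = NULL, chrom = "chr1", samples = NULL) {
  dosage <- as.matrix(dosage)
  if (is.null(pos)) pos <- seq_len(nrow(dosage)) * 1000
  if (is.null(samples)) samples <- sprintf("S%03d", seq_len(ncol(dosage)))
  geno_matrix(data.frame(id = sprintf("snp%03d", seq_len(nrow(dosage))),
                         chrom = chrom, pos = pos, ref = "A", alt = "G"),
              samples, dosage)
}

# Fragment records for one (sample, snp, cpg) with the given counts.
make_frags <- function(ref_meth, ref_unmeth, alt_meth, alt_unmeth,
                       sample_id = "S1", snp_id = "snp001",
                       cpg_chrom = "chr1", cpg_pos = 101) {
  n <- c(ref_meth, ref_unmeth, alt_meth, alt_unmeth)
  data.frame(
    sample_id = rep(sample_id, sum(n)), snp_id = rep(snp_id, sum(n)),
    allele = rep(c("ref", "ref", "alt", "alt"), n),
    cpg_chrom = rep(cpg_chrom, sum(n)), cpg_pos = rep(cpg_pos, sum(n)),
    methylated = rep(c(TRUE, FALSE, TRUE, FALSE), n),
    stringsAsFactors = FALSE)
}
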