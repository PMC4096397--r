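#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test on the heterozygote count: given the observed
#' allele counts, the p-value is the sum of the probabilities of all
#' heterozygote counts whose conditional probability does not exceed that of
#' the observed configuration (evaluated with a 1e-9 relative tolerance so
#' exact ties are not split by floating-point rounding). A monomorphic SNP
#' has a single attainable configuration and p = 1.
#'
#' @param n_AA,n_AB,n_BB genotype counts (non-negative, total >= 1).
#' @return two-sided exact p-value.
#' @export
hwe_test <- function(n_AA, n_AB, n_BB) {
  stopifnot(n_AA >= 0, n_AB >= 0, n_BB >= 0)
  n <- n_AA + n_AB + n_BB
  if (n < 1) stop("at least one genotyped sample required")
  nA <- 2 * n_AA + n_AB
  nB <- 2 * n_BB + n_AB
  if (nA == 0 || nB == 0) return(1)
  hets <- seq(nA %% 2, min(nA, nB), by = 2)
  # log P(h | n, nA) = log [ n! 2^h / (nAA! h! nBB!) ] - log [ (2n)! / (nA! nB!) ]
  logp <- lgamma(n + 1) + hets * log(2) -
    lgamma((nA - hets) / 2 + 1) - lgamma(hets + 1) -
    lgamma((nB - hets) / 2 + 1) +
    lgamma(nA + 1) + lgamma(nB + 1) - lgamma(2 * n + 1)
  p <- exp(logp)
  p_obs <- p[match(n_AB, hets)]
  sum(p[p <= p_obs * (1 + 1e-9)])
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment; input order is preserved and
#' ties are handled stably.
#'
#' @param pvals numeric vector of p-values in [0, 1].
#' @return q-values in the input order.
#' @export
bh_fdr <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  if (any(!is.na(pvals) & (pvals < 0 | pvals > 1)))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Count Mendel errors in trios
#'
#' A Mendel error is a trio genotype combination impossible under biallelic
#' Mendelian transmission (the child's dosage cannot be written as one
#' allele from each parent). Trios with any missing member genotype at a
#' SNP are not tested there.
#'
#' @param genotypes a \code{\link{geno_matrix}}.
#' @param trios a \code{\link{trio_set}}.
#' @return list with \code{per_family} (family_id, n_tested, n_errors,
#'   error_rate), \code{n_errors}, \code{n_tested}.
#' @export
mendel_errors <- function(genotypes, trios) {
  d <- genotypes$dosage
  fi <- match(trios$father_id, genotypes$samples)
  mi <- match(trios$mother_id, genotypes$samples)
  ci <- match(trios$child_id, genotypes$samples)
  if (anyNA(c(fi, mi, ci)))
    stop("all trio members must be genotyped samples")
  # transmissible allele sets by parental dosage: 0 -> {0}, 1 -> {0,1}, 2 -> {1}
  lo <- function(x) ifelse(x == 2, 1, 0)
  hi <- function(x) ifelse(x == 0, 0, 1)
  fam <- unique(trios$family_id)
  n_tested <- n_err <- stats::setNames(rep(0L, length(fam)), fam)
  for (t in seq_len(nrow(trios))) {
    f <- d[, fi[t]]; m <- d[, mi[t]]; c <- d[, ci[t]]
    ok <- !is.na(f) & !is.na(m) & !is.na(c)
    err <- ok & (c < lo(f) + lo(m) | c > hi(f) + hi(m))
    fm <- trios$family_id[t]
    n_tested[fm] <- n_tested[fm] + sum(ok)
    n_err[fm] <- n_err[fm] + sum(err)
  }
  per <- data.frame(family_id = fam, n_tested = as.integer(n_tested),
                    n_errors = as.integer(n_err),
                    error_rate = ifelse(n_tested > 0, n_err / n_tested, NA),
                    stringsAsFactors = FALSE)
  rownames(per) <- NULL
  list(per_family = per, n_errors = sum(n_err), n_tested = sum(n_tested))
}

#' SNP quality control
#'
#' Keeps SNPs with minor allele frequency at least \code{maf_min}
#' (inclusive; allele counts pooled over all non-missing samples) and exact
#' HWE p-value strictly greater than \code{hwe_min_p} (HWE computed over
#' founders when a trio set is supplied, so transmitted copies do not
#' inflate the test). Also reports per-family Mendel error rates.
#'
#' @param genotypes a \code{\link{geno_matrix}}.
#' @param trios a \code{\link{trio_set}} or NULL.
#' @param maf_min MAF threshold (default 0.05).
#' @param hwe_min_p HWE threshold (default 0.001).
#' @return list with \code{genotypes} (filtered), \code{stats} (per-SNP id,
#'   maf, hwe_p, kept) and \code{mendel} (NULL without trios).
#' @export
snp_qc <- function(genotypes, trios = NULL, maf_min = 0.05,
                   hwe_min_p = 0.001) {
  d <- genotypes$dosage
  founder_cols <- seq_len(ncol(d))
  mend <- NULL
  if (!is.null(trios) && nrow(trios) > 0) {
    founder_cols <- which(!(genotypes$samples %in% trios$child_id))
    mend <- mendel_errors(genotypes, trios)
  }
  maf <- apply(d, 1, function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) return(NA_real_)
    f <- sum(x) / (2 * length(x))
    min(f, 1 - f)
  })
  hwe_p <- apply(d[, founder_cols, drop = FALSE], 1, function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) return(NA_real_)
    hwe_test(sum(x == 0), sum(x == 1), sum(x == 2))
  })
  kept <- !is.na(maf) & maf >= maf_min & !is.na(hwe_p) & hwe_p > hwe_min_p
  if (!any(kept)) warning("all SNPs removed by QC")
  g <- genotypes
  g$snps <- g$snps[kept, , drop = FALSE]
  rownames(g$snps) <- NULL
  g$dosage <- g$dosage[kept, , drop = FALSE]
  list(genotypes = g,
       stats = data.frame(id = genotypes$snps$id, maf = maf, hwe_p = hwe_p,
                          kept = kept, stringsAsFactors = FALSE),
       mendel = mend)
}

# One family-aware permutation of sample indices: whole-family phenotype
# blocks are swapped among families of identical size, then member labels
# are shuffled within each family. Samples outside the pedigree (or with
# no family) are permuted among themselves.
family_permutation <- function(samples, pedigree = NULL) {
  n <- length(samples)
  idx <- seq_len(n)
  if (is.null(pedigree)) return(sample(idx))
  fam <- pedigree$samples$family_id[match(samples, pedigree$samples$sample_id)]
  out <- idx
  loose <- which(is.na(fam))
  if (length(loose) > 1) out[loose] <- sample(idx[loose])
  fams <- split(which(!is.na(fam)), fam[!is.na(fam)])
  sizes <- lengths(fams)
  for (s in unique(sizes)) {
    grp <- fams[sizes == s]
    src <- grp[sample(length(grp))]
    for (k in seq_along(grp))
      out[grp[[k]]] <- sample(src[[k]])
  }
  out
}

# slope, t and asymptotic p of y ~ x over complete cases; NULL when the
# pair is untestable (< 3 complete cases or constant genotype).
ols_pair <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 3) return(NULL)
  x <- x[ok]; y <- y[ok]
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  if (sxx == 0) return(NULL)
  b <- sum(xc * y) / sxx
  syy <- sum((y - mean(y))^2)
  rss <- max(syy - b^2 * sxx, 0)
  se <- sqrt(rss / ((n - 2) * sxx))
  t <- if (se > 0) b / se else sign(b) * Inf
  list(n = n, beta = b, t = t, p = 2 * stats::pt(-abs(t), n - 2))
}

#' Cis methylation-QTL scan
#'
#' Tests every (CpG, SNP) pair on the same chromosome with |SNP pos - CpG
#' pos| <= \code{window} by least-squares regression of methylation on
#' additive allele dosage (0/1/2). Reports the slope (methylation units per
#' alternate allele), the t statistic, its asymptotic two-sided p-value and,
#' when \code{n_perm > 0}, an empirical p-value: the fraction of
#' family-aware permutations whose |t| exceeds the observed |t|. Whole
#' families are permuted among families of equal size, then members within
#' each family, so familial correlation is preserved under the null.
#' Benjamini-Hochberg q-values are computed over all tested pairs, from the
#' empirical p when available.
#'
#' @param m a \code{\link{meth_matrix}}.
#' @param genotypes a QC'd \code{\link{geno_matrix}}.
#' @param pedigree a \code{\link{pedigree_set}} or NULL (free permutation).
#' @param window cis window in bp (default 1 Mb).
#' @param n_perm number of permutations (default 10,000; 0 disables).
#' @param seed integer seed for the permutation stream.
#' @param smooth_p use (k+1)/(n+1) instead of the plain fraction k/n for the
#'   empirical p (default FALSE).
#' @return data.frame: \code{cpg_chrom}, \code{cpg_pos}, \code{snp_id},
#'   \code{snp_pos}, \code{distance} (SNP pos - CpG pos), \code{n},
#'   \code{beta}, \code{t}, \code{p_asym}, \code{p_emp}, \code{q}.
#' @export
mqtl_scan <- function(m, genotypes, pedigree = NULL, window = 1e6,
                      n_perm = 10000, seed = 1L, smooth_p = FALSE) {
  stopifnot(inherits(m, "meth_matrix"), inherits(genotypes, "geno_matrix"))
  common <- intersect(m$samples, genotypes$samples)
  if (length(common) == 0) stop("no shared samples")
  B <- m$beta[, match(common, m$samples), drop = FALSE]
  D <- genotypes$dosage[, match(common, genotypes$samples), drop = FALSE]
  pairs <- list()
  for (j in seq_len(nrow(m$sites))) {
    hit <- which(genotypes$snps$chrom == m$sites$chrom[j] &
                   abs(genotypes$snps$pos - m$sites$pos[j]) <= window)
    if (length(hit))
      pairs[[length(pairs) + 1L]] <- data.frame(cpg = j, snp = hit)
  }
  empty <- data.frame(cpg_chrom = character(0), cpg_pos = numeric(0),
                      snp_id = character(0), snp_pos = numeric(0),
                      distance = numeric(0), n = integer(0),
                      beta = numeric(0), t = numeric(0),
                      p_asym = numeric(0), p_emp = numeric(0),
                      q = numeric(0), stringsAsFactors = FALSE)
  if (length(pairs) == 0) return(empty)
  pairs <- do.call(rbind, pairs)
  fits <- vector("list", nrow(pairs))
  for (r in seq_len(nrow(pairs)))
    fits[r] <- list(ols_pair(D[pairs$snp[r], ], B[pairs$cpg[r], ]))
  testable <- !vapply(fits, is.null, logical(1))
  pairs <- pairs[testable, , drop = FALSE]
  fits <- fits[testable]
  if (nrow(pairs) == 0) return(empty)
  t_obs <- vapply(fits, `[[`, numeric(1), "t")
  p_emp <- rep(NA_real_, nrow(pairs))
  if (n_perm > 0) {
    set.seed(stage_seed(seed, "mqtl_perm"))
    exceed <- numeric(nrow(pairs))
    for (it in seq_len(n_perm)) {
      px <- family_permutation(common, pedigree)
      Bp <- B[, px, drop = FALSE]
      for (r in seq_len(nrow(pairs))) {
        f <- ols_pair(D[pairs$snp[r], ], Bp[pairs$cpg[r], ])
        if (!is.null(f) && abs(f$t) > abs(t_obs[r]))
          exceed[r] <- exceed[r] + 1
      }
    }
    p_emp <- if (smooth_p) (exceed + 1) / (n_perm + 1) else exceed / n_perm
  }
  out <- data.frame(
    cpg_chrom = m$sites$chrom[pairs$cpg],
    cpg_pos = m$sites$pos[pairs$cpg],
    snp_id = genotypes$snps$id[pairs$snp],
    snp_pos = genotypes$snps$pos[pairs$snp],
    distance = genotypes$snps$pos[pairs$snp] - m$sites$pos[pairs$cpg],
    n = vapply(fits, `[[`, numeric(1), "n"),
    beta = vapply(fits, `[[`, numeric(1), "beta"),
    t = t_obs,
    p_asym = vapply(fits, `[[`, numeric(1), "p"),
    p_emp = p_emp,
    stringsAsFactors = FALSE)
  out$q <- bh_fdr(if (n_perm > 0) out$p_emp else out$p_asym)
  out
}
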