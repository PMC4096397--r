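#' Mid-parent-offspring regression per CpG
#'
#' For each CpG, regresses the child's methylation level on the mean of the
#' two parents' levels across all trios in which father, mother and child
#' all have non-missing values. The slope of the fitted line estimates the
#' narrow-sense heritability h2 of methylation at that site; the p-value is
#' the two-sided t-test on the slope. Trios sharing parents contribute
#' independent points. CpGs with fewer than 3 informative trios, or with no
#' variance in the mid-parent values, are reported with undefined slope/p.
#'
#' @param m a \code{\link{meth_matrix}}.
#' @param trios a \code{\link{trio_set}}.
#' @return data.frame with one row per CpG: \code{chrom}, \code{pos},
#'   \code{h2}, \code{se}, \code{p}, \code{n_trios}.
#' @export
midparent_regression <- function(m, trios) {
  stopifnot(inherits(m, "meth_matrix"), inherits(trios, "trio_set"))
  fi <- match(trios$father_id, m$samples)
  mi <- match(trios$mother_id, m$samples)
  ci <- match(trios$child_id, m$samples)
  if (anyNA(c(fi, mi, ci)))
    stop("all trio members must be samples of the methylation matrix")
  B <- m$beta
  n_cpg <- nrow(B)
  out <- data.frame(chrom = m$sites$chrom, pos = m$sites$pos,
                    h2 = NA_real_, se = NA_real_, p = NA_real_,
                    n_trios = 0L, stringsAsFactors = FALSE)
  if (n_cpg == 0 || nrow(trios) == 0) return(out)
  FA <- B[, fi, drop = FALSE]
  MO <- B[, mi, drop = FALSE]
  CH <- B[, ci, drop = FALSE]
  MP <- (FA + MO) / 2
  ok <- !is.na(MP) & !is.na(CH)
  for (j in seq_len(n_cpg)) {
    use <- ok[j, ]
    n <- sum(use)
    out$n_trios[j] <- n
    if (n < 3) next
    x <- MP[j, use]; y <- CH[j, use]
    sxx <- sum((x - mean(x))^2)
    if (sxx == 0) next  # untestable: no mid-parent variance
    b <- sum((x - mean(x)) * (y - mean(y))) / sxx
    res <- y - mean(y) - b * (x - mean(x))
    s2 <- sum(res^2) / (n - 2)
    se <- sqrt(s2 / sxx)
    out$h2[j] <- b
    out$se[j] <- se
    out$p[j] <- if (se > 0) 2 * stats::pt(-abs(b / se), n - 2) else 0
  }
  out
}

#' Call heritable CpGs
#'
#' Applies the heritability thresholds to mid-parent-offspring results: a
#' CpG is heritable when h2 strictly exceeds \code{h2_min}, at least
#' \code{min_trios} informative trios were available, and the
#' Benjamini-Hochberg q-value of the slope test is strictly below
#' \code{fdr}. BH is computed over all CpGs with a defined p-value.
#'
#' @param results output of \code{\link{midparent_regression}}.
#' @param h2_min heritability threshold (strict; default 0.2).
#' @param min_trios minimum informative trios (default 10).
#' @param fdr BH q-value cutoff (strict; default 0.05).
#' @return The input with added \code{q} and logical \code{heritable}.
#' @export
call_heritable_cpgs <- function(results, h2_min = 0.2, min_trios = 10,
                                fdr = 0.05) {
  results$q <- rep(NA_real_, nrow(results))
  tested <- !is.na(results$p)
  results$q[tested] <- bh_fdr(results$p[tested])
  results$heritable <- !is.na(results$h2) & results$h2 > h2_min &
    results$n_trios >= min_trios & !is.na(results$q) & results$q < fdr
  results
}

#' Flag CpGs whose dinucleotide carries a SNP
#'
#' A CpG is a "SNP-CpG" when a polymorphic SNP sits at the C position or at
#' the following base (the G of the CG dinucleotide): the polymorphism
#' directly removes the methyltransferase substrate on one allele.
#' Monomorphic SNP records do not trigger the flag.
#'
#' @param sites data.frame with \code{chrom}, \code{pos} (1-based C).
#' @param genotypes a \code{\link{geno_matrix}}.
#' @return logical vector, one per site.
#' @export
classify_snp_cpg <- function(sites, genotypes) {
  d <- genotypes$dosage
  poly <- apply(d, 1, function(x) {
    x <- x[!is.na(x)]
    length(x) > 0 && length(unique(x)) > 1
  })
  key <- paste(genotypes$snps$chrom[poly], genotypes$snps$pos[poly])
  paste(sites$chrom, sites$pos) %in% key |
    paste(sites$chrom, sites$pos + 1) %in% key
}

#' Cluster adjacent heritable CpGs
#'
#' Single-linkage grouping of (heritable, non-SNP) CpGs: consecutive sites
#' on the same chromosome at most \code{max_gap} bp apart join one cluster;
#' singletons are allowed.
#'
#' @param sites data.frame with \code{chrom}, \code{pos}, sorted within
#'   chromosome.
#' @param max_gap maximum distance between consecutive member CpGs (bp).
#' @return data.frame: \code{cluster}, \code{chrom}, \code{start},
#'   \code{end}, \code{n_cpgs}.
#' @export
cluster_heritable_cpgs <- function(sites, max_gap = 1000) {
  if (nrow(sites) == 0)
    return(data.frame(cluster = integer(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      n_cpgs = integer(0)))
  ord <- order(sites$chrom, sites$pos)
  s <- sites[ord, , drop = FALSE]
  new_cl <- c(TRUE, s$chrom[-1] != s$chrom[-nrow(s)] |
                diff(s$pos) > max_gap)
  cl <- cumsum(new_cl)
  agg <- lapply(split(seq_len(nrow(s)), cl), function(ix) {
    data.frame(chrom = s$chrom[ix[1]], start = min(s$pos[ix]),
               end = max(s$pos[ix]), n_cpgs = length(ix),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out <- cbind(cluster = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Full mid-parent-offspring analysis
#'
#' Regression, heritable-CpG calling, SNP-CpG classification and clustering
#' of heritable non-SNP CpGs in one call.
#'
#' @param m a filtered \code{\link{meth_matrix}}.
#' @param trios a \code{\link{trio_set}}.
#' @param genotypes a \code{\link{geno_matrix}} for SNP-CpG flagging.
#' @param config an \code{\link{analysis_config}}.
#' @param cluster_max_gap gap for heritable-CpG clustering (bp).
#' @return list with \code{results} (per-CpG table incl. \code{snp_cpg}) and
#'   \code{clusters}.
#' @export
run_mpo <- function(m, trios, genotypes, config = analysis_config(),
                    cluster_max_gap = 1000) {
  res <- midparent_regression(m, trios)
  res <- call_heritable_cpgs(res, config$h2_min, config$min_trios,
                             config$fdr)
  res$snp_cpg <- classify_snp_cpg(m$sites, genotypes)
  her <- res[res$heritable & !res$snp_cpg, c("chrom", "pos")]
  list(results = res,
       clusters = cluster_heritable_cpgs(her, cluster_max_gap))
}
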