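#' Regress per-genotype methylation variance on genotype
#'
#' For one (CpG, SNP) pair, computes the sample variance of methylation
#' within each genotype class (0/1/2 alternate alleles) and fits a least
#' squares line of the three variances on the genotype codes. With three
#' points and two coefficients the fit has a single residual degree of
#' freedom; the slope's t-score is reported on that df. The pair is
#' untestable when fewer than three genotype classes are present or any
#' class has fewer than \code{min_group_n} non-missing samples.
#'
#' @param meth_values numeric vector of methylation fractions per sample.
#' @param dosages matching dosage vector (0/1/2/NA).
#' @param min_group_n minimum samples per genotype class (default 3).
#' @return list(slope, t, group_var, group_n) or NULL when untestable.
#' @export
variance_regression <- function(meth_values, dosages, min_group_n = 3) {
  ok <- !is.na(meth_values) & !is.na(dosages)
  x <- dosages[ok]; y <- meth_values[ok]
  gn <- vapply(0:2, function(g) sum(x == g), integer(1))
  if (any(gn < max(min_group_n, 2))) return(NULL)
  v <- vapply(0:2, function(g) stats::var(y[x == g]), numeric(1))
  b <- (v[3] - v[1]) / 2          # slope on codes 0,1,2
  fit <- mean(v) + b * (0:2 - 1)
  rss <- sum((v - fit)^2)
  se <- sqrt(rss / 2)             # 1 residual df; sum((x - xbar)^2) = 2
  t <- if (se > 0) b / se else if (b == 0) 0 else sign(b) * Inf
  list(slope = b, t = t, group_var = v, group_n = gn)
}

#' Variance-QTL scan over cis pairs
#'
#' Applies \code{\link{variance_regression}} to every (CpG, SNP) pair on
#' the same chromosome within \code{window} bp.
#'
#' @param m a \code{\link{meth_matrix}}.
#' @param genotypes a \code{\link{geno_matrix}}.
#' @param window cis window in bp (default 1 Mb).
#' @param min_group_n minimum samples per genotype class.
#' @return data.frame: \code{cpg_chrom}, \code{cpg_pos}, \code{snp_id},
#'   \code{snp_pos}, \code{slope}, \code{t}; untestable pairs are omitted.
#' @export
vmr_scan <- function(m, genotypes, window = 1e6, min_group_n = 3) {
  common <- intersect(m$samples, genotypes$samples)
  if (length(common) == 0) stop("no shared samples")
  B <- m$beta[, match(common, m$samples), drop = FALSE]
  D <- genotypes$dosage[, match(common, genotypes$samples), drop = FALSE]
  rows <- list()
  for (j in seq_len(nrow(m$sites))) {
    hit <- which(genotypes$snps$chrom == m$sites$chrom[j] &
                   abs(genotypes$snps$pos - m$sites$pos[j]) <= window)
    for (s in hit) {
      f <- variance_regression(B[j, ], D[s, ], min_group_n)
      if (is.null(f)) next
      rows[[length(rows) + 1L]] <- data.frame(
        cpg_chrom = m$sites$chrom[j], cpg_pos = m$sites$pos[j],
        snp_id = genotypes$snps$id[s], snp_pos = genotypes$snps$pos[s],
        slope = f$slope, t = f$t, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(cpg_chrom = character(0), cpg_pos = numeric(0),
                      snp_id = character(0), snp_pos = numeric(0),
                      slope = numeric(0), t = numeric(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assemble variably methylated regions from variance scores
#'
#' For each SNP, scans its tested CpGs in genomic order and emits a VMR for
#' every maximal run of at least \code{min_cpgs} consecutive CpGs that all
#' reach |t| >= \code{t_min}, share the slope sign, and are spaced at most
#' \code{max_spacing} bp apart. A CpG failing any condition breaks the run.
#'
#' @param scores output of \code{\link{vmr_scan}}.
#' @param t_min per-CpG |t| threshold (default 2).
#' @param min_cpgs minimum run length (default 5).
#' @param max_spacing maximum distance between consecutive member CpGs
#'   (default 200 bp).
#' @return data.frame: \code{snp_id}, \code{chrom}, \code{start},
#'   \code{end}, \code{n_cpgs}, \code{direction} (+1/-1),
#'   \code{mean_abs_t}.
#' @export
call_vmrs <- function(scores, t_min = 2, min_cpgs = 5, max_spacing = 200) {
  empty <- data.frame(snp_id = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      n_cpgs = integer(0), direction = numeric(0),
                      mean_abs_t = numeric(0), stringsAsFactors = FALSE)
  if (nrow(scores) == 0) return(empty)
  out <- list()
  for (grp in split(scores, paste(scores$snp_id, scores$cpg_chrom))) {
    g <- grp[order(grp$cpg_pos), , drop = FALSE]
    run <- integer(0)
    flush <- function(run) {
      if (length(run) >= min_cpgs)
        out[[length(out) + 1L]] <<- data.frame(
          snp_id = g$snp_id[1], chrom = g$cpg_chrom[1],
          start = g$cpg_pos[run[1]], end = g$cpg_pos[run[length(run)]],
          n_cpgs = length(run), direction = sign(g$slope[run[1]]),
          mean_abs_t = mean(abs(g$t[run])), stringsAsFactors = FALSE)
    }
    for (i in seq_len(nrow(g))) {
      qual <- !is.na(g$t[i]) && abs(g$t[i]) >= t_min && g$slope[i] != 0
      joins <- length(run) > 0 && qual &&
        sign(g$slope[i]) == sign(g$slope[run[1]]) &&
        g$cpg_pos[i] - g$cpg_pos[run[length(run)]] <= max_spacing
      if (joins) {
        run <- c(run, i)
      } else {
        flush(run)
        run <- if (qual) i else integer(0)
      }
    }
    flush(run)
  }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start, res$snp_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Estimate the VMR false-positive rate by permutation
#'
#' Permutes the sample columns of the methylation matrix (breaking the
#' genotype-methylation linkage while preserving each CpG's marginal
#' distribution), re-runs the full variance scan and VMR assembly, and
#' reports the mean permuted VMR count relative to the observed count.
#'
#' @param m,genotypes inputs as for \code{\link{vmr_scan}}.
#' @param n_perm number of permutations (>= 1).
#' @param t_min,min_cpgs,max_spacing,window,min_group_n VMR parameters.
#' @param seed integer seed.
#' @return list: \code{observed} (VMR count), \code{perm_counts},
#'   \code{fpr} (mean permuted / observed; NA when observed is 0).
#' @export
estimate_fpr_by_permutation <- function(m, genotypes, n_perm = 10,
                                        t_min = 2, min_cpgs = 5,
                                        max_spacing = 200, window = 1e6,
                                        min_group_n = 3, seed = 1L) {
  stopifnot(n_perm >= 1)
  obs <- nrow(call_vmrs(vmr_scan(m, genotypes, window, min_group_n),
                        t_min, min_cpgs, max_spacing))
  set.seed(stage_seed(seed, "vmr_perm"))
  perm_counts <- integer(n_perm)
  for (it in seq_len(n_perm)) {
    mp <- m
    mp$beta <- m$beta[, sample(ncol(m$beta)), drop = FALSE]
    colnames(mp$beta) <- m$samples
    perm_counts[it] <- nrow(call_vmrs(
      vmr_scan(mp, genotypes, window, min_group_n),
      t_min, min_cpgs, max_spacing))
  }
  list(observed = obs, perm_counts = perm_counts,
       fpr = if (obs > 0) mean(perm_counts) / obs else NA_real_)
}

#' Calibrate the variance-score threshold to a target false-positive rate
#'
#' Walks a grid of |t| cutoffs from liberal to strict and returns the first
#' whose permutation-estimated false-positive rate is at or below the
#' target.
#'
#' @param m,genotypes inputs as for \code{\link{vmr_scan}}.
#' @param grid increasing candidate t cutoffs.
#' @param target_fpr target false-positive rate (default 0.10).
#' @param n_perm permutations per grid point.
#' @param ... passed to \code{\link{estimate_fpr_by_permutation}}.
#' @return chosen t cutoff (the strictest grid value if none qualifies).
#' @export
calibrate_t_min <- function(m, genotypes, grid = c(1.5, 2, 3, 5, 10),
                            target_fpr = 0.10, n_perm = 5, ...) {
  for (t in grid) {
    est <- estimate_fpr_by_permutation(m, genotypes, n_perm = n_perm,
                                       t_min = t, ...)
    if (is.na(est$fpr) || est$fpr <= target_fpr) return(t)
  }
  grid[length(grid)]
}

#' Group VMRs into clusters
#'
#' Single-linkage merge of VMR spans that lie within \code{max_distance} bp
#' of each other (edge to edge, inclusive; overlap counts). VMRs driven by
#' different vSNPs merge into the same cluster when their spans are close.
#'
#' @param vmrs output of \code{\link{call_vmrs}}.
#' @param max_distance linkage distance in bp (default 100 kb).
#' @return data.frame: \code{cluster}, \code{chrom}, \code{start},
#'   \code{end}, \code{n_vmrs}, \code{n_snps}.
#' @export
cluster_vmrs <- function(vmrs, max_distance = 1e5) {
  if (nrow(vmrs) == 0)
    return(data.frame(cluster = integer(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      n_vmrs = integer(0), n_snps = integer(0),
                      stringsAsFactors = FALSE))
  v <- vmrs[order(vmrs$chrom, vmrs$start, vmrs$end, vmrs$snp_id), ,
            drop = FALSE]
  cl <- integer(nrow(v))
  cl[1] <- 1L
  run_end <- v$end[1]
  if (nrow(v) > 1) {
    for (i in 2:nrow(v)) {
      same <- v$chrom[i] == v$chrom[i - 1] &&
        v$start[i] - run_end <= max_distance
      cl[i] <- if (same) cl[i - 1] else cl[i - 1] + 1L
      run_end <- if (same) max(run_end, v$end[i]) else v$end[i]
    }
  }
  agg <- lapply(split(seq_len(nrow(v)), cl), function(ix) {
    data.frame(chrom = v$chrom[ix[1]], start = min(v$start[ix]),
               end = max(v$end[ix]), n_vmrs = length(ix),
               n_snps = length(unique(v$snp_id[ix])),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out <- cbind(cluster = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Full variance-QTL analysis
#'
#' Scan, VMR assembly, permutation FPR estimate and clustering with the
#' thresholds of an \code{\link{analysis_config}}.
#'
#' @param m a filtered \code{\link{meth_matrix}}.
#' @param genotypes a QC'd \code{\link{geno_matrix}}.
#' @param config an \code{\link{analysis_config}}.
#' @param n_perm_fpr permutations for the FPR estimate (0 skips it).
#' @param seed integer seed.
#' @return list: \code{scores}, \code{vmrs}, \code{clusters}, \code{fpr}.
#' @export
run_vmr <- function(m, genotypes, config = analysis_config(),
                    n_perm_fpr = 10, seed = 1L) {
  scores <- vmr_scan(m, genotypes, config$window, config$vmr_min_group_n)
  vmrs <- call_vmrs(scores, config$vmr_t_min, config$vmr_min_cpgs,
                    config$vmr_max_spacing)
  fpr <- if (n_perm_fpr > 0)
    estimate_fpr_by_permutation(m, genotypes, n_perm = n_perm_fpr,
                                t_min = config$vmr_t_min,
                                min_cpgs = config$vmr_min_cpgs,
                                max_spacing = config$vmr_max_spacing,
                                window = config$window,
                                min_group_n = config$vmr_min_group_n,
                                seed = seed)
  else NULL
  list(scores = scores, vmrs = vmrs,
       clusters = cluster_vmrs(vmrs, config$vmr_cluster_distance),
       fpr = fpr)
}
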