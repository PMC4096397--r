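#' Mask methylation calls below a minimum read depth
#'
#' Cells supported by fewer than \code{min_depth} reads are set to missing;
#' matrix dimensions are unchanged.
#'
#' @param m a \code{\link{meth_matrix}}.
#' @param min_depth minimum depth (default 10x).
#' @return The masked \code{meth_matrix}.
#' @export
apply_depth_filter <- function(m, min_depth = 10) {
  stopifnot(inherits(m, "meth_matrix"), min_depth >= 0)
  low <- !is.na(m$depth) & m$depth < min_depth
  m$beta[low] <- NA_real_
  m
}

#' Drop CpG sites with too many missing calls
#'
#' A site is kept when the fraction of samples with a non-missing call is at
#' least \code{min_present_fraction} (inclusive comparison).
#'
#' @param m a \code{\link{meth_matrix}}.
#' @param min_present_fraction fraction in [0, 1] (default 0.8).
#' @return The filtered \code{meth_matrix}.
#' @export
filter_missingness <- function(m, min_present_fraction = 0.8) {
  stopifnot(inherits(m, "meth_matrix"),
            min_present_fraction >= 0, min_present_fraction <= 1)
  if (nrow(m$beta) == 0) return(m)
  present <- rowMeans(!is.na(m$beta))
  subset_sites(m, present >= min_present_fraction)
}

#' Keep variable CpG sites
#'
#' Retains sites whose sample standard deviation (n-1 denominator, computed
#' over non-missing values) is at least \code{sd_min}. Sites with fewer than
#' two non-missing values have no defined SD and are removed.
#'
#' @param m a \code{\link{meth_matrix}}.
#' @param sd_min SD floor (default 0.1; use 0.3 for highly variable sites).
#' @return The filtered \code{meth_matrix}.
#' @export
select_variable_cpgs <- function(m, sd_min = 0.1) {
  stopifnot(inherits(m, "meth_matrix"), sd_min >= 0)
  if (nrow(m$beta) == 0) return(m)
  sds <- apply(m$beta, 1, stats::sd, na.rm = TRUE)
  keep <- !is.na(sds) & sds >= sd_min
  subset_sites(m, keep)
}

#' Drop sex-chromosome sites
#'
#' The analyses operate on autosomal CpGs by default.
#'
#' @param m a \code{\link{meth_matrix}}.
#' @param sex_chroms chromosome names treated as sex chromosomes.
#' @return The filtered \code{meth_matrix}.
#' @export
drop_sex_chromosomes <- function(m, sex_chroms = c("chrX", "chrY", "X", "Y")) {
  subset_sites(m, !(m$sites$chrom %in% sex_chroms))
}

subset_sites <- function(m, keep) {
  m$sites <- m$sites[keep, , drop = FALSE]
  rownames(m$sites) <- NULL
  m$beta <- m$beta[keep, , drop = FALSE]
  m$depth <- m$depth[keep, , drop = FALSE]
  m
}

#' Strand concordance of duplicate CpG measurements
#'
#' Compares methylation measured independently on the two strands of the
#' same CG dinucleotides: per-sample Pearson correlation and mean absolute
#' difference, plus the pooled (global) versions. Applies no filtering.
#'
#' @param m_fwd,m_rev \code{meth_matrix} objects indexed to the same CG
#'   dinucleotides (matched on chrom and position) with identical samples.
#' @return list with \code{per_sample} (data.frame: sample, r, mean_abs_diff,
#'   n), \code{global_r}, \code{global_mean_abs_diff}, \code{n_shared_sites}.
#' @export
strand_concordance <- function(m_fwd, m_rev) {
  stopifnot(inherits(m_fwd, "meth_matrix"), inherits(m_rev, "meth_matrix"))
  if (!identical(m_fwd$samples, m_rev$samples))
    stop("the two matrices must cover the same samples in order")
  kf <- cpg_key(m_fwd$sites$chrom, m_fwd$sites$pos)
  kr <- cpg_key(m_rev$sites$chrom, m_rev$sites$pos)
  shared <- intersect(kf, kr)
  if (length(shared) == 0) {
    warning("no shared CG dinucleotides between strands")
    return(list(per_sample = data.frame(sample = character(0), r = numeric(0),
                                        mean_abs_diff = numeric(0),
                                        n = integer(0)),
                global_r = NA_real_, global_mean_abs_diff = NA_real_,
                n_shared_sites = 0L))
  }
  a <- m_fwd$beta[match(shared, kf), , drop = FALSE]
  b <- m_rev$beta[match(shared, kr), , drop = FALSE]
  per <- lapply(seq_along(m_fwd$samples), function(j) {
    ok <- !is.na(a[, j]) & !is.na(b[, j])
    r <- if (sum(ok) >= 2 && stats::sd(a[ok, j]) > 0 && stats::sd(b[ok, j]) > 0)
      stats::cor(a[ok, j], b[ok, j]) else NA_real_
    data.frame(sample = m_fwd$samples[j], r = r,
               mean_abs_diff = mean(abs(a[ok, j] - b[ok, j])),
               n = sum(ok), stringsAsFactors = FALSE)
  })
  ok <- !is.na(a) & !is.na(b)
  av <- a[ok]; bv <- b[ok]
  gr <- if (length(av) >= 2 && stats::sd(av) > 0 && stats::sd(bv) > 0)
    stats::cor(av, bv) else NA_real_
  list(per_sample = do.call(rbind, per),
       global_r = gr,
       global_mean_abs_diff = mean(abs(av - bv)),
       n_shared_sites = length(shared))
}

#' Site-level QC in one pass
#'
#' Depth masking, missingness filtering and variable-site selection with the
#' thresholds of an \code{\link{analysis_config}}, returning the filtered
#' matrix and a per-step site-count report.
#'
#' @param m a \code{\link{meth_matrix}}.
#' @param config an \code{\link{analysis_config}}.
#' @param autosomes_only drop sex-chromosome sites first (default TRUE).
#' @return list with \code{meth} (filtered matrix) and \code{report}
#'   (data.frame: step, sites_kept).
#' @export
preprocess_meth <- function(m, config = analysis_config(),
                            autosomes_only = TRUE) {
  steps <- character(0); kept <- integer(0)
  note <- function(step, mm) {
    steps <<- c(steps, step); kept <<- c(kept, nrow(mm$beta)); mm
  }
  m <- note("input", m)
  if (autosomes_only) m <- note("autosomes", drop_sex_chromosomes(m))
  m <- note("depth_mask", apply_depth_filter(m, config$min_depth))
  m <- note("missingness", filter_missingness(m, config$min_present_fraction))
  m <- note("variable", select_variable_cpgs(m, config$sd_variable))
  list(meth = m,
       report = data.frame(step = steps, sites_kept = kept,
                           stringsAsFactors = FALSE))
}
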