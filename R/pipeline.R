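#' Run the full genome-methylome analysis pipeline
#'
#' Orchestrates the stages in dependency order on a loaded (or simulated)
#' study: site-level QC of the methylation matrix, SNP QC with Mendel-error
#' reporting, mid-parent-offspring heritability analysis, cis-mQTL scanning
#' with family-aware permutation, allele-specific methylation calling (when
#' fragments are present), variance-QTL / VMR detection, and the
#' cross-method comparison. All randomness derives from \code{config$seed},
#' so identical inputs and configuration give identical results.
#'
#' @param study list with \code{pedigree}, \code{genotypes}, \code{meth}
#'   and optional \code{fragments} / \code{annotation} (see
#'   \code{\link{load_study}} and \code{\link{simulate_study_cohort}}).
#' @param config an \code{\link{analysis_config}}.
#' @param n_perm_fpr permutations for the VMR false-positive-rate estimate.
#' @return list of class \code{pedmeth_results}: \code{qc_report},
#'   \code{meth} (filtered), \code{snp_qc}, \code{mendel}, \code{mpo},
#'   \code{mqtl}, \code{asm}, \code{asm_merged}, \code{vmr},
#'   \code{comparison}, \code{config}.
#' @export
run_pipeline <- function(study, config = analysis_config(),
                         n_perm_fpr = 5) {
  stopifnot(inherits(config, "pedmeth_config"))
  trios <- trio_set(study$pedigree)
  message("stage qc: ", nrow(study$meth$beta), " CpG sites in")
  prep <- preprocess_meth(study$meth, config)
  m <- prep$meth
  message("stage qc: ", nrow(m$beta), " variable CpG sites kept")

  qc <- snp_qc(study$genotypes, trios, config$maf_min, config$hwe_min_p)
  g <- qc$genotypes
  message("stage snp_qc: ", nrow(g$snps), "/", nrow(study$genotypes$snps),
          " SNPs kept; ", if (is.null(qc$mendel)) 0 else qc$mendel$n_errors,
          " Mendel errors")

  mpo <- run_mpo(m, trios, g, config)
  message("stage mpo: ", sum(mpo$results$heritable), " heritable CpGs (",
          sum(mpo$results$heritable & mpo$results$snp_cpg), " SNP-CpGs)")

  mqtl <- mqtl_scan(m, g, study$pedigree, config$window, config$n_perm,
                    seed = stage_seed(config$seed, "mqtl"))
  message("stage mqtl: ", nrow(mqtl), " cis pairs tested, ",
          sum(!is.na(mqtl$q) & mqtl$q < config$fdr), " significant")

  asm <- NULL; asm_merged <- NULL
  if (!is.null(study$fragments)) {
    asm <- call_asm(study$fragments, config$asm_p_max, config$asm_delta_min,
                    config$asm_min_frags, genotypes = g)
    asm_merged <- merge_asm_events(asm)
    message("stage asm: ", nrow(asm), " testable tables, ",
            sum(asm$asm), " events, ", nrow(asm_merged), " merged")
  }

  vmr <- run_vmr(m, g, config, n_perm_fpr = n_perm_fpr,
                 seed = stage_seed(config$seed, "vmr"))
  message("stage vmr: ", nrow(vmr$vmrs), " VMRs in ",
          nrow(vmr$clusters), " clusters")

  comparison <- compare_methods(
    mpo$results, mqtl,
    if (is.null(asm_merged))
      data.frame(cpg_chrom = character(0), cpg_pos = numeric(0))
    else asm_merged,
    fdr = config$fdr)

  structure(list(qc_report = prep$report, meth = m, snp_qc = qc$stats,
                 mendel = qc$mendel, mpo = mpo, mqtl = mqtl, asm = asm,
                 asm_merged = asm_merged, vmr = vmr,
                 comparison = comparison, config = config),
            class = "pedmeth_results")
}

#' Write a result bundle to disk
#'
#' Emits the per-stage tables as TSV (plus a BED of heritable-CpG cluster
#' spans and VMR cluster spans) into \code{dir}.
#'
#' @param results a \code{pedmeth_results} from \code{\link{run_pipeline}}.
#' @param dir output directory (created if needed).
#' @return invisible character vector of written paths.
#' @export
write_results <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "NA")
    p
  }
  paths <- c(
    wr(results$qc_report, "qc_report.tsv"),
    wr(results$snp_qc, "snp_qc.tsv"),
    wr(results$mpo$results, "mpo_results.tsv"),
    wr(results$mpo$clusters, "mpo_clusters.tsv"),
    wr(results$mqtl, "mqtl_associations.tsv"),
    wr(results$vmr$vmrs, "vmrs.tsv"),
    wr(results$vmr$clusters, "vmr_clusters.tsv"))
  if (!is.null(results$mendel))
    paths <- c(paths, wr(results$mendel$per_family, "mendel_errors.tsv"))
  if (!is.null(results$asm)) {
    paths <- c(paths, wr(results$asm, "asm_events.tsv"),
               wr(results$asm_merged, "asm_merged.tsv"))
  }
  if (nrow(results$vmr$clusters)) {
    bed <- with(results$vmr$clusters,
                data.frame(chrom, start - 1, end,
                           paste0("vmr_cluster_", cluster)))
    p <- file.path(dir, "vmr_clusters.bed")
    utils::write.table(bed, p, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    paths <- c(paths, p)
  }
  ov <- results$comparison$mqtl_vs_mpo
  comp <- data.frame(
    comparison = c("mqtl_vs_mpo", "asm_vs_mpo"),
    n_intersect = c(ov$n_intersect, results$comparison$asm_vs_mpo$n_intersect),
    frac_a_in_b = c(ov$frac_a_in_b, results$comparison$asm_vs_mpo$frac_a_in_b),
    frac_b_in_a = c(ov$frac_b_in_a, results$comparison$asm_vs_mpo$frac_b_in_a))
  paths <- c(paths, wr(comp, "comparison.tsv"))
  invisible(paths)
}

#' @export
print.pedmeth_results <- function(x, ...) {
  cat("pedmeth result bundle\n")
  cat(sprintf("  variable CpGs: %d   heritable: %d (SNP-CpGs: %d)\n",
              nrow(x$meth$beta), sum(x$mpo$results$heritable),
              sum(x$mpo$results$heritable & x$mpo$results$snp_cpg)))
  cat(sprintf("  mQTL pairs tested: %d   significant (q < %.2g): %d\n",
              nrow(x$mqtl), x$config$fdr,
              sum(!is.na(x$mqtl$q) & x$mqtl$q < x$config$fdr)))
  if (!is.null(x$asm))
    cat(sprintf("  ASM events: %d (merged: %d)\n", sum(x$asm$asm),
                nrow(x$asm_merged)))
  cat(sprintf("  VMRs: %d in %d clusters\n", nrow(x$vmr$vmrs),
              nrow(x$vmr$clusters)))
  invisible(x)
}
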