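#' Analysis configuration
#'
#' Collects every numeric threshold used by the pipeline in one auditable
#' object. The defaults are the study's operating point: 10x minimum read
#' depth, valid calls in at least 80% of samples, a standard-deviation floor
#' of 0.1 for "variable" CpGs (0.3 for "highly variable"), heritability
#' called at h2 > 0.2 over at least 10 informative trios at 5% FDR, a 1 Mb
#' cis window, MAF >= 0.05 and exact HWE p > 0.001 for SNP QC, 10,000
#' permutations for empirical mQTL p-values, ASM called at Fisher p < 0.001
#' with an allelic methylation difference > 0.2, and VMRs requiring at least
#' 5 adjacent CpGs spaced <= 200 bp, grouped into clusters within 100 kb.
#'
#' @param min_depth minimum read depth for a methylation call to be valid.
#' @param min_present_fraction minimum fraction of samples with a valid call
#'   for a CpG to be analyzed (inclusive).
#' @param sd_variable standard-deviation floor defining variable CpGs
#'   (inclusive).
#' @param sd_highly_variable floor defining highly variable CpGs.
#' @param h2_min heritability threshold; heritable calls require h2 strictly
#'   greater than this value.
#' @param min_trios minimum number of complete trios for a heritability call.
#' @param fdr Benjamini-Hochberg FDR cutoff (calls require q strictly below).
#' @param window cis window in bp for mQTL and variance-QTL pairing.
#' @param maf_min minimum minor allele frequency (inclusive).
#' @param hwe_min_p SNPs are kept when the exact HWE p-value is strictly
#'   greater than this.
#' @param n_perm number of permutations for empirical mQTL p-values.
#' @param asm_p_max ASM calls require Fisher p strictly below this.
#' @param asm_delta_min ASM calls require an absolute allelic methylation
#'   difference strictly greater than this.
#' @param asm_min_frags minimum fragment count per allele for an ASM table
#'   to be testable.
#' @param vmr_min_cpgs minimum number of adjacent consistent CpGs per VMR.
#' @param vmr_max_spacing maximum spacing (bp) between consecutive VMR
#'   member CpGs.
#' @param vmr_cluster_distance VMRs within this distance (bp, edge to edge,
#'   inclusive) are grouped into one cluster.
#' @param vmr_t_min per-CpG |t| threshold for the variance regression.
#' @param vmr_min_group_n minimum samples per genotype class for the
#'   variance regression to be testable.
#' @param seed integer seed from which all per-stage random streams derive.
#' @return A list of class \code{pedmeth_config}.
#' @export
analysis_config <- function(min_depth = 10,
                            min_present_fraction = 0.8,
                            sd_variable = 0.1,
                            sd_highly_variable = 0.3,
                            h2_min = 0.2,
                            min_trios = 10,
                            fdr = 0.05,
                            window = 1e6,
                            maf_min = 0.05,
                            hwe_min_p = 0.001,
                            n_perm = 10000,
                            asm_p_max = 0.001,
                            asm_delta_min = 0.2,
                            asm_min_frags = 5,
                            vmr_min_cpgs = 5,
                            vmr_max_spacing = 200,
                            vmr_cluster_distance = 1e5,
                            vmr_t_min = 2.0,
                            vmr_min_group_n = 3,
                            seed = 1L) {
  cfg <- list(
    min_depth = min_depth,
    min_present_fraction = min_present_fraction,
    sd_variable = sd_variable,
    sd_highly_variable = sd_highly_variable,
    h2_min = h2_min,
    min_trios = min_trios,
    fdr = fdr,
    window = window,
    maf_min = maf_min,
    hwe_min_p = hwe_min_p,
    n_perm = n_perm,
    asm_p_max = asm_p_max,
    asm_delta_min = asm_delta_min,
    asm_min_frags = asm_min_frags,
    vmr_min_cpgs = vmr_min_cpgs,
    vmr_max_spacing = vmr_max_spacing,
    vmr_cluster_distance = vmr_cluster_distance,
    vmr_t_min = vmr_t_min,
    vmr_min_group_n = vmr_min_group_n,
    seed = as.integer(seed)
  )
  frac <- c("min_present_fraction", "sd_variable", "sd_highly_variable",
            "fdr", "maf_min", "hwe_min_p", "asm_p_max", "asm_delta_min")
  for (f in frac) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v > 1)
      stop("config field '", f, "' must be a fraction in [0, 1]")
  }
  pos <- c("min_depth", "min_trios", "window", "n_perm", "vmr_min_cpgs",
           "vmr_max_spacing", "vmr_cluster_distance", "vmr_min_group_n",
           "asm_min_frags")
  for (f in pos) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || v < 0)
      stop("config field '", f, "' must be a non-negative count")
  }
  class(cfg) <- "pedmeth_config"
  cfg
}

#' @export
print.pedmeth_config <- function(x, ...) {
  cat("pedmeth analysis configuration\n")
  for (nm in setdiff(names(x), "seed"))
    cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  cat(sprintf("  %-22s %d\n", "seed", x$seed))
  invisible(x)
}

# Derive a reproducible sub-seed for a named stage so that adding draws in
# one stage never perturbs another. Kept below 2^31 - 1.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 2654435761 + h) %% 2147483647)
}
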