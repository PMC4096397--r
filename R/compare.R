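#' Overlap between two CpG sets
#'
#' Exact set arithmetic on CpGs keyed by (chrom, pos): the intersection
#' size, the fraction of A found in B, and the fraction of B found in A.
#' Fractions with an empty denominator are NA, not 0.
#'
#' @param set_a,set_b data.frames with \code{chrom} and \code{pos}.
#' @return list: \code{n_intersect}, \code{frac_a_in_b}, \code{frac_b_in_a},
#'   \code{n_a}, \code{n_b}.
#' @export
overlap_fractions <- function(set_a, set_b) {
  ka <- unique(cpg_key(set_a$chrom, set_a$pos))
  kb <- unique(cpg_key(set_b$chrom, set_b$pos))
  ni <- length(intersect(ka, kb))
  list(n_intersect = ni,
       frac_a_in_b = if (length(ka)) ni / length(ka) else NA_real_,
       frac_b_in_a = if (length(kb)) ni / length(kb) else NA_real_,
       n_a = length(ka), n_b = length(kb))
}

#' Distance distribution of cis associations
#'
#' Bins the absolute CpG-SNP distances of an association table by the given
#' upper bin edges and returns the fraction of associations per bin; the
#' fractions sum to 1 over the window.
#'
#' @param associations data.frame with a \code{distance} column (signed bp).
#' @param bin_edges increasing vector of upper edges (bp), e.g.
#'   \code{c(2e3, 1e5, 1e6)}; each bin is (previous edge, edge].
#' @return data.frame: \code{upper_edge}, \code{count}, \code{fraction};
#'   empty input yields an empty histogram.
#' @export
distance_distribution <- function(associations, bin_edges) {
  stopifnot(!is.unsorted(bin_edges, strictly = TRUE))
  if (nrow(associations) == 0)
    return(data.frame(upper_edge = numeric(0), count = integer(0),
                      fraction = numeric(0)))
  d <- abs(associations$distance)
  if (any(d > bin_edges[length(bin_edges)]))
    stop("association distance beyond the last bin edge")
  idx <- findInterval(d, c(-Inf, bin_edges), left.open = TRUE)
  counts <- tabulate(idx, nbins = length(bin_edges))
  data.frame(upper_edge = bin_edges, count = counts,
             fraction = counts / sum(counts))
}

#' Read a BED annotation of genomic regions
#'
#' Standard BED semantics: 0-based half-open intervals; the 4th column is
#' the region label. Intervals with different labels may overlap.
#'
#' @param path BED file path.
#' @return data.frame of class \code{region_annotation}: \code{chrom},
#'   \code{start} (0-based), \code{end}, \code{label}.
#' @export
read_bed_annotation <- function(path) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(bed) < 4) stop("BED annotation needs 4 columns (chrom, start, end, label)")
  ann <- data.frame(chrom = bed[[1]], start = bed[[2]], end = bed[[3]],
                    label = bed[[4]], stringsAsFactors = FALSE)
  class(ann) <- c("region_annotation", "data.frame")
  ann
}

# label set for each CpG (chrom, pos 1-based); CpGs overlapping no interval
# get "intergenic". BED half-open: a C at 1-based position p overlaps
# [start, end) iff start < p <= end, i.e. 0-based p-1 in [start, end).
cpg_labels <- function(sites, ann) {
  cg <- GenomicRanges::GRanges(sites$chrom,
                               IRanges::IRanges(sites$pos, sites$pos))
  iv <- GenomicRanges::GRanges(ann$chrom,
                               IRanges::IRanges(ann$start + 1, ann$end))
  hits <- GenomicRanges::findOverlaps(cg, iv)
  lab <- split(ann$label[S4Vectors::subjectHits(hits)],
               factor(S4Vectors::queryHits(hits), levels = seq_len(nrow(sites))))
  lapply(lab, function(l) if (length(l)) unique(l) else "intergenic")
}

#' Region enrichment of a significant CpG set
#'
#' For each annotation label, compares the share of significant CpGs
#' overlapping that region class with the share of the analysis background
#' doing so; the enrichment ratio is their quotient. A CpG overlapping
#' multiple labels counts once per label; a CpG overlapping no interval is
#' labelled "intergenic".
#'
#' @param significant,background data.frames with \code{chrom}, \code{pos};
#'   the background must contain every significant CpG.
#' @param ann a \code{region_annotation} (see
#'   \code{\link{read_bed_annotation}}).
#' @return data.frame: \code{label}, \code{n_sig}, \code{frac_sig},
#'   \code{n_bg}, \code{frac_bg}, \code{ratio} (NA when the background
#'   share is 0); labels absent from both sets are omitted.
#' @export
annotate_enrichment <- function(significant, background, ann) {
  ks <- cpg_key(significant$chrom, significant$pos)
  kb <- cpg_key(background$chrom, background$pos)
  if (!all(ks %in% kb))
    stop("background must contain every significant CpG")
  count_labels <- function(sites) {
    if (nrow(sites) == 0) return(integer(0))
    labs <- cpg_labels(sites, ann)
    table(unlist(labs))
  }
  cs <- count_labels(significant)
  cb <- count_labels(background)
  labels <- sort(union(names(cs), names(cb)))
  n_sig <- as.integer(ifelse(labels %in% names(cs), cs[labels], 0))
  n_bg <- as.integer(ifelse(labels %in% names(cb), cb[labels], 0))
  frac_sig <- if (nrow(significant)) n_sig / nrow(significant) else
    rep(NA_real_, length(labels))
  frac_bg <- if (nrow(background)) n_bg / nrow(background) else
    rep(NA_real_, length(labels))
  data.frame(label = labels, n_sig = n_sig, frac_sig = frac_sig,
             n_bg = n_bg, frac_bg = frac_bg,
             ratio = ifelse(frac_bg > 0, frac_sig / frac_bg, NA_real_),
             stringsAsFactors = FALSE)
}

#' Cross-method comparison of CpG calls
#'
#' Pairwise overlap fractions between the CpG sets called by the
#' mid-parent-offspring, mQTL and ASM analyses, reported separately where a
#' SNP-CpG flag is available.
#'
#' @param mpo_results per-CpG table from \code{\link{run_mpo}}.
#' @param mqtl_results association table from \code{\link{mqtl_scan}}.
#' @param asm_merged merged events from \code{\link{merge_asm_events}}.
#' @param fdr q-value cutoff defining mQTL-significant CpGs.
#' @return list of overlap summaries (\code{mqtl_vs_mpo}, \code{asm_vs_mpo},
#'   and non-SNP-CpG restricted variants when flags are present) plus the
#'   three CpG sets.
#' @export
compare_methods <- function(mpo_results, mqtl_results, asm_merged,
                            fdr = 0.05) {
  her <- mpo_results[mpo_results$heritable,
                     c("chrom", "pos", if ("snp_cpg" %in% names(mpo_results))
                       "snp_cpg")]
  sig <- mqtl_results[!is.na(mqtl_results$q) & mqtl_results$q < fdr, ,
                      drop = FALSE]
  mq <- unique(data.frame(chrom = sig$cpg_chrom, pos = sig$cpg_pos,
                          stringsAsFactors = FALSE))
  as_ <- unique(data.frame(chrom = asm_merged$cpg_chrom,
                           pos = asm_merged$cpg_pos,
                           stringsAsFactors = FALSE))
  out <- list(mqtl_vs_mpo = overlap_fractions(mq, her),
              asm_vs_mpo = overlap_fractions(as_, her),
              heritable = her, mqtl_cpgs = mq, asm_cpgs = as_)
  if ("snp_cpg" %in% names(mpo_results)) {
    her_non <- her[!her$snp_cpg, , drop = FALSE]
    out$mqtl_vs_mpo_non_snp <- overlap_fractions(mq, her_non)
    out$asm_vs_mpo_non_snp <- overlap_fractions(as_, her_non)
  }
  out
}
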