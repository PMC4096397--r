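#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Conditional on the margins, the two-sided p-value sums the
#' hypergeometric probabilities of all tables whose probability does not
#' exceed the observed table's (point-probability rule). A table with a
#' zero margin admits a single configuration and has p = 1.
#'
#' @param table 2x2 matrix of non-negative integer counts (alleles in rows,
#'   methylation states in columns, or vice versa).
#' @return two-sided p-value.
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) return(1)
  stats::fisher.test(table)$p.value
}

#' Call allele-specific methylation events
#'
#' Builds one 2x2 table (allele x methylation state) per (sample, SNP, CpG)
#' triple by counting allele-tagged fragments, and emits an ASM event when
#' the two-sided Fisher p-value is strictly below \code{p_max} and the
#' absolute difference in methylation fraction between the two alleles is
#' strictly above \code{delta_min}. Triples with fewer than
#' \code{min_frags} fragments on either allele are untestable and skipped
#' (the allelic difference is undefined or unstable there).
#'
#' @param frags a \code{\link{fragment_set}}.
#' @param p_max Fisher p-value threshold (strict; default 0.001).
#' @param delta_min allelic methylation difference threshold (strict;
#'   default 0.2).
#' @param min_frags minimum fragments per allele (default 5; set to 1 to
#'   test every covered triple).
#' @param genotypes optional \code{\link{geno_matrix}} used to flag events
#'   whose CpG dinucleotide itself carries a SNP.
#' @return data.frame of events: \code{sample_id}, \code{snp_id},
#'   \code{cpg_chrom}, \code{cpg_pos}, counts \code{ref_meth},
#'   \code{ref_unmeth}, \code{alt_meth}, \code{alt_unmeth}, \code{delta}
#'   (absolute), \code{hypo_allele}, \code{p}, \code{asm} (logical call)
#'   and, with genotypes, \code{snp_cpg}.
#' @export
call_asm <- function(frags, p_max = 0.001, delta_min = 0.2, min_frags = 5,
                     genotypes = NULL) {
  stopifnot(inherits(frags, "fragment_set"))
  r <- frags$records
  empty <- data.frame(sample_id = character(0), snp_id = character(0),
                      cpg_chrom = character(0), cpg_pos = numeric(0),
                      ref_meth = integer(0), ref_unmeth = integer(0),
                      alt_meth = integer(0), alt_unmeth = integer(0),
                      delta = numeric(0), hypo_allele = character(0),
                      p = numeric(0), asm = logical(0),
                      stringsAsFactors = FALSE)
  if (nrow(r) == 0) return(empty)
  key <- paste(r$sample_id, r$snp_id, r$cpg_chrom, r$cpg_pos, sep = "\r")
  rows <- lapply(split(seq_len(nrow(r)), key), function(ix) {
    g <- r[ix, ]
    rm_ <- sum(g$allele == "ref" & g$methylated)
    ru <- sum(g$allele == "ref" & !g$methylated)
    am <- sum(g$allele == "alt" & g$methylated)
    au <- sum(g$allele == "alt" & !g$methylated)
    if (rm_ + ru < min_frags || am + au < min_frags) return(NULL)
    fr <- rm_ / (rm_ + ru)
    fa <- am / (am + au)
    data.frame(sample_id = g$sample_id[1], snp_id = g$snp_id[1],
               cpg_chrom = g$cpg_chrom[1], cpg_pos = g$cpg_pos[1],
               ref_meth = rm_, ref_unmeth = ru, alt_meth = am,
               alt_unmeth = au, delta = abs(fr - fa),
               hypo_allele = if (fr == fa) NA_character_ else
                 if (fr < fa) "ref" else "alt",
               p = fisher_exact(matrix(c(rm_, ru, am, au), 2, byrow = TRUE)),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- out[order(out$cpg_chrom, out$cpg_pos, out$snp_id, out$sample_id), ]
  rownames(out) <- NULL
  out$asm <- out$p < p_max & out$delta > delta_min
  if (!is.null(genotypes))
    out$snp_cpg <- classify_snp_cpg(
      data.frame(chrom = out$cpg_chrom, pos = out$cpg_pos), genotypes)
  out
}

#' Merge ASM events across individuals
#'
#' Groups called events by CpG (and SNP), reporting per merged event the
#' number of distinct supporting samples and whether all of them agree on
#' which allele is hypomethylated. Merging is idempotent with respect to
#' the supporting-sample set and independent of input order.
#'
#' @param events data.frame from \code{\link{call_asm}}; only rows with
#'   \code{asm == TRUE} are merged (all rows if no \code{asm} column).
#' @return data.frame: \code{cpg_chrom}, \code{cpg_pos}, \code{snp_id},
#'   \code{support} (distinct samples), \code{direction_consistent},
#'   \code{hypo_allele} (NA when inconsistent), and \code{snp_cpg} when
#'   present in the input.
#' @export
merge_asm_events <- function(events) {
  if (!is.null(events$asm)) events <- events[events$asm, , drop = FALSE]
  empty <- data.frame(cpg_chrom = character(0), cpg_pos = numeric(0),
                      snp_id = character(0), support = integer(0),
                      direction_consistent = logical(0),
                      hypo_allele = character(0), stringsAsFactors = FALSE)
  if (nrow(events) == 0) return(empty)
  key <- paste(events$cpg_chrom, events$cpg_pos, events$snp_id, sep = "\r")
  rows <- lapply(split(seq_len(nrow(events)), key), function(ix) {
    g <- events[ix, ]
    dirs <- unique(g$hypo_allele[!is.na(g$hypo_allele)])
    consistent <- length(dirs) <= 1
    out <- data.frame(cpg_chrom = g$cpg_chrom[1], cpg_pos = g$cpg_pos[1],
                      snp_id = g$snp_id[1],
                      support = length(unique(g$sample_id)),
                      direction_consistent = consistent,
                      hypo_allele = if (consistent && length(dirs) == 1)
                        dirs else NA_character_,
                      stringsAsFactors = FALSE)
    if (!is.null(g$snp_cpg)) out$snp_cpg <- any(g$snp_cpg)
    out
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$cpg_chrom, out$cpg_pos, out$snp_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
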