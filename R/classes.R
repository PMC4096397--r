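#' CpG methylation matrix
#'
#' The pipeline's central quantitative trait: per-CpG, per-sample methylation
#' fractions in [0, 1] together with the read depth supporting each call.
#' Missing calls are \code{NA} in \code{beta}.
#'
#' @param sites data.frame with columns \code{chrom}, \code{pos} (1-based
#'   position of the C of the CG dinucleotide on the forward strand) and
#'   \code{strand} (strand of capture).
#' @param samples character vector of unique sample ids, one per column.
#' @param beta numeric matrix, sites x samples, fractions in [0, 1] or NA.
#' @param depth integer matrix of read depths, same shape as \code{beta}.
#' @return An object of class \code{meth_matrix}.
#' @export
meth_matrix <- function(sites, samples, beta, depth) {
  sites <- as.data.frame(sites)
  stopifnot(all(c("chrom", "pos", "strand") %in% names(sites)))
  samples <- as.character(samples)
  beta <- as.matrix(beta)
  depth <- as.matrix(depth)
  if (anyDuplicated(samples)) stop("sample ids must be unique")
  if (nrow(beta) != nrow(sites) || ncol(beta) != length(samples))
    stop("beta must be sites x samples")
  if (!all(dim(depth) == dim(beta))) stop("depth must match beta's shape")
  if (any(sites$pos < 1)) stop("positions are 1-based; pos >= 1 required")
  ok <- is.na(beta) | (beta >= 0 & beta <= 1)
  if (!all(ok)) stop("methylation fractions must lie in [0, 1]")
  for (ch in unique(sites$chrom)) {
    p <- sites$pos[sites$chrom == ch]
    if (is.unsorted(p, strictly = TRUE))
      stop("site positions must be strictly increasing within chromosome")
  }
  dimnames(beta) <- list(NULL, samples)
  dimnames(depth) <- list(NULL, samples)
  structure(list(sites = sites, samples = samples, beta = beta,
                 depth = depth),
            class = "meth_matrix")
}

#' @export
print.meth_matrix <- function(x, ...) {
  cat(sprintf("meth_matrix: %d CpG sites x %d samples (%.1f%% missing)\n",
              nrow(x$beta), ncol(x$beta), 100 * mean(is.na(x$beta))))
  invisible(x)
}

#' @export
dim.meth_matrix <- function(x) dim(x$beta)

#' Genotype matrix
#'
#' Biallelic SNP dosages (count of alternate alleles, 0/1/2, NA when
#' missing) for a set of samples.
#'
#' @param snps data.frame with columns \code{id}, \code{chrom}, \code{pos}
#'   (1-based), \code{ref}, \code{alt}.
#' @param samples character vector of unique sample ids.
#' @param dosage numeric matrix, SNPs x samples, values in \{0, 1, 2, NA\}.
#' @return An object of class \code{geno_matrix}.
#' @export
geno_matrix <- function(snps, samples, dosage) {
  snps <- as.data.frame(snps)
  stopifnot(all(c("id", "chrom", "pos", "ref", "alt") %in% names(snps)))
  samples <- as.character(samples)
  dosage <- as.matrix(dosage)
  if (anyDuplicated(samples)) stop("sample ids must be unique")
  if (nrow(dosage) != nrow(snps) || ncol(dosage) != length(samples))
    stop("dosage must be SNPs x samples")
  ok <- is.na(dosage) | dosage %in% c(0, 1, 2)
  if (!all(ok)) stop("dosages must be 0, 1, 2 or NA")
  for (ch in unique(snps$chrom)) {
    p <- snps$pos[snps$chrom == ch]
    if (is.unsorted(p)) stop("SNP positions must be sorted within chromosome")
  }
  dimnames(dosage) <- list(snps$id, samples)
  structure(list(snps = snps, samples = samples, dosage = dosage),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d SNPs x %d samples\n",
              nrow(x$dosage), ncol(x$dosage)))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosage)

#' Pedigree of nuclear families
#'
#' @param samples data.frame with columns \code{sample_id}, \code{family_id},
#'   \code{father_id}, \code{mother_id} (NA for founders) and \code{sex}
#'   (1 = male, 2 = female, 0 = unknown).
#' @return An object of class \code{pedigree_set}.
#' @export
pedigree_set <- function(samples) {
  samples <- as.data.frame(samples)
  need <- c("sample_id", "family_id", "father_id", "mother_id", "sex")
  stopifnot(all(need %in% names(samples)))
  if (anyDuplicated(samples$sample_id)) stop("sample ids must be unique")
  nonf <- !is.na(samples$father_id) | !is.na(samples$mother_id)
  for (i in which(nonf)) {
    for (pid in c(samples$father_id[i], samples$mother_id[i])) {
      if (is.na(pid)) next
      j <- match(pid, samples$sample_id)
      if (is.na(j))
        stop("parent '", pid, "' of '", samples$sample_id[i],
             "' is absent from the pedigree")
      if (samples$family_id[j] != samples$family_id[i])
        stop("parent '", pid, "' belongs to a different family than '",
             samples$sample_id[i], "'")
    }
  }
  structure(list(samples = samples), class = "pedigree_set")
}

#' @export
print.pedigree_set <- function(x, ...) {
  s <- x$samples
  cat(sprintf("pedigree_set: %d samples in %d families (%d founders)\n",
              nrow(s), length(unique(s$family_id)),
              sum(is.na(s$father_id) & is.na(s$mother_id))))
  invisible(x)
}

#' Extract parent-child trios from a pedigree
#'
#' Each child with both parents present contributes one trio; two children
#' of the same parents contribute two trios.
#'
#' @param pedigree a \code{pedigree_set}.
#' @return data.frame of class \code{trio_set} with columns
#'   \code{father_id}, \code{mother_id}, \code{child_id}, \code{family_id}.
#' @export
trio_set <- function(pedigree) {
  s <- pedigree$samples
  kid <- !is.na(s$father_id) & !is.na(s$mother_id)
  tr <- data.frame(father_id = s$father_id[kid],
                   mother_id = s$mother_id[kid],
                   child_id = s$sample_id[kid],
                   family_id = s$family_id[kid],
                   stringsAsFactors = FALSE)
  bad <- tr$father_id == tr$child_id | tr$mother_id == tr$child_id |
    tr$father_id == tr$mother_id
  if (any(bad)) stop("trio member ids must be distinct")
  class(tr) <- c("trio_set", "data.frame")
  tr
}

#' Allele-tagged fragment set
#'
#' Read-level records pairing the allele observed at a heterozygous SNP with
#' the methylation state of a CpG on the same fragment; the unit of analysis
#' for allele-specific methylation.
#'
#' @param records data.frame with columns \code{sample_id}, \code{snp_id},
#'   \code{allele} ("ref"/"alt"), \code{cpg_chrom}, \code{cpg_pos},
#'   \code{methylated} (logical).
#' @return An object of class \code{fragment_set}.
#' @export
fragment_set <- function(records) {
  records <- as.data.frame(records)
  need <- c("sample_id", "snp_id", "allele", "cpg_chrom", "cpg_pos",
            "methylated")
  stopifnot(all(need %in% names(records)))
  if (nrow(records) > 0 && !all(records$allele %in% c("ref", "alt")))
    stop("allele must be 'ref' or 'alt'")
  structure(list(records = records), class = "fragment_set")
}

#' @export
print.fragment_set <- function(x, ...) {
  cat(sprintf("fragment_set: %d fragment-CpG records (%d samples, %d SNPs)\n",
              nrow(x$records), length(unique(x$records$sample_id)),
              length(unique(x$records$snp_id))))
  invisible(x)
}

# Shared key for CpG identity across modules.
cpg_key <- function(chrom, pos) paste(chrom, pos, sep = ":")
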