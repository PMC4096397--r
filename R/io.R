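#' Write genotypes as a minimal VCF
#'
#' Biallelic SNVs with a GT field only; positions 1-based per the VCF spec.
#'
#' @param genotypes a \code{\link{geno_matrix}}.
#' @param path output file.
#' @export
write_vcf <- function(genotypes, path) {
  gt_code <- function(d) ifelse(is.na(d), "./.",
                                c("0/0", "0/1", "1/1")[d + 1])
  s <- genotypes$snps
  lines <- c("##fileformat=VCFv4.2",
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", genotypes$samples), collapse = "\t"))
  body <- vapply(seq_len(nrow(s)), function(i) {
    paste(c(s$chrom[i], s$pos[i], s$id[i], s$ref[i], s$alt[i], ".", "PASS",
            ".", "GT", gt_code(genotypes$dosage[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
}

#' Read genotypes from a VCF
#'
#' Parses GT fields into 0/1/2 alternate-allele dosages. Multi-allelic
#' records are skipped with a warning; phased separators are accepted.
#'
#' @param path VCF file.
#' @return A \code{\link{geno_matrix}}.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT)
  if (any(multi))
    warning(sum(multi), " multi-allelic VCF record(s) skipped")
  gt <- vcfR::extract.gt(v, element = "GT")
  keep <- which(!multi)
  dosage <- t(apply(gt[keep, , drop = FALSE], 1, function(x) {
    x <- gsub("\\|", "/", x)
    ifelse(is.na(x) | x == "./.", NA_real_,
           vapply(strsplit(x, "/"), function(a)
             sum(as.numeric(a)), numeric(1)))
  }))
  snps <- data.frame(id = fix$ID[keep], chrom = fix$CHROM[keep],
                     pos = as.numeric(fix$POS[keep]), ref = fix$REF[keep],
                     alt = fix$ALT[keep], stringsAsFactors = FALSE)
  ord <- order(snps$chrom, snps$pos)
  geno_matrix(snps[ord, , drop = FALSE], colnames(gt),
              dosage[ord, , drop = FALSE])
}

#' Write a pedigree as a PLINK FAM file
#'
#' Columns: family, sample, father (0 if founder), mother (0 if founder),
#' sex (1/2/0), phenotype (-9).
#'
#' @param pedigree a \code{\link{pedigree_set}}.
#' @param path output file.
#' @export
write_fam <- function(pedigree, path) {
  s <- pedigree$samples
  utils::write.table(
    data.frame(s$family_id, s$sample_id,
               ifelse(is.na(s$father_id), "0", s$father_id),
               ifelse(is.na(s$mother_id), "0", s$mother_id),
               s$sex, -9),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
}

#' Read a PLINK FAM pedigree
#'
#' @param path FAM file.
#' @return A \code{\link{pedigree_set}}.
#' @export
read_fam <- function(path) {
  f <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(f) < 5) stop("FAM file needs at least 5 columns")
  pedigree_set(data.frame(
    sample_id = as.character(f[[2]]), family_id = as.character(f[[1]]),
    father_id = ifelse(f[[3]] == "0", NA_character_, as.character(f[[3]])),
    mother_id = ifelse(f[[4]] == "0", NA_character_, as.character(f[[4]])),
    sex = as.integer(f[[5]]), stringsAsFactors = FALSE))
}

#' Write a methylation matrix as TSV
#'
#' Layout: \code{chrom}, \code{pos}, \code{strand}, then per sample a
#' \code{<id>.frac} and \code{<id>.depth} column pair; missing fractions are
#' \code{NA}.
#'
#' @param m a \code{\link{meth_matrix}}.
#' @param path output file.
#' @export
write_meth_tsv <- function(m, path) {
  out <- m$sites[, c("chrom", "pos", "strand")]
  for (j in seq_along(m$samples)) {
    out[[paste0(m$samples[j], ".frac")]] <- m$beta[, j]
    out[[paste0(m$samples[j], ".depth")]] <- m$depth[, j]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
}

#' Read a methylation matrix from TSV
#'
#' Rows whose fraction falls outside [0, 1] are rejected with a warning
#' naming the offending line numbers.
#'
#' @param path TSV written by \code{\link{write_meth_tsv}}.
#' @return A \code{\link{meth_matrix}}.
#' @export
read_meth_tsv <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, check.names = FALSE)
  fc <- grep("\\.frac$", names(d), value = TRUE)
  samples <- sub("\\.frac$", "", fc)
  beta <- as.matrix(d[, paste0(samples, ".frac"), drop = FALSE])
  depth <- as.matrix(d[, paste0(samples, ".depth"), drop = FALSE])
  bad <- which(apply(beta, 1, function(x)
    any(!is.na(x) & (x < 0 | x > 1))))
  if (length(bad)) {
    warning("rejected methylation record(s) with fraction outside [0, 1] ",
            "at line(s) ", paste(bad + 1L, collapse = ", "))
    beta <- beta[-bad, , drop = FALSE]
    depth <- depth[-bad, , drop = FALSE]
    d <- d[-bad, , drop = FALSE]
  }
  meth_matrix(d[, c("chrom", "pos", "strand")], samples, beta, depth)
}

#' Write allele-tagged fragments as TSV
#' @param frags a \code{\link{fragment_set}}.
#' @param path output file.
#' @export
write_fragments_tsv <- function(frags, path) {
  utils::write.table(frags$records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Read allele-tagged fragments from TSV
#' @param path TSV written by \code{\link{write_fragments_tsv}}.
#' @return A \code{\link{fragment_set}}.
#' @export
read_fragments_tsv <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  d$methylated <- as.logical(d$methylated)
  fragment_set(d)
}

#' Write the simulation ground truth as JSON
#' @param truth truth list from \code{\link{simulate_methylome}}.
#' @param path output file.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
}

#' Write a synthetic study to disk
#'
#' Emits the VCF, FAM, methylation TSV, fragments TSV and truth JSON of a
#' cohort from \code{\link{simulate_study_cohort}}.
#'
#' @param study cohort list.
#' @param dir output directory (created if needed).
#' @return invisible named vector of file paths.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(dir, "genotypes.vcf"),
             fam = file.path(dir, "pedigree.fam"),
             meth = file.path(dir, "methylation.tsv"),
             frags = file.path(dir, "fragments.tsv"),
             truth = file.path(dir, "truth.json"))
  write_vcf(study$genotypes, paths["vcf"])
  write_fam(study$pedigree, paths["fam"])
  write_meth_tsv(study$meth, paths["meth"])
  if (!is.null(study$fragments))
    write_fragments_tsv(study$fragments, paths["frags"])
  if (!is.null(study$truth)) write_truth_json(study$truth, paths["truth"])
  invisible(paths)
}

#' Load a study from its on-disk representation
#'
#' Reads genotypes (VCF), pedigree (FAM), methylation matrix (TSV) and
#' optionally fragments (TSV) and a BED region annotation, harmonizes the
#' sample ordering to the pedigree order restricted to samples present in
#' all mandatory inputs, and logs a one-line summary.
#'
#' @param vcf_path,fam_path,meth_path mandatory input files.
#' @param frags_path,bed_path optional inputs.
#' @return list: \code{pedigree}, \code{genotypes}, \code{meth},
#'   \code{fragments} (or NULL), \code{annotation} (or NULL).
#' @export
load_study <- function(vcf_path, fam_path, meth_path, frags_path = NULL,
                       bed_path = NULL) {
  pedigree <- read_fam(fam_path)
  genotypes <- read_vcf(vcf_path)
  meth <- read_meth_tsv(meth_path)
  common <- pedigree$samples$sample_id
  common <- common[common %in% genotypes$samples & common %in% meth$samples]
  if (length(common) == 0)
    stop("no sample overlap between pedigree, genotypes and methylation")
  genotypes$dosage <- genotypes$dosage[, match(common, genotypes$samples),
                                       drop = FALSE]
  genotypes$samples <- common
  meth$beta <- meth$beta[, match(common, meth$samples), drop = FALSE]
  meth$depth <- meth$depth[, match(common, meth$samples), drop = FALSE]
  meth$samples <- common
  keep <- pedigree$samples$sample_id %in% common
  pedigree$samples <- pedigree$samples[keep, , drop = FALSE]
  rownames(pedigree$samples) <- NULL
  frags <- if (!is.null(frags_path)) read_fragments_tsv(frags_path) else NULL
  ann <- if (!is.null(bed_path)) read_bed_annotation(bed_path) else NULL
  message(sprintf(
    "loaded study: %d samples, %d SNPs, %d CpGs, %d trios%s",
    length(common), nrow(genotypes$snps), nrow(meth$sites),
    nrow(trio_set(pedigree)),
    if (is.null(frags)) "" else sprintf(", %d fragment records",
                                        nrow(frags$records))))
  list(pedigree = pedigree, genotypes = genotypes, meth = meth,
       fragments = frags, annotation = ann)
}
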