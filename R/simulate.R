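#' Effect configuration for the synthetic cohort
#'
#' Describes the generative model of the synthetic pedigree methylome: how
#' many SNPs and CpGs to place on the simulated chromosome, the founder
#' allele-frequency range, the baseline methylation distribution, and the
#' ground-truth genetic effects of each class the pipeline is built to
#' detect — CpG-destroying SNPs ("SNP-CpGs"), additive cis effects on mean
#' methylation (mQTL/ASM substrate), variance effects (vSNPs), and
#' family-shared non-genetic variation (heritable in a mid-parent-offspring
#' sense without any simulated polymorphism).
#'
#' @param n_snps,n_cpgs numbers of simulated SNPs and CpGs.
#' @param chrom_length simulated chromosome length in bp.
#' @param maf_range founder minor-allele-frequency range, within (0, 0.5].
#' @param baseline_range range of the uniform baseline methylation level.
#' @param snp_cpg_sites integer vector of SNP indices that destroy a CpG
#'   dinucleotide; each destroying SNP is paired 1:1 with a dedicated CpG
#'   placed at the SNP's position.
#' @param cis_effects data.frame (\code{snp}, \code{cpg}, \code{beta}):
#'   additive shift in methylation fraction per alternate allele.
#' @param vsnp_effects list of lists with fields \code{snp}, \code{cpgs}
#'   (integer vector, a block of adjacent CpGs), \code{sigma} (length-3
#'   residual SD for genotype classes 0/1/2).
#' @param asm_effects data.frame (\code{snp}, \code{cpg}, \code{p_ref},
#'   \code{p_alt}): per-allele methylation probabilities used by
#'   \code{\link{simulate_allelic_fragments}}.
#' @param family_cpgs integer vector of CpGs receiving family-shared noise.
#' @param family_noise_sd SD of the family-shared ("heritable non-genetic")
#'   component, drawn once per family per CpG.
#' @param resid_sd SD of the independent per-sample residual at CpGs without
#'   a variance effect.
#' @param read_depth mean read depth for binomial sampling of observed
#'   methylation fractions; \code{Inf} switches off read sampling so that
#'   observed values equal the latent ones (analytic mode).
#' @param vmr_spacing bp spacing used when laying out vSNP CpG blocks.
#' @return A list of class \code{effect_config}.
#' @export
effect_config <- function(n_snps = 20, n_cpgs = 60, chrom_length = 2e6,
                          maf_range = c(0.2, 0.4),
                          baseline_range = c(0.2, 0.8),
                          snp_cpg_sites = integer(0),
                          cis_effects = NULL,
                          vsnp_effects = list(),
                          asm_effects = NULL,
                          family_cpgs = integer(0),
                          family_noise_sd = 0,
                          resid_sd = 0.03,
                          read_depth = 100,
                          vmr_spacing = 100) {
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop("maf_range must lie within (0, 0.5]")
  if (is.null(cis_effects))
    cis_effects <- data.frame(snp = integer(0), cpg = integer(0),
                              beta = numeric(0))
  if (is.null(asm_effects))
    asm_effects <- data.frame(snp = integer(0), cpg = integer(0),
                              p_ref = numeric(0), p_alt = numeric(0))
  chk_idx <- function(i, n, what)
    if (length(i) && (any(i < 1) || any(i > n)))
      stop(what, " indices out of range")
  chk_idx(snp_cpg_sites, n_snps, "snp_cpg_sites SNP")
  chk_idx(cis_effects$snp, n_snps, "cis_effects SNP")
  chk_idx(cis_effects$cpg, n_cpgs, "cis_effects CpG")
  chk_idx(asm_effects$snp, n_snps, "asm_effects SNP")
  chk_idx(asm_effects$cpg, n_cpgs, "asm_effects CpG")
  chk_idx(family_cpgs, n_cpgs, "family_cpgs CpG")
  for (v in vsnp_effects) {
    chk_idx(v$snp, n_snps, "vsnp_effects SNP")
    chk_idx(v$cpgs, n_cpgs, "vsnp_effects CpG")
    if (length(v$sigma) != 3 || any(v$sigma < 0))
      stop("vsnp_effects sigma must be 3 non-negative SDs")
  }
  if (family_noise_sd < 0 || resid_sd < 0) stop("noise SDs must be >= 0")
  structure(list(n_snps = n_snps, n_cpgs = n_cpgs,
                 chrom_length = chrom_length, maf_range = maf_range,
                 baseline_range = baseline_range,
                 snp_cpg_sites = as.integer(snp_cpg_sites),
                 cis_effects = cis_effects, vsnp_effects = vsnp_effects,
                 asm_effects = asm_effects,
                 family_cpgs = as.integer(family_cpgs),
                 family_noise_sd = family_noise_sd, resid_sd = resid_sd,
                 read_depth = read_depth, vmr_spacing = vmr_spacing),
            class = "effect_config")
}

#' Simulate a pedigree and its genotypes
#'
#' Founder genotypes are drawn allele-wise from Hardy-Weinberg proportions
#' at each SNP's allele frequency; each child inherits one allele from each
#' parent, chosen uniformly and independently per SNP, so simulated trios
#' are Mendel-consistent by construction.
#'
#' SNP positions are laid out on a 4-bp lattice (positions == 0 mod 4)
#' distinct from the CpG lattice (positions == 1 mod 4) so that a SNP only
#' ever overlaps a CpG dinucleotide when the configuration says it destroys
#' that CpG.
#'
#' @param n_families number of nuclear families (>= 0).
#' @param children_per_family a single count, a length-2 inclusive range to
#'   sample from, or a vector of length \code{n_families}.
#' @param effect an \code{\link{effect_config}}.
#' @param seed integer seed; all draws are reproducible given it.
#' @return list with \code{pedigree} (\code{pedigree_set}) and
#'   \code{genotypes} (\code{geno_matrix}).
#' @export
simulate_cohort <- function(n_families, children_per_family = 2, effect,
                            seed = 1L) {
  stopifnot(inherits(effect, "effect_config"), n_families >= 0)
  ped <- build_pedigree(n_families, children_per_family,
                        stage_seed(seed, "pedigree"))
  set.seed(stage_seed(seed, "genotypes"))
  n_snps <- effect$n_snps
  snp_pos <- snp_lattice(n_snps, effect$chrom_length)
  maf <- stats::runif(n_snps, effect$maf_range[1], effect$maf_range[2])
  s <- ped$samples
  n <- nrow(s)
  a1 <- matrix(0L, n_snps, max(n, 0))
  a2 <- matrix(0L, n_snps, max(n, 0))
  if (n > 0) {
    founder <- is.na(s$father_id) & is.na(s$mother_id)
    for (i in which(founder)) {
      a1[, i] <- stats::rbinom(n_snps, 1, maf)
      a2[, i] <- stats::rbinom(n_snps, 1, maf)
    }
    for (i in which(!founder)) {
      f <- match(s$father_id[i], s$sample_id)
      m <- match(s$mother_id[i], s$sample_id)
      pickf <- stats::rbinom(n_snps, 1, 0.5) == 1
      pickm <- stats::rbinom(n_snps, 1, 0.5) == 1
      a1[, i] <- ifelse(pickf, a1[, f], a2[, f])
      a2[, i] <- ifelse(pickm, a1[, m], a2[, m])
    }
  }
  snps <- data.frame(id = sprintf("snp%04d", seq_len(n_snps)),
                     chrom = "chr1", pos = snp_pos,
                     ref = "A", alt = "G", maf = maf,
                     stringsAsFactors = FALSE)
  g <- geno_matrix(snps, s$sample_id, a1 + a2)
  list(pedigree = ped, genotypes = g)
}

build_pedigree <- function(n_families, children_per_family, seed) {
  set.seed(seed)
  if (n_families == 0)
    return(pedigree_set(data.frame(sample_id = character(0),
                                   family_id = character(0),
                                   father_id = character(0),
                                   mother_id = character(0),
                                   sex = integer(0))))
  k <- children_per_family
  if (length(k) == 1L) {
    nk <- rep(k, n_families)
  } else if (length(k) == 2L && n_families != 2L) {
    nk <- sample(seq(k[1], k[2]), n_families, replace = TRUE)
  } else if (length(k) == n_families) {
    nk <- k
  } else stop("children_per_family must be a count, a range, or one value per family")
  rows <- lapply(seq_len(n_families), function(f) {
    fam <- sprintf("F%02d", f)
    fa <- paste0(fam, "_FA"); mo <- paste0(fam, "_MO")
    kids <- if (nk[f] > 0) sprintf("%s_C%d", fam, seq_len(nk[f])) else character(0)
    data.frame(
      sample_id = c(fa, mo, kids),
      family_id = fam,
      father_id = c(NA, NA, rep(fa, nk[f])),
      mother_id = c(NA, NA, rep(mo, nk[f])),
      sex = c(1L, 2L, rep(0L, nk[f])),
      stringsAsFactors = FALSE)
  })
  pedigree_set(do.call(rbind, rows))
}

snp_lattice <- function(n, chrom_length) {
  slots <- seq(4, chrom_length - 4, by = 4)
  if (n > length(slots)) stop("chromosome too short for requested SNP count")
  sort(sample(slots, n))
}

#' Simulate a methylome over a genotyped pedigree
#'
#' Latent methylation at CpG j in sample i is
#' \code{baseline_j + sum(beta * dosage) + familyNoise(family_i, j) +
#' residual}, with the residual SD depending on the sample's genotype class
#' at any configured variance-SNP, and the sum clamped to [0, 1]. At
#' CpG-destroying SNP sites each alternate allele removes half the
#' methylation substrate, so the observed level is the latent level scaled
#' by (2 - dosage)/2. Observed fractions are Binomial(depth, latent)/depth
#' with per-cell Poisson depths; with \code{read_depth = Inf} the latent
#' values are returned unchanged.
#'
#' @param pedigree,genotypes output of \code{\link{simulate_cohort}}.
#' @param effect the same \code{\link{effect_config}}.
#' @param seed integer seed.
#' @return list with \code{meth} (a \code{\link{meth_matrix}}) and
#'   \code{truth}, a list recording the per-CpG effect class and every
#'   configured effect for parameter-recovery tests.
#' @export
simulate_methylome <- function(pedigree, genotypes, effect, seed = 1L) {
  stopifnot(inherits(effect, "effect_config"))
  s <- pedigree$samples
  if (!identical(genotypes$samples, s$sample_id))
    stop("genotypes must cover the pedigree samples in order")
  set.seed(stage_seed(seed, "methylome"))
  n_cpg <- effect$n_cpgs
  n <- nrow(s)
  cpg_pos <- cpg_positions(effect, genotypes)
  baseline <- stats::runif(n_cpg, effect$baseline_range[1],
                           effect$baseline_range[2])

  cls <- rep("null", n_cpg)
  cls[effect$family_cpgs] <- "family"
  if (nrow(effect$cis_effects)) cls[effect$cis_effects$cpg] <- "cis"
  for (v in effect$vsnp_effects) cls[v$cpgs] <- "vsnp"
  destroyed_cpg <- attr(cpg_pos, "snp_cpg_idx")
  cls[destroyed_cpg] <- "snp_cpg"

  mu <- matrix(rep(baseline, n), n_cpg, n)
  if (nrow(effect$cis_effects)) {
    for (r in seq_len(nrow(effect$cis_effects))) {
      e <- effect$cis_effects[r, ]
      mu[e$cpg, ] <- mu[e$cpg, ] + e$beta * genotypes$dosage[e$snp, ]
    }
  }
  if (length(effect$family_cpgs) && effect$family_noise_sd > 0) {
    fams <- unique(s$family_id)
    fam_of <- match(s$family_id, fams)
    fn <- matrix(stats::rnorm(length(effect$family_cpgs) * length(fams),
                              0, effect$family_noise_sd),
                 length(effect$family_cpgs), length(fams))
    mu[effect$family_cpgs, ] <- mu[effect$family_cpgs, ] + fn[, fam_of, drop = FALSE]
  }
  sdm <- matrix(effect$resid_sd, n_cpg, n)
  for (v in effect$vsnp_effects) {
    d <- genotypes$dosage[v$snp, ]
    sdm[v$cpgs, ] <- matrix(v$sigma[d + 1], length(v$cpgs), n, byrow = TRUE)
  }
  latent <- mu + stats::rnorm(n_cpg * n) * sdm
  latent <- pmin(pmax(latent, 0), 1)
  if (length(destroyed_cpg)) {
    scal <- (2 - genotypes$dosage[effect$snp_cpg_sites, , drop = FALSE]) / 2
    latent[destroyed_cpg, ] <- latent[destroyed_cpg, , drop = FALSE] * scal
  }

  if (is.infinite(effect$read_depth)) {
    beta <- latent
    depth <- matrix(Inf, n_cpg, n)
  } else {
    depth <- matrix(stats::rpois(n_cpg * n, effect$read_depth), n_cpg, n)
    beta <- matrix(NA_real_, n_cpg, n)
    pos_d <- depth > 0
    beta[pos_d] <- stats::rbinom(sum(pos_d), depth[pos_d], latent[pos_d]) /
      depth[pos_d]
  }
  sites <- data.frame(chrom = "chr1", pos = cpg_pos, strand = "+",
                      stringsAsFactors = FALSE)
  ord <- order(sites$pos)
  m <- meth_matrix(sites[ord, , drop = FALSE], s$sample_id,
                   beta[ord, , drop = FALSE], depth[ord, , drop = FALSE])
  remap <- match(seq_len(n_cpg), ord)  # original index -> row in m
  truth <- list(
    class = cls[ord],
    baseline = baseline[ord],
    cpg_index = remap,
    snp_cpg = data.frame(snp = effect$snp_cpg_sites,
                         cpg = remap[destroyed_cpg]),
    cis = transform_idx(effect$cis_effects, remap),
    vsnp = lapply(effect$vsnp_effects, function(v) {
      v$cpgs <- sort(remap[v$cpgs]); v
    }),
    asm = transform_idx(effect$asm_effects, remap),
    family_cpgs = sort(remap[effect$family_cpgs])
  )
  list(meth = m, truth = truth)
}

transform_idx <- function(df, remap) {
  if (nrow(df)) df$cpg <- remap[df$cpg]
  df
}

# CpGs sit at positions == 1 (mod 4); a CpG destroyed by SNP k is moved to
# that SNP's exact position so the dinucleotide overlap is real.
cpg_positions <- function(effect, genotypes) {
  slots <- seq(5, effect$chrom_length - 5, by = 4)
  n_free <- effect$n_cpgs - length(effect$snp_cpg_sites)
  if (n_free < 0) stop("more destroying SNPs than CpGs")
  # lay vSNP blocks as runs of adjacent CpGs at the configured spacing
  pos <- rep(NA_real_, effect$n_cpgs)
  used <- c()
  for (v in effect$vsnp_effects) {
    anchor <- genotypes$snps$pos[v$snp] + 400
    pos[v$cpgs] <- anchor + effect$vmr_spacing * (seq_along(v$cpgs) - 1) + 1
    used <- c(used, v$cpgs)
  }
  # destruction CpGs must not double as cis/family/ASM/vSNP targets
  reserved <- unique(c(used, effect$cis_effects$cpg, effect$family_cpgs,
                       effect$asm_effects$cpg))
  snp_cpg_idx <- setdiff(seq_len(effect$n_cpgs), reserved)[
    seq_along(effect$snp_cpg_sites)]
  if (length(effect$snp_cpg_sites) && anyNA(snp_cpg_idx))
    stop("not enough unreserved CpGs for the destruction sites")
  pos[snp_cpg_idx] <- genotypes$snps$pos[effect$snp_cpg_sites]
  free <- which(is.na(pos))
  if (length(free))
    pos[free] <- sort(sample(setdiff(slots, pos), length(free)))
  if (anyDuplicated(pos)) stop("CpG position collision; enlarge chrom_length")
  structure(pos, snp_cpg_idx = snp_cpg_idx)
}

#' Simulate allele-tagged read fragments
#'
#' Fragments are generated only where a sample is heterozygous at a
#' configured (SNP, CpG) pair: each fragment carries one of the two alleles
#' with equal probability and a Bernoulli methylation call with the
#' allele-specific methylation probability recorded in the ground truth.
#'
#' @param genotypes a \code{geno_matrix}.
#' @param truth the truth list from \code{\link{simulate_methylome}}.
#' @param meth the matching \code{meth_matrix} (for CpG coordinates).
#' @param depth fragments per heterozygous (sample, SNP, CpG) triple.
#' @param seed integer seed.
#' @return A \code{\link{fragment_set}}.
#' @export
simulate_allelic_fragments <- function(genotypes, truth, meth, depth = 20,
                                       seed = 1L) {
  stopifnot(depth >= 0)
  set.seed(stage_seed(seed, "fragments"))
  asm <- truth$asm
  out <- list()
  if (depth > 0 && nrow(asm) > 0) {
    for (r in seq_len(nrow(asm))) {
      snp <- asm$snp[r]; cpg <- asm$cpg[r]
      het <- which(!is.na(genotypes$dosage[snp, ]) &
                     genotypes$dosage[snp, ] == 1)
      for (i in het) {
        allele <- ifelse(stats::rbinom(depth, 1, 0.5) == 1, "alt", "ref")
        p <- ifelse(allele == "alt", asm$p_alt[r], asm$p_ref[r])
        out[[length(out) + 1L]] <- data.frame(
          sample_id = genotypes$samples[i],
          snp_id = genotypes$snps$id[snp],
          allele = allele,
          cpg_chrom = meth$sites$chrom[cpg],
          cpg_pos = meth$sites$pos[cpg],
          methylated = stats::rbinom(depth, 1, p) == 1,
          stringsAsFactors = FALSE)
      }
    }
  }
  recs <- if (length(out)) do.call(rbind, out) else
    data.frame(sample_id = character(0), snp_id = character(0),
               allele = character(0), cpg_chrom = character(0),
               cpg_pos = numeric(0), methylated = logical(0))
  fragment_set(recs)
}

#' Simulate the canonical study cohort
#'
#' Builds a synthetic cohort with the structure of the study design the
#' pipeline targets — 22 nuclear families, 96 samples, 52 parent-child
#' trios (14 families with two children, 8 with three) — and a mixture of
#' ground-truth effect classes: CpG-destroying SNPs, additive cis mQTL
#' effects, a variance-SNP block, family-shared non-genetic variation,
#' allele-specific methylation pairs, and null CpGs.
#'
#' @param seed integer seed.
#' @param effect optional \code{\link{effect_config}} overriding the default.
#' @param fragment_depth fragments per heterozygous sample-SNP-CpG triple.
#' @return list with \code{pedigree}, \code{genotypes}, \code{meth},
#'   \code{truth}, \code{fragments}, \code{effect}.
#' @export
simulate_study_cohort <- function(seed = 1L, effect = NULL,
                                  fragment_depth = 20) {
  if (is.null(effect)) effect <- default_study_effects()
  co <- simulate_cohort(22, rep(c(2L, 3L), c(14L, 8L)), effect, seed = seed)
  my <- simulate_methylome(co$pedigree, co$genotypes, effect, seed = seed)
  fr <- simulate_allelic_fragments(co$genotypes, my$truth, my$meth,
                                   depth = fragment_depth, seed = seed)
  list(pedigree = co$pedigree, genotypes = co$genotypes, meth = my$meth,
       truth = my$truth, fragments = fr, effect = effect)
}

default_study_effects <- function() {
  effect_config(
    n_snps = 24, n_cpgs = 72, chrom_length = 3e6,
    maf_range = c(0.2, 0.4), baseline_range = c(0.3, 0.7),
    snp_cpg_sites = 1:4,
    cis_effects = data.frame(snp = 5:8, cpg = 5:8, beta = 0.2),
    vsnp_effects = list(list(snp = 9, cpgs = 9:16,
                             sigma = c(0.05, 0.13, 0.22))),
    asm_effects = data.frame(snp = c(5, 10), cpg = c(5, 17),
                             p_ref = c(0.85, 0.5), p_alt = c(0.15, 0.5)),
    family_cpgs = 18:25,
    family_noise_sd = 0.12,
    resid_sd = 0.03,
    read_depth = 100)
}
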