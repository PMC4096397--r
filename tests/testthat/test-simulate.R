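test_that("empty cohort request yields empty pedigree and genotypes", {
  eff <- effect_config(n_snps = 3, n_cpgs = 5)
  co <- simulate_cohort(0, 2, eff, seed = 1)
  expect_equal(nrow(co$pedigree$samples), 0)
  expect_equal(ncol(co$genotypes$dosage), 0)
  expect_equal(nrow(co$genotypes$dosage), 3)
})

test_that("founder genotypes follow Hardy-Weinberg proportions", {
  eff <- effect_config(n_snps = 2, n_cpgs = 2, maf_range = c(0.3, 0.3))
  co <- simulate_cohort(5000, 0, eff, seed = 11)
  n <- ncol(co$genotypes$dosage)
  expect_equal(n, 10000)
  het <- rowMeans(co$genotypes$dosage == 1)
  se <- sqrt(0.42 * 0.58 / n)
  expect_true(all(abs(het - 0.42) < 3 * se))
})

test_that("simulated trios carry zero Mendel errors", {
  eff <- effect_config(n_snps = 15, n_cpgs = 5)
  for (seed in c(1, 2, 3)) {
    co <- simulate_cohort(12, c(1, 3), eff, seed = seed)
    me <- mendel_errors(co$genotypes, trio_set(co$pedigree))
    expect_equal(me$n_errors, 0)
    expect_gt(me$n_tested, 0)
  }
})

test_that("identical effect config and seed reproduce the cohort bit for bit", {
  a <- simulate_study_cohort(seed = 5)
  b <- simulate_study_cohort(seed = 5)
  expect_identical(a$genotypes$dosage, b$genotypes$dosage)
  expect_identical(a$meth$beta, b$meth$beta)
  expect_identical(a$fragments$records, b$fragments$records)
  c <- simulate_study_cohort(seed = 6)
  expect_false(identical(a$meth$beta, c$meth$beta))
})

test_that("founder genotype counts are HWE-consistent in >=99% of SNPs", {
  eff <- effect_config(n_snps = 100, n_cpgs = 2, chrom_length = 5e6)
  pass <- 0L
  total <- 0L
  for (seed in c(21, 22, 23)) {
    co <- simulate_cohort(100, 0, eff, seed = seed)
    d <- co$genotypes$dosage
    p <- apply(d, 1, function(x)
      hwe_test(sum(x == 0), sum(x == 1), sum(x == 2)))
    pass <- pass + sum(p > 0.001)
    total <- total + length(p)
  }
  expect_gte(pass / total, 0.99)
})

test_that("noise-free infinite-depth methylome equals the baseline", {
  eff <- effect_config(n_snps = 3, n_cpgs = 6, resid_sd = 0,
                       read_depth = Inf)
  co <- simulate_cohort(4, 2, eff, seed = 3)
  my <- simulate_methylome(co$pedigree, co$genotypes, eff, seed = 3)
  n <- nrow(co$pedigree$samples)
  expect_equal(my$meth$beta,
               matrix(my$truth$baseline, 6, n,
                      dimnames = list(NULL, co$pedigree$samples$sample_id)),
               tolerance = 1e-12)
})

test_that("a destroying SNP removes methylation substrate allele by allele", {
  # observed = latent * (2 - dosage) / 2, checked via truth at zero noise
  eff <- effect_config(n_snps = 4, n_cpgs = 8, snp_cpg_sites = 1:2,
                       baseline_range = c(0.8, 0.8), resid_sd = 0,
                       read_depth = Inf)
  co <- simulate_cohort(30, 2, eff, seed = 9)
  my <- simulate_methylome(co$pedigree, co$genotypes, eff, seed = 9)
  for (r in seq_len(nrow(my$truth$snp_cpg))) {
    snp <- my$truth$snp_cpg$snp[r]
    cpg <- my$truth$snp_cpg$cpg[r]
    d <- co$genotypes$dosage[snp, ]
    expect_equal(unname(my$meth$beta[cpg, ]), unname(0.8 * (2 - d) / 2),
                 tolerance = 1e-12)
    # the CpG sits exactly on the SNP
    expect_equal(my$meth$sites$pos[cpg], co$genotypes$snps$pos[snp])
  }
  # stratified means: dosage 2 -> 0, dosage 1 -> 0.4
  snp <- my$truth$snp_cpg$snp[1]; cpg <- my$truth$snp_cpg$cpg[1]
  d <- co$genotypes$dosage[snp, ]
  if (any(d == 1)) expect_equal(mean(my$meth$beta[cpg, d == 1]), 0.4)
  if (any(d == 2)) expect_equal(mean(my$meth$beta[cpg, d == 2]), 0)
})

test_that("per-genotype residual SDs of a vSNP block match configuration", {
  eff <- effect_config(n_snps = 2, n_cpgs = 6, maf_range = c(0.5, 0.5),
                       baseline_range = c(0.5, 0.5),
                       vsnp_effects = list(list(snp = 1, cpgs = 1:3,
                                                sigma = c(0.02, 0.08, 0.15))),
                       resid_sd = 0.02, read_depth = Inf)
  co <- simulate_cohort(1000, 0, eff, seed = 13)
  my <- simulate_methylome(co$pedigree, co$genotypes, eff, seed = 13)
  d <- co$genotypes$dosage[1, ]
  blk <- my$truth$vsnp[[1]]$cpgs
  for (g in 0:2) {
    expect_gt(sum(d == g), 400)
    sds <- apply(my$meth$beta[blk, d == g, drop = FALSE], 1, sd)
    expect_true(all(abs(sds / c(0.02, 0.08, 0.15)[g + 1] - 1) < 0.10))
  }
})

test_that("allelic fragments appear only at heterozygous samples", {
  st <- simulate_study_cohort(seed = 17, fragment_depth = 12)
  r <- st$fragments$records
  expect_gt(nrow(r), 0)
  for (key in unique(paste(r$sample_id, r$snp_id))) {
    parts <- strsplit(key, " ")[[1]]
    d <- st$genotypes$dosage[match(parts[2], st$genotypes$snps$id),
                             match(parts[1], st$genotypes$samples)]
    expect_equal(unname(d), 1)
  }
})

test_that("zero fragment depth yields an empty fragment set", {
  st <- simulate_study_cohort(seed = 17, fragment_depth = 0)
  expect_equal(nrow(st$fragments$records), 0)
})

test_that("fragment allele balance is fair at high depth", {
  eff <- effect_config(n_snps = 2, n_cpgs = 4, maf_range = c(0.5, 0.5),
                       asm_effects = data.frame(snp = 1, cpg = 1,
                                                p_ref = 0.9, p_alt = 0.1))
  co <- simulate_cohort(20, 0, eff, seed = 23)
  my <- simulate_methylome(co$pedigree, co$genotypes, eff, seed = 23)
  fr <- simulate_allelic_fragments(co$genotypes, my$truth, my$meth,
                                   depth = 10000, seed = 23)
  r <- fr$records
  for (s in unique(r$sample_id)) {
    sub <- r[r$sample_id == s, ]
    bal <- mean(sub$allele == "alt")
    se <- sqrt(0.25 / nrow(sub))
    expect_lt(abs(bal - 0.5), 3 * se)
  }
})

test_that("invalid allele-frequency ranges are rejected", {
  expect_error(effect_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(effect_config(maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(effect_config(n_snps = 2, n_cpgs = 3,
                             cis_effects = data.frame(snp = 5, cpg = 1,
                                                      beta = 0.1)),
               "out of range")
})
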