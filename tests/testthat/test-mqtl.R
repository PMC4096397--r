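test_that("exact HWE test matches hand cases and the enumeration oracle", {
  expect_gt(hwe_test(25, 50, 25), 0.5)   # modal configuration
  expect_equal(hwe_test(0, 0, 10), 1)    # monomorphic
  expect_equal(hwe_test(10, 0, 0), 1)
  expect_equal(hwe_test(3, 0, 3), oracle_hwe(3, 0, 3), tolerance = 1e-12)
  # spot checks across the configuration space
  for (cfg in list(c(1, 1, 1), c(5, 0, 5), c(2, 8, 2), c(0, 4, 6),
                   c(7, 1, 0), c(4, 4, 4))) {
    expect_equal(hwe_test(cfg[1], cfg[2], cfg[3]),
                 oracle_hwe(cfg[1], cfg[2], cfg[3]),
                 tolerance = 1e-12)
  }
})

test_that("BH q-values reproduce the hand-computed example and edge cases", {
  expect_equal(bh_fdr(c(0.01, 0.04, 0.03, 0.005)),
               c(0.02, 0.04, 0.04, 0.02))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(0.123), 0.123)
  expect_equal(bh_fdr(numeric(0)), numeric(0))
  expect_error(bh_fdr(c(0.5, 1.2)), "p-values")
})

test_that("Mendel errors count impossible transmissions only", {
  # trio columns: father, mother, child
  ped <- pedigree_set(data.frame(
    sample_id = c("FA", "MO", "C1", "C2"),
    family_id = "f1",
    father_id = c(NA, NA, "FA", "FA"),
    mother_id = c(NA, NA, "MO", "MO"),
    sex = c(1L, 2L, 0L, 0L)))
  trios <- trio_set(ped)
  # SNP1: parents 0/0, child1 1 -> error; SNP2: 0/2 -> child must be 1;
  # SNP3: 1/1 -> anything goes; SNP4: missing parent -> untested
  d <- rbind(c(0, 0, 1, 0),
             c(0, 2, 1, 2),
             c(1, 1, 0, 2),
             c(NA, 0, 2, 0))
  g <- make_geno(d, samples = c("FA", "MO", "C1", "C2"))
  me <- mendel_errors(g, trios)
  expect_equal(me$n_errors, 2)  # SNP1/C1 and SNP2/C2
  expect_equal(me$n_tested, 6)
  expect_equal(me$per_family$error_rate, 2 / 6)
})

test_that("SNP QC applies MAF and HWE thresholds with the stated strictness", {
  # dosages [0,0,1,2]: alt freq 3/8 -> MAF 0.375, kept at 0.05
  d1 <- c(0, 0, 1, 2)
  # 4 samples with 8 alleles: single het -> alt freq 1/8 = 0.125; to get
  # MAF 0.04 use 25 samples with 2 alt alleles
  d2 <- c(rep(0, 23), 1, 1)
  g1 <- make_geno(rbind(d1), samples = sprintf("s%d", 1:4))
  q1 <- snp_qc(g1, NULL, maf_min = 0.05, hwe_min_p = 0)
  expect_equal(q1$stats$maf, 0.375)
  expect_true(q1$stats$kept)
  g2 <- make_geno(rbind(d2), samples = sprintf("s%d", 1:25))
  q2 <- suppressWarnings(snp_qc(g2, NULL, maf_min = 0.05, hwe_min_p = 0))
  expect_equal(q2$stats$maf, 0.04)
  expect_warning(
    expect_false(snp_qc(g2, NULL, 0.05, 0.001)$stats$kept), "removed")
  # HWE threshold is strict (>): all-het SNP has tiny exact p
  d3 <- rep(1, 30)
  g3 <- make_geno(rbind(d3), samples = sprintf("s%d", 1:30))
  p3 <- hwe_test(0, 30, 0)
  expect_warning(q3 <- snp_qc(g3, NULL, 0.05, p3), "removed")
  expect_false(q3$stats$kept)
})

test_that("cis pairing respects the 1 Mb window boundary", {
  beta <- matrix(runif(5 * 10, 0.2, 0.8), 5, 10)
  m <- make_meth(beta, pos = rep(2e6 + 1, 5) + (0:4) * 4)
  g <- make_geno(matrix(rep(c(0, 1, 2), length.out = 30), 3, 10,
                        byrow = TRUE),
                 pos = c(2e6 + 1 - 1e6 - 1,   # 1,000,001 bp away: out
                         2e6 + 1 - 1e6,        # exactly 1 Mb: in
                         2e6 + 5e5))
  sc <- mqtl_scan(m, g, NULL, window = 1e6, n_perm = 0)
  expect_false("snp001" %in% sc$snp_id[sc$cpg_pos == 2e6 + 1])
  expect_true("snp002" %in% sc$snp_id[sc$cpg_pos == 2e6 + 1])
  expect_true(all(abs(sc$distance) <= 1e6))
  # widening the window only adds pairs
  sc2 <- mqtl_scan(m, g, NULL, window = 2e6, n_perm = 0)
  expect_true(all(paste(sc$cpg_pos, sc$snp_id) %in%
                    paste(sc2$cpg_pos, sc2$snp_id)))
})

test_that("the regression slope is exact on a deterministic pair", {
  m <- make_meth(matrix(c(0.1, 0.2, 0.3), 1, 3), pos = 1501)
  g <- make_geno(matrix(c(0, 1, 2), 1, 3), pos = 1000)
  sc <- mqtl_scan(m, g, NULL, window = 1e6, n_perm = 0)
  expect_equal(sc$beta, 0.1)
  expect_equal(sc$distance, -501)
  expect_equal(sc$n, 3)
})

test_that("pairs with too few observations or constant genotype are skipped", {
  m <- make_meth(matrix(c(0.1, 0.2, 0.3, NA, NA, 0.5), 2, 3, byrow = TRUE),
                 pos = c(1001, 2001))
  g <- make_geno(rbind(c(0, 1, 2), c(1, 1, 1)), pos = c(1000, 1004))
  sc <- mqtl_scan(m, g, NULL, window = 1e6, n_perm = 0)
  expect_equal(nrow(sc), 1)   # only CpG1 x SNP1 is testable
  expect_equal(sc$cpg_pos, 1001)
  expect_equal(sc$snp_id, "snp001")
})

test_that("empirical p-values agree with asymptotic ones for unrelated samples", {
  set.seed(47)
  n <- 60
  d <- rbinom(n, 2, 0.4)
  y <- pmin(pmax(0.5 + 0.06 * d + rnorm(n, 0, 0.1), 0), 1)
  m <- make_meth(matrix(y, 1, n), pos = 1001,
                 samples = sprintf("u%02d", 1:n))
  g <- make_geno(matrix(d, 1, n), pos = 1000,
                 samples = sprintf("u%02d", 1:n))
  sc <- mqtl_scan(m, g, NULL, window = 1e6, n_perm = 2000, seed = 7)
  se_mc <- sqrt(sc$p_asym * (1 - sc$p_asym) / 2000)
  expect_lt(abs(sc$p_emp - sc$p_asym), 4 * se_mc + 0.01)
})

test_that("permutation p-values are deterministic given the seed", {
  st <- simulate_study_cohort(seed = 3)
  m <- preprocess_meth(st$meth)$meth
  a <- mqtl_scan(m, st$genotypes, st$pedigree, n_perm = 30, seed = 11)
  b <- mqtl_scan(m, st$genotypes, st$pedigree, n_perm = 30, seed = 11)
  expect_identical(a, b)
  c <- mqtl_scan(m, st$genotypes, st$pedigree, n_perm = 30, seed = 12)
  expect_false(identical(a$p_emp, c$p_emp))
})

test_that("family-aware permutation preserves family blocks", {
  st <- simulate_study_cohort(seed = 3)
  fam <- st$pedigree$samples$family_id
  set.seed(1)
  for (i in 1:20) {
    px <- pedmeth:::family_permutation(st$pedigree$samples$sample_id,
                                       st$pedigree)
    expect_equal(sort(px), seq_along(px))
    # members of one family land on the positions of exactly one family
    for (f in unique(fam)) {
      src <- unique(fam[px[fam == f]])
      expect_length(src, 1)
      expect_equal(sum(fam == src), sum(fam == f))
    }
  }
})

test_that("a destroying SNP shows the analytic negative cis slope", {
  eff <- effect_config(n_snps = 4, n_cpgs = 10, snp_cpg_sites = 1:2,
                       baseline_range = c(0.8, 0.8), resid_sd = 0.01,
                       read_depth = 500)
  co <- simulate_cohort(40, 2, eff, seed = 53)
  my <- simulate_methylome(co$pedigree, co$genotypes, eff, seed = 53)
  sc <- mqtl_scan(my$meth, co$genotypes, NULL, window = 1e6, n_perm = 0)
  for (r in seq_len(nrow(my$truth$snp_cpg))) {
    snp_id <- co$genotypes$snps$id[my$truth$snp_cpg$snp[r]]
    cpg_pos <- my$meth$sites$pos[my$truth$snp_cpg$cpg[r]]
    hit <- sc[sc$snp_id == snp_id & sc$cpg_pos == cpg_pos, ]
    expect_equal(hit$beta, -0.8 / 2, tolerance = 0.05)
  }
})
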