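test_that("variance regression matches the closed-form slope", {
  # build samples whose per-group variances are controlled
  set.seed(71)
  make_groups <- function(sds, n = 40) {
    d <- rep(0:2, each = n)
    y <- unlist(lapply(1:3, function(i) rnorm(n, 0.5, sds[i])))
    list(d = d, y = y)
  }
  g <- make_groups(c(0.05, 0.05, 0.05))
  vr <- variance_regression(g$y, g$d)
  expect_false(is.null(vr))
  # slope equals (var2 - var0)/2 exactly
  v <- vapply(0:2, function(k) var(g$y[g$d == k]), numeric(1))
  expect_equal(vr$slope, (v[3] - v[1]) / 2)
  # identical group variances give slope 0 and t 0
  vr0 <- variance_regression(rep(c(0.4, 0.6), 30), rep(0:2, each = 20))
  expect_equal(vr0$slope, 0)
  expect_equal(vr0$t, 0)
})

test_that("hand-set group variances give the documented slope", {
  # variances 0.01, 0.04, 0.09 on codes 0,1,2 -> slope 0.04
  vals <- c(0.01, 0.04, 0.09)
  scale_to_var <- function(x, v) 0.5 + (x - mean(x)) * sqrt(v / var(x))
  y <- c(scale_to_var(1:10, vals[1]), scale_to_var(1:10, vals[2]),
         scale_to_var(1:10, vals[3]))
  # scaled values can leave [0,1]; variance_regression takes raw vectors
  vr <- variance_regression(y, rep(0:2, each = 10))
  expect_equal(vr$slope, 0.04, tolerance = 1e-10)
  expect_equal(vr$group_var, vals, tolerance = 1e-10)
})

test_that("groups below the minimum size are untestable", {
  y <- c(rnorm(10, 0, 0.1), rnorm(1, 0, 0.1), rnorm(10, 0, 0.1))
  d <- c(rep(0, 10), 1, rep(2, 10))
  expect_null(variance_regression(y, d, min_group_n = 3))
  expect_null(variance_regression(rnorm(20), rep(c(0, 2), 10)))  # 2 groups
})

test_that("VMR assembly enforces run length, spacing and sign consistency", {
  mk_scores <- function(pos, t, slope = NULL) {
    if (is.null(slope)) slope <- sign(t) * 0.01
    k <- length(pos)
    data.frame(cpg_chrom = rep("chr1", k), cpg_pos = pos,
               snp_id = rep("snp001", k), snp_pos = rep(50, k),
               slope = slope, t = t, stringsAsFactors = FALSE)
  }
  # 4 qualifying CpGs: below the 5-CpG minimum
  expect_equal(nrow(call_vmrs(mk_scores(100 + 0:3 * 100, rep(3, 4)))), 0)
  # 5 qualifying CpGs but a 201-bp gap: run broken
  pos <- c(100, 200, 300, 501, 601)
  expect_equal(nrow(call_vmrs(mk_scores(pos, rep(3, 5)), max_spacing = 200)),
               0)
  # 200 bp spacing is inclusive
  expect_equal(nrow(call_vmrs(mk_scores(c(100, 300, 500, 700, 900),
                                        rep(3, 5)), max_spacing = 200)), 1)
  # 6 consistent CpGs at 100 bp: one VMR of 6
  v <- call_vmrs(mk_scores(100 + 0:5 * 100, rep(3, 6)))
  expect_equal(v$n_cpgs, 6)
  expect_equal(v$start, 100)
  expect_equal(v$end, 600)
  expect_equal(v$direction, 1)
  # a sign flip in the middle breaks the run
  v2 <- call_vmrs(mk_scores(100 + 0:5 * 100, c(3, 3, 3, -3, 3, 3)))
  expect_equal(nrow(v2), 0)
  # sub-threshold |t| in the middle breaks the run
  v3 <- call_vmrs(mk_scores(100 + 0:6 * 100, c(3, 3, 3, 1, 3, 3, 3)))
  expect_equal(nrow(v3), 0)
  expect_equal(nrow(call_vmrs(mk_scores(numeric(0), numeric(0))[0, ])), 0)
})

test_that("VMR clustering merges spans within the linkage distance", {
  mk_vmrs <- function(starts, ends, snp = NULL) {
    if (is.null(snp)) snp <- sprintf("snp%03d", seq_along(starts))
    data.frame(snp_id = snp, chrom = "chr1", start = starts, end = ends,
               n_cpgs = 5, direction = 1, mean_abs_t = 3,
               stringsAsFactors = FALSE)
  }
  # 99 kb apart: one cluster; 101 kb apart: two
  cl <- cluster_vmrs(mk_vmrs(c(1e5, 1e5 + 500 + 99e3), c(1e5 + 500, 1e5 + 1000 + 99e3)),
                     max_distance = 1e5)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$n_vmrs, 2)
  expect_equal(cl$n_snps, 2)
  cl2 <- cluster_vmrs(mk_vmrs(c(1e5, 1e5 + 500 + 101e3),
                              c(1e5 + 500, 1e5 + 1000 + 101e3)),
                      max_distance = 1e5)
  expect_equal(nrow(cl2), 2)
  # single VMR: one cluster
  expect_equal(nrow(cluster_vmrs(mk_vmrs(100, 600))), 1)
  # overlapping VMRs from different vSNPs merge
  cl3 <- cluster_vmrs(mk_vmrs(c(100, 400), c(600, 900)), max_distance = 0)
  expect_equal(nrow(cl3), 1)
  # input order invariance and idempotence
  v <- mk_vmrs(c(5e5, 100, 2e5), c(5e5 + 400, 500, 2e5 + 400))
  expect_identical(cluster_vmrs(v, 1e5), cluster_vmrs(v[c(2, 3, 1), ], 1e5))
  cl4 <- cluster_vmrs(v, 1e5)
  again <- cluster_vmrs(data.frame(snp_id = "x", chrom = cl4$chrom,
                                   start = cl4$start, end = cl4$end,
                                   n_cpgs = 1, direction = 1,
                                   mean_abs_t = 3), 1e5)
  expect_equal(nrow(again), nrow(cl4))
})

test_that("permutation FPR estimation is seeded and reproducible", {
  eff <- effect_config(n_snps = 3, n_cpgs = 12, maf_range = c(0.5, 0.5),
                       vsnp_effects = list(list(snp = 1, cpgs = 1:8,
                                                sigma = c(0.02, 0.08, 0.15))),
                       resid_sd = 0.02, read_depth = Inf)
  co <- simulate_cohort(100, 0, eff, seed = 73)
  my <- simulate_methylome(co$pedigree, co$genotypes, eff, seed = 73)
  a <- estimate_fpr_by_permutation(my$meth, co$genotypes, n_perm = 4,
                                   seed = 5)
  b <- estimate_fpr_by_permutation(my$meth, co$genotypes, n_perm = 4,
                                   seed = 5)
  expect_identical(a, b)
  expect_equal(a$observed, 1)
  expect_lte(mean(a$perm_counts), a$observed)
})
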