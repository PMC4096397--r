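cpgs <- function(pos, chrom = "chr1")
  data.frame(chrom = rep(chrom, length(pos)), pos = pos)

test_that("overlap fractions follow exact set arithmetic", {
  a <- cpgs(1:10 * 100)
  expect_equal(overlap_fractions(a, a)$frac_a_in_b, 1.0)
  expect_equal(overlap_fractions(a, a)$frac_b_in_a, 1.0)
  b <- cpgs(11:20 * 100)
  ov <- overlap_fractions(a, b)
  expect_equal(ov$n_intersect, 0)
  expect_equal(ov$frac_a_in_b, 0.0)
  # |A|=200, |B|=100, |A and B|=50 -> 0.25 and 0.50
  A <- cpgs(1:200 * 10)
  B <- cpgs(c(1:50 * 10, 100000 + 1:50 * 10))
  ov <- overlap_fractions(A, B)
  expect_equal(ov$n_intersect, 50)
  expect_equal(ov$frac_a_in_b, 0.25)
  expect_equal(ov$frac_b_in_a, 0.50)
  # empty denominators are NA, not 0
  ov0 <- overlap_fractions(cpgs(numeric(0)), b)
  expect_true(is.na(ov0$frac_a_in_b))
  expect_equal(ov0$frac_b_in_a, 0)
  # chromosome is part of the key
  expect_equal(overlap_fractions(cpgs(100), cpgs(100, "chr2"))$n_intersect, 0)
})

test_that("distance histograms bin absolute distances and sum to one", {
  assoc <- data.frame(distance = c(0, 0, 0))
  h <- distance_distribution(assoc, c(2e3, 1e5, 1e6))
  expect_equal(h$fraction, c(1, 0, 0))
  assoc <- data.frame(distance = c(1e3, -3e3, 150e3))
  h <- distance_distribution(assoc, c(2e3, 1e5, 1e6))
  expect_equal(h$fraction, rep(1 / 3, 3))
  expect_equal(sum(h$fraction), 1, tolerance = 1e-12)
  expect_error(distance_distribution(data.frame(distance = 2e6),
                                     c(2e3, 1e6)), "beyond")
  expect_equal(nrow(distance_distribution(assoc[0, , drop = FALSE],
                                          c(2e3))), 0)
})

test_that("region enrichment uses BED half-open semantics and label ratios", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\tpromoter",
               "chr1\t150\t400\tgene_body",
               "chr1\t1000\t2000\tgene_body"), bed)
  ann <- read_bed_annotation(bed)
  # 0-based start 100 covers 1-based positions 101..200
  inside <- annotate_enrichment(cpgs(101), cpgs(101), ann)
  expect_true("promoter" %in% inside$label)
  at_end <- annotate_enrichment(cpgs(201), cpgs(201), ann)
  expect_false("promoter" %in% at_end$label)  # end is exclusive
  expect_true("gene_body" %in% at_end$label)
  # significant = background -> every ratio 1
  bg <- cpgs(c(101, 160, 1500, 5000))
  eq <- annotate_enrichment(bg, bg, ann)
  expect_true(all(eq$ratio == 1))
  expect_true("intergenic" %in% eq$label)  # 5000 overlaps nothing
  # 20% of significant vs 10% of background in gene body -> ratio 2
  sig <- cpgs(c(1500, rep(5000, 4)))
  bg2 <- cpgs(c(1500, 1600, rep(5000, 18)))
  en <- annotate_enrichment(sig, bg2, ann)
  gb <- en[en$label == "gene_body", ]
  expect_equal(gb$frac_sig, 0.2)
  expect_equal(gb$frac_bg, 0.1)
  expect_equal(gb$ratio, 2.0)
  # significant CpGs outside the background are rejected
  expect_error(annotate_enrichment(cpgs(1), bg, ann), "background")
})

test_that("a CpG overlapping two labels counts once per label", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\tpromoter",
               "chr1\t150\t400\tgene_body"), bed)
  ann <- read_bed_annotation(bed)
  en <- annotate_enrichment(cpgs(160), cpgs(160), ann)
  expect_setequal(en$label, c("promoter", "gene_body"))
  expect_equal(en$n_sig, c(1, 1))
})

test_that("cross-method comparison separates SNP-CpGs when flagged", {
  mpo <- data.frame(chrom = "chr1", pos = c(100, 200, 300, 400),
                    heritable = c(TRUE, TRUE, TRUE, FALSE),
                    snp_cpg = c(TRUE, FALSE, FALSE, FALSE))
  mqtl <- data.frame(cpg_chrom = "chr1", cpg_pos = c(200, 500),
                     q = c(0.01, 0.01))
  asm <- data.frame(cpg_chrom = "chr1", cpg_pos = 100)
  cmp <- compare_methods(mpo, mqtl, asm, fdr = 0.05)
  expect_equal(cmp$mqtl_vs_mpo$n_intersect, 1)
  expect_equal(cmp$mqtl_vs_mpo$frac_a_in_b, 0.5)
  expect_equal(cmp$mqtl_vs_mpo_non_snp$n_intersect, 1)
  expect_equal(cmp$asm_vs_mpo_non_snp$n_intersect, 0)
})

test_that("truly genetic CpGs overlap heritable calls more than null CpGs do", {
  st <- simulate_study_cohort(seed = 83)
  m <- preprocess_meth(st$meth)$meth
  r <- run_mpo(m, trio_set(st$pedigree), st$genotypes, analysis_config())
  genetic <- which(st$truth$class %in% c("snp_cpg", "cis"))
  null_c <- which(st$truth$class == "null")
  her <- r$results[r$results$heritable, c("chrom", "pos")]
  ov_gen <- overlap_fractions(
    data.frame(chrom = "chr1", pos = st$meth$sites$pos[genetic]), her)
  ov_null <- overlap_fractions(
    data.frame(chrom = "chr1", pos = st$meth$sites$pos[null_c]), her)
  expect_gt(ov_gen$frac_a_in_b, ov_null$frac_a_in_b)
})
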