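mk_truth <- function(chrom, pos, a, b, geno, samples = colnames(geno)) {
  truth_table(data.frame(marker_id = sprintf("m%d", seq_along(pos)),
                         chrom = chrom, pos = pos, allele_a = a, allele_b = b,
                         stringsAsFactors = FALSE),
              matrix(geno, nrow = length(pos),
                     dimnames = list(NULL, samples)))
}

test_that("truth markers match on position and allele set, with strand rules", {
  t <- mk_vt(rbind(c("0/1", "1/1"), c("0/0", "0/1"), c("0/1", "0/0"),
                   c("0/1", "0/1")),
             pos = c(10L, 20L, 30L, 40L),
             ref = c("A", "A", "A", "A"), alt = c("G", "G", "C", "T"))
  tr <- mk_truth("Chr01", c(10L, 20L, 30L, 40L),
                 a = c("A", "T", "A", "A"), b = c("G", "C", "C", "T"),
                 geno = c("AG", "CC", "AA", "AT", "GG", "TT", "AC", "AT"),
                 samples = c("s01", "s02"))
  m <- match_truth(t, tr)
  # m1: direct allele match; m2: reverse complement of A/G -> excluded;
  # m3 direct; m4: A/T palindromic -> excluded
  expect_setequal(m$pairs$marker_id, c("m1", "m3"))
  expect_setequal(m$strand_ambiguous, c("m2", "m4"))
  # truth "AG" at an A->G site recodes to 0/1, "GG" to 1/1
  expect_equal(unname(m$truth_geno[m$pairs$marker_id == "m1", ]),
               c("0/1", "1/1"))
  # marker with alleles absent from the site is unmatched, not fatal
  t2 <- mk_vt(matrix(c("0/1", "1/1"), 1, 2), pos = 10L, ref = "A", alt = "G")
  tr2 <- mk_truth("Chr01", 10L, "A", "C", c("AA", "AC"), c("s01", "s02"))
  m2 <- match_truth(t2, tr2)
  expect_equal(nrow(m2$pairs), 0)
  expect_equal(m2$n_unmatched, 1)
})

test_that("genotyping accuracy is the percent identical of comparable pairs", {
  t <- mk_vt(rbind(c("0/1", "0/0"), c("1/1", "0/1"), c("0/0", NA),
                   c("0/1", "1/1")),
             pos = c(10L, 20L, 30L, 40L))
  # s01 truth column AG,GG,AA,GG: agrees at 3 of 4 pairs;
  # s02 column AA,AG,AA,GG: 3 comparable pairs (one call missing)
  tr <- mk_truth("Chr01", c(10L, 20L, 30L, 40L), "A", "G",
                 c("AG", "GG", "AA", "GG", "AA", "AG", "AA", "GG"),
                 samples = c("s01", "s02"))
  rep <- genotyping_accuracy(match_truth(t, tr))
  ps <- rep$per_sample
  expect_equal(ps$accuracy[ps$sample == "s01"], 75)
  expect_equal(ps$n_comparable[ps$sample == "s02"], 3)
  expect_equal(rep$n_common_positions, 4)
  expect_true(rep$overall > 0 && rep$overall <= 100)
})

test_that("a table scored against its own genotypes is 100% accurate", {
  set.seed(8)
  cfg <- simulation_config(seed = 8, n_sites = 300)
  sim <- simulate_truth(cfg)
  chip <- simulate_chip(sim, 100, chip_error_rate = 0, seed = 9)
  rep <- genotyping_accuracy(match_truth(sim$truth, chip))
  expect_equal(rep$overall, 100)
  expect_true(all(rep$per_sample$accuracy == 100))
})

test_that("accuracy is invariant to site and sample order", {
  set.seed(12)
  g <- matrix(sample(c("0/0", "0/1", "1/1"), 40, replace = TRUE), 20, 2)
  t <- mk_vt(g)
  tr_geno <- matrix(sample(c("AA", "AG", "GG"), 40, replace = TRUE), 20, 2,
                    dimnames = list(NULL, c("s01", "s02")))
  tr <- mk_truth("Chr01", t$sites$pos, "A", "G", tr_geno)
  r1 <- genotyping_accuracy(match_truth(t, tr))
  t_shuf <- subset_samples(t, rev(t$samples))
  r2 <- genotyping_accuracy(match_truth(t_shuf, tr))
  expect_equal(sort(r1$per_sample$accuracy), sort(r2$per_sample$accuracy))
  expect_equal(r1$overall, r2$overall)
})

test_that("sample mismatch flagging is thresholded and monotone", {
  rep <- structure(list(per_sample = data.frame(
    sample = c("a", "b", "c"), n_common = 10, n_comparable = 10,
    n_identical = c(10, 9, 6), accuracy = c(99, 95, 60))),
    class = "accuracy_report")
  expect_equal(flag_sample_mismatches(rep, 90), "c")
  expect_equal(flag_sample_mismatches(rep, 0), character(0))
  f96 <- flag_sample_mismatches(rep, 96)
  expect_true(all(flag_sample_mismatches(rep, 90) %in% f96))
})

test_that("repeatability fractions behave at the identity and disjoint limits", {
  set.seed(3)
  g <- matrix(sample(c("0/0", "0/1", "1/1", NA), 30, replace = TRUE), 10, 3)
  t <- mk_vt(g)
  r <- repeatability(t, t)
  expect_equal(r$shared_fraction, 1)
  expect_equal(r$genotype_concordant_fraction, 1)
  t2 <- mk_vt(g, pos = t$sites$pos + 1000L)
  r2 <- repeatability(t, t2)
  expect_equal(r2$shared_fraction, 0)
  expect_equal(r2$genotype_concordant_fraction, 0)
  expect_error(repeatability(t, mk_vt(g[, 1:2])), "roster")
})

test_that("repeatability counts full genotype-vector identity", {
  first <- mk_vt(rbind(c("0/1", "0/0"), c("1/1", "0/1"), c("0/0", "0/0")),
                 pos = c(10L, 20L, 30L))
  g2 <- rbind(c("0/1", "0/0"),    # shared, identical
              c("1/1", "1/1"),    # shared, one sample differs
              c("0/1", "0/1"))    # not shared
  second <- mk_vt(g2, pos = c(10L, 20L, 50L))
  r <- repeatability(first, second)
  expect_equal(r$shared_fraction, 2 / 3)
  expect_equal(r$genotype_concordant_fraction, 1 / 3)
})

test_that("accuracy-count regression handles exact, degenerate and error cases", {
  pts <- data.frame(n_snps = c(1, 2, 3), accuracy = c(99, 98, 97))
  r <- accuracy_vs_count_regression(pts)
  expect_equal(r$slope, -1)
  expect_equal(r$r_squared, 1)
  expect_equal(unname(r$points$residual), c(0, 0, 0))
  flat <- data.frame(n_snps = c(1, 2, 3), accuracy = c(95, 95, 95))
  expect_equal(accuracy_vs_count_regression(flat)$r_squared, 0)
  expect_error(accuracy_vs_count_regression(
    data.frame(n_snps = c(2, 2, 2), accuracy = c(1, 2, 3))), "undefined|equal")
  expect_error(accuracy_vs_count_regression(
    data.frame(n_snps = 1:2, accuracy = 1:2)), "3 points")
  # residual sign: above the fitted line is positive
  pts2 <- data.frame(n_snps = c(1, 2, 3, 4), accuracy = c(100, 98, 97, 96))
  r2 <- accuracy_vs_count_regression(pts2)
  expect_gt(r2$points$residual[1], 0)
})
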