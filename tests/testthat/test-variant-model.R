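test_that("read_vcf parses records, normalizes phase/order and missing calls", {
  path <- write_vcf_fixture(c(
    "Chr01\t100\t.\tA\tG\t45.2\t.\t.\tGT:DP\t0|1:10\t1/0:12",
    "Chr01\t200\t.\tT\tC\t30\t.\t.\tGT\t0/0\t./.",
    "Chr02\t50\t.\tG\tA,T\t12\t.\t.\tGT\t1/2\t0/0"))
  t <- read_vcf(path)
  expect_equal(n_sites(t), 3)
  expect_equal(t$samples, c("s01", "s02"))
  # phase and allele order both collapse to the same unordered call
  expect_equal(unname(t$geno[1, ]), c("0/1", "0/1"))
  # "./." is missing, site retained
  expect_true(is.na(t$geno[2, "s02"]))
  expect_equal(t$geno[2, "s01"], c(s01 = "0/0"))
  # multiallelic record preserved with kind set
  expect_equal(t$sites$kind, c("SNP", "SNP", "SNP"))
  expect_equal(t$sites$alt[3], "A,T")
  expect_equal(t$geno[3, "s01"], c(s01 = "1/2"))
  expect_equal(t$sites$qual, c(45.2, 30, 12))
})

test_that("read_vcf restricts to a sample subset in the requested order", {
  path <- write_vcf_fixture(
    "Chr01\t100\t.\tA\tG\t45\t.\t.\tGT\t0/1\t1/1", c("sa", "sb"))
  t <- read_vcf(path, sample_subset = c("sb"))
  expect_equal(t$samples, "sb")
  expect_equal(unname(t$geno[1, ]), "1/1")
  expect_error(read_vcf(path, sample_subset = "nope"), "not in roster")
})

test_that("read_vcf rejects duplicates and missing GT, sorts unsorted input", {
  dup <- write_vcf_fixture(c(
    "Chr01\t100\t.\tA\tG\t45\t.\t.\tGT\t0/1\t1/1",
    "Chr01\t100\t.\tA\tG\t50\t.\t.\tGT\t0/1\t1/1"))
  expect_error(read_vcf(dup), "duplicate")
  nogt <- write_vcf_fixture("Chr01\t100\t.\tA\tG\t45\t.\t.\tDP\t10\t12")
  expect_error(read_vcf(nogt), "GT")
  uns <- write_vcf_fixture(c(
    "Chr01\t200\t.\tA\tG\t45\t.\t.\tGT\t0/1\t1/1",
    "Chr01\t100\t.\tT\tC\t45\t.\t.\tGT\t0/0\t0/1"))
  expect_warning(t <- read_vcf(uns), "sort")
  expect_equal(t$sites$pos, c(100L, 200L))
})

test_that("write_vcf round-trips and is byte-stable", {
  g <- matrix(c("0/1", NA, "1/1", "0/0", "0/0", "0/1"), nrow = 3, byrow = TRUE)
  t <- mk_vt(g, pos = c(10L, 20L, 30L), qual = c(31.5, 29.9, NA))
  p1 <- tempfile(fileext = ".vcf")
  write_vcf(t, p1)
  t2 <- read_vcf(p1)
  expect_identical(t2$sites, t$sites)
  expect_identical(unname(t2$geno), unname(t$geno))
  p2 <- tempfile(fileext = ".vcf")
  write_vcf(t2, p2)
  expect_identical(readLines(p1), readLines(p2))
  # missing call serialized as ./.
  expect_true(any(grepl("\\./\\.", readLines(p1))))
})

test_that("an empty table writes a header-only VCF that reads back empty", {
  t <- mk_vt(matrix(character(0), 0, 2))
  p <- tempfile(fileext = ".vcf")
  write_vcf(t, p)
  lines <- readLines(p)
  expect_true(all(startsWith(lines, "#")))
  t2 <- read_vcf(p)
  expect_equal(n_sites(t2), 0)
  expect_equal(t2$samples, t$samples)
})

test_that("decompose splits an MNP into per-base SNPs with projected genotypes", {
  t <- variant_table("s1",
                     data.frame(chrom = "Chr01", pos = 100L, ref = "AT",
                                alt = "GC", qual = 77, stringsAsFactors = FALSE),
                     matrix("1/1", 1, 1))
  d <- decompose(t)
  expect_equal(d$sites$pos, c(100L, 101L))
  expect_equal(d$sites$ref, c("A", "T"))
  expect_equal(d$sites$alt, c("G", "C"))
  expect_equal(d$sites$kind, c("SNP", "SNP"))
  expect_equal(d$sites$qual, c(77, 77))   # inherited
  expect_equal(unname(d$geno[, 1]), c("1/1", "1/1"))
})

test_that("primitive SNP and pure-deletion records pass through decompose", {
  t <- variant_table("s1",
                     data.frame(chrom = "Chr01", pos = c(10L, 20L),
                                ref = c("A", "ATG"), alt = c("G", "A"),
                                qual = 50, stringsAsFactors = FALSE),
                     matrix(c("0/1", "0/1"), 2, 1))
  d <- decompose(t)
  expect_identical(d$sites[, c("chrom", "pos", "ref", "alt")],
                   t$sites[, c("chrom", "pos", "ref", "alt")])
  expect_identical(d$geno, t$geno)
  expect_equal(d$sites$kind, c("SNP", "INDEL"))
})

test_that("decompose is idempotent and preserves missingness at untouched SNPs", {
  set.seed(42)
  g <- matrix(sample(c("0/0", "0/1", "1/1", NA), 30, replace = TRUE), 10, 3)
  t <- variant_table(c("a", "b", "c"),
                     data.frame(chrom = "Chr01", pos = seq(10, 100, 10),
                                ref = c(rep("A", 8), "AT", "CCA"),
                                alt = c(rep("G", 8), "GC", "TCG"),
                                qual = 50, stringsAsFactors = FALSE), g)
  d1 <- decompose(t)
  d2 <- decompose(d1)
  expect_identical(d1$sites, d2$sites)
  expect_identical(d1$geno, d2$geno)
  # untouched SNP records keep their exact missing/non-missing pattern
  snp_keys <- site_keys(t)[t$sites$kind == "SNP"]
  m1 <- t$geno[match(snp_keys, site_keys(t)), ]
  m2 <- d1$geno[match(snp_keys, site_keys(d1)), ]
  expect_identical(is.na(m1), is.na(m2))
  expect_identical(m1, m2)
})

test_that("symbolic alternate alleles are skipped with a warning", {
  t <- variant_table("s1",
                     data.frame(chrom = "Chr01", pos = c(10L, 20L),
                                ref = c("A", "AT"), alt = c("<DEL>", "GC"),
                                qual = 50, kind = c("COMPLEX", "MNP"),
                                stringsAsFactors = FALSE),
                     matrix(c("0/1", "1/1"), 2, 1))
  expect_warning(d <- decompose(t), "symbolic")
  expect_false(any(grepl("<", d$sites$alt, fixed = TRUE)))
  expect_equal(n_sites(d), 2)  # the MNP became two SNPs
})

test_that("truth tables parse, normalize letter order and reject bad letters", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("marker_id\tchrom\tpos\tallele_a\tallele_b\ts1\ts2\ts3",
               "m1\tChr01\t500\tA\tG\tAG\tGG\tNA",
               "m2\tChr01\t600\tA\tG\tGA\tAA\tAG"), p)
  tt <- read_truth_table(p)
  expect_equal(unname(tt$geno[1, ]), c("AG", "GG", NA))
  # "GA" and "AG" store identically
  expect_equal(unname(tt$geno[2, "s1"]), unname(tt$geno[2, "s3"]))
  writeLines(c("marker_id\tchrom\tpos\tallele_a\tallele_b\ts1",
               "m1\tChr01\t500\tA\tG\tAC"), p)
  expect_error(read_truth_table(p), "m1.*s1|outside")
  # round trip
  writeLines(c("marker_id\tchrom\tpos\tallele_a\tallele_b\ts1\ts2",
               "m1\tChr01\t500\tA\tG\tAG\tNA"), p)
  tt <- read_truth_table(p)
  p2 <- tempfile(fileext = ".tsv")
  write_truth_table(tt, p2)
  tt2 <- read_truth_table(p2)
  expect_identical(tt$markers, tt2$markers)
  expect_identical(tt$geno, tt2$geno)
})

test_that("variant_table enforces uniqueness and normalize_gt handles edge forms", {
  expect_error(
    variant_table("s1",
                  data.frame(chrom = "Chr01", pos = c(10L, 10L), ref = "A",
                             alt = "G", qual = 50, stringsAsFactors = FALSE),
                  matrix("0/1", 2, 1)),
    "duplicate")
  expect_equal(normalize_gt(c("0|1", "1/0", "2/1", ".", "./.", ".|.", NA)),
               c("0/1", "0/1", "1/2", NA, NA, NA, NA))
})
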