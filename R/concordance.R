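#' Match called SNPs to array truth markers
#'
#' Pairs biallelic SNP sites to truth markers on `(chrom, pos)`. A pair is
#' kept when the marker allele set equals the site's `{ref, alt}`. When the
#' marker alleles instead equal the reverse complement of `{ref, alt}` the
#' marker is flagged strand-ambiguous and excluded from scoring rather than
#' guessed; A/T and C/G sites are their own reverse complement and are always
#' excluded. Truth nucleotide genotypes are recoded to allele indices against
#' the VCF ref/alt.
#'
#' @param table A [variant_table()] (non-biallelic sites are ignored).
#' @param truth A `truth_table` (see [read_truth_table()]).
#' @return A `matched_pairs` object: `pairs` data frame, aligned `vcf_geno`
#'   and `truth_geno` index-genotype matrices over the shared `samples`,
#'   `strand_ambiguous` marker ids, and `n_unmatched` markers without a
#'   co-located, allele-compatible site.
#' @export
match_truth <- function(table, truth) {
  samples <- intersect(table$samples, truth$samples)
  if (length(samples) == 0) stop("no shared samples between calls and truth")
  bi <- filter_biallelic_snps(table)
  site_pos <- paste(bi$sites$chrom, bi$sites$pos, sep = ":")
  mk_pos <- paste(truth$markers$chrom, truth$markers$pos, sep = ":")
  idx <- match(mk_pos, site_pos)
  hit <- !is.na(idx)

  ref <- bi$sites$ref[idx[hit]]
  alt <- bi$sites$alt[idx[hit]]
  aa <- truth$markers$allele_a[hit]
  ab <- truth$markers$allele_b[hit]
  same <- (aa == ref & ab == alt) | (aa == alt & ab == ref)
  rc_ref <- revcomp_base(ref)
  rc_alt <- revcomp_base(alt)
  rc <- (aa == rc_ref & ab == rc_alt) | (aa == rc_alt & ab == rc_ref)

  ambiguous <- hit
  ambiguous[hit] <- same & rc          # palindromic allele pair (A/T, C/G)
  flagged <- hit
  flagged[hit] <- (!same & rc)         # opposite-strand marker
  matched <- hit
  matched[hit] <- same & !rc

  mi <- which(matched)
  si <- idx[mi]
  vcf_geno <- bi$geno[si, match(samples, bi$samples), drop = FALSE]
  tg <- truth$geno[mi, match(samples, truth$samples), drop = FALSE]
  truth_geno <- recode_truth_geno(tg, bi$sites$ref[si], bi$sites$alt[si])
  pairs <- data.frame(marker_id = truth$markers$marker_id[mi],
                      chrom = bi$sites$chrom[si], pos = bi$sites$pos[si],
                      ref = bi$sites$ref[si], alt = bi$sites$alt[si],
                      stringsAsFactors = FALSE)
  structure(list(pairs = pairs, vcf_geno = vcf_geno, truth_geno = truth_geno,
                 samples = samples,
                 strand_ambiguous = truth$markers$marker_id[flagged | ambiguous],
                 n_unmatched = sum(!hit) + sum(!same & !rc)),
            class = "matched_pairs")
}

revcomp_base <- function(x) chartr("ACGT", "TGCA", x)

recode_truth_geno <- function(geno, ref, alt) {
  out <- matrix(NA_character_, nrow = nrow(geno), ncol = ncol(geno),
                dimnames = dimnames(geno))
  for (j in seq_len(ncol(geno))) {
    g <- geno[, j]
    ok <- !is.na(g)
    a <- ifelse(substr(g[ok], 1, 1) == ref[ok], 0L, 1L)
    b <- ifelse(substr(g[ok], 2, 2) == ref[ok], 0L, 1L)
    out[ok, j] <- paste0(pmin(a, b), "/", pmax(a, b))
  }
  out
}

#' Genotyping accuracy against matched truth markers
#'
#' Per sample, accuracy is 100 times the fraction of matched pairs where
#' both the called and the truth genotype are non-missing and identical,
#' over the pairs where both are non-missing. Pairs with a missing call on
#' either side are excluded from numerator and denominator and counted
#' separately; a sample with zero comparable pairs has accuracy `NA`
#' (undefined, not 0). The overall accuracy pools all comparable
#' (site, sample) cells.
#'
#' @param matched A `matched_pairs` object from [match_truth()].
#' @return An `accuracy_report`: `per_sample` data frame (`sample`,
#'   `n_common`, `n_comparable`, `n_identical`, `accuracy`), `overall`
#'   pooled accuracy (percent), `n_common_positions`.
#' @export
genotyping_accuracy <- function(matched) {
  stopifnot(inherits(matched, "matched_pairs"))
  if (nrow(matched$pairs) == 0) stop("no matched pairs to score")
  v <- matched$vcf_geno
  t <- matched$truth_geno
  comparable <- !is.na(v) & !is.na(t)
  identical_ <- comparable & v == t
  per_sample <- data.frame(
    sample = matched$samples,
    n_common = nrow(matched$pairs),
    n_comparable = colSums(comparable),
    n_identical = colSums(identical_),
    stringsAsFactors = FALSE, row.names = NULL
  )
  per_sample$accuracy <- ifelse(per_sample$n_comparable > 0,
                                100 * per_sample$n_identical / per_sample$n_comparable,
                                NA_real_)
  structure(list(per_sample = per_sample,
                 overall = 100 * sum(identical_) / sum(comparable),
                 n_common_positions = nrow(matched$pairs),
                 n_missing_pairs = sum(!comparable)),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("accuracy_report: %d common positions, overall %.2f%%\n",
              x$n_common_positions, x$overall))
  print(x$per_sample, row.names = FALSE)
  invisible(x)
}

#' Flag samples whose genotypes disagree with the truth set
#'
#' Samples with accuracy below the threshold are candidates for labeling
#' errors or sample swaps and are listed for exclusion.
#'
#' @param report An `accuracy_report` from [genotyping_accuracy()].
#' @param threshold Accuracy threshold in percent, default 90.
#' @return Character vector of flagged sample ids.
#' @export
flag_sample_mismatches <- function(report, threshold = 90) {
  stopifnot(inherits(report, "accuracy_report"))
  ps <- report$per_sample
  ps$sample[!is.na(ps$accuracy) & ps$accuracy < threshold]
}

#' Inter-experiment repeatability of SNP detection and genotyping
#'
#' Compares a second, independent experiment against a first one over the
#' same genotypes: `shared_fraction` is the fraction of the second
#' experiment's sites found at the same `(chrom, pos, ref, alt)` in the
#' first; `genotype_concordant_fraction` is the fraction of the second
#' experiment's sites that are shared *and* carry an identical full genotype
#' vector (missing patterns included) — the stricter, headline quantity.
#'
#' @param first,second [variant_table()]s with identical rosters.
#' @return A list with `shared_fraction`, `genotype_concordant_fraction` and
#'   `per_sample` (data frame of per-sample call concordance over shared
#'   sites).
#' @export
repeatability <- function(first, second) {
  if (!identical(first$samples, second$samples)) {
    stop("rosters differ between the two experiments")
  }
  n2 <- n_sites(second)
  if (n2 == 0) stop("second experiment has no sites")
  k1 <- site_keys(first)
  k2 <- site_keys(second)
  idx <- match(k2, k1)
  shared <- !is.na(idx)
  sig1 <- geno_signature(first$geno)
  sig2 <- geno_signature(second$geno)
  concordant <- shared & sig2 == sig1[ifelse(shared, idx, 1L)]

  g1 <- first$geno[idx[shared], , drop = FALSE]
  g2 <- second$geno[shared, , drop = FALSE]
  cell_eq <- (is.na(g1) & is.na(g2)) | (!is.na(g1) & !is.na(g2) & g1 == g2)
  per_sample <- data.frame(sample = first$samples,
                           concordance = if (sum(shared) > 0)
                             colMeans(cell_eq) else NA_real_,
                           stringsAsFactors = FALSE, row.names = NULL)
  list(shared_fraction = sum(shared) / n2,
       genotype_concordant_fraction = sum(concordant) / n2,
       per_sample = per_sample)
}

#' OLS regression of genotyping accuracy on the number of SNPs detected
#'
#' Quantifies the quantity/quality trade-off across calling modalities:
#' ordinary least squares of accuracy (percent) on SNP count. Residuals are
#' signed so that positive means better accuracy than predicted ("above the
#' line" = better-performing modality).
#'
#' @param points Data frame with columns `n_snps` and `accuracy` (>= 3 rows),
#'   optionally `modality` labels.
#' @return List with `slope`, `intercept`, `r_squared` and `points` (the
#'   input with fitted values and signed residuals).
#' @export
accuracy_vs_count_regression <- function(points) {
  stopifnot(is.data.frame(points), all(c("n_snps", "accuracy") %in% names(points)))
  if (nrow(points) < 3) stop("need at least 3 points for the regression")
  if (stats::var(points$n_snps) == 0) {
    stop("all n_snps values are equal; slope undefined")
  }
  fit <- stats::lm(accuracy ~ n_snps, data = points)
  out <- points
  out$fitted <- as.numeric(stats::fitted(fit))
  out$residual <- points$accuracy - out$fitted
  ss_tot <- sum((points$accuracy - mean(points$accuracy))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - sum(out$residual^2) / ss_tot
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2, points = out)
}
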