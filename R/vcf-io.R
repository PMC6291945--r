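#' Read a VCF file into a variant table
#'
#' Parses a VCF v4.x file (plain or gzip-compressed) via \pkg{vcfR} and keeps
#' only what the pipeline consumes: site coordinates, alleles, QUAL and the
#' GT FORMAT field. Phase separators are discarded (`"0|1"` and `"1/0"` both
#' become `"0/1"`) and `"./."`-style calls become missing. FORMAT fields
#' other than GT are dropped; no downstream operation consumes them.
#'
#' @param path Path to a VCF file.
#' @param sample_subset Optional character vector of sample ids; the returned
#'   roster is restricted to (and ordered as) this subset.
#' @return A [variant_table()].
#' @details Unsorted input is sorted with a warning. A duplicated
#'   `(chrom, pos, ref, alt)` record or a missing GT FORMAT field is an error.
#' @export
read_vcf <- function(path, sample_subset = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  gt_slot <- v@gt
  if (is.null(gt_slot) || ncol(gt_slot) < 2) {
    stop("VCF has no genotype columns: ", path)
  }
  samples <- colnames(gt_slot)[-1]
  if (nrow(fix) == 0) {
    tab <- empty_variant_table(samples)
  } else {
    fmt <- gt_slot[, "FORMAT"]
    if (!all(grepl("(^|:)GT($|:)", fmt))) {
      stop("record(s) without GT in FORMAT field: ", path)
    }
    raw <- vcfR::extract.gt(v, element = "GT")
    geno <- matrix(normalize_gt(raw), nrow = nrow(raw))
    qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
    sites <- data.frame(chrom = fix[, "CHROM"],
                        pos = as.integer(fix[, "POS"]),
                        ref = fix[, "REF"], alt = fix[, "ALT"],
                        qual = qual, stringsAsFactors = FALSE)
    ord <- order(sites$chrom, sites$pos, sites$ref, sites$alt)
    if (any(ord != seq_along(ord))) {
      warning("VCF records were not coordinate-sorted; sorting: ", path)
    }
    key <- paste(sites$chrom, sites$pos, sites$ref, sites$alt, sep = ":")
    if (anyDuplicated(key)) {
      stop("duplicate VCF record: ", key[duplicated(key)][1], " in ", path)
    }
    tab <- variant_table(samples, sites, geno)
  }
  if (!is.null(sample_subset)) tab <- subset_samples(tab, sample_subset)
  tab
}

#' Write a variant table as a GT-only VCF v4.2 file
#'
#' Emits unphased `"a/b"` genotypes with `a <= b` and `"./."` for missing
#' calls, so `read_vcf(write_vcf(t))` reproduces `t` and a second write of a
#' re-read file is byte-identical.
#'
#' @param table A [variant_table()].
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(table, path) {
  s <- table$sites
  header <- c("##fileformat=VCFv4.2",
              "##source=consensnp",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", table$samples), collapse = "\t"))
  if (nrow(s) > 0) {
    qual <- ifelse(is.na(s$qual), ".", as.character(s$qual))
    g <- table$geno
    g[is.na(g)] <- "./."
    body <- paste(s$chrom, s$pos, ".", s$ref, s$alt, qual, ".", ".", "GT",
                  apply_paste_rows(g), sep = "\t")
  } else {
    body <- character(0)
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

apply_paste_rows <- function(m) {
  if (ncol(m) == 1) return(m[, 1])
  do.call(paste, c(as.data.frame(m, stringsAsFactors = FALSE), sep = "\t"))
}

#' Read an array-genotype truth table
#'
#' The truth table stands in for an SNP-array genotyping reference: a
#' tab-delimited file with header columns `marker_id`, `chrom`, `pos`,
#' `allele_a`, `allele_b`, followed by one column per sample holding
#' two-letter nucleotide genotypes (`"AG"`) or `"NA"`. Letter order is
#' normalized alphabetically on read, so `"GA"` and `"AG"` are the same call.
#'
#' @param path Path to the TSV file.
#' @return A `truth_table`: list with `markers` (data frame), `geno`
#'   (character matrix of normalized two-letter genotypes or `NA`) and
#'   `samples`.
#' @details A genotype letter outside `{allele_a, allele_b}` is an error
#'   naming the marker and sample.
#' @export
read_truth_table <- function(path) {
  d <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  need <- c("marker_id", "chrom", "pos", "allele_a", "allele_b")
  if (!all(need %in% names(d))) {
    stop("truth table must have header columns: ", paste(need, collapse = ", "))
  }
  samples <- setdiff(names(d), need)
  markers <- data.frame(marker_id = d$marker_id, chrom = d$chrom,
                        pos = as.integer(d$pos), allele_a = d$allele_a,
                        allele_b = d$allele_b, stringsAsFactors = FALSE)
  geno <- as.matrix(d[, samples, drop = FALSE])
  geno[geno %in% c("NA", "", ".")] <- NA_character_
  geno <- matrix(normalize_nuc_gt(geno), nrow = nrow(geno),
                 dimnames = list(NULL, samples))
  truth_table(markers, geno)
}

normalize_nuc_gt <- function(x) {
  out <- rep(NA_character_, length(x))
  ok <- !is.na(x)
  bad <- ok & !grepl("^[ACGT]{2}$", x)
  if (any(bad)) stop("malformed truth genotype: ", x[bad][1])
  a <- substr(x[ok], 1, 1)
  b <- substr(x[ok], 2, 2)
  out[ok] <- paste0(pmin(a, b), pmax(a, b))
  out
}

#' Construct a truth table object
#' @param markers Data frame with columns `marker_id`, `chrom`, `pos`,
#'   `allele_a`, `allele_b`.
#' @param geno Character matrix of normalized two-letter genotypes (`NA`
#'   missing), one column per sample.
#' @return A `truth_table` object.
#' @export
truth_table <- function(markers, geno) {
  stopifnot(nrow(markers) == nrow(geno))
  samples <- colnames(geno)
  if (any(markers$allele_a == markers$allele_b)) {
    stop("marker with identical alleles: ",
         markers$marker_id[markers$allele_a == markers$allele_b][1])
  }
  for (j in seq_along(samples)) {
    g <- geno[, j]
    ok <- !is.na(g)
    legal <- paste0(pmin(markers$allele_a, markers$allele_b),
                    pmax(markers$allele_a, markers$allele_b))
    hom_a <- paste0(markers$allele_a, markers$allele_a)
    hom_b <- paste0(markers$allele_b, markers$allele_b)
    bad <- ok & !(g == legal | g == hom_a | g == hom_b)
    if (any(bad)) {
      i <- which(bad)[1]
      stop(sprintf("genotype %s at marker %s uses letters outside {%s,%s} for sample %s",
                   g[i], markers$marker_id[i], markers$allele_a[i],
                   markers$allele_b[i], samples[j]))
    }
  }
  structure(list(markers = markers, geno = geno, samples = samples),
            class = "truth_table")
}

#' Write a truth table to TSV
#' @param truth A `truth_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(truth, path) {
  g <- truth$geno
  g[is.na(g)] <- "NA"
  d <- cbind(truth$markers, as.data.frame(g, stringsAsFactors = FALSE))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.truth_table <- function(x, ...) {
  cat(sprintf("truth_table: %d markers x %d samples\n",
              nrow(x$markers), length(x$samples)))
  invisible(x)
}
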