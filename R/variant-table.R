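#' Variant table: biallelic/multiallelic sites with per-sample genotype calls
#'
#' A `variant_table` is the package's central container: an ordered roster of
#' sample ids together with variant sites sorted by (chrom, pos), each site
#' carrying one unordered, unphased genotype call per sample. Genotype calls
#' are stored as strings `"a/b"` with allele indices `a <= b` (0 = reference,
#' 1, 2, ... = alternates) or `NA` for a missing call. Phase is discarded on
#' input: the pipeline compares genotypes, never haplotypes.
#'
#' @param samples Character vector of sample ids (roster order is meaningful).
#' @param sites Data frame with columns `chrom` (character), `pos` (1-based
#'   integer), `ref`, `alt` (alternate alleles, comma-separated if several),
#'   `qual` (numeric site quality, `NA` if absent) and optionally `kind`
#'   (recomputed when missing).
#' @param geno Character matrix, `nrow(sites)` x `length(samples)`, of
#'   normalized genotype strings or `NA`.
#' @return An object of class `variant_table` with elements `samples`,
#'   `sites` and `geno`.
#' @export
variant_table <- function(samples, sites, geno) {
  samples <- as.character(samples)
  if (is.null(dim(geno))) geno <- matrix(geno, nrow = nrow(sites))
  stopifnot(is.character(samples), is.data.frame(sites),
            nrow(geno) == nrow(sites), ncol(geno) == length(samples))
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "qual")
  missing_cols <- setdiff(need, names(sites))
  if (length(missing_cols) > 0) {
    stop("sites is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  sites$chrom <- as.character(sites$chrom)
  sites$pos <- as.integer(sites$pos)
  sites$ref <- as.character(sites$ref)
  sites$alt <- as.character(sites$alt)
  sites$qual <- as.numeric(sites$qual)
  if (is.null(sites$kind)) sites$kind <- classify_kind(sites$ref, sites$alt)
  ord <- order(sites$chrom, sites$pos, sites$ref, sites$alt)
  if (any(ord != seq_along(ord))) {
    sites <- sites[ord, , drop = FALSE]
    geno <- geno[ord, , drop = FALSE]
  }
  rownames(sites) <- NULL
  key <- paste(sites$chrom, sites$pos, sites$ref, sites$alt, sep = ":")
  dup <- duplicated(key)
  if (any(dup)) {
    stop("duplicate variant record(s): ", paste(utils::head(key[dup], 3), collapse = ", "))
  }
  mode(geno) <- "character"
  dimnames(geno) <- list(NULL, samples)
  structure(list(samples = samples, sites = sites, geno = geno),
            class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("variant_table: %d sites x %d samples\n", nrow(x$sites), length(x$samples)))
  kinds <- table(x$sites$kind)
  cat("  kinds:", paste(sprintf("%s=%d", names(kinds), kinds), collapse = ", "), "\n")
  invisible(x)
}

#' Number of sites / samples in a variant table
#' @param table A `variant_table`.
#' @return Integer count.
#' @export
n_sites <- function(table) nrow(table$sites)

#' @rdname n_sites
#' @export
n_samples <- function(table) length(table$samples)

#' Site identity keys
#'
#' Site identity across files and callers is `(chrom, pos, ref, alt)` after
#' decomposition; two records are "the same site" only if reference and
#' alternate alleles match, since genotype comparison is meaningless across
#' different allele pairs.
#'
#' @param table A `variant_table`.
#' @return Character vector of `chrom:pos:ref:alt` keys.
#' @export
site_keys <- function(table) {
  paste(table$sites$chrom, table$sites$pos, table$sites$ref, table$sites$alt,
        sep = ":")
}

# keep = logical or integer index over sites; preserves order
subset_sites <- function(table, keep) {
  variant_table(table$samples,
                table$sites[keep, , drop = FALSE],
                table$geno[keep, , drop = FALSE])
}

#' Restrict a variant table to a subset of samples
#' @param table A `variant_table`.
#' @param samples Character vector of sample ids to keep, in the desired order.
#' @return A `variant_table` over `samples`.
#' @export
subset_samples <- function(table, samples) {
  missing <- setdiff(samples, table$samples)
  if (length(missing) > 0) {
    stop("sample(s) not in roster: ", paste(missing, collapse = ", "))
  }
  variant_table(samples, table$sites,
                table$geno[, match(samples, table$samples), drop = FALSE])
}

# Classify a ref/alt record. kind = SNP iff ref and every alt have length 1.
classify_kind <- function(ref, alt) {
  vapply(seq_along(ref), function(i) {
    alts <- strsplit(alt[i], ",", fixed = TRUE)[[1]]
    cls <- vapply(alts, function(a) classify_pair(ref[i], a), character(1))
    u <- unique(cls)
    if (length(u) == 1) u else "COMPLEX"
  }, character(1))
}

classify_pair <- function(ref, alt) {
  nr <- nchar(ref); na <- nchar(alt)
  if (nr == 1L && na == 1L) return("SNP")
  if (nr == na) return("MNP")
  if (startsWith(ref, alt) || startsWith(alt, ref)) return("INDEL")
  "COMPLEX"
}

#' Normalize raw GT strings to unordered unphased genotype calls
#'
#' `"0|1"`, `"1/0"` and `"0/1"` all normalize to `"0/1"`; `"."`, `"./."` and
#' `".|."` (and any call containing a `.` allele) become `NA`.
#'
#' @param x Character vector of raw GT field values.
#' @return Character vector of `"a/b"` calls (`a <= b`) or `NA`.
#' @export
normalize_gt <- function(x) {
  x <- gsub("|", "/", x, fixed = TRUE)
  out <- rep(NA_character_, length(x))
  ok <- !is.na(x) & grepl("^[0-9]+/[0-9]+$", x)
  if (any(ok)) {
    a <- as.integer(sub("/.*", "", x[ok]))
    b <- as.integer(sub(".*/", "", x[ok]))
    out[ok] <- paste0(pmin(a, b), "/", pmax(a, b))
  }
  out
}

# One string per site summarizing the full genotype vector (NA printed ".");
# two sites have equal genotype vectors iff their signatures are equal.
geno_signature <- function(geno) {
  g <- geno
  g[is.na(g)] <- "."
  do.call(paste, c(as.data.frame(g, stringsAsFactors = FALSE), sep = ","))
}

# Dosage matrix for biallelic tables: 0/1/2 alt-allele copies, NA missing.
geno_dosage <- function(table) {
  d <- match(table$geno, c("0/0", "0/1", "1/1")) - 1L
  matrix(d, nrow = nrow(table$geno), dimnames = dimnames(table$geno))
}

empty_variant_table <- function(samples) {
  variant_table(samples,
                data.frame(chrom = character(0), pos = integer(0),
                           ref = character(0), alt = character(0),
                           qual = numeric(0), kind = character(0),
                           stringsAsFactors = FALSE),
                matrix(character(0), nrow = 0, ncol = length(samples)))
}
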