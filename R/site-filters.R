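#' Retain biallelic SNPs only
#'
#' Keeps sites that are single-nucleotide substitutions with exactly one
#' alternate allele; indels and multiallelic SNPs are removed. Order is
#' preserved and calls are untouched.
#'
#' @param table A decomposed [variant_table()].
#' @return The filtered [variant_table()].
#' @export
filter_biallelic_snps <- function(table) {
  keep <- table$sites$kind == "SNP" & !grepl(",", table$sites$alt, fixed = TRUE)
  subset_sites(table, keep)
}

#' Filter sites on phred-scaled quality
#'
#' Retains sites with `qual >= min_qual` (the threshold is inclusive); sites
#' with an absent QUAL are removed.
#'
#' @param table A [variant_table()].
#' @param min_qual Minimum site quality, default 30.
#' @return The filtered [variant_table()].
#' @export
filter_quality <- function(table, min_qual = 30) {
  keep <- !is.na(table$sites$qual) & table$sites$qual >= min_qual
  subset_sites(table, keep)
}

#' Retain intra-specific polymorphisms
#'
#' When reads are mapped to a cross-species reference genome, many called
#' "variants" are fixed interspecific differences: every individual carries
#' the same non-reference homozygote. This filter keeps only sites that
#' segregate within the sample roster: at least one heterozygous non-missing
#' call, or at least two distinct homozygous non-missing calls. Sites where
#' all non-missing calls are one identical homozygote, and sites with no
#' non-missing call at all, are dropped. All-heterozygous sites (possible
#' paralog collapses) are retained but counted in the filter log of
#' [apply_site_filters()].
#'
#' @param table A [variant_table()].
#' @return The filtered [variant_table()].
#' @export
filter_intraspecific <- function(table) {
  keep <- apply(table$geno, 1, site_segregates)
  subset_sites(table, keep)
}

site_segregates <- function(calls) {
  calls <- calls[!is.na(calls)]
  if (length(calls) == 0) return(FALSE)
  ab <- matrix(unlist(strsplit(calls, "/", fixed = TRUE)), nrow = 2)
  if (any(ab[1, ] != ab[2, ])) return(TRUE)      # heterozygote present
  length(unique(calls)) >= 2                     # two distinct homozygotes
}

site_all_het <- function(calls) {
  calls <- calls[!is.na(calls)]
  if (length(calls) == 0) return(FALSE)
  ab <- matrix(unlist(strsplit(calls, "/", fixed = TRUE)), nrow = 2)
  all(ab[1, ] != ab[2, ])
}

#' Filter sites on missing genotype calls
#'
#' The three missing-value modalities: `"noNA"` keeps sites with zero missing
#' calls, `"2NA"` keeps sites with at most two missing calls, `"anyNA"`
#' applies no missingness filter. Missingness is counted at the roster level
#' (one call per genotype), not per sequencing replicate.
#'
#' @param table A [variant_table()].
#' @param modality One of `"noNA"`, `"2NA"`, `"anyNA"`.
#' @return The filtered [variant_table()].
#' @export
filter_missing <- function(table, modality = c("noNA", "2NA", "anyNA")) {
  modality <- match.arg(modality)
  n_na <- rowSums(is.na(table$geno))
  keep <- switch(modality,
                 noNA = n_na == 0,
                 `2NA` = n_na <= 2,
                 anyNA = rep(TRUE, length(n_na)))
  subset_sites(table, keep)
}

#' Apply the full per-caller filter cascade with a machine-readable log
#'
#' Runs biallelic-SNP selection, the quality threshold and the
#' intra-specific polymorphism filter in that order, optionally followed by
#' a missing-value modality, and records per-stage input/output/removed
#' counts. All stages are per-site predicates, so the final site set does not
#' depend on their order.
#'
#' @param table A decomposed [variant_table()].
#' @param min_qual Minimum site quality (default 30).
#' @param modality Optional missing-value modality (see [filter_missing()]);
#'   `NULL` skips the missingness stage.
#' @return A list with `table` (the filtered [variant_table()]) and `log`
#'   (data frame with columns `stage`, `n_in`, `n_out`, `n_removed`, plus an
#'   `n_all_het_retained` attribute).
#' @export
apply_site_filters <- function(table, min_qual = 30, modality = NULL) {
  stages <- list(
    biallelic_snps = function(t) filter_biallelic_snps(t),
    qual = function(t) filter_quality(t, min_qual = min_qual),
    intraspecific = function(t) filter_intraspecific(t)
  )
  if (!is.null(modality)) {
    stages[[paste0("missing_", modality)]] <-
      function(t) filter_missing(t, modality = modality)
  }
  log <- data.frame(stage = character(0), n_in = integer(0),
                    n_out = integer(0), n_removed = integer(0),
                    stringsAsFactors = FALSE)
  cur <- table
  for (nm in names(stages)) {
    n_in <- n_sites(cur)
    cur <- stages[[nm]](cur)
    log <- rbind(log, data.frame(stage = nm, n_in = n_in, n_out = n_sites(cur),
                                 n_removed = n_in - n_sites(cur),
                                 stringsAsFactors = FALSE))
  }
  n_all_het <- if (n_sites(cur) > 0) sum(apply(cur$geno, 1, site_all_het)) else 0L
  attr(log, "n_all_het_retained") <- n_all_het
  list(table = cur, log = log)
}
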