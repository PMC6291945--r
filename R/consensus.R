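#' Bundle per-caller variant tables over one shared sample roster
#'
#' @param tables Named list of [variant_table()]s, one per variant caller
#'   (2 to 8 callers). All tables must share an identical roster, order
#'   included.
#' @return A `caller_set` object.
#' @export
caller_set <- function(tables) {
  if (is.null(names(tables)) || any(!nzchar(names(tables)))) {
    stop("tables must be a named list (one name per caller)")
  }
  if (length(tables) < 2 || length(tables) > 8) {
    stop("a caller_set holds between 2 and 8 callers, got ", length(tables))
  }
  roster <- tables[[1]]$samples
  for (nm in names(tables)) {
    if (!identical(tables[[nm]]$samples, roster)) {
      stop("caller '", nm, "' has a different sample roster")
    }
  }
  structure(list(tables = tables, samples = roster), class = "caller_set")
}

#' @export
print.caller_set <- function(x, ...) {
  cat(sprintf("caller_set: %d callers, %d samples\n",
              length(x$tables), length(x$samples)))
  for (nm in names(x$tables)) {
    cat(sprintf("  %s: %d sites\n", nm, n_sites(x$tables[[nm]])))
  }
  invisible(x)
}

#' Strict k-of-n caller intersection
#'
#' A site enters the output iff (a) the same `(chrom, pos, ref, alt)` record
#' is present in at least `min_callers` tables and (b) every table containing
#' it reports an identical genotype call for every sample (missing calls must
#' also match). Callers that did not detect the site do not veto it unless
#' `require_all = TRUE`, which additionally demands detection by all callers.
#' A position present in different callers with mismatching ref/alt pairs
#' counts as not co-detected.
#'
#' @param callers A [caller_set()] of pre-filtered tables.
#' @param min_callers Minimum number of callers that must detect the site.
#' @param require_all If `TRUE`, require detection by every caller.
#' @return A [variant_table()] of unanimous sites; QUAL is the mean across
#'   detecting callers.
#' @export
intersect_strict <- function(callers, min_callers, require_all = FALSE) {
  stopifnot(inherits(callers, "caller_set"))
  n <- length(callers$tables)
  if (min_callers < 2 || min_callers > n) {
    stop("min_callers must be between 2 and the number of callers (", n, ")")
  }
  need <- if (require_all) n else min_callers
  keys <- lapply(callers$tables, site_keys)
  counts <- table(unlist(keys, use.names = FALSE))
  cand <- names(counts)[counts >= need]
  if (length(cand) == 0) return(empty_variant_table(callers$samples))

  # unanimity: one distinct genotype signature per candidate key
  kv <- do.call(rbind, lapply(names(callers$tables), function(nm) {
    t <- callers$tables[[nm]]
    data.frame(key = keys[[nm]], sig = geno_signature(t$geno),
               stringsAsFactors = FALSE)
  }))
  kv <- kv[kv$key %in% cand, , drop = FALSE]
  u <- unique(kv)
  good <- setdiff(cand, u$key[duplicated(u$key)])
  build_combined_table(callers, good)
}

# assemble sites/geno for a set of keys: records from the first detecting
# caller, QUAL averaged over detecting callers
build_combined_table <- function(callers, keep_keys, geno_override = NULL) {
  if (length(keep_keys) == 0) return(empty_variant_table(callers$samples))
  qual_sum <- stats::setNames(numeric(length(keep_keys)), keep_keys)
  qual_n <- stats::setNames(integer(length(keep_keys)), keep_keys)
  sites <- NULL
  geno <- NULL
  taken <- stats::setNames(logical(length(keep_keys)), keep_keys)
  for (t in callers$tables) {
    k <- site_keys(t)
    idx <- which(k %in% keep_keys)
    if (length(idx) == 0) next
    q <- t$sites$qual[idx]
    ok <- !is.na(q)
    qual_sum[k[idx][ok]] <- qual_sum[k[idx][ok]] + q[ok]
    qual_n[k[idx][ok]] <- qual_n[k[idx][ok]] + 1L
    new <- idx[!taken[k[idx]]]
    if (length(new) > 0) {
      sites <- rbind(sites, t$sites[new, , drop = FALSE])
      geno <- rbind(geno, t$geno[new, , drop = FALSE])
      taken[k[new]] <- TRUE
    }
  }
  k_out <- paste(sites$chrom, sites$pos, sites$ref, sites$alt, sep = ":")
  sites$qual <- ifelse(qual_n[k_out] > 0, qual_sum[k_out] / qual_n[k_out], NA)
  if (!is.null(geno_override)) {
    geno <- geno_override[match(k_out, keep_keys), , drop = FALSE]
  }
  variant_table(callers$samples, sites, geno)
}

#' Per-individual consensus genotyping across callers
#'
#' Candidate sites are those detected (same `(chrom, pos, ref, alt)`) by at
#' least `min_agree` callers. For each sample the consensus call is the
#' genotype reported identically by at least `min_agree` callers; a missing
#' call is never a votable genotype and the fallback when no genotype reaches
#' `min_agree` votes is missing. Sites whose consensus calls are all missing
#' are dropped.
#'
#' @param callers A [caller_set()] of pre-filtered tables.
#' @param min_agree Number of agreeing callers required, default 3. Must
#'   exceed half the number of callers (ties are then impossible by
#'   construction) and not exceed it.
#' @return A [variant_table()] of consensus genotypes; QUAL is the mean
#'   across detecting callers.
#' @export
consensus_genotypes <- function(callers, min_agree = 3) {
  stopifnot(inherits(callers, "caller_set"))
  n <- length(callers$tables)
  if (min_agree > n) stop("min_agree (", min_agree, ") exceeds the number of callers (", n, ")")
  if (min_agree <= n / 2) {
    stop("min_agree must exceed half the number of callers to rule out ties")
  }
  keys <- lapply(callers$tables, site_keys)
  counts <- table(unlist(keys, use.names = FALSE))
  cand <- names(counts)[counts >= min_agree]
  if (length(cand) == 0) return(empty_variant_table(callers$samples))

  m <- length(callers$samples)
  aligned <- lapply(seq_len(n), function(i) {
    t <- callers$tables[[i]]
    g <- matrix(NA_character_, nrow = length(cand), ncol = m)
    idx <- match(cand, keys[[i]])
    ok <- !is.na(idx)
    g[ok, ] <- t$geno[idx[ok], , drop = FALSE]
    g
  })
  alphabet <- sort(unique(unlist(lapply(aligned, function(g) g[!is.na(g)]))))
  consensus <- matrix(NA_character_, nrow = length(cand), ncol = m)
  for (g in alphabet) {
    votes <- Reduce(`+`, lapply(aligned, function(a) !is.na(a) & a == g))
    consensus[votes >= min_agree] <- g
  }
  informative <- rowSums(!is.na(consensus)) > 0
  out <- build_combined_table(callers, cand[informative],
                              geno_override = consensus[informative, , drop = FALSE])
  out
}

#' The calling-modality count grid
#'
#' Crosses every calling modality — each single caller, the strict
#' (n-1)-of-n and n-of-n intersections, and the (n-1)-caller consensus —
#' with the three missing-value modalities and tabulates site counts. With
#' the four callers of a typical run this is the 7 x 3 grid
#' (per-caller, "3Callers", "4Callers", "3CallersConsensus") x
#' (noNA, 2NA, anyNA).
#'
#' @param callers A [caller_set()] of pre-filtered tables.
#' @return A `modality_grid`: list with `counts` (data frame `modality` x
#'   `noNA`/`2NA`/`anyNA`) and `tables` (named list of the modality
#'   [variant_table()]s before missingness filtering).
#' @export
modality_grid <- function(callers) {
  stopifnot(inherits(callers, "caller_set"))
  n <- length(callers$tables)
  tables <- callers$tables
  tables[[sprintf("%dCallers", n - 1)]] <- intersect_strict(callers, n - 1)
  tables[[sprintf("%dCallers", n)]] <- intersect_strict(callers, n)
  tables[[sprintf("%dCallersConsensus", n - 1)]] <-
    consensus_genotypes(callers, min_agree = n - 1)
  counts <- data.frame(
    modality = names(tables),
    noNA = vapply(tables, function(t) n_sites(filter_missing(t, "noNA")), integer(1)),
    `2NA` = vapply(tables, function(t) n_sites(filter_missing(t, "2NA")), integer(1)),
    anyNA = vapply(tables, function(t) n_sites(t), integer(1)),
    check.names = FALSE, row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(counts = counts, tables = tables), class = "modality_grid")
}

#' @export
print.modality_grid <- function(x, ...) {
  cat("modality_grid:\n")
  print(x$counts, row.names = FALSE)
  invisible(x)
}
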