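#' Decompose complex variant records into primitive SNPs and indels
#'
#' Haplotype-based callers emit multi-nucleotide and complex records; before
#' sites can be compared across callers they must be reduced to a canonical
#' primitive representation. Each MNP/COMPLEX record is replaced by primitive
#' SNP and indel records obtained by pairing the reference against each
#' alternate allele (longest shared prefix/suffix trimmed, equal-length
#' blocks split per differing base, remaining length differences kept as a
#' single left-anchored indel). Per-sample genotypes are projected onto each
#' primitive; primitives identical across source alternates are merged;
#' SNP/INDEL records pass through unchanged; primitives inherit the source
#' record's QUAL.
#'
#' @param table A [variant_table()].
#' @return A decomposed [variant_table()]. Decomposition is idempotent.
#' @details Records with symbolic alternates (`<DEL>`, breakends) are skipped
#'   with a warning. If two decomposed records collapse onto the same
#'   `(chrom, pos, ref, alt)` key the first is kept with a warning.
#' @export
decompose <- function(table) {
  s <- table$sites
  symbolic <- grepl("[][<>]", s$alt)
  if (any(symbolic)) {
    warning(sum(symbolic), " record(s) with symbolic alternate alleles skipped")
  }
  todo <- !symbolic & s$kind %in% c("MNP", "COMPLEX")
  keep <- !symbolic & !todo

  out_sites <- list(s[keep, , drop = FALSE])
  out_geno <- list(table$geno[keep, , drop = FALSE])
  for (i in which(todo)) {
    dec <- decompose_record(s$chrom[i], s$pos[i], s$ref[i], s$alt[i],
                            s$qual[i], table$geno[i, ])
    out_sites[[length(out_sites) + 1]] <- dec$sites
    out_geno[[length(out_geno) + 1]] <- dec$geno
  }
  sites <- do.call(rbind, out_sites)
  geno <- do.call(rbind, out_geno)
  key <- paste(sites$chrom, sites$pos, sites$ref, sites$alt, sep = ":")
  dup <- duplicated(key)
  if (any(dup)) {
    warning("decomposition produced ", sum(dup),
            " duplicate primitive record(s); keeping first occurrence")
    sites <- sites[!dup, , drop = FALSE]
    geno <- geno[!dup, , drop = FALSE]
  }
  sites$kind <- classify_kind(sites$ref, sites$alt)
  variant_table(table$samples, sites, geno)
}

# Pair ref against one alt: trim shared suffix then prefix, split equal-length
# remainders into per-base SNPs, keep unequal-length remainders as one
# left-anchored record. Returns data.frame(pos, ref, alt).
decompose_pair <- function(pos, ref, alt) {
  if (nchar(ref) == 1L && nchar(alt) == 1L) {
    return(data.frame(pos = pos, ref = ref, alt = alt, stringsAsFactors = FALSE))
  }
  r <- strsplit(ref, "", fixed = TRUE)[[1]]
  a <- strsplit(alt, "", fixed = TRUE)[[1]]
  while (length(r) > 1 && length(a) > 1 && r[length(r)] == a[length(a)]) {
    r <- r[-length(r)]; a <- a[-length(a)]
  }
  off <- 0L
  while (length(r) > 1 && length(a) > 1 && r[1] == a[1]) {
    r <- r[-1]; a <- a[-1]; off <- off + 1L
  }
  if (length(r) == length(a)) {
    d <- which(r != a)
    return(data.frame(pos = pos + off + d - 1L, ref = r[d], alt = a[d],
                      stringsAsFactors = FALSE))
  }
  # unequal lengths: left-anchored indel; re-attach one trimmed prefix base
  # as the anchor when the first remaining bases differ
  if (r[1] != a[1] && off > 0) {
    anchor <- substr(ref, off, off)
    r <- c(anchor, r); a <- c(anchor, a); off <- off - 1L
  }
  data.frame(pos = pos + off, ref = paste(r, collapse = ""),
             alt = paste(a, collapse = ""), stringsAsFactors = FALSE)
}

decompose_record <- function(chrom, pos, ref, alt, qual, calls) {
  alts <- strsplit(alt, ",", fixed = TRUE)[[1]]
  prims <- lapply(seq_along(alts), function(j) {
    p <- decompose_pair(pos, ref, alts[j])
    p$source_alt <- j
    p
  })
  prims <- do.call(rbind, prims)
  pkey <- paste(prims$pos, prims$ref, prims$alt, sep = ":")
  upos <- !duplicated(pkey)
  uniq <- prims[upos, , drop = FALSE]
  sources <- split(prims$source_alt, pkey)[pkey[upos]]

  n_prim <- nrow(uniq)
  alle <- strsplit(calls, "/", fixed = TRUE)
  geno <- matrix(NA_character_, nrow = n_prim, ncol = length(calls))
  for (k in seq_len(n_prim)) {
    src <- sources[[k]]
    geno[k, ] <- vapply(alle, function(ab) {
      if (is.null(ab) || anyNA(ab)) return(NA_character_)
      idx <- as.integer(ab)
      proj <- sort(ifelse(idx %in% src, 1L, 0L))
      paste0(proj[1], "/", proj[2])
    }, character(1))
  }
  na_calls <- is.na(calls)
  if (any(na_calls)) geno[, na_calls] <- NA_character_
  list(sites = data.frame(chrom = chrom, pos = uniq$pos, ref = uniq$ref,
                          alt = uniq$alt, qual = qual,
                          kind = classify_kind(uniq$ref, uniq$alt),
                          stringsAsFactors = FALSE),
       geno = geno)
}
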