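#' Per-site minor allele frequency
#'
#' For each biallelic site, the alternate-allele frequency is the alternate
#' allele count over twice the number of non-missing calls, and the MAF is
#' `min(f, 1 - f)`. Sites with zero non-missing calls have `NA` MAF
#' (undefined) and their count is attached as an attribute.
#'
#' @param table A biallelic [variant_table()].
#' @return Numeric vector of MAFs in `[0, 0.5]` (or `NA`), one per site,
#'   with attribute `n_undefined`.
#' @export
compute_maf <- function(table) {
  d <- geno_dosage(table)
  if (any(is.na(d) & !is.na(table$geno))) {
    stop("compute_maf requires a biallelic table (calls 0/0, 0/1, 1/1)")
  }
  ac <- rowSums(d, na.rm = TRUE)
  nn <- rowSums(!is.na(d))
  f <- ifelse(nn > 0, ac / (2 * nn), NA_real_)
  maf <- pmin(f, 1 - f)
  attr(maf, "n_undefined") <- sum(nn == 0)
  maf
}

#' Filter sites on minor allele frequency
#'
#' Retains sites with MAF strictly greater than `min_maf` ("higher than").
#' Sites with undefined MAF are dropped.
#'
#' @param table A biallelic [variant_table()].
#' @param min_maf MAF threshold (strict), default 0.05.
#' @return The filtered [variant_table()].
#' @export
filter_maf <- function(table, min_maf = 0.05) {
  maf <- compute_maf(table)
  subset_sites(table, !is.na(maf) & maf > min_maf)
}

#' Windowed genome-wide SNP density
#'
#' Tiles every chromosome with fixed windows `[k*w + 1, (k+1)*w]` (the last
#' window truncated at the chromosome end) and counts SNPs per window. SNPs
#' on chromosomes absent from the annotation are excluded and counted.
#'
#' @param table A [variant_table()].
#' @param ann A [genome_annotation()] (chromosome lengths are used).
#' @param window_size Window size in bp, default 100,000.
#' @return A `window_density` object: `windows` data frame (`chrom`,
#'   `start`, `end`, `snp_count`), `window_size` and `summary` (min, max,
#'   mean, median, fraction of windows with at least one SNP, number of
#'   located and excluded SNPs).
#' @export
window_density <- function(table, ann, window_size = 100000) {
  if (window_size <= 0) stop("window_size must be positive")
  chroms <- names(ann$chrom_lengths)
  located <- table$sites$chrom %in% chroms
  wins <- lapply(chroms, function(ch) {
    len <- ann$chrom_lengths[[ch]]
    n_win <- ceiling(len / window_size)
    start <- (seq_len(n_win) - 1L) * window_size + 1L
    pos <- table$sites$pos[table$sites$chrom == ch]
    data.frame(chrom = ch, start = start,
               end = pmin(start + window_size - 1, len),
               snp_count = tabulate((pos - 1) %/% window_size + 1L, n_win),
               stringsAsFactors = FALSE)
  })
  windows <- do.call(rbind, wins)
  cnt <- windows$snp_count
  structure(list(windows = windows, window_size = window_size,
                 summary = list(min = min(cnt), max = max(cnt),
                                mean = mean(cnt), median = stats::median(cnt),
                                frac_nonempty = mean(cnt >= 1),
                                n_located = sum(located),
                                n_excluded = sum(!located))),
            class = "window_density")
}

#' @export
print.window_density <- function(x, ...) {
  s <- x$summary
  cat(sprintf("window_density (%d bp): %d windows, counts %d-%d (mean %.1f, median %.1f), %.1f%% non-empty\n",
              x$window_size, nrow(x$windows), s$min, s$max, s$mean, s$median,
              100 * s$frac_nonempty))
  invisible(x)
}

#' Correlation between windowed SNP density and summed gene expression
#'
#' Each gene is assigned to the window containing its start coordinate; per
#' window, x is the sum of expression of assigned genes and y is the SNP
#' count. Returns the OLS fit of y on x over windows containing at least one
#' gene.
#'
#' @param density A `window_density` from [window_density()].
#' @param expression Data frame `gene_id`, `expression` (log2
#'   counts-per-million).
#' @param ann A [genome_annotation()].
#' @return List with `r_squared`, `slope`, `n_windows` and the per-window
#'   data frame.
#' @export
density_expression_correlation <- function(density, expression, ann) {
  w <- density$window_size
  genes <- ann$genes
  gkey <- paste(genes$chrom, (genes$start - 1) %/% w + 1, sep = ":")
  expr <- expression$expression[match(genes$gene_id, expression$gene_id)]
  expr_sum <- tapply(expr, gkey, sum, na.rm = TRUE)
  wkey <- paste(density$windows$chrom,
                (density$windows$start - 1) %/% w + 1, sep = ":")
  has_gene <- wkey %in% names(expr_sum)
  if (sum(has_gene) < 3) stop("fewer than 3 windows contain genes")
  pts <- data.frame(window = wkey[has_gene],
                    expression_sum = as.numeric(expr_sum[wkey[has_gene]]),
                    snp_count = density$windows$snp_count[has_gene],
                    stringsAsFactors = FALSE)
  fit <- stats::lm(snp_count ~ expression_sum, data = pts)
  list(r_squared = summary(fit)$r.squared,
       slope = unname(stats::coef(fit)[2]),
       n_windows = nrow(pts), points = pts)
}

ann_feature_granges <- function(ann, type) {
  f <- ann$features[ann$features$type %in% type, , drop = FALSE]
  chrom <- ann$genes$chrom[match(f$gene_id, ann$genes$gene_id)]
  GenomicRanges::GRanges(chrom, IRanges::IRanges(f$start, f$end),
                         gene_id = f$gene_id)
}

ann_gene_granges <- function(ann) {
  GenomicRanges::GRanges(ann$genes$chrom,
                         IRanges::IRanges(ann$genes$start, ann$genes$end),
                         gene_id = ann$genes$gene_id)
}

# splice regions: first/last `margin` bp of each intron
ann_splice_granges <- function(ann, margin = 2L) {
  out <- list()
  for (gid in unique(ann$features$gene_id)) {
    ex <- ann$features[ann$features$gene_id == gid &
                         ann$features$type == "exon", , drop = FALSE]
    if (nrow(ex) < 2) next
    ex <- ex[order(ex$start), , drop = FALSE]
    chrom <- ann$genes$chrom[ann$genes$gene_id == gid]
    for (i in seq_len(nrow(ex) - 1)) {
      is_ <- ex$end[i] + 1L
      ie <- ex$start[i + 1] - 1L
      if (ie < is_) next
      out[[length(out) + 1]] <- data.frame(
        chrom = chrom,
        start = c(is_, max(ie - margin + 1L, is_)),
        end = c(min(is_ + margin - 1L, ie), ie))
    }
  }
  if (length(out) == 0) {
    return(GenomicRanges::GRanges())
  }
  d <- unique(do.call(rbind, out))
  GenomicRanges::GRanges(d$chrom, IRanges::IRanges(d$start, d$end))
}

#' Assign each SNP to a genomic region category
#'
#' Labels every site with exactly one of `CDS_exonic`, `UTR5`, `UTR3`,
#' `splicing`, `intronic`, `intergenic`. `splicing` means within
#' `splice_margin` bp of an exon-intron boundary on the intron side (the
#' canonical splice dinucleotides for the default margin of 2); `intronic`
#' means inside a gene span but in no exon. When a SNP hits overlapping
#' genes the precedence is CDS > UTR > splicing > intronic. Exonic positions
#' not covered by an explicit CDS or UTR feature are assigned to the UTR
#' side implied by their position relative to the gene's CDS span.
#'
#' @param table A [variant_table()].
#' @param ann A [genome_annotation()].
#' @param splice_margin Intron-side margin in bp, default 2.
#' @return Character vector of categories, one per site. SNPs on
#'   chromosomes absent from the annotation are `intergenic` with a warning.
#' @export
annotate_regions <- function(table, ann, splice_margin = 2L) {
  s <- table$sites
  unknown <- !(s$chrom %in% names(ann$chrom_lengths))
  if (any(unknown)) {
    warning(sum(unknown), " SNP(s) on chromosomes absent from the annotation; labeled intergenic")
  }
  snps <- GenomicRanges::GRanges(s$chrom, IRanges::IRanges(s$pos, s$pos))
  category <- rep("intergenic", nrow(s))

  hit <- function(gr) {
    if (length(gr) == 0) rep(FALSE, nrow(s))
    else IRanges::overlapsAny(snps, gr)
  }
  category[hit(ann_gene_granges(ann))] <- "intronic"
  category[hit(ann_splice_granges(ann, splice_margin))] <- "splicing"
  exon_gr <- ann_feature_granges(ann, "exon")
  in_exon <- hit(exon_gr)
  category[hit(ann_feature_granges(ann, "three_prime_UTR"))] <- "UTR3"
  category[hit(ann_feature_granges(ann, "five_prime_UTR"))] <- "UTR5"
  category[hit(ann_feature_granges(ann, "CDS"))] <- "CDS_exonic"

  # exonic but not CDS/UTR: derive the UTR side from the CDS span
  orphan <- which(in_exon & category %in% c("intronic", "splicing"))
  if (length(orphan) > 0) {
    ov <- GenomicRanges::findOverlaps(snps[orphan], exon_gr)
    for (k in seq_along(orphan)) {
      i <- orphan[k]
      gids <- exon_gr$gene_id[S4Vectors::subjectHits(ov)[S4Vectors::queryHits(ov) == k]]
      category[i] <- orphan_utr_side(ann, gids[1], s$pos[i])
    }
  }
  category
}

orphan_utr_side <- function(ann, gid, pos) {
  cds <- ann$features[ann$features$gene_id == gid &
                        ann$features$type == "CDS", , drop = FALSE]
  if (nrow(cds) == 0) return("UTR3")
  strand <- ann$genes$strand[ann$genes$gene_id == gid]
  upstream <- pos < min(cds$start)
  if ((strand == "+" && upstream) || (strand == "-" && !upstream && pos > max(cds$end))) {
    "UTR5"
  } else {
    "UTR3"
  }
}

#' Classify coding effects of biallelic SNPs
#'
#' For each SNP inside a CDS, locates the codon through the gene's CDS
#' intervals, strand and phase, translates the reference and alternate
#' codons with the standard genetic code, and classifies the substitution:
#' `stopgain` (alternate introduces a stop), `stoploss` (reference stop
#' lost), `synonymous` (identical amino acids), `nonsynonymous` otherwise.
#' SNPs outside any CDS are `not_coding`. Only the first gene model covering
#' the SNP is used.
#'
#' @param table A biallelic [variant_table()].
#' @param ann A [genome_annotation()] with reference sequence.
#' @return Character vector of effect classes, one per site.
#' @details A mismatch between the VCF reference allele and the reference
#'   sequence base is a data-inconsistency error naming the site.
#' @export
classify_coding_effect <- function(table, ann) {
  s <- table$sites
  snps <- GenomicRanges::GRanges(s$chrom, IRanges::IRanges(s$pos, s$pos))
  cds_gr <- ann_feature_granges(ann, "CDS")
  out <- rep("not_coding", nrow(s))
  if (length(cds_gr) == 0 || nrow(s) == 0) return(out)
  ov <- GenomicRanges::findOverlaps(snps, cds_gr)
  qh <- S4Vectors::queryHits(ov)
  first <- !duplicated(qh)
  for (k in which(first)) {
    i <- qh[k]
    gid <- cds_gr$gene_id[S4Vectors::subjectHits(ov)[k]]
    out[i] <- coding_effect_one(ann, gid, s$chrom[i], s$pos[i],
                                s$ref[i], s$alt[i])
  }
  out
}

coding_effect_one <- function(ann, gid, chrom, pos, ref, alt) {
  genome_base <- substr(ann$reference[[chrom]], pos, pos)
  if (genome_base != ref) {
    stop(sprintf("reference base %s at %s:%d does not match VCF ref %s",
                 genome_base, chrom, pos, ref))
  }
  strand <- ann$genes$strand[ann$genes$gene_id == gid]
  cds <- ann$features[ann$features$gene_id == gid &
                        ann$features$type == "CDS", , drop = FALSE]
  cds <- cds[order(cds$start), , drop = FALSE]
  if (strand == "-") cds <- cds[rev(seq_len(nrow(cds))), , drop = FALSE]

  pieces <- vapply(seq_len(nrow(cds)), function(i) {
    seq_ <- substr(ann$reference[[chrom]], cds$start[i], cds$end[i])
    if (strand == "-") seq_ <- revcomp_seq(seq_)
    seq_
  }, character(1))
  spliced <- paste(pieces, collapse = "")

  widths <- cds$end - cds$start + 1L
  piece_i <- which(cds$start <= pos & cds$end >= pos)
  before <- if (piece_i > 1) sum(widths[seq_len(piece_i - 1)]) else 0L
  within <- if (strand == "+") pos - cds$start[piece_i] + 1L
            else cds$end[piece_i] - pos + 1L
  cds_pos <- before + within

  phase0 <- cds$phase[1]
  if (is.na(phase0)) phase0 <- 0L
  rel <- cds_pos - phase0
  if (rel < 1) return("not_coding")      # inside a partial leading codon
  codon_i <- (rel - 1) %/% 3
  cstart <- phase0 + codon_i * 3 + 1
  if (cstart + 2 > nchar(spliced)) return("not_coding")  # trailing partial codon
  ref_codon <- substr(spliced, cstart, cstart + 2)
  off <- cds_pos - cstart + 1
  alt_base <- if (strand == "+") alt else revcomp_seq(alt)
  alt_codon <- ref_codon
  substr(alt_codon, off, off) <- alt_base

  code <- Biostrings::GENETIC_CODE
  ref_aa <- unname(code[ref_codon])
  alt_aa <- unname(code[alt_codon])
  if (is.na(ref_aa) || is.na(alt_aa)) return("not_coding")
  if (ref_aa != "*" && alt_aa == "*") return("stopgain")
  if (ref_aa == "*" && alt_aa != "*") return("stoploss")
  if (ref_aa == alt_aa) "synonymous" else "nonsynonymous"
}

revcomp_seq <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Genes covered by a minimum number of SNPs
#'
#' Counts SNPs falling within each gene span (introns and UTRs included) and
#' returns the genes reaching the threshold.
#'
#' @param table A [variant_table()].
#' @param ann A [genome_annotation()].
#' @param min_snps Minimum SNP count per gene, default 5.
#' @return Character vector of gene ids, sorted.
#' @export
genes_with_min_snps <- function(table, ann, min_snps = 5) {
  snps <- GenomicRanges::GRanges(table$sites$chrom,
                                 IRanges::IRanges(table$sites$pos, table$sites$pos))
  genes_gr <- ann_gene_granges(ann)
  cnt <- GenomicRanges::countOverlaps(genes_gr, snps)
  sort(genes_gr$gene_id[cnt >= min_snps])
}
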