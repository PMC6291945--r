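#' Genome annotation container
#'
#' Holds chromosome lengths, single-transcript gene models (exon, CDS with
#' phase, 5'/3' UTR intervals, all 1-based closed) and the reference
#' sequence. Only one transcript model per gene is represented; multi-isoform
#' resolution is out of scope.
#'
#' @param chrom_lengths Named integer vector of chromosome lengths (bp).
#' @param genes Data frame with columns `gene_id`, `chrom`, `strand`
#'   (`"+"`/`"-"`), `start`, `end`.
#' @param features Data frame with columns `gene_id`, `type` (one of
#'   `exon`, `CDS`, `five_prime_UTR`, `three_prime_UTR`), `start`, `end`,
#'   `phase` (`NA` except for CDS).
#' @param reference Named character vector of chromosome sequences.
#' @return A `genome_annotation` object.
#' @details Validates that exon intervals do not overlap within a gene and
#'   that every CDS interval lies inside an exon.
#' @export
genome_annotation <- function(chrom_lengths, genes, features, reference) {
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  genes <- genes[order(genes$chrom, genes$start, genes$gene_id), , drop = FALSE]
  features <- features[order(match(features$gene_id, genes$gene_id),
                             features$start, features$type), , drop = FALSE]
  rownames(genes) <- rownames(features) <- NULL
  features$phase <- suppressWarnings(as.integer(features$phase))
  for (gid in unique(features$gene_id)) {
    f <- features[features$gene_id == gid, , drop = FALSE]
    ex <- f[f$type == "exon", , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    if (nrow(ex) > 1 && any(ex$start[-1] <= ex$end[-nrow(ex)])) {
      stop("overlapping exons in gene ", gid)
    }
    cds <- f[f$type == "CDS", , drop = FALSE]
    for (i in seq_len(nrow(cds))) {
      if (!any(ex$start <= cds$start[i] & ex$end >= cds$end[i])) {
        stop("CDS interval outside exons in gene ", gid)
      }
    }
  }
  structure(list(chrom_lengths = chrom_lengths, genes = genes,
                 features = features, reference = reference),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("genome_annotation: %d chromosomes (%d bp), %d genes\n",
              length(x$chrom_lengths), sum(x$chrom_lengths), nrow(x$genes)))
  invisible(x)
}

#' Write gene models as GFF3
#'
#' Emits one `gene`, one `mRNA` and the exon/CDS/UTR features per gene model,
#' with `##sequence-region` pragmas for chromosome lengths. The companion
#' reader is [read_annotation()]; write-then-read reproduces the model.
#'
#' @param ann A [genome_annotation()].
#' @param path Output GFF3 path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(ann, path) {
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d", names(ann$chrom_lengths),
                     as.integer(ann$chrom_lengths)))
  for (i in seq_len(nrow(ann$genes))) {
    g <- ann$genes[i, ]
    f <- ann$features[ann$features$gene_id == g$gene_id, , drop = FALSE]
    f <- f[order(f$start, f$type), , drop = FALSE]
    mrna_id <- paste0(g$gene_id, ".1")
    lines <- c(lines,
               sprintf("%s\tconsensnp\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       g$chrom, g$start, g$end, g$strand, g$gene_id),
               sprintf("%s\tconsensnp\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                       g$chrom, g$start, g$end, g$strand, mrna_id, g$gene_id),
               sprintf("%s\tconsensnp\t%s\t%d\t%d\t.\t%s\t%s\tID=%s;Parent=%s",
                       g$chrom, f$type, f$start, f$end, g$strand,
                       ifelse(is.na(f$phase), ".", as.character(f$phase)),
                       paste0(mrna_id, ":", f$type, ":", seq_len(nrow(f))),
                       mrna_id))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models and reference sequence into a genome annotation
#'
#' Parses GFF3 via \pkg{rtracklayer} and the reference FASTA via
#' \pkg{Biostrings}. Features are attached to genes through their
#' `Parent` attribute (directly or via an mRNA record); chromosome lengths
#' are taken from the FASTA.
#'
#' @param gff_path Path to a GFF3 file.
#' @param fasta_path Path to the reference FASTA.
#' @return A [genome_annotation()].
#' @export
read_annotation <- function(gff_path, fasta_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*", "", names(seqs))
  reference <- stats::setNames(as.character(seqs), names(seqs))
  chrom_lengths <- stats::setNames(nchar(reference), names(reference))

  gr <- rtracklayer::import(gff_path, format = "gff3")
  d <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                  start = GenomicRanges::start(gr),
                  end = GenomicRanges::end(gr),
                  strand = as.character(GenomicRanges::strand(gr)),
                  type = as.character(gr$type),
                  id = if (!is.null(gr$ID)) as.character(gr$ID) else NA_character_,
                  phase = if (!is.null(gr$phase)) as.integer(gr$phase) else NA_integer_,
                  stringsAsFactors = FALSE)
  d$parent <- vapply(as.list(gr$Parent), function(p)
    if (length(p) == 0) NA_character_ else as.character(p[1]), character(1))

  genes_d <- d[d$type == "gene", , drop = FALSE]
  genes <- data.frame(gene_id = genes_d$id, chrom = genes_d$chrom,
                      strand = genes_d$strand, start = genes_d$start,
                      end = genes_d$end, stringsAsFactors = FALSE)
  # map transcript ids to their gene
  tx <- d[d$type %in% c("mRNA", "transcript"), , drop = FALSE]
  tx_gene <- stats::setNames(tx$parent, tx$id)
  feat_types <- c("exon", "CDS", "five_prime_UTR", "three_prime_UTR")
  fd <- d[d$type %in% feat_types, , drop = FALSE]
  gid <- ifelse(fd$parent %in% names(tx_gene), unname(tx_gene[fd$parent]), fd$parent)
  features <- data.frame(gene_id = gid, type = fd$type, start = fd$start,
                         end = fd$end, phase = fd$phase,
                         stringsAsFactors = FALSE)
  features$phase[features$type != "CDS"] <- NA_integer_
  genome_annotation(chrom_lengths, genes, features, reference)
}

#' Write the reference sequence as FASTA
#' @param ann A [genome_annotation()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(ann, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(ann$reference), path)
  invisible(path)
}

#' Read / write a per-gene expression table
#'
#' Two-column tab-delimited table `gene_id`, `expression` with expression on
#' the log2 counts-per-million scale. The package consumes the table; it
#' does not quantify reads.
#'
#' @param path TSV path.
#' @return Data frame with columns `gene_id` and `expression`.
#' @export
read_expression <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "expression") %in% names(d))) {
    stop("expression table must have columns gene_id, expression")
  }
  d$expression <- as.numeric(d$expression)
  d[, c("gene_id", "expression")]
}

#' @rdname read_expression
#' @param expression Data frame with columns `gene_id`, `expression`.
#' @export
write_expression <- function(expression, path) {
  utils::write.table(expression[, c("gene_id", "expression")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
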