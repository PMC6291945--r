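# A 400-bp single-gene genome with hand-placed codons, used for region and
# coding-effect checks. Gene g1 on the plus strand:
#   gene span [101, 260]
#   exon1 [101, 140] = UTR5 [101, 110] + CDS1 [111, 140]
#   intron [141, 200]
#   exon2 [201, 260] = CDS2 [201, 230] + UTR3 [231, 260]
# Reference: A everywhere except CDS1 = GCT TGG TAT then C-fill, and
# CDS2 = TGA then G-fill (an internal reference stop for the stoploss case).
toy_annotation <- function() {
  base <- rep("A", 400)
  base[111:113] <- c("G", "C", "T")
  base[114:116] <- c("T", "G", "G")
  base[117:119] <- c("T", "A", "T")
  base[120:140] <- "C"
  base[201:203] <- c("T", "G", "A")
  base[204:230] <- "G"
  reference <- c(chrT = paste(base, collapse = ""))
  genes <- data.frame(gene_id = "g1", chrom = "chrT", strand = "+",
                      start = 101L, end = 260L, stringsAsFactors = FALSE)
  features <- data.frame(
    gene_id = "g1",
    type = c("exon", "exon", "five_prime_UTR", "CDS", "CDS", "three_prime_UTR"),
    start = c(101L, 201L, 101L, 111L, 201L, 231L),
    end = c(140L, 260L, 110L, 140L, 230L, 260L),
    phase = c(NA, NA, NA, 0L, 0L, NA), stringsAsFactors = FALSE)
  genome_annotation(c(chrT = 400L), genes, features, reference)
}

# mirror of the toy genome: reverse-complemented chromosome, gene on the
# minus strand at mirrored coordinates; UTR/CDS roles are strand-relative
# and therefore unchanged
mirror_annotation <- function(ann) {
  L <- ann$chrom_lengths[[1]]
  chrom <- names(ann$chrom_lengths)
  rc <- function(s) paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]),
                          collapse = "")
  genes <- ann$genes
  new_start <- L - genes$end + 1L
  genes$end <- L - genes$start + 1L
  genes$start <- new_start
  genes$strand <- ifelse(genes$strand == "+", "-", "+")
  features <- ann$features
  fs <- L - features$end + 1L
  features$end <- L - features$start + 1L
  features$start <- fs
  genome_annotation(ann$chrom_lengths, genes, features,
                    stats::setNames(rc(ann$reference[[1]]), chrom))
}

mirror_pos <- function(pos, L = 400L) L - pos + 1L
comp_base <- function(b) chartr("ACGT", "TGCA", b)

# 30 hand-derived (position, ref, alt, region, effect) cases on the toy gene
toy_case_table <- function() {
  read.table(header = TRUE, stringsAsFactors = FALSE, text = "
pos ref alt region effect
50  A G intergenic not_coding
100 A G intergenic not_coding
101 A G UTR5 not_coding
110 A G UTR5 not_coding
111 G A CDS_exonic nonsynonymous
140 C A CDS_exonic synonymous
141 A G splicing not_coding
142 A G splicing not_coding
143 A G intronic not_coding
170 A G intronic not_coding
198 A G intronic not_coding
199 A G splicing not_coding
200 A G splicing not_coding
201 T C CDS_exonic stoploss
230 G T CDS_exonic synonymous
231 A G UTR3 not_coding
260 A G UTR3 not_coding
261 A G intergenic not_coding
350 A G intergenic not_coding
113 T C CDS_exonic synonymous
116 G A CDS_exonic stopgain
117 T G CDS_exonic nonsynonymous
119 T C CDS_exonic synonymous
203 A G CDS_exonic stoploss
105 A G UTR5 not_coding
150 A G intronic not_coding
240 A T UTR3 not_coding
120 C T CDS_exonic nonsynonymous
122 C A CDS_exonic synonymous
55  A T intergenic not_coding
")
}

bare_annotation <- function(chrom_lengths) {
  genes <- data.frame(gene_id = character(0), chrom = character(0),
                      strand = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE)
  features <- data.frame(gene_id = character(0), type = character(0),
                         start = integer(0), end = integer(0),
                         phase = integer(0), stringsAsFactors = FALSE)
  reference <- stats::setNames(
    vapply(chrom_lengths, function(L) paste(rep("A", min(L, 10)), collapse = ""),
           character(1)),
    names(chrom_lengths))
  genome_annotation(chrom_lengths, genes, features, reference)
}
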