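#' Simulation configuration for the synthetic multi-caller generator
#'
#' Defines the study conditions the generator emulates: a structured
#' population of diploid genotypes (Balding-Nichols allele-frequency
#' divergence between populations), several variant callers with independent
#' detection, genotype-error and missingness processes, QUAL values
#' straddling the quality threshold, contaminant records (indels,
#' multiallelic SNPs, interspecific fixed-difference sites) and a small
#' annotated genome whose per-gene expression drives SNP placement.
#'
#' @param seed Mandatory integer seed (< 2^30); there is no unseeded
#'   randomness anywhere in the generator.
#' @param n_populations Number of populations, default 6.
#' @param samples_per_population Genotypes per population, default 2 (the
#'   default layout is therefore 12 genotypes from 6 populations).
#' @param n_sites Number of true segregating SNPs, default 20000.
#' @param fst Balding-Nichols differentiation parameter F in (0, 1),
#'   default 0.1.
#' @param callers Named list of per-caller error models, each a list with
#'   `detection_prob`, `genotype_error_rate`, `missing_rate`,
#'   `qual_below30_frac`. Defaults to four callers with genotype error rates
#'   spanning 0.002-0.02, landing per-caller genotyping accuracy in the
#'   90-99 percent band.
#' @param shared_error_rate Probability that a genotype error is shared by
#'   all callers (callers consume the same reads, so their errors correlate;
#'   0 keeps errors independent so analytic oracles apply exactly).
#' @param contaminants List with fractions (of `n_sites`) of injected
#'   `indel`, `multiallelic` and `fixed_difference` records per caller.
#' @param genome List with `n_chroms`, `chrom_length`, `n_genes`,
#'   `window_size` and log-normal expression parameters `expr_meanlog`,
#'   `expr_sdlog`.
#' @return A validated `simulation_config` object.
#' @export
simulation_config <- function(seed,
                              n_populations = 6,
                              samples_per_population = 2,
                              n_sites = 20000,
                              fst = 0.1,
                              callers = NULL,
                              shared_error_rate = 0,
                              contaminants = list(indel = 0.05,
                                                  multiallelic = 0.03,
                                                  fixed_difference = 0.10),
                              genome = list(n_chroms = 3,
                                            chrom_length = 1000000,
                                            n_genes = 90,
                                            window_size = 100000,
                                            expr_meanlog = 2,
                                            expr_sdlog = 1)) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  seed <- as.integer(seed)
  if (is.na(seed) || seed < 0 || seed >= 2^30) stop("seed must be an integer in [0, 2^30)")
  if (is.null(callers)) {
    eps <- c(0.002, 0.008, 0.014, 0.02)
    callers <- stats::setNames(lapply(eps, function(e) {
      list(detection_prob = 0.9, genotype_error_rate = e,
           missing_rate = 0.02, qual_below30_frac = 0.1)
    }), c("GATK", "gVCF_GATK", "FreeBayes", "Mpileup"))
  }
  probs <- c(unlist(lapply(callers, function(cl)
    c(cl$detection_prob, cl$genotype_error_rate, cl$missing_rate,
      cl$qual_below30_frac))),
    shared_error_rate, unlist(contaminants))
  if (any(probs < 0 | probs > 1)) stop("all probabilities must be in [0, 1]")
  if (fst <= 0 || fst >= 1) stop("fst must lie strictly in (0, 1)")
  structure(list(seed = seed, n_populations = n_populations,
                 samples_per_population = samples_per_population,
                 n_sites = n_sites, fst = fst, callers = callers,
                 shared_error_rate = shared_error_rate,
                 contaminants = contaminants, genome = genome),
            class = "simulation_config")
}

#' Simulate an annotated genome with expression-graded genes
#'
#' Lays out non-overlapping multi-exon gene models (explicit 5'/3' UTRs and
#' CDS intervals with phases; total CDS length divisible by 3) on random
#' reference sequences, and draws per-gene expression from a log-normal.
#'
#' @param config A [simulation_config()].
#' @return List with `annotation` (a [genome_annotation()]) and `expression`
#'   (data frame `gene_id`, `expression`).
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 1L)
  g <- config$genome
  chroms <- sprintf("Chr%02d", seq_len(g$n_chroms))
  reference <- stats::setNames(vapply(chroms, function(ch) {
    paste(sample(c("A", "C", "G", "T"), g$chrom_length, replace = TRUE),
          collapse = "")
  }, character(1)), chroms)
  chrom_lengths <- stats::setNames(rep(as.integer(g$chrom_length),
                                       g$n_chroms), chroms)

  per_chrom <- rep(g$n_genes %/% g$n_chroms, g$n_chroms)
  extra <- g$n_genes %% g$n_chroms
  if (extra > 0) per_chrom[seq_len(extra)] <- per_chrom[seq_len(extra)] + 1L

  # one gene per equal-width slot so genes (and hence expression-coupled
  # SNP placement) spread over every window of every chromosome
  genes <- list(); features <- list(); gi <- 0L
  for (ci in seq_len(g$n_chroms)) {
    slot <- g$chrom_length %/% per_chrom[ci]
    if (slot < 4000) stop("chrom_length too small for n_genes gene slots")
    for (k in seq_len(per_chrom[ci])) {
      gi <- gi + 1L
      gid <- sprintf("gene%03d", gi)
      start <- (k - 1L) * slot + sample.int(slot - 3500L, 1)
      mdl <- build_gene_model(gid, chroms[ci], as.integer(start))
      genes[[length(genes) + 1]] <- mdl$gene
      features[[length(features) + 1]] <- mdl$features
    }
  }
  genes <- do.call(rbind, genes)
  features <- do.call(rbind, features)
  expression <- data.frame(
    gene_id = genes$gene_id,
    expression = round(stats::rlnorm(nrow(genes), g$expr_meanlog, g$expr_sdlog), 4),
    stringsAsFactors = FALSE)
  list(annotation = genome_annotation(chrom_lengths, genes, features, reference),
       expression = expression)
}

# one gene model starting at `start`; returns gene row, feature rows, end pos
build_gene_model <- function(gid, chrom, start) {
  strand <- sample(c("+", "-"), 1)
  n_ex <- sample(2:4, 1)
  cds_len <- 3L * sample(60:180, 1)
  cuts <- sort(sample(seq_len(cds_len - 1), n_ex - 1))
  cds_w <- diff(c(0L, cuts, cds_len))
  intron_w <- sample(80:400, n_ex - 1, replace = TRUE)
  u5 <- sample(60:200, 1)
  u3 <- sample(60:200, 1)

  # genomic layout left -> right; left UTR is 5' on +, 3' on -
  left_u <- if (strand == "+") u5 else u3
  right_u <- if (strand == "+") u3 else u5
  if (strand == "-") cds_w <- rev(cds_w)   # translation runs right -> left

  rows <- list()
  pos <- start
  exon_bounds <- matrix(0L, nrow = n_ex, ncol = 2)
  cds_bounds <- matrix(0L, nrow = n_ex, ncol = 2)
  for (i in seq_len(n_ex)) {
    ex_start <- pos
    if (i == 1) {
      rows[[length(rows) + 1]] <- data.frame(
        gene_id = gid, type = if (strand == "+") "five_prime_UTR" else "three_prime_UTR",
        start = pos, end = pos + left_u - 1L, phase = NA_integer_)
      pos <- pos + left_u
    }
    cds_bounds[i, ] <- c(pos, pos + cds_w[i] - 1L)
    pos <- pos + cds_w[i]
    if (i == n_ex) {
      rows[[length(rows) + 1]] <- data.frame(
        gene_id = gid, type = if (strand == "+") "three_prime_UTR" else "five_prime_UTR",
        start = pos, end = pos + right_u - 1L, phase = NA_integer_)
      pos <- pos + right_u
    }
    exon_bounds[i, ] <- c(ex_start, pos - 1L)
    if (i < n_ex) pos <- pos + intron_w[i]
  }
  # CDS phases in translation order
  tr_order <- if (strand == "+") seq_len(n_ex) else rev(seq_len(n_ex))
  widths_tr <- cds_bounds[tr_order, 2] - cds_bounds[tr_order, 1] + 1L
  phase_tr <- c(0L, (3L - cumsum(widths_tr)[-n_ex] %% 3L) %% 3L)
  phases <- integer(n_ex)
  phases[tr_order] <- phase_tr
  for (i in seq_len(n_ex)) {
    rows[[length(rows) + 1]] <- data.frame(
      gene_id = gid, type = "CDS", start = cds_bounds[i, 1],
      end = cds_bounds[i, 2], phase = phases[i])
    rows[[length(rows) + 1]] <- data.frame(
      gene_id = gid, type = "exon", start = exon_bounds[i, 1],
      end = exon_bounds[i, 2], phase = NA_integer_)
  }
  features <- do.call(rbind, rows)
  list(gene = data.frame(gene_id = gid, chrom = chrom, strand = strand,
                         start = start, end = pos - 1L,
                         stringsAsFactors = FALSE),
       features = cbind(features, stringsAsFactors = FALSE),
       end = pos - 1L)
}

#' Simulate the true genotype table of a structured population
#'
#' Per site: an ancestral allele frequency p ~ Uniform(0.05, 0.95), a
#' per-population frequency from the Balding-Nichols Beta distribution
#' Beta(p(1-F)/F, (1-p)(1-F)/F), and Hardy-Weinberg genotypes within each
#' population. SNP positions are drawn per 100-kb window with probability
#' proportional to the window's summed gene expression (plus a small
#' intergenic baseline), which makes the density-expression relationship of
#' the downstream summaries testable by construction.
#'
#' @param config A [simulation_config()].
#' @param annotation Optional result of [simulate_annotation()]; generated
#'   from `config` when omitted.
#' @return List with `truth` (a [variant_table()]; the true genotypes),
#'   `labels` (population of each sample), `annotation`, `expression` and
#'   `bookkeeping` (per-site ancestral and population frequencies and window
#'   assignment).
#' @export
simulate_truth <- function(config, annotation = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(annotation)) annotation <- simulate_annotation(config)
  ann <- annotation$annotation
  expr <- annotation$expression
  set.seed(config$seed)

  w <- config$genome$window_size
  win <- window_table(ann, w)
  gkey <- paste(ann$genes$chrom, (ann$genes$start - 1) %/% w + 1, sep = ":")
  esum <- tapply(expr$expression[match(ann$genes$gene_id, expr$gene_id)],
                 gkey, sum)
  win$expr_sum <- ifelse(win$key %in% names(esum), as.numeric(esum[win$key]), 0)
  baseline <- 0.05 * mean(win$expr_sum)
  weight <- win$expr_sum + baseline
  n_per_win <- as.integer(stats::rmultinom(1, config$n_sites, weight / sum(weight)))

  pos_l <- vector("list", nrow(win))
  for (i in seq_len(nrow(win))) {
    if (n_per_win[i] == 0) next
    pos_l[[i]] <- data.frame(
      chrom = win$chrom[i],
      pos = sort(sample(win$start[i]:win$end[i], n_per_win[i])),
      window = win$key[i], stringsAsFactors = FALSE)
  }
  placed <- do.call(rbind, pos_l)
  placed <- placed[order(placed$chrom, placed$pos), , drop = FALSE]
  n <- nrow(placed)

  ref <- substring(ann$reference[placed$chrom],
                   placed$pos, placed$pos)
  alt <- other_base(ref, stats::runif(n))

  npop <- config$n_populations
  spp <- config$samples_per_population
  p <- stats::runif(n, 0.05, 0.95)
  a <- p * (1 - config$fst) / config$fst
  b <- (1 - p) * (1 - config$fst) / config$fst
  pop_freq <- matrix(0, n, npop)
  for (k in seq_len(npop)) pop_freq[, k] <- stats::rbeta(n, a, b)

  labels <- rep(seq_len(npop), each = spp)
  samples <- sprintf("pop%d_g%d", labels, rep(seq_len(spp), npop))
  geno <- matrix(NA_character_, n, length(samples))
  gt_levels <- c("0/0", "0/1", "1/1")
  for (j in seq_along(samples)) {
    dos <- stats::rbinom(n, 2, pop_freq[, labels[j]])
    geno[, j] <- gt_levels[dos + 1]
  }
  sites <- data.frame(chrom = placed$chrom, pos = placed$pos, ref = ref,
                      alt = alt, qual = 90, kind = "SNP",
                      stringsAsFactors = FALSE)
  truth <- variant_table(samples, sites, geno)
  book <- data.frame(key = site_keys(truth), window = placed$window,
                     ancestral_freq = p, stringsAsFactors = FALSE)
  book <- cbind(book, stats::setNames(as.data.frame(pop_freq),
                                      sprintf("pop%d_freq", seq_len(npop))))
  list(truth = truth, labels = stats::setNames(labels, samples),
       annotation = annotation$annotation, expression = expr,
       bookkeeping = book)
}

window_table <- function(ann, window_size) {
  out <- lapply(names(ann$chrom_lengths), function(ch) {
    len <- ann$chrom_lengths[[ch]]
    n_win <- ceiling(len / window_size)
    start <- (seq_len(n_win) - 1L) * window_size + 1L
    data.frame(chrom = ch, start = start,
               end = pmin(start + window_size - 1, len),
               key = paste(ch, seq_len(n_win), sep = ":"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# deterministic "pick another base": u in [0,1) selects one of the 3 others
other_base <- function(ref, u) {
  bases <- c("A", "C", "G", "T")
  vapply(seq_along(ref), function(i) {
    others <- bases[bases != ref[i]]
    others[1 + floor(u[i] * 3) %% 3]
  }, character(1))
}

#' Simulate per-caller corrupted variant tables
#'
#' Applies each caller's error model to the truth: a site is detected with
#' `detection_prob`; per sample, the true genotype is replaced by one of the
#' two other biallelic genotypes with probability `genotype_error_rate / 2`
#' each and set missing with probability `missing_rate`; QUAL is drawn so
#' that `qual_below30_frac` of sites fall below 30. Contaminant indel,
#' multiallelic and interspecific fixed-difference records are injected at
#' the configured fractions at positions free of true SNPs, with QUAL >= 30
#' so that exactly one filter stage is responsible for removing each class.
#' With `shared_error_rate > 0`, a corresponding fraction of genotype errors
#' is drawn once and copied into every caller, emulating callers that read
#' the same alignments.
#'
#' @param sim Result of [simulate_truth()].
#' @param config The same [simulation_config()].
#' @param run Experiment index (default 1); a second run of the same truth
#'   with `run = 2` draws an independent corruption realization, emulating a
#'   repeated sequencing experiment on the same genotypes.
#' @return List with `callers` (a [caller_set()]) and `bookkeeping`
#'   (per-caller detected site keys, corruption counts and contaminant keys
#'   by class).
#' @export
simulate_callers <- function(sim, config, run = 1L) {
  stopifnot(inherits(config, "simulation_config"))
  truth <- sim$truth
  set.seed(config$seed + 2L + 1000L * (as.integer(run) - 1L))
  n <- n_sites(truth)
  m <- n_samples(truth)
  G <- truth$geno

  shared_err <- matrix(FALSE, n, m)
  shared_g <- NULL
  if (config$shared_error_rate > 0) {
    shared_err <- matrix(stats::runif(n * m) < config$shared_error_rate, n, m)
    shared_g <- G
    shared_g[shared_err] <- wrong_genotype(G[shared_err],
                                           stats::runif(sum(shared_err)))
  }

  free_pos <- contaminant_positions(sim, config)
  tables <- list()
  book <- list()
  for (nm in names(config$callers)) {
    cl <- config$callers[[nm]]
    det <- stats::runif(n) < cl$detection_prob
    Gc <- G
    if (!is.null(shared_g)) Gc[shared_err] <- shared_g[shared_err]
    err <- matrix(stats::runif(n * m) < cl$genotype_error_rate, n, m) & !shared_err
    if (any(err)) Gc[err] <- wrong_genotype(G[err], stats::runif(sum(err)))
    miss <- matrix(stats::runif(n * m) < cl$missing_rate, n, m)
    Gc[miss] <- NA_character_

    low <- stats::runif(n) < cl$qual_below30_frac
    qual <- ifelse(low, stats::runif(n, 10, 29.9), stats::runif(n, 30, 90))

    sites <- truth$sites[det, , drop = FALSE]
    sites$qual <- round(qual[det], 2)
    cont <- make_contaminants(sim, config, free_pos[[nm]], m)
    tab <- variant_table(truth$samples,
                         rbind(sites, cont$sites),
                         rbind(Gc[det, , drop = FALSE], cont$geno))
    tables[[nm]] <- tab
    book[[nm]] <- list(detected_keys = site_keys(truth)[det],
                       n_genotype_errors = sum((err | shared_err) & det),
                       n_missing = sum(miss & det),
                       contaminant_keys = cont$keys)
  }
  list(callers = caller_set(tables), bookkeeping = book)
}

# replace genotype g by one of the two other biallelic genotypes, u uniform
wrong_genotype <- function(g, u) {
  others <- rbind("0/0" = c("0/1", "1/1"),
                  "0/1" = c("0/0", "1/1"),
                  "1/1" = c("0/0", "0/1"))
  pick <- 1L + (u < 0.5)
  others[cbind(match(g, rownames(others)), pick)]
}

# reserve disjoint contaminant positions per caller, away from true SNPs
contaminant_positions <- function(sim, config) {
  n <- n_sites(sim$truth)
  frac <- config$contaminants
  per_caller <- round(n * (frac$indel + frac$multiallelic + frac$fixed_difference))
  ann <- sim$annotation
  chroms <- names(ann$chrom_lengths)
  used <- paste(sim$truth$sites$chrom, sim$truth$sites$pos)
  out <- list()
  for (nm in names(config$callers)) {
    chrom <- sample(chroms, per_caller, replace = TRUE)
    pos <- vapply(chrom, function(ch)
      sample(10:(ann$chrom_lengths[[ch]] - 10), 1), numeric(1))
    keep <- !(paste(chrom, pos) %in% used) & !duplicated(paste(chrom, pos))
    out[[nm]] <- data.frame(chrom = chrom[keep], pos = as.integer(pos[keep]),
                            stringsAsFactors = FALSE)
  }
  out
}

make_contaminants <- function(sim, config, posdf, m) {
  n <- n_sites(sim$truth)
  frac <- config$contaminants
  counts <- c(indel = round(n * frac$indel),
              multiallelic = round(n * frac$multiallelic),
              fixed_difference = round(n * frac$fixed_difference))
  take <- min(sum(counts), nrow(posdf))
  cls <- rep(names(counts), counts)[seq_len(take)]
  posdf <- posdf[seq_len(take), , drop = FALSE]
  refseq <- sim$annotation$reference
  gt_levels <- c("0/0", "0/1", "1/1")

  sites <- list(); geno <- list(); keys <- list()
  for (class_ in unique(cls)) {
    idx <- which(cls == class_)
    if (length(idx) == 0) next
    ch <- posdf$chrom[idx]; po <- posdf$pos[idx]
    base <- substring(refseq[ch], po, po)
    if (class_ == "indel") {
      ref <- paste0(base, substring(refseq[ch], po + 1, po + 1))
      alt <- base
      g <- matrix(gt_levels[stats::rbinom(length(idx) * m, 2, 0.3) + 1],
                  length(idx), m)
    } else if (class_ == "multiallelic") {
      a1 <- other_base(base, stats::runif(length(idx)))
      a2 <- other_base2(base, a1)
      ref <- base
      alt <- paste(a1, a2, sep = ",")
      pool <- c("0/0", "0/1", "1/1", "0/2", "2/2", "1/2")
      g <- matrix(pool[1 + floor(stats::runif(length(idx) * m) * 6)],
                  length(idx), m)
    } else {
      ref <- base
      alt <- other_base(base, stats::runif(length(idx)))
      g <- matrix("1/1", length(idx), m)
    }
    sdf <- data.frame(chrom = ch, pos = po, ref = ref, alt = alt,
                      qual = round(stats::runif(length(idx), 30, 90), 2),
                      kind = classify_kind(ref, alt), stringsAsFactors = FALSE)
    sites[[class_]] <- sdf
    geno[[class_]] <- g
    keys[[class_]] <- paste(sdf$chrom, sdf$pos, sdf$ref, sdf$alt, sep = ":")
  }
  list(sites = do.call(rbind, sites), geno = do.call(rbind, geno), keys = keys)
}

# a third base distinct from ref and alt1 (deterministic: first in ACGT order)
other_base2 <- function(ref, alt1) {
  bases <- c("A", "C", "G", "T")
  vapply(seq_along(ref), function(i) {
    setdiff(bases, c(ref[i], alt1[i]))[1]
  }, character(1))
}

#' Simulate an array-genotype truth table from the true genotypes
#'
#' Draws a random marker subset of the truth sites, recodes genotypes to
#' nucleotide pairs, applies independent chip genotyping errors, and
#' optionally swaps two samples' columns to create a detectable
#' sample-identity failure.
#'
#' @param sim Result of [simulate_truth()].
#' @param n_markers Number of array markers (must not exceed the truth site
#'   count).
#' @param chip_error_rate Per-call genotype error rate on the chip, default 0.
#' @param seed Integer seed.
#' @param swap_samples Optional character vector of two sample ids whose
#'   chip columns are exchanged.
#' @return A `truth_table`.
#' @export
simulate_chip <- function(sim, n_markers, chip_error_rate = 0, seed,
                          swap_samples = NULL) {
  truth <- sim$truth
  if (n_markers > n_sites(truth)) stop("n_markers exceeds the number of truth sites")
  set.seed(as.integer(seed))
  idx <- sort(sample(n_sites(truth), n_markers))
  s <- truth$sites[idx, , drop = FALSE]
  g <- truth$geno[idx, , drop = FALSE]
  if (chip_error_rate > 0) {
    err <- matrix(stats::runif(length(g)) < chip_error_rate, nrow(g), ncol(g))
    if (any(err)) g[err] <- wrong_genotype(g[err], stats::runif(sum(err)))
  }
  nuc <- matrix(NA_character_, nrow(g), ncol(g), dimnames = dimnames(g))
  for (j in seq_len(ncol(g))) {
    a1 <- ifelse(substr(g[, j], 1, 1) == "0", s$ref, s$alt)
    a2 <- ifelse(substr(g[, j], 3, 3) == "0", s$ref, s$alt)
    nuc[, j] <- paste0(pmin(a1, a2), pmax(a1, a2))
  }
  if (!is.null(swap_samples)) {
    stopifnot(length(swap_samples) == 2, all(swap_samples %in% truth$samples))
    i1 <- match(swap_samples[1], truth$samples)
    i2 <- match(swap_samples[2], truth$samples)
    tmp <- nuc[, i1]
    nuc[, i1] <- nuc[, i2]
    nuc[, i2] <- tmp
  }
  markers <- data.frame(marker_id = sprintf("m%06d", seq_len(n_markers)),
                        chrom = s$chrom, pos = s$pos,
                        allele_a = pmin(s$ref, s$alt),
                        allele_b = pmax(s$ref, s$alt),
                        stringsAsFactors = FALSE)
  truth_table(markers, nuc)
}
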