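# shared fixture builders and independent oracles

# quick variant_table: geno is a matrix (sites x samples) or vector
mk_vt <- function(geno, pos = NULL, chrom = "Chr01", ref = "A", alt = "G",
                  qual = 50, samples = NULL) {
  if (is.null(dim(geno))) geno <- matrix(geno, nrow = 1)
  n <- nrow(geno)
  if (is.null(pos)) pos <- seq_len(n) * 10L
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(geno)))
  variant_table(samples,
                data.frame(chrom = rep_len(chrom, n), pos = pos,
                           ref = rep_len(ref, n), alt = rep_len(alt, n),
                           qual = rep_len(qual, n), stringsAsFactors = FALSE),
                geno)
}

# hand-written VCF fixture text, independent of write_vcf()
vcf_fixture_lines <- function(records, samples = c("s01", "s02")) {
  c("##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    records)
}

write_vcf_fixture <- function(records, samples = c("s01", "s02")) {
  path <- tempfile(fileext = ".vcf")
  writeLines(vcf_fixture_lines(records, samples), path)
  path
}

# ---- independent brute-force consensus oracles -----------------------------
# Deliberately naive: per-key loops and table() tallies, sharing no code path
# with intersect_strict()/consensus_genotypes().

oracle_geno_map <- function(table) {
  keys <- site_keys(table)
  out <- lapply(seq_along(keys), function(i) table$geno[i, ])
  names(out) <- keys
  out
}

oracle_intersect <- function(tables, min_callers, require_all = FALSE) {
  maps <- lapply(tables, oracle_geno_map)
  all_keys <- unique(unlist(lapply(maps, names)))
  need <- if (require_all) length(tables) else min_callers
  res <- structure(list(), names = character(0))
  for (k in all_keys) {
    vecs <- list()
    for (m in maps) if (k %in% names(m)) vecs[[length(vecs) + 1]] <- m[[k]]
    if (length(vecs) < need) next
    agree <- TRUE
    for (v in vecs[-1]) {
      same <- (is.na(v) & is.na(vecs[[1]])) |
        (!is.na(v) & !is.na(vecs[[1]]) & v == vecs[[1]])
      if (!all(same)) { agree <- FALSE; break }
    }
    if (agree) res[[k]] <- vecs[[1]]
  }
  res[order(names(res))]
}

oracle_consensus <- function(tables, min_agree) {
  maps <- lapply(tables, oracle_geno_map)
  all_keys <- unique(unlist(lapply(maps, names)))
  n_samples <- length(tables[[1]]$samples)
  res <- structure(list(), names = character(0))
  for (k in all_keys) {
    vecs <- list()
    for (m in maps) if (k %in% names(m)) vecs[[length(vecs) + 1]] <- m[[k]]
    if (length(vecs) < min_agree) next
    cons <- rep(NA_character_, n_samples)
    for (j in seq_len(n_samples)) {
      calls <- unlist(lapply(vecs, `[`, j))
      calls <- calls[!is.na(calls)]
      if (length(calls) == 0) next
      tab <- table(calls)
      if (max(tab) >= min_agree) cons[j] <- names(tab)[which.max(tab)]
    }
    if (any(!is.na(cons))) res[[k]] <- cons
  }
  res[order(names(res))]
}

# package output -> comparable key->genotype-vector list
as_geno_map <- function(table) {
  m <- oracle_geno_map(table)
  lapply(m[order(names(m))], unname)
}

random_micro_callerset <- function(seed, n_callers = 4, n_samples = 12) {
  set.seed(seed)
  samples <- sprintf("s%02d", seq_len(n_samples))
  n_pos <- sample(5:20, 1)
  pos <- sort(sample(seq_len(500), n_pos))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_pos, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  tabs <- lapply(seq_len(n_callers), function(ci) {
    det <- stats::runif(n_pos) < 0.8
    if (!any(det)) det[1] <- TRUE
    idx <- which(det)
    g <- matrix(sample(c("0/0", "0/1", "1/1", NA), length(idx) * n_samples,
                       replace = TRUE, prob = c(0.3, 0.3, 0.3, 0.1)),
                ncol = n_samples)
    variant_table(samples,
                  data.frame(chrom = "c1", pos = pos[idx], ref = ref[idx],
                             alt = alt[idx], qual = 50,
                             stringsAsFactors = FALSE),
                  g)
  })
  caller_set(stats::setNames(tabs, paste0("caller", seq_len(n_callers))))
}

# exhaustive enumeration over the 3^n caller-outcome table: each caller
# reports the true genotype w.p. 1-eps or one of the two other genotypes
# w.p. eps/2 each; consensus requires >= min_agree identical reports
enumerate_consensus <- function(eps, n_callers = 4, min_agree = 3) {
  outcomes <- as.matrix(expand.grid(rep(list(1:3), n_callers)))
  probs <- c(1 - eps, eps / 2, eps / 2)
  p_correct <- p_wrong <- p_missing <- 0
  for (r in seq_len(nrow(outcomes))) {
    o <- outcomes[r, ]
    pr <- prod(probs[o])
    counts <- tabulate(o, 3)
    if (counts[1] >= min_agree) p_correct <- p_correct + pr
    else if (max(counts[2:3]) >= min_agree) p_wrong <- p_wrong + pr
    else p_missing <- p_missing + pr
  }
  list(correct = p_correct, wrong = p_wrong, missing = p_missing)
}
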