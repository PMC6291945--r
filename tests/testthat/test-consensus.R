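mk_cs <- function(genos, pos = NULL, samples = NULL) {
  # genos: list of genotype matrices, one per caller, same sample count
  tabs <- lapply(genos, function(g) mk_vt(g, pos = pos, samples = samples))
  caller_set(stats::setNames(tabs, paste0("c", seq_along(tabs))))
}

test_that("caller_set validates roster identity and caller count", {
  a <- mk_vt(matrix("0/1", 1, 2))
  b <- mk_vt(matrix("0/1", 1, 2), samples = c("x", "y"))
  expect_error(caller_set(list(A = a, B = b)), "roster")
  expect_error(caller_set(list(A = a)), "between 2 and 8")
  expect_error(caller_set(list(a, a)), "named")
})

test_that("strict intersection needs co-detection and full unanimity", {
  # 4 callers, 2 samples, 5 sites:
  #  pos 10: in all 4, unanimous        -> strict3 and strict4
  #  pos 20: in 3 of 4, unanimous       -> strict3 only
  #  pos 30: in all 4, one caller disagrees for one sample -> neither
  #  pos 40: in 2 of 4                  -> neither
  #  pos 50: in all 4, missing matches  -> both (NA must match, and does)
  base <- rbind(c("0/1", "1/1"), c("0/0", "0/1"), c("0/1", "0/1"),
                c("1/1", "1/1"), c(NA, "0/1"))
  g1 <- base
  g2 <- base
  g3 <- base[-4, ]
  g4 <- base[-c(2, 4), ]
  g4[2, 1] <- "0/0"   # pos 30 disagreement, sample 1
  cs <- caller_set(list(c1 = mk_vt(g1, pos = c(10L, 20L, 30L, 40L, 50L)),
                        c2 = mk_vt(g2, pos = c(10L, 20L, 30L, 40L, 50L)),
                        c3 = mk_vt(g3, pos = c(10L, 20L, 30L, 50L)),
                        c4 = mk_vt(g4, pos = c(10L, 30L, 50L))))
  s3 <- intersect_strict(cs, 3)
  s4 <- intersect_strict(cs, 4)
  expect_setequal(s3$sites$pos, c(10L, 20L, 50L))
  expect_setequal(s4$sites$pos, c(10L, 50L))
  expect_equal(unname(s3$geno[s3$sites$pos == 50, ]), c(NA, "0/1"))
  # matches the brute-force oracle exactly
  expect_identical(as_geno_map(s3), lapply(oracle_intersect(cs$tables, 3), unname))
  expect_identical(as_geno_map(s4), lapply(oracle_intersect(cs$tables, 4), unname))
})

test_that("a position with mismatching ref/alt pairs is not co-detected", {
  t1 <- mk_vt(matrix("0/1", 1, 2), pos = 10L, alt = "G")
  t2 <- mk_vt(matrix("0/1", 1, 2), pos = 10L, alt = "T")
  t3 <- mk_vt(matrix("0/1", 1, 2), pos = 10L, alt = "G")
  cs <- caller_set(list(a = t1, b = t2, c = t3))
  expect_equal(n_sites(intersect_strict(cs, 3)), 0)
  expect_equal(site_keys(intersect_strict(cs, 2)), "Chr01:10:A:G")
})

test_that("consensus votes per individual with missing as fallback only", {
  pos <- c(10L, 20L, 30L)
  # sample 1: 3 of 4 agree at pos 10 -> 0/1 ; 2-2 split at pos 20 -> NA
  g1 <- rbind(c("0/1", "0/0"), c("0/1", "0/0"), c("0/1", NA))
  g2 <- rbind(c("0/1", "0/0"), c("0/1", "0/0"), c("0/1", "1/1"))
  g3 <- rbind(c("0/1", "0/0"), c("0/0", "0/0"), c("0/1", "1/1"))
  g4 <- rbind(c("0/0", "0/0"), c("0/0", "0/0"), NULL)
  cs <- caller_set(list(c1 = mk_vt(g1, pos = pos), c2 = mk_vt(g2, pos = pos),
                        c3 = mk_vt(g3, pos = pos),
                        c4 = mk_vt(g4, pos = pos[1:2])))
  cons <- consensus_genotypes(cs, 3)
  g <- cons$geno[match(c(10L, 20L, 30L), cons$sites$pos), ]
  expect_equal(unname(g[1, ]), c("0/1", "0/0"))
  expect_equal(unname(g[2, ]), c(NA, "0/0"))
  # pos 30: detected by exactly 3, one call missing -> only 2 votes -> NA
  expect_equal(unname(g[3, ]), c("0/1", NA))
  expect_identical(as_geno_map(cons), lapply(oracle_consensus(cs$tables, 3), unname))
})

test_that("consensus rejects impossible agreement thresholds", {
  cs <- mk_cs(list(matrix("0/1", 1, 2), matrix("0/1", 1, 2),
                   matrix("0/1", 1, 2), matrix("0/1", 1, 2)))
  expect_error(consensus_genotypes(cs, 5), "exceeds")
  expect_error(consensus_genotypes(cs, 2), "half")
})

test_that("strict intersections nest and embed in the consensus set", {
  set.seed(99)
  for (rep in 1:10) {
    cs <- random_micro_callerset(1000 + rep)
    s4 <- intersect_strict(cs, 4)
    s3 <- intersect_strict(cs, 3)
    s2 <- intersect_strict(cs, 2)
    expect_true(all(site_keys(s4) %in% site_keys(s3)))
    expect_true(all(site_keys(s3) %in% site_keys(s2)))
    cons <- consensus_genotypes(cs, 3)
    expect_true(all(site_keys(s3) %in% site_keys(cons)))
    shared <- site_keys(s3)
    if (length(shared) > 0) {
      expect_identical(s3$geno[match(shared, site_keys(s3)), , drop = FALSE],
                       cons$geno[match(shared, site_keys(cons)), , drop = FALSE])
    }
    # every consensus genotype was reported verbatim by >= 3 callers
    ck <- site_keys(cons)
    for (i in seq_along(ck)) {
      for (j in seq_along(cs$samples)) {
        g <- cons$geno[i, j]
        if (is.na(g)) next
        votes <- sum(vapply(cs$tables, function(t) {
          k <- match(ck[i], site_keys(t))
          !is.na(k) && !is.na(t$geno[k, j]) && t$geno[k, j] == g
        }, logical(1)))
        expect_gte(votes, 3)
      }
    }
  }
})

test_that("exhaustive 81-outcome enumeration gives the consensus accuracy", {
  en <- enumerate_consensus(eps = 0.1, n_callers = 4, min_agree = 3)
  expect_equal(en$correct, 0.9477, tolerance = 1e-12)
  expect_equal(en$correct + en$wrong + en$missing, 1, tolerance = 1e-12)
  # at eps = 0 consensus is always right
  en0 <- enumerate_consensus(0)
  expect_equal(en0$correct, 1)
})

test_that("zero-error callers give identical sets across all modalities", {
  cfg <- simulation_config(
    seed = 5, n_sites = 500,
    callers = stats::setNames(rep(list(list(detection_prob = 1,
                                            genotype_error_rate = 0,
                                            missing_rate = 0,
                                            qual_below30_frac = 0)), 4),
                              paste0("c", 1:4)),
    contaminants = list(indel = 0, multiallelic = 0, fixed_difference = 0))
  sim <- simulate_truth(cfg)
  cal <- simulate_callers(sim, cfg)
  grid <- modality_grid(cal$callers)
  expect_true(all(grid$counts$noNA == grid$counts$noNA[1]))
  expect_true(all(grid$counts$anyNA == grid$counts$noNA[1]))
  for (t in grid$tables) expect_identical(site_keys(t), site_keys(sim$truth))
})
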