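test_that("occurrence sets respect exact matching on both strands", {
  regs <- data.frame(chrom = "chr1", start = 0L, end = 30L,
                     id = paste0("r", 1:3))
  seqs <- Biostrings::DNAStringSet(c(
    paste0("AACCGGTT", strrep("A", 22)),            # forward hit
    paste0(strrep("C", 22), "AACCGGTT"),            # forward hit
    paste0(strrep("G", 11), revcomp("TTGGCCAA"), strrep("G", 11))))
  ds <- new_dhs_dataset("t", NA, regs, seqs)
  occ <- occurrence_sets(c("AACCGGTT", "TTGGCCAA", "ACACACAC"), ds)
  expect_identical(occ$AACCGGTT, c(1L, 2L))
  # reverse-complement-only occurrence still counts
  expect_identical(occ$TTGGCCAA, 3L)
  expect_length(occ$ACACACAC, 0L)
})

test_that("module p-values equal the exact binomial tail", {
  # sets of sizes 6 and 5 over n = 10 with intersection 5:
  # q = 0.3, P(X >= 5 | 10, 0.3)
  sets <- list(1:6, 1:5)
  expect_equal(module_pvalue(sets, 10L), 0.1502683, tolerance = 1e-6)
  expect_equal(module_pvalue(sets, 10L), oracle_binom_tail(5, 10, 0.3),
               tolerance = 1e-12)
  # empty member set -> 1 by convention
  expect_equal(module_pvalue(list(1:3, integer(0)), 10L), 1)
  # disjoint sets: support 0 -> 1
  expect_equal(module_pvalue(list(1:3, 4:6), 10L), 1)
  # saturated null: both sets cover everything
  expect_equal(module_pvalue(list(1:10, 1:10), 10L), 1)
})

test_that("pattern overlap eligibility matches the brute-force rule", {
  cases <- rbind(
    c("AGGGCCCT", "AAGGGCCC"),   # shift by one
    c("ACGAGAAC", "AGTTCTCG"),   # shift via reverse complement
    c("AAAACCCC", "GGGGTTTT"),   # rc-identical pair
    c("AACCGGTT", "ACGTACGA"),   # unrelated
    c("TTTGAAAA", "TTTCAAAA"))   # rc-shift
  for (i in seq_len(nrow(cases))) {
    expect_identical(pattern_overlap_exceeds(cases[i, 1], cases[i, 2], 5L),
                     oracle_overlap_too_long(cases[i, 1], cases[i, 2], 5L),
                     label = paste(cases[i, ], collapse = "/"))
  }
  # vectorized form agrees with elementwise
  a <- cases[, 1]; b <- cases[, 2]
  expect_identical(pattern_overlap_exceeds(a, b, 5L),
                   mapply(oracle_overlap_too_long, a, b, 5L,
                          USE.NAMES = FALSE))
})

test_that("a planted pair is reported with exact support", {
  out <- fixture_planted()
  ds <- out$datasets[[1]]
  cons <- canonical_pattern(vapply(out$spec$motifs, attr, "", "consensus"))
  occ <- occurrence_sets(cons, ds)
  mods <- discover_modules(occ, nrow(ds$regions))
  keys <- vapply(mods$motif_ids, paste, character(1), collapse = ",")
  for (mod in out$spec$modules) {
    key <- paste(sort(cons[mod$members]), collapse = ",")
    expect_true(key %in% keys)
  }
  # support equals the exact intersection of member region sets
  for (i in seq_len(nrow(mods))) {
    expect_identical(mods$support[i],
                     length(Reduce(intersect, occ[mods$motif_ids[[i]]])))
  }
})

test_that("pruned search equals exhaustive enumeration on random instances", {
  cfg <- default_config()
  pats <- c("AAAACCCC", "AATTGGCC", "ACACGTGT", "AGAGAGCC", "CCGGAATT",
            "CATGCATC", "GATCGATG", "TACGTACG", "AAGGCCTT", "ACCGGTAC")
  for (inst in 1:10) {
    set.seed(500 + inst)
    n_regions <- sample(20:50, 1)
    m <- sample(6:10, 1)
    occ <- stats::setNames(lapply(seq_len(m), function(i) {
      sort(sample.int(n_regions, rbinom(1, n_regions, runif(1, 0.1, 0.6))))
    }), pats[seq_len(m)])
    # implant a correlated trio so some instances have signal
    core <- sort(sample.int(n_regions, ceiling(n_regions / 2)))
    occ[[1]] <- sort(union(occ[[1]], core))
    occ[[2]] <- sort(union(occ[[2]], core))
    occ[[3]] <- sort(union(occ[[3]], core))
    got <- discover_modules(occ, n_regions, cfg)
    want <- oracle_modules(occ, n_regions, cfg)
    got_keys <- sort(vapply(got$motif_ids, paste, character(1),
                            collapse = ","))
    expect_identical(got_keys, want$key)
    ord <- match(want$key, vapply(got$motif_ids, paste, character(1),
                                  collapse = ","))
    expect_equal(got$support[ord], want$support)
    expect_equal(got$pvalue[ord], want$pvalue, tolerance = 1e-12)
  }
})

test_that("family-wise error stays controlled under an independent null", {
  cfg <- default_config()
  pats <- c("AAAACCCC", "AATTGGCC", "ACACGTGT", "AGAGAGCC", "CCGGAATT",
            "CATGCATC", "GATCGATG", "TACGTACG", "AAGGCCTT", "ACCGGTAC",
            "AGTCAGCA", "CTAGCAGA")
  set.seed(2024)
  n_false <- 0L
  for (rep in 1:100) {
    n_regions <- 100L
    occ <- stats::setNames(lapply(seq_along(pats), function(i) {
      which(runif(n_regions) < runif(1, 0.1, 0.5))   # independent patterns
    }), pats)
    if (nrow(discover_modules(occ, n_regions, cfg))) n_false <- n_false + 1L
  }
  expect_lte(n_false, 5L)   # nominal FWER 0.01 per replicate
})

test_that("discovery is invariant to region input order", {
  out <- fixture_planted()
  ds <- out$datasets[[1]]
  small <- new_dhs_dataset("s", NA, head(ds$regions, 300),
                           head(ds$sequences, 300))
  set.seed(42)
  perm <- sample.int(300)
  shuffled <- new_dhs_dataset("s", NA, small$regions[perm, ],
                              small$sequences[perm])
  cons <- canonical_pattern(vapply(out$spec$motifs, attr, "", "consensus"))
  occ1 <- occurrence_sets(cons, small)
  occ2 <- occurrence_sets(cons, shuffled)
  m1 <- discover_modules(occ1, 300L)
  m2 <- discover_modules(occ2, 300L)
  k1 <- sort(vapply(m1$motif_ids, paste, character(1), collapse = ","))
  k2 <- sort(vapply(m2$motif_ids, paste, character(1), collapse = ","))
  expect_identical(k1, k2)
  expect_equal(sort(m1$support), sort(m2$support))
})

test_that("reported modules are anti-monotone in support", {
  out <- fixture_planted()
  ds <- out$datasets[[1]]
  st <- run_discovery(ds)
  keys <- lapply(st$modules$motif_ids, identity)
  if (nrow(st$modules) >= 2L) {
    for (i in seq_along(keys)) {
      for (j in seq_along(keys)) {
        if (i != j && all(keys[[i]] %in% keys[[j]])) {
          expect_gte(st$modules$support[i], st$modules$support[j])
        }
      }
    }
  }
  # every discovered motif appears in some module
  expect_setequal(st$motifs, unique(unlist(st$modules$motif_ids)))
})

test_that("the discovery loop obeys its stopping rules", {
  out <- fixture_planted()
  ds <- out$datasets[[1]]
  cfg <- default_config(motif_cap = 2L)
  st <- run_discovery(ds, cfg)
  # cap checked after each round: at most cap + max module members overshoot
  expect_lte(length(st$motifs), 2L + 6L - 1L)
  st2 <- run_discovery(ds)
  expect_true(st2$rounds_without_new <= default_config()$stop_rounds_r)
  expect_true(length(st2$motifs) >= 4L)   # both planted pairs recovered
})
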