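flank_fixture <- function(n_sites = 12L, left = NULL, right = NULL,
                          core = "ACGTTGCA", seed = 7L) {
  set.seed(seed)
  seqs <- vapply(seq_len(n_sites), function(i) {
    rnd <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                             collapse = "")
    paste0(rnd(10), if (is.null(left)) rnd(1) else left, core,
           if (is.null(right)) rnd(1) else right, rnd(10))
  }, character(1))
  list(sequences = Biostrings::DNAStringSet(seqs),
       sites = data.frame(region = seq_len(n_sites), offset = 11L,
                          strand = "+", width = nchar(core)))
}

test_that("PWMs from aligned sites follow the pseudocount rule", {
  fx <- flank_fixture(10L)
  m0 <- build_pwm(fx$sites, fx$sequences, pseudocount = 0)
  expect_true(all(apply(m0$matrix, 1L, max) == 1))   # identical sites
  m <- build_pwm(fx$sites, fx$sequences, pseudocount = 0.25)
  expect_equal(max(m$matrix), 10.25 / 11, tolerance = 1e-12)
  expect_lt(max(abs(rowSums(m$matrix) - 1)), 1e-12)
  # minus-strand sites are reverse-complemented before counting
  seqs <- Biostrings::DNAStringSet(c("AACCGGTTAA", "TTAACCGGTT"))
  sites <- data.frame(region = 1:2, offset = c(1L, 2L),
                      strand = c("+", "-"), width = 8L)
  # site 1 fwd: ACCGGTTA; site 2 rev: revcomp(AACCGGTT) = AACCGGTT
  mm <- build_pwm(sites, seqs, pseudocount = 0)
  s1 <- "ACCGGTTA"; s2 <- "AACCGGTT"
  for (p in 1:8) {
    b1 <- substr(s1, p, p); b2 <- substr(s2, p, p)
    if (b1 == b2) {
      expect_equal(unname(mm$matrix[p, b1]), 1)
    } else {
      expect_equal(unname(mm$matrix[p, b1]), 0.5)
      expect_equal(unname(mm$matrix[p, b2]), 0.5)
    }
  }
  expect_error(build_pwm(data.frame(region = 1L, offset = 5L,
                                    strand = "+", width = 8L),
                         seqs, 0.25),
               "beyond")
})

test_that("column information is 2 + sum p log2 p", {
  expect_equal(column_information(rep(0.25, 4)), 0)
  expect_equal(column_information(c(1, 0, 0, 0)), 2)
  expect_equal(column_information(c(0.5, 0.5, 0, 0)), 1)
})

test_that("length adjustment extends informative flanks only", {
  # every site flanked by C on the right: one extension, near-unit column
  fx <- flank_fixture(12L, right = "C")
  m <- build_pwm(fx$sites, fx$sequences, 0.25)
  adj <- adjust_length(m, fx$sequences, ic_min = 0.5)
  expect_gte(nrow(adj$matrix), 9L)
  # the column adjacent to the core on the right is (nearly) unit C
  expect_gt(adj$matrix[9L, "C"], 0.9)
  expect_true(all(adj$sites$width == nrow(adj$matrix)))
  # random flanks: no extension with enough sites
  fx2 <- flank_fixture(40L, seed = 21L)
  m2 <- build_pwm(fx2$sites, fx2$sequences, 0.25)
  adj2 <- adjust_length(m2, fx2$sequences, ic_min = 0.5)
  expect_identical(nrow(adj2$matrix), 8L)
  # idempotence
  adj_again <- adjust_length(adj, fx$sequences, ic_min = 0.5)
  expect_equal(adj_again$matrix, adj$matrix, tolerance = 1e-12)
  expect_identical(adj_again$sites, adj$sites)
})

test_that("length adjustment respects width bounds and sequence edges", {
  # constant flanks on both sides would extend forever; width_max stops it
  fx <- flank_fixture(10L, left = "G", right = "C")
  # make flanks constant beyond one bp by using fixed sequence context
  seqs <- Biostrings::DNAStringSet(rep(
    paste0("GGGGGGGGGGG", "ACGTTGCA", "CCCCCCCCCCC"), 10))
  sites <- data.frame(region = 1:10, offset = 11L, strand = "+",
                      width = 8L)
  m <- build_pwm(sites, seqs, 0.25)
  adj <- adjust_length(m, seqs, ic_min = 0.5, width_min = 6L,
                       width_max = 16L)
  expect_identical(nrow(adj$matrix), 16L)
  # a site at the sequence start freezes the left side
  seqs2 <- Biostrings::DNAStringSet(c("ACGTTGCAC",
                                      "TACGTTGCAC"))
  sites2 <- data.frame(region = 1:2, offset = c(0L, 1L), strand = "+",
                       width = 8L)
  m2 <- build_pwm(sites2, seqs2, 0.25)
  adj2 <- adjust_length(m2, seqs2, ic_min = 0.5)
  expect_identical(min(adj2$sites$offset), 0L)   # never ran off the edge
  expect_lte(nrow(adj2$matrix), 9L)
})

test_that("uninformative terminal columns are trimmed", {
  # 10-wide sites whose first column is random: IC ~ 0 -> trimmed
  set.seed(5)
  core <- "CGTTGCAAC"
  seqs <- Biostrings::DNAStringSet(vapply(1:30, function(i) {
    paste0(paste(sample(c("A", "C", "G", "T"), 12, TRUE), collapse = ""),
           core, paste(sample(c("A", "C", "G", "T"), 12, TRUE),
                       collapse = ""))
  }, character(1)))
  sites <- data.frame(region = 1:30, offset = 11L, strand = "+",
                      width = 10L)   # 1 random + core (9)
  m <- build_pwm(sites, seqs, 0.25)
  adj <- adjust_length(m, seqs, ic_min = 0.5, width_min = 6L)
  expect_lte(nrow(adj$matrix), 9L)
  expect_gt(min(apply(adj$matrix, 1L, column_information)), 0.4)
})

test_that("module updates after adjustment recompute supports", {
  out <- fixture_planted()
  ds <- out$datasets[[1]]
  st <- run_discovery(ds)
  motifs <- refine_motifs(st, ds)
  upd <- update_modules(st$modules, motifs)
  expect_true(all(upd$size >= 2L))
  region_sets <- lapply(motifs, function(m) unique(m$sites$region))
  for (i in seq_len(nrow(upd))) {
    expect_identical(upd$support[i],
                     length(Reduce(intersect,
                                   region_sets[upd$motif_ids[[i]]])))
  }
  # identity case: no motifs merged means membership preserved
  if (!anyDuplicated(vapply(motifs, modmotif:::site_key, character(1)))) {
    expect_setequal(unlist(upd$motif_ids), unlist(st$modules$motif_ids))
  }
  # all row-stochastic, widths within bounds
  for (m in motifs) {
    expect_lt(max(abs(rowSums(m$matrix) - 1)), 1e-9)
    expect_gte(nrow(m$matrix), 6L)
    expect_lte(nrow(m$matrix), 16L)
  }
})

test_that("motifs merging into identical site sets collapse their module", {
  seqs <- Biostrings::DNAStringSet(rep(strrep("ACGT", 8), 10))
  sites <- data.frame(region = 1:10, offset = 4L, strand = "+", width = 8L)
  mA <- build_pwm(sites, seqs, 0.25, id = "patA")
  mB <- build_pwm(sites, seqs, 0.25, id = "patB")   # same adjusted sites
  mC <- build_pwm(data.frame(region = 1:10, offset = 12L, strand = "+",
                             width = 8L), seqs, 0.25, id = "patC")
  modules <- data.frame(module_id = c("m1", "m2"), size = 2L,
                        support = 10L, pvalue = 1e-10,
                        corrected_pvalue = 1e-6, n_tested = 1)
  modules$motif_ids <- list(c("patA", "patB"), c("patA", "patC"))
  upd <- update_modules(modules, list(patA = mA, patB = mB, patC = mC))
  # m1 collapses (its two members merged into one motif); m2 survives
  keys <- vapply(upd$motif_ids, paste, character(1), collapse = ",")
  expect_identical(keys, "patA,patC")
  expect_identical(upd$support, 10L)
})
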