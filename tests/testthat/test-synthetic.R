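test_that("generated genomes match their background model", {
  g <- make_genome(1e6, gc = 0.5, markov_order = 2L, seed = 11L)
  gc <- sum(Biostrings::letterFrequency(g, c("C", "G"))) /
    sum(Biostrings::width(g))
  expect_lt(abs(gc - 0.5), 0.01)
  expect_error(make_genome(1e6, gc = 0), "gc")
  expect_error(make_genome(5000, gc = 0.5), "10 kb")
  g2 <- make_genome(50000, gc = 0.4, markov_order = 1L, seed = 3L)
  g3 <- make_genome(50000, gc = 0.4, markov_order = 1L, seed = 3L)
  expect_identical(as.character(g2), as.character(g3))
  bg <- attr(g2, "background")
  expect_equal(unname(rowSums(bg$trans)), rep(1, 4), tolerance = 1e-12)
})

test_that("gene models are valid and strand conventions hold", {
  g <- fixture_genome_300kb()
  ann <- make_annotation(g, 6L, seed = 5L)
  expect_equal(nrow(ann$genes), 6L)
  # genes do not overlap
  o <- order(ann$genes$start)
  expect_true(all(ann$genes$start[o][-1] >= ann$genes$end[o][-6]))
  # minus-strand TSS is the rightmost transcribed coordinate
  minus <- ann$genes$strand == "-"
  expect_true(all(ann$genes$tss[minus] == ann$genes$end[minus]))
  expect_true(all(ann$genes$tss[!minus] == ann$genes$start[!minus]))
  # every gene has >= 2 introns with a distinct first intron
  for (gid in ann$genes$gene_id) {
    introns <- ann$features[ann$features$gene_id == gid &
                            ann$features$feature == "intron", ]
    expect_gte(nrow(introns), 2L)
    expect_identical(sum(introns$rank == 1L), 1L)
    # first intron is nearest the TSS in transcription order
    gene <- ann$genes[ann$genes$gene_id == gid, ]
    d1 <- abs(introns$start[introns$rank == 1L] - gene$tss)
    d2 <- abs(introns$start[introns$rank == 2L] - gene$tss)
    if (gene$strand == "-") {
      d1 <- abs(gene$tss - introns$end[introns$rank == 1L])
      d2 <- abs(gene$tss - introns$end[introns$rank == 2L])
    }
    expect_lt(d1, d2)
  }
  # features stay inside their gene
  for (i in seq_len(nrow(ann$features))) {
    f <- ann$features[i, ]
    gene <- ann$genes[ann$genes$gene_id == f$gene_id, ]
    expect_gte(f$start, gene$start)
    expect_lte(f$end, gene$end)
  }
  expect_equal(nrow(make_annotation(g, 0L, seed = 1L)$genes), 0L)
  expect_error(make_annotation(g, 10000L, seed = 1L), "too small")
})

test_that("random motifs follow the normalized-uniform row rule", {
  for (s in 1:20) {
    m <- make_random_motif(8L, seed = s)
    expect_identical(dim(m), c(8L, 4L))
    expect_lt(max(abs(rowSums(m) - 1)), 1e-12)
    expect_true(all(m >= 0 & m <= 1))
  }
  expect_identical(make_random_motif(5L, seed = 9L),
                   make_random_motif(5L, seed = 9L))
  expect_false(identical(make_random_motif(5L, seed = 9L),
                         make_random_motif(5L, seed = 10L)))
  expect_equal(nrow(make_random_motif(8L, seed = 1L)), 8L)
})

test_that("planted sites are logged faithfully and rescannable", {
  out <- fixture_planted()
  ds <- out$datasets[[1]]
  log <- out$truth$site_log
  expect_gt(nrow(log), 0L)
  idx <- match(log$region, ds$regions$id)
  expect_false(anyNA(idx))
  w <- nchar(log$site)
  raw <- unname(substring(as.character(ds$sequences)[idx],
                          log$offset + 1L, log$offset + w))
  expect_identical(raw, log$site)            # sites never masked or moved
  expect_true(all(log$offset >= 0L))
  expect_true(all(log$offset + w <= 800L))   # inside the region
})

test_that("planting counts and mask fraction match their targets", {
  out <- fixture_planted()
  log <- out$truth$site_log
  # ~0.3 * 1000 = 300 regions per module; binomial 99.9% interval
  for (mod in out$spec$modules) {
    hosts <- length(unique(log$region[log$motif == mod$members[1]]))
    expect_gt(hosts, 250L)
    expect_lt(hosts, 350L)
  }
  n_frac <- sum(Biostrings::letterFrequency(out$datasets[[1]]$sequences,
                                            "N")) / (1000 * 800)
  expect_lt(abs(n_frac - 0.1), 0.02)
})

test_that("degenerate planting specs behave as stated", {
  g <- fixture_genome_300kb()
  fams <- make_motif_families(2L, seed = 77L)
  spec0 <- list(motifs = fams,
                modules = list(list(members = names(fams), prob = 0)))
  out0 <- plant_datasets(g, NULL, spec0, n_regions = 50L,
                         region_len = 400L, mask_fraction = 0,
                         seed = 1L)
  expect_equal(nrow(out0$truth$site_log), 0L)
  # region too short for all member sites
  wide <- list(motifs = list(a = make_planted_pwm(150L, seed = 1L),
                             b = make_planted_pwm(100L, seed = 2L)),
               modules = list(list(members = c("a", "b"), prob = 1)))
  expect_error(plant_datasets(g, NULL, wide, n_regions = 10L,
                              region_len = 200L, mask_fraction = 0,
                              seed = 1L),
               "too short")
  # region geometry: non-overlapping within a dataset
  regs <- out0$datasets[[1]]$regions
  o <- order(regs$start)
  expect_true(all(regs$start[o][-1] >= regs$end[o][-length(o)]))
})

test_that("typed collections plant shared and type-specific motifs", {
  coll <- make_typed_collection(3L, 4L, shared_motifs = 2L,
                                specific_motifs_per_type = 2L,
                                seed = 8L, genome = fixture_genome_300kb(),
                                n_regions = 60L, region_len = 400L)
  expect_length(coll$datasets, 12L)
  expect_equal(unname(table(coll$labels)), rep(4L, 3L),
               ignore_attr = TRUE)
  expect_length(coll$truth$type_profiles, 3L)
  for (prof in coll$truth$type_profiles) {
    expect_true(all(sprintf("shared%02d", 1:2) %in% prof))
  }
  log <- coll$truth$site_log
  # type-specific motifs appear only in their own type's datasets
  sp_ds <- unique(log$dataset[log$motif == "t01_m01"])
  expect_true(all(grepl("^type01", sp_ds)))
})

test_that("interaction lists are the module pair closure plus noise", {
  truth <- list(motifs = stats::setNames(
    lapply(1:5, function(i) make_random_motif(8L, seed = i)),
    c("A", "B", "C", "D", "E")),
    modules = list(list(members = c("A", "B", "C"), prob = 0.5)))
  pairs <- make_interactions(truth, noise_pairs = 0L)
  expect_identical(pairs,
                   data.frame(tf_a = c("A", "A", "B"),
                              tf_b = c("B", "C", "C"),
                              stringsAsFactors = FALSE))
  noisy <- make_interactions(truth, noise_pairs = 3L, seed = 2L)
  expect_equal(nrow(noisy), 6L)
  expect_true(all(noisy$tf_a < noisy$tf_b))   # symmetric canonical form
  expect_identical(noisy, make_interactions(truth, noise_pairs = 3L,
                                            seed = 2L))
})
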