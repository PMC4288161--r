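test_that("region types on the two-gene toy match hand-derived intervals", {
  ann <- fixture_toy_annotation()
  lens <- c(chr1 = 60000L)
  rt <- build_region_types(ann, lens, default_config())
  expect_length(attr(rt, "primary"), 16L)
  # proximal windows: gA '+' TSS 10000, gB '-' TSS 44000 (strand flip)
  expect_granges_equal(rt$proximal_tss,
                       cbind(c(7500, 44000), c(10000, 46500)))
  expect_granges_equal(rt$proximal_tts,
                       cbind(c(14000, 37500), c(16500, 40000)))
  # annotation-derived types
  expect_granges_equal(rt$five_utr, cbind(c(10000, 43800), c(10200, 44000)))
  expect_granges_equal(rt$three_utr, cbind(c(13800, 40000), c(14000, 40200)))
  expect_granges_equal(rt$first_intron,
                       cbind(c(10500, 43000), c(11000, 43400)))
  expect_granges_equal(rt$other_intron,
                       cbind(c(12000, 41000), c(12400, 41500)))
  # distal 2.5 kb: upstream/downstream rays minus other gene +- 2.5 kb
  expect_granges_equal(rt$distal_5p_2500,
                       cbind(c(0, 46500), c(7500, 60000)))
  expect_granges_equal(rt$distal_3p_2500,
                       cbind(c(0, 16500, 46500), c(7500, 37500, 60000)))
  # distal 10 kb: gA ray vanishes; gB rays clipped by the other gene
  expect_granges_equal(rt$distal_5p_10000, cbind(54000, 60000))
  expect_granges_equal(rt$distal_3p_10000,
                       cbind(c(24000, 54000), c(30000, 60000)))
  # 20 kb and 100 kb cutoffs exceed the toy geometry: empty
  expect_length(rt$distal_5p_20000, 0L)
  expect_length(rt$distal_3p_100000, 0L)
  # pure variants subtract the opposing type
  expect_granges_equal(rt$pure_proximal_tss,
                       cbind(c(7500, 44000), c(10000, 46500)))
  expect_length(rt$pure_distal_5p_2500, 0L)
  expect_granges_equal(rt$pure_distal_3p_2500, cbind(16500, 37500))
  # pure variants are subsets of their primaries
  for (nm in grep("^pure_", names(rt), value = TRUE)) {
    primary <- rt[[sub("^pure_", "", nm)]]
    inter <- GenomicRanges::intersect(rt[[nm]], primary)
    expect_equal(sum(GenomicRanges::width(inter)),
                 sum(GenomicRanges::width(rt[[nm]])))
  }
  # per-type interval sets are merged and disjoint
  for (nm in names(rt)) {
    expect_identical(length(GenomicRanges::reduce(rt[[nm]])),
                     length(rt[[nm]]))
  }
})

test_that("a single minus-strand gene gets the mirrored proximal window", {
  ann <- list(genes = data.frame(gene_id = "g", chrom = "chr1",
                                 start = 6000L, end = 10000L, strand = "-",
                                 tss = 10000L, tts = 6000L,
                                 stringsAsFactors = FALSE),
              features = fixture_toy_annotation()$features[0, ])
  class(ann) <- "modmotif_annotation"
  rt <- build_region_types(ann, c(chr1 = 50000L), default_config(),
                           pure = FALSE)
  expect_granges_equal(rt$proximal_tss, cbind(10000, 12500))
  expect_granges_equal(rt$proximal_tts, cbind(3500, 6000))
})

test_that("background fractions are DHS base-pair ratios", {
  regions <- data.frame(chrom = "chr1", start = c(0L, 2000L),
                        end = c(500L, 2500L), id = c("r1", "r2"))
  all_gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 10000))
  expect_equal(background_fraction(all_gr, regions), 1)
  off_gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5001, 6000))
  expect_equal(background_fraction(off_gr, regions), 0)
  part <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 200))
  expect_equal(background_fraction(part, regions), 200 / 1000)
  expect_error(background_fraction(all_gr, regions[0, ]), "zero")
})

test_that("enrichment p-values match the independent summation oracle", {
  r <- test_enrichment(10L, 5L, 0.2, n_tests = 1)
  expect_equal(r$pvalue, 0.0327935, tolerance = 1e-6)
  expect_equal(r$pvalue, oracle_binom_tail(5, 10, 0.2), tolerance = 1e-12)
  expect_equal(test_enrichment(10L, 3L, 1, 1)$pvalue, 1)
  expect_equal(test_enrichment(10L, 0L, 0.2, 1)$pvalue, 1)
  deg <- test_enrichment(10L, 2L, 0, 1)
  expect_true(deg$degenerate)
  expect_equal(deg$pvalue, 0)
  set.seed(123)
  for (i in 1:100) {
    n <- sample(1:50, 1); k <- sample(0:n, 1); p <- runif(1)
    expect_equal(test_enrichment(n, k, p, 1)$pvalue,
                 oracle_binom_tail(k, n, p), tolerance = 1e-12)
  }
})

test_that("module p-values also match the oracle on random cases", {
  set.seed(321)
  for (i in 1:100) {
    n <- sample(5:50, 1)
    sets <- lapply(1:sample(2:4, 1), function(j) {
      sort(sample.int(n, sample(0:n, 1)))
    })
    sizes <- lengths(sets)
    want <- if (any(sizes == 0)) 1 else
      oracle_binom_tail(length(Reduce(intersect, sets)), n,
                        prod(sizes / n))
    expect_equal(module_pvalue(sets, n), want, tolerance = 1e-12)
  }
})

test_that("profiles find planted location preference and control type I", {
  cfg <- default_config()
  g <- fixture_genome_300kb()
  ann <- make_annotation(g, 12L, seed = 17L)
  lens <- chrom_lengths(g)
  rt <- build_region_types(ann, lens, cfg)
  # DHS regions scattered genome-wide
  set.seed(31)
  starts <- sort(sample.int(lens[["chr1"]] - 400L, 300L))
  regions <- preprocess_regions(
    data.frame(chrom = "chr1", start = starts, end = starts + 400L,
               id = sprintf("d%03d", seq_along(starts))), lens, cfg)
  # motif A: all sites at proximal-TSS midpoints; motif B: uniform
  in_tss <- which(IRanges::overlapsAny(
    modmotif:::site_midpoints(data.frame(region = seq_len(nrow(regions)),
                                         offset = 200L, width = 8L),
                              regions),
    rt$proximal_tss))
  site_sets <- list(
    tss_motif = data.frame(region = rep(in_tss, length.out = 60L),
                           offset = 200L, width = 8L),
    uniform_motif = data.frame(
      region = sample.int(nrow(regions), 60L, replace = TRUE),
      offset = sample.int(780L, 60L, replace = TRUE), width = 8L))
  expect_gt(length(in_tss), 2L)
  prof <- enrichment_profile(site_sets, rt, regions, cfg)
  tssrow <- prof[prof$motif == "tss_motif" &
                 prof$region_type == "proximal_tss", ]
  expect_true(tssrow$enriched)
  distal <- prof[prof$motif == "tss_motif" &
                 grepl("^distal", prof$region_type), ]
  expect_false(any(distal$enriched))
  # a uniformly scattered motif shows no location preference
  unif <- prof[prof$motif == "uniform_motif", ]
  expect_false(any(unif$enriched))
})
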