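## Shared fixtures, built lazily and memoized for the test run ------------

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

## 1 Mb background genome shared across discovery tests.
fixture_genome_1mb <- function() {
  memo("genome_1mb",
       make_genome(1000000L, gc = 0.41, markov_order = 2L, seed = 20260901L))
}

## 300 kb genome for lighter tests.
fixture_genome_300kb <- function() {
  memo("genome_300kb",
       make_genome(300000L, gc = 0.41, markov_order = 2L, seed = 20260902L))
}

## Shared similarity engine (nulls calibrated once).
fixture_engine <- function() {
  memo("engine", new_similarity_engine(default_config(), seed = 20260903L))
}

## A planted dataset with two pair modules, reused by several tests.
fixture_planted <- function() {
  memo("planted", {
    fams <- make_motif_families(4L, seed = 20260904L)
    spec <- list(
      motifs = fams,
      modules = list(list(members = c("fam01", "fam02"), prob = 0.3),
                     list(members = c("fam03", "fam04"), prob = 0.3)))
    out <- plant_datasets(fixture_genome_1mb(), NULL, spec,
                          n_regions = 1000L, region_len = 800L,
                          mask_fraction = 0.1, seed = 20260905L)
    out$spec <- spec
    out
  })
}

## Perturbed-family motif sets for clustering tests: n_fam families,
## copies_per_ds copies of each family in each of n_ds datasets.
fixture_family_sets <- function(n_fam = 10L, n_ds = 10L,
                                copies_per_ds = 2L, amount = 0.25,
                                seed = 20260906L) {
  key <- paste("famsets", n_fam, n_ds, copies_per_ds, amount, seed)
  memo(key, {
    fams <- make_motif_families(n_fam, seed = seed)
    sets <- list()
    for (d in seq_len(n_ds)) {
      ms <- list()
      for (f in seq_len(n_fam)) {
        for (cc in seq_len(copies_per_ds)) {
          id <- sprintf("f%02d_d%02d_c%d", f, d, cc)
          ms[[length(ms) + 1L]] <- new_motif(
            id,
            perturb_motif(fams[[f]], amount,
                          seed = seed + 977L * f + 31L * d + cc),
            source_dataset = sprintf("ds%02d", d))
        }
      }
      sets[[sprintf("ds%02d", d)]] <- ms
    }
    list(families = fams, sets = sets)
  })
}

## Two-gene toy annotation (one gene per strand) used by region-geometry
## tests; intervals chosen so every hand derivation is short.
fixture_toy_annotation <- function() {
  ann <- list(
    genes = data.frame(
      gene_id = c("gA", "gB"), chrom = "chr1",
      start = c(10000L, 40000L), end = c(14000L, 44000L),
      strand = c("+", "-"),
      tss = c(10000L, 44000L), tts = c(14000L, 40000L),
      stringsAsFactors = FALSE),
    features = data.frame(
      gene_id = rep(c("gA", "gB"), each = 4L),
      feature = rep(c("five_utr", "three_utr", "intron", "intron"), 2L),
      chrom = "chr1",
      start = c(10000L, 13800L, 10500L, 12000L,
                43800L, 40000L, 43000L, 41000L),
      end = c(10200L, 14000L, 11000L, 12400L,
              44000L, 40200L, 43400L, 41500L),
      strand = rep(c("+", "-"), each = 4L),
      rank = rep(c(1L, 1L, 1L, 2L), 2L),
      stringsAsFactors = FALSE))
  class(ann) <- "modmotif_annotation"
  ann
}

expect_granges_equal <- function(gr, expected_0based) {
  df <- data.frame(start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr))
  df <- df[order(df$start), , drop = FALSE]
  rownames(df) <- NULL
  exp <- as.data.frame(expected_0based)
  names(exp) <- c("start", "end")
  exp <- exp[order(exp$start), , drop = FALSE]
  rownames(exp) <- NULL
  expect_equal(df, exp)
}
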