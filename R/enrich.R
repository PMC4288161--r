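#' Genomic region types and motif enrichment
#'
#' Sixteen region types are derived from a gene annotation: proximal TSS
#' and TTS windows (2.5 kb), 5'/3' UTRs, first and other introns, and 5'
#' and 3' distal territories at five distance cutoffs; "pure" variants
#' subtract the opposing type.  A motif's enrichment in a region type is
#' an exact upper-tail binomial test of its site count inside the type
#' against the fraction of DHS base pairs the type covers.
#'
#' @name region_enrichment
NULL

gr0 <- function(chrom, start0, end0) {
  keep <- end0 > start0
  GenomicRanges::GRanges(chrom[keep],
                         IRanges::IRanges(start = start0[keep] + 1L,
                                          end = end0[keep]))
}

reduce_gr <- function(gr) GenomicRanges::reduce(gr)

## intersect two GRanges that may disagree on seqlevels.
isect <- function(x, y) {
  lv <- union(GenomeInfoDb::seqlevels(x), GenomeInfoDb::seqlevels(y))
  GenomeInfoDb::seqlevels(x) <- lv
  GenomeInfoDb::seqlevels(y) <- lv
  GenomicRanges::intersect(x, y, ignore.strand = TRUE)
}

setdiff_gr <- function(x, y) {
  lv <- union(GenomeInfoDb::seqlevels(x), GenomeInfoDb::seqlevels(y))
  GenomeInfoDb::seqlevels(x) <- lv
  GenomeInfoDb::seqlevels(y) <- lv
  GenomicRanges::setdiff(x, y, ignore.strand = TRUE)
}

#' Build the genomic region-type map from a gene annotation
#'
#' Strand-aware: upstream of a minus-strand gene lies to its right.  With
#' TSS/TTS at coordinate `t` (0-based half-open gene spans), the proximal
#' TSS window of a plus-strand gene is `[t-w, t)` and of a minus-strand
#' gene `[t, t+w)`; proximal TTS windows mirror this downstream.  The
#' 5' >x distal territory of a gene is the upstream ray beyond distance x
#' from its TSS, minus every other gene's body expanded by x on both
#' sides; 3' >x distal territories mirror this downstream of the TTS.
#' Pure variants subtract the opposing type (proximal TSS vs TTS, 5' vs
#' 3' distal at the same cutoff).
#'
#' @param annotation a `modmotif_annotation`.
#' @param chrom_lens named chromosome lengths.
#' @param config a [default_config()] (`proximal_window`,
#'   `distal_cutoffs`).
#' @param pure also build the pure variants (default TRUE).
#' @return Named list of reduced [GenomicRanges::GRanges], one per type;
#'   attribute `primary` names the 16 primary types.
#' @export
build_region_types <- function(annotation, chrom_lens,
                               config = default_config(), pure = TRUE) {
  g <- annotation$genes
  f <- annotation$features
  w <- config$proximal_window
  plus <- g$strand == "+"
  clen <- unname(chrom_lens[g$chrom])

  types <- list()
  types$proximal_tss <- reduce_gr(gr0(
    g$chrom,
    pmax(0L, ifelse(plus, g$tss - w, g$tss)),
    pmin(clen, ifelse(plus, g$tss, g$tss + w))))
  types$proximal_tts <- reduce_gr(gr0(
    g$chrom,
    pmax(0L, ifelse(plus, g$tts, g$tts - w)),
    pmin(clen, ifelse(plus, g$tts + w, g$tts))))
  pick <- function(feature, ranks = NULL) {
    sel <- f$feature == feature
    if (!is.null(ranks)) sel <- sel & f$rank %in% ranks
    ff <- f[sel, , drop = FALSE]
    if (!nrow(ff)) return(GenomicRanges::GRanges())
    reduce_gr(gr0(ff$chrom, ff$start, ff$end))
  }
  types$five_utr <- pick("five_utr")
  types$three_utr <- pick("three_utr")
  types$first_intron <- pick("intron", 1L)
  types$other_intron <- pick("intron",
                             setdiff(unique(f$rank[f$feature == "intron"]),
                                     1L))

  expand_body <- function(x) {
    reduce_gr(gr0(g$chrom, pmax(0L, g$start - x), pmin(clen, g$end + x)))
  }
  for (x in config$distal_cutoffs) {
    per_gene_5 <- list(); per_gene_3 <- list()
    for (i in seq_len(nrow(g))) {
      ray5 <- if (plus[i]) {
        gr0(g$chrom[i], 0L, min(clen[i], g$tss[i] - x))
      } else {
        gr0(g$chrom[i], min(clen[i], g$tss[i] + x), clen[i])
      }
      ray3 <- if (plus[i]) {
        gr0(g$chrom[i], min(clen[i], g$tts[i] + x), clen[i])
      } else {
        gr0(g$chrom[i], 0L, max(0L, g$tts[i] - x))
      }
      others <- if (nrow(g) > 1L) {
        reduce_gr(gr0(g$chrom[-i], pmax(0L, g$start[-i] - x),
                      pmin(clen[-i], g$end[-i] + x)))
      } else GenomicRanges::GRanges()
      per_gene_5[[i]] <- setdiff_gr(ray5, others)
      per_gene_3[[i]] <- setdiff_gr(ray3, others)
    }
    nm5 <- sprintf("distal_5p_%d", x)
    nm3 <- sprintf("distal_3p_%d", x)
    types[[nm5]] <- reduce_gr(do.call(c, per_gene_5))
    types[[nm3]] <- reduce_gr(do.call(c, per_gene_3))
  }
  primary <- names(types)
  if (pure) {
    types$pure_proximal_tss <- setdiff_gr(types$proximal_tss,
                                          types$proximal_tts)
    types$pure_proximal_tts <- setdiff_gr(types$proximal_tts,
                                          types$proximal_tss)
    for (x in config$distal_cutoffs) {
      nm5 <- sprintf("distal_5p_%d", x); nm3 <- sprintf("distal_3p_%d", x)
      types[[paste0("pure_", nm5)]] <- setdiff_gr(types[[nm5]],
                                                  types[[nm3]])
      types[[paste0("pure_", nm3)]] <- setdiff_gr(types[[nm3]],
                                                  types[[nm5]])
    }
  }
  attr(types, "primary") <- primary
  types
}

#' Fraction of DHS base pairs covered by a region type
#'
#' `p_bg = overlap_bp(type, DHS union) / total_bp(DHS union)` --- the
#' binomial null parameter for site enrichment.
#'
#' @param type_gr a region type ([GenomicRanges::GRanges]).
#' @param regions DHS region data frame (`chrom,start,end`).
#' @return The background fraction in `[0, 1]`.
#' @export
background_fraction <- function(type_gr, regions) {
  if (!nrow(regions)) {
    stop("DHS regions cover zero base pairs", call. = FALSE)
  }
  dhs <- reduce_gr(regions_to_granges(regions))
  total <- sum(GenomicRanges::width(dhs))
  if (total == 0) stop("DHS regions cover zero base pairs", call. = FALSE)
  sum(GenomicRanges::width(isect(type_gr, dhs))) / total
}

#' Exact binomial enrichment test of a motif in a region type
#'
#' @param n_sites number of motif sites (trials, >= 1).
#' @param k_in sites whose midpoint falls inside the type.
#' @param p_bg background fraction from [background_fraction()].
#' @param n_tests Bonferroni denominator.
#' @param alpha significance level on the corrected p-value.
#' @return List: `pvalue`, `corrected_pvalue`, `enriched`, `degenerate`
#'   (TRUE when `p_bg == 0` with `k_in > 0`).
#' @export
test_enrichment <- function(n_sites, k_in, p_bg, n_tests = 1,
                            alpha = 0.01) {
  stopifnot(n_sites >= 1L, k_in >= 0L, k_in <= n_sites,
            p_bg >= 0, p_bg <= 1)
  degenerate <- p_bg == 0 && k_in > 0
  pvalue <- if (degenerate) 0 else binom_upper_tail(k_in, n_sites, p_bg)
  corrected <- min(1, pvalue * n_tests)
  list(pvalue = pvalue, corrected_pvalue = corrected,
       enriched = corrected < alpha, degenerate = degenerate)
}

## genomic midpoints of motif sites (site-in-type convention).
site_midpoints <- function(sites, regions) {
  pos <- regions$start[sites$region] + sites$offset + sites$width %/% 2L
  gr0(regions$chrom[sites$region], pos, pos + 1L)
}

#' Enrichment profile of motifs across region types
#'
#' Tests every motif against every region type; the Bonferroni denominator
#' is the number of motifs times the number of types.  A site lies in a
#' type iff its midpoint does.
#'
#' @param site_sets named list: motif id -> site data frame
#'   (`region,offset,width`; `region` indexes `regions`).
#' @param region_types output of [build_region_types()].
#' @param regions the dataset's DHS region data frame.
#' @param config a [default_config()] (`enrich_alpha`).
#' @return Data frame with one row per motif x type: `motif`,
#'   `region_type`, `n_sites`, `k_in`, `p_bg`, `pvalue`,
#'   `corrected_pvalue`, `enriched`.
#' @export
enrichment_profile <- function(site_sets, region_types, regions,
                               config = default_config()) {
  p_bg <- vapply(region_types, background_fraction, numeric(1),
                 regions = regions)
  n_tests <- length(site_sets) * length(region_types)
  rows <- list()
  for (m in names(site_sets)) {
    sites <- site_sets[[m]]
    if (!nrow(sites)) next
    mids <- site_midpoints(sites, regions)
    for (t in names(region_types)) {
      ty <- region_types[[t]]
      lv <- union(GenomeInfoDb::seqlevels(mids), GenomeInfoDb::seqlevels(ty))
      GenomeInfoDb::seqlevels(mids) <- lv
      GenomeInfoDb::seqlevels(ty) <- lv
      k_in <- sum(IRanges::overlapsAny(mids, ty))
      res <- test_enrichment(nrow(sites), k_in, p_bg[[t]], n_tests,
                             config$enrich_alpha)
      rows[[length(rows) + 1L]] <- data.frame(
        motif = m, region_type = t, n_sites = nrow(sites), k_in = k_in,
        p_bg = p_bg[[t]], pvalue = res$pvalue,
        corrected_pvalue = res$corrected_pvalue, enriched = res$enriched,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Count enriched motifs per region type
#'
#' @param profile output of [enrichment_profile()].
#' @return Data frame `region_type`, `n_enriched`.
#' @export
enrichment_summary <- function(profile) {
  agg <- stats::aggregate(enriched ~ region_type, data = profile, FUN = sum)
  names(agg) <- c("region_type", "n_enriched")
  agg
}
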