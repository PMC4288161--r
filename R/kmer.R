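#' k-mer pattern counting and ranking
#'
#' Candidate motifs are seeded from exhaustive k-mer counts over a
#' dataset's masked sequences.  Windows containing `N` are skipped; a
#' pattern and its reverse complement are merged under the
#' lexicographically smaller key (binding is strand-symmetric), and a
#' reverse-complement-palindromic pattern counts each window once.
#'
#' @name pattern_ranking
NULL

## All 4^k patterns in lexicographic order plus canonical-merge indices.
kmer_universe <- function(k) {
  pats <- Biostrings::mkAllStrings(DNA_BASES, k)
  rc <- revcomp(pats)
  rc_idx <- match(rc, pats)
  canon <- pats <= rc
  list(patterns = pats, rc_idx = rc_idx, is_canon = canon,
       palindromic = pats == rc)
}

#' Count k-mers in a dataset's masked sequences
#'
#' @param dataset a [new_dhs_dataset()] object.
#' @param k k-mer width (>= 4).
#' @param chunk sequences per counting chunk (memory/speed trade-off).
#' @return Data frame with one row per canonical pattern: `pattern`,
#'   `observed` (window matches on both strands) and `n_regions` (regions
#'   containing at least one match).  Attribute `n_windows` holds the total
#'   number of N-free windows.
#' @export
count_kmers <- function(dataset, k, chunk = 250L) {
  stopifnot(k >= 4L)
  uni <- kmer_universe(k)
  n_pat <- length(uni$patterns)
  seqs <- dataset$sequences
  total <- numeric(n_pat)
  regions <- numeric(sum(uni$is_canon))
  canon_cols <- which(uni$is_canon)
  rc_of_canon <- uni$rc_idx[canon_cols]
  for (lo in seq(1L, length(seqs), by = chunk)) {
    hi <- min(lo + chunk - 1L, length(seqs))
    f <- Biostrings::oligonucleotideFrequency(seqs[lo:hi], width = k,
                                              step = 1L)
    if (is.null(dim(f))) f <- matrix(f, nrow = 1L)
    total <- total + colSums(f)
    both <- f[, canon_cols, drop = FALSE] + f[, rc_of_canon, drop = FALSE]
    regions <- regions + colSums(both > 0L)
  }
  merged <- total[canon_cols] +
    ifelse(uni$palindromic[canon_cols], 0, total[rc_of_canon])
  out <- data.frame(pattern = uni$patterns[canon_cols],
                    observed = as.integer(merged),
                    n_regions = as.integer(regions),
                    stringsAsFactors = FALSE)
  attr(out, "n_windows") <- sum(total)
  attr(out, "k") <- k
  out
}

#' Fit a Markov background model on a dataset's masked sequences
#'
#' Conditional base probabilities are estimated from (order+1)-mer window
#' counts with an additive pseudocount; the initial context distribution
#' from order-mer counts.  This is the null model against which observed
#' k-mer counts are ranked.
#'
#' @param dataset a [new_dhs_dataset()] object.
#' @param order Markov order (0--3).
#' @return A list `(order, trans, init)` of class `modmotif_background`.
#' @export
fit_markov_background <- function(dataset, order = 2L) {
  stopifnot(order %in% 0:3)
  seqs <- dataset$sequences
  if (order == 0L) {
    cnt <- colSums(Biostrings::oligonucleotideFrequency(seqs, 1L)) + 1
    p <- cnt / sum(cnt)
    return(structure(list(order = 0L,
                          trans = matrix(p, nrow = 1L,
                                         dimnames = list("", DNA_BASES)),
                          init = stats::setNames(1, "")),
                     class = "modmotif_background"))
  }
  ctx_cnt <- colSums(Biostrings::oligonucleotideFrequency(seqs, order)) + 1
  full_cnt <- colSums(Biostrings::oligonucleotideFrequency(seqs,
                                                           order + 1L)) + 1
  ctxs <- Biostrings::mkAllStrings(DNA_BASES, order)
  trans <- matrix(full_cnt, nrow = 4L^order, ncol = 4L, byrow = TRUE,
                  dimnames = list(ctxs, DNA_BASES))
  trans <- trans / rowSums(trans)
  init <- ctx_cnt / sum(ctx_cnt)
  structure(list(order = order, trans = trans, init = init),
            class = "modmotif_background")
}

## Pr(pattern) for every pattern of width k under a fitted background,
## vectorized over the full 4^k universe via base-4 digit arithmetic.
kmer_probabilities <- function(background, k) {
  ord <- background$order
  n <- 4L^k
  idx <- seq_len(n) - 1L
  digit <- function(j) (idx %/% 4L^(k - j)) %% 4L  # base at position j, 0..3
  if (ord == 0L) {
    logp <- numeric(n)
    lt <- log(background$trans[1L, ])
    for (j in seq_len(k)) logp <- logp + lt[digit(j) + 1L]
    return(exp(logp))
  }
  # context code of positions (j-ord)..(j-1), base 4
  ctx <- numeric(n)
  for (j in seq_len(ord)) ctx <- ctx * 4L + digit(j)
  logp <- log(background$init)[ctx + 1L]
  lt <- log(background$trans)
  pow <- 4L^(ord - 1L)
  for (j in (ord + 1L):k) {
    b <- digit(j)
    logp <- logp + lt[cbind(ctx + 1L, b + 1L)]
    ctx <- (ctx %% pow) * 4L + b
  }
  exp(logp)
}

#' Rank k-mer patterns against a background model
#'
#' The ranking statistic is a Poisson z-approximation,
#' `(observed - expected) / sqrt(expected)`, with the expected both-strand
#' count derived from the background model and the number of N-free
#' windows.  Descending by score; ties broken lexicographically; excluded
#' patterns omitted.
#'
#' @param stats output of [count_kmers()].
#' @param background output of [fit_markov_background()].
#' @param exclude character vector of canonical patterns to omit.
#' @return `stats` with `expected` and `score` columns, ranked.
#' @export
rank_patterns <- function(stats, background, exclude = character(0)) {
  k <- attr(stats, "k")
  uni <- kmer_universe(k)
  pr <- kmer_probabilities(background, k)
  canon_cols <- which(uni$is_canon)
  pr_canon <- pr[canon_cols] +
    ifelse(uni$palindromic[canon_cols], 0, pr[uni$rc_idx[canon_cols]])
  expected <- attr(stats, "n_windows") * pr_canon
  if (any(expected <= 0 & stats$observed > 0)) {
    stop("background model assigns zero probability to an observed pattern",
         call. = FALSE)
  }
  out <- stats
  out$expected <- expected
  out$score <- ifelse(expected > 0,
                      (out$observed - expected) / sqrt(expected), 0)
  if (length(exclude)) out <- out[!out$pattern %in% exclude, , drop = FALSE]
  out <- out[order(-out$score, out$pattern), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Take the top m ranked patterns
#'
#' @param ranked output of [rank_patterns()].
#' @param m number of candidates (returns `min(m, available)`).
#' @return Character vector of candidate patterns, rank order preserved.
#' @export
top_candidates <- function(ranked, m) {
  head(ranked$pattern, max(0L, m))
}
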