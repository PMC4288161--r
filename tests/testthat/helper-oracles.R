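## Independent oracles -----------------------------------------------------

## Direct log-space summation of the upper binomial tail (independent of
## stats::pbinom/dbinom).
oracle_binom_tail <- function(k, n, p) {
  if (k <= 0) return(1)
  if (p <= 0) return(0)
  if (p >= 1) return(1)
  i <- k:n
  sum(exp(lchoose(n, i) + i * log(p) + (n - i) * log1p(-p)))
}

## Exact-overlap check between two patterns by brute string loops,
## independent of pattern_overlap_exceeds().
oracle_overlap_too_long <- function(a, b, max_ov) {
  k <- nchar(a)
  rc <- function(x) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
  }
  for (y in c(b, rc(b))) {
    if (a == y) return(TRUE)
    for (o in (max_ov + 1):(k - 1)) {
      if (substr(a, k - o + 1, k) == substr(y, 1, o)) return(TRUE)
      if (substr(y, k - o + 1, k) == substr(a, 1, o)) return(TRUE)
    }
  }
  FALSE
}

## Brute-force module discovery: enumerate every subset of sizes 2..max,
## apply the identical level-wise significance-closure definition.
## Returns a data frame keyed by comma-joined sorted member ids.
oracle_modules <- function(occ, n_regions, cfg) {
  ids <- names(occ)
  m <- length(ids)
  out <- list()
  if (m < 2) {
    return(data.frame(key = character(), support = integer(),
                      pvalue = numeric(), stringsAsFactors = FALSE))
  }
  sig_by_size <- list()
  ## level 2: all pairs, Bonferroni over choose(m, 2)
  pairs <- utils::combn(m, 2)
  denom2 <- choose(m, 2)
  sig2 <- list()
  for (c_i in seq_len(ncol(pairs))) {
    i <- pairs[1, c_i]; j <- pairs[2, c_i]
    if (oracle_overlap_too_long(ids[i], ids[j], cfg$pattern_overlap_max)) next
    supp <- length(intersect(occ[[i]], occ[[j]]))
    p_i <- length(occ[[i]]) / n_regions
    p_j <- length(occ[[j]]) / n_regions
    pv <- if (p_i == 0 || p_j == 0) 1 else
      oracle_binom_tail(supp, n_regions, p_i * p_j)
    if (min(1, pv * denom2) < cfg$module_alpha) {
      sig2[[length(sig2) + 1]] <- sort(c(i, j))
      out[[length(out) + 1]] <- list(items = sort(c(i, j)), support = supp,
                                     pvalue = pv)
    }
  }
  sig_by_size[[2]] <- sig2
  ## levels 3..max: candidates are sets with every (s-1)-subset significant
  for (s in seq_len(cfg$module_max_size)[-seq_len(2)]) {
    prev_keys <- vapply(sig_by_size[[s - 1]], paste, character(1),
                        collapse = ".")
    if (length(prev_keys) < 2 || m < s) { sig_by_size[[s]] <- list(); next }
    cands <- list()
    allsets <- utils::combn(m, s)
    for (c_i in seq_len(ncol(allsets))) {
      set <- allsets[, c_i]
      subs_ok <- all(vapply(seq_len(s), function(d) {
        paste(set[-d], collapse = ".") %in% prev_keys
      }, logical(1)))
      if (subs_ok) cands[[length(cands) + 1]] <- set
    }
    denom <- length(cands)
    sig_s <- list()
    for (set in cands) {
      supp <- length(Reduce(intersect, occ[set]))
      q <- prod(lengths(occ[set]) / n_regions)
      pv <- if (q == 0) 1 else oracle_binom_tail(supp, n_regions, q)
      if (min(1, pv * denom) < cfg$module_alpha) {
        sig_s[[length(sig_s) + 1]] <- set
        out[[length(out) + 1]] <- list(items = set, support = supp,
                                       pvalue = pv)
      }
    }
    sig_by_size[[s]] <- sig_s
  }
  if (!length(out)) {
    return(data.frame(key = character(), support = integer(),
                      pvalue = numeric(), stringsAsFactors = FALSE))
  }
  df <- data.frame(
    key = vapply(out, function(r) paste(sort(ids[r$items]), collapse = ","),
                 character(1)),
    support = vapply(out, function(r) as.integer(r$support), integer(1)),
    pvalue = vapply(out, function(r) r$pvalue, numeric(1)),
    stringsAsFactors = FALSE)
  df[order(df$key), , drop = FALSE]
}

## Brute-force canonical k-mer window count of one sequence string.
oracle_count_windows <- function(seq, pattern) {
  k <- nchar(pattern)
  rc <- function(x) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
  }
  pats <- unique(c(pattern, rc(pattern)))
  n <- 0
  for (i in seq_len(nchar(seq) - k + 1)) {
    w <- substr(seq, i, i + k - 1)
    if (grepl("N", w, fixed = TRUE)) next
    if (w %in% pats) n <- n + 1
  }
  n
}
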