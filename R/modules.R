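#' Motif-module discovery
#'
#' A motif module is a set of 2--6 candidate patterns whose exact-match
#' binding sites co-occur in significantly more regions than expected if
#' the patterns occurred independently.  Significance is an exact
#' upper-tail binomial test of the co-occurrence count against the product
#' of the patterns' marginal region frequencies, Bonferroni-corrected.
#' The search is level-wise over the itemset lattice with significance
#' closure: all pairs are tested; a size-s set (s >= 3) is a candidate only
#' if every (s-1)-subset is itself a significant module, with a per-level
#' Bonferroni denominator equal to the number of candidate sets tested at
#' that level.
#'
#' @name module_discovery
NULL

#' Per-pattern occurrence region sets
#'
#' Region `r` belongs to a pattern's set iff the pattern or its reverse
#' complement occurs (exact match) in the sequence of region `r`.
#'
#' @param candidates character vector of N-free patterns (equal width).
#' @param dataset a [new_dhs_dataset()] object.
#' @return Named list of sorted integer region indices, one per candidate.
#' @export
occurrence_sets <- function(candidates, dataset) {
  if (!length(candidates)) return(stats::setNames(list(), character(0)))
  stopifnot(!anyNA(candidates), !grepl("N", candidates, fixed = TRUE))
  pd_fwd <- Biostrings::PDict(candidates)
  rc <- revcomp(candidates)
  pd_rev <- Biostrings::PDict(rc)
  hits_f <- Biostrings::vwhichPDict(pd_fwd, dataset$sequences)
  hits_r <- Biostrings::vwhichPDict(pd_rev, dataset$sequences)
  sets <- vector("list", length(candidates))
  for (r in seq_along(hits_f)) {
    for (p in unique(c(hits_f[[r]], hits_r[[r]]))) {
      sets[[p]] <- c(sets[[p]], r)
    }
  }
  stats::setNames(lapply(sets, function(s) sort(unique(s))), candidates)
}

#' Do two patterns share an exact overlap longer than allowed?
#'
#' Two equal-width patterns whose prefix/suffix (in either orientation)
#' coincide over more than `max_overlap` positions are fragments of one
#' longer word: their co-occurrence reflects a single underlying site, not
#' two co-binding motifs, so such pairs are ineligible as module members.
#' Vectorized over pattern pairs.
#'
#' @param a,b character vectors of equal-width patterns.
#' @param max_overlap largest allowed exact overlap (bp).
#' @return Logical vector: `TRUE` where the pair is ineligible.
#' @export
pattern_overlap_exceeds <- function(a, b, max_overlap = 5L) {
  k <- nchar(a[1L])
  rb <- revcomp(b)
  out <- a == b
  for (o in seq.int(max_overlap + 1L, k - 1L)) {
    out <- out |
      substring(a, k - o + 1L, k) == substring(b, 1L, o) |
      substring(b, k - o + 1L, k) == substring(a, 1L, o) |
      substring(a, k - o + 1L, k) == substring(rb, 1L, o) |
      substring(rb, k - o + 1L, k) == substring(a, 1L, o)
  }
  out | a == rb
}

#' Exact binomial co-occurrence p-value of a motif module
#'
#' With marginal region frequencies `p_i = |set_i| / n_regions`, the null
#' co-occurrence probability is `q = prod(p_i)` and the p-value the exact
#' upper binomial tail `P(X >= support | n_regions, q)`, where `support` is
#' the number of regions containing all members.  Any empty member set
#' gives p-value 1 by convention.
#'
#' @param sets list of member region-index sets.
#' @param n_regions total number of regions (> 0).
#' @return The p-value.
#' @export
module_pvalue <- function(sets, n_regions) {
  stopifnot(n_regions > 0)
  sizes <- lengths(sets)
  if (any(sizes == 0L)) return(1)
  q <- prod(sizes / n_regions)
  support <- length(Reduce(intersect, sets))
  binom_upper_tail(support, n_regions, q)
}

## Apriori-style candidate generation: join significant (s-1)-sets sharing
## their first s-2 items, then require every (s-1)-subset significant.
## `sig_prev` is a list of sorted integer vectors.
gen_candidates <- function(sig_prev) {
  if (length(sig_prev) < 2L) return(list())
  keys <- vapply(sig_prev, function(s) paste(s, collapse = "."), character(1))
  prefix <- vapply(sig_prev, function(s) {
    paste(s[-length(s)], collapse = ".")
  }, character(1))
  last <- vapply(sig_prev, function(s) s[length(s)], integer(1))
  out <- list()
  for (grp in split(seq_along(sig_prev), prefix)) {
    if (length(grp) < 2L) next
    grp <- grp[order(last[grp])]
    for (a in seq_len(length(grp) - 1L)) {
      for (b in (a + 1L):length(grp)) {
        cand <- c(sig_prev[[grp[a]]], last[grp[b]])
        # closure: every (s-1)-subset must be significant
        ok <- all(vapply(seq_along(cand), function(drop) {
          paste(cand[-drop], collapse = ".") %in% keys
        }, logical(1)))
        if (ok) out[[length(out) + 1L]] <- cand
      }
    }
  }
  out
}

#' Discover motif modules from occurrence sets
#'
#' @param occ named list of region-index sets, as from [occurrence_sets()].
#' @param n_regions number of regions in the dataset.
#' @param config a [default_config()] object (`module_min_size`,
#'   `module_max_size`, `module_alpha`).
#' @return Data frame of significant modules: `module_id`, list-column
#'   `motif_ids` (sorted member patterns), `size`, `support`, `pvalue`,
#'   `corrected_pvalue`, `n_tested` (the level's Bonferroni denominator).
#' @export
discover_modules <- function(occ, n_regions, config = default_config()) {
  empty <- data.frame(module_id = character(), size = integer(),
                      support = integer(), pvalue = numeric(),
                      corrected_pvalue = numeric(), n_tested = numeric(),
                      stringsAsFactors = FALSE)
  empty$motif_ids <- list()
  empty <- empty[c("module_id", "motif_ids", "size", "support", "pvalue",
                   "corrected_pvalue", "n_tested")]
  m <- length(occ)
  if (m < config$module_min_size) return(empty)
  ids <- names(occ)
  sizes <- lengths(occ)
  marg <- sizes / n_regions
  alpha <- config$module_alpha

  ## incidence matrix for fast supports
  nz <- sizes > 0L
  X <- Matrix::sparseMatrix(
    i = unlist(occ[nz]),
    j = rep(which(nz), sizes[nz]),
    x = 1, dims = c(n_regions, m))

  results <- list()
  sig_sets <- list()

  ## ---- level 2: all pairs ------------------------------------------------
  n_tested2 <- choose(m, 2)
  co <- Matrix::crossprod(X)
  tri <- Matrix::summary(co)
  tri <- tri[tri$i < tri$j, , drop = FALSE]
  if (nrow(tri)) {
    # overlapping patterns are fragments of one longer word, not a module
    tri <- tri[!pattern_overlap_exceeds(ids[tri$i], ids[tri$j],
                                        config$pattern_overlap_max), ,
               drop = FALSE]
  }
  if (nrow(tri)) {
    q <- marg[tri$i] * marg[tri$j]
    pv <- binom_upper_tail(tri$x, n_regions, q)
    corr <- pmin(1, pv * n_tested2)
    sig <- which(corr < alpha)
    for (s in sig) {
      set <- sort(c(tri$i[s], tri$j[s]))
      sig_sets[[length(sig_sets) + 1L]] <- set
      results[[length(results) + 1L]] <- list(
        items = set, support = as.integer(tri$x[s]), pvalue = pv[s],
        corrected = corr[s], n_tested = n_tested2)
    }
  }

  ## ---- levels 3..max: significance closure -------------------------------
  sig_prev <- sig_sets
  s <- 3L
  while (s <= config$module_max_size && length(sig_prev) >= 2L) {
    cands <- gen_candidates(sig_prev)
    n_tested <- length(cands)
    if (!n_tested) break
    sig_now <- list()
    for (cand in cands) {
      support <- length(Reduce(intersect, occ[cand]))
      q <- prod(marg[cand])
      pv <- if (q == 0) 1 else binom_upper_tail(support, n_regions, q)
      corr <- min(1, pv * n_tested)
      if (corr < alpha) {
        sig_now[[length(sig_now) + 1L]] <- cand
        results[[length(results) + 1L]] <- list(
          items = cand, support = as.integer(support), pvalue = pv,
          corrected = corr, n_tested = n_tested)
      }
    }
    sig_prev <- sig_now
    s <- s + 1L
  }

  if (!length(results)) return(empty)
  motif_ids <- lapply(results, function(r) sort(ids[r$items]))
  out <- data.frame(
    module_id = NA_character_,
    size = vapply(results, function(r) length(r$items), integer(1)),
    support = vapply(results, `[[`, integer(1), "support"),
    pvalue = vapply(results, `[[`, numeric(1), "pvalue"),
    corrected_pvalue = vapply(results, `[[`, numeric(1), "corrected"),
    n_tested = vapply(results, `[[`, numeric(1), "n_tested"),
    stringsAsFactors = FALSE)
  out$motif_ids <- motif_ids
  key <- vapply(motif_ids, paste, character(1), collapse = ",")
  ord <- order(out$size, out$corrected_pvalue, key)
  out <- out[ord, , drop = FALSE]
  out$module_id <- sprintf("module%05d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[c("module_id", "motif_ids", "size", "support", "pvalue",
        "corrected_pvalue", "n_tested")]
}

#' Run the iterative motif-discovery loop on one dataset
#'
#' Each round ranks the not-yet-discovered k-mer patterns, takes the top
#' `top_patterns` as candidates, discovers significant motif modules among
#' them, and outputs the module member patterns as motifs.  The loop stops
#' when `motif_cap` motifs have been discovered or no new motif appeared in
#' `stop_rounds_r` consecutive rounds.  (A round with no new motif leaves
#' the exclusion list unchanged, so every following round is identical; the
#' stop condition is then reached deterministically.)
#'
#' @param dataset a [new_dhs_dataset()] object (preprocessed).
#' @param config a [default_config()] object.
#' @param background optional pre-fitted background model.
#' @return A `discovery_state` list: `motifs` (character patterns),
#'   `modules` (data frame across rounds, deduplicated by member set),
#'   `rounds_without_new`, `round_index`, `n_regions`.
#' @export
run_discovery <- function(dataset, config = default_config(),
                          background = NULL) {
  stats <- count_kmers(dataset, config$kmer_width)
  if (is.null(background)) background <- fit_markov_background(dataset, 2L)
  n_regions <- nrow(dataset$regions)
  discovered <- character(0)
  modules <- NULL
  seen_keys <- character(0)
  rounds_without_new <- 0L
  round_index <- 0L
  repeat {
    round_index <- round_index + 1L
    ranked <- rank_patterns(stats, background, exclude = discovered)
    cands <- top_candidates(ranked, config$top_patterns)
    occ <- occurrence_sets(cands, dataset)
    mods <- discover_modules(occ, n_regions, config)
    # add member patterns module by module; once the cap is reached no
    # further members are added, so overshoot < module_max_size
    new_motifs <- character(0)
    for (ids_m in mods$motif_ids) {
      if (length(discovered) + length(new_motifs) >= config$motif_cap) break
      new_motifs <- union(new_motifs, setdiff(ids_m, discovered))
    }
    if (nrow(mods)) {
      keys <- vapply(mods$motif_ids, paste, character(1), collapse = ",")
      keep <- !keys %in% seen_keys
      seen_keys <- c(seen_keys, keys[keep])
      mods$round <- round_index
      modules <- rbind(modules, mods[keep, , drop = FALSE])
    }
    if (length(new_motifs)) {
      discovered <- c(discovered, new_motifs)
      rounds_without_new <- 0L
    } else {
      # identical exclusion list => identical future rounds; reach the
      # r-consecutive-rounds stop immediately
      rounds_without_new <- config$stop_rounds_r
    }
    if (length(discovered) >= config$motif_cap ||
        rounds_without_new >= config$stop_rounds_r) break
  }
  if (is.null(modules)) {
    modules <- discover_modules(stats::setNames(list(), character(0)),
                                max(1L, n_regions), config)
    modules$round <- integer(0)
  }
  if (nrow(modules)) {
    modules$module_id <- sprintf("module%05d", seq_len(nrow(modules)))
  }
  rownames(modules) <- NULL
  structure(list(motifs = discovered, modules = modules,
                 rounds_without_new = min(rounds_without_new,
                                          config$stop_rounds_r),
                 round_index = round_index, n_regions = n_regions,
                 dataset_id = dataset$id),
            class = "discovery_state")
}

#' @export
print.discovery_state <- function(x, ...) {
  cat(sprintf("<discovery_state> %s: %d motifs, %d modules in %d round(s)\n",
              x$dataset_id, length(x$motifs), nrow(x$modules),
              x$round_index))
  invisible(x)
}
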