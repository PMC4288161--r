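#' Motif similarity with calibrated empirical E-values
#'
#' PWM pairs are compared by ungapped sliding alignment in both
#' orientations under two column metrics --- Pearson column correlation and
#' the average log-likelihood ratio (ALLR) against a flat background.  Raw
#' best-alignment scores are converted to E-values against a null
#' distribution of random-motif comparisons, and the two-threshold
#' similarity rule combines both metrics: correlation guards against
#' length artifacts, ALLR against low-information matches.
#'
#' @name motif_similarity
NULL

## column metric: mean Pearson correlation between aligned columns.
## Zero-variance (uniform) columns score 0 by convention.
metric_corr <- function(a, b) {
  ca <- a - rowMeans(a)
  cb <- b - rowMeans(b)
  va <- rowSums(ca * ca)
  vb <- rowSums(cb * cb)
  num <- rowSums(ca * cb)
  den <- sqrt(va * vb)
  mean(ifelse(den > 0, num / den, 0))
}

## column metric: mean average log-likelihood ratio vs flat background.
metric_allr <- function(a, b) {
  ap <- pmax(a, 1e-6); bp <- pmax(b, 1e-6)
  mean((rowSums(a * log2(bp / 0.25)) + rowSums(b * log2(ap / 0.25))) / 2)
}

## reverse complement of a PWM: reverse positions, swap A<->T, C<->G.
revcomp_pwm <- function(m) {
  out <- m[rev(seq_len(nrow(m))), c("T", "G", "C", "A"), drop = FALSE]
  colnames(out) <- DNA_BASES
  out
}

as_pwm <- function(x) {
  if (inherits(x, "motif")) x$matrix else x
}

#' Best ungapped alignment score of two motifs
#'
#' Maximizes the mean per-column metric over all offsets with overlap at
#' least `min(6, shorter width)`, trying `b` also reverse-complemented.
#' Deterministic tie-break: forward orientation first, then smaller
#' offset.
#'
#' @param a,b motifs or PWM matrices (widths >= 4).
#' @param metric `"corr"` or `"allr"`.
#' @return List with `score`, `offset` (of b's first column relative to
#'   a's) and `orientation` (`"forward"`/`"reverse"`).
#' @export
align_score <- function(a, b, metric = c("corr", "allr")) {
  metric <- match.arg(metric)
  f <- if (metric == "corr") metric_corr else metric_allr
  ma <- as_pwm(a); mb <- as_pwm(b)
  wa <- nrow(ma); wb <- nrow(mb)
  stopifnot(wa >= 4L, wb >= 4L)
  minov <- min(6L, wa, wb)
  best <- list(score = -Inf, offset = NA_integer_, orientation = NA)
  for (orient in c("forward", "reverse")) {
    mbo <- if (orient == "forward") mb else revcomp_pwm(mb)
    for (off in seq(-(wb - minov), wa - minov)) {
      lo_a <- max(1L, off + 1L); hi_a <- min(wa, off + wb)
      sc <- f(ma[lo_a:hi_a, , drop = FALSE],
              mbo[(lo_a - off):(hi_a - off), , drop = FALSE])
      if (sc > best$score) {
        best <- list(score = sc, offset = off, orientation = orient)
      }
    }
  }
  best
}

#' Null distribution of alignment scores for random motifs
#'
#' Samples `n_samples` pairs of random motifs ([make_random_motif()]) of
#' the given widths and records their best alignment scores.
#'
#' @param width_a,width_b motif widths.
#' @param metric `"corr"` or `"allr"`.
#' @param n_samples number of random pairs (>= 1000).
#' @param seed integer seed.
#' @return Sorted numeric vector of null scores with attributes `mu` and
#'   `sigma` (its moments, used by the fitted-tail E-value).
#' @export
calibrate_null <- function(width_a, width_b, metric = c("corr", "allr"),
                           n_samples = 2000L, seed = 1L) {
  metric <- match.arg(metric)
  stopifnot(n_samples >= 1000L)
  with_seed(stage_seed(seed, paste("null", width_a, width_b, metric)), {
    scores <- vapply(seq_len(n_samples), function(i) {
      align_score(make_random_motif(width_a), make_random_motif(width_b),
                  metric)$score
    }, numeric(1))
    scores <- sort(scores)
    attr(scores, "mu") <- mean(scores)
    attr(scores, "sigma") <- sd(scores)
    scores
  })
}

#' E-value of an alignment score against a calibrated null
#'
#' `method = "empirical"` uses the add-one empirical tail,
#' `E = n_comparisons * (1 + #null >= score) / (1 + |null|)`, whose floor
#' is `n_comparisons / (1 + |null|)`.  `method = "fitted"` (the pipeline
#' default) extrapolates the tail with a Gaussian fitted to the null ---
#' scores are means over at least six aligned columns, so their null is
#' near-normal --- which resolves E-values far below the empirical floor,
#' as the clustering thresholds require.
#'
#' @param score observed best alignment score.
#' @param null vector from [calibrate_null()].
#' @param n_comparisons number of comparisons the E-value accounts for.
#' @param method `"fitted"` or `"empirical"`.
#' @return The E-value (>= 0).
#' @export
motif_evalue <- function(score, null, n_comparisons = 1,
                         method = c("fitted", "empirical")) {
  method <- match.arg(method)
  stopifnot(length(null) >= 1L)
  if (method == "empirical") {
    n_comparisons * (1 + sum(null >= score)) / (1 + length(null))
  } else {
    mu <- attr(null, "mu"); sigma <- attr(null, "sigma")
    if (is.null(mu)) mu <- mean(null)
    if (is.null(sigma)) sigma <- sd(null)
    if (!isTRUE(sigma > 0)) return(if (score > mu) 0 else n_comparisons)
    n_comparisons * pnorm(score, mu, sigma, lower.tail = FALSE)
  }
}

#' Similarity engine: configuration plus a cache of calibrated nulls
#'
#' @param config a [default_config()] object.
#' @param n_samples null sample size per width pair and metric.
#' @param seed integer seed for all calibrations.
#' @return An object of class `similarity_engine`.
#' @export
new_similarity_engine <- function(config = default_config(),
                                  n_samples = config$null_samples,
                                  seed = config$random_seed) {
  structure(list(config = config, n_samples = as.integer(n_samples),
                 seed = seed, cache = new.env(parent = emptyenv()),
                 pair_cache = new.env(parent = emptyenv())),
            class = "similarity_engine")
}

engine_null <- function(engine, width_a, width_b, metric) {
  w <- sort(c(width_a, width_b))
  key <- paste(w[1L], w[2L], metric, sep = ":")
  if (is.null(engine$cache[[key]])) {
    engine$cache[[key]] <- calibrate_null(w[1L], w[2L], metric,
                                          engine$n_samples, engine$seed)
  }
  engine$cache[[key]]
}

#' Full similarity comparison of two motifs
#'
#' @param a,b motifs or PWM matrices.
#' @param engine a [new_similarity_engine()].
#' @param n_comparisons comparisons the E-values account for.
#' @param method E-value method, see [motif_evalue()].
#' @return List: `score_corr`, `score_allr`, `evalue_corr`, `evalue_allr`,
#'   `offset`, `orientation` (of the ALLR best alignment).
#' @export
compare_motifs <- function(a, b, engine, n_comparisons = 1,
                           method = "fitted") {
  ma <- as_pwm(a); mb <- as_pwm(b)
  ac <- align_score(ma, mb, "corr")
  aa <- align_score(ma, mb, "allr")
  list(score_corr = ac$score,
       score_allr = aa$score,
       evalue_corr = motif_evalue(ac$score,
                                  engine_null(engine, nrow(ma), nrow(mb),
                                              "corr"),
                                  n_comparisons, method),
       evalue_allr = motif_evalue(aa$score,
                                  engine_null(engine, nrow(ma), nrow(mb),
                                              "allr"),
                                  n_comparisons, method),
       offset = aa$offset, orientation = aa$orientation)
}

## cheap content-derived cache key for a motif.
motif_key <- function(x) {
  if (inherits(x, "motif")) {
    m <- x$matrix
    sprintf("%s@%s#%.12g", x$id, x$source_dataset, sum(m * seq_along(m)))
  } else {
    sprintf("pwm#%d#%.12g", nrow(x), sum(x * seq_along(x)))
  }
}

## ALLR-only E-value (the clustering rules use only the second metric);
## cached per motif pair inside the engine.
evalue_allr_pair <- function(a, b, engine, method = "fitted") {
  key <- paste(sort(c(motif_key(a), motif_key(b))), collapse = "|")
  hit <- engine$pair_cache[[key]]
  if (!is.null(hit)) return(hit)
  ma <- as_pwm(a); mb <- as_pwm(b)
  s <- align_score(ma, mb, "allr")$score
  e <- motif_evalue(s, engine_null(engine, nrow(ma), nrow(mb), "allr"),
                    1, method)
  engine$pair_cache[[key]] <- e
  e
}

#' Two-threshold motif similarity rule
#'
#' Two motifs are similar iff (corr E-value < `sim_e1_strict` and ALLR
#' E-value < `sim_e2_strict`) or (corr E-value < `sim_e1_loose` and ALLR
#' E-value < `sim_e2_loose`).  Symmetric in its arguments.
#'
#' @param a,b motifs or PWM matrices.
#' @param engine a [new_similarity_engine()].
#' @param result optional precomputed [compare_motifs()] result.
#' @return List with `similar` (logical) and `result`.
#' @export
is_similar <- function(a, b, engine, result = NULL) {
  cfg <- engine$config
  if (is.null(result)) result <- compare_motifs(a, b, engine)
  sim <- (result$evalue_corr < cfg$sim_e1_strict &&
          result$evalue_allr < cfg$sim_e2_strict) ||
         (result$evalue_corr < cfg$sim_e1_loose &&
          result$evalue_allr < cfg$sim_e2_loose)
  list(similar = sim, result = result)
}
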