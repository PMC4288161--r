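#' @importFrom stats pbinom dbinom pnorm quantile sd runif rbinom
#' @importFrom utils head read.delim write.table combn
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Derive a reproducible per-stage seed from the pipeline seed
#'
#' All randomness in the pipeline flows from one master seed; each stage
#' draws from its own substream so that adding a stage never perturbs the
#' random numbers seen by another.
#'
#' @param seed integer master seed.
#' @param stage character stage label.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 2147483647
  as.integer((abs(seed) * 2654435761 + h) %% 2147483647)
}

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    set.seed(as.integer(seed))
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
  }
  force(code)
}

#' Reverse complement of a DNA string
#'
#' @param x character vector of DNA strings over `ACGTN`.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Canonical (strand-merged) form of a DNA pattern
#'
#' A pattern and its reverse complement denote the same double-stranded
#' word; the lexicographically smaller of the two is the canonical key.
#'
#' @param x character vector of DNA patterns.
#' @return Character vector of canonical keys.
#' @export
canonical_pattern <- function(x) {
  rc <- revcomp(x)
  ifelse(x <= rc, x, rc)
}

## Exact upper-tail binomial probability P(X >= k | n, p).
binom_upper_tail <- function(k, n, p) {
  k <- pmax(k, 0)
  out <- numeric(length(k))
  n <- rep_len(n, length(k))
  p <- rep_len(p, length(k))
  zero <- k <= 0
  out[zero] <- 1
  if (any(!zero)) {
    out[!zero] <- pbinom(k[!zero] - 1, n[!zero], p[!zero], lower.tail = FALSE)
  }
  out
}

## 0-based half-open interval data frame sanity check.
check_regions <- function(regions, chrom_lengths = NULL) {
  stopifnot(is.data.frame(regions),
            all(c("chrom", "start", "end") %in% names(regions)))
  if (any(regions$start < 0) || any(regions$end <= regions$start)) {
    stop("invalid region coordinates: need 0 <= start < end", call. = FALSE)
  }
  if (!is.null(chrom_lengths)) {
    unknown <- setdiff(unique(regions$chrom), names(chrom_lengths))
    if (length(unknown)) {
      stop("regions on unknown chromosome(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    over <- regions$end > chrom_lengths[regions$chrom]
    if (any(over)) {
      stop("region(s) exceed chromosome length: ",
           paste(head(regions$id[over]), collapse = ", "), call. = FALSE)
    }
  }
  invisible(regions)
}

regions_to_granges <- function(regions) {
  GenomicRanges::GRanges(
    seqnames = regions$chrom,
    ranges = IRanges::IRanges(start = regions$start + 1L, end = regions$end),
    strand = if ("strand" %in% names(regions)) regions$strand else "*"
  )
}

granges_to_regions <- function(gr, ids = NULL) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    id = if (is.null(ids)) as.character(seq_along(gr)) else ids,
    stringsAsFactors = FALSE
  )
}
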