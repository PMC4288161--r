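#' Motif construction and length refinement
#'
#' Discovered patterns are turned into position weight matrices from their
#' exact-match sites; motif lengths are then adjusted from the nucleotides
#' flanking the sites: informative flanking columns are appended, and
#' uninformative terminal columns trimmed, within fixed width bounds.
#'
#' @name motif_refinement
NULL

#' Construct a motif object
#'
#' @param id motif id.
#' @param matrix row-stochastic `width x 4` matrix (columns `A,C,G,T`).
#' @param sites data frame `region` (index), `offset` (0-based), `strand`,
#'   `width`.
#' @param source_dataset provenance dataset id.
#' @return An object of class `motif`.
#' @export
new_motif <- function(id, matrix, sites = NULL, source_dataset = NA) {
  stopifnot(ncol(matrix) == 4L)
  if (max(abs(rowSums(matrix) - 1)) > 1e-9) {
    stop("motif matrix rows must sum to 1", call. = FALSE)
  }
  colnames(matrix) <- DNA_BASES
  structure(list(id = id, matrix = matrix, sites = sites,
                 source_dataset = source_dataset), class = "motif")
}

#' @export
print.motif <- function(x, ...) {
  cat(sprintf("<motif> %s: width %d, %d site(s)%s\n", x$id, nrow(x$matrix),
              if (is.null(x$sites)) 0L else nrow(x$sites),
              if (is.na(x$source_dataset)) "" else
                paste0(" [", x$source_dataset, "]")))
  invisible(x)
}

#' Motif consensus string
#' @param motif a `motif` object or PWM matrix.
#' @return The consensus (argmax base per position).
#' @export
motif_consensus <- function(motif) {
  mat <- if (inherits(motif, "motif")) motif$matrix else motif
  paste(DNA_BASES[apply(mat, 1L, which.max)], collapse = "")
}

## Oriented site strings: minus-strand sites are reverse-complemented so
## every string reads in motif orientation.  May contain N (masked flanks).
site_strings <- function(sites, sequences) {
  raw <- substring(as.character(sequences)[sites$region],
                   sites$offset + 1L, sites$offset + sites$width)
  minus <- sites$strand == "-"
  if (any(minus)) raw[minus] <- revcomp(raw[minus])
  raw
}

## Per-column base counts of equal-length strings, ignoring N.
column_counts <- function(strings) {
  if (!length(strings)) stop("no sites", call. = FALSE)
  w <- unique(nchar(strings))
  stopifnot(length(w) == 1L)
  mat <- matrix(0, nrow = w, ncol = 4L, dimnames = list(NULL, DNA_BASES))
  chars <- do.call(rbind, strsplit(strings, ""))
  for (b in seq_along(DNA_BASES)) {
    mat[, b] <- colSums(chars == DNA_BASES[b])
  }
  mat
}

#' Build a PWM from aligned sites
#'
#' Column frequencies with an additive pseudocount per base; minus-strand
#' sites are reverse-complemented before counting; `N` bases (masked
#' flanks) are ignored.
#'
#' @param sites data frame `region,offset,strand,width` (equal widths).
#' @param sequences the dataset's [Biostrings::DNAStringSet].
#' @param pseudocount additive pseudocount per base (default 0.25).
#' @param id,source_dataset motif metadata.
#' @return A [new_motif()] object.
#' @export
build_pwm <- function(sites, sequences, pseudocount = 0.25,
                      id = "motif", source_dataset = NA) {
  stopifnot(nrow(sites) >= 1L, length(unique(sites$width)) == 1L)
  seq_len_by_region <- Biostrings::width(sequences)[sites$region]
  if (any(sites$offset < 0L) ||
      any(sites$offset + sites$width > seq_len_by_region)) {
    stop("site extends beyond its sequence", call. = FALSE)
  }
  counts <- column_counts(site_strings(sites, sequences)) + pseudocount
  new_motif(id, counts / rowSums(counts), sites, source_dataset)
}

#' Information content of a PWM column, in bits
#'
#' `2 + sum(p * log2(p))` with `0 * log2(0) == 0`: 0 bits for a uniform
#' column, 2 bits for a fixed base.
#'
#' @param col row-stochastic probability vector of length 4.
#' @return Information content in bits.
#' @export
column_information <- function(col) {
  stopifnot(length(col) == 4L, abs(sum(col) - 1) < 1e-6)
  nz <- col > 0
  2 + sum(col[nz] * log2(col[nz]))
}

## Flank bases one position beyond the motif on the given motif side
## ("left"/"right"), in motif orientation.  Returns NULL if any site runs
## off its sequence on that side (side frozen); N flanks are dropped.
flank_bases <- function(sites, sequences, side) {
  plus <- sites$strand == "+"
  genome_left <- (side == "left") == plus  # genome side per site
  pos <- ifelse(genome_left, sites$offset - 1L, sites$offset + sites$width)
  if (any(pos < 0L) ||
      any(pos >= Biostrings::width(sequences)[sites$region])) {
    return(NULL)
  }
  b <- substring(as.character(sequences)[sites$region], pos + 1L, pos + 1L)
  b[!plus] <- chartr("ACGTN", "TGCAN", b[!plus])  # complement for minus
  b <- b[b != "N"]
  if (!length(b)) return(NULL)
  b
}

flank_column <- function(bases, pseudocount) {
  cnt <- vapply(DNA_BASES, function(x) sum(bases == x), numeric(1)) +
    pseudocount
  cnt / sum(cnt)
}

## Grow/shrink site coordinates by one column on a motif side.
shift_sites <- function(sites, side, grow) {
  plus <- sites$strand == "+"
  genome_left <- (side == "left") == plus
  if (grow) {
    sites$offset <- ifelse(genome_left, sites$offset - 1L, sites$offset)
    sites$width <- sites$width + 1L
  } else {
    sites$offset <- ifelse(genome_left, sites$offset + 1L, sites$offset)
    sites$width <- sites$width - 1L
  }
  sites
}

#' Adjust a motif's length from its site flanks
#'
#' Iteratively appends the flanking column (built from the bases adjacent
#' to all sites) on either side while its information content is at least
#' `ic_min` and the width is below `width_max` --- when both sides qualify
#' the higher-information side is extended first (ties go right) --- then
#' trims terminal columns with information below `ic_min` while the width
#' exceeds `width_min`.  Site offsets and widths are updated consistently;
#' a side where any site touches its sequence bound is frozen.  The
#' operation is idempotent.
#'
#' @param motif a [new_motif()] with sites.
#' @param sequences the dataset's sequences.
#' @param ic_min information threshold in bits (default 0.5).
#' @param width_min,width_max width bounds (defaults 6 and 16).
#' @param pseudocount PWM pseudocount.
#' @return The adjusted `motif`.
#' @export
adjust_length <- function(motif, sequences, ic_min = 0.5,
                          width_min = 6L, width_max = 16L,
                          pseudocount = 0.25) {
  stopifnot(inherits(motif, "motif"), !is.null(motif$sites),
            nrow(motif$sites) >= 1L)
  sites <- motif$sites

  ## -- extension ----------------------------------------------------------
  repeat {
    if (unique(sites$width) >= width_max) break
    cand <- list()
    for (side in c("left", "right")) {
      fb <- flank_bases(sites, sequences, side)
      if (is.null(fb)) next
      col <- flank_column(fb, pseudocount)
      ic <- column_information(col)
      if (ic >= ic_min) cand[[side]] <- ic
    }
    if (!length(cand)) break
    side <- if (length(cand) == 2L) {
      if (cand$right >= cand$left) "right" else "left"
    } else names(cand)
    sites <- shift_sites(sites, side, grow = TRUE)
  }

  ## -- trimming -----------------------------------------------------------
  repeat {
    if (unique(sites$width) <= width_min) break
    mat <- column_counts(site_strings(sites, sequences)) + pseudocount
    mat <- mat / rowSums(mat)
    if (column_information(mat[1L, ]) < ic_min) {
      sites <- shift_sites(sites, "left", grow = FALSE)
    } else if (column_information(mat[nrow(mat), ]) < ic_min) {
      sites <- shift_sites(sites, "right", grow = FALSE)
    } else break
  }

  build_pwm(sites, sequences, pseudocount, id = motif$id,
            source_dataset = motif$source_dataset)
}

## Exact-match sites of a pattern (both strands) in a dataset.
pattern_sites <- function(pattern, dataset) {
  w <- nchar(pattern)
  rc <- revcomp(pattern)
  out <- list()
  for (str in unique(c("+", "-"))) {
    pat <- if (str == "+") pattern else rc
    hits <- Biostrings::vmatchPattern(pat, dataset$sequences)
    starts <- Biostrings::startIndex(hits)
    for (r in which(lengths(starts) > 0L)) {
      out[[length(out) + 1L]] <- data.frame(
        region = r, offset = starts[[r]] - 1L, strand = str, width = w,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(region = integer(), offset = integer(),
                      strand = character(), width = integer(),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, out)
  if (revcomp(pattern) == pattern) {   # palindrome: one site per window
    df <- df[df$strand == "+", , drop = FALSE]
  }
  df[order(df$region, df$offset, df$strand), , drop = FALSE]
}

#' Build and length-adjust PWMs for all discovered motifs
#'
#' @param state a `discovery_state` from [run_discovery()].
#' @param dataset the dataset the state was discovered on.
#' @param config a [default_config()] object.
#' @return Named list of adjusted [new_motif()] objects (names are the
#'   originating patterns).
#' @export
refine_motifs <- function(state, dataset, config = default_config()) {
  out <- list()
  for (pat in state$motifs) {
    sites <- pattern_sites(pat, dataset)
    if (!nrow(sites)) next
    m <- build_pwm(sites, dataset$sequences, config$pwm_pseudocount,
                   id = pat, source_dataset = dataset$id)
    out[[pat]] <- adjust_length(m, dataset$sequences, config$ic_min,
                                config$width_min, config$width_max,
                                config$pwm_pseudocount)
  }
  out
}

## Canonical key of a motif's genomic site set (used to detect motifs that
## became identical after length adjustment).
site_key <- function(motif) {
  s <- motif$sites
  paste(sort(sprintf("%d:%d:%d:%s", s$region, s$offset, s$width, s$strand)),
        collapse = ";")
}

#' Re-express modules over adjusted motifs
#'
#' Module membership is mapped onto adjusted motif ids (motifs whose
#' adjusted site sets coincide are merged, keeping the first id); supports
#' are recomputed from the adjusted site lists; modules that fall below
#' `module_min_size` are removed.
#'
#' @param modules module data frame from [discover_modules()].
#' @param motifs named list of adjusted motifs from [refine_motifs()].
#' @param config a [default_config()] object.
#' @return The updated module data frame.
#' @export
update_modules <- function(modules, motifs, config = default_config()) {
  if (!nrow(modules)) return(modules)
  keys <- vapply(motifs, site_key, character(1))
  canon <- stats::setNames(names(motifs)[match(keys, keys)], names(motifs))
  region_sets <- lapply(motifs, function(m) unique(m$sites$region))
  new_members <- lapply(modules$motif_ids, function(ids) {
    sort(unique(unname(canon[ids[ids %in% names(canon)]])))
  })
  keep <- lengths(new_members) >= config$module_min_size
  out <- modules[keep, , drop = FALSE]
  out$motif_ids <- new_members[keep]
  out$size <- lengths(out$motif_ids)
  out$support <- vapply(out$motif_ids, function(ids) {
    length(Reduce(intersect, region_sets[ids]))
  }, integer(1))
  # drop modules made redundant by the merge
  key <- vapply(out$motif_ids, paste, character(1), collapse = ",")
  out <- out[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}
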