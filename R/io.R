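#' DHS dataset container
#'
#' One DHS dataset: an id, a cell/tissue type label, preprocessed regions
#' (0-based half-open) and one masked sequence per region.
#'
#' @param id dataset id.
#' @param type_label cell/tissue type label (or `NA`).
#' @param regions data frame with `chrom,start,end,id`.
#' @param sequences [Biostrings::DNAStringSet], one element per region,
#'   over `A,C,G,T,N`.
#' @return An object of class `dhs_dataset`.
#' @export
new_dhs_dataset <- function(id, type_label, regions, sequences) {
  stopifnot(nrow(regions) == length(sequences))
  if (!all(Biostrings::width(sequences) == regions$end - regions$start)) {
    stop("sequence lengths disagree with region lengths", call. = FALSE)
  }
  structure(list(id = id, type_label = type_label, regions = regions,
                 sequences = sequences),
            class = "dhs_dataset")
}

#' @export
print.dhs_dataset <- function(x, ...) {
  cat(sprintf("<dhs_dataset> %s (%s): %d regions, %d--%d bp\n",
              x$id, x$type_label, nrow(x$regions),
              min(Biostrings::width(x$sequences)),
              max(Biostrings::width(x$sequences))))
  invisible(x)
}

#' Preprocess DHS regions: extend short, discard long
#'
#' Every region shorter than `region_target_len` grows by equal amounts on
#' both ends to exactly the target (an odd deficit puts the extra bp on the
#' right end); extensions are clamped at chromosome bounds with the
#' shortfall shifted to the other side when possible.  Regions longer than
#' `region_max_len` are discarded.  Idempotent on its own output.
#'
#' @param regions data frame `chrom,start,end[,id]`, 0-based half-open.
#' @param chrom_lens named vector of chromosome lengths.
#' @param config a [default_config()] object.
#' @return The preprocessed regions, input order preserved.
#' @export
preprocess_regions <- function(regions, chrom_lens, config = default_config()) {
  if (!"id" %in% names(regions)) {
    regions$id <- sprintf("region%05d", seq_len(nrow(regions)))
  }
  check_regions(regions, chrom_lens)
  len <- regions$end - regions$start
  keep <- len <= config$region_max_len
  regions <- regions[keep, , drop = FALSE]
  len <- len[keep]
  tgt <- config$region_target_len
  short <- len < tgt
  if (any(short)) {
    deficit <- tgt - len[short]
    left <- deficit %/% 2L
    right <- deficit - left              # odd deficit: extra bp to the right
    s <- regions$start[short] - left
    e <- regions$end[short] + right
    clens <- unname(chrom_lens[regions$chrom[short]])
    # clamp at chromosome start, shift shortfall right
    shift <- pmax(0L, -s)
    s <- s + shift; e <- e + shift
    # clamp at chromosome end, shift shortfall left
    shift <- pmax(0L, e - clens)
    s <- s - shift; e <- e - shift
    s <- pmax(s, 0L)                     # chromosome shorter than target
    regions$start[short] <- s
    regions$end[short] <- e
  }
  rownames(regions) <- NULL
  regions
}

#' Extract masked region sequences from a genome
#'
#' Slices the genome at each region, uppercases, turns soft-masked
#' (lowercase) bases into `N`, and hard-masks any base falling inside the
#' supplied mask intervals (e.g. repeats and exons).
#'
#' @param genome [Biostrings::DNAStringSet] (may contain lowercase bases) or
#'   a character vector of chromosome sequences.
#' @param regions data frame `chrom,start,end,id` (0-based half-open).
#' @param mask optional data frame of mask intervals (`chrom,start,end`).
#' @param id,type_label metadata for the resulting dataset.
#' @return A [new_dhs_dataset()] object.
#' @export
extract_sequences <- function(genome, regions, mask = NULL,
                              id = "dataset", type_label = NA_character_) {
  gseq <- if (is.character(genome)) genome else
    stats::setNames(as.character(genome), names(genome))
  lens <- stats::setNames(nchar(gseq), names(gseq))
  check_regions(regions, lens)
  seqs <- substring(gseq[regions$chrom], regions$start + 1L, regions$end)
  # soft-masked bases become N, everything else uppercased
  seqs <- chartr("acgtn", "NNNNN", seqs)
  if (!is.null(mask) && nrow(mask)) {
    for (i in seq_len(nrow(regions))) {
      mm <- mask[mask$chrom == regions$chrom[i] &
                 mask$end > regions$start[i] &
                 mask$start < regions$end[i], , drop = FALSE]
      if (!nrow(mm)) next
      s <- strsplit(seqs[i], "")[[1]]
      for (j in seq_len(nrow(mm))) {
        a <- max(mm$start[j], regions$start[i]) - regions$start[i]
        b <- min(mm$end[j], regions$end[i]) - regions$start[i]
        if (b > a) s[(a + 1L):b] <- "N"
      }
      seqs[i] <- paste(s, collapse = "")
    }
  }
  new_dhs_dataset(id, type_label, regions,
                  Biostrings::DNAStringSet(unname(seqs)))
}

## ---------------------------------------------------------------------------
## FASTA / BED / GTF

#' Write a genome to FASTA
#' @param genome [Biostrings::DNAStringSet].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Read a genome from FASTA, preserving soft-mask case
#' @param path FASTA path.
#' @return A named character vector of chromosome sequences.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write regions as 6-column BED (0-based, half-open)
#' @param regions data frame `chrom,start,end,id` and optional
#'   `score`,`strand`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  df <- data.frame(regions$chrom, regions$start, regions$end,
                   if ("id" %in% names(regions)) regions$id else ".",
                   if ("score" %in% names(regions)) regions$score else 0,
                   if ("strand" %in% names(regions)) regions$strand else ".")
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a 6-column BED file of regions
#' @param path BED path.
#' @return Data frame `chrom,start,end,id,score,strand`.
#' @export
read_regions_bed <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("malformed BED: fewer than 3 columns", call. = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4L) names(df)[4L] <- "id" else df$id <- "."
  if (ncol(df) >= 5L) names(df)[5L] <- "score" else df$score <- 0
  if (ncol(df) >= 6L) names(df)[6L] <- "strand" else df$strand <- "."
  df[c("chrom", "start", "end", "id", "score", "strand")]
}

#' Write motif binding sites as BED6
#'
#' One row per site: region coordinates are translated to genome
#' coordinates, the name column carries `motif_id`, and the strand column
#' records the matched strand.
#'
#' @param sites data frame `region,offset,strand,motif` with widths in
#'   `width`.
#' @param regions the dataset's region table (`id,chrom,start`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(sites, regions, path) {
  idx <- match(sites$region, regions$id)
  if (anyNA(idx)) stop("site references unknown region id", call. = FALSE)
  bed <- data.frame(chrom = regions$chrom[idx],
                    start = regions$start[idx] + sites$offset,
                    end = regions$start[idx] + sites$offset + sites$width,
                    id = sites$motif,
                    score = if ("score" %in% names(sites)) sites$score else 0,
                    strand = sites$strand)
  write_regions_bed(bed, path)
}

#' Write a gene annotation as GTF
#'
#' Emits gene, exon, five_utr, three_utr and intron features; GTF is
#' 1-based closed, converted from the internal 0-based half-open
#' representation at this boundary.
#'
#' @param annotation a `modmotif_annotation`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(annotation, path) {
  g <- annotation$genes
  f <- annotation$features
  rows <- c(
    sprintf('%s\tmodmotif\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s";',
            g$chrom, g$start + 1L, g$end, g$strand, g$gene_id),
    sprintf('%s\tmodmotif\t%s\t%d\t%d\t.\t%s\t.\tgene_id "%s"; rank "%d";',
            f$chrom, f$feature, f$start + 1L, f$end, f$strand, f$gene_id,
            f$rank))
  writeLines(rows, path)
  invisible(path)
}

#' Read a GTF written by [write_gtf()]
#' @param path GTF path.
#' @return A `modmotif_annotation`.
#' @export
read_gtf <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                   comment.char = "#", quote = "")
  if (ncol(df) != 9L) stop("malformed GTF: expected 9 columns", call. = FALSE)
  names(df) <- c("chrom", "source", "feature", "start", "end", "score",
                 "strand", "frame", "attr")
  df$gene_id <- sub('.*gene_id "([^"]+)".*', "\\1", df$attr)
  df$rank <- 1L
  has_rank <- grepl('rank "', df$attr)
  df$rank[has_rank] <- as.integer(sub('.*rank "([0-9]+)".*', "\\1",
                                      df$attr[has_rank]))
  df$start <- df$start - 1L  # to 0-based half-open
  genes_df <- df[df$feature == "gene", ]
  genes <- data.frame(gene_id = genes_df$gene_id, chrom = genes_df$chrom,
                      start = genes_df$start, end = genes_df$end,
                      strand = genes_df$strand,
                      tss = ifelse(genes_df$strand == "+", genes_df$start,
                                   genes_df$end),
                      tts = ifelse(genes_df$strand == "+", genes_df$end,
                                   genes_df$start),
                      stringsAsFactors = FALSE)
  fdf <- df[df$feature != "gene", ]
  features <- data.frame(gene_id = fdf$gene_id, feature = fdf$feature,
                         chrom = fdf$chrom, start = fdf$start, end = fdf$end,
                         strand = fdf$strand, rank = fdf$rank,
                         stringsAsFactors = FALSE)
  structure(list(genes = genes, features = features),
            class = "modmotif_annotation")
}

## ---------------------------------------------------------------------------
## MEME-minimal motif format

#' Write motifs in MEME minimal format
#'
#' @param motifs named list of row-stochastic PWM matrices, or a list of
#'   `motif` objects (with `$id` and `$matrix`).
#' @param path output path.
#' @param background background letter frequencies.
#' @return `path`, invisibly.
#' @export
write_meme_motifs <- function(motifs, path, background = rep(0.25, 4)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               paste(sprintf("%s %.6f", DNA_BASES, background),
                     collapse = " "), ""), con)
  nm <- names(motifs)
  for (i in seq_along(motifs)) {
    m <- motifs[[i]]
    id <- if (is.list(m) && !is.null(m$id)) m$id else nm[i]
    mat <- if (is.list(m)) m$matrix else m
    nsites <- if (is.list(m) && !is.null(m$sites)) nrow(m$sites) else 20L
    writeLines(c(sprintf("MOTIF %s", id),
                 sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                         nrow(mat), nsites)), con)
    writeLines(apply(mat, 1L, function(r) {
      paste(sprintf("%.6f", r), collapse = "  ")
    }), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read motifs from MEME minimal format
#'
#' @param path MEME file path.
#' @return Named list of PWM matrices (columns `A,C,G,T`), values faithful
#'   to 6 decimal places.
#' @export
read_meme_motifs <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^MOTIF\\s", lines)
  if (!length(starts)) return(list())
  out <- list()
  for (s in starts) {
    id <- strsplit(trimws(lines[s]), "\\s+")[[1]][2]
    hdr <- s + which(grepl("letter-probability matrix",
                           lines[(s + 1):min(s + 5, length(lines))]))[1]
    if (is.na(hdr)) stop("malformed MEME record near line ", s, call. = FALSE)
    w <- as.integer(sub(".*w=\\s*([0-9]+).*", "\\1", lines[hdr]))
    rows <- lines[(hdr + 1):(hdr + w)]
    mat <- do.call(rbind, lapply(seq_along(rows), function(k) {
      v <- suppressWarnings(as.numeric(strsplit(trimws(rows[k]), "\\s+")[[1]]))
      if (length(v) != 4L || anyNA(v)) {
        stop("malformed MEME matrix row at line ", hdr + k, call. = FALSE)
      }
      v
    }))
    colnames(mat) <- DNA_BASES
    out[[id]] <- mat
  }
  out
}

## ---------------------------------------------------------------------------
## Motif-module tables

#' Write motif modules as TSV
#'
#' Columns: module id, comma-separated motif ids, support, p-value,
#' Bonferroni-corrected p-value.
#'
#' @param modules module data frame from [discover_modules()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_modules_tsv <- function(modules, path) {
  df <- data.frame(
    module_id = if ("module_id" %in% names(modules)) modules$module_id else
      sprintf("module%05d", seq_len(nrow(modules))),
    motif_ids = vapply(modules$motif_ids, paste, character(1),
                       collapse = ","),
    support = modules$support,
    pvalue = modules$pvalue,
    corrected_pvalue = modules$corrected_pvalue)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a motif-module TSV written by [write_modules_tsv()]
#' @param path TSV path.
#' @return Data frame with a list-column `motif_ids`.
#' @export
read_modules_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("module_id", "motif_ids", "support", "pvalue",
            "corrected_pvalue")
  if (!all(need %in% names(df))) {
    stop("malformed module table: missing column(s) ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  }
  df$motif_ids <- strsplit(df$motif_ids, ",", fixed = TRUE)
  df
}
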