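#' Synthetic genomes, annotations and DHS datasets with planted truth
#'
#' The synthetic-data generator is the statistical stand-in for real
#' DNase-seq DHS collections: many short open-chromatin regions over a
#' Markov background, a minority of regions carrying co-occurring binding
#' sites of planted PWMs (motif modules), datasets grouped into types that
#' share type-specific motif profiles, and masked (`N`) stretches.
#'
#' @name synthetic_data
NULL

## Perturbed conditional distributions for a Markov background.  Every
## context keeps exactly `gc` mass on C+G so the stationary and hence
## empirical GC content matches the target.
markov_conditionals <- function(gc, order) {
  n_ctx <- 4L^order
  base <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  eps <- matrix(exp(stats::rnorm(n_ctx * 4L, 0, 0.15)), nrow = n_ctx)
  p <- sweep(eps, 2L, base, `*`)
  at <- p[, c(1L, 4L), drop = FALSE]
  cg <- p[, c(2L, 3L), drop = FALSE]
  at <- at / rowSums(at) * (1 - gc)
  cg <- cg / rowSums(cg) * gc
  m <- cbind(A = at[, 1L], C = cg[, 1L], G = cg[, 2L], T = at[, 2L])
  rownames(m) <- if (order == 0L) "" else {
    apply(do.call(expand.grid, rev(replicate(order, DNA_BASES,
                                             simplify = FALSE))),
          1L, function(r) paste(rev(r), collapse = ""))
  }
  m
}

## Sample one chromosome from the chain; contexts are encoded base-4.
sample_markov_chain <- function(len, trans, order) {
  probs <- t(apply(trans, 1L, cumsum))
  out <- integer(len)
  u <- runif(len)
  if (order == 0L) {
    out <- findInterval(u, probs[1L, ], left.open = TRUE) + 1L
  } else {
    ctx <- 0L
    pow <- 4L^(order - 1L)
    for (i in seq_len(len)) {
      b <- findInterval(u[i], probs[ctx + 1L, ], left.open = TRUE) + 1L
      out[i] <- b
      ctx <- (ctx %% pow) * 4L + (b - 1L)
      if (i < order) ctx <- ctx %% (4L^i * 4L)  # warm-up truncation
    }
  }
  paste(DNA_BASES[out], collapse = "")
}

#' Generate a synthetic genome from a Markov background model
#'
#' @param length total genome length in bp (>= 10 kb).
#' @param gc target GC fraction in (0, 1); every conditional distribution
#'   of the chain carries exactly this C+G mass, so empirical GC
#'   concentrates tightly around it.
#' @param markov_order Markov order of the background chain (0--3).
#' @param n_chroms number of equally sized chromosomes.
#' @param seed integer seed; the same seed reproduces the same genome.
#' @return A [Biostrings::DNAStringSet] with one element per chromosome and
#'   attributes `background` (the chain parameters) and `chrom_lengths`.
#' @export
make_genome <- function(length, gc = 0.41, markov_order = 2L, n_chroms = 1L,
                        seed = 1L) {
  if (gc <= 0 || gc >= 1) stop("gc must lie strictly in (0, 1)", call. = FALSE)
  if (length < 10000L) stop("genome length must be >= 10 kb", call. = FALSE)
  if (!markov_order %in% 0:3) stop("markov_order must be 0..3", call. = FALSE)
  with_seed(seed, {
    trans <- markov_conditionals(gc, markov_order)
    lens <- rep(length %/% n_chroms, n_chroms)
    lens[1L] <- lens[1L] + length %% n_chroms
    seqs <- vapply(lens, sample_markov_chain, character(1),
                   trans = trans, order = markov_order)
    genome <- Biostrings::DNAStringSet(seqs)
    names(genome) <- paste0("chr", seq_len(n_chroms))
    attr(genome, "background") <- list(order = markov_order, trans = trans,
                                       gc = gc)
    attr(genome, "chrom_lengths") <- stats::setNames(lens, names(genome))
    genome
  })
}

#' Chromosome lengths of a genome
#' @param genome a [Biostrings::DNAStringSet].
#' @return Named integer vector of chromosome lengths.
#' @export
chrom_lengths <- function(genome) {
  stats::setNames(Biostrings::width(genome), names(genome))
}

## Jitter a length by +/-30%, keeping it at least 20 bp.
jitter_len <- function(x) {
  pmax(20L, as.integer(round(x * runif(length(x), 0.7, 1.3))))
}

#' Generate a synthetic gene annotation
#'
#' Lays out non-overlapping three-exon gene models (5'UTR, coding exons,
#' two introns, 3'UTR) with random strands.  On the minus strand the TSS is
#' the rightmost transcribed coordinate and the first intron is the intron
#' nearest the TSS in transcription order.
#'
#' @param genome genome as returned by [make_genome()].
#' @param n_genes number of genes to place.
#' @param seed integer seed.
#' @return A list of class `modmotif_annotation` with elements `genes`
#'   (gene_id, chrom, start, end, strand, tss, tts; 0-based half-open) and
#'   `features` (per-gene five_utr/three_utr/exon/intron rows with
#'   transcription-order ranks).
#' @export
make_annotation <- function(genome, n_genes, seed = 1L) {
  lens <- chrom_lengths(genome)
  if (n_genes == 0L) {
    return(structure(list(
      genes = data.frame(gene_id = character(), chrom = character(),
                         start = integer(), end = integer(),
                         strand = character(), tss = integer(),
                         tts = integer(), stringsAsFactors = FALSE),
      features = data.frame(gene_id = character(), feature = character(),
                            chrom = character(), start = integer(),
                            end = integer(), strand = character(),
                            rank = integer(), stringsAsFactors = FALSE)),
      class = "modmotif_annotation"))
  }
  with_seed(seed, {
    per_chrom <- table(factor(sample(names(lens), n_genes, replace = TRUE,
                                     prob = lens / sum(lens)),
                              levels = names(lens)))
    genes <- list(); feats <- list(); gid <- 0L
    for (ch in names(lens)) {
      ng <- per_chrom[[ch]]
      if (ng == 0L) next
      slot <- lens[[ch]] %/% ng
      if (slot < 4000L) {
        stop("genome too small to place ", n_genes, " gene(s)", call. = FALSE)
      }
      for (i in seq_len(ng)) {
        gid <- gid + 1L
        # transcription-order component lengths
        comp <- c(u5 = 150L, ex1 = 120L, in1 = 800L, ex2 = 300L,
                  in2 = 500L, ex3 = 120L, u3 = 250L)
        comp <- stats::setNames(jitter_len(comp), names(comp))
        span <- sum(comp)
        lo <- (i - 1L) * slot
        hi <- i * slot - span - 1L
        if (hi <= lo) stop("genome too small to place gene models",
                           call. = FALSE)
        gstart <- lo + sample.int(hi - lo, 1L)
        strand <- sample(c("+", "-"), 1L)
        # genomic-order blocks (transcription order for '+', reversed for '-')
        blocks <- if (strand == "+") comp else rev(comp)
        ends <- gstart + cumsum(blocks)
        starts <- c(gstart, head(ends, -1L))
        names(starts) <- names(ends) <- names(blocks)
        gene_id <- sprintf("gene%03d", gid)
        tss <- if (strand == "+") gstart else gstart + span
        tts <- if (strand == "+") gstart + span else gstart
        genes[[gid]] <- data.frame(
          gene_id = gene_id, chrom = ch, start = gstart,
          end = gstart + span, strand = strand, tss = tss, tts = tts,
          stringsAsFactors = FALSE)
        fr <- function(feature, key, rank) {
          data.frame(gene_id = gene_id, feature = feature, chrom = ch,
                     start = starts[[key]], end = ends[[key]],
                     strand = strand, rank = rank, stringsAsFactors = FALSE)
        }
        feats[[gid]] <- rbind(
          fr("five_utr", "u5", 1L),
          fr("exon", "u5", 1L), fr("exon", "ex1", 1L),
          fr("intron", "in1", 1L),
          fr("exon", "ex2", 2L),
          fr("intron", "in2", 2L),
          fr("exon", "ex3", 3L), fr("exon", "u3", 3L),
          fr("three_utr", "u3", 1L))
      }
    }
    structure(list(genes = do.call(rbind, genes),
                   features = do.call(rbind, feats)),
              class = "modmotif_annotation")
  })
}

#' Generate a random (null) motif
#'
#' Each row is four iid uniform(0,1) draws normalized to sum to one --- the
#' null model used to calibrate motif-similarity E-values and random
#' coverage baselines.
#'
#' @param width motif width (>= 1).
#' @param seed optional integer seed.
#' @return A `width x 4` row-stochastic matrix with columns `A,C,G,T`.
#' @export
make_random_motif <- function(width, seed = NULL) {
  stopifnot(width >= 1)
  with_seed(seed, {
    m <- matrix(runif(width * 4L), ncol = 4L,
                dimnames = list(NULL, DNA_BASES))
    m / rowSums(m)
  })
}

#' Generate an informative planted PWM
#'
#' A random consensus with a fixed dominant-base probability per position
#' (default 0.9, about 1.5 bits per column --- a strong, realistic TF
#' motif).
#'
#' @param width motif width.
#' @param dominant probability of the consensus base at each position.
#' @param seed optional integer seed.
#' @return A row-stochastic matrix with attribute `consensus`.
#' @export
make_planted_pwm <- function(width, dominant = 0.9, seed = NULL) {
  stopifnot(width >= 1, dominant > 0.25, dominant <= 1)
  with_seed(seed, {
    cons <- sample.int(4L, width, replace = TRUE)
    m <- matrix((1 - dominant) / 3, nrow = width, ncol = 4L,
                dimnames = list(NULL, DNA_BASES))
    m[cbind(seq_len(width), cons)] <- dominant
    attr(m, "consensus") <- paste(DNA_BASES[cons], collapse = "")
    m
  })
}

## best matching fraction between two consensus strings over all ungapped
## alignments with >= min_ov overlap, both orientations.
consensus_agreement <- function(a, b, min_ov = 6L) {
  wa <- nchar(a); wb <- nchar(b)
  best <- 0
  for (bb in c(b, revcomp(b))) {
    for (off in seq(-(wb - min_ov), wa - min_ov)) {
      lo <- max(1L, off + 1L); hi <- min(wa, off + wb)
      ca <- substring(a, lo, hi)
      cb <- substring(bb, lo - off, hi - off)
      frac <- mean(strsplit(ca, "")[[1]] == strsplit(cb, "")[[1]])
      if (frac > best) best <- frac
    }
  }
  best
}

#' Generate mutually distinct planted motif families
#'
#' Draws sharp PWMs ([make_planted_pwm()]) whose consensus strings agree
#' at no more than `max_agreement` of aligned positions under any ungapped
#' alignment in either orientation --- planted families represent distinct
#' TFs, so they are kept distinguishable by construction.
#'
#' @param n number of families.
#' @param width motif width.
#' @param dominant dominant-base probability per position.
#' @param max_agreement largest allowed matching fraction between two
#'   family consensi (default 0.5).
#' @param seed integer seed.
#' @return Named list of PWMs (`fam01`, `fam02`, ...).
#' @export
make_motif_families <- function(n, width = 8L, dominant = 0.9,
                                max_agreement = 0.5, seed = 1L) {
  out <- list()
  tries <- 0L
  with_seed(stage_seed(seed, "motif_families"), {
    while (length(out) < n) {
      tries <- tries + 1L
      if (tries > 200L * n) {
        stop("cannot draw ", n, " families at max_agreement = ",
             max_agreement, call. = FALSE)
      }
      cand <- make_planted_pwm(width, dominant)
      cc <- attr(cand, "consensus")
      ok <- all(vapply(out, function(f) {
        consensus_agreement(cc, attr(f, "consensus")) <= max_agreement
      }, logical(1)))
      if (ok) out[[sprintf("fam%02d", length(out) + 1L)]] <- cand
    }
  })
  out
}

#' Perturb a PWM (noisy copy of a planted motif)
#'
#' Multiplies each probability by a log-normal factor and renormalizes
#' rows --- the model for how one underlying motif appears with small
#' variations when discovered independently in different datasets.
#'
#' @param pwm row-stochastic matrix.
#' @param amount standard deviation of the log-normal factor.
#' @param seed optional integer seed.
#' @return A perturbed row-stochastic matrix.
#' @export
perturb_motif <- function(pwm, amount = 0.25, seed = NULL) {
  with_seed(seed, {
    p <- pwm * matrix(exp(stats::rnorm(length(pwm), 0, amount)),
                      nrow = nrow(pwm))
    out <- p / rowSums(p)
    attr(out, "consensus") <- attr(pwm, "consensus")
    out
  })
}

## Sample a site string from a PWM.
sample_site <- function(pwm) {
  idx <- apply(pwm, 1L, function(p) sample.int(4L, 1L, prob = p))
  paste(DNA_BASES[idx], collapse = "")
}

## Place k non-overlapping intervals of the given widths in [0, len),
## also avoiding already-occupied intervals (sites of other modules
## planted earlier in the same region).
place_sites <- function(widths, len, occupied = NULL, max_tries = 1000L) {
  occ_bp <- if (is.null(occupied)) 0L else
    sum(occupied[, 2L] - occupied[, 1L])
  if (sum(widths) + occ_bp > len) {
    stop("region too short to host all member sites", call. = FALSE)
  }
  clear <- function(a, b, ivs) {
    is.null(ivs) || all(b <= ivs[, 1L] | a >= ivs[, 2L])
  }
  for (try in seq_len(max_tries)) {
    offs <- vapply(widths, function(w) sample.int(len - w + 1L, 1L) - 1L,
                   integer(1))
    o <- order(offs)
    so <- offs[o]; sw <- widths[o]
    ok <- length(offs) == 1L || all(so[-1L] >= (so + sw)[-length(so)])
    if (ok && !is.null(occupied)) {
      ok <- all(vapply(seq_along(offs), function(j) {
        clear(offs[j], offs[j] + widths[j], occupied)
      }, logical(1)))
    }
    if (ok) return(offs)
  }
  # deterministic fallback: first-fit scan left to right
  offs <- integer(length(widths))
  ivs <- occupied
  for (j in seq_along(widths)) {
    placed <- FALSE
    for (a in 0:(len - widths[j])) {
      if (clear(a, a + widths[j], ivs)) {
        offs[j] <- a
        ivs <- rbind(ivs, c(a, a + widths[j]))
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("region too short to host all member sites",
                      call. = FALSE)
  }
  offs
}

#' Plant motif-module sites into synthetic DHS datasets
#'
#' For each region selected for a module (independently with the module's
#' planting probability), one site per member motif is sampled from its PWM
#' and placed at non-overlapping offsets on random strands.  Background
#' positions are then masked to `N` in short stretches until about
#' `mask_fraction` of background bp are masked; planted sites are never
#' masked.
#'
#' @param genome genome from [make_genome()].
#' @param annotation optional annotation (unused for placement unless
#'   `placement` is given; carried through for downstream analyses).
#' @param truth_spec list with elements `motifs` (named list of PWMs) and
#'   `modules` (list of `list(members = <motif ids>, prob = <planting
#'   probability>)`).
#' @param n_regions number of regions per dataset.
#' @param region_len region length in bp (within `[200, 5000]`).
#' @param mask_fraction target fraction of background bp masked to `N`.
#' @param seed integer seed.
#' @param n_datasets number of independent datasets to generate.
#' @param placement optional data frame of intervals (`chrom,start,end`,
#'   0-based half-open) from which region starts are drawn; default is
#'   genome-wide.
#' @param ids,type_labels dataset ids and type labels (recycled).
#' @return A list with `datasets` (list of [dhs_dataset] objects) and
#'   `truth` (a `PlantedTruth`-style list: `motifs`, `modules`, `site_log`,
#'   `type_profiles`).
#' @export
plant_datasets <- function(genome, annotation = NULL, truth_spec,
                           n_regions, region_len = 800L,
                           mask_fraction = 0.1, seed = 1L,
                           n_datasets = 1L, placement = NULL,
                           ids = NULL, type_labels = NA_character_) {
  stopifnot(region_len >= 200L, region_len <= 5000L)
  probs <- vapply(truth_spec$modules, `[[`, numeric(1), "prob")
  if (any(probs < 0 | probs > 1)) {
    stop("planting probabilities must lie in [0, 1]", call. = FALSE)
  }
  lens <- chrom_lengths(genome)
  if (is.null(ids)) ids <- sprintf("ds%02d", seq_len(n_datasets))
  type_labels <- rep_len(type_labels, n_datasets)
  gseq <- as.character(genome)

  with_seed(seed, {
    site_log <- list()
    datasets <- vector("list", n_datasets)
    for (d in seq_len(n_datasets)) {
      ## --- region geometry ------------------------------------------------
      ## Default placement is non-overlapping, mirroring real DHS peaks
      ## (disjoint within a dataset); overlapping regions would induce
      ## co-occurrence between all patterns sharing the duplicated
      ## sequence and invalidate the independence null.
      if (is.null(placement)) {
        if (n_regions * region_len > 0.8 * sum(lens)) {
          stop("genome too small for ", n_regions, " non-overlapping ",
               "regions of ", region_len, " bp", call. = FALSE)
        }
        alloc <- table(factor(sample(names(lens), n_regions, replace = TRUE,
                                     prob = lens / sum(lens)),
                              levels = names(lens)))
        ch <- character(0); starts <- integer(0)
        for (cn in names(lens)) {
          nc <- alloc[[cn]]
          if (nc == 0L) next
          free <- lens[[cn]] - nc * region_len
          if (free < 0L) stop("chromosome ", cn, " too small for its ",
                              "region allocation", call. = FALSE)
          u <- sort(as.integer(floor(runif(nc, 0, free + 1))))
          ch <- c(ch, rep(cn, nc))
          starts <- c(starts, u + (seq_len(nc) - 1L) * region_len)
        }
      } else {
        ok <- placement$end - placement$start >= region_len
        pl <- placement[ok, , drop = FALSE]
        if (!nrow(pl)) stop("no placement interval can host a region",
                            call. = FALSE)
        pick <- sample.int(nrow(pl), n_regions, replace = TRUE,
                           prob = pl$end - pl$start - region_len + 1L)
        ch <- pl$chrom[pick]
        starts <- pl$start[pick] +
          vapply(pl$end[pick] - pl$start[pick] - region_len + 1L,
                 function(m) sample.int(m, 1L), integer(1)) - 1L
      }
      regions <- data.frame(chrom = ch, start = starts,
                            end = starts + region_len,
                            id = sprintf("%s_r%05d", ids[d],
                                         seq_len(n_regions)),
                            stringsAsFactors = FALSE)
      seqs <- substring(gseq[ch], starts + 1L, starts + region_len)

      ## --- plant module sites --------------------------------------------
      site_mask <- vector("list", n_regions)  # occupied intervals per region
      for (mi in seq_along(truth_spec$modules)) {
        mod <- truth_spec$modules[[mi]]
        if (mod$prob == 0) next
        hosts <- which(runif(n_regions) < mod$prob)
        widths <- vapply(truth_spec$motifs[mod$members], nrow, integer(1))
        for (r in hosts) {
          offs <- place_sites(widths, region_len, site_mask[[r]])
          for (j in seq_along(mod$members)) {
            pwm <- truth_spec$motifs[[mod$members[j]]]
            site <- sample_site(pwm)
            strand <- sample(c("+", "-"), 1L)
            placed <- if (strand == "+") site else revcomp(site)
            substr(seqs[r], offs[j] + 1L, offs[j] + widths[j]) <- placed
            site_mask[[r]] <- rbind(site_mask[[r]],
                                    c(offs[j], offs[j] + widths[j]))
            site_log[[length(site_log) + 1L]] <- data.frame(
              dataset = ids[d], region = regions$id[r],
              motif = mod$members[j], offset = offs[j], strand = strand,
              site = placed, stringsAsFactors = FALSE)
          }
        }
      }

      ## --- mask background stretches -------------------------------------
      if (mask_fraction > 0) {
        n_runs <- ceiling(n_regions * region_len * mask_fraction / 20)
        run_region <- sample.int(n_regions, n_runs, replace = TRUE)
        run_start <- sample.int(region_len, n_runs, replace = TRUE) - 1L
        run_len <- 1L + stats::rgeom(n_runs, 1 / 20)
        for (k in seq_len(n_runs)) {
          r <- run_region[k]
          a <- run_start[k]
          b <- min(region_len, a + run_len[k])
          if (b <= a) next
          pos <- seq.int(a, b - 1L)
          occ <- site_mask[[r]]
          if (!is.null(occ)) {
            for (row in seq_len(nrow(occ))) {
              pos <- pos[pos < occ[row, 1L] | pos >= occ[row, 2L]]
            }
          }
          if (length(pos)) {
            s <- strsplit(seqs[r], "")[[1]]
            s[pos + 1L] <- "N"
            seqs[r] <- paste(s, collapse = "")
          }
        }
      }

      datasets[[d]] <- new_dhs_dataset(ids[d], type_labels[d], regions,
                                       Biostrings::DNAStringSet(seqs))
    }
    truth <- list(
      motifs = truth_spec$motifs,
      modules = truth_spec$modules,
      site_log = if (length(site_log)) do.call(rbind, site_log) else
        data.frame(dataset = character(), region = character(),
                   motif = character(), offset = integer(),
                   strand = character(), site = character(),
                   stringsAsFactors = FALSE),
      type_profiles = {
        mem <- unique(as.character(unlist(
          lapply(truth_spec$modules, `[[`, "members"))))
        stats::setNames(list(mem), as.character(type_labels[1L]))
      }
    )
    list(datasets = datasets, truth = truth)
  })
}

#' Generate a labeled multi-type collection of planted datasets
#'
#' Each dataset of a type plants all shared motifs plus the type's specific
#' motifs, emulating dataset collections in which cell/tissue types carry
#' type-specific motif profiles.
#'
#' @param n_types number of types (>= 2).
#' @param datasets_per_type datasets per type.
#' @param shared_motifs number of motifs planted in every dataset.
#' @param specific_motifs_per_type number of motifs private to each type.
#' @param seed integer seed.
#' @param genome optional genome (default: 1 Mb, GC 0.41, order 2).
#' @param n_regions,region_len,mask_fraction,plant_prob dataset geometry and
#'   per-module planting probability.
#' @return A list with `datasets`, `labels`, and `truth` (including
#'   `type_profiles`).
#' @export
make_typed_collection <- function(n_types, datasets_per_type,
                                  shared_motifs = 2L,
                                  specific_motifs_per_type = 2L,
                                  seed = 1L, genome = NULL,
                                  n_regions = 800L, region_len = 800L,
                                  mask_fraction = 0.05,
                                  plant_prob = 0.3) {
  stopifnot(n_types >= 2L)
  with_seed(stage_seed(seed, "typed_collection"), {
    if (is.null(genome)) {
      genome <- make_genome(1000000L, gc = 0.41, markov_order = 2L,
                            seed = stage_seed(seed, "collection_genome"))
    }
    n_shared <- shared_motifs
    n_spec <- specific_motifs_per_type
    # one distinct family per motif so types stay distinguishable
    pool <- make_motif_families(n_shared + n_types * n_spec,
                                seed = stage_seed(seed, "family_pool"))
    nm <- c(if (n_shared) sprintf("shared%02d", seq_len(n_shared)),
            if (n_spec) as.vector(outer(seq_len(n_spec), seq_len(n_types),
                                        function(i, t) {
                                          sprintf("t%02d_m%02d", t, i)
                                        })))
    motifs <- stats::setNames(pool, nm)
    # plant motifs in co-occurring pairs (module discovery needs
    # co-occurrence); an odd leftover motif is planted alone
    pair_up <- function(ids) {
      if (!length(ids)) return(list())
      idx <- seq_len(length(ids) %/% 2L * 2L)
      mods <- if (length(idx)) {
        unname(lapply(split(ids[idx], ceiling(idx / 2)), function(p) {
          list(members = p, prob = plant_prob)
        }))
      } else list()
      if (length(ids) %% 2L) {
        mods <- c(mods, list(list(members = ids[length(ids)],
                                  prob = plant_prob)))
      }
      mods
    }
    datasets <- list(); labels <- character(0); logs <- list()
    type_profiles <- list()
    for (t in seq_len(n_types)) {
      type <- sprintf("type%02d", t)
      spec_ids <- if (n_spec) sprintf("t%02d_m%02d", t, seq_len(n_spec)) else
        character(0)
      shared_ids <- if (n_shared) sprintf("shared%02d", seq_len(n_shared)) else
        character(0)
      type_profiles[[type]] <- c(shared_ids, spec_ids)
      spec <- list(motifs = motifs,
                   modules = c(pair_up(shared_ids), pair_up(spec_ids)))
      out <- plant_datasets(genome, NULL, spec, n_regions, region_len,
                            mask_fraction,
                            seed = stage_seed(seed, paste0("plant_t", t)),
                            n_datasets = datasets_per_type,
                            ids = sprintf("%s_ds%02d", type,
                                          seq_len(datasets_per_type)),
                            type_labels = type)
      datasets <- c(datasets, out$datasets)
      labels <- c(labels, rep(type, datasets_per_type))
      logs[[t]] <- out$truth$site_log
    }
    truth <- list(motifs = motifs, type_profiles = type_profiles,
                  site_log = do.call(rbind, logs))
    list(datasets = datasets, labels = labels, truth = truth)
  })
}

#' Derive a known-interaction list from planted truth
#'
#' Emits every unordered pair of motif ids that co-occur in a planted
#' module as a "known interaction", plus `noise_pairs` random non-module
#' pairs; symmetric and deduplicated.
#'
#' @param truth planted truth (needs `modules` and `motifs`).
#' @param noise_pairs number of random non-module pairs to add.
#' @param seed integer seed.
#' @return Data frame with columns `tf_a`, `tf_b` (`tf_a < tf_b`).
#' @export
make_interactions <- function(truth, noise_pairs = 0L, seed = 1L) {
  pairs <- list()
  for (mod in truth$modules) {
    mem <- sort(unique(mod$members))
    if (length(mem) >= 2L) {
      cp <- combn(mem, 2L)
      pairs[[length(pairs) + 1L]] <- data.frame(
        tf_a = cp[1L, ], tf_b = cp[2L, ], stringsAsFactors = FALSE)
    }
  }
  known <- if (length(pairs)) unique(do.call(rbind, pairs)) else
    data.frame(tf_a = character(), tf_b = character(),
               stringsAsFactors = FALSE)
  if (noise_pairs > 0L) {
    ids <- names(truth$motifs)
    with_seed(stage_seed(seed, "interaction_noise"), {
      added <- 0L; guard <- 0L
      key <- paste(known$tf_a, known$tf_b)
      while (added < noise_pairs && guard < 100L * noise_pairs) {
        guard <- guard + 1L
        p <- sort(sample(ids, 2L))
        k <- paste(p[1L], p[2L])
        if (!k %in% key) {
          known <- rbind(known, data.frame(tf_a = p[1L], tf_b = p[2L],
                                           stringsAsFactors = FALSE))
          key <- c(key, k)
          added <- added + 1L
        }
      }
    })
  }
  rownames(known) <- NULL
  known
}
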