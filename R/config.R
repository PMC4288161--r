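#' Pipeline configuration
#'
#' All tunable constants of the motif/motif-module discovery pipeline live
#' in one flat configuration object.  Defaults reflect the study design the
#' pipeline implements: 8-mer seed patterns, the top 2000 candidates per
#' ranking round, a cap of 2000 motifs per dataset, DHS regions extended to
#' 800 bp and discarded above 5000 bp, module sizes 2--6 at a
#' Bonferroni-corrected 0.01 co-occurrence level, the two-threshold motif
#' similarity rule, the cross-dataset clustering thresholds, proximal
#' windows of 2.5 kb with distal cutoffs of 2.5/5/10/20/100 kb, and
#' 10-fold cross-validated classification over types with at least 8
#' datasets.
#'
#' @param ... named overrides of any default field.
#' @return An object of class `modmotif_config` (a named list).
#' @examples
#' cfg <- default_config(kmer_width = 6)
#' cfg$top_patterns
#' @export
default_config <- function(...) {
  cfg <- list(
    kmer_width = 8L,
    top_patterns = 2000L,
    motif_cap = 2000L,
    stop_rounds_r = 3L,
    region_target_len = 800L,
    region_max_len = 5000L,
    module_min_size = 2L,
    module_max_size = 6L,
    module_alpha = 0.01,
    pattern_overlap_max = 5L,
    sim_e1_strict = 0.5,
    sim_e2_strict = 1e-4,
    sim_e1_loose = 1.0,
    sim_e2_loose = 1e-5,
    cluster_e_anchor = 1e-8,
    cluster_e_member = 1e-5,
    cluster_small_size = 4L,
    cluster_frac = 0.90,
    enrich_alpha = 0.01,
    distal_cutoffs = c(2500L, 5000L, 10000L, 20000L, 100000L),
    proximal_window = 2500L,
    min_class_size = 8L,
    cv_folds = 10L,
    pwm_pseudocount = 0.25,
    ic_min = 0.5,
    width_min = 6L,
    width_max = 16L,
    null_samples = 2000L,
    random_seed = 1L
  )
  override_config(cfg, list(...))
}

INT_FIELDS <- c("kmer_width", "top_patterns", "motif_cap", "stop_rounds_r",
                "region_target_len", "region_max_len", "module_min_size",
                "module_max_size", "cluster_small_size", "min_class_size",
                "cv_folds", "width_min", "width_max", "null_samples",
                "random_seed", "proximal_window", "pattern_overlap_max")

override_config <- function(cfg, overrides) {
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(cfg))
    if (length(bad)) {
      stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    for (k in names(overrides)) {
      v <- overrides[[k]]
      cfg[[k]] <- if (k %in% INT_FIELDS) as.integer(v) else
        if (k == "distal_cutoffs") as.integer(v) else as.numeric(v)
    }
  }
  validate_config(structure(cfg, class = "modmotif_config"))
}

validate_config <- function(cfg) {
  pos <- c("kmer_width", "top_patterns", "motif_cap", "stop_rounds_r",
           "region_target_len", "region_max_len", "module_min_size",
           "module_max_size", "proximal_window", "min_class_size",
           "cv_folds", "width_min", "width_max", "null_samples",
           "sim_e1_strict", "sim_e2_strict", "sim_e1_loose", "sim_e2_loose",
           "cluster_e_anchor", "cluster_e_member", "pwm_pseudocount")
  for (f in setdiff(pos, "pwm_pseudocount")) {
    if (any(cfg[[f]] <= 0)) {
      stop("configuration error: '", f, "' must be strictly positive",
           call. = FALSE)
    }
  }
  if (cfg$pwm_pseudocount < 0) {
    stop("configuration error: 'pwm_pseudocount' must be non-negative",
         call. = FALSE)
  }
  if (any(cfg$distal_cutoffs <= 0)) {
    stop("configuration error: 'distal_cutoffs' must be strictly positive",
         call. = FALSE)
  }
  if (cfg$pattern_overlap_max < 0L ||
      cfg$pattern_overlap_max >= cfg$kmer_width) {
    stop("configuration error: 'pattern_overlap_max' must lie in ",
         "[0, kmer_width)", call. = FALSE)
  }
  if (cfg$module_min_size < 2L) {
    stop("configuration error: 'module_min_size' must be >= 2", call. = FALSE)
  }
  if (cfg$module_max_size < cfg$module_min_size) {
    stop("configuration error: 'module_max_size' < 'module_min_size'",
         call. = FALSE)
  }
  if (cfg$cluster_frac <= 0 || cfg$cluster_frac > 1) {
    stop("configuration error: 'cluster_frac' must lie in (0, 1]",
         call. = FALSE)
  }
  if (cfg$module_alpha <= 0 || cfg$module_alpha >= 1 ||
      cfg$enrich_alpha <= 0 || cfg$enrich_alpha >= 1) {
    stop("configuration error: significance levels must lie in (0, 1)",
         call. = FALSE)
  }
  if (cfg$width_min > cfg$width_max) {
    stop("configuration error: 'width_min' > 'width_max'", call. = FALSE)
  }
  cfg
}

#' Load a configuration from a flat key=value file
#'
#' Lines are `key = value` pairs; blank lines and `#` comments are ignored.
#' Values for `distal_cutoffs` are comma-separated.  Unknown keys and
#' invariant violations are rejected with an error naming the key.
#'
#' @param path path to a configuration file, or `""`/`NULL` for defaults.
#' @return A `modmotif_config` object.
#' @export
load_config <- function(path = "") {
  if (is.null(path) || !nzchar(path)) return(default_config())
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  overrides <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) {
      stop("configuration error: malformed line (no '='): '", ln, "'",
           call. = FALSE)
    }
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    parsed <- suppressWarnings(as.numeric(strsplit(val, ",")[[1]]))
    if (anyNA(parsed)) {
      stop("configuration error: non-numeric value for key '", key, "'",
           call. = FALSE)
    }
    overrides[[key]] <- parsed
  }
  override_config(unclass(default_config()), overrides)
}

#' Write a configuration to a flat key=value file
#'
#' `load_config(write_config(cfg, path))` round-trips exactly.
#'
#' @param config a `modmotif_config`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "modmotif_config"))
  lines <- vapply(names(config), function(k) {
    paste0(k, " = ", paste(format(config[[k]], scientific = FALSE,
                                  trim = TRUE), collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.modmotif_config <- function(x, ...) {
  cat("Motif-module pipeline configuration:\n")
  for (k in names(x)) {
    cat(sprintf("  %-18s %s\n", k, paste(format(x[[k]]), collapse = ", ")))
  }
  invisible(x)
}
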