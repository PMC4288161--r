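#' Downstream validation: coverage, interactions, classification
#'
#' Predicted motifs are validated by coverage against known-motif
#' collections (with a matched random-motif baseline), motif modules by
#' coverage of known interacting TF pairs (after mapping motifs to TFs via
#' a labelled reference collection), and the motif features by how well
#' they classify the cell/tissue types of the datasets.
#'
#' @name validation
NULL

#' Coverage of a motif collection by predicted motifs
#'
#' A collection motif is covered iff it is [is_similar()] to at least one
#' predicted motif; the symmetric percentage (predicted motifs similar to
#' at least one collection motif) is computed likewise.
#'
#' @param predicted list of predicted motifs or PWMs.
#' @param collection list of collection motifs or PWMs.
#' @param engine a [new_similarity_engine()].
#' @return List of class `coverage_report`: `n_collection`, `n_covered`,
#'   `pct_covered`, `n_predicted`, `pct_predicted_known` (percentages in
#'   0--100; `NA` and `flagged = TRUE` for an empty collection).
#' @export
motif_coverage <- function(predicted, collection, engine) {
  covered_by_any <- function(x, others) {
    for (o in others) if (is_similar(x, o, engine)$similar) return(TRUE)
    FALSE
  }
  n_col <- length(collection)
  if (n_col == 0L) {
    return(structure(list(n_collection = 0L, n_covered = 0L,
                          pct_covered = NA_real_,
                          n_predicted = length(predicted),
                          pct_predicted_known = NA_real_, flagged = TRUE),
                     class = "coverage_report"))
  }
  n_cov <- sum(vapply(collection, covered_by_any, logical(1),
                      others = predicted))
  n_known <- sum(vapply(predicted, covered_by_any, logical(1),
                        others = collection))
  structure(list(n_collection = n_col, n_covered = n_cov,
                 pct_covered = 100 * n_cov / n_col,
                 n_predicted = length(predicted),
                 pct_predicted_known =
                   if (length(predicted)) 100 * n_known / length(predicted)
                   else NA_real_,
                 flagged = FALSE),
            class = "coverage_report")
}

#' Random-motif coverage baseline
#'
#' Generates `n_random` random motifs with the given width multiset per
#' replicate and reports the mean percentage of the collection they cover
#' --- the significance baseline for [motif_coverage()].
#'
#' @param collection list of collection motifs or PWMs.
#' @param n_random motifs per replicate (typically the number of predicted
#'   motifs).
#' @param widths width multiset for the random motifs (typically the
#'   predicted motifs' widths).
#' @param reps replicates (default 10).
#' @param seed integer seed.
#' @param engine a [new_similarity_engine()].
#' @return List: `mean_pct_covered`, `per_rep`.
#' @export
random_baseline <- function(collection, n_random, widths, reps = 10L,
                            seed = 1L, engine) {
  stopifnot(reps >= 1L)
  widths <- rep_len(widths, n_random)
  per_rep <- vapply(seq_len(reps), function(r) {
    rand <- with_seed(stage_seed(seed, paste0("baseline", r)), {
      lapply(widths, make_random_motif)
    })
    motif_coverage(rand, collection, engine)$pct_covered
  }, numeric(1))
  list(mean_pct_covered = mean(per_rep), per_rep = per_rep)
}

#' Map a predicted motif to a transcription factor
#'
#' Returns the TF of the reference motif most similar to the query (lowest
#' ALLR E-value; ties broken by corr E-value, then lexicographic TF id),
#' or `NA` if no reference motif passes [is_similar()].
#'
#' @param motif query motif or PWM.
#' @param reference list of entries `list(tf = <label>, matrix = <PWM>)`.
#' @param engine a [new_similarity_engine()].
#' @return TF label or `NA_character_`.
#' @export
map_motif_to_tf <- function(motif, reference, engine) {
  stopifnot(length(reference) >= 1L)
  best <- NULL
  for (ref in reference) {
    res <- compare_motifs(motif, ref$matrix, engine)
    if (!is_similar(motif, ref$matrix, engine, result = res)$similar) next
    cand <- list(tf = ref$tf, e2 = res$evalue_allr, e1 = res$evalue_corr)
    if (is.null(best) ||
        cand$e2 < best$e2 ||
        (cand$e2 == best$e2 && cand$e1 < best$e1) ||
        (cand$e2 == best$e2 && cand$e1 == best$e1 && cand$tf < best$tf)) {
      best <- cand
    }
  }
  if (is.null(best)) NA_character_ else best$tf
}

canon_pairs <- function(a, b) {
  unique(data.frame(tf_a = pmin(a, b), tf_b = pmax(a, b),
                    stringsAsFactors = FALSE))
}

#' Interaction coverage of predicted motif modules
#'
#' Predicted TF pairs are all unordered TF pairs co-occurring in at least
#' one module after mapping motifs to TFs (unmapped motifs skipped).  Both
#' percentages are computed on the intersection universe: known pairs
#' whose TFs both occur among the mapped TFs.
#'
#' @param modules module data frame (list-column `motif_ids`).
#' @param tf_map named character vector: motif id -> TF (may contain
#'   `NA`).
#' @param known_pairs data frame `tf_a`, `tf_b` of known interactions.
#' @return List: `pct_known_discovered`, `pct_predicted_supported`,
#'   `n_known_universe`, `n_predicted`, `flagged` (TRUE when a percentage
#'   is undefined).
#' @export
interaction_coverage <- function(modules, tf_map, known_pairs) {
  preds <- list()
  if (nrow(modules)) {
    for (ids in modules$motif_ids) {
      tfs <- sort(unique(stats::na.omit(unname(tf_map[ids]))))
      if (length(tfs) >= 2L) {
        cp <- combn(tfs, 2L)
        preds[[length(preds) + 1L]] <- data.frame(
          tf_a = cp[1L, ], tf_b = cp[2L, ], stringsAsFactors = FALSE)
      }
    }
  }
  predicted <- if (length(preds)) unique(do.call(rbind, preds)) else
    data.frame(tf_a = character(), tf_b = character(),
               stringsAsFactors = FALSE)
  known <- canon_pairs(known_pairs$tf_a, known_pairs$tf_b)
  tf_universe <- sort(unique(stats::na.omit(unname(tf_map))))
  known_uni <- known[known$tf_a %in% tf_universe &
                     known$tf_b %in% tf_universe, , drop = FALSE]
  pk <- paste(predicted$tf_a, predicted$tf_b)
  kk <- paste(known_uni$tf_a, known_uni$tf_b)
  pct_known <- if (nrow(known_uni)) 100 * mean(kk %in% pk) else NA_real_
  pct_supp <- if (nrow(predicted)) 100 * mean(pk %in% kk) else NA_real_
  list(pct_known_discovered = if (nrow(known_uni)) pct_known else 0,
       pct_predicted_supported = pct_supp,
       n_known_universe = nrow(known_uni), n_predicted = nrow(predicted),
       flagged = !nrow(predicted) || !nrow(known_uni))
}

#' Rank-sum (Mann-Whitney) AUC
#'
#' Area under the ROC curve of `scores` for predicting `positive`, with
#' ties counted half.
#'
#' @param scores numeric prediction scores (higher = more positive).
#' @param positive logical vector.
#' @return AUC in `[0, 1]`.
#' @export
rank_auc <- function(scores, positive) {
  stopifnot(length(scores) == length(positive))
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Presence-of-cluster feature matrix for a dataset collection
#'
#' Feature `j` of dataset `d` is 1 iff non-redundant cluster `j` contains
#' a motif discovered in `d`.
#'
#' @param clusters list of `motif_cluster` objects.
#' @param dataset_ids the datasets (row order of the result).
#' @return Binary matrix, datasets x clusters.
#' @export
cluster_presence_matrix <- function(clusters, dataset_ids) {
  m <- matrix(0L, nrow = length(dataset_ids), ncol = length(clusters),
              dimnames = list(dataset_ids,
                              sprintf("nrMotif%04d", seq_along(clusters))))
  for (j in seq_along(clusters)) {
    m[unique(clusters[[j]]$datasets), j] <- 1L
  }
  m
}

## orient a decision-value vector so higher = more positive.
orient_scores <- function(dec, positive) {
  if (mean(dec[positive]) < mean(dec[!positive])) -dec else dec
}

#' Classify dataset cell/tissue types from motif features
#'
#' Types with fewer than `min_class_size` datasets are excluded; the rest
#' are classified by one-vs-rest linear maximum-margin SVMs (kernlab's SMO
#' solver) under stratified `cv_folds`-fold cross-validation with a fixed
#' seed.  Out-of-fold decision values yield per-class one-vs-rest AUCs.
#'
#' @param features numeric matrix, datasets x features (e.g.
#'   [cluster_presence_matrix()]).
#' @param labels type label per dataset.
#' @param config a [default_config()] (`min_class_size`, `cv_folds`).
#' @param seed integer seed for fold assignment.
#' @param C SVM cost parameter.
#' @return List of class `classification_report`: `accuracy`,
#'   `fold_accuracy`, `confusion`, `class_auc`, `weighted_auc`,
#'   `classes`, `n_used`.
#' @export
classify_types <- function(features, labels, config = default_config(),
                           seed = config$random_seed, C = 1) {
  stopifnot(nrow(features) == length(labels))
  tab <- table(labels)
  keep_classes <- names(tab)[tab >= config$min_class_size]
  keep <- labels %in% keep_classes
  x <- as.matrix(features[keep, , drop = FALSE])
  y <- factor(labels[keep])
  n <- length(y)
  k <- config$cv_folds
  if (any(table(y) < k)) {
    stop("stratification error: a class has fewer datasets than folds",
         call. = FALSE)
  }

  fold <- integer(n)
  with_seed(stage_seed(seed, "cv_folds"), {
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })

  pred <- factor(rep(NA_character_, n), levels = levels(y))
  dec_mat <- matrix(NA_real_, n, nlevels(y),
                    dimnames = list(NULL, levels(y)))
  for (f in seq_len(k)) {
    tr <- fold != f; te <- !tr
    for (cl in levels(y)) {
      ybin <- factor(ifelse(y == cl, "pos", "neg"),
                     levels = c("neg", "pos"))
      fit <- kernlab::ksvm(x[tr, , drop = FALSE], ybin[tr],
                           type = "C-svc",
                           kernel = "vanilladot",
                           kpar = list(), C = C, scaled = FALSE)
      dtr <- kernlab::predict(fit, x[tr, , drop = FALSE],
                              type = "decision")[, 1L]
      flip <- mean(dtr[ybin[tr] == "pos"]) < mean(dtr[ybin[tr] == "neg"])
      dte <- kernlab::predict(fit, x[te, , drop = FALSE],
                              type = "decision")[, 1L]
      dec_mat[te, cl] <- if (flip) -dte else dte
    }
    pred[te] <- levels(y)[apply(dec_mat[te, , drop = FALSE], 1L,
                                which.max)]
  }

  fold_acc <- vapply(seq_len(k), function(f) {
    mean(pred[fold == f] == y[fold == f])
  }, numeric(1))
  class_auc <- vapply(levels(y), function(cl) {
    rank_auc(dec_mat[, cl], y == cl)
  }, numeric(1))
  sizes <- as.numeric(table(y)[levels(y)])
  structure(list(accuracy = mean(pred == y),
                 fold_accuracy = fold_acc,
                 confusion = table(truth = y, predicted = pred),
                 class_auc = class_auc,
                 weighted_auc = sum(sizes / n * class_auc),
                 classes = levels(y), n_used = n),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf(paste0("<classification_report> %d datasets, %d classes: ",
                     "accuracy %.2f%% (folds %.2f--%.2f%%), ",
                     "weighted AUC %.3f\n"),
              x$n_used, length(x$classes), 100 * x$accuracy,
              100 * min(x$fold_accuracy), 100 * max(x$fold_accuracy),
              x$weighted_auc))
  invisible(x)
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf(paste0("<coverage_report> %d/%d collection motifs covered ",
                     "(%.2f%%); %.2f%% of %d predictions known\n"),
              x$n_covered, x$n_collection,
              if (is.na(x$pct_covered)) NA else x$pct_covered,
              if (is.na(x$pct_predicted_known)) NA else
                x$pct_predicted_known,
              x$n_predicted))
  invisible(x)
}
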