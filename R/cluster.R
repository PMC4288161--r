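#' Non-redundant motif clustering across datasets
#'
#' Motifs discovered in many datasets are merged into non-redundant
#' clusters by a sequential procedure: clusters are seeded from the dataset
#' with the most motifs; motifs from the remaining datasets (processed in
#' descending motif-count order) join the first cluster satisfying the
#' anchor-and-membership rule; motifs joining no cluster are pooled, and
#' mutually similar pooled motifs found new clusters.  Each cluster is
#' represented by the member most similar to its other members, and
#' clusters with similar representatives are refined by hierarchical
#' clustering.
#'
#' @name nonredundant_clustering
NULL

new_motif_cluster <- function(member, dataset) {
  structure(list(members = list(member), datasets = dataset,
                 representative = member$id),
            class = "motif_cluster")
}

#' @export
print.motif_cluster <- function(x, ...) {
  cat(sprintf("<motif_cluster> %d member(s), representative %s\n",
              length(x$members), x$representative))
  invisible(x)
}

#' Anchor-and-membership rule for joining a cluster
#'
#' Motif `x` is similar to cluster `A` iff (anchor) its ALLR E-value to at
#' least one member is below `cluster_e_anchor`, and (membership) its ALLR
#' E-value is below `cluster_e_member` to every member when
#' `|A| < cluster_small_size`, or to at least `cluster_frac` of the
#' members otherwise.
#'
#' @param x motif or PWM.
#' @param A a `motif_cluster`.
#' @param engine a [new_similarity_engine()].
#' @return Logical.
#' @export
similar_to_cluster <- function(x, A, engine) {
  cfg <- engine$config
  ev <- vapply(A$members, function(m) evalue_allr_pair(x, m, engine),
               numeric(1))
  if (!any(ev < cfg$cluster_e_anchor)) return(FALSE)
  n_sim <- sum(ev < cfg$cluster_e_member)
  n <- length(ev)
  if (n < cfg$cluster_small_size) n_sim == n else
    n_sim / n >= cfg$cluster_frac
}

## pairwise "similar" for pooling/representatives: ALLR E < cluster_e_member.
pairwise_similar_matrix <- function(motifs, engine) {
  n <- length(motifs)
  sim <- matrix(FALSE, n, n)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        s <- evalue_allr_pair(motifs[[i]], motifs[[j]], engine) <
          engine$config$cluster_e_member
        sim[i, j] <- sim[j, i] <- s
      }
    }
  }
  diag(sim) <- TRUE
  sim
}

## Greedy max-degree grouping of pooled motifs; returns list of index sets.
pool_groups <- function(sim) {
  n <- nrow(sim)
  left <- rep(TRUE, n)
  groups <- list()
  repeat {
    deg <- vapply(seq_len(n), function(i) {
      if (!left[i]) -1L else sum(sim[i, left]) - 1L
    }, integer(1))
    if (all(deg < 1L)) break
    seed <- which.max(deg)          # ties: smallest index (pool order)
    grp <- which(left & sim[seed, ])
    groups[[length(groups) + 1L]] <- grp
    left[grp] <- FALSE
  }
  c(groups, as.list(which(left)))   # leftovers become singletons
}

#' Cluster motifs from many datasets into non-redundant clusters
#'
#' @param motif_sets named list: dataset id -> list of [new_motif()]
#'   objects discovered in that dataset.
#' @param engine a [new_similarity_engine()].
#' @param order `"descending"` (default: seed from the dataset with most
#'   motifs) or `"ascending"` (the robustness variant).
#' @return List of `motif_cluster` objects, in creation order, with
#'   representatives chosen.
#' @export
cluster_all <- function(motif_sets, engine, order = c("descending",
                                                      "ascending")) {
  order <- match.arg(order)
  stopifnot(length(motif_sets) >= 1L)
  counts <- lengths(motif_sets)
  ids <- names(motif_sets)
  ord <- order(if (order == "descending") -counts else counts, ids)
  ids <- ids[ord]

  clusters <- list()
  first <- ids[1L]
  for (m in motif_sets[[first]]) {
    clusters[[length(clusters) + 1L]] <- new_motif_cluster(m, first)
  }
  for (d in ids[-1L]) {
    pool <- list()
    for (m in motif_sets[[d]]) {
      joined <- FALSE
      for (ci in seq_along(clusters)) {
        if (similar_to_cluster(m, clusters[[ci]], engine)) {
          clusters[[ci]]$members <- c(clusters[[ci]]$members, list(m))
          clusters[[ci]]$datasets <- c(clusters[[ci]]$datasets, d)
          joined <- TRUE
          break
        }
      }
      if (!joined) pool[[length(pool) + 1L]] <- m
    }
    if (length(pool)) {
      sim <- pairwise_similar_matrix(pool, engine)
      for (grp in pool_groups(sim)) {
        cl <- new_motif_cluster(pool[[grp[1L]]], d)
        for (k in grp[-1L]) {
          cl$members <- c(cl$members, list(pool[[k]]))
          cl$datasets <- c(cl$datasets, d)
        }
        clusters[[length(clusters) + 1L]] <- cl
      }
    }
  }
  lapply(clusters, choose_representative, engine = engine)
}

#' Choose a cluster's representative motif
#'
#' The member similar (ALLR E-value < `cluster_e_member`) to the largest
#' number of other members; ties go to the earliest-added member.
#'
#' @param A a `motif_cluster`.
#' @param engine a [new_similarity_engine()].
#' @return `A` with its `representative` field set.
#' @export
choose_representative <- function(A, engine) {
  n <- length(A$members)
  if (n == 1L) {
    A$representative <- A$members[[1L]]$id
    return(A)
  }
  sim <- pairwise_similar_matrix(A$members, engine)
  n_sim <- rowSums(sim) - 1L
  A$representative <- A$members[[which.max(n_sim)]]$id  # ties: earliest
  A
}

representative_motif <- function(A) {
  A$members[[match(A$representative,
                   vapply(A$members, `[[`, character(1), "id"))]]
}

## union-find components over a logical adjacency matrix.
adj_components <- function(adj) {
  n <- nrow(adj)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (adj[i, j]) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  split(seq_len(n), vapply(seq_len(n), find, integer(1)))
}

#' Refine clusters whose representatives are similar
#'
#' Groups of clusters with pairwise-similar representatives are pooled and
#' re-clustered by average-linkage hierarchical clustering on one minus
#' the normalized ALLR alignment score, cut at the smallest number of
#' clusters for which every resulting cluster satisfies the
#' anchor-and-membership rule for all its members.  Repeats until no
#' representative pair is similar, at most `max_iter` times.
#'
#' @param clusters list of `motif_cluster` objects.
#' @param engine a [new_similarity_engine()].
#' @param max_iter iteration cap (default 10).
#' @return The refined cluster list.
#' @export
refine_clusters <- function(clusters, engine, max_iter = 10L) {
  for (iter in seq_len(max_iter)) {
    reps <- lapply(clusters, representative_motif)
    sim <- pairwise_similar_matrix(reps, engine)
    diag(sim) <- FALSE
    if (!any(sim)) break
    diag(sim) <- TRUE
    comps <- adj_components(sim)
    keep <- list(); rebuilt <- list()
    for (comp in comps) {
      if (length(comp) == 1L) {
        keep[[length(keep) + 1L]] <- clusters[[comp]]
        next
      }
      members <- list(); datasets <- character(0)
      for (ci in comp) {
        members <- c(members, clusters[[ci]]$members)
        datasets <- c(datasets, clusters[[ci]]$datasets)
      }
      for (grp in hclust_cut_valid(members, engine)) {
        cl <- new_motif_cluster(members[[grp[1L]]], datasets[grp[1L]])
        for (k in grp[-1L]) {
          cl$members <- c(cl$members, list(members[[k]]))
          cl$datasets <- c(cl$datasets, datasets[k])
        }
        rebuilt[[length(rebuilt) + 1L]] <- cl
      }
    }
    clusters <- lapply(c(keep, rebuilt), choose_representative,
                       engine = engine)
  }
  clusters
}

## Average-linkage clustering of pooled members; returns the coarsest cut
## (smallest k) whose clusters all satisfy the membership rule internally.
hclust_cut_valid <- function(members, engine) {
  n <- length(members)
  if (n == 1L) return(list(1L))
  sc <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    s <- align_score(members[[i]], members[[j]], "allr")$score
    sc[i, j] <- sc[j, i] <- s
  }
  rng <- range(sc[upper.tri(sc)])
  d <- if (diff(rng) > 0) 1 - (sc - rng[1L]) / diff(rng) else
    matrix(0, n, n)
  diag(d) <- 0
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  for (k in seq_len(n)) {
    grps <- split(seq_len(n), stats::cutree(hc, k))
    ok <- all(vapply(grps, function(g) {
      if (length(g) == 1L) return(TRUE)
      all(vapply(seq_along(g), function(ii) {
        rest <- g[-ii]
        cl <- new_motif_cluster(members[[rest[1L]]], "pool")
        for (r in rest[-1L]) cl$members <- c(cl$members, list(members[[r]]))
        similar_to_cluster(members[[g[ii]]], cl, engine)
      }, logical(1)))
    }, logical(1)))
    if (ok) return(unname(grps))
  }
  as.list(seq_len(n))
}

#' Cluster membership table
#'
#' @param clusters list of `motif_cluster` objects.
#' @return Data frame: `cluster_id`, `representative`, `motif_id`,
#'   `dataset`.
#' @export
cluster_table <- function(clusters) {
  rows <- lapply(seq_along(clusters), function(ci) {
    cl <- clusters[[ci]]
    data.frame(cluster_id = sprintf("nrMotif%04d", ci),
               representative = cl$representative,
               motif_id = vapply(cl$members, `[[`, character(1), "id"),
               dataset = cl$datasets, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
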