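#' Total variation distance between copying vectors
#'
#' `TVD(i, j) = 0.5 * sum_k |x_ik - x_jk|`, a metric on the simplex taking
#' values in \[0, 1\]: 0 for identical vectors, 1 for disjoint support.
#'
#' @param vectors Matrix of simplex row vectors on a common donor-cluster
#'   basis (e.g. from [copying_vectors()]).
#' @return Symmetric matrix of pairwise TVD with zero diagonal.
#' @export
tvd_pairwise <- function(vectors) {
  vectors <- as.matrix(vectors)
  half_l1_dist(vectors)
}

#' Hierarchical clustering of copying vectors on TVD distance
#'
#' A deterministic agglomerative stand-in for MCMC-based coancestry
#' clustering: individuals are merged by average (or complete) linkage on the
#' pairwise TVD of their copying vectors, and the dendrogram is cut into `k`
#' clusters (or at height `h`).  Externally produced assignments can be used
#' everywhere downstream instead (see [read_assignment()]).
#'
#' @param vectors Copying-vector matrix (individuals x donor clusters).
#' @param k Number of initial clusters to cut (>= 1), or `NULL` to use `h`.
#' @param h Cut height (TVD units), used when `k` is NULL.
#' @param linkage `"average"` (default) or `"complete"`.
#' @return A list: `tree` (an `hclust` over individuals), `assignment`
#'   (tibble `id`, `cluster`).
#' @export
build_tree <- function(vectors, k = NULL, h = NULL, linkage = c("average", "complete")) {
  linkage <- match.arg(linkage)
  vectors <- as.matrix(vectors)
  if (nrow(vectors) < 2L) abort("need at least 2 individuals.")
  if (!is.null(k) && k < 1) abort("`k` must be >= 1.")
  d <- stats::as.dist(tvd_pairwise(vectors))
  tree <- hclust(d, method = linkage)
  ids <- rownames(vectors) %||% paste0("ind", seq_len(nrow(vectors)))
  tree$labels <- ids
  cl <- if (!is.null(k)) cutree(tree, k = k) else if (!is.null(h)) {
    cutree(tree, h = h)
  } else {
    abort("supply `k` or `h`.")
  }
  list(tree = tree,
       assignment = tibble(id = ids, cluster = paste0("C", unname(cl))))
}

cluster_members <- function(assignment) {
  split(assignment$id, assignment$cluster)
}

cluster_means <- function(vectors, assignment, stat = c("mean", "median")) {
  stat <- match.arg(stat)
  f <- if (stat == "mean") colMeans else function(m) apply(m, 2, median)
  mem <- cluster_members(assignment)
  out <- t(vapply(mem, function(ids) {
    f(vectors[ids, , drop = FALSE])
  }, numeric(ncol(vectors))))
  rownames(out) <- names(mem)
  out
}

#' Size-based tree refinement (collapse small branches)
#'
#' Climbs the cluster dendrogram bottom-up and collapses every maximal
#' internal node whose descendant leaves comprise fewer than
#' `max_branch_clusters` clusters AND at least one of those clusters has
#' fewer than `min_cluster_individuals` members.  The collapse is repeated to
#' a fixpoint, rebuilding the cluster tree (average-linkage TVD between
#' cluster mean vectors) after each pass, so the result is idempotent.
#'
#' @param assignment Tibble (`id`, `cluster`).
#' @param vectors Copying-vector matrix (used to build the cluster tree).
#' @param max_branch_clusters Collapse only nodes with fewer leaf clusters
#'   than this (default 5).
#' @param min_cluster_individuals A node qualifies only if some descendant
#'   cluster is smaller than this (default 5).
#' @return The refined assignment tibble.
#' @export
refine_tree_size <- function(assignment, vectors, max_branch_clusters = 5,
                             min_cluster_individuals = 5) {
  assignment <- as_tibble(assignment)
  if (!all(assignment$id %in% rownames(vectors))) {
    abort("assignment and copying vectors are inconsistent (unknown ids).")
  }
  repeat {
    sizes <- table(assignment$cluster)
    if (length(sizes) < 2L) break
    cm <- cluster_means(vectors, assignment)
    tree <- hclust(stats::as.dist(half_l1_dist(cm)), method = "average")
    tree$labels <- rownames(cm)
    merges <- collapse_nodes(tree, sizes, max_branch_clusters,
                             min_cluster_individuals)
    if (!length(merges)) break
    for (grp in merges) {
      new_lab <- grp[1]
      assignment$cluster[assignment$cluster %in% grp] <- new_lab
    }
  }
  assignment
}

# Find maximal qualifying internal nodes of an hclust tree.
# Returns a list of character vectors of leaf-cluster labels to pool.
collapse_nodes <- function(tree, sizes, max_branch, min_ind) {
  m <- tree$merge
  n_nodes <- nrow(m)
  leaves <- vector("list", n_nodes)
  for (v in seq_len(n_nodes)) {
    get_side <- function(x) if (x < 0) tree$labels[-x] else leaves[[x]]
    leaves[[v]] <- c(get_side(m[v, 1]), get_side(m[v, 2]))
  }
  qual <- vapply(seq_len(n_nodes), function(v) {
    lv <- leaves[[v]]
    length(lv) < max_branch && any(sizes[lv] < min_ind)
  }, logical(1))
  parent <- rep(NA_integer_, n_nodes)
  for (v in seq_len(n_nodes)) {
    for (s in m[v, ]) if (s > 0) parent[s] <- v
  }
  maximal <- which(qual & vapply(seq_len(n_nodes), function(v) {
    p <- parent[v]
    is.na(p) || !qual[p]
  }, logical(1)))
  leaves[maximal]
}

#' TVD-based cluster pooling
#'
#' Pools clusters whose mean copying vectors (chunk-count basis by default)
#' are closer (merge-if-below mode, the default) or farther (merge-if-above)
#' than a TVD `threshold`, greedily from the most extreme eligible pair and
#' re-evaluating after every merge.  A pool never grows beyond `max_pool`
#' original clusters (default 3: pairs or triplets).
#'
#' The merge direction is a mandatory explicit flag because the two readings
#' of a pooling threshold are both defensible; `"below"` (merge
#' indistinguishable clusters) is the default.
#'
#' @param assignment Tibble (`id`, `cluster`).
#' @param vectors Copying-vector matrix.
#' @param threshold TVD threshold in (0, 1) (default 0.035).
#' @param max_pool Maximum original clusters per pool (default 3).
#' @param direction `"below"` or `"above"`.
#' @param stat Cluster summary vector: `"mean"` (default) or `"median"`.
#' @return The refined assignment tibble.
#' @export
refine_tree_tvd <- function(assignment, vectors, threshold = 0.035,
                            max_pool = 3, direction = c("below", "above"),
                            stat = c("mean", "median")) {
  direction <- match.arg(direction)
  stat <- match.arg(stat)
  if (threshold <= 0 || threshold >= 1) abort("`threshold` must lie in (0, 1).")
  assignment <- as_tibble(assignment)
  # Pool sizes count *original* clusters per pool.  They are carried on the
  # returned assignment as an attribute so that re-applying the refinement is
  # the identity (a pool capped at max_pool stays capped).
  pool_size <- attr(assignment, "pool_sizes") %||%
    setNames(rep(1L, length(unique(assignment$cluster))),
             unique(assignment$cluster))
  repeat {
    labs <- unique(assignment$cluster)
    if (length(labs) < 2L) break
    cm <- cluster_means(vectors, assignment, stat = stat)
    tv <- half_l1_dist(cm)
    best <- NULL; best_val <- if (direction == "below") Inf else -Inf
    for (i in seq_len(nrow(tv) - 1L)) {
      for (j in seq((i + 1L), nrow(tv))) {
        li <- rownames(tv)[i]; lj <- rownames(tv)[j]
        if (pool_size[li] + pool_size[lj] > max_pool) next
        v <- tv[i, j]
        eligible <- if (direction == "below") v < threshold else v > threshold
        if (!eligible) next
        better <- if (direction == "below") v < best_val else v > best_val
        if (better) { best <- c(li, lj); best_val <- v }
      }
    }
    if (is.null(best)) break
    keep <- best[1]; gone <- best[2]
    assignment$cluster[assignment$cluster == gone] <- keep
    pool_size[keep] <- pool_size[keep] + pool_size[gone]
    pool_size <- pool_size[names(pool_size) != gone]
  }
  attr(assignment, "pool_sizes") <- pool_size
  assignment
}

#' Pairwise TVD at three analysis levels
#'
#' For each cluster, computes the distribution of pairwise TVD between
#' copying vectors at the three levels used to quantify within-cluster
#' heterogeneity:
#' * `intra_cluster_all`: all pairs of cluster members;
#' * `focal_vs_all`: pairs with at least one member of the focal group(s);
#' * `focal_only`: pairs where both members are focal.
#'
#' Clusters with no eligible pair at a level appear in the per-cluster
#' summary with `n_pairs = 0` rather than being dropped.
#'
#' @param vectors Copying-vector matrix.
#' @param assignment Tibble (`id`, `cluster`).
#' @param groups Named vector id -> group label (e.g. population).
#' @param focal_labels Group label(s) defining the focal set.
#' @param basis Label recorded in the output (`"counts"` or `"lengths"`; pass
#'   the matching `vectors`).
#' @return A list: `pairs` (tibble `level`, `basis`, `cluster`, `id1`, `id2`,
#'   `tvd`) and `per_cluster` (tibble with `n_pairs` and `median_tvd` per
#'   cluster and level).
#' @export
tvd_levels <- function(vectors, assignment, groups, focal_labels,
                       basis = c("counts", "lengths")) {
  basis <- match.arg(basis)
  assignment <- as_tibble(assignment)
  if (!all(focal_labels %in% groups)) {
    abort("unknown focal label(s): not present in `groups`.")
  }
  focal_ids <- names(groups)[groups %in% focal_labels]
  rows <- list()
  for (cl in unique(assignment$cluster)) {
    ids <- assignment$id[assignment$cluster == cl]
    if (length(ids) >= 2L) {
      tv <- half_l1_dist(vectors[ids, , drop = FALSE])
      pr <- which(upper.tri(tv), arr.ind = TRUE)
      id1 <- ids[pr[, 1]]; id2 <- ids[pr[, 2]]
      tvv <- tv[pr]
      f1 <- id1 %in% focal_ids; f2 <- id2 %in% focal_ids
      lev <- list(
        intra_cluster_all = rep(TRUE, length(tvv)),
        focal_vs_all = f1 | f2,
        focal_only = f1 & f2
      )
      for (lv in names(lev)) {
        sel <- lev[[lv]]
        if (any(sel)) {
          rows[[length(rows) + 1L]] <- tibble(
            level = lv, basis = basis, cluster = cl,
            id1 = id1[sel], id2 = id2[sel], tvd = tvv[sel]
          )
        }
      }
    }
  }
  pairs <- if (length(rows)) bind_rows(rows) else
    tibble(level = character(), basis = character(), cluster = character(),
           id1 = character(), id2 = character(), tvd = numeric())
  grid <- tidyr::expand_grid(
    cluster = unique(assignment$cluster),
    level = c("intra_cluster_all", "focal_vs_all", "focal_only")
  )
  per_cluster <- pairs |>
    group_by(.data$cluster, .data$level) |>
    summarise(n_pairs = dplyr::n(), median_tvd = median(.data$tvd),
              .groups = "drop") |>
    dplyr::right_join(grid, by = c("cluster", "level")) |>
    mutate(n_pairs = ifelse(is.na(.data$n_pairs), 0L, .data$n_pairs),
           basis = basis)
  list(pairs = pairs, per_cluster = per_cluster)
}

#' Read / write cluster assignments as two-column TSV
#'
#' @param path File path.
#' @param assignment Tibble (`id`, `cluster`).
#' @return `read_assignment()` returns the assignment tibble.
#' @export
read_assignment <- function(path) {
  x <- read.table(path, header = TRUE, sep = "\t", colClasses = "character")
  as_tibble(x[, c("id", "cluster")])
}

#' @rdname read_assignment
#' @export
write_assignment <- function(assignment, path) {
  write.table(assignment, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
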