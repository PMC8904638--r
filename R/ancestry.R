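#' Constrained NNLS ancestry profile of a copying vector
#'
#' Decomposes a copying vector `y` as a non-negative mixture of source
#' copying profiles with proportions summing to one:
#' minimise `|| y - t(S) beta ||^2` subject to `beta >= 0`, with the
#' sum-to-one constraint enforced softly by appending a penalty row of weight
#' `penalty` to the design (so the solver sees `penalty * sum(beta) ~
#' penalty`), followed by exact renormalisation of the solution.  A
#' pre-renormalisation sum outside \[0.99, 1.01\] raises a warning that the
#' penalty is too weak.
#'
#' Donor-cluster columns listed in `drop` (typically the recipient's own
#' cluster) are removed from `y` and from every source profile, and both are
#' renormalised, before solving.
#'
#' @param y Copying vector (simplex over donor clusters), named.
#' @param sources Matrix of source profiles, sources x donor clusters, named
#'   rows; at least 2 linearly independent rows.
#' @param penalty Sum-to-one penalty weight; default 100 times the largest
#'   entry magnitude of `sources`.
#' @param drop Donor-cluster columns (names or indices) to remove before
#'   solving.
#' @return An object of class `ancestry_profile`: list with `weights` (named
#'   simplex vector over sources), `residual` (L2 norm of the fit residual on
#'   the renormalised basis) and `pre_normalisation_sum`.
#' @export
nnls_profile <- function(y, sources, penalty = NULL, drop = NULL) {
  sources <- as.matrix(sources)
  if (nrow(sources) < 2L) abort("need at least 2 source profiles.")
  if (is.null(rownames(sources))) rownames(sources) <- paste0("source", seq_len(nrow(sources)))
  if (length(y) != ncol(sources)) abort("`y` and source profiles differ in length.")
  if (anyDuplicated(round(sources, 12))) {
    warn("duplicate source profiles: the decomposition is degenerate.")
  }
  if (!is.null(drop)) {
    di <- if (is.character(drop)) match(drop, colnames(sources)) else drop
    di <- di[!is.na(di)]
    if (length(di)) {
      y <- y[-di]
      sources <- sources[, -di, drop = FALSE]
    }
  }
  if (sum(y) <= 0) abort("copying vector is all zero after column removal.")
  y <- y / sum(y)
  rs <- rowSums(sources)
  if (any(rs <= 0)) abort("a source profile is all zero after column removal.")
  sources <- sources / rs
  if (is.null(penalty)) penalty <- 100 * max(abs(sources))
  if (penalty <= 0) abort("`penalty` must be positive.")
  A <- rbind(t(sources), penalty)
  b <- c(y, penalty)
  beta <- pracma::lsqnonneg(A, b)$x
  s <- sum(beta)
  if (s < 0.99 || s > 1.01) {
    warn(sprintf("pre-renormalisation weight sum %.4f outside [0.99, 1.01]; increase `penalty`.", s))
  }
  if (s <= 0) abort("NNLS returned an all-zero solution.")
  w <- setNames(beta / s, rownames(sources))
  structure(list(
    weights = w,
    residual = sqrt(sum((y - drop(t(sources) %*% w))^2)),
    pre_normalisation_sum = s
  ), class = "ancestry_profile")
}

#' @export
print.ancestry_profile <- function(x, ...) {
  cat("<ancestry_profile>\n")
  print(round(x$weights, 4))
  cat(sprintf("residual: %.4g\n", x$residual))
  invisible(x)
}

#' @export
tidy.ancestry_profile <- function(x, ...) {
  tibble(source = names(x$weights), weight = unname(x$weights))
}

#' @export
glance.ancestry_profile <- function(x, ...) {
  tibble(n_sources = length(x$weights), residual = x$residual,
         pre_normalisation_sum = x$pre_normalisation_sum)
}

#' NNLS ancestry profiles for clusters and individuals
#'
#' Builds each putative source's copying profile as the mean copying vector
#' of the source cluster's members, then decomposes every target individual
#' (and every target cluster) against those sources, removing the target's
#' own donor-cluster column from both sides before solving.  Cluster profiles
#' are the profile of the cluster's mean vector by default; set
#' `mean_of_individual_profiles = TRUE` to average the per-individual
#' profiles instead.
#'
#' @param vectors Copying-vector matrix on the donor-cluster basis (columns
#'   named by cluster; e.g. `copying_vectors(M, assignment)`).
#' @param assignment Tibble (`id`, `cluster`) covering the rows of `vectors`.
#' @param source_clusters Cluster labels to use as putative sources (any
#'   number of panels can be run by calling once per panel, e.g. a 5-source
#'   and a 3-source set).
#' @param targets Cluster labels to profile (default: all non-source
#'   clusters).
#' @param penalty,mean_of_individual_profiles See above / [nnls_profile()].
#' @return A tibble: `target`, `target_type` (`"cluster"`/`"individual"`),
#'   `source`, `weight`, `residual`.
#' @export
cluster_profiles <- function(vectors, assignment, source_clusters,
                             targets = NULL, penalty = NULL,
                             mean_of_individual_profiles = FALSE) {
  assignment <- as_tibble(assignment)
  mem <- cluster_members(assignment)
  missing_src <- setdiff(source_clusters, names(mem))
  if (length(missing_src)) {
    abort(paste0("source cluster(s) with no members: ",
                 paste(missing_src, collapse = ", ")))
  }
  S <- cluster_means(vectors, assignment)[source_clusters, , drop = FALSE]
  if (is.null(targets)) targets <- setdiff(names(mem), source_clusters)
  rows <- list()
  push <- function(target, type, prof_w, resid) {
    rows[[length(rows) + 1L]] <<- tibble(
      target = target, target_type = type,
      source = names(prof_w), weight = unname(prof_w), residual = resid
    )
  }
  for (cl in targets) {
    ind_w <- list()
    for (id in mem[[cl]]) {
      pr <- nnls_profile(vectors[id, ], S, penalty = penalty, drop = cl)
      push(id, "individual", pr$weights, pr$residual)
      ind_w[[id]] <- pr$weights
    }
    if (mean_of_individual_profiles && length(ind_w)) {
      w <- colMeans(do.call(rbind, ind_w))
      push(cl, "cluster", w / sum(w), NA_real_)
    } else {
      mv <- colMeans(vectors[mem[[cl]], , drop = FALSE])
      pr <- nnls_profile(mv, S, penalty = penalty, drop = cl)
      push(cl, "cluster", pr$weights, pr$residual)
    }
  }
  bind_rows(rows)
}

#' Stacked-bar plot of ancestry profiles
#'
#' @param profiles Output of [cluster_profiles()].
#' @param type Which targets to show (`"cluster"` or `"individual"`).
#' @return A ggplot.
#' @export
plot_ancestry_profiles <- function(profiles, type = "cluster") {
  dat <- profiles |> filter(.data$target_type == type)
  ggplot2::ggplot(dat, ggplot2::aes(.data$target, .data$weight, fill = .data$source)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "ancestry proportion", fill = "source") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
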