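#' Weir-Cockerham FST between two populations
#'
#' Computes the per-SNP variance components of Weir & Cockerham's (1984)
#' FST estimator with r = 2 populations: `a` (among populations), `b` (among
#' individuals within populations) and `c` (within individuals, i.e.
#' heterozygosity), and returns the ratio-of-sums estimate
#' `FST = sum(a) / sum(a + b + c)`.  SNPs monomorphic across both samples, or
#' with a zero total variance component, are excluded from the sums.
#' Negative estimates are reported as computed (set `clip = TRUE` for
#' display-style clipping at 0).
#'
#' @param G A [geno_matrix()].
#' @param pop_a,pop_b Population labels in `G$samples$pop`, or character
#'   vectors of sample ids.
#' @param clip Clip negative estimates to zero (default `FALSE`).
#' @return A one-row tibble: `fst`, `sum_a`, `sum_abc`, `n_snps_used`.
#' @export
wc_fst <- function(G, pop_a, pop_b, clip = FALSE) {
  stopifnot(inherits(G, "geno_matrix"))
  ga <- pop_calls(G, pop_a)
  gb <- pop_calls(G, pop_b)
  comp <- wc_components(ga, gb)
  used <- comp$used
  if (!any(used)) abort("all SNPs were excluded; FST undefined.")
  sum_a <- sum(comp$a[used])
  sum_abc <- sum(comp$a[used] + comp$b[used] + comp$c[used])
  fst <- sum_a / sum_abc
  if (clip) fst <- max(fst, 0)
  tibble(fst = fst, sum_a = sum_a, sum_abc = sum_abc, n_snps_used = sum(used))
}

pop_calls <- function(G, pop) {
  sel <- if (all(pop %in% G$samples$id)) G$samples$id %in% pop else G$samples$pop %in% pop
  if (!any(sel)) abort(sprintf("population '%s' has no individuals.", paste(pop, collapse = ",")))
  G$calls[sel, , drop = FALSE]
}

# Per-SNP Weir-Cockerham (1984) components for r = 2 samples.
wc_components <- function(ga, gb) {
  r <- 2
  n1 <- colSums(!is.na(ga)); n2 <- colSums(!is.na(gb))
  p1 <- colMeans(ga, na.rm = TRUE) / 2
  p2 <- colMeans(gb, na.rm = TRUE) / 2
  h1 <- colMeans(ga == 1L, na.rm = TRUE)
  h2 <- colMeans(gb == 1L, na.rm = TRUE)
  nbar <- (n1 + n2) / r
  ok <- n1 >= 2 & n2 >= 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  mono <- pbar == 0 | pbar == 1
  tot <- a + b + cc
  used <- ok & !mono & !is.na(tot) & tot != 0
  list(a = a, b = b, c = cc, used = used)
}

#' Pairwise FST matrix over population groups
#'
#' @param G A [geno_matrix()].
#' @param grouping Column of `G$samples` to group by (`"pop"` or
#'   `"subgroup"`), or a vector of labels aligned with the samples.
#' @inheritParams wc_fst
#' @return A tibble with one row per unordered pair: `pop1`, `pop2`, `fst`,
#'   `n_snps_used`, `flagged` (group with < 2 individuals).  Use
#'   [fst_matrix()] to reshape into a symmetric matrix with a zero diagonal.
#' @export
pairwise_fst <- function(G, grouping = "pop", clip = FALSE) {
  labs <- grouping_labels(G, grouping)
  groups <- unique(labs)
  if (length(groups) < 2L) abort("need at least two groups.")
  sizes <- table(labs)
  rows <- list()
  for (i in seq_len(length(groups) - 1L)) {
    for (j in seq((i + 1L), length(groups))) {
      small <- sizes[groups[i]] < 2 || sizes[groups[j]] < 2
      res <- if (small) {
        tibble(fst = NA_real_, sum_a = NA_real_, sum_abc = NA_real_,
               n_snps_used = 0L)
      } else {
        Gi <- G
        Gi$samples$pop <- labs
        dimnames(Gi$calls)[[1]] <- Gi$samples$id
        wc_fst(Gi, groups[i], groups[j], clip = clip)
      }
      rows[[length(rows) + 1L]] <- tibble(
        pop1 = groups[i], pop2 = groups[j], fst = res$fst,
        n_snps_used = res$n_snps_used, flagged = small
      )
    }
  }
  bind_rows(rows)
}

grouping_labels <- function(G, grouping) {
  if (length(grouping) == 1L && grouping %in% names(G$samples)) {
    G$samples[[grouping]]
  } else if (length(grouping) == nrow(G$samples)) {
    as.character(grouping)
  } else {
    abort("`grouping` must name a sample-metadata column or give one label per individual.")
  }
}

#' @rdname pairwise_fst
#' @param pf Output of `pairwise_fst()`.
#' @export
fst_matrix <- function(pf) {
  groups <- unique(c(pf$pop1, pf$pop2))
  m <- matrix(0, length(groups), length(groups), dimnames = list(groups, groups))
  for (k in seq_len(nrow(pf))) {
    m[pf$pop1[k], pf$pop2[k]] <- m[pf$pop2[k], pf$pop1[k]] <- pf$fst[k]
  }
  m
}

#' Runs-of-homozygosity scan
#'
#' Sliding-window RoH caller: per individual and chromosome, every window of
#' `window_snps` consecutive SNPs is a "hit" if it contains at most `max_het`
#' heterozygous and at most `max_missing` missing calls.  Each SNP's score is
#' the proportion of overlapping windows that are hits; SNPs scoring at least
#' `hit_fraction` are in the homozygous state, and maximal runs of such SNPs
#' spanning at least `min_kb` kb and `min_seg_snps` SNPs are emitted as
#' segments.  Chromosomes with fewer SNPs than `window_snps` are skipped with
#' a warning.
#'
#' @param G A [geno_matrix()].
#' @param window_snps Window size in SNPs.
#' @param max_het,max_missing Tolerated heterozygous / missing calls per window.
#' @param min_kb Minimum segment span in kb.
#' @param hit_fraction Minimum proportion of hit windows covering a SNP.
#' @param min_seg_snps Minimum SNPs per emitted segment.
#' @return Tibble of segments: `id`, `chrom`, `start_bp`, `end_bp`, `n_snps`,
#'   `length_kb` (span in kb, `(end - start + 1)/1000`).
#' @export
detect_roh <- function(G, window_snps = 100, max_het = 1, max_missing = 5,
                       min_kb = 1000, hit_fraction = 0.05, min_seg_snps = 100) {
  stopifnot(inherits(G, "geno_matrix"))
  segs <- list()
  for (ch in unique(G$snps$chrom)) {
    idx <- which(G$snps$chrom == ch)
    L <- length(idx)
    if (L < window_snps) {
      warn(sprintf("chromosome %s has %d SNPs (< window of %d); skipped.",
                   ch, L, window_snps))
      next
    }
    bp <- G$snps$bp[idx]
    n_win <- L - window_snps + 1L
    # windows covering SNP t: starts in [t - w + 1, t] clipped to [1, n_win]
    cover_lo <- pmax(1L, seq_len(L) - window_snps + 1L)
    cover_hi <- pmin(n_win, seq_len(L))
    n_cover <- cover_hi - cover_lo + 1L
    for (i in seq_len(nrow(G$calls))) {
      g <- G$calls[i, idx]
      het <- as.integer(!is.na(g) & g == 1L)
      mis <- as.integer(is.na(g))
      win_het <- roll_sum(het, window_snps)
      win_mis <- roll_sum(mis, window_snps)
      hit <- as.integer(win_het <= max_het & win_mis <= max_missing)
      chit <- c(0L, cumsum(hit))
      n_hit <- chit[cover_hi + 1L] - chit[cover_lo]
      hom <- n_hit / n_cover >= hit_fraction
      runs <- rle_runs(hom)
      for (k in seq_len(nrow(runs))) {
        s <- runs$start[k]; e <- runs$end[k]
        nsnp <- e - s + 1L
        span_kb <- (bp[e] - bp[s] + 1) / 1000
        if (nsnp >= min_seg_snps && span_kb >= min_kb) {
          segs[[length(segs) + 1L]] <- tibble(
            id = G$samples$id[i], chrom = ch,
            start_bp = bp[s], end_bp = bp[e],
            n_snps = nsnp, length_kb = span_kb
          )
        }
      }
    }
  }
  if (length(segs)) bind_rows(segs) else
    tibble(id = character(), chrom = character(), start_bp = integer(),
           end_bp = integer(), n_snps = integer(), length_kb = numeric())
}

roll_sum <- function(x, w) {
  cx <- c(0L, cumsum(x))
  cx[(w + 1L):length(cx)] - cx[1L:(length(cx) - w)]
}

rle_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  tibble(start = starts[keep], end = ends[keep])
}

#' Per-individual and per-group RoH summaries
#'
#' Individuals without segments contribute (0, 0).
#'
#' @param segments Output of [detect_roh()].
#' @param samples Sample tibble (id, pop) or a [geno_matrix()].
#' @param grouping Grouping column, as in [pairwise_fst()].
#' @return A list of tibbles: `individuals` (`id`, `n_segments`, `total_kb`)
#'   and `groups` (`group`, `mean_n_segments`, `mean_total_kb`).
#' @export
roh_summary <- function(segments, samples, grouping = "pop") {
  if (inherits(samples, "geno_matrix")) samples <- samples$samples
  per_ind <- segments |>
    group_by(id = .data$id) |>
    summarise(n_segments = dplyr::n(), total_kb = sum(.data$length_kb)) |>
    ungroup()
  individuals <- samples |>
    select("id") |>
    left_join(per_ind, by = "id") |>
    mutate(n_segments = ifelse(is.na(.data$n_segments), 0L, .data$n_segments),
           total_kb = ifelse(is.na(.data$total_kb), 0, .data$total_kb))
  labs <- if (length(grouping) == 1L) samples[[grouping]] else grouping
  groups <- individuals |>
    mutate(group = labs) |>
    group_by(.data$group) |>
    summarise(mean_n_segments = mean(.data$n_segments),
              mean_total_kb = mean(.data$total_kb)) |>
    ungroup()
  list(individuals = individuals, groups = groups)
}

#' PCA of genotype dosages
#'
#' Each SNP is centred by its mean dosage and scaled by `sqrt(p (1 - p))`
#' with `p` the sample allele frequency (the normalisation used for
#' genotype-matrix eigenanalysis); missing calls are set to zero after
#' centring, and the individual-by-individual covariance matrix is
#' eigendecomposed.  Component signs follow the convention that the score of
#' largest magnitude on each component is positive, so results are
#' deterministic.
#'
#' @param G A [geno_matrix()].
#' @param n_components Number of components to return (truncated to the rank
#'   with a warning if too large).
#' @return An object of class `pop_pca`: list with `scores` (tibble: `id`,
#'   `pop`, `PC1`...) and `var_frac` (fraction of variance per component).
#' @export
pca_genotypes <- function(G, n_components = 10) {
  stopifnot(inherits(G, "geno_matrix"))
  x <- G$calls
  if (any(colSums(!is.na(x)) == 0L)) abort("remove all-missing SNPs before PCA.")
  p <- colMeans(x, na.rm = TRUE) / 2
  keep <- p > 0 & p < 1
  x <- x[, keep, drop = FALSE]
  p <- p[keep]
  xc <- sweep(x, 2, 2 * p)
  xc[is.na(xc)] <- 0
  xc <- sweep(xc, 2, sqrt(p * (1 - p)), "/")
  cov_ii <- tcrossprod(xc) / ncol(xc)
  eig <- eigen(cov_ii, symmetric = TRUE)
  pos <- pmax(eig$values, 0)
  rank <- sum(pos > 1e-10)
  if (n_components > rank) {
    warn(sprintf("n_components truncated from %d to rank %d.", n_components, rank))
    n_components <- rank
  }
  scores <- eig$vectors[, seq_len(n_components), drop = FALSE] %*%
    diag(sqrt(pos[seq_len(n_components)]), n_components)
  scores <- fix_signs(scores)
  colnames(scores) <- paste0("PC", seq_len(n_components))
  out <- list(
    scores = bind_cols(G$samples[, c("id", "pop")], as_tibble(scores)),
    var_frac = pos[seq_len(n_components)] / sum(pos)
  )
  class(out) <- "pop_pca"
  out
}

fix_signs <- function(scores) {
  for (k in seq_len(ncol(scores))) {
    i <- which.max(abs(scores[, k]))
    if (scores[i, k] < 0) scores[, k] <- -scores[, k]
  }
  scores
}

#' PCA of a coancestry matrix
#'
#' Rows of the chunk-count (or chunk-length) coancestry matrix are treated as
#' observations and columns as variables; the matrix is centred but not
#' scaled, matching a default principal-components call on the raw matrix.
#' Signs follow the same largest-score-positive convention as
#' [pca_genotypes()].
#'
#' @param M Square numeric matrix (recipients x donors), e.g.
#'   `paint_all_vs_all()$chunk_counts`.
#' @param n_components Number of components.
#' @param groups Optional labels for the rows (for plotting).
#' @return A `pop_pca` object.
#' @export
pca_coancestry <- function(M, n_components = 10, groups = NULL) {
  M <- as.matrix(M)
  if (nrow(M) != ncol(M)) abort("coancestry matrix must be square.")
  pr <- prcomp(M, center = TRUE, scale. = FALSE)
  rank <- max(1L, sum(pr$sdev > 1e-12))
  if (n_components > rank) {
    warn(sprintf("n_components truncated from %d to rank %d.", n_components, rank))
    n_components <- rank
  }
  scores <- fix_signs(pr$x[, seq_len(n_components), drop = FALSE])
  colnames(scores) <- paste0("PC", seq_len(n_components))
  ids <- rownames(M) %||% paste0("ind", seq_len(nrow(M)))
  tot_var <- sum(pr$sdev^2)
  out <- list(
    scores = bind_cols(
      tibble(id = ids, pop = groups %||% "all"),
      as_tibble(scores)
    ),
    var_frac = if (tot_var > 0) pr$sdev[seq_len(n_components)]^2 / tot_var else
      rep(0, n_components)
  )
  class(out) <- "pop_pca"
  out
}

#' @export
print.pop_pca <- function(x, ...) {
  cat(sprintf("<pop_pca> %d individuals, %d components\n",
              nrow(x$scores), length(x$var_frac)))
  cat("variance fractions:",
      paste(sprintf("%.3g", head(x$var_frac, 5)), collapse = ", "),
      if (length(x$var_frac) > 5) "...\n" else "\n")
  invisible(x)
}

#' @export
tidy.pop_pca <- function(x, ...) {
  x$scores |>
    tidyr::pivot_longer(dplyr::starts_with("PC"),
                        names_to = "component", values_to = "score")
}

#' @export
glance.pop_pca <- function(x, ...) {
  tibble(n_components = length(x$var_frac),
         var_frac_pc1 = x$var_frac[1],
         var_frac_total = sum(x$var_frac))
}

#' @export
autoplot.pop_pca <- function(object, x = "PC1", y = "PC2", ...) {
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(.data[[x]], .data[[y]], colour = .data$pop)) +
    ggplot2::geom_point(...) +
    ggplot2::labs(
      x = sprintf("%s (%.2g%%)", x, 100 * object$var_frac[as.integer(sub("PC", "", x))]),
      y = sprintf("%s (%.2g%%)", y, 100 * object$var_frac[as.integer(sub("PC", "", y))]),
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}
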