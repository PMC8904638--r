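#' All-vs-all haplotype painting (Li-Stephens copying model, Viterbi)
#'
#' Paints every haplotype of every individual as a mosaic of the haplotypes
#' of all *other* individuals, under the Li-Stephens copying model: between
#' adjacent SNPs separated by `delta` Morgans the copied donor switches with
#' probability `1 - exp(-rho * delta)` to a uniformly chosen donor haplotype
#' (possibly the current one), and the emission probability is `1 - mu` when
#' the recipient allele matches the donor and `mu` otherwise.  The single
#' best donor path is found by Viterbi decoding (deterministic, unlike
#' ChromoPainter's expected counts from the forward-backward recursion; this
#' is a documented simplification that makes the output exactly checkable
#' against exhaustive path enumeration).  Ties are broken toward the lowest
#' donor index.
#'
#' A chunk is a maximal run copied from one donor haplotype.  Chunk lengths
#' are measured in cM between the midpoints of the inter-SNP intervals at the
#' chunk boundaries; first and last chunks extend to the ends of the map, so
#' each haplotype's chunk lengths sum to its chromosome spans and each row of
#' `chunk_lengths` sums to twice the total map span.
#'
#' @param panel A phased [hap_panel()] with at least 3 individuals.
#' @param rho Expected copy-switches per Morgan (default 50).
#' @param mu Per-site copying error probability, in (0, 0.5) (default 0.001).
#' @return A list of class `coancestry`: `chunk_counts` and
#'   `chunk_lengths_cm`, both recipients x donors matrices aggregated to
#'   individuals (diagonal identically 0), plus `samples` and `map_cm` (total
#'   map span).
#' @export
paint_all_vs_all <- function(panel, rho = 50, mu = 0.001) {
  stopifnot(inherits(panel, "hap_panel"))
  if (mu <= 0 || mu >= 0.5) abort("`mu` must lie in (0, 0.5).")
  if (rho <= 0) abort("`rho` must be positive.")
  n <- nrow(panel$samples)
  if (n < 3L) abort("all-vs-all painting needs at least 3 individuals.")
  snps <- panel$snps
  chroms <- unique(snps$chrom)
  span <- 0
  for (ch in chroms) {
    cm <- snps$cm[snps$chrom == ch]
    if (max(cm) - min(cm) <= 0) abort("zero map length on a chromosome.")
    span <- span + (max(cm) - min(cm))
  }
  ids <- panel$samples$id
  hap_owner <- rep(seq_len(n), each = 2)
  counts <- matrix(0, n, n, dimnames = list(ids, ids))
  lengths_cm <- matrix(0, n, n, dimnames = list(ids, ids))
  for (r in seq_len(2L * n)) {
    rec_owner <- hap_owner[r]
    donors <- which(hap_owner != rec_owner)
    for (ch in chroms) {
      idx <- which(snps$chrom == ch)
      path <- viterbi_path(panel$haps[r, idx],
                           panel$haps[donors, idx, drop = FALSE],
                           snps$cm[idx], rho, mu)
      agg <- chunk_aggregate(path, snps$cm[idx])
      don_ind <- hap_owner[donors[agg$donor]]
      for (k in seq_along(don_ind)) {
        counts[rec_owner, don_ind[k]] <- counts[rec_owner, don_ind[k]] + 1
        lengths_cm[rec_owner, don_ind[k]] <- lengths_cm[rec_owner, don_ind[k]] + agg$len_cm[k]
      }
    }
  }
  structure(list(chunk_counts = counts, chunk_lengths_cm = lengths_cm,
                 samples = panel$samples, map_cm = span),
            class = "coancestry")
}

# Viterbi decoding of the copying path for one recipient haplotype.
# y: recipient alleles (length L); Dm: donors x L matrix; cm: positions.
# Returns integer donor index (row of Dm) per SNP.
viterbi_path <- function(y, Dm, cm, rho, mu) {
  D <- nrow(Dm); L <- length(y)
  em <- matrix(log(mu), D, L)
  em[Dm == matrix(y, D, L, byrow = TRUE)] <- log1p(-mu)
  v <- -log(D) + em[, 1L]
  ptr <- matrix(0L, D, L)
  if (L > 1L) {
    delta <- diff(cm) / 100
    p_sw <- -expm1(-rho * delta)
    log_stay <- log((1 - p_sw) + p_sw / D)
    log_move <- log(p_sw / D)
    for (t in 2:L) {
      jstar <- which.max(v)
      m <- v[jstar]
      stay <- v + log_stay[t - 1L]
      move <- m + log_move[t - 1L]
      take_stay <- stay > move | (stay == move & seq_len(D) <= jstar)
      ptr[, t] <- ifelse(take_stay, seq_len(D), jstar)
      v <- em[, t] + pmax(stay, move)
    }
  }
  path <- integer(L)
  path[L] <- which.max(v)
  if (L > 1L) for (t in L:2) path[t - 1L] <- ptr[path[t], t]
  path
}

# Collapse a donor path into chunks with midpoint-based cM lengths.
chunk_aggregate <- function(path, cm) {
  r <- rle(path)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  # boundaries: map ends for the outermost chunks, interval midpoints inside
  lo <- c(cm[1], (cm[ends[-length(ends)]] + cm[starts[-1]]) / 2)
  hi <- c(lo[-1], cm[length(cm)])
  tibble(donor = r$values, len_cm = hi - lo)
}

#' @export
print.coancestry <- function(x, ...) {
  cat(sprintf("<coancestry> %d individuals, %.1f cM map\n",
              nrow(x$chunk_counts), x$map_cm))
  cat(sprintf("total chunks: %d\n", as.integer(sum(x$chunk_counts))))
  invisible(x)
}

#' Copying vectors from a coancestry matrix
#'
#' Sums each recipient's donor columns within donor clusters and renormalizes
#' to a simplex vector.  By default the recipient's own cluster column is
#' dropped before renormalization (standard practice: prevents the trivial
#' self-copy signal from dominating); set `drop_self = FALSE` to retain it.
#'
#' @param M A `coancestry` object from [paint_all_vs_all()], or a plain
#'   recipients x donors matrix.
#' @param assignment Optional cluster assignment (tibble `id`, `cluster`, or
#'   named vector id -> cluster).  Default: every donor individual is its own
#'   cluster.
#' @param basis `"counts"` (default) or `"lengths"`.
#' @param drop_self Drop the recipient's own cluster column (default TRUE).
#' @return Matrix of copying vectors, recipients x donor clusters, rows
#'   summing to 1.
#' @export
copying_vectors <- function(M, assignment = NULL, basis = c("counts", "lengths"),
                            drop_self = TRUE) {
  basis <- match.arg(basis)
  raw <- if (inherits(M, "coancestry")) {
    if (basis == "counts") M$chunk_counts else M$chunk_lengths_cm
  } else {
    as.matrix(M)
  }
  ids <- rownames(raw) %||% paste0("ind", seq_len(nrow(raw)))
  cl <- if (is.null(assignment)) {
    setNames(colnames(raw) %||% ids, colnames(raw) %||% ids)
  } else {
    assignment_vector(assignment)
  }
  donors <- colnames(raw) %||% ids
  if (!all(donors %in% names(cl))) abort("assignment must cover every donor.")
  cl_f <- factor(cl[donors], levels = unique(cl[donors]))
  grouped <- t(rowsum(t(raw), cl_f))
  colnames(grouped) <- levels(cl_f)
  if (drop_self) {
    for (i in seq_len(nrow(grouped))) {
      own <- as.character(cl[ids[i]])
      if (!is.na(own) && own %in% colnames(grouped)) grouped[i, own] <- 0
    }
  }
  rs <- rowSums(grouped)
  if (any(rs == 0)) {
    abort(paste0("all-zero copying vector for: ",
                 paste(ids[rs == 0], collapse = ", ")))
  }
  grouped / rs
}

assignment_vector <- function(assignment) {
  if (is.data.frame(assignment)) {
    setNames(as.character(assignment$cluster), assignment$id)
  } else {
    setNames(as.character(assignment), names(assignment))
  }
}
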