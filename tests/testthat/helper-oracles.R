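# Independent brute-force oracles and fixture builders.  These deliberately
# re-derive every quantity from first principles, without reusing package
# internals, so agreement is evidence of correctness rather than tautology.

# --- fixtures ---------------------------------------------------------------

# a small geno_matrix from an explicit call matrix
toy_geno <- function(calls, pops = NULL, morgans = 1, n_chrom = 1) {
  calls <- as.matrix(calls)
  snps <- uniform_map(ncol(calls), morgans = morgans, n_chrom = n_chrom)
  samples <- tibble::tibble(
    id = sprintf("i%02d", seq_len(nrow(calls))),
    pop = pops %||% rep("pop", nrow(calls))
  )
  geno_matrix(calls, snps, samples)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# two-source admixed scenario reused by several suites
sim_two_source <- function(n_snps = 2000, morgans = 1, f = 0.05, n_src = 30,
                           n_adm = 30, props = c(A = 0.5, B = 0.5), g = 10,
                           seed = 1) {
  set.seed(seed)
  p <- runif(n_snps, 0.1, 0.9)
  fr <- sim_source_freqs(p, c(A = f, B = f), seed = seed + 1)
  map <- uniform_map(n_snps, morgans = morgans)
  sp <- sim_panel(fr, n_src, map = map, seed = seed + 2)
  adm <- sim_admixed(sp$panel, props, g = g, n = n_adm, seed = seed + 3)
  list(freqs = fr, sources = sp, adm = adm,
       all = hap_to_geno(combine_panels(list(sp$panel, adm$panel))))
}

# --- Weir-Cockerham oracle --------------------------------------------------

# direct transcription of the 1984 two-population component formulas,
# one SNP at a time, scalar arithmetic only
wc_fst_oracle <- function(ga, gb) {
  L <- ncol(ga)
  a_sum <- 0; abc_sum <- 0; used <- 0
  for (j in seq_len(L)) {
    x <- ga[, j][!is.na(ga[, j])]
    y <- gb[, j][!is.na(gb[, j])]
    n1 <- length(x); n2 <- length(y)
    if (n1 < 2 || n2 < 2) next
    p1 <- sum(x) / (2 * n1); p2 <- sum(y) / (2 * n2)
    h1 <- mean(x == 1); h2 <- mean(y == 1)
    r <- 2
    nbar <- (n1 + n2) / 2
    nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    if (pbar == 0 || pbar == 1) next
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
    cc <- hbar / 2
    if (a + b + cc == 0) next
    a_sum <- a_sum + a
    abc_sum <- abc_sum + a + b + cc
    used <- used + 1
  }
  list(fst = a_sum / abc_sum, n_used = used)
}

# --- RoH brute-force re-scan ------------------------------------------------

roh_oracle_one <- function(g, bp, window = 100, max_het = 1, max_missing = 5,
                           min_kb = 1000, hit_fraction = 0.05, min_seg_snps = 100) {
  L <- length(g)
  if (L < window) return(data.frame())
  n_win <- L - window + 1
  hit <- logical(n_win)
  for (s in seq_len(n_win)) {
    w <- g[s:(s + window - 1)]
    hit[s] <- sum(w == 1, na.rm = TRUE) <= max_het && sum(is.na(w)) <= max_missing
  }
  hom <- logical(L)
  for (t in seq_len(L)) {
    covering <- max(1, t - window + 1):min(n_win, t)
    hom[t] <- mean(hit[covering]) >= hit_fraction
  }
  segs <- list()
  t <- 1
  while (t <= L) {
    if (hom[t]) {
      e <- t
      while (e < L && hom[e + 1]) e <- e + 1
      n_snps <- e - t + 1
      kb <- (bp[e] - bp[t] + 1) / 1000
      if (n_snps >= min_seg_snps && kb >= min_kb) {
        segs[[length(segs) + 1]] <- data.frame(start = t, end = e,
                                               n_snps = n_snps, kb = kb)
      }
      t <- e + 1
    } else t <- t + 1
  }
  do.call(rbind, segs) %||% data.frame()
}

# --- Li-Stephens exhaustive path enumeration --------------------------------

# enumerate all D^L donor paths; return max log-probability
viterbi_oracle_logp <- function(y, Dm, cm, rho, mu) {
  D <- nrow(Dm); L <- length(y)
  delta <- diff(cm) / 100
  p_sw <- 1 - exp(-rho * delta)
  log_stay <- log((1 - p_sw) + p_sw / D)
  log_move <- log(p_sw / D)
  paths <- as.matrix(expand.grid(rep(list(seq_len(D)), L)))
  best <- -Inf
  for (r in seq_len(nrow(paths))) {
    pth <- paths[r, ]
    lp <- -log(D)
    for (t in seq_len(L)) {
      lp <- lp + if (Dm[pth[t], t] == y[t]) log(1 - mu) else log(mu)
      if (t > 1) {
        lp <- lp + if (pth[t] == pth[t - 1]) log_stay[t - 1] else log_move[t - 1]
      }
    }
    best <- max(best, lp)
  }
  best
}

# log-probability of a specific path (to score the Viterbi output)
path_logp <- function(pth, y, Dm, cm, rho, mu) {
  D <- nrow(Dm)
  delta <- diff(cm) / 100
  p_sw <- 1 - exp(-rho * delta)
  lp <- -log(D)
  for (t in seq_along(y)) {
    lp <- lp + if (Dm[pth[t], t] == y[t]) log(1 - mu) else log(mu)
    if (t > 1) {
      lp <- lp + if (pth[t] == pth[t - 1]) log((1 - p_sw[t - 1]) + p_sw[t - 1] / D)
        else log(p_sw[t - 1] / D)
    }
  }
  lp
}

# --- weighted-LD double loop -------------------------------------------------

wld_oracle <- function(calls, w, cm, bin_width, d_max) {
  n <- nrow(calls)
  xc <- sweep(calls, 2, colMeans(calls, na.rm = TRUE))
  xc[is.na(xc)] <- 0
  n_bins <- ceiling(d_max / bin_width)
  sums <- numeric(n_bins); cnts <- numeric(n_bins)
  L <- ncol(calls)
  for (i in seq_len(L - 1)) {
    for (j in (i + 1):L) {
      d <- cm[j] - cm[i]
      if (d <= 0 || d > d_max) next
      z <- sum(xc[, i] * xc[, j]) / (n - 1)
      b <- min(n_bins, ceiling(d / bin_width))
      sums[b] <- sums[b] + z * w[i] * w[j]
      cnts[b] <- cnts[b] + 1
    }
  }
  list(a = ifelse(cnts > 0, sums / cnts, NA), n_pairs = cnts)
}

# --- refinement rule oracles -------------------------------------------------

# exhaustive size-rule application on an explicit tree given as nested lists
# of cluster labels, e.g. list(list("c1","c2"),"c3")
size_rule_oracle <- function(tree, sizes, max_branch = 5, min_ind = 5) {
  leaves_of <- function(nd) if (is.character(nd)) nd else unlist(lapply(nd, leaves_of))
  qualifies <- function(nd) {
    lv <- leaves_of(nd)
    length(lv) < max_branch && any(sizes[lv] < min_ind)
  }
  # returns list of groups (maximal qualifying nodes) or leaves untouched
  collect <- function(nd) {
    if (!is.character(nd) && qualifies(nd)) return(list(leaves_of(nd)))
    if (is.character(nd)) return(list())
    unlist(lapply(nd, collect), recursive = FALSE)
  }
  collect(tree)
}

# naive greedy TVD pooling: explicit loops over cluster pairs, recomputing
# cluster means from the individual vectors after every merge
tvd_pool_oracle <- function(vectors, assignment, threshold, max_pool = 3,
                            direction = "below") {
  cl <- setNames(assignment$cluster, assignment$id)
  pool_n <- setNames(rep(1, length(unique(cl))), unique(cl))
  tvd1 <- function(u, v) sum(abs(u - v)) / 2
  repeat {
    labs <- unique(cl)
    if (length(labs) < 2) break
    means <- sapply(labs, function(l) {
      colMeans(vectors[names(cl)[cl == l], , drop = FALSE])
    })
    best <- NULL
    best_v <- if (direction == "below") Inf else -Inf
    for (i in seq_along(labs)) for (j in seq_along(labs)) {
      if (j <= i) next
      if (pool_n[labs[i]] + pool_n[labs[j]] > max_pool) next
      v <- tvd1(means[, i], means[, j])
      ok <- if (direction == "below") v < threshold else v > threshold
      bet <- if (direction == "below") v < best_v else v > best_v
      if (ok && bet) { best <- c(labs[i], labs[j]); best_v <- v }
    }
    if (is.null(best)) break
    cl[cl == best[2]] <- best[1]
    pool_n[best[1]] <- pool_n[best[1]] + pool_n[best[2]]
    pool_n <- pool_n[names(pool_n) != best[2]]
  }
  cl
}

# partition comparison helpers
partition_of <- function(assignment) {
  split(assignment$id, assignment$cluster)
}
same_partition <- function(a, b) {
  canon <- function(p) unname(lapply(p, sort))[order(sapply(lapply(p, sort), paste, collapse = ","))]
  identical(canon(partition_of(a)), canon(partition_of(b)))
}
adjusted_rand <- function(x, y) {
  tab <- table(x, y)
  ch2 <- function(n) n * (n - 1) / 2
  sum_ij <- sum(ch2(tab))
  a <- sum(ch2(rowSums(tab)))
  b <- sum(ch2(colSums(tab)))
  n <- ch2(sum(tab))
  exp_idx <- a * b / n
  (sum_ij - exp_idx) / ((a + b) / 2 - exp_idx)
}
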