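#' Per-population allele frequencies
#'
#' Sample frequency of allele 1 and the count of non-missing chromosomes per
#' population and SNP, the inputs of all f-statistics.
#'
#' @param G A [geno_matrix()].
#' @param grouping As in [pairwise_fst()]: a sample-metadata column name or a
#'   label vector.
#' @return A list of class `freq_table`: `freq` and `n_chrom` matrices
#'   (populations x SNPs) plus the SNP tibble.
#' @export
allele_freqs <- function(G, grouping = "pop") {
  labs <- grouping_labels(G, grouping)
  groups <- unique(labs)
  L <- ncol(G$calls)
  freq <- matrix(NA_real_, length(groups), L, dimnames = list(groups, G$snps$id))
  n_chrom <- matrix(0L, length(groups), L, dimnames = list(groups, G$snps$id))
  for (g in groups) {
    x <- G$calls[labs == g, , drop = FALSE]
    n_chrom[g, ] <- 2L * colSums(!is.na(x))
    freq[g, ] <- colSums(x, na.rm = TRUE) / n_chrom[g, ]
  }
  structure(list(freq = freq, n_chrom = n_chrom, snps = G$snps),
            class = "freq_table")
}

#' Assemble a frequency table directly from frequency/count matrices
#'
#' Mainly for tests and for population-frequency mode (known frequencies,
#' effectively infinite sample size: pass `n_chrom = Inf`).
#'
#' @param freq Populations x SNPs frequency matrix (named rows).
#' @param n_chrom Matching matrix of chromosome counts, or a scalar
#'   (recycled); `Inf` disables finite-sample corrections.
#' @param snps Optional SNP tibble (defaults to a uniform map).
#' @return A `freq_table`.
#' @export
freq_table <- function(freq, n_chrom = Inf, snps = NULL) {
  freq <- as.matrix(freq)
  if (is.null(rownames(freq))) rownames(freq) <- paste0("pop", seq_len(nrow(freq)))
  if (length(n_chrom) == 1L) {
    n_chrom <- matrix(n_chrom, nrow(freq), ncol(freq), dimnames = dimnames(freq))
  }
  if (is.null(snps)) snps <- uniform_map(ncol(freq), morgans = 1)
  structure(list(freq = freq, n_chrom = n_chrom, snps = snps),
            class = "freq_table")
}

#' Contiguous jackknife blocks
#'
#' Assigns SNPs to contiguous blocks of `block_cm` centimorgans within each
#' chromosome (the ADMIXTOOLS convention, default 5 cM), or to fixed-size
#' blocks of `block_snps` SNPs when no genetic map is available.
#'
#' @param snps SNP tibble (with `chrom`, `cm`).
#' @param block_cm Block length in cM.
#' @param block_snps Alternative: block size in SNPs (overrides `block_cm`).
#' @return Integer block id per SNP.
#' @export
make_blocks <- function(snps, block_cm = 5, block_snps = NULL) {
  out <- integer(nrow(snps))
  nxt <- 1L
  for (ch in unique(snps$chrom)) {
    idx <- which(snps$chrom == ch)
    if (!is.null(block_snps)) {
      b <- (seq_along(idx) - 1L) %/% block_snps
    } else {
      cm <- snps$cm[idx]
      b <- floor((cm - cm[1]) / block_cm)
    }
    out[idx] <- nxt + as.integer(b)
    nxt <- max(out[idx]) + 1L
  }
  match(out, unique(out))
}

#' Weighted block jackknife
#'
#' Delete-one-block jackknife for a ratio-of-sums statistic
#' `theta = sum(values) / sum(weights)`, with block weights proportional to
#' the weight they carry (SNP counts for unit weights).  The variance uses
#' the weighted-jackknife form of Busing, Meijer & van der Leeden (1999),
#' which reduces to the textbook delete-1 formula for equal blocks.
#'
#' @param values Per-SNP numerator terms.
#' @param weights Per-SNP weights (default 1 per SNP).
#' @param blocks Integer block assignment per SNP; blocks must be contiguous
#'   SNP ranges (see [make_blocks()]).
#' @return A list: `estimate`, `se`, `n_blocks`.
#' @export
block_jackknife <- function(values, weights = NULL, blocks) {
  if (is.null(weights)) weights <- rep(1, length(values))
  stopifnot(length(values) == length(weights), length(values) == length(blocks))
  ok <- !is.na(values) & !is.na(weights)
  values <- values[ok]; weights <- weights[ok]; blocks <- blocks[ok]
  ub <- unique(blocks)
  g <- length(ub)
  if (g < 2L) abort("need at least 2 jackknife blocks (one block holds all SNPs).")
  sv <- vapply(split(values, blocks), sum, numeric(1))[as.character(ub)]
  sw <- vapply(split(weights, blocks), sum, numeric(1))[as.character(ub)]
  tot_v <- sum(sv); tot_w <- sum(sw)
  theta <- tot_v / tot_w
  theta_del <- (tot_v - sv) / (tot_w - sw)
  hj <- tot_w / sw
  theta_j <- g * theta - sum((1 - sw / tot_w) * theta_del)
  tau <- hj * theta - (hj - 1) * theta_del
  var_j <- mean((tau - theta_j)^2 / (hj - 1))
  list(estimate = theta, se = sqrt(var_j), n_blocks = g)
}

fstat_result <- function(stat, pops, bj, n_snps, extra = NULL) {
  out <- tibble(
    statistic = stat,
    pops = paste(pops, collapse = ";"),
    estimate = bj$estimate,
    se = bj$se,
    z = if (is.finite(bj$se) && bj$se > 0) bj$estimate / bj$se else NA_real_,
    n_blocks = bj$n_blocks,
    n_snps = n_snps
  )
  if (!is.null(extra)) out <- bind_cols(out, as_tibble(extra))
  class(out) <- c("fstat", class(out))
  out
}

# SNPs usable for a set of populations: finite data everywhere required.
usable_snps <- function(ft, pops, min_target_chrom = NULL, target = NULL) {
  ok <- rep(TRUE, ncol(ft$freq))
  for (p in pops) {
    if (!p %in% rownames(ft$freq)) abort(sprintf("unknown population '%s'.", p))
    ok <- ok & is.finite(ft$freq[p, ]) & ft$n_chrom[p, ] > 0
  }
  if (!is.null(min_target_chrom)) {
    ok <- ok & ft$n_chrom[target, ] >= min_target_chrom
  }
  ok
}

#' Admixture f3 statistic
#'
#' `f3(A, B; C) = E[(c - a)(c - b)]` with the unbiased finite-sample
#' correction `- c(1-c) / (n_C - 1)` subtracted per SNP (the target's sampling
#' heterozygosity; disable with `correct = FALSE` when frequencies are
#' population values rather than sample estimates).  A significantly negative
#' value (conventionally Z < -3) indicates that the target C is admixed
#' between sources related to A and B.  With `normalize = TRUE` the statistic
#' is divided by the target heterozygosity `sum 2 c (1 - c) n_C / (n_C - 1)`,
#' as some implementations do; the raw estimator is the default.
#'
#' Standard errors are weighted block-jackknife over contiguous blocks.
#'
#' @param ft A `freq_table` from [allele_freqs()] or [freq_table()].
#' @param a,b Source population labels.
#' @param target Target population label.
#' @param blocks Per-SNP block ids (default: [make_blocks()] at `block_cm`).
#' @param block_cm Block length in cM when `blocks` is NULL.
#' @param correct Apply the finite-sample bias correction (default TRUE;
#'   forced off when target chromosome counts are infinite).
#' @param normalize Heterozygosity normalization flag (default FALSE).
#' @return A one-row `fstat` tibble: estimate, se, z, n_blocks, n_snps.
#' @export
f3 <- function(ft, a, b, target, blocks = NULL, block_cm = 5,
               correct = TRUE, normalize = FALSE) {
  ok <- usable_snps(ft, c(a, b, target))
  nC <- ft$n_chrom[target, ]
  finite_n <- is.finite(nC)
  if (correct) ok <- ok & (!finite_n | nC >= 2)
  if (!any(ok)) abort("no usable SNPs (target needs >= 2 chromosomes everywhere).")
  fa <- ft$freq[a, ok]; fb <- ft$freq[b, ok]; fc <- ft$freq[target, ok]
  n <- nC[ok]
  num <- (fc - fa) * (fc - fb)
  if (correct) {
    corr <- ifelse(is.finite(n), fc * (1 - fc) / (n - 1), 0)
    num <- num - corr
  }
  if (is.null(blocks)) blocks <- make_blocks(ft$snps, block_cm = block_cm)
  blocks <- blocks[ok]
  if (normalize) {
    den <- ifelse(is.finite(n), 2 * fc * (1 - fc) * n / (n - 1), 2 * fc * (1 - fc))
    bj <- block_jackknife_ratio(num, den, blocks)
  } else {
    bj <- block_jackknife(num, NULL, blocks)
  }
  fstat_result("f3", c(a, b, target), bj, sum(ok))
}

# jackknife of sum(num)/sum(den) over blocks
block_jackknife_ratio <- function(num, den, blocks) {
  ub <- unique(blocks)
  g <- length(ub)
  if (g < 2L) abort("need at least 2 jackknife blocks.")
  sn <- vapply(split(num, blocks), sum, numeric(1))[as.character(ub)]
  sd_ <- vapply(split(den, blocks), sum, numeric(1))[as.character(ub)]
  sw <- vapply(split(rep(1, length(num)), blocks), sum, numeric(1))[as.character(ub)]
  tn <- sum(sn); td <- sum(sd_); tw <- sum(sw)
  theta <- tn / td
  theta_del <- (tn - sn) / (td - sd_)
  hj <- tw / sw
  theta_j <- g * theta - sum((1 - sw / tw) * theta_del)
  tau <- hj * theta - (hj - 1) * theta_del
  var_j <- mean((tau - theta_j)^2 / (hj - 1))
  list(estimate = theta, se = sqrt(var_j), n_blocks = g)
}

#' Outgroup f3 statistic
#'
#' [f3()] with the outgroup in the target role and no admixture
#' interpretation: larger values mean more drift shared by `pop1` and `pop2`
#' since their divergence from the outgroup.  Symmetric in `pop1`/`pop2`.
#'
#' @param ft A `freq_table`.
#' @param outgroup Outgroup population label.
#' @param pop1,pop2 Populations whose shared drift is measured.
#' @inheritParams f3
#' @return A one-row `fstat` tibble.
#' @export
f3_outgroup <- function(ft, outgroup, pop1, pop2, blocks = NULL, block_cm = 5,
                        correct = TRUE) {
  out <- f3(ft, pop1, pop2, outgroup, blocks = blocks, block_cm = block_cm,
            correct = correct)
  out$statistic <- "f3_outgroup"
  out
}

#' f4 statistic
#'
#' `f4(A, B; C, D) = E[(a - b)(c - d)]`; no bias correction is needed.
#' Nonzero values indicate gene flow violating the unrooted tree
#' `((A,B),(C,D))`.
#'
#' @inheritParams f3
#' @param a,b,c,d Population labels.
#' @return A one-row `fstat` tibble.
#' @export
f4 <- function(ft, a, b, c, d, blocks = NULL, block_cm = 5) {
  ok <- usable_snps(ft, c(a, b, c, d))
  if (!any(ok)) abort("no SNPs with data in all four populations.")
  v <- (ft$freq[a, ok] - ft$freq[b, ok]) * (ft$freq[c, ok] - ft$freq[d, ok])
  if (is.null(blocks)) blocks <- make_blocks(ft$snps, block_cm = block_cm)
  bj <- block_jackknife(v, NULL, blocks[ok])
  fstat_result("f4", c(a, b, c, d), bj, sum(ok))
}

#' f4-ratio admixture-proportion estimate
#'
#' `alpha = f4(A, O; X, C) / f4(A, O; B, C)`, the classical ratio estimate of
#' the proportion of ancestry that X derives from the B-related source (with
#' C the other source and O an outgroup).  The ratio is jackknifed per block;
#' a denominator Z below 3 in magnitude flags the estimate as unstable rather
#' than silently dividing.
#'
#' @inheritParams f3
#' @param a,o,x,b,c Population labels in the roles above.
#' @return A one-row `fstat` tibble with extra columns `denominator_z` and
#'   `unstable`.
#' @export
f4_ratio <- function(ft, a, o, x, b, c, blocks = NULL, block_cm = 5) {
  ok <- usable_snps(ft, c(a, o, x, b, c))
  if (!any(ok)) abort("no SNPs with data in all five populations.")
  w <- ft$freq[a, ok] - ft$freq[o, ok]
  num <- w * (ft$freq[x, ok] - ft$freq[c, ok])
  den <- w * (ft$freq[b, ok] - ft$freq[c, ok])
  if (is.null(blocks)) blocks <- make_blocks(ft$snps, block_cm = block_cm)
  blocks <- blocks[ok]
  bj_den <- block_jackknife(den, NULL, blocks)
  den_z <- if (is.finite(bj_den$se) && bj_den$se > 0) {
    bj_den$estimate / bj_den$se
  } else if (bj_den$estimate == 0) 0 else Inf
  bj <- block_jackknife_ratio(num, den, blocks)
  if (!is.finite(bj$estimate)) bj$estimate <- NA_real_
  if (!is.finite(bj$se)) bj$se <- NA_real_
  out <- fstat_result("f4_ratio", c(a, o, x, b, c), bj, sum(ok),
                      extra = list(denominator_z = den_z,
                                   unstable = abs(den_z) < 3))
  if (out$unstable) {
    warn(sprintf("f4-ratio denominator Z = %.2f (< 3): estimate flagged unstable.", den_z))
  }
  out
}

#' @export
tidy.fstat <- function(x, ...) as_tibble(unclass(x))

#' @export
glance.fstat <- function(x, ...) {
  tibble(estimate = x$estimate, se = x$se, z = x$z,
         significant = abs(x$z) > 3, n_snps = x$n_snps)
}
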