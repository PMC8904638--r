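#' Genotype and haplotype containers
#'
#' `geno_matrix()` wraps an individuals-by-SNPs matrix of diploid allele-1
#' dosages (0, 1, 2, or `NA` for missing) together with per-SNP and per-sample
#' metadata tibbles.  `hap_panel()` wraps a phased haplotype matrix
#' (two rows per individual, entries 0/1 indicating carriage of allele 1).
#' These are the substrates of every downstream analysis: QC, FST, RoH, PCA,
#' f-statistics, haplotype painting and weighted-LD dating.
#'
#' Invariants enforced at construction: SNP metadata sorted by (chrom, bp)
#' with strictly increasing bp within a chromosome; matrix dimensions match
#' the metadata; missing genotypes are `NA` (a single sentinel).
#'
#' @param calls Integer matrix, individuals x SNPs, values in {0,1,2,NA}.
#' @param snps Tibble with columns `id`, `chrom`, `bp` (1-based), `cm`
#'   (genetic position), `a1`, `a2` (counted and alternative allele).
#' @param samples Tibble with columns `id`, `pop` and optionally `subgroup`.
#' @param haps Integer matrix of 0/1 with two consecutive rows per individual.
#'
#' @return An object of class `geno_matrix` or `hap_panel`.
#' @export
geno_matrix <- function(calls, snps, samples) {
  calls <- as.matrix(calls)
  snps <- as_tibble(snps)
  samples <- as_tibble(samples)
  if (!"subgroup" %in% names(samples)) samples$subgroup <- samples$pop
  req <- c("id", "chrom", "bp", "cm", "a1", "a2")
  if (!all(req %in% names(snps))) {
    abort(paste0("`snps` must have columns: ", paste(req, collapse = ", ")))
  }
  if (nrow(calls) != nrow(samples)) {
    abort(sprintf("calls has %d rows but samples has %d.", nrow(calls), nrow(samples)))
  }
  if (ncol(calls) != nrow(snps)) {
    abort(sprintf("calls has %d columns but snps has %d rows.", ncol(calls), nrow(snps)))
  }
  check_snp_order(snps)
  bad <- !(calls %in% c(0L, 1L, 2L) | is.na(calls))
  if (any(bad)) abort("genotype calls must be 0, 1, 2 or NA.")
  dimnames(calls) <- list(samples$id, snps$id)
  structure(list(calls = calls, snps = snps, samples = samples),
            class = "geno_matrix")
}

#' @rdname geno_matrix
#' @export
hap_panel <- function(haps, snps, samples) {
  haps <- as.matrix(haps)
  snps <- as_tibble(snps)
  samples <- as_tibble(samples)
  req <- c("id", "chrom", "bp", "cm", "a1", "a2")
  if (!all(req %in% names(snps))) {
    abort(paste0("`snps` must have columns: ", paste(req, collapse = ", ")))
  }
  if (nrow(haps) != 2L * nrow(samples)) {
    abort("`haps` must have two rows per individual.")
  }
  if (ncol(haps) != nrow(snps)) abort("haps/snps dimension mismatch.")
  if (!all(haps %in% c(0L, 1L))) abort("haplotype alleles must be 0 or 1.")
  check_snp_order(snps)
  dimnames(haps) <- list(paste0(rep(samples$id, each = 2), c("_a", "_b")), snps$id)
  structure(list(haps = haps, snps = snps, samples = samples),
            class = "hap_panel")
}

check_snp_order <- function(snps) {
  by_chrom <- split(snps$bp, factor(snps$chrom, levels = unique(snps$chrom)))
  ok <- all(vapply(by_chrom, function(x) all(diff(x) > 0), logical(1)))
  if (!ok) abort("SNPs must be strictly increasing in bp within each chromosome.")
  invisible(snps)
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d individuals x %d SNPs (%.2f%% missing)\n",
              nrow(x$calls), ncol(x$calls), 100 * mean(is.na(x$calls))))
  cat("populations:", paste(unique(x$samples$pop), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.hap_panel <- function(x, ...) {
  cat(sprintf("<hap_panel> %d individuals (%d haplotypes) x %d SNPs\n",
              nrow(x$samples), nrow(x$haps), ncol(x$haps)))
  cat("populations:", paste(unique(x$samples$pop), collapse = ", "), "\n")
  invisible(x)
}

#' Collapse a phased panel to unphased genotypes
#'
#' Sums the two haplotypes of each individual into an allele-1 dosage.
#'
#' @param panel A [hap_panel()].
#' @return A [geno_matrix()].
#' @export
hap_to_geno <- function(panel) {
  stopifnot(inherits(panel, "hap_panel"))
  n <- nrow(panel$samples)
  a <- panel$haps[seq(1, 2 * n, by = 2), , drop = FALSE]
  b <- panel$haps[seq(2, 2 * n, by = 2), , drop = FALSE]
  geno_matrix(a + b, panel$snps, panel$samples)
}

#' Uniform genetic map
#'
#' Builds a SNP table with evenly spaced markers on a single chromosome (or
#' several equal chromosomes), using the conventional 1 cM/Mb scaling so that
#' `bp = cm * 1e6`.
#'
#' @param n_snps Total number of SNPs.
#' @param morgans Total map length in Morgans.
#' @param n_chrom Number of equally sized chromosomes.
#' @return A SNP tibble suitable for [geno_matrix()] / [hap_panel()].
#' @export
uniform_map <- function(n_snps, morgans = 1, n_chrom = 1) {
  stopifnot(n_snps >= n_chrom, morgans > 0, n_chrom >= 1)
  per <- diff(round(seq(0, n_snps, length.out = n_chrom + 1)))
  cm_per_chrom <- 100 * morgans / n_chrom
  out <- purrr::map2_dfr(seq_len(n_chrom), per, function(ch, k) {
    cm <- seq(0, cm_per_chrom, length.out = k + 1)[-1]
    tibble(
      id = sprintf("snp%d_%d", ch, seq_len(k)),
      chrom = as.character(ch),
      bp = as.integer(round(cm * 1e6)),
      cm = cm,
      a1 = "A", a2 = "G"
    )
  })
  out
}

#' Subset a genotype matrix
#'
#' @param G A [geno_matrix()].
#' @param samples,snps Logical/integer/character selectors for individuals and
#'   SNPs (default: keep all).
#' @return A [geno_matrix()].
#' @export
subset_geno <- function(G, samples = NULL, snps = NULL) {
  stopifnot(inherits(G, "geno_matrix"))
  si <- if (is.null(samples)) seq_len(nrow(G$calls)) else samples
  vi <- if (is.null(snps)) seq_len(ncol(G$calls)) else snps
  if (is.character(si)) si <- match(si, G$samples$id)
  if (is.character(vi)) vi <- match(vi, G$snps$id)
  geno_matrix(G$calls[si, vi, drop = FALSE], G$snps[vi, ], G$samples[si, ])
}

# population label lookup: named vector id -> pop
pop_of <- function(G) setNames(G$samples$pop, G$samples$id)
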