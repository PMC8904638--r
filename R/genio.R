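#' Read genotypes from PLINK text, EIGENSTRAT or VCF
#'
#' Supported formats:
#' * `"plink-text"`: `<path>.ped` / `<path>.map`.  Alleles are re-coded with
#'   `a1` the lexicographically smaller observed allele, so round-trips are
#'   exact for matrices written in that canonical orientation.
#' * `"eigenstrat"`: `<path>.geno` / `<path>.snp` / `<path>.ind`; genotype
#'   digits count copies of the `.snp` reference allele (a1); `9` is missing.
#' * `"vcf"`: a plain-text VCF; only the GT field is used, `a1` is the ALT
#'   allele (calls are ALT dosages), `.` is missing, phasing is ignored.
#'
#' @param path File prefix (without extension) for plink-text/eigenstrat, or
#'   the VCF file name.
#' @param format One of `"plink-text"`, `"eigenstrat"`, `"vcf"`.
#' @return A [geno_matrix()].
#' @export
read_genotypes <- function(path, format = c("plink-text", "eigenstrat", "vcf")) {
  format <- match.arg(format)
  switch(format,
    "plink-text" = read_plink_text(path),
    "eigenstrat" = read_eigenstrat(path),
    "vcf" = read_vcf_gt(path)
  )
}

#' Write genotypes to PLINK text, EIGENSTRAT or VCF
#'
#' @param G A [geno_matrix()].
#' @inheritParams read_genotypes
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(G, path, format = c("plink-text", "eigenstrat", "vcf")) {
  stopifnot(inherits(G, "geno_matrix"))
  format <- match.arg(format)
  switch(format,
    "plink-text" = write_plink_text(G, path),
    "eigenstrat" = write_eigenstrat(G, path),
    "vcf" = write_vcf_gt(G, path)
  )
  invisible(path)
}

read_plink_text <- function(prefix) {
  map_f <- paste0(prefix, ".map")
  ped_f <- paste0(prefix, ".ped")
  if (!file.exists(map_f) || !file.exists(ped_f)) {
    abort(sprintf("expected %s and %s to exist.", map_f, ped_f))
  }
  if (length(readLines(map_f, n = 1L)) == 0L) {
    abort(sprintf("%s contains no SNPs.", map_f))
  }
  map <- read.table(map_f, colClasses = c("character", "character", "numeric", "integer"))
  names(map) <- c("chrom", "id", "cm", "bp")
  L <- nrow(map)
  if (L == 0L) abort(sprintf("%s contains no SNPs.", map_f))
  lines <- readLines(ped_f)
  toks <- strsplit(trimws(lines), "[ \t]+")
  n_exp <- 6L + 2L * L
  calls <- matrix(NA_integer_, length(toks), L)
  a1 <- rep(NA_character_, L); a2 <- rep(NA_character_, L)
  al1 <- matrix(NA_character_, length(toks), L)
  al2 <- matrix(NA_character_, length(toks), L)
  fam <- character(length(toks)); iid <- character(length(toks))
  for (i in seq_along(toks)) {
    tk <- toks[[i]]
    if (length(tk) != n_exp) {
      abort(sprintf("%s line %d: expected %d fields, found %d.",
                    ped_f, i, n_exp, length(tk)))
    }
    fam[i] <- tk[1]; iid[i] <- tk[2]
    al1[i, ] <- tk[seq(7L, by = 2L, length.out = L)]
    al2[i, ] <- tk[seq(8L, by = 2L, length.out = L)]
  }
  for (j in seq_len(L)) {
    obs <- setdiff(unique(c(al1[, j], al2[, j])), "0")
    obs <- sort(obs)
    if (length(obs) > 2L) {
      abort(sprintf("%s: SNP %s has >2 alleles.", ped_f, map$id[j]))
    }
    a1[j] <- if (length(obs) >= 1L) obs[1] else "0"
    a2[j] <- if (length(obs) == 2L) obs[2] else "0"
    miss <- al1[, j] == "0" | al2[, j] == "0"
    calls[, j] <- (al1[, j] == a1[j]) + (al2[, j] == a1[j])
    calls[miss, j] <- NA_integer_
  }
  snps <- as_tibble(map) |> mutate(a1 = a1, a2 = a2) |>
    select("id", "chrom", "bp", "cm", "a1", "a2")
  samples <- tibble(id = iid, pop = fam)
  geno_matrix(calls, snps, samples)
}

write_plink_text <- function(G, prefix) {
  snps <- G$snps
  write.table(
    data.frame(snps$chrom, snps$id, snps$cm, snps$bp),
    paste0(prefix, ".map"),
    quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t"
  )
  n <- nrow(G$calls); L <- ncol(G$calls)
  out <- matrix("0", n, 2L * L)
  for (j in seq_len(L)) {
    g <- G$calls[, j]
    c1 <- ifelse(is.na(g), "0", ifelse(g >= 1L, G$snps$a1[j], G$snps$a2[j]))
    c2 <- ifelse(is.na(g), "0", ifelse(g == 2L, G$snps$a1[j], G$snps$a2[j]))
    out[, 2L * j - 1L] <- c1
    out[, 2L * j] <- c2
  }
  lead <- cbind(G$samples$pop, G$samples$id, "0", "0", "0", "-9")
  write.table(cbind(lead, out), paste0(prefix, ".ped"),
              quote = FALSE, row.names = FALSE, col.names = FALSE, sep = " ")
  invisible(prefix)
}

read_eigenstrat <- function(prefix) {
  geno_f <- paste0(prefix, ".geno")
  snp_f <- paste0(prefix, ".snp")
  ind_f <- paste0(prefix, ".ind")
  for (f in c(geno_f, snp_f, ind_f)) {
    if (!file.exists(f)) abort(sprintf("expected %s to exist.", f))
  }
  snp <- read.table(snp_f, colClasses = "character")
  if (ncol(snp) < 6L) abort(sprintf("%s: expected 6 columns (id chrom cm bp a1 a2).", snp_f))
  names(snp)[1:6] <- c("id", "chrom", "cm", "bp", "a1", "a2")
  ind <- read.table(ind_f, colClasses = "character")
  names(ind)[1:3] <- c("id", "sex", "pop")
  lines <- readLines(geno_f)
  if (length(lines) == 0L) abort(sprintf("%s contains no SNPs.", geno_f))
  if (length(lines) != nrow(snp)) {
    abort(sprintf("%s has %d rows but %s lists %d SNPs.",
                  geno_f, length(lines), snp_f, nrow(snp)))
  }
  n <- nrow(ind)
  calls <- matrix(NA_integer_, n, length(lines))
  for (j in seq_along(lines)) {
    if (nchar(lines[j]) != n) {
      abort(sprintf("%s line %d: %d genotypes for %d individuals.",
                    geno_f, j, nchar(lines[j]), n))
    }
    v <- as.integer(strsplit(lines[j], "")[[1]])
    v[v == 9L] <- NA_integer_
    calls[, j] <- v
  }
  snps <- tibble(
    id = snp$id, chrom = snp$chrom, bp = as.integer(snp$bp),
    cm = as.numeric(snp$cm) * 100, a1 = snp$a1, a2 = snp$a2
  )
  # EIGENSTRAT .snp genetic positions are in Morgans; stored internally as cM.
  geno_matrix(calls, snps, tibble(id = ind$id, pop = ind$pop))
}

write_eigenstrat <- function(G, prefix) {
  g <- G$calls
  g[is.na(g)] <- 9L
  writeLines(apply(g, 2, paste0, collapse = ""), paste0(prefix, ".geno"))
  write.table(
    data.frame(G$snps$id, G$snps$chrom,
               formatC(G$snps$cm / 100, format = "g", digits = 17),
               G$snps$bp, G$snps$a1, G$snps$a2),
    paste0(prefix, ".snp"),
    quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t"
  )
  write.table(
    data.frame(G$samples$id, "U", G$samples$pop),
    paste0(prefix, ".ind"),
    quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t"
  )
  invisible(prefix)
}

read_vcf_gt <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1)
  # ALT dosage: count of '1' alleles in the GT string, '.' -> missing.
  dose <- function(x) {
    a <- strsplit(gsub("\\|", "/", x), "/")
    vapply(a, function(z) {
      if (any(z == "." | is.na(z))) NA_integer_ else sum(z == "1")
    }, integer(1))
  }
  calls <- t(apply(gt, 1, dose))
  if (nrow(gt) == 1L) calls <- matrix(calls, nrow = 1L)
  snps <- tibble(
    id = fix[, "ID"], chrom = fix[, "CHROM"], bp = as.integer(fix[, "POS"]),
    cm = as.integer(fix[, "POS"]) / 1e6, a1 = fix[, "ALT"], a2 = fix[, "REF"]
  )
  samples <- tibble(id = colnames(gt), pop = "unknown")
  geno_matrix(t(calls), snps, samples)
}

write_vcf_gt <- function(G, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=mosaicpop",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", G$samples$id), collapse = "\t")
  ), con)
  gt_str <- matrix("./.", nrow(G$calls), ncol(G$calls))
  gt_str[!is.na(G$calls) & G$calls == 0L] <- "0/0"
  gt_str[!is.na(G$calls) & G$calls == 1L] <- "0/1"
  gt_str[!is.na(G$calls) & G$calls == 2L] <- "1/1"
  body <- cbind(G$snps$chrom, G$snps$bp, G$snps$id, G$snps$a2, G$snps$a1,
                ".", "PASS", ".", "GT", t(gt_str))
  write.table(body, con, quote = FALSE, row.names = FALSE, col.names = FALSE,
              sep = "\t")
  invisible(path)
}

#' Sequential quality-control filtering
#'
#' Filters are applied in a fixed, documented order: (1) SNP missingness,
#' (2) individual missingness, (3) minor-allele frequency, (4) optional
#' Hardy-Weinberg equilibrium (1-df chi-square test).  Each removed SNP or
#' individual is listed in the report with the reason and the offending value.
#'
#' @param G A [geno_matrix()].
#' @param max_snp_missing,max_ind_missing Maximum tolerated missing-call
#'   fraction per SNP / individual.
#' @param min_maf Minimum minor-allele frequency.
#' @param hwe_p_floor HWE p-value floor, or `NULL` (default) to skip the test.
#' @return A list: `genotypes` (filtered [geno_matrix()]) and `report`
#'   (tibble with columns `item`, `type`, `step`, `value`, `threshold`).
#' @export
qc_filter <- function(G, max_snp_missing = 0.05, max_ind_missing = 0.05,
                      min_maf = 0.01, hwe_p_floor = NULL) {
  stopifnot(inherits(G, "geno_matrix"))
  check_fraction(c(max_snp_missing, max_ind_missing, min_maf), "thresholds")
  if (!is.null(hwe_p_floor)) check_fraction(hwe_p_floor, "hwe_p_floor")
  rep_rows <- list()
  add <- function(item, type, step, value, threshold) {
    rep_rows[[length(rep_rows) + 1L]] <<- tibble(
      item = unname(item), type = type, step = step,
      value = unname(value), threshold = threshold
    )
  }

  snp_miss <- colMeans(is.na(G$calls))
  drop <- snp_miss > max_snp_missing
  if (any(drop)) add(G$snps$id[drop], "snp", "snp_missingness",
                     snp_miss[drop], max_snp_missing)
  G <- subset_geno(G, snps = which(!drop))

  ind_miss <- rowMeans(is.na(G$calls))
  drop <- ind_miss > max_ind_missing
  if (any(drop)) add(G$samples$id[drop], "individual", "ind_missingness",
                     ind_miss[drop], max_ind_missing)
  G <- subset_geno(G, samples = which(!drop))

  p <- colMeans(G$calls, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0
  drop <- maf < min_maf
  if (any(drop)) add(G$snps$id[drop], "snp", "maf", maf[drop], min_maf)
  G <- subset_geno(G, snps = which(!drop))

  if (!is.null(hwe_p_floor)) {
    pv <- apply(G$calls, 2, hwe_chisq_p)
    drop <- !is.na(pv) & pv < hwe_p_floor
    if (any(drop)) add(G$snps$id[drop], "snp", "hwe", pv[drop], hwe_p_floor)
    G <- subset_geno(G, snps = which(!drop))
  }

  list(genotypes = G,
       report = if (length(rep_rows)) bind_rows(rep_rows) else
         tibble(item = character(), type = character(), step = character(),
                value = numeric(), threshold = numeric()))
}

hwe_chisq_p <- function(g) {
  g <- g[!is.na(g)]
  n <- length(g)
  if (n == 0L) return(NA_real_)
  obs <- tabulate(g + 1L, 3L)
  p <- (2 * obs[3] + obs[2]) / (2 * n)
  if (p == 0 || p == 1) return(1)
  exp_cnt <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  x2 <- sum((obs - exp_cnt)^2 / exp_cnt)
  pchisq(x2, df = 1, lower.tail = FALSE)
}

#' Relatedness filtering by method-of-moments IBD (PI_HAT)
#'
#' Estimates pairwise PI_HAT (the expected proportion of alleles shared
#' identical-by-descent, P(IBD=2) + P(IBD=1)/2) by the method of moments from
#' identity-by-state counts, conditioning the expected IBS-state probabilities
#' on sample allele frequencies.  For every pair above `cutoff`, the member
#' with higher genotype missingness is removed (ties broken by sample-id
#' order).  Run on LD-pruned SNPs for best behaviour (pass `snps`).
#'
#' @param G A [geno_matrix()].
#' @param cutoff PI_HAT threshold above which a pair is considered related
#'   (default 0.25, second degree).
#' @param snps Optional SNP selector (e.g. output of [ld_prune()]) used for
#'   the estimation; removal applies to the full matrix.
#' @return A list: `genotypes` (filtered), `pairs` (tibble of all pairs with
#'   `pi_hat`), `removed` (ids removed).
#' @export
relatedness_filter <- function(G, cutoff = 0.25, snps = NULL) {
  stopifnot(inherits(G, "geno_matrix"))
  n <- nrow(G$calls)
  if (n < 2L) abort("need at least two individuals.")
  Gi <- if (is.null(snps)) G else subset_geno(G, snps = snps)
  x <- Gi$calls
  all_missing <- rowSums(!is.na(x)) == 0L
  if (any(all_missing)) {
    abort(paste0("individual(s) with no called genotypes: ",
                 paste(Gi$samples$id[all_missing], collapse = ", ")))
  }
  p <- colMeans(x, na.rm = TRUE) / 2
  keep_snp <- p > 0 & p < 1
  x <- x[, keep_snp, drop = FALSE]
  p <- p[keep_snp]
  q <- 1 - p
  # P(IBS = s | IBD = z) per SNP (frequencies treated as known):
  e <- rbind(
    ibs0_ibd0 = 2 * p^2 * q^2,
    ibs1_ibd0 = 4 * p^3 * q + 4 * p * q^3,
    ibs2_ibd0 = p^4 + q^4 + 4 * p^2 * q^2,
    ibs1_ibd1 = 2 * p^2 * q + 2 * p * q^2,
    ibs2_ibd1 = p^3 + q^3 + p^2 * q + p * q^2
  )
  ids <- Gi$samples$id
  miss_rate <- rowMeans(is.na(Gi$calls))
  pair_rows <- list()
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      ok <- !is.na(x[i, ]) & !is.na(x[j, ])
      nsnp <- sum(ok)
      if (nsnp == 0L) next
      d <- abs(x[i, ok] - x[j, ok])
      # IBS 2 when equal; IBS 1 when one step apart unless opposite homs,
      # which are IBS 0 (difference of 2).
      ibs0 <- sum(d == 2)
      ibs2 <- sum(d == 0)
      ibs1 <- nsnp - ibs0 - ibs2
      es <- rowSums(e[, ok, drop = FALSE])
      p0 <- ibs0 / es["ibs0_ibd0"]
      p1 <- (ibs1 - p0 * es["ibs1_ibd0"]) / es["ibs1_ibd1"]
      p2 <- (ibs2 - p0 * es["ibs2_ibd0"] - p1 * es["ibs2_ibd1"]) / nsnp
      z <- pmax(c(p0, p1, p2), 0)
      z <- z / sum(z)
      pair_rows[[length(pair_rows) + 1L]] <- tibble(
        id1 = ids[i], id2 = ids[j], pi_hat = z[3] + z[2] / 2, n_snps = nsnp
      )
    }
  }
  pairs <- bind_rows(pair_rows)
  removed <- character()
  flagged <- pairs |> filter(.data$pi_hat > cutoff)
  if (nrow(flagged)) {
    for (k in seq_len(nrow(flagged))) {
      i1 <- flagged$id1[k]; i2 <- flagged$id2[k]
      if (i1 %in% removed || i2 %in% removed) next
      m1 <- miss_rate[match(i1, ids)]
      m2 <- miss_rate[match(i2, ids)]
      drop_id <- if (m1 > m2) i1 else if (m2 > m1) i2 else sort(c(i1, i2))[2]
      removed <- c(removed, drop_id)
    }
  }
  keep <- !(G$samples$id %in% removed)
  list(genotypes = subset_geno(G, samples = which(keep)),
       pairs = pairs, removed = removed)
}

#' Sliding-window LD pruning on genotype r-squared
#'
#' Within each window of `window_snps` SNPs (advanced by `step_snps`), pairs
#' of retained SNPs with squared dosage correlation above `r2_max` are visited
#' in position order and the later SNP of each offending pair is removed;
#' removal is permanent across windows, so the procedure is idempotent.
#'
#' @param G A [geno_matrix()].
#' @param r2_max Maximum tolerated r-squared, in (0, 1].
#' @param window_snps,step_snps Window size and step in SNPs
#'   (`window_snps >= step_snps >= 1`).
#' @return Character vector of retained SNP ids.
#' @export
ld_prune <- function(G, r2_max = 0.4, window_snps = 200, step_snps = 25) {
  stopifnot(inherits(G, "geno_matrix"))
  if (r2_max <= 0 || r2_max > 1) abort("`r2_max` must lie in (0, 1].")
  if (step_snps < 1 || window_snps < step_snps) {
    abort("need window_snps >= step_snps >= 1.")
  }
  keep <- rep(TRUE, ncol(G$calls))
  for (ch in unique(G$snps$chrom)) {
    idx <- which(G$snps$chrom == ch)
    L <- length(idx)
    starts <- seq(1L, max(1L, L), by = step_snps)
    for (s in starts) {
      w <- idx[s:min(s + window_snps - 1L, L)]
      w <- w[keep[w]]
      if (length(w) < 2L) next
      r2 <- suppressWarnings(
        cor(G$calls[, w, drop = FALSE], use = "pairwise.complete.obs")
      )^2
      r2[is.na(r2)] <- 0
      alive <- rep(TRUE, length(w))
      for (a in seq_len(length(w) - 1L)) {
        if (!alive[a]) next
        for (b in seq(a + 1L, length(w))) {
          if (alive[b] && r2[a, b] > r2_max) alive[b] <- FALSE
        }
      }
      keep[w[!alive]] <- FALSE
      if (s + window_snps - 1L >= L) break
    }
  }
  G$snps$id[keep]
}

#' Merge two genotype datasets on their shared SNPs
#'
#' SNPs are intersected by id; allele pairs are reconciled by direct match,
#' allele swap (calls flipped), strand complement, or complement-plus-swap.
#' Strand-ambiguous A/T and C/G SNPs and SNPs with irreconcilable alleles are
#' dropped and reported.
#'
#' @param G1,G2 [geno_matrix()] objects.
#' @return A list: `genotypes` (merged matrix on the reconciled intersection,
#'   samples stacked) and `report` (tibble of per-SNP actions).
#' @export
merge_datasets <- function(G1, G2) {
  stopifnot(inherits(G1, "geno_matrix"), inherits(G2, "geno_matrix"))
  shared <- intersect(G1$snps$id, G2$snps$id)
  if (length(shared) == 0L) abort("no overlapping SNP ids between the datasets.")
  i1 <- match(shared, G1$snps$id)
  i2 <- match(shared, G2$snps$id)
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  act <- character(length(shared))
  flip <- logical(length(shared))
  for (k in seq_along(shared)) {
    a <- c(G1$snps$a1[i1[k]], G1$snps$a2[i1[k]])
    b <- c(G2$snps$a1[i2[k]], G2$snps$a2[i2[k]])
    ambiguous <- function(al) all(sort(al) == c("A", "T")) || all(sort(al) == c("C", "G"))
    if (ambiguous(a) || ambiguous(b)) {
      act[k] <- "dropped_ambiguous"
    } else if (identical(a, b)) {
      act[k] <- "kept"
    } else if (identical(a, rev(b))) {
      act[k] <- "flipped_alleles"; flip[k] <- TRUE
    } else if (all(b %in% names(comp)) && identical(a, unname(comp[b]))) {
      act[k] <- "strand_complemented"
    } else if (all(b %in% names(comp)) && identical(a, unname(rev(comp[b])))) {
      act[k] <- "strand_complemented_flipped"; flip[k] <- TRUE
    } else {
      act[k] <- "dropped_incompatible"
    }
  }
  keep <- !startsWith(act, "dropped")
  report <- tibble(id = shared, action = act)
  i1 <- i1[keep]; i2 <- i2[keep]; flip <- flip[keep]
  c2 <- G2$calls[, i2, drop = FALSE]
  if (any(flip)) c2[, flip] <- 2L - c2[, flip]
  calls <- rbind(G1$calls[, i1, drop = FALSE], c2)
  snps <- G1$snps[i1, ]
  samples <- bind_rows(G1$samples, G2$samples)
  ord <- order(factor(snps$chrom, levels = unique(snps$chrom)), snps$bp)
  list(genotypes = geno_matrix(calls[, ord, drop = FALSE], snps[ord, ], samples),
       report = report)
}
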