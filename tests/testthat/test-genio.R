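canonical_geno <- function(n = 8, L = 20, seed = 1, miss = 0.05) {
  set.seed(seed)
  calls <- matrix(sample(c(0:2, NA), n * L, replace = TRUE,
                         prob = c((1 - miss) / 3, (1 - miss) / 3, (1 - miss) / 3, miss)),
                  n, L)
  snps <- uniform_map(L, morgans = 0.5)
  # canonical allele orientation (a1 < a2) so plink-text round-trips exactly
  snps$a1 <- "A"; snps$a2 <- "G"
  geno_matrix(calls, snps, tibble::tibble(id = sprintf("s%02d", 1:n),
                                          pop = rep(c("P1", "P2"), length.out = n)))
}

test_that("all three genotype formats round-trip", {
  G <- canonical_geno()
  for (fmt in c("plink-text", "eigenstrat", "vcf")) {
    path <- file.path(
      withr::local_tempdir(),
      if (fmt == "vcf") "g.vcf" else "g"
    )
    write_genotypes(G, path, fmt)
    G2 <- read_genotypes(path, fmt)
    expect_equal(unname(G2$calls), unname(G$calls), label = fmt)
    expect_equal(G2$snps$id, G$snps$id, label = fmt)
    expect_equal(G2$snps$bp, G$snps$bp, label = fmt)
    if (fmt != "vcf") {
      expect_equal(G2$snps$cm, G$snps$cm, tolerance = 1e-9, label = fmt)
      expect_equal(G2$samples$pop, G$samples$pop, label = fmt)
    }
  }
})

test_that("hand-written .ped/.map parses to the expected matrix", {
  d <- withr::local_tempdir()
  writeLines(c("1\tsnp1\t0\t100", "1\tsnp2\t0\t200", "1\tsnp3\t0\t300"),
             file.path(d, "toy.map"))
  # individual 1: A/A at snp1? encode calls [[0,1,2],[2,1,0]] with a1<a2 (A<G)
  writeLines(c(
    "F1 ind1 0 0 0 -9 G G A G A A",
    "F2 ind2 0 0 0 -9 A A A G G G"
  ), file.path(d, "toy.ped"))
  G <- read_genotypes(file.path(d, "toy"), "plink-text")
  expect_equal(unname(G$calls), rbind(c(0L, 1L, 2L), c(2L, 1L, 0L)))
  expect_equal(G$samples$id, c("ind1", "ind2"))

  # empty SNP list errors rather than returning an empty matrix
  writeLines(character(), file.path(d, "empty.map"))
  writeLines("F1 i 0 0 0 -9", file.path(d, "empty.ped"))
  expect_error(read_genotypes(file.path(d, "empty"), "plink-text"), "no SNPs")

  # dimension mismatch names the offending line
  writeLines(c("1\tsnp1\t0\t100", "1\tsnp2\t0\t200"), file.path(d, "bad.map"))
  writeLines(c("F1 i1 0 0 0 -9 A A G G", "F1 i2 0 0 0 -9 A A"),
             file.path(d, "bad.ped"))
  expect_error(read_genotypes(file.path(d, "bad"), "plink-text"), "line 2")
})

test_that("VCF unphased and phased GT map to ALT dosage", {
  d <- withr::local_tempdir()
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
    "1\t100\tv1\tA\tC\t.\tPASS\t.\tGT\t0/1\t1|1",
    "1\t200\tv2\tG\tT\t.\tPASS\t.\tGT\t./.\t0|0"
  ), file.path(d, "t.vcf"))
  G <- read_genotypes(file.path(d, "t.vcf"), "vcf")
  expect_equal(unname(G$calls), rbind(c(1L, NA), c(2L, 0L)))
  expect_equal(G$snps$a1, c("C", "T")) # ALT is the counted allele
})

test_that("QC filters run in the documented order and report removals", {
  # SNP missing in 3/10 individuals at threshold 0.2 -> removed
  calls <- matrix(1L, 10, 4)
  calls[1:3, 2] <- NA
  G <- toy_geno(calls)
  res <- qc_filter(G, max_snp_missing = 0.2, max_ind_missing = 1, min_maf = 0)
  expect_false(G$snps$id[2] %in% res$genotypes$snps$id)
  expect_equal(res$report$step, "snp_missingness")
  expect_equal(res$report$value, 0.3)

  # identity thresholds change nothing
  res2 <- qc_filter(G, max_snp_missing = 1, max_ind_missing = 1, min_maf = 0)
  expect_equal(res2$genotypes$calls, G$calls)
  expect_equal(nrow(res2$report), 0L)

  # monomorphic SNP removed at min_maf = 0.01
  calls3 <- cbind(rep(0L, 10), sample(0:2, 10, TRUE))
  G3 <- toy_geno(calls3)
  res3 <- qc_filter(G3, max_snp_missing = 1, max_ind_missing = 1, min_maf = 0.01)
  expect_false(G3$snps$id[1] %in% res3$genotypes$snps$id)
  expect_true("maf" %in% res3$report$step)

  expect_error(qc_filter(G, max_snp_missing = 1.2), "lie in")
})

test_that("relatedness filter flags duplicates and spares unrelated pairs", {
  set.seed(42)
  p <- runif(8000, 0.2, 0.8)
  fr <- sim_source_freqs(p, 0, seed = 1)
  sp <- sim_panel(fr, 6, seed = 2)
  G <- sp$genotypes
  # append an exact duplicate of individual 1
  G2 <- geno_matrix(rbind(G$calls, G$calls[1, ]), G$snps,
                    dplyr::bind_rows(G$samples,
                                     tibble::tibble(id = "dup1", pop = "pop1")))
  res <- relatedness_filter(G2, cutoff = 0.25)
  dup_pair <- res$pairs |>
    dplyr::filter(id1 == G$samples$id[1], id2 == "dup1")
  expect_gt(dup_pair$pi_hat, 0.9)
  expect_length(res$removed, 1)
  expect_true(res$removed %in% c(G$samples$id[1], "dup1"))

  # independent individuals: PI_HAT near zero
  others <- res$pairs |> dplyr::filter(id2 != "dup1", id1 != G$samples$id[1])
  expect_true(all(abs(others$pi_hat) < 0.05))

  # cutoff above 1 removes nothing
  res2 <- relatedness_filter(G2, cutoff = 1.01)
  expect_length(res2$removed, 0)

  # all-missing individual errors before estimation
  G3 <- G2
  G3$calls[2, ] <- NA_integer_
  expect_error(relatedness_filter(G3), "no called genotypes")
})

test_that("LD pruning removes duplicates, keeps independent SNPs, and is idempotent", {
  set.seed(5)
  # independent SNPs: all kept (verify max pairwise r2 actually < 0.4)
  calls <- matrix(rbinom(60 * 40, 2, 0.5), 60, 40)
  G <- toy_geno(calls)
  r2max <- max((cor(calls)^2)[upper.tri(diag(40))])
  skip_if(r2max >= 0.4, "random fixture unexpectedly correlated")
  kept <- ld_prune(G, r2_max = 0.4, window_snps = 20, step_snps = 5)
  expect_equal(kept, G$snps$id)

  # duplicated SNP column: exactly one of the pair survives
  calls2 <- cbind(calls, calls[, 1])
  G2 <- toy_geno(calls2)
  kept2 <- ld_prune(G2, r2_max = 0.4, window_snps = 41, step_snps = 5)
  expect_equal(sum(c(G2$snps$id[1], G2$snps$id[41]) %in% kept2), 1L)

  # idempotence
  G3 <- subset_geno(G2, snps = kept2)
  expect_equal(ld_prune(G3, r2_max = 0.4, window_snps = 41, step_snps = 5),
               kept2)

  expect_error(ld_prune(G, r2_max = 0), "\\(0, 1\\]")
  expect_error(ld_prune(G, window_snps = 2, step_snps = 5), "window_snps")
})

test_that("r-squared used by the pruner matches a brute-force correlation oracle", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- 25; L <- 12
    calls <- matrix(rbinom(n * L, 2, runif(L, 0.2, 0.8)[rep(1:L, each = n)]), n, L)
    r2_pkg <- suppressWarnings(cor(calls))^2
    # brute force: explicit covariance/variance ratio
    r2_brute <- matrix(NA_real_, L, L)
    for (i in 1:L) for (j in 1:L) {
      xi <- calls[, i]; xj <- calls[, j]
      cov_ij <- sum((xi - mean(xi)) * (xj - mean(xj))) / (n - 1)
      r2_brute[i, j] <- cov_ij^2 / (var(xi) * var(xj))
    }
    expect_equal(unname(r2_pkg), r2_brute, tolerance = 1e-12)
  }
})

test_that("dataset merging reconciles alleles and drops ambiguous SNPs", {
  base <- canonical_geno(n = 4, L = 6, seed = 3, miss = 0)
  # identical panels: intersection is the original SNP set
  m <- merge_datasets(base, base)
  expect_equal(m$genotypes$snps$id, base$snps$id)
  expect_true(all(m$report$action == "kept"))
  expect_equal(nrow(m$genotypes$calls), 8)

  # swapped allele labels: calls flipped back to match
  flipped <- base
  flipped$snps$a1 <- "G"; flipped$snps$a2 <- "A"
  flipped$calls <- 2L - flipped$calls
  m2 <- merge_datasets(base, flipped)
  expect_true(all(m2$report$action == "flipped_alleles"))
  expect_equal(unname(m2$genotypes$calls[5:8, ]), unname(base$calls))

  # A/T ambiguous SNP dropped and reported
  amb <- base
  amb$snps$a1[2] <- "A"; amb$snps$a2[2] <- "T"
  m3 <- merge_datasets(amb, amb)
  expect_equal(m3$report$action[2], "dropped_ambiguous")
  expect_false(base$snps$id[2] %in% m3$genotypes$snps$id)

  # zero overlap errors
  other <- base
  other$snps$id <- paste0("x", other$snps$id)
  expect_error(merge_datasets(base, other), "no overlapping")
})

test_that("filters are stable under individual permutation", {
  G <- canonical_geno(n = 10, L = 30, seed = 8, miss = 0.1)
  perm <- sample(10)
  Gp <- subset_geno(G, samples = perm)
  r1 <- qc_filter(G, min_maf = 0.05)
  r2 <- qc_filter(Gp, min_maf = 0.05)
  expect_setequal(r1$genotypes$snps$id, r2$genotypes$snps$id)
  expect_setequal(r1$genotypes$samples$id, r2$genotypes$samples$id)
  expect_equal(ld_prune(G, window_snps = 10, step_snps = 5),
               ld_prune(Gp, window_snps = 10, step_snps = 5))
})
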