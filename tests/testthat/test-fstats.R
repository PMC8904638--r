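test_that("allele frequencies match brute-force counting", {
  # {0,1,2} in 3 individuals -> freq 0.5 over 6 chromosomes
  G <- toy_geno(matrix(c(0L, 1L, 2L), 3, 1), pops = rep("P", 3))
  ft <- allele_freqs(G)
  expect_equal(unname(ft$freq["P", 1]), 0.5)
  expect_equal(unname(ft$n_chrom["P", 1]), 6L)

  # all-missing SNP: zero chromosomes, NaN frequency, excluded downstream
  G2 <- toy_geno(cbind(c(0L, 2L), c(NA, NA)), pops = c("P", "P"))
  ft2 <- allele_freqs(G2)
  expect_equal(unname(ft2$n_chrom["P", 2]), 0L)
  expect_true(is.nan(ft2$freq["P", 2]))

  # random instances vs counting oracle
  for (seed in 1:10) {
    set.seed(seed)
    calls <- matrix(sample(c(0:2, NA), 40, TRUE), 8, 5)
    labs <- sample(c("X", "Y"), 8, TRUE)
    if (length(unique(labs)) < 2) next
    ft3 <- allele_freqs(toy_geno(calls, pops = labs))
    for (g in c("X", "Y")) for (j in 1:5) {
      x <- calls[labs == g, j]
      x <- x[!is.na(x)]
      expect_equal(unname(ft3$n_chrom[g, j]), 2L * length(x))
      if (length(x)) expect_equal(unname(ft3$freq[g, j]), sum(x) / (2 * length(x)))
    }
  }

  expect_error(f3(allele_freqs(G), "P", "Q", "P"), "unknown population")
})

test_that("f3 reproduces direct arithmetic and algebraic identities", {
  # population-frequency mode over 2 SNPs: mean of (0.4)(-0.4) and (-0.4)(0.4)
  ft <- freq_table(rbind(A = c(0.1, 0.9), B = c(0.9, 0.1), C = c(0.5, 0.5)))
  res <- f3(ft, "A", "B", "C", blocks = c(1, 2), correct = FALSE)
  expect_equal(res$estimate, -0.16)

  # identical populations, infinite-n mode: exactly zero
  ft0 <- freq_table(rbind(A = c(0.2, 0.7, 0.4), B = c(0.2, 0.7, 0.4),
                          C = c(0.2, 0.7, 0.4)))
  expect_equal(f3(ft0, "A", "B", "C", blocks = c(1, 1, 2))$estimate, 0)

  # outgroup f3 is symmetric in pop1/pop2
  set.seed(2)
  fr <- matrix(runif(3 * 200, 0.1, 0.9), 3, dimnames = list(c("O", "P1", "P2"), NULL))
  ftq <- freq_table(fr)
  s12 <- f3_outgroup(ftq, "O", "P1", "P2", block_cm = 20)
  s21 <- f3_outgroup(ftq, "O", "P2", "P1", block_cm = 20)
  expect_equal(s12$estimate, s21$estimate, tolerance = 1e-15)
  expect_equal(s12$se, s21$se, tolerance = 1e-15)
})

test_that("admixture f3 detects a simulated 50/50 mixture at Z < -3", {
  set.seed(13)
  p <- runif(4000, 0.1, 0.9)
  fr <- sim_source_freqs(p, c(A = 0.05, B = 0.05), seed = 14)
  # shallow post-admixture drift of the target around the mixture frequency
  mix <- 0.5 * fr["A", ] + 0.5 * fr["B", ]
  tgt <- sim_source_freqs(pmin(pmax(mix, 1e-4), 1 - 1e-4), 0.002, seed = 15)
  sp <- sim_panel(rbind(fr, C = tgt[1, ]), 30, seed = 16)
  ft <- allele_freqs(sp$genotypes)
  res <- f3(ft, "A", "B", "C", block_cm = 2)
  expect_lt(res$z, -3)

  # an unadmixed sister population shows no signal
  fr2 <- sim_source_freqs(p, c(A = 0.05, B = 0.05, C = 0.05), seed = 17)
  sp2 <- sim_panel(fr2, 30, seed = 18)
  res2 <- f3(allele_freqs(sp2$genotypes), "A", "B", "C", block_cm = 2)
  expect_gt(res2$z, -3)
})

test_that("f3 outgroup ranks sister populations above distant ones", {
  set.seed(23)
  # tree: O far; P1,P2 sisters sharing drift; Q independent
  p <- runif(3000, 0.1, 0.9)
  anc12 <- sim_source_freqs(p, 0.05, seed = 24)[1, ]
  fr <- rbind(
    O = sim_source_freqs(p, 0.3, seed = 25)[1, ],
    P1 = sim_source_freqs(pmin(pmax(anc12, 1e-4), 1 - 1e-4), 0.02, seed = 26)[1, ],
    P2 = sim_source_freqs(pmin(pmax(anc12, 1e-4), 1 - 1e-4), 0.02, seed = 27)[1, ],
    Q = sim_source_freqs(p, 0.05, seed = 28)[1, ]
  )
  sp <- sim_panel(fr, 25, seed = 29)
  ft <- allele_freqs(sp$genotypes)
  sisters <- f3_outgroup(ft, "O", "P1", "P2", block_cm = 5)
  distant <- f3_outgroup(ft, "O", "P1", "Q", block_cm = 5)
  expect_gt(sisters$estimate, distant$estimate)
  # self-comparison is maximal holding the outgroup fixed
  self <- f3_outgroup(ft, "O", "P1", "P1", block_cm = 5)
  expect_gt(self$estimate, sisters$estimate)
})

test_that("f4 reproduces direct arithmetic, antisymmetry and additivity", {
  ft <- freq_table(rbind(
    A = c(0.1, 0.5), B = c(0.2, 0.4), C = c(0.3, 0.9), D = c(0.6, 0.1),
    E = c(0.8, 0.3)
  ))
  blocks <- c(1, 2)
  expect_equal(f4(ft, "A", "B", "C", "D", blocks = blocks)$estimate, 0.055)

  # C = D: exactly zero
  ft2 <- freq_table(rbind(A = c(0.1, 0.5), B = c(0.2, 0.4),
                          C = c(0.3, 0.9), D = c(0.3, 0.9)))
  expect_equal(f4(ft2, "A", "B", "C", "D", blocks = blocks)$estimate, 0)

  # antisymmetry
  e1 <- f4(ft, "A", "B", "C", "D", blocks = blocks)$estimate
  e2 <- f4(ft, "B", "A", "C", "D", blocks = blocks)$estimate
  e3 <- f4(ft, "A", "B", "D", "C", blocks = blocks)$estimate
  expect_equal(e1, -e2, tolerance = 1e-15)
  expect_equal(e1, -e3, tolerance = 1e-15)

  # additivity: f4(A,B;C,D) + f4(A,B;D,E) = f4(A,B;C,E)
  lhs <- f4(ft, "A", "B", "C", "D", blocks = blocks)$estimate +
    f4(ft, "A", "B", "D", "E", blocks = blocks)$estimate
  rhs <- f4(ft, "A", "B", "C", "E", blocks = blocks)$estimate
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("f4-ratio recovers construction and flags unstable denominators", {
  set.seed(31)
  L <- 400
  b <- runif(L, 0.1, 0.9)
  cc <- runif(L, 0.1, 0.9)
  # A must share drift with B for the denominator f4(A,O;B,C) to be nonzero
  a <- sim_source_freqs(b, 0.05, seed = 32)[1, ]
  o <- runif(L, 0.1, 0.9)
  alpha <- 0.25
  x <- alpha * b + (1 - alpha) * cc
  ft <- freq_table(rbind(A = a, O = o, X = x, B = b, C = cc))
  blocks <- rep(1:8, each = L / 8)
  est <- f4_ratio(ft, "A", "O", "X", "B", "C", blocks = blocks)
  expect_equal(est$estimate, alpha, tolerance = 1e-10)
  expect_false(est$unstable)

  # X = B gives alpha = 1
  ftb <- freq_table(rbind(A = a, O = o, X = b, B = b, C = cc))
  expect_equal(f4_ratio(ftb, "A", "O", "X", "B", "C", blocks = blocks)$estimate, 1)

  # B = C collapses the denominator: flagged, not silent division
  ftu <- freq_table(rbind(A = a, O = o, X = x, B = b, C = b))
  expect_warning(res <- f4_ratio(ftu, "A", "O", "X", "B", "C", blocks = blocks),
                 "unstable")
  expect_true(res$unstable)
})

test_that("f4-ratio recovers a simulated minority-introgression fraction", {
  set.seed(41)
  alphas <- replicate(20, {
    L <- 4000
    p <- runif(L, 0.1, 0.9)
    bb <- sim_source_freqs(p, 0.2, seed = NULL)[1, ]   # introgressing lineage
    ccc <- sim_source_freqs(p, 0.02, seed = NULL)[1, ] # recipient-related
    x <- 0.03 * bb + 0.97 * ccc
    fr <- rbind(
      A = sim_source_freqs(pmin(pmax(bb, 1e-4), 1 - 1e-4), 0.02, seed = NULL)[1, ],
      O = sim_source_freqs(p, 0.3, seed = NULL)[1, ],
      X = x, B = bb, C = ccc
    )
    sp <- sim_panel(fr, 30, seed = NULL)
    ft <- allele_freqs(sp$genotypes)
    f4_ratio(ft, "A", "O", "X", "B", "C", block_cm = 2)$estimate
  })
  expect_lt(abs(mean(alphas) - 0.03), 0.01)
})

test_that("block jackknife matches the textbook delete-1 formula and edge cases", {
  # identical per-block estimates -> se = 0
  v <- rep(0.3, 50)
  bj <- block_jackknife(v, blocks = rep(1:5, each = 10))
  expect_equal(bj$estimate, 0.3)
  expect_equal(bj$se, 0)

  # equal-size blocks reduce to the classical delete-1 jackknife
  set.seed(5)
  v2 <- rnorm(50)
  blocks <- rep(1:5, each = 10)
  bj2 <- block_jackknife(v2, blocks = blocks)
  theta <- mean(v2)
  theta_del <- vapply(1:5, function(b) mean(v2[blocks != b]), numeric(1))
  se_classic <- sqrt((5 - 1) / 5 * sum((theta_del - mean(theta_del))^2))
  expect_equal(bj2$estimate, theta)
  expect_equal(bj2$se, se_classic, tolerance = 1e-12)

  # one block holding everything is an error
  expect_error(block_jackknife(v, blocks = rep(1, 50)), "blocks")
})

test_that("f4 Z-scores are calibrated under a no-gene-flow tree", {
  set.seed(51)
  zs <- replicate(200, {
    L <- 1000
    p <- runif(L, 0.1, 0.9)
    clamp <- function(x) pmin(pmax(x, 1e-4), 1 - 1e-4)
    pab <- clamp(sim_source_freqs(p, 0.05, seed = NULL)[1, ])
    pcd <- clamp(sim_source_freqs(p, 0.05, seed = NULL)[1, ])
    fr <- rbind(
      A = sim_source_freqs(pab, 0.03, seed = NULL)[1, ],
      B = sim_source_freqs(pab, 0.03, seed = NULL)[1, ],
      C = sim_source_freqs(pcd, 0.03, seed = NULL)[1, ],
      D = sim_source_freqs(pcd, 0.03, seed = NULL)[1, ]
    )
    sp <- sim_panel(fr, 20, seed = NULL)
    f4(allele_freqs(sp$genotypes), "A", "B", "C", "D", block_cm = 2.5)$z
  })
  ks <- suppressWarnings(stats::ks.test(zs, "pnorm"))
  expect_gt(ks$p.value, 0.01)
  expect_lte(mean(abs(zs) > 3), 0.02)
})
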