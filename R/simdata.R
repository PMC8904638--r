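#' Simulate source-population allele frequencies (Balding-Nichols model)
#'
#' Each source population drifts away from a shared ancestral allele-frequency
#' vector `p` under the Balding-Nichols model: the source frequency at a SNP
#' is Beta(p(1-F)/F, (1-p)(1-F)/F), whose mean is `p` and whose variance is
#' F p (1-p).  `F` is the per-source divergence (drift) parameter; for two
#' populations simulated at the same `F`, the expected Weir-Cockerham FST
#' between them is close to `2F / (1 + F)` (shared ancestral variance removed).
#' `F = 0` returns the ancestral frequencies unchanged.
#'
#' @param p_anc Ancestral allele-1 frequencies, strictly inside (0, 1).
#' @param fst Drift parameter per source, each in `[0, 1)`.  Length gives the
#'   number of sources.
#' @param pop_names Optional source names (default `pop1`, `pop2`, ...).
#' @param seed Optional integer seed.
#' @return Numeric matrix, sources x SNPs, of allele-1 frequencies.
#' @export
sim_source_freqs <- function(p_anc, fst, pop_names = NULL, seed = NULL) {
  if (any(p_anc <= 0) || any(p_anc >= 1)) {
    abort("`p_anc` must be strictly inside (0, 1): monomorphic ancestral sites are invalid.")
  }
  if (any(fst < 0) || any(fst >= 1)) abort("each drift parameter must lie in [0, 1).")
  k <- length(fst)
  if (is.null(pop_names)) pop_names <- names(fst) %||% paste0("pop", seq_len(k))
  L <- length(p_anc)
  with_seed(seed, {
    out <- matrix(NA_real_, k, L, dimnames = list(pop_names, names(p_anc)))
    for (s in seq_len(k)) {
      if (fst[s] == 0) {
        out[s, ] <- p_anc
      } else {
        lam <- (1 - fst[s]) / fst[s]
        out[s, ] <- rbeta(L, p_anc * lam, (1 - p_anc) * lam)
      }
    }
    out
  })
}

#' Simulate a phased haplotype panel from population allele frequencies
#'
#' Haplotype alleles are independent Bernoulli draws of allele 1 at each
#' site's population frequency; genotypes are the sums of an individual's two
#' haplotypes.  Output is byte-identical under a fixed seed.
#'
#' @param freqs Matrix of allele-1 frequencies (sources x SNPs) from
#'   [sim_source_freqs()], or a single frequency vector.
#' @param n_per_pop Diploid individuals per source (scalar or per-source).
#' @param map SNP tibble (see [uniform_map()]); defaults to a uniform 1-Morgan
#'   map over the SNPs.
#' @param seed Optional integer seed.
#' @return A list with elements `panel` ([hap_panel()]) and `genotypes`
#'   ([geno_matrix()]).
#' @export
sim_panel <- function(freqs, n_per_pop, map = NULL, seed = NULL) {
  if (is.vector(freqs)) freqs <- matrix(freqs, 1, dimnames = list("pop1", names(freqs)))
  if (any(n_per_pop < 1)) abort("`n_per_pop` must be >= 1.")
  check_fraction(freqs, "freqs")
  k <- nrow(freqs)
  L <- ncol(freqs)
  n_per_pop <- rep_len(as.integer(n_per_pop), k)
  if (is.null(map)) map <- uniform_map(L, morgans = 1)
  stopifnot(nrow(map) == L)
  with_seed(seed, {
    haps <- matrix(0L, 2 * sum(n_per_pop), L)
    samples <- tibble(
      id = sprintf("%s_i%d", rep(rownames(freqs), n_per_pop),
                   unlist(lapply(n_per_pop, seq_len))),
      pop = rep(rownames(freqs), n_per_pop)
    )
    r0 <- 0L
    for (s in seq_len(k)) {
      nh <- 2L * n_per_pop[s]
      haps[r0 + seq_len(nh), ] <- matrix(
        rbinom(nh * L, 1L, rep(freqs[s, ], each = nh)), nh, L
      )
      r0 <- r0 + nh
    }
    panel <- hap_panel(haps, map, samples)
    list(panel = panel, genotypes = hap_to_geno(panel))
  })
}

#' Simulate admixed mosaic genomes with a single admixture pulse
#'
#' Each admixed haplotype is a mosaic of the source panels: ancestry
#' breakpoints form a Poisson process of rate `g` per Morgan along each
#' chromosome (the expected segment length is `1/g` Morgans, which is what
#' makes admixture LD decay as `exp(-g d)` and lets weighted-LD fitting
#' recover the admixture time), each segment's source is drawn independently
#' from `proportions`, and the segment's alleles are copied from a randomly
#' chosen haplotype of that source's panel.
#'
#' @param panel A [hap_panel()] holding the source haplotypes; `proportions`
#'   is matched to its population labels.
#' @param proportions Named simplex weights over source populations (names
#'   matching `panel$samples$pop`), or unnamed in the order of first
#'   appearance.
#' @param g Admixture time in generations (>= 1).
#' @param n Number of admixed diploid individuals.
#' @param prefix Sample-id prefix and population label for the admixed group.
#' @param seed Optional integer seed.
#' @return A list: `panel` (admixed [hap_panel()]), `genotypes`
#'   ([geno_matrix()]) and `truth` with per-individual realized ancestry
#'   proportions, the per-haplotype breakpoint table (cM positions and source
#'   labels) and the true admixture time.
#' @export
sim_admixed <- function(panel, proportions, g, n, prefix = "adm", seed = NULL) {
  stopifnot(inherits(panel, "hap_panel"))
  if (g < 1) abort("`g` must be a positive number of generations (>= 1).")
  pops <- unique(panel$samples$pop)
  if (is.null(names(proportions))) {
    if (length(proportions) != length(pops)) {
      abort("unnamed `proportions` must have one entry per source population.")
    }
    names(proportions) <- pops
  }
  check_simplex(proportions, "proportions", tol = 1e-12)
  used <- names(proportions)[proportions > 0]
  missing_pop <- setdiff(used, pops)
  if (length(missing_pop)) {
    abort(paste0("no haplotypes available for source(s): ",
                 paste(missing_pop, collapse = ", ")))
  }
  hap_pop <- rep(panel$samples$pop, each = 2)
  rows_by_pop <- split(seq_len(nrow(panel$haps)), hap_pop)
  snps <- panel$snps
  chroms <- unique(snps$chrom)
  K <- length(proportions)
  src_names <- names(proportions)

  chrom_idx <- split(seq_len(nrow(snps)), factor(snps$chrom, levels = chroms))
  total_cm <- sum(vapply(chrom_idx, function(i) diff(range(snps$cm[i])), numeric(1)))

  with_seed(seed, {
    haps <- matrix(0L, 2L * n, ncol(panel$haps))
    anc_len <- matrix(0, n, K, dimnames = list(NULL, src_names))
    bp_rows <- list()
    for (h in seq_len(2L * n)) {
      ind <- (h + 1L) %/% 2L
      for (ch in chroms) {
        idx <- chrom_idx[[ch]]
        cm <- snps$cm[idx]
        lo <- cm[1L]; hi <- cm[length(cm)]
        nbp <- rpois(1L, g * (hi - lo) / 100)
        bks <- sort(runif(nbp, lo, hi))
        bounds <- c(lo, bks, hi)
        nseg <- nbp + 1L
        seg_src <- sample.int(K, nseg, replace = TRUE, prob = proportions)
        # SNPs are cm-sorted, so segment membership comes from findInterval
        # and each segment is a contiguous slice of `idx`.
        seg_of <- findInterval(cm, bks) + 1L
        cnt <- tabulate(seg_of, nseg)
        ends <- cumsum(cnt)
        starts <- ends - cnt + 1L
        for (s in seq_len(nseg)) {
          src <- src_names[seg_src[s]]
          if (cnt[s] > 0L) {
            sel <- idx[starts[s]:ends[s]]
            donor <- rows_by_pop[[src]][sample.int(length(rows_by_pop[[src]]), 1L)]
            haps[h, sel] <- panel$haps[donor, sel]
          }
          anc_len[ind, seg_src[s]] <- anc_len[ind, seg_src[s]] +
            (bounds[s + 1L] - bounds[s])
        }
        bp_rows[[length(bp_rows) + 1L]] <- tibble(
          hap = h, chrom = ch,
          start_cm = bounds[-length(bounds)], end_cm = bounds[-1],
          source = src_names[seg_src]
        )
      }
    }
    samples <- tibble(id = sprintf("%s_i%d", prefix, seq_len(n)), pop = prefix)
    adm <- hap_panel(haps, snps, samples)
    ancestry <- as_tibble(anc_len / (2 * total_cm)) |>
      mutate(id = samples$id, .before = 1)
    truth <- list(
      ancestry = ancestry,
      breakpoints = bind_rows(bp_rows),
      g = g,
      proportions = proportions
    )
    list(panel = adm, genotypes = hap_to_geno(adm), truth = truth)
  })
}

#' Simulate Dirichlet copying vectors with known mixture weights
#'
#' Generates per-individual copying vectors (simplex vectors over donor
#' clusters) whose expectation is the mixture `weights %*% source_profiles`,
#' with Dirichlet noise controlled by `concentration` (larger = tighter;
#' `Inf` returns the exact mixture for every individual).
#'
#' @param source_profiles Matrix, sources x donor clusters; each row a simplex.
#' @param weights Simplex mixture weights over the sources.
#' @param concentration Positive scalar, or `Inf` for the noise-free mode.
#' @param n Number of vectors to draw.
#' @param seed Optional integer seed.
#' @return A list: `vectors` (n x donor-clusters matrix, rows summing to 1)
#'   and `truth` (the exact mixture vector and the generating weights).
#' @export
sim_copying_vectors <- function(source_profiles, weights, concentration, n, seed = NULL) {
  source_profiles <- as.matrix(source_profiles)
  if (length(weights) != nrow(source_profiles)) {
    abort("`weights` must have one entry per source profile row.")
  }
  apply(source_profiles, 1, check_simplex, name = "source_profiles")
  check_simplex(weights, "weights")
  if (concentration <= 0) abort("`concentration` must be positive.")
  mix <- drop(weights %*% source_profiles)
  D <- length(mix)
  with_seed(seed, {
    vectors <- if (is.infinite(concentration)) {
      matrix(mix, n, D, byrow = TRUE)
    } else {
      gm <- matrix(rgamma(n * D, shape = rep(concentration * mix, each = n)), n, D)
      gm / rowSums(gm)
    }
    colnames(vectors) <- colnames(source_profiles) %||% paste0("donor", seq_len(D))
    rownames(vectors) <- paste0("ind", seq_len(n))
    list(vectors = vectors, truth = list(mix = mix, weights = weights))
  })
}
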