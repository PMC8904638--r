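#' Demonstration scenario configuration
#'
#' Default configuration for the self-contained synthetic demonstration:
#' three divergent source populations (Balding-Nichols drift F = 0.05 from a
#' shared ancestral frequency pool), one recently admixed group (single pulse
#' 13 generations ago, equal mixture of two sources) and one older admixed
#' pair (19 generations ago), mirroring a two-wave admixture history.  All
#' sizes are chosen so the full pipeline runs in minutes on one CPU; scale
#' `n_snps` / `n_per_pop` up for sharper statistics.
#'
#' @param seed Master seed; stage seeds are derived by fixed offsets.
#' @param n_snps,n_per_pop,n_admixed,morgans,n_chrom Scenario dimensions.
#' @return A nested configuration list understood by [run_pipeline()].
#' @export
demo_config <- function(seed = 1, n_snps = 1500, n_per_pop = 12,
                        n_admixed = 12, morgans = 1.5, n_chrom = 3) {
  list(
    seed = seed,
    simulate = list(
      n_snps = n_snps, n_per_pop = n_per_pop, n_admixed = n_admixed,
      morgans = morgans, n_chrom = n_chrom,
      fst = c(SrcA = 0.05, SrcB = 0.05, SrcC = 0.05),
      admixed_groups = list(
        AdmRecent = list(proportions = c(SrcA = 0.5, SrcB = 0, SrcC = 0.5), g = 13),
        AdmOld1 = list(proportions = c(SrcA = 0.3, SrcB = 0.7, SrcC = 0), g = 19),
        AdmOld2 = list(proportions = c(SrcA = 0.5, SrcB = 0.5, SrcC = 0), g = 19)
      )
    ),
    qc = list(max_snp_missing = 0.05, max_ind_missing = 0.05, min_maf = 0.01),
    prune = list(r2_max = 0.4, window_snps = 200, step_snps = 25),
    paint = list(rho = 50, mu = 0.001),
    cluster = list(k = 6),
    refine = list(max_branch_clusters = 5, min_cluster_individuals = 5,
                  tvd_threshold = 0.035, max_pool = 3, direction = "below"),
    nnls = list(),
    dating = list(bin_width_cm = 0.5, d_min_cm = 0.5, d_max_cm = 30)
  )
}

#' Generate the self-contained demonstration dataset
#'
#' Simulates the [demo_config()] scenario and writes it to `dir` as PLINK
#' text plus truth tables (tab-separated with header).  Byte-identical under
#' a fixed seed.
#'
#' @param seed Master seed.
#' @param dir Output directory (created if needed).
#' @param config Optional configuration overriding [demo_config()].
#' @return Invisibly, a list with the simulated panels, genotypes and truth.
#' @export
make_demo <- function(seed = 1, dir = NULL, config = demo_config(seed)) {
  sim <- config$simulate
  p_anc <- with_seed(derive_seed(config$seed, 1L),
                     runif(sim$n_snps, 0.1, 0.9))
  freqs <- sim_source_freqs(p_anc, sim$fst, pop_names = names(sim$fst),
                            seed = derive_seed(config$seed, 2L))
  map <- uniform_map(sim$n_snps, morgans = sim$morgans, n_chrom = sim$n_chrom)
  src <- sim_panel(freqs, sim$n_per_pop, map = map,
                   seed = derive_seed(config$seed, 3L))
  panels <- list(src$panel)
  truth_rows <- list()
  off <- 10L
  for (grp in names(sim$admixed_groups)) {
    spec_g <- sim$admixed_groups[[grp]]
    adm <- sim_admixed(src$panel, spec_g$proportions, g = spec_g$g,
                       n = sim$n_admixed, prefix = grp,
                       seed = derive_seed(config$seed, off))
    off <- off + 1L
    panels[[length(panels) + 1L]] <- adm$panel
    truth_rows[[grp]] <- adm$truth$ancestry |> mutate(group = grp, g = spec_g$g)
  }
  combined <- combine_panels(panels)
  out <- list(
    panel = combined,
    genotypes = hap_to_geno(combined),
    truth = bind_rows(truth_rows)
  )
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_genotypes(out$genotypes, file.path(dir, "demo"), "plink-text")
    write.table(out$truth, file.path(dir, "truth_ancestry.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(out)
}

#' Concatenate haplotype panels sharing one SNP table
#'
#' @param panels List of [hap_panel()] objects with identical SNP tables.
#' @return A single [hap_panel()].
#' @export
combine_panels <- function(panels) {
  snps <- panels[[1]]$snps
  for (p in panels[-1]) {
    if (!identical(p$snps$id, snps$id)) abort("panels must share the same SNPs.")
  }
  hap_panel(do.call(rbind, lapply(panels, function(p) p$haps)),
            snps,
            bind_rows(lapply(panels, function(p) p$samples)))
}

#' Run the full analysis pipeline on a configuration
#'
#' Executes the stages in the canonical order — simulate, QC, LD-prune,
#' allele-frequency statistics (pairwise FST, PCA, RoH), f3 admixture scan,
#' haplotype painting, clustering and refinement, TVD heterogeneity, NNLS
#' ancestry profiles, weighted-LD dating — writing each stage's artifacts as
#' TSV under `out_dir` plus a JSON `manifest.json` recording parameters, file
#' MD5 hashes, package version and wall time per stage.  A rerun with an
#' intact manifest skips completed stages (hash-checked resume): artifacts
#' whose hash no longer matches are recomputed.
#'
#' @param config Configuration list (see [demo_config()]).
#' @param out_dir Output directory.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(out_dir, "manifest.json")
  manifest <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  } else {
    list(package = "mosaicpop",
         version = as.character(utils::packageVersion("mosaicpop")),
         seed = config$seed, stages = list())
  }
  state <- new.env(parent = emptyenv())

  stage <- function(name, params, outputs, compute) {
    rec <- manifest$stages[[name]]
    files <- file.path(out_dir, outputs)
    param_json <- as.character(jsonlite::toJSON(params, auto_unbox = TRUE,
                                                digits = NA))
    fresh <- !is.null(rec) &&
      identical(rec$param_json, param_json) &&
      all(file.exists(files)) &&
      identical(unname(tools::md5sum(files)), unname(unlist(rec$md5)))
    t0 <- Sys.time()
    res <- tryCatch(
      compute(skip = fresh),
      error = function(e) abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    )
    manifest$stages[[name]] <<- list(
      param_json = param_json,
      outputs = outputs,
      md5 = as.list(tools::md5sum(files)),
      seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")),
      skipped = fresh
    )
    res
  }
  tsv <- function(x, f) {
    write.table(x, file.path(out_dir, f), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }

  ## simulate ----------------------------------------------------------------
  stage("simulate", config$simulate, c("demo.ped", "demo.map", "truth_ancestry.tsv"),
        function(skip) {
    demo <- make_demo(config$seed, dir = if (skip) NULL else out_dir,
                      config = config)
    state$panel <- demo$panel
    state$genotypes <- demo$genotypes
    state$truth <- demo$truth
    invisible(NULL)
  })

  ## qc ----------------------------------------------------------------------
  stage("qc", config$qc, "qc_report.tsv", function(skip) {
    qc <- qc_filter(state$genotypes,
                    max_snp_missing = config$qc$max_snp_missing,
                    max_ind_missing = config$qc$max_ind_missing,
                    min_maf = config$qc$min_maf)
    tsv(qc$report, "qc_report.tsv")
    state$genotypes_qc <- qc$genotypes
    # haplotype panel restricted to the SNPs passing QC
    keep <- match(qc$genotypes$snps$id, state$panel$snps$id)
    state$panel_qc <- hap_panel(state$panel$haps[, keep, drop = FALSE],
                                state$panel$snps[keep, ], state$panel$samples)
    invisible(NULL)
  })

  ## prune -------------------------------------------------------------------
  stage("prune", config$prune, "pruned_snps.tsv", function(skip) {
    kept <- ld_prune(state$genotypes_qc, r2_max = config$prune$r2_max,
                     window_snps = config$prune$window_snps,
                     step_snps = config$prune$step_snps)
    tsv(tibble(id = kept), "pruned_snps.tsv")
    state$genotypes_pruned <- subset_geno(state$genotypes_qc, snps = kept)
    invisible(NULL)
  })

  ## allele-frequency statistics ----------------------------------------------
  stage("popstats", list(), c("fst_pairs.tsv", "pca_scores.tsv", "roh_segments.tsv"),
        function(skip) {
    pf <- pairwise_fst(state$genotypes_pruned)
    tsv(pf, "fst_pairs.tsv")
    pca <- pca_genotypes(state$genotypes_pruned, n_components = 5)
    tsv(pca$scores, "pca_scores.tsv")
    roh <- detect_roh(state$genotypes_qc, window_snps = 50, min_kb = 100,
                      min_seg_snps = 25)
    tsv(roh, "roh_segments.tsv")
    invisible(NULL)
  })

  ## f3 admixture scan ---------------------------------------------------------
  stage("fstats", list(), "f3_scan.tsv", function(skip) {
    ft <- allele_freqs(state$genotypes_qc)
    pops <- unique(state$genotypes_qc$samples$pop)
    sources <- grep("^Src", pops, value = TRUE)
    targets <- setdiff(pops, sources)
    rows <- list()
    for (tg in targets) {
      for (k in seq_len(length(sources) - 1L)) {
        for (l in seq((k + 1L), length(sources))) {
          rows[[length(rows) + 1L]] <-
            f3(ft, sources[k], sources[l], tg, block_cm = 10)
        }
      }
    }
    tsv(bind_rows(lapply(rows, as_tibble)), "f3_scan.tsv")
    invisible(NULL)
  })

  ## painting ------------------------------------------------------------------
  stage("paint", config$paint, c("chunk_counts.tsv", "chunk_lengths.tsv"),
        function(skip) {
    if (skip) {
      cc <- as.matrix(read.table(file.path(out_dir, "chunk_counts.tsv"),
                                 check.names = FALSE))
      cl <- as.matrix(read.table(file.path(out_dir, "chunk_lengths.tsv"),
                                 check.names = FALSE))
      span <- sum(vapply(split(state$panel_qc$snps$cm, state$panel_qc$snps$chrom),
                         function(x) diff(range(x)), numeric(1)))
      state$coancestry <- structure(
        list(chunk_counts = cc, chunk_lengths_cm = cl,
             samples = state$panel_qc$samples, map_cm = span),
        class = "coancestry")
    } else {
      co <- paint_all_vs_all(state$panel_qc, rho = config$paint$rho,
                             mu = config$paint$mu)
      state$coancestry <- co
      write.table(co$chunk_counts, file.path(out_dir, "chunk_counts.tsv"),
                  sep = "\t", quote = FALSE)
      write.table(co$chunk_lengths_cm, file.path(out_dir, "chunk_lengths.tsv"),
                  sep = "\t", quote = FALSE)
    }
    invisible(NULL)
  })

  ## clustering + refinement ----------------------------------------------------
  stage("cluster", c(config$cluster, config$refine), "clusters.tsv", function(skip) {
    vectors <- copying_vectors(state$coancestry, drop_self = FALSE)
    bt <- build_tree(vectors, k = config$cluster$k)
    ref1 <- refine_tree_size(bt$assignment, vectors,
                             config$refine$max_branch_clusters,
                             config$refine$min_cluster_individuals)
    ref2 <- refine_tree_tvd(ref1, vectors,
                            threshold = config$refine$tvd_threshold,
                            max_pool = config$refine$max_pool,
                            direction = config$refine$direction)
    state$assignment <- ref2
    write_assignment(ref2, file.path(out_dir, "clusters.tsv"))
    invisible(NULL)
  })

  ## TVD heterogeneity -----------------------------------------------------------
  stage("tvd", list(), "tvd_levels.tsv", function(skip) {
    vec_cl <- copying_vectors(state$coancestry, state$assignment,
                              drop_self = length(unique(state$assignment$cluster)) > 1)
    groups <- setNames(state$panel_qc$samples$pop, state$panel_qc$samples$id)
    focal <- grep("^Adm", unique(groups), value = TRUE)
    tl <- tvd_levels(vec_cl, state$assignment, groups, focal, basis = "counts")
    tsv(tl$pairs, "tvd_levels.tsv")
    invisible(NULL)
  })

  ## NNLS ancestry ---------------------------------------------------------------
  stage("nnls", config$nnls, "ancestry_profiles.tsv", function(skip) {
    vec_cl <- copying_vectors(state$coancestry, state$assignment,
                              drop_self = length(unique(state$assignment$cluster)) > 1)
    # sources: the clusters dominated by source-population individuals
    groups <- setNames(state$panel_qc$samples$pop, state$panel_qc$samples$id)
    ass <- state$assignment
    dom <- ass |>
      mutate(pop = groups[.data$id]) |>
      group_by(.data$cluster) |>
      summarise(src_frac = mean(startsWith(.data$pop, "Src")), .groups = "drop")
    src_clusters <- dom$cluster[dom$src_frac > 0.5]
    prof <- if (length(src_clusters) >= 2) {
      cluster_profiles(vec_cl, ass, src_clusters)
    } else {
      tibble(target = character(), target_type = character(),
             source = character(), weight = numeric(), residual = numeric())
    }
    tsv(prof, "ancestry_profiles.tsv")
    invisible(NULL)
  })

  ## dating (toggled off by leaving `config$dating` NULL) -----------------------
  if (!is.null(config$dating)) stage("dating", config$dating, "admixture_dates.tsv", function(skip) {
    pops <- unique(state$genotypes_qc$samples$pop)
    adm <- grep("^Adm", pops, value = TRUE)
    rows <- list()
    for (grp in adm) {
      props <- config$simulate$admixed_groups[[grp]]$proportions
      refs <- names(sort(props, decreasing = TRUE))[1:2]
      tg <- subset_geno(state$genotypes_qc,
                        samples = which(state$genotypes_qc$samples$pop == grp))
      ft <- allele_freqs(state$genotypes_qc)
      curve <- weighted_ld_curve(tg, ft$freq[refs[1], ], ft$freq[refs[2], ],
                                 bin_width_cm = config$dating$bin_width_cm,
                                 d_min_cm = config$dating$d_min_cm,
                                 d_max_cm = config$dating$d_max_cm)
      fit <- fit_exp_decay(curve)
      rows[[grp]] <- glance(fit) |> mutate(group = grp, .before = 1)
    }
    tsv(bind_rows(rows), "admixture_dates.tsv")
    invisible(NULL)
  })

  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}
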