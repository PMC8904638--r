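#' FST heatmap
#'
#' @param pf Output of [pairwise_fst()].
#' @param clip Floor negative estimates at zero for display (default TRUE).
#' @return A ggplot.
#' @export
plot_fst_heatmap <- function(pf, clip = TRUE) {
  m <- fst_matrix(pf)
  dat <- as_tibble(as.table(m), .name_repair = ~c("pop1", "pop2", "fst"))
  if (clip) dat$fst <- pmax(dat$fst, 0)
  ggplot2::ggplot(dat, ggplot2::aes(.data$pop1, .data$pop2, fill = .data$fst)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "FST") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' RoH burden scatter (mean segment count vs mean total length per group)
#'
#' @param summary Output of [roh_summary()].
#' @return A ggplot.
#' @export
plot_roh_summary <- function(summary) {
  ggplot2::ggplot(summary$groups,
                  ggplot2::aes(.data$mean_total_kb, .data$mean_n_segments,
                               label = .data$group)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.8, size = 3) +
    ggplot2::labs(x = "mean total RoH length (kb)",
                  y = "mean number of RoH segments") +
    ggplot2::theme_minimal()
}

#' Weighted-LD decay curve
#'
#' @param object A `wld_curve` from [weighted_ld_curve()].
#' @param ... Passed to `geom_point()`.
#' @return A ggplot.
#' @export
autoplot.wld_curve <- function(object, ...) {
  dat <- as_tibble(object) |> filter(.data$n_pairs > 0)
  ggplot2::ggplot(dat, ggplot2::aes(.data$bin_cm, .data$a)) +
    ggplot2::geom_point(...) +
    ggplot2::labs(x = "genetic distance (cM)", y = "weighted LD a(d)") +
    ggplot2::theme_minimal()
}

#' Per-cluster TVD distributions at the three analysis levels
#'
#' @param tl Output of [tvd_levels()].
#' @return A ggplot.
#' @export
plot_tvd_levels <- function(tl) {
  ggplot2::ggplot(tl$pairs,
                  ggplot2::aes(.data$cluster, .data$tvd, fill = .data$level)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(x = NULL, y = "pairwise TVD", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Forest plot of f-statistic scans
#'
#' @param fstats A tibble of stacked `fstat` rows (e.g. several [f3()] calls).
#' @return A ggplot.
#' @export
plot_fstat_scan <- function(fstats) {
  dat <- as_tibble(fstats) |>
    mutate(label = paste(.data$statistic, .data$pops))
  ggplot2::ggplot(dat, ggplot2::aes(.data$estimate, .data$label)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$estimate - 3 * .data$se,
                   xmax = .data$estimate + 3 * .data$se),
      height = 0.2
    ) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "estimate (whiskers: ±3 SE)", y = NULL) +
    ggplot2::theme_minimal()
}
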