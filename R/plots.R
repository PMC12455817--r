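#' Plot a LOD curve
#'
#' @param scan An [hk_scan()] result.
#' @param phenotype Scan column to plot.
#' @param threshold Optional significance threshold line.
#' @return A ggplot.
#' @export
plot_lod_curve <- function(scan, phenotype = 1, threshold = NULL) {
  df <- scan$grid |> mutate(lod = scan$lod[, phenotype])
  p <- ggplot(df, aes(x = .data$pos / 1e6, y = .data$lod)) +
    geom_line() +
    facet_wrap(~chrom, nrow = 1, scales = "free_x") +
    labs(x = "position (Mbp)", y = "LOD") +
    theme_bw()
  if (!is.null(threshold)) p <- p + geom_hline(yintercept = threshold,
                                               linetype = 2)
  p
}

#' @exportS3Method ggplot2::autoplot
autoplot.eqtl_scan <- function(object, phenotype = 1, threshold = NULL, ...) {
  plot_lod_curve(object, phenotype = phenotype, threshold = threshold)
}

#' Boxplots of per-hybrid SPE pattern counts
#'
#' @param spe_summary [summarize_spe()] tibble.
#' @return A ggplot.
#' @export
plot_spe_patterns <- function(spe_summary) {
  ggplot(spe_summary, aes(x = .data$pattern, y = .data$n)) +
    geom_boxplot() +
    labs(x = "SPE pattern", y = "genes per hybrid") +
    theme_bw()
}

#' Heterosis distribution across hybrids
#'
#' @param heterosis [compute_heterosis()] tibble.
#' @param which `"mph_pct"` or `"bph_pct"`.
#' @return A ggplot.
#' @export
plot_heterosis <- function(heterosis, which = c("mph_pct", "bph_pct")) {
  which <- match.arg(which)
  ggplot(heterosis, aes(x = .data[[which]])) +
    ggplot2::geom_histogram(bins = 30) +
    geom_hline(yintercept = 0) +
    labs(x = if (which == "mph_pct") "mid-parent heterosis (%)"
         else "better-parent heterosis (%)", y = "hybrids") +
    theme_bw()
}

#' Active-gene count against heterozygosity fraction
#'
#' @param counts Tibble `genotype`, `n_active`.
#' @param het_fractions Tibble `genotype`, `het_fraction`.
#' @return A ggplot.
#' @export
plot_activity_heterozygosity <- function(counts, het_fractions) {
  df <- counts |> inner_join(het_fractions, by = "genotype")
  ggplot(df, aes(x = .data$het_fraction, y = .data$n_active)) +
    geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    labs(x = "heterozygous genome fraction", y = "active genes") +
    theme_bw()
}
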