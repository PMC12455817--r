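#' Transcriptome-wide association scan (simplified per-gene model)
#'
#' Associates a phenotypic trait with gene expression within one
#' population. Genes are filtered to those active in at least 5% of the
#' genotypes, expression is rescaled to `[0, 2]` per gene within the
#' population, and each gene is tested in a linear model of the trait on
#' its rescaled expression adjusting for the first three expression
#' principal components. Family-wise error is controlled by Bonferroni at
#' 0.05. This deliberately simplified single-locus model (no kinship
#' matrix, no multi-locus forward selection) is not expected to reproduce
#' hit lists of multi-locus mixed-model software.
#'
#' @param expr Genotypes x genes expression matrix (genotype means).
#' @param trait Named numeric vector of genotype trait values (model-scale
#'   adjusted means).
#' @param activity Logical genes x genotypes matrix for the activity
#'   filter (`NULL` to skip filtering).
#' @param min_active_frac Activity filter threshold.
#' @param n_pcs Number of expression principal components.
#' @param alpha Family-wise error rate for the Bonferroni cutoff.
#' @return Tibble `gene_id`, `estimate`, `p_value`, `n_tested`,
#'   `bonferroni_cutoff`, `passes_bonferroni`.
#' @export
twas_scan <- function(expr, trait, activity = NULL, min_active_frac = 0.05,
                      n_pcs = 3, alpha = 0.05) {
  expr <- as.matrix(expr)
  common <- intersect(rownames(expr), names(trait))
  if (length(common) < 4) abort("need >= 4 genotypes with trait values")
  expr <- expr[common, , drop = FALSE]
  trait <- trait[common]
  if (!is.null(activity)) {
    frac <- rowMeans(activity[colnames(expr), common, drop = FALSE])
    expr <- expr[, frac >= min_active_frac, drop = FALSE]
  }
  if (ncol(expr) == 0) abort("no genes pass the activity filter")
  resc <- apply(expr, 2, function(x) {
    rng <- range(x)
    if (diff(rng) == 0) rep(0, length(x)) else (x - rng[1]) / diff(rng) * 2
  })
  n_pcs <- min(n_pcs, nrow(resc) - 2L, ncol(resc))
  pcs <- prcomp(resc, center = TRUE, scale. = FALSE)$x[, seq_len(n_pcs),
                                                       drop = FALSE]
  res <- purrr::map_dfr(seq_len(ncol(resc)), function(j) {
    x <- resc[, j]
    if (sd(x) == 0) {
      return(tibble(gene_id = colnames(resc)[j], estimate = NA_real_,
                    p_value = NA_real_))
    }
    fit <- lm(trait ~ x + pcs)
    cf <- summary(fit)$coefficients
    if (!"x" %in% rownames(cf)) {
      return(tibble(gene_id = colnames(resc)[j], estimate = NA_real_,
                    p_value = NA_real_))
    }
    tibble(gene_id = colnames(resc)[j], estimate = cf["x", 1],
           p_value = cf["x", 4])
  })
  n_tested <- sum(!is.na(res$p_value))
  res |>
    mutate(n_tested = n_tested,
           bonferroni_cutoff = alpha / n_tested,
           passes_bonferroni = !is.na(.data$p_value) &
             .data$p_value < .data$bonferroni_cutoff)
}

#' Nominate TWAS-and-SPE (TSG) genes
#'
#' A TWAS hit that shows SPE complementation in more than `min_hybrids`
#' hybrids is a TSG candidate.
#'
#' @param twas_hits [twas_scan()] result.
#' @param assignments SPE assignment tibble
#'   ([classify_spe()]/[classify_spe_all()]).
#' @param min_hybrids Strict lower bound on the SPE hybrid count.
#' @return Tibble `gene_id`, `n_hybrids_with_spe`, `dominant_pattern`,
#'   `p_value`, `is_tsg`.
#' @export
identify_tsg <- function(twas_hits, assignments, min_hybrids = 10) {
  spe_levels <- c(as.character(1:8), "REF_SPE_MATERNAL", "REF_SPE_PATERNAL",
                  "UNCLASSIFIED")
  spe_by_gene <- assignments |>
    filter(.data$pattern %in% spe_levels) |>
    group_by(.data$gene_id) |>
    summarise(
      n_hybrids_with_spe = dplyr::n_distinct(.data$hybrid_id),
      dominant_pattern = names(sort(table(.data$pattern),
                                    decreasing = TRUE))[1],
      .groups = "drop"
    )
  twas_hits |>
    left_join(spe_by_gene, by = "gene_id") |>
    mutate(
      n_hybrids_with_spe = dplyr::coalesce(.data$n_hybrids_with_spe, 0L),
      is_tsg = .data$passes_bonferroni & .data$n_hybrids_with_spe > min_hybrids
    ) |>
    select("gene_id", "n_hybrids_with_spe", "dominant_pattern", "p_value",
           "is_tsg")
}

#' Trait difference by gene activity
#'
#' Equal-variance two-sample Student's t-test of the trait between hybrids
#' in which the gene is active and hybrids in which it is inactive.
#'
#' @param trait Named trait values per hybrid.
#' @param active Named logical activity per hybrid.
#' @return Tibble `statistic`, `df`, `p_value`, `mean_on`, `mean_off`,
#'   `direction`.
#' @export
activity_trait_test <- function(trait, active) {
  common <- intersect(names(trait), names(active))
  on <- trait[common][active[common]]
  off <- trait[common][!active[common]]
  if (length(on) < 2 || length(off) < 2) {
    abort("each activity group needs >= 2 hybrids")
  }
  if (sd(c(on - mean(on), off - mean(off))) == 0) {
    # degenerate within-group variance: t is 0 (equal means) or infinite
    same <- isTRUE(all.equal(mean(on), mean(off)))
    tt <- list(statistic = if (same) 0 else sign(mean(on) - mean(off)) * Inf,
               parameter = length(on) + length(off) - 2,
               p.value = if (same) 1 else 0)
  } else {
    tt <- t.test(on, off, var.equal = TRUE)
  }
  tibble(
    statistic = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value, mean_on = mean(on), mean_off = mean(off),
    direction = if_else(mean(on) > mean(off), "higher_when_active",
                        "lower_when_active")
  )
}

#' Synteny enrichment of cis vs trans regulation
#'
#' Two-sided Fisher's exact test on the 2x2 table of regulation (cis,
#' trans) by synteny status.
#'
#' @param gene_table Tibble with `regulation` (`"cis"`/`"trans"`) and
#'   logical `syntenic` per gene.
#' @return Tibble `odds_ratio`, `p_value`, and the four cell counts.
#' @export
synteny_enrichment <- function(gene_table) {
  tab <- table(
    factor(gene_table$regulation, levels = c("cis", "trans")),
    factor(if_else(gene_table$syntenic, "syntenic", "non_syntenic"),
           levels = c("syntenic", "non_syntenic"))
  )
  ft <- fisher.test(tab, alternative = "two.sided")
  tibble(
    odds_ratio = unname(ft$estimate), p_value = ft$p.value,
    cis_syntenic = tab["cis", "syntenic"],
    cis_non_syntenic = tab["cis", "non_syntenic"],
    trans_syntenic = tab["trans", "syntenic"],
    trans_non_syntenic = tab["trans", "non_syntenic"]
  )
}
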