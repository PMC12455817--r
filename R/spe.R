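#' Classify single-parent-expression patterns for one hybrid
#'
#' A gene shows SPE when it is active in the hybrid and in exactly one
#' parent. In backcross hybrids the pattern number encodes the genomic
#' constitution of the gene (heterozygous vs homozygous, from the RIL
#' mosaic) and which parent is active: patterns 1-4 for B73 x RIL hybrids
#' (1 = heterozygous/maternal B73 active, 2 = heterozygous/paternal RIL
#' active, 3 = homozygous B73/maternal active, 4 = homozygous B73/paternal
#' active) and the mirrored 5-8 for Mo17 x RIL hybrids. In the fully
#' heterozygous reference hybrids SPE is labelled by the active parent
#' only. SPE genes whose zygosity is masked or unknown are `UNCLASSIFIED`;
#' genes active in both or neither parent are `NON_SPE`.
#'
#' @param activity Logical genes x genotypes matrix ([call_activity()]).
#' @param hybrid,maternal,paternal Genotype (column) names.
#' @param cross `"B73xRIL"`, `"MO17xRIL"`, or `"REF"` for the fully
#'   heterozygous reference hybrids.
#' @param zygosity Tibble `gene_id`, `zygosity` from
#'   [annotate_gene_zygosity()] (ignored for `cross = "REF"`).
#' @return Tibble `hybrid_id`, `gene_id`, `pattern`, `zygosity`,
#'   `active_parent`.
#' @export
classify_spe <- function(activity, hybrid, maternal, paternal,
                         cross = c("B73xRIL", "MO17xRIL", "REF"),
                         zygosity = NULL) {
  cross <- match.arg(cross)
  stopifnot(all(c(hybrid, maternal, paternal) %in% colnames(activity)))
  genes <- rownames(activity)
  h <- activity[, hybrid]
  m <- activity[, maternal]
  p <- activity[, paternal]
  spe <- h & (m != p)
  active_parent <- ifelse(!spe, NA_character_,
                          ifelse(m, "maternal", "paternal"))
  if (cross == "REF") {
    pattern <- ifelse(!spe, "NON_SPE",
                      ifelse(m, "REF_SPE_MATERNAL", "REF_SPE_PATERNAL"))
    zyg <- rep("HET", length(genes))
  } else {
    stopifnot(!is.null(zygosity))
    zyg <- zygosity$zygosity[match(genes, zygosity$gene_id)]
    zyg[is.na(zyg)] <- "NO_INFO"
    hom_label <- if (cross == "B73xRIL") "HOM_B73" else "HOM_MO17"
    base <- if (cross == "B73xRIL") 0L else 4L
    num <- ifelse(zyg == "HET", ifelse(m, 1L, 2L),
                  ifelse(zyg == hom_label, ifelse(m, 3L, 4L), NA_integer_))
    pattern <- ifelse(!spe, "NON_SPE",
                      ifelse(is.na(num), "UNCLASSIFIED",
                             as.character(base + num)))
  }
  tibble(hybrid_id = hybrid, gene_id = genes, pattern = unname(pattern),
         zygosity = unname(zyg), active_parent = unname(active_parent))
}

#' Classify SPE for every hybrid of a simulated or assembled cross
#'
#' @param activity Genes x genotypes activity matrix.
#' @param manifest Genotype manifest (`sample`, `type`, `ril_id`) whose
#'   `sample` labels match activity columns.
#' @param zygosity_by_hybrid Named list: for each backcross hybrid
#'   genotype, its gene-zygosity tibble.
#' @return Long SPE assignment tibble (rows = hybrid x gene).
#' @export
classify_spe_all <- function(activity, manifest, zygosity_by_hybrid) {
  hyb <- manifest |> filter(.data$type %in% c("B73xRIL", "MO17xRIL"))
  purrr::map_dfr(seq_len(nrow(hyb)), function(i) {
    type <- hyb$type[i]
    ril_geno <- manifest$sample[manifest$type == "RIL" &
                                  manifest$ril_id == hyb$ril_id[i]]
    maternal <- if (type == "B73xRIL") {
      manifest$sample[manifest$type == "B73"][1]
    } else {
      manifest$sample[manifest$type == "MO17"][1]
    }
    classify_spe(activity, hyb$sample[i], maternal, ril_geno[1],
                 cross = type, zygosity = zygosity_by_hybrid[[hyb$sample[i]]])
  })
}

#' Per-hybrid SPE pattern counts
#'
#' @param assignments Long tibble from [classify_spe()]/[classify_spe_all()].
#' @return Tibble `hybrid_id`, `pattern`, `n` plus per-hybrid `total`
#'   (total SPE genes across numbered patterns and `UNCLASSIFIED`).
#' @export
summarize_spe <- function(assignments) {
  spe_levels <- c(as.character(1:8), "REF_SPE_MATERNAL", "REF_SPE_PATERNAL",
                  "UNCLASSIFIED")
  hybrids <- unique(assignments$hybrid_id)
  present <- intersect(spe_levels, unique(assignments$pattern))
  if (length(present) == 0) present <- "1"
  counts <- assignments |>
    filter(.data$pattern %in% spe_levels) |>
    count(.data$hybrid_id, .data$pattern)
  tidyr::expand_grid(hybrid_id = hybrids, pattern = present) |>
    left_join(counts, by = c("hybrid_id", "pattern")) |>
    mutate(n = dplyr::coalesce(.data$n, 0L)) |>
    group_by(.data$hybrid_id) |>
    mutate(total = sum(.data$n)) |>
    ungroup()
}

#' Test for differences between SPE pattern counts
#'
#' Fits a Gaussian mixed model to the per-hybrid pattern counts with the
#' hybrid as random effect, the pattern as fixed factor and a separate
#' (diagonal) residual variance per pattern, then reports Wald contrasts
#' between all pattern pairs.
#'
#' @param pattern_counts Tibble `hybrid_id`, `pattern`, `n` (e.g. from
#'   [summarize_spe()], optionally including a non-SPE count per hybrid as
#'   one more level).
#' @return Object of class `spe_pattern_test`: list with `means` (per
#'   pattern), `contrasts` tibble (`contrast`, `estimate`, `se`,
#'   `statistic`, `df`, `p_value`) and the underlying fit.
#' @export
pattern_count_test <- function(pattern_counts) {
  df <- pattern_counts |>
    mutate(pattern = factor(.data$pattern), hybrid_id = factor(.data$hybrid_id))
  if (length(unique(df$hybrid_id)) < 2) abort("need >= 2 hybrids")
  fit <- tryCatch(
    nlme::lme(n ~ 0 + pattern, random = ~ 1 | hybrid_id,
              weights = nlme::varIdent(form = ~ 1 | pattern),
              data = df, method = "REML",
              control = nlme::lmeControl(opt = "optim", returnObject = TRUE)),
    error = function(e) tryCatch(
      nlme::lme(n ~ 0 + pattern, random = ~ 1 | hybrid_id, data = df,
                method = "REML",
                control = nlme::lmeControl(returnObject = TRUE)),
      error = function(e2) stats::lm(n ~ 0 + pattern, data = df)
    )
  )
  b <- if (inherits(fit, "lme")) nlme::fixef(fit) else coef(fit)
  V <- vcov(fit)
  lev <- levels(df$pattern)
  prs <- utils::combn(seq_along(lev), 2)
  dfree <- if (inherits(fit, "lme")) {
    length(unique(df$hybrid_id)) - 1
  } else {
    stats::df.residual(fit)
  }
  contrasts <- purrr::map_dfr(seq_len(ncol(prs)), function(k) {
    i <- prs[1, k]; j <- prs[2, k]
    est <- b[i] - b[j]
    se <- sqrt(V[i, i] + V[j, j] - 2 * V[i, j])
    stat <- if (se > 0) est / se else 0
    tibble(contrast = paste(lev[i], "-", lev[j]), estimate = unname(est),
           se = unname(se), statistic = unname(stat), df = dfree,
           p_value = 2 * pt(-abs(stat), dfree))
  })
  structure(list(means = setNames(unname(b), lev), contrasts = contrasts,
                 fit = fit),
            class = "spe_pattern_test")
}

#' @exportS3Method generics::tidy
tidy.spe_pattern_test <- function(x, ...) x$contrasts

#' @export
print.spe_pattern_test <- function(x, ...) {
  cat("<spe_pattern_test> pattern means:\n")
  print(round(x$means, 1))
  print(x$contrasts)
  invisible(x)
}

#' Active-gene counts and their relation to heterozygosity
#'
#' Counts active genes per genotype and, for backcross hybrids, correlates
#' the count with the heterozygous genome fraction.
#'
#' @param activity Genes x genotypes activity matrix.
#' @param het_fractions Tibble `genotype`, `het_fraction` for hybrids
#'   (optional).
#' @return List: `counts` tibble (`genotype`, `n_active`), `correlation`
#'   (`estimate`, `p_value`; `NA` when undefined).
#' @export
active_gene_summary <- function(activity, het_fractions = NULL) {
  counts <- tibble(genotype = colnames(activity),
                   n_active = colSums(activity))
  correlation <- tibble(estimate = NA_real_, p_value = NA_real_)
  if (!is.null(het_fractions)) {
    dd <- counts |> inner_join(het_fractions, by = "genotype")
    if (nrow(dd) >= 3 && sd(dd$n_active) > 0 && sd(dd$het_fraction) > 0) {
      ct <- cor.test(dd$n_active, dd$het_fraction)
      correlation <- tibble(estimate = unname(ct$estimate),
                            p_value = ct$p.value)
    }
  }
  list(counts = counts, correlation = correlation)
}
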