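#' Variance-stabilizing trait transform
#'
#' Size-like root traits (total length, total volume, number of tips) are
#' square-root transformed after adding an offset of 0.5; lateral root
#' density is analysed untransformed. [inverse_transform_trait()] maps
#' model-scale values back for reporting.
#'
#' @param values Numeric trait values.
#' @param trait One of `"root_tips"`, `"root_length"`, `"root_volume"`,
#'   `"lateral_root_density"`.
#' @param offset Offset added before the square root.
#' @return Transformed values.
#' @export
transform_trait <- function(values,
                            trait = c("root_tips", "root_length",
                                      "root_volume", "lateral_root_density"),
                            offset = 0.5) {
  trait <- match.arg(trait)
  if (trait == "lateral_root_density") values else sqrt(values + offset)
}

#' @rdname transform_trait
#' @export
inverse_transform_trait <- function(values,
                                    trait = c("root_tips", "root_length",
                                              "root_volume",
                                              "lateral_root_density"),
                                    offset = 0.5) {
  trait <- match.arg(trait)
  if (trait == "lateral_root_density") values else values^2 - offset
}

design_random_terms <- function(records,
                                candidates = c("batch_id", "system_id",
                                               "triplet_id", "row_id")) {
  present <- intersect(candidates, names(records))
  keep <- present[purrr::map_lgl(present, function(v) {
    length(unique(records[[v]])) >= 2
  })]
  keep
}

#' Fit the baseline phenotype model
#'
#' REML fit of the design model: fixed genotype and block effects, nested
#' random effects for batch, system, triplet and row, residual within-row
#' variance. Returns genotype adjusted means (genotype effect plus the
#' average block effect).
#'
#' @param records Plant-level tibble with `value`, `genotype`, `block` and
#'   the nested design labels `batch_id`, `system_id`, `triplet_id`,
#'   `row_id` (missing or single-level terms are dropped).
#' @return Object of class `baseline_fit`: list with `means` (tibble
#'   `genotype`, `mean`, `n_obs`, `unreplicated`), `varcomp`, `fit`.
#' @export
fit_baseline_model <- function(records) {
  df <- as.data.frame(records)
  df$genotype <- factor(df$genotype)
  fixed <- "0 + genotype"
  if (length(unique(df$block)) >= 2) {
    df$blockf <- factor(df$block)
    fixed <- paste(fixed, "+ blockf")
  } else {
    warn("single block level: block effect inestimable, dropped")
  }
  rand <- design_random_terms(df)
  fml <- stats::as.formula(paste(
    "value ~", fixed,
    if (length(rand) > 0) paste0(" + ", paste0("(1 | ", rand, ")",
                                               collapse = " + ")) else ""
  ))
  fit <- if (length(rand) > 0) {
    lme4::lmer(fml, data = df, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore",
                                           calc.derivs = FALSE))
  } else {
    lm(fml, data = df)
  }
  fe <- if (inherits(fit, "merMod")) lme4::fixef(fit) else coef(fit)
  gl <- levels(df$genotype)
  gmean <- fe[paste0("genotype", gl)]
  blk <- fe[grepl("^blockf", names(fe))]
  adj <- unname(gmean) + mean(c(0, unname(blk)))
  nobs <- table(df$genotype)[gl]
  vc <- if (inherits(fit, "merMod")) {
    vcdf <- as.data.frame(lme4::VarCorr(fit))
    tibble(component = vcdf$grp, variance = vcdf$vcov)
  } else {
    tibble(component = "Residual", variance = summary(fit)$sigma^2)
  }
  structure(
    list(
      means = tibble(genotype = gl, mean = adj, n_obs = as.integer(nobs),
                     unreplicated = as.integer(nobs) < 2),
      varcomp = vc,
      fit = fit
    ),
    class = "baseline_fit"
  )
}

#' @exportS3Method generics::tidy
tidy.baseline_fit <- function(x, ...) x$means

#' @exportS3Method generics::glance
glance.baseline_fit <- function(x, ...) {
  x$varcomp |> pivot_wider(names_from = "component", values_from = "variance")
}

#' Mid-parent and better-parent heterosis
#'
#' MPH% = 100 (H - MP) / MP with MP the parental mean; BPH% = 100 (H - BP)
#' / BP with BP the better (larger) parent value.
#'
#' @param means Tibble `genotype`, `mean` (e.g. `tidy()` of a
#'   [fit_baseline_model()] fit).
#' @param pedigree Tibble `genotype`, `parent1`, `parent2`.
#' @return Tibble `genotype`, `hybrid`, `mid_parent`, `better_parent`,
#'   `mph_pct`, `bph_pct`, one row per hybrid.
#' @export
compute_heterosis <- function(means, pedigree) {
  mv <- setNames(means$mean, means$genotype)
  pedigree |>
    filter(!is.na(.data$parent1), !is.na(.data$parent2)) |>
    filter(.data$genotype %in% names(mv), .data$parent1 %in% names(mv),
           .data$parent2 %in% names(mv)) |>
    mutate(
      hybrid = unname(mv[.data$genotype]),
      mid_parent = unname(mv[.data$parent1] + mv[.data$parent2]) / 2,
      better_parent = unname(pmax(mv[.data$parent1], mv[.data$parent2])),
      mph_pct = 100 * (.data$hybrid - .data$mid_parent) / .data$mid_parent,
      bph_pct = 100 * (.data$hybrid - .data$better_parent) /
        .data$better_parent
    ) |>
    select("genotype", "hybrid", "mid_parent", "better_parent", "mph_pct",
           "bph_pct")
}

#' Build the covariate rows for the heterosis regression
#'
#' Every observation gets one covariate per parental genotype: a parent's
#' own covariate is 1 (others 0); a hybrid observation carries 0.5 on each
#' of its two parents under mid-parent heterosis, or 1 on the better parent
#' and 0 on the other under better-parent heterosis. SPE-pattern counts
#' `sa`..`sd` are attached to hybrid observations and 0 for parents; the
#' hybrid dummy `z` is 1 for hybrids. Block enters as dummies for blocks
#' 2..k with block 1 as reference (no intercept).
#'
#' @param records Plant-level tibble (`value`, `genotype`, `block`, design
#'   labels).
#' @param pedigree Tibble `genotype`, `parent1`, `parent2`.
#' @param spe_counts Tibble `genotype`, `sa`, `sb`, `sc`, `sd` for hybrids.
#' @param mode `"MPH"` or `"BPH"`.
#' @param parent_means Named parental means, required for `mode = "BPH"`
#'   to pick the better parent.
#' @return Data frame with columns `value`, `x_<parent>` covariates,
#'   `blk<j>` dummies, `sa`..`sd`, `z`, `genotype` and design labels;
#'   attribute `"parents"` lists the parent column order.
#' @export
build_heterosis_covariates <- function(records, pedigree, spe_counts,
                                       mode = c("MPH", "BPH"),
                                       parent_means = NULL) {
  mode <- match.arg(mode)
  ped <- pedigree |> filter(!is.na(.data$parent1))
  unknown <- setdiff(c(ped$parent1, ped$parent2), pedigree$genotype)
  if (length(unknown) > 0) {
    abort(paste0("hybrid with unknown parent(s): ",
                 paste(head(unknown, 3), collapse = ", ")))
  }
  if (mode == "BPH" && is.null(parent_means)) {
    abort("parent_means is required for BPH covariates")
  }
  parents <- sort(unique(c(ped$parent1, ped$parent2,
                           setdiff(records$genotype, ped$genotype))))
  df <- as.data.frame(records)
  n <- nrow(df)
  X <- matrix(0, n, length(parents),
              dimnames = list(NULL, paste0("x_", make.names(parents))))
  hyb_idx <- match(df$genotype, ped$genotype)
  is_hyb <- !is.na(hyb_idx)
  for (i in seq_len(n)) {
    g <- df$genotype[i]
    if (!is_hyb[i]) {
      X[i, paste0("x_", make.names(g))] <- 1
    } else {
      p1 <- ped$parent1[hyb_idx[i]]
      p2 <- ped$parent2[hyb_idx[i]]
      if (mode == "MPH") {
        X[i, paste0("x_", make.names(p1))] <- 0.5
        X[i, paste0("x_", make.names(p2))] <- 0.5
      } else {
        better <- if (parent_means[p1] >= parent_means[p2]) p1 else p2
        X[i, paste0("x_", make.names(better))] <- 1
      }
    }
  }
  out <- cbind(df, as.data.frame(X))
  blocks <- sort(unique(df$block))
  for (b in blocks[-1]) out[[paste0("blk", b)]] <- as.numeric(df$block == b)
  sc <- spe_counts[match(df$genotype, spe_counts$genotype), c("sa", "sb", "sc", "sd")]
  sc[is.na(sc)] <- 0
  sc[!is_hyb, ] <- 0
  out$sa <- sc$sa; out$sb <- sc$sb; out$sc <- sc$sc; out$sd <- sc$sd
  out$z <- as.numeric(is_hyb)
  attr(out, "parents") <- colnames(X)
  attr(out, "blocks") <- if (length(blocks) > 1) paste0("blk", blocks[-1]) else character()
  out
}

fit_heterosis_lmm <- function(cov_data, spe_terms) {
  rand <- design_random_terms(cov_data)
  fixed <- c(attr(cov_data, "parents"), attr(cov_data, "blocks"),
             spe_terms, "z")
  fml <- stats::as.formula(paste(
    "value ~ 0 +", paste(fixed, collapse = " + "),
    "+ (0 + z | genotype)",
    if (length(rand) > 0) paste0("+ ", paste0("(1 | ", rand, ")",
                                              collapse = " + ")) else ""
  ))
  fit <- suppressMessages(lme4::lmer(
    fml, data = cov_data, REML = TRUE,
    control = lme4::lmerControl(check.conv.singular = "ignore",
                                calc.derivs = FALSE)
  ))
  vc <- as.data.frame(lme4::VarCorr(fit))
  s2_het <- vc$vcov[vc$grp == "genotype" & !is.na(vc$var1) & vc$var1 == "z"]
  fe <- lme4::fixef(fit)
  list(
    fit = fit,
    sigma2_het = s2_het,
    phi = unname(fe["z"]),
    gamma = fe[intersect(spe_terms, names(fe))],
    beta = fe[intersect(attr(cov_data, "parents"), names(fe))],
    varcomp = tibble(component = paste0(vc$grp,
                                        if_else(is.na(vc$var1), "",
                                                paste0(".", vc$var1))),
                     variance = vc$vcov)
  )
}

#' Fit the full heterosis model (with SPE-count regression)
#'
#' REML mixed model with the parental covariates, block dummies, the four
#' SPE-count slopes, the hybrid intercept `z` and a genotype random effect
#' switched on only for hybrids (`(0 + z | genotype)`), plus the nested
#' design random effects. Its hybrid-deviation variance is the heterotic
#' variance left unexplained by the SPE counts.
#'
#' @param cov_data From [build_heterosis_covariates()].
#' @param shared_slope Fit one common slope on the summed SPE count
#'   instead of four pattern-specific slopes.
#' @return List: `fit`, `sigma2_het`, `phi`, `gamma`, `beta`, `varcomp`.
#' @export
fit_full_model <- function(cov_data, shared_slope = FALSE) {
  if (shared_slope) {
    cov_data$s_total <- cov_data$sa + cov_data$sb + cov_data$sc + cov_data$sd
    fit_heterosis_lmm(cov_data, "s_total")
  } else {
    keep <- c("sa", "sb", "sc", "sd")[vapply(
      cov_data[c("sa", "sb", "sc", "sd")], function(x) sd(x) > 0, logical(1))]
    if (length(keep) < 4) {
      warn(sprintf("dropping constant SPE covariate(s): %s; rank = %d",
                   paste(setdiff(c("sa", "sb", "sc", "sd"), keep),
                         collapse = ", "), length(keep)))
    }
    fit_heterosis_lmm(cov_data, keep)
  }
}

#' Fit the null heterosis model (no SPE-count terms)
#'
#' Identical to [fit_full_model()] with the SPE covariates removed; its
#' hybrid-deviation variance is the total genetic variance among hybrids.
#'
#' @inheritParams fit_full_model
#' @return As [fit_full_model()] (empty `gamma`).
#' @export
fit_null_model <- function(cov_data) {
  fit_heterosis_lmm(cov_data, character())
}

#' Proportion of heterotic variance explained by SPE counts
#'
#' `p_Het = 1 - sigma2_Het / sigma2_G`, where `sigma2_Het` is the hybrid
#' deviation variance of the full model (unexplained by SPE counts) and
#' `sigma2_G` the hybrid deviation variance of the null model (total
#' genetic variance among hybrids). Negative values mean the null model
#' outperformed the full model, not a negative influence of SPE.
#'
#' @param sigma2_het,sigma2_g Variance components (both >= 0, `sigma2_g`
#'   > 0).
#' @return Scalar p_Het (may be negative).
#' @export
compute_p_het <- function(sigma2_het, sigma2_g) {
  if (sigma2_g <= 0) abort("sigma2_g must be > 0; p_Het undefined")
  1 - sigma2_het / sigma2_g
}

#' Decompose heterotic variance into an SPE-explained fraction
#'
#' One-stop wrapper: builds the covariates, fits the full and null models
#' by REML and reports p_Het with the regression coefficients.
#'
#' @inheritParams build_heterosis_covariates
#' @inheritParams fit_full_model
#' @return Object of class `heterosis_phet` with elements `p_het`,
#'   `sigma2_het`, `sigma2_g`, `gamma`, `phi`, `beta`, `varcomp_full`,
#'   `varcomp_null`, `mode`, and the two fits.
#' @export
phet <- function(records, pedigree, spe_counts, mode = c("MPH", "BPH"),
                 parent_means = NULL, shared_slope = FALSE) {
  mode <- match.arg(mode)
  cov_data <- build_heterosis_covariates(records, pedigree, spe_counts,
                                         mode = mode,
                                         parent_means = parent_means)
  full <- fit_full_model(cov_data, shared_slope = shared_slope)
  null <- fit_null_model(cov_data)
  structure(
    list(
      p_het = compute_p_het(full$sigma2_het, null$sigma2_het),
      sigma2_het = full$sigma2_het,
      sigma2_g = null$sigma2_het,
      gamma = full$gamma,
      phi = full$phi,
      beta = full$beta,
      varcomp_full = full$varcomp,
      varcomp_null = null$varcomp,
      mode = mode,
      full_fit = full$fit,
      null_fit = null$fit
    ),
    class = "heterosis_phet"
  )
}

#' @export
print.heterosis_phet <- function(x, digits = 3, ...) {
  cat("<heterosis_phet> mode =", x$mode, "\n")
  cat("  sigma2_Het =", signif(x$sigma2_het, digits),
      " sigma2_G =", signif(x$sigma2_g, digits),
      " p_Het =", round(x$p_het, 2), "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.heterosis_phet <- function(x, ...) {
  bind_rows(
    tibble(term = names(x$gamma), estimate = unname(x$gamma),
           role = "spe_slope"),
    tibble(term = "phi", estimate = x$phi, role = "hybrid_intercept"),
    tibble(term = names(x$beta), estimate = unname(x$beta),
           role = "parental_effect")
  )
}

#' @exportS3Method generics::glance
glance.heterosis_phet <- function(x, ...) {
  tibble(sigma2_het = x$sigma2_het, sigma2_g = x$sigma2_g, p_het = x$p_het,
         mode = x$mode)
}
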