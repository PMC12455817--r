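# Simulation studies used to validate the pipeline against ground truth.
# Each experiment is a pure function of its seed so the same numbers can be
# recomputed by the test suite and the reproduction script.

#' Region-classification recovery experiment
#'
#' Simulates a contaminated RIL population with realistic call noise,
#' classifies the genomes and measures (i) the fraction of non-third-origin
#' genome length assigned its true founder origin and (ii) whether every
#' injected third-origin segment of at least `min_third_bp` is masked.
#'
#' @param n_rils,n_chrom,chrom_mbp,marker_density Population and genome size.
#' @param error_rate,missing_rate,low_gq Call-noise settings.
#' @param third_fraction Fraction of contaminated RILs.
#' @param min_third_bp Minimum injected segment length that must be masked.
#' @param seed Integer seed.
#' @return Tibble with `correct_fraction`, `n_third_segments`,
#'   `n_third_masked`, `all_third_masked`.
#' @export
experiment_region_recovery <- function(n_rils = 12, n_chrom = 3,
                                       chrom_mbp = 30, marker_density = 20,
                                       error_rate = 0.006,
                                       missing_rate = 0.02, low_gq = 0.05,
                                       third_fraction = 0.25,
                                       min_third_bp = 2e6, seed = 1) {
  spec <- genome_spec(
    tibble(chrom = paste0("chr", seq_len(n_chrom)),
           length_bp = rep(chrom_mbp * 1e6, n_chrom)),
    marker_density = marker_density
  )
  map <- build_marker_map(spec, seed = seed)
  mos <- simulate_ril_population(spec, n_rils = n_rils, seed = seed + 1)
  mos <- inject_third_origin(mos, spec,
                             fraction_contaminated_rils = third_fraction,
                             mean_segment_bp = 4e6, seed = seed + 2)
  sim <- simulate_genotype_calls(mos, map, error_rate = error_rate,
                                 missing_rate = missing_rate,
                                 gq_model = list(low_fraction = low_gq,
                                                 high = 99),
                                 seed = seed + 3)
  cls <- classify_ril_regions(sim$calls, sim$manifest)
  reg <- cls$regions
  correct <- 0; assigned <- 0
  for (i in seq_len(nrow(reg))) {
    tr <- mos |>
      filter(.data$ril_id == reg$ril_id[i], .data$chrom == reg$chrom[i],
             .data$end >= reg$start[i], .data$start <= reg$end[i])
    for (j in seq_len(nrow(tr))) {
      ov <- min(tr$end[j], reg$end[i]) - max(tr$start[j], reg$start[i]) + 1
      if (tr$origin[j] != "THIRD") {
        assigned <- assigned + ov
        if (tr$origin[j] == reg$origin[i]) correct <- correct + ov
      }
    }
  }
  third <- mos |> filter(.data$origin == "THIRD",
                         .data$end - .data$start + 1 >= min_third_bp)
  masked_hits <- purrr::map_lgl(seq_len(nrow(third)), function(i) {
    nrow(cls$masked |>
           filter(.data$ril_id == third$ril_id[i],
                  .data$chrom == third$chrom[i],
                  .data$start <= third$end[i],
                  .data$end >= third$start[i])) > 0
  })
  tibble(
    correct_fraction = correct / assigned,
    n_third_segments = nrow(third),
    n_third_masked = sum(masked_hits),
    all_third_masked = all(masked_hits)
  )
}

#' SPE oracle-equivalence experiment
#'
#' With noise off, compares pipeline SPE calls against exhaustive
#' enumeration from the regulatory architecture, restricted to genes whose
#' expressed means clear the activity threshold (so activity is decided by
#' the regulatory mechanism, not expression magnitude).
#'
#' @param n_rils,n_genes Problem size.
#' @param seed Integer seed.
#' @return Tibble with `n_compared`, `n_agree`, `agreement`.
#' @export
experiment_spe_oracle <- function(n_rils = 6, n_genes = 200, seed = 1) {
  spec <- genome_spec(tibble(chrom = paste0("chr", 1:2),
                             length_bp = rep(20e6, 2)))
  mos <- simulate_ril_population(spec, n_rils = n_rils, seed = seed)
  sim <- simulate_genotype_calls(mos, build_marker_map(spec, seed = seed + 1),
                                 error_rate = 0, missing_rate = 0,
                                 gq_model = list(low_fraction = 0, high = 99),
                                 seed = seed + 2)
  genes <- simulate_genes(spec, n_genes = n_genes, seed = seed + 3)
  arch <- regulatory_architecture(genes, spec, silenced_fraction = 0.4,
                                  seed = seed + 4)
  expr <- simulate_expression_counts(
    genes, arch, mos, sim$manifest, nb_dispersion = 0,
    library_sizes = rep(1, nrow(sim$manifest) * 3),
    baseline_meanlog = log(500), baseline_sdlog = 0.2, seed = seed + 5
  )
  act <- call_gene_activity(expr$counts, expr$samples, genes)
  hyb <- sim$manifest |> filter(.data$type %in% c("B73xRIL", "MO17xRIL"))
  zyg <- setNames(purrr::map(seq_len(nrow(hyb)), function(i) {
    org <- mosaic_origin_at(
      mos |> filter(.data$ril_id == hyb$ril_id[i]),
      genes |> mutate(pos = .data$start) |> select("chrom", "pos")
    )
    z <- org$origin[match(paste0(genes$chrom, "_", genes$start),
                          paste0(org$chrom, "_", org$pos))]
    tibble(gene_id = genes$gene_id,
           zygosity = dplyr::case_when(
             hyb$type[i] == "B73xRIL" & z == "MO17" ~ "HET",
             hyb$type[i] == "B73xRIL" & z == "B73" ~ "HOM_B73",
             hyb$type[i] == "MO17xRIL" & z == "B73" ~ "HET",
             hyb$type[i] == "MO17xRIL" & z == "MO17" ~ "HOM_MO17",
             TRUE ~ "NO_INFO"
           ))
  }), hyb$sample)
  got <- classify_spe_all(act$activity, sim$manifest, zyg)
  truth <- true_activity(arch, mos, sim$manifest)
  wide <- truth |>
    select("genotype", "gene_id", "active") |>
    pivot_wider(names_from = "genotype", values_from = "active")
  oracle <- purrr::map_dfr(seq_len(nrow(hyb)), function(i) {
    mat <- if (hyb$type[i] == "B73xRIL") "B73_rep1" else "MO17_rep1"
    h <- wide[[hyb$sample[i]]]
    m <- wide[[mat]]
    p <- wide[[paste0("RIL_", hyb$ril_id[i])]]
    tibble(hybrid_id = hyb$sample[i], gene_id = wide$gene_id,
           spe_true = h & (m != p))
  })
  decided <- rownames(act$means)[apply(act$means, 1, function(m) {
    any(m > 0) && all(m[m > 0] > act$tau)
  })]
  cmp <- got |>
    mutate(spe_called = .data$pattern != "NON_SPE") |>
    inner_join(oracle, by = c("hybrid_id", "gene_id")) |>
    filter(.data$gene_id %in% decided)
  tibble(n_compared = nrow(cmp),
         n_agree = sum(cmp$spe_called == cmp$spe_true),
         agreement = mean(cmp$spe_called == cmp$spe_true))
}

#' p_Het parameter-recovery experiment
#'
#' Generates phenotypes from the generative model with SPE-count slopes
#' scaled so the implied true p_Het hits each target, fits the full and
#' null REML models and reports the mean estimate per target.
#'
#' @param truths Target p_Het values.
#' @param n_hybrids Hybrids per replicate.
#' @param n_reps Replicates per target.
#' @param sigma2_het True unexplained hybrid variance.
#' @param seed Integer seed.
#' @return Tibble `true_p_het`, `mean_estimate`, `sd_estimate`, `n_reps`.
#' @export
experiment_phet_recovery <- function(truths = c(0, 0.15, 0.3),
                                     n_hybrids = 80, n_reps = 100,
                                     sigma2_het = 0.05, seed = 1) {
  ril_ids <- sprintf("R%03d", seq_len(n_hybrids))
  base_gamma <- c(2, 2, 1, 1)
  purrr::map_dfr(truths, function(p_true) {
    est <- purrr::map_dbl(seq_len(n_reps), function(r) {
      sd_off <- round(seed * 1e4 + p_true * 1e3 + r)
      des <- build_experimental_design(ril_ids, plants_per_row = 2,
                                       seed = sd_off)
      des <- des |> filter(.data$type %in% c("B73", "MO17", "RIL", "B73xRIL"))
      parents <- unique(des$genotype[des$type != "B73xRIL"])
      hyb <- unique(des$genotype[des$type == "B73xRIL"])
      withr_seed(sd_off + 1)
      beta <- setNames(rnorm(length(parents), 10, 1), parents)
      spe <- tibble(genotype = hyb,
                    sa = rpois(n_hybrids, 400), sb = rpois(n_hybrids, 300),
                    sc = rpois(n_hybrids, 150), sd = rpois(n_hybrids, 150))
      gamma <- if (p_true == 0) rep(0, 4) else {
        v_target <- p_true * sigma2_het / (1 - p_true)
        v0 <- stats::var(as.matrix(spe[, c("sa", "sb", "sc", "sd")]) %*%
                           base_gamma)[1, 1]
        base_gamma * sqrt(v_target / v0)
      }
      gm <- phenotype_gen_model(
        beta = beta, phi = 1, gamma = gamma,
        sigma2 = c(batch = 0.02, system = 0.02, triplet = 0.02, row = 0.02,
                   het = sigma2_het, resid = 0.1)
      )
      sim <- simulate_phenotypes(des, gm, spe, seed = sd_off + 2)
      ph <- suppressWarnings(
        phet(sim$phenotypes, pedigree_from_design(des), spe)
      )
      ph$p_het
    })
    tibble(true_p_het = p_true, mean_estimate = mean(est),
           sd_estimate = sd(est), n_reps = n_reps)
  })
}

# shared scaffold: RIL genotypes on a grid plus genotype probabilities
eqtl_sim_cross <- function(n_ind, seed, n_chrom = 2, chrom_mbp = 50,
                           marker_density = 2) {
  spec <- genome_spec(
    tibble(chrom = paste0("chr", seq_len(n_chrom)),
           length_bp = rep(chrom_mbp * 1e6, n_chrom)),
    marker_density = marker_density
  )
  map <- build_marker_map(spec, seed = seed)
  mos <- simulate_ril_population(spec, n_rils = n_ind, seed = seed + 1)
  cross <- ril_cross_from_truth(mos, map)
  list(spec = spec, map = map, mosaics = mos, cross = cross)
}

#' Null calibration of the permutation threshold
#'
#' Scans pure-noise phenotypes and reports the genome-wide type-I error at
#' the permutation alpha.
#'
#' @param n_genes Null genes.
#' @param n_ind Individuals.
#' @param n_perm Permutations per gene.
#' @param alpha Significance level.
#' @param seed Integer seed.
#' @return Tibble `n_genes`, `n_significant`, `type1_rate`.
#' @export
experiment_eqtl_null <- function(n_genes = 500, n_ind = 150, n_perm = 1000,
                                 alpha = 0.001, seed = 1) {
  sc <- eqtl_sim_cross(n_ind, seed)
  prep <- prepare_markers(sc$cross)
  pr <- genotype_probabilities(prep)
  withr_seed(seed + 2)
  Y <- matrix(rnorm(nrow(pr$prob) * n_genes), nrow(pr$prob), n_genes,
              dimnames = list(rownames(pr$prob),
                              sprintf("null%03d", seq_len(n_genes))))
  res <- scan_permutations(pr, Y, n_perm = n_perm, alpha = alpha,
                           seed = seed + 3)
  tibble(n_genes = n_genes, n_significant = sum(res$significant),
         type1_rate = mean(res$significant))
}

#' Cis/trans recovery on the standard simulated architecture
#'
#' 100 genes, half cis and half trans, eQTL effect 1.5 phenotype SD,
#' n individuals; maps eQTL end to end and scores the detected peaks
#' against the true regulatory mode. Also checks that moving the 2.5-Mbp
#' cis window by +-0.5 Mbp flips no label for eQTL placed well inside
#' (<= 1 Mbp) or well outside (>= 5 Mbp) the window.
#'
#' @param n_genes,n_ind Problem size.
#' @param effect_sd eQTL effect in residual-SD units.
#' @param n_perm Permutations per gene.
#' @param seed Integer seed.
#' @return Tibble `n_detected`, `n_correct`, `accuracy`,
#'   `robust_to_window`.
#' @export
experiment_cis_trans <- function(n_genes = 100, n_ind = 150,
                                 effect_sd = 1.5, n_perm = 1000, seed = 1) {
  sc <- eqtl_sim_cross(n_ind, seed)
  genes <- simulate_genes(sc$spec, n_genes = n_genes, seed = seed + 4)
  arch <- regulatory_architecture(genes, sc$spec, cis_fraction = 0.5,
                                  silenced_fraction = 0,
                                  cis_max_dist = 0.8e6, seed = seed + 5)
  prep <- prepare_markers(sc$cross)
  pr <- genotype_probabilities(prep)
  inds <- rownames(pr$prob)
  # expression: effect at the true eQTL dosage (Mo17 allele count / 2)
  dos <- genotype_allele_dosage(
    sc$mosaics |> filter(.data$ril_id %in% inds),
    tibble(sample = inds, type = "RIL", ril_id = inds),
    arch |> mutate(locus_id = .data$gene_id) |>
      select("locus_id", chrom = "eqtl_chrom", pos = "eqtl_pos")
  )
  dmat <- dos |>
    select("genotype", "locus_id", "n_mo17") |>
    pivot_wider(names_from = "locus_id", values_from = "n_mo17")
  D <- as.matrix(dmat[, genes$gene_id]) / 2
  rownames(D) <- dmat$genotype
  withr_seed(seed + 6)
  Y <- effect_sd * D[inds, ] + matrix(rnorm(length(D)), nrow(D))
  peaks <- map_eqtl(sc$cross, Y, n_perm = n_perm, seed = seed + 7)
  peaks <- merge_peaks(peaks)
  cls <- classify_cis_trans(peaks, genes)
  truth <- setNames(arch$mode, arch$gene_id)
  ok <- cls$regulation == truth[cls$phenotype]
  # window robustness for clearly-placed eQTL
  dist <- abs(cls$pos - cls$gene_start)
  clear <- cls$chrom != cls$gene_chrom | dist <= 1e6 | dist >= 5e6
  lab_lo <- classify_cis_trans(peaks, genes, cis_window = 2.0e6)$regulation
  lab_hi <- classify_cis_trans(peaks, genes, cis_window = 3.0e6)$regulation
  robust <- all(lab_lo[clear] == cls$regulation[clear]) &&
    all(lab_hi[clear] == cls$regulation[clear])
  tibble(n_detected = nrow(cls), n_correct = sum(ok), accuracy = mean(ok),
         robust_to_window = robust)
}

#' Directional findings on synthetic data
#'
#' One synthetic cross, checking three qualitative observations: hybrids
#' express more genes than their parental average, SPE counts are larger
#' in heterozygous than homozygous patterns, and the active-gene count
#' rises with the heterozygous genome fraction.
#'
#' @param n_rils,n_genes Problem size.
#' @param seed Integer seed.
#' @return Tibble with `mean_hybrid_surplus`, `frac_hybrids_het_dominant`,
#'   `het_correlation`, `het_correlation_p`.
#' @export
experiment_directional <- function(n_rils = 20, n_genes = 300, seed = 1) {
  spec <- genome_spec(tibble(chrom = paste0("chr", 1:3),
                             length_bp = rep(30e6, 3)))
  mos <- simulate_ril_population(spec, n_rils = n_rils, seed = seed)
  man <- simulate_genotype_calls(mos, build_marker_map(spec, seed = seed + 1),
                                 seed = seed + 2)$manifest
  genes <- simulate_genes(spec, n_genes = n_genes, seed = seed + 3)
  arch <- regulatory_architecture(genes, spec, silenced_fraction = 0.5,
                                  seed = seed + 4)
  expr <- simulate_expression_counts(genes, arch, mos, man,
                                     nb_dispersion = 0.02,
                                     baseline_meanlog = log(300),
                                     baseline_sdlog = 0.3, seed = seed + 5)
  act <- call_gene_activity(expr$counts, expr$samples, genes)
  counts <- colSums(act$activity)
  hyb <- man |> filter(.data$type %in% c("B73xRIL", "MO17xRIL"))
  surplus <- purrr::map_dbl(seq_len(nrow(hyb)), function(i) {
    mat <- if (hyb$type[i] == "B73xRIL") "B73_rep1" else "MO17_rep1"
    counts[hyb$sample[i]] -
      (counts[mat] + counts[paste0("RIL_", hyb$ril_id[i])]) / 2
  })
  # SPE pattern counts from true zygosity
  zyg <- setNames(purrr::map(seq_len(nrow(hyb)), function(i) {
    org <- mosaic_origin_at(
      mos |> filter(.data$ril_id == hyb$ril_id[i]),
      genes |> mutate(pos = .data$start) |> select("chrom", "pos")
    )
    z <- org$origin[match(paste0(genes$chrom, "_", genes$start),
                          paste0(org$chrom, "_", org$pos))]
    tibble(gene_id = genes$gene_id,
           zygosity = dplyr::case_when(
             hyb$type[i] == "B73xRIL" & z == "MO17" ~ "HET",
             hyb$type[i] == "B73xRIL" & z == "B73" ~ "HOM_B73",
             hyb$type[i] == "MO17xRIL" & z == "B73" ~ "HET",
             hyb$type[i] == "MO17xRIL" & z == "MO17" ~ "HOM_MO17",
             TRUE ~ "NO_INFO"
           ))
  }), hyb$sample)
  spe <- classify_spe_all(act$activity, man, zyg)
  pat <- summarize_spe(spe) |>
    mutate(region = dplyr::case_when(
      .data$pattern %in% c("1", "2", "5", "6") ~ "het",
      .data$pattern %in% c("3", "4", "7", "8") ~ "hom",
      TRUE ~ NA_character_
    )) |>
    filter(!is.na(.data$region)) |>
    group_by(.data$hybrid_id, .data$region) |>
    summarise(n = sum(.data$n), .groups = "drop") |>
    pivot_wider(names_from = "region", values_from = "n",
                values_fill = 0)
  if (!"hom" %in% names(pat)) pat$hom <- 0
  if (!"het" %in% names(pat)) pat$het <- 0
  hf <- purrr::map_dfr(seq_len(nrow(hyb)), function(i) {
    segs <- mos |> filter(.data$ril_id == hyb$ril_id[i]) |>
      rename(sample = "ril_id")
    tibble(genotype = hyb$sample[i],
           het_fraction = heterozygosity_fraction(
             segs, if (hyb$type[i] == "B73xRIL") "B73xRIL" else "MO17xRIL"))
  })
  s <- active_gene_summary(act$activity, hf)
  tibble(
    mean_hybrid_surplus = mean(surplus),
    frac_hybrids_het_dominant = mean(pat$het > pat$hom),
    het_correlation = s$correlation$estimate,
    het_correlation_p = s$correlation$p_value
  )
}
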