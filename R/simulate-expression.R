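#' Simulate gene models on a synthetic genome
#'
#' Genes are placed uniformly along chromosomes with log-normal lengths,
#' uniform GC fractions and a configurable fraction of syntenic genes
#' (positionally conserved across related grasses).
#'
#' @param spec A [genome_spec()].
#' @param n_genes Number of genes.
#' @param syntenic_fraction Fraction flagged syntenic (default 0.6,
#'   matching a genome where ~40% of genes are non-syntenic).
#' @param seed Integer seed.
#' @return Gene tibble `gene_id`, `chrom`, `start`, `end`, `gc`, `length`,
#'   `syntenic`.
#' @export
simulate_genes <- function(spec, n_genes = 500, syntenic_fraction = 0.6,
                           seed = 1) {
  withr_seed(seed)
  ci <- sample.int(nrow(spec$chromosomes), n_genes, replace = TRUE,
                   prob = spec$chromosomes$length_bp)
  len <- pmax(200, round(stats::rlnorm(n_genes, log(3000), 0.6)))
  L <- spec$chromosomes$length_bp[ci]
  start <- floor(runif(n_genes, 1, pmax(2, L - len)))
  tibble(
    gene_id = sprintf("gene%04d", seq_len(n_genes)),
    chrom = spec$chromosomes$chrom[ci],
    start = start,
    end = start + len - 1,
    gc = runif(n_genes, 0.3, 0.7),
    length = len,
    syntenic = runif(n_genes) < syntenic_fraction
  ) |>
    arrange(.data$chrom, .data$start) |>
    mutate(gene_id = sprintf("gene%04d", row_number()))
}

#' Draw a cis/trans regulatory architecture
#'
#' Each gene gets one regulatory locus (its eQTL). Cis eQTL lie within
#' `cis_max_dist` of the gene start on the same chromosome; trans eQTL lie
#' on another chromosome (fraction `trans_other_chrom`) or at least
#' `trans_min_dist` away on the same chromosome. A `silenced_fraction` of
#' genes carries a silencing allele from one founder: such a gene is active
#' in a genotype only when at least one copy of the required active allele
#' (the other founder's) is present at the eQTL locus — the generative
#' mechanism behind single-parent expression. Optionally the enrichment of
#' trans regulation among non-syntenic genes can be injected.
#'
#' @param genes Gene tibble from [simulate_genes()].
#' @param spec The [genome_spec()].
#' @param cis_fraction Fraction of genes with cis eQTL (default 0.88).
#' @param silenced_fraction Fraction of genes silenced in one founder.
#' @param mo17_silenced_bias Probability that the silencing allele is the
#'   Mo17 allele (0.5 = symmetric).
#' @param cis_max_dist,trans_min_dist,trans_other_chrom Placement rules.
#' @param trans_nonsyntenic_or Odds multiplier favouring trans regulation
#'   for non-syntenic genes (1 = no association).
#' @param seed Integer seed.
#' @return Tibble `gene_id`, `eqtl_chrom`, `eqtl_pos`, `mode`,
#'   `silencing_allele` (`B73`/`MO17`/`none`), `required_allele`.
#' @export
regulatory_architecture <- function(genes, spec, cis_fraction = 0.88,
                                    silenced_fraction = 0.35,
                                    mo17_silenced_bias = 0.5,
                                    cis_max_dist = 1e6, trans_min_dist = 5e6,
                                    trans_other_chrom = 0.83,
                                    trans_nonsyntenic_or = 1, seed = 1) {
  withr_seed(seed)
  n <- nrow(genes)
  p_cis <- rep(cis_fraction, n)
  if (trans_nonsyntenic_or != 1) {
    odds <- cis_fraction / (1 - cis_fraction)
    p_cis[!genes$syntenic] <- odds / trans_nonsyntenic_or /
      (1 + odds / trans_nonsyntenic_or)
  }
  mode <- if_else(runif(n) < p_cis, "cis", "trans")
  chrom_len <- setNames(spec$chromosomes$length_bp, spec$chromosomes$chrom)
  eqtl_chrom <- character(n)
  eqtl_pos <- numeric(n)
  for (i in seq_len(n)) {
    if (mode[i] == "cis") {
      eqtl_chrom[i] <- genes$chrom[i]
      off <- round(runif(1, -cis_max_dist, cis_max_dist))
      eqtl_pos[i] <- min(max(1, genes$start[i] + off), chrom_len[genes$chrom[i]])
    } else if (runif(1) < trans_other_chrom && length(chrom_len) > 1) {
      eqtl_chrom[i] <- sample(setdiff(names(chrom_len), genes$chrom[i]), 1)
      eqtl_pos[i] <- sample.int(chrom_len[eqtl_chrom[i]], 1)
    } else {
      eqtl_chrom[i] <- genes$chrom[i]
      L <- chrom_len[genes$chrom[i]]
      lo_ok <- genes$start[i] - trans_min_dist >= 1
      hi_ok <- genes$start[i] + trans_min_dist <= L
      side <- if (lo_ok && hi_ok) sample(c(-1, 1), 1) else if (hi_ok) 1 else -1
      eqtl_pos[i] <- if (side > 0) {
        sample.int(L - genes$start[i] - trans_min_dist + 1, 1) +
          genes$start[i] + trans_min_dist - 1
      } else {
        sample.int(genes$start[i] - trans_min_dist, 1)
      }
    }
  }
  silenced <- runif(n) < silenced_fraction
  sil <- if_else(silenced,
                 if_else(runif(n) < mo17_silenced_bias, "MO17", "B73"),
                 "none")
  tibble(
    gene_id = genes$gene_id,
    eqtl_chrom = eqtl_chrom,
    eqtl_pos = unname(eqtl_pos),
    mode = mode,
    silencing_allele = sil,
    required_allele = dplyr::case_when(sil == "MO17" ~ "B73",
                                       sil == "B73" ~ "MO17",
                                       TRUE ~ NA_character_)
  )
}

#' Founder-allele dosage of every genotype at arbitrary loci
#'
#' For each genotype in the manifest, counts B73 and Mo17 allele copies at
#' the supplied loci: founders are homozygous, RILs carry their mosaic
#' origin doubled, backcross hybrids combine the recurrent parent's allele
#' with the RIL's mosaic allele. Third-origin segments contribute neither
#' founder allele.
#'
#' @param mosaics Mosaic tibble.
#' @param manifest Genotype manifest (`sample`, `type`, `ril_id`).
#' @param loci Tibble `locus_id`, `chrom`, `pos`.
#' @return Tibble `genotype`, `type`, `locus_id`, `n_b73`, `n_mo17`.
#' @export
genotype_allele_dosage <- function(mosaics, manifest, loci) {
  ril_org <- mosaics |>
    inner_join(loci, by = "chrom", relationship = "many-to-many") |>
    filter(.data$pos >= .data$start, .data$pos <= .data$end) |>
    select("ril_id", "locus_id", "origin")
  per_type <- function(type) {
    m <- manifest |> filter(.data$type == .env$type)
    if (type %in% c("B73", "MO17")) {
      nb <- if (type == "B73") 2L else 0L
      tidyr::expand_grid(m |> select(genotype = "sample", "type"),
                         loci |> select("locus_id")) |>
        mutate(n_b73 = nb, n_mo17 = 2L - nb)
    } else {
      rec_b <- switch(type, RIL = 0L, B73xRIL = 1L, MO17xRIL = 0L)
      rec_m <- switch(type, RIL = 0L, B73xRIL = 0L, MO17xRIL = 1L)
      ril_mult <- if (type == "RIL") 2L else 1L
      m |>
        select(genotype = "sample", "type", "ril_id") |>
        inner_join(ril_org, by = "ril_id", relationship = "many-to-many") |>
        mutate(
          n_b73 = rec_b + ril_mult * (.data$origin == "B73"),
          n_mo17 = rec_m + ril_mult * (.data$origin == "MO17")
        ) |>
        select("genotype", "type", "locus_id", "n_b73", "n_mo17")
    }
  }
  purrr::map_dfr(unique(manifest$type), per_type)
}

#' Ground-truth gene activity per genotype
#'
#' Exhaustive enumeration of the regulatory model: a gene is active in a
#' genotype unless it carries a silencing allele and the genotype has no
#' copy of the required active allele at the eQTL locus.
#'
#' @param architecture From [regulatory_architecture()].
#' @param mosaics,manifest Cross material.
#' @return Tibble `genotype`, `type`, `gene_id`, `active`.
#' @export
true_activity <- function(architecture, mosaics, manifest) {
  loci <- architecture |>
    mutate(locus_id = .data$gene_id) |>
    select("locus_id", chrom = "eqtl_chrom", pos = "eqtl_pos")
  dos <- genotype_allele_dosage(mosaics, manifest, loci)
  dos |>
    rename(gene_id = "locus_id") |>
    inner_join(architecture |> select("gene_id", "silencing_allele"),
               by = "gene_id") |>
    mutate(active = dplyr::case_when(
      .data$silencing_allele == "none" ~ TRUE,
      .data$silencing_allele == "MO17" ~ .data$n_b73 >= 1,
      .data$silencing_allele == "B73" ~ .data$n_mo17 >= 1
    )) |>
    select("genotype", "type", "gene_id", "active")
}

#' Simulate negative-binomial expression counts
#'
#' Expected count = baseline x activity(genotype at the eQTL locus) x
#' artifact(GC, log length) x library size; counts are negative binomial
#' with gene-shared dispersion (Poisson when `nb_dispersion = 0`).
#'
#' @param genes Gene tibble.
#' @param architecture From [regulatory_architecture()].
#' @param mosaics,manifest Cross material.
#' @param n_reps Replicates per genotype.
#' @param nb_dispersion NB dispersion (1/size); 0 gives Poisson counts.
#' @param library_sizes Optional named per-sample relative library sizes
#'   (must be positive); default log-normal around 1.
#' @param artifact `NULL` for no gene-level artifact, or
#'   `function(gc, log_length)` returning a positive multiplicative bias.
#' @param baseline_meanlog,baseline_sdlog Log-normal baseline expression.
#' @param seed Integer seed.
#' @return List of class `expression_sim`: `counts` (genes x samples
#'   matrix), `samples` (`sample`, `genotype`, `type`, `ril_id`), `genes`,
#'   `activity` (ground truth per genotype), `mu` (expected counts).
#' @export
simulate_expression_counts <- function(genes, architecture, mosaics, manifest,
                                       n_reps = 3, nb_dispersion = 0.05,
                                       library_sizes = NULL, artifact = NULL,
                                       baseline_meanlog = log(100),
                                       baseline_sdlog = 1, seed = 1) {
  withr_seed(seed)
  activity <- true_activity(architecture, mosaics, manifest)
  act_mat <- activity |>
    pivot_wider(id_cols = "gene_id", names_from = "genotype",
                values_from = "active") |>
    arrange(match(.data$gene_id, genes$gene_id))
  act <- as.matrix(act_mat[, -1])
  rownames(act) <- act_mat$gene_id
  act <- act[genes$gene_id, manifest$sample, drop = FALSE]

  samples <- manifest |>
    tidyr::expand_grid(rep = seq_len(n_reps)) |>
    mutate(sample = paste0(.data$sample, "_r", .data$rep),
           genotype = rep(manifest$sample, each = n_reps)) |>
    select("sample", "genotype", "type", "ril_id", "rep")
  if (is.null(library_sizes)) {
    library_sizes <- setNames(stats::rlnorm(nrow(samples), 0, 0.2),
                              samples$sample)
  }
  if (is.null(names(library_sizes))) {
    stopifnot(length(library_sizes) == nrow(samples))
    names(library_sizes) <- samples$sample
  }
  if (any(library_sizes <= 0)) abort("library sizes must be positive")

  baseline <- stats::rlnorm(nrow(genes), baseline_meanlog, baseline_sdlog)
  art <- if (is.null(artifact)) rep(1, nrow(genes)) else {
    a <- artifact(genes$gc, log(genes$length))
    if (any(a <= 0)) abort("artifact values must be positive")
    a
  }
  mu <- (baseline * art) %o% unname(library_sizes[samples$sample]) *
    act[, samples$genotype, drop = FALSE]
  counts <- matrix(0L, nrow(mu), ncol(mu), dimnames = list(genes$gene_id,
                                                           samples$sample))
  nz <- mu > 0
  counts[nz] <- if (nb_dispersion > 0) {
    rnbinom(sum(nz), mu = mu[nz], size = 1 / nb_dispersion)
  } else {
    rpois(sum(nz), mu[nz])
  }
  structure(
    list(counts = counts, samples = samples, genes = genes,
         activity = activity, mu = mu),
    class = "expression_sim"
  )
}
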