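#' Default pipeline configuration
#'
#' All thresholds default to the analysis values: GQ >= 10, 90%/min-3
#' founder locus rule, 95% sample homozygosity, 2.5-Mbp third-origin
#' grouping with the 10/5 block rule, 15-locus windows with 11 (Mo17) and
#' 12 (B73) majorities, 0.5-Mbp block gaps, 50% contamination exclusion,
#' 0.25 activity quantile, 2.5-Mbp cis window, permutation alpha 0.001 and
#' FDR 0.001. The configuration round-trips to JSON losslessly.
#'
#' @param ... Named overrides of any default.
#' @return Named list of class `speqtl_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1,
    n_rils = 24,
    n_genes = 300,
    n_intermating_gens = 4,
    chrom_mbp = 50,
    n_chrom = 3,
    marker_density = 20,
    cm_per_mbp = 2.5,
    error_rate = 0.006,
    missing_rate = 0.02,
    gq_low_fraction = 0.05,
    third_origin_fraction = 0.05,
    min_gq = 10,
    window = 15, mo17_min = 11, b73_min = 12,
    mask_gap = 2.5e6, block_gap = 0.5e6,
    activity_quantile = 0.25,
    n_perm = 500, alpha = 0.001, fdr = 0.001,
    cis_window = 2.5e6
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) {
    abort(paste0("unknown config field(s): ", paste(unknown, collapse = ", ")))
  }
  cfg[names(over)] <- over
  structure(cfg, class = "speqtl_config")
}

#' @rdname default_config
#' @param path JSON file.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname default_config
#' @export
read_config <- function(path) {
  do.call(default_config, jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Run the analysis pipeline end to end on simulated inputs
#'
#' Executes the stages in dependency order — simulate, classify regions,
#' normalize and call SPE, map eQTL, classify cis/trans, test synteny
#' enrichment — writing each stage's outputs as plain files (VCF, GFF3,
#' BED, TSV, JSON) plus a provenance manifest with input/output MD5 hashes,
#' the configuration and the seed. Reruns with the same configuration are
#' byte-identical for the deterministic stages.
#'
#' @param config A [default_config()] list.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list of the in-memory stage results.
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("speqtl_run_")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- config
  spec <- genome_spec(
    tibble(chrom = paste0("chr", seq_len(cfg$n_chrom)),
           length_bp = rep(cfg$chrom_mbp * 1e6, cfg$n_chrom)),
    marker_density = cfg$marker_density, cm_per_mbp = cfg$cm_per_mbp
  )
  map <- build_marker_map(spec, seed = cfg$seed)
  mosaics <- simulate_ril_population(spec, n_rils = cfg$n_rils,
                                     n_intermating_gens = cfg$n_intermating_gens,
                                     seed = cfg$seed + 1)
  mosaics <- inject_third_origin(mosaics, spec,
                                 fraction_contaminated_rils = cfg$third_origin_fraction,
                                 seed = cfg$seed + 2)
  sim <- simulate_genotype_calls(mosaics, map, error_rate = cfg$error_rate,
                                 missing_rate = cfg$missing_rate,
                                 gq_model = list(low_fraction = cfg$gq_low_fraction,
                                                 high = 99),
                                 seed = cfg$seed + 3)
  write_genotype_vcf(sim$calls, file.path(out_dir, "calls.vcf"))
  readr::write_tsv(sim$manifest, file.path(out_dir, "manifest.tsv"))

  cls <- classify_ril_regions(sim$calls, sim$manifest, window = cfg$window,
                              mo17_min = cfg$mo17_min, b73_min = cfg$b73_min,
                              min_gq = cfg$min_gq, mask_gap = cfg$mask_gap,
                              block_gap = cfg$block_gap)
  write_regions_bed(bind_rows(cls$regions, cls$masked),
                    file.path(out_dir, "regions.bed"))

  genes <- simulate_genes(spec, n_genes = cfg$n_genes, seed = cfg$seed + 4)
  arch <- regulatory_architecture(genes, spec, seed = cfg$seed + 5)
  write_genes_gff3(genes, file.path(out_dir, "genes.gff3"))
  expr <- simulate_expression_counts(genes, arch, mosaics, sim$manifest,
                                     seed = cfg$seed + 6)
  act <- call_gene_activity(expr$counts, expr$samples, genes,
                            quantile_prob = cfg$activity_quantile)

  kept_rils <- cls$ril_status$ril_id[cls$ril_status$kept]
  zyg <- hybrid_zygosities(genes, cls, sim$manifest, kept_rils)
  spe <- classify_spe_all(act$activity, sim$manifest |>
                            filter(is.na(.data$ril_id) |
                                     .data$ril_id %in% kept_rils), zyg)
  spe_summary <- summarize_spe(spe)
  readr::write_tsv(spe, file.path(out_dir, "spe_assignments.tsv"))
  readr::write_tsv(spe_summary, file.path(out_dir, "spe_summary.tsv"))

  cross <- ril_cross_from_truth(mosaics, map, kept_rils)
  means_ril <- t(act$means[, paste0("RIL_", kept_rils), drop = FALSE])
  rownames(means_ril) <- kept_rils
  eqtl <- map_eqtl(cross, means_ril, n_perm = cfg$n_perm, alpha = cfg$alpha,
                   fdr = cfg$fdr, seed = cfg$seed + 7)
  eqtl <- classify_cis_trans(merge_peaks(eqtl), genes,
                             cis_window = cfg$cis_window)
  readr::write_tsv(eqtl, file.path(out_dir, "eqtl.tsv"))

  enrich <- if (nrow(eqtl) > 0) {
    synteny_enrichment(eqtl |>
                         left_join(genes |> select(phenotype = "gene_id",
                                                   "syntenic"),
                                   by = "phenotype"))
  } else {
    tibble()
  }
  jsonlite::write_json(enrich, file.path(out_dir, "synteny_enrichment.json"),
                       auto_unbox = TRUE, digits = NA)

  outputs <- list.files(out_dir, full.names = TRUE)
  manifest <- tibble(
    file = basename(outputs),
    md5 = unname(tools::md5sum(outputs))
  )
  jsonlite::write_json(
    list(config = unclass(cfg), files = manifest),
    file.path(out_dir, "provenance.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(list(map = map, mosaics = mosaics, sim = sim, regions = cls,
                 genes = genes, architecture = arch, activity = act,
                 spe = spe, spe_summary = spe_summary, eqtl = eqtl,
                 enrichment = enrich, out_dir = out_dir))
}

#' Per-hybrid gene zygosity tables from classified regions
#'
#' @param genes Gene tibble.
#' @param cls [classify_ril_regions()] output.
#' @param manifest Genotype manifest.
#' @param kept_rils RILs that passed contamination filtering.
#' @return Named list of zygosity tibbles, one per backcross hybrid
#'   genotype.
#' @export
hybrid_zygosities <- function(genes, cls, manifest, kept_rils) {
  hyb <- manifest |>
    filter(.data$type %in% c("B73xRIL", "MO17xRIL"),
           .data$ril_id %in% kept_rils)
  out <- purrr::map(seq_len(nrow(hyb)), function(i) {
    rid <- hyb$ril_id[i]
    suppressWarnings(annotate_gene_zygosity(
      genes,
      cls$regions |> filter(.data$ril_id == rid),
      cls$masked |> filter(.data$ril_id == rid),
      cross = hyb$type[i]
    ))
  })
  setNames(out, hyb$sample)
}

#' Build a RIL-self cross object from simulator truth
#'
#' Genotype codes from the true mosaics at the mapped markers (B73
#' homozygote = 1, Mo17 homozygote = 2, third origin = NA).
#'
#' @param mosaics Mosaic tibble.
#' @param map Marker map.
#' @param ril_ids RILs to include (rownames of the genotype matrix).
#' @return A [cross_geno()] with `cross_type = "rilself"`.
#' @export
ril_cross_from_truth <- function(mosaics, map, ril_ids = NULL) {
  ril_ids <- ril_ids %||% unique(mosaics$ril_id)
  org <- mosaic_origin_at(mosaics |> filter(.data$ril_id %in% ril_ids), map)
  code <- org |>
    mutate(code = dplyr::case_when(.data$origin == "B73" ~ 1L,
                                   .data$origin == "MO17" ~ 2L,
                                   TRUE ~ NA_integer_),
           locus_id = paste0(.data$chrom, "_", .data$pos)) |>
    select("ril_id", "locus_id", "code") |>
    pivot_wider(names_from = "locus_id", values_from = "code")
  g <- as.matrix(code[, -1])
  rownames(g) <- code$ril_id
  m <- map |> mutate(marker = .data$locus_id) |>
    select("marker", "chrom", "pos", "cm")
  g <- g[, m$marker, drop = FALSE]
  cross_geno(g, m, cross_type = "rilself")
}
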