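# Shared fixture builders. Everything is generated in code; sizes are kept
# small so the whole suite runs quickly on one CPU.

tiny_spec <- function(n_chrom = 2, mbp = 20, density = 20, cm_per_mbp = 2.5) {
  genome_spec(
    tibble::tibble(chrom = paste0("chr", seq_len(n_chrom)),
                   length_bp = rep(mbp * 1e6, n_chrom)),
    marker_density = density, cm_per_mbp = cm_per_mbp
  )
}

# a small clean cross: mosaics + calls with configurable noise
tiny_cross <- function(n_rils = 6, seed = 42, error_rate = 0, missing_rate = 0,
                       low_gq = 0, spec = tiny_spec(), third = 0) {
  map <- build_marker_map(spec, seed = seed)
  mos <- simulate_ril_population(spec, n_rils = n_rils, seed = seed + 1)
  if (third > 0) {
    mos <- inject_third_origin(mos, spec, fraction_contaminated_rils = third,
                               seed = seed + 2)
  }
  sim <- simulate_genotype_calls(mos, map, error_rate = error_rate,
                                 missing_rate = missing_rate,
                                 gq_model = list(low_fraction = low_gq,
                                                 high = 99),
                                 seed = seed + 3)
  list(spec = spec, map = map, mosaics = mos, calls = sim$calls,
       manifest = sim$manifest)
}

# hand-built genotype call table: one founder panel + explicit RIL calls
calls_tbl <- function(...) {
  df <- tibble::tribble(...)
  if (!"other_hom" %in% names(df)) df$other_hom <- NA
  if (!"gq" %in% names(df)) df$gq <- 99L
  df
}

founder_panel <- function(n_b73 = 5, n_mo17 = 5, loci = tibble::tibble(
                            chrom = "chr1", pos = c(1e6, 2e6, 3e6))) {
  b <- tidyr::expand_grid(sample = sprintf("B73_rep%d", seq_len(n_b73)),
                          loci) |>
    dplyr::mutate(call = "HOM_REF")
  m <- tidyr::expand_grid(sample = sprintf("MO17_rep%d", seq_len(n_mo17)),
                          loci) |>
    dplyr::mutate(call = "HOM_ALT")
  dplyr::bind_rows(b, m) |>
    dplyr::mutate(other_hom = NA, gq = 99L)
}

founder_manifest <- function(n_b73 = 5, n_mo17 = 5) {
  dplyr::bind_rows(
    tibble::tibble(sample = sprintf("B73_rep%d", seq_len(n_b73)),
                   type = "B73", ril_id = NA_character_),
    tibble::tibble(sample = sprintf("MO17_rep%d", seq_len(n_mo17)),
                   type = "MO17", ril_id = NA_character_)
  )
}

# check that segments exactly tile [1, len] for every ril x chrom
expect_tiling <- function(mosaics, spec) {
  ok <- mosaics |>
    dplyr::left_join(spec$chromosomes, by = "chrom") |>
    dplyr::group_by(ril_id, chrom) |>
    dplyr::arrange(start, .by_group = TRUE) |>
    dplyr::summarise(
      complete = dplyr::first(start) == 1 &
        dplyr::last(end) == dplyr::first(length_bp) &
        all(start[-1] == end[-dplyr::n()] + 1),
      .groups = "drop"
    )
  expect_true(all(ok$complete))
}

# brute-force SPE truth from the regulatory architecture (independent of the
# expression pipeline): enumerate activity of hybrid + parents per gene
oracle_spe <- function(architecture, mosaics, manifest) {
  act <- true_activity(architecture, mosaics, manifest)
  wide <- act |>
    dplyr::select(genotype, gene_id, active) |>
    tidyr::pivot_wider(names_from = genotype, values_from = active)
  hyb <- manifest[manifest$type %in% c("B73xRIL", "MO17xRIL"), ]
  purrr::map_dfr(seq_len(nrow(hyb)), function(i) {
    mat <- if (hyb$type[i] == "B73xRIL") "B73_rep1" else "MO17_rep1"
    pat <- paste0("RIL_", hyb$ril_id[i])
    h <- wide[[hyb$sample[i]]]
    m <- wide[[mat]]
    p <- wide[[pat]]
    tibble::tibble(
      hybrid_id = hyb$sample[i], gene_id = wide$gene_id,
      spe = h & (m != p),
      active_parent = ifelse(h & (m != p),
                             ifelse(m, "maternal", "paternal"),
                             NA_character_)
    )
  })
}
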