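#' Select high-confidence founder-discriminating loci
#'
#' A locus is retained when, among founder genotype calls with GQ >= 10,
#' at least 90% and at least 3 of the Mo17-sample calls are homozygous for
#' the non-reference allele and at least 90% and at least 3 of the
#' B73-sample calls are homozygous for the reference allele. By convention
#' the reference allele is the B73 allele and the non-reference allele the
#' Mo17 allele.
#'
#' @param calls Long genotype-call tibble (`sample`, `chrom`, `pos`, `call`,
#'   `gq`).
#' @param manifest Sample manifest (`sample`, `type`) with founder types
#'   `B73` and `MO17`.
#' @param min_gq Minimum genotype quality for a call to qualify.
#' @param min_frac Minimum fraction of qualifying founder calls that must be
#'   the expected homozygote.
#' @param min_n Minimum number of such calls.
#' @return Tibble of retained loci: `chrom`, `pos`.
#' @export
select_high_confidence_loci <- function(calls, manifest, min_gq = 10,
                                        min_frac = 0.9, min_n = 3) {
  founders <- manifest |> filter(.data$type %in% c("B73", "MO17"))
  if (nrow(founders) == 0) abort("no founder samples in manifest")
  fc <- calls |>
    inner_join(founders, by = "sample") |>
    filter(.data$gq >= min_gq, .data$call != "MISSING")
  fc |>
    group_by(.data$chrom, .data$pos) |>
    summarise(
      n_b73 = sum(.data$type == "B73"),
      n_b73_ref = sum(.data$type == "B73" & .data$call == "HOM_REF"),
      n_mo17 = sum(.data$type == "MO17"),
      n_mo17_alt = sum(.data$type == "MO17" & .data$call == "HOM_ALT"),
      .groups = "drop"
    ) |>
    filter(
      .data$n_b73_ref >= min_n, .data$n_b73_ref >= min_frac * .data$n_b73,
      .data$n_mo17_alt >= min_n, .data$n_mo17_alt >= min_frac * .data$n_mo17
    ) |>
    select("chrom", "pos")
}

#' Filter samples by homozygosity at expectedly homozygous loci
#'
#' Samples with less than 95% homozygous calls across the supplied loci are
#' excluded. Homozygous means `HOM_REF`, `HOM_ALT`, or an `OTHER` call
#' flagged homozygous; `MISSING` calls are not informative.
#'
#' @param calls Genotype-call tibble.
#' @param expected_hom_loci Tibble of loci (`chrom`, `pos`) expected to be
#'   homozygous in these samples.
#' @param min_rate Exclusion threshold (strict `<`).
#' @return Tibble `sample`, `n_informative`, `hom_rate`, `kept`, `reason`.
#' @export
filter_samples_by_homozygosity <- function(calls, expected_hom_loci,
                                           min_rate = 0.95) {
  calls |>
    inner_join(expected_hom_loci, by = c("chrom", "pos")) |>
    group_by(.data$sample) |>
    summarise(
      n_informative = sum(.data$call != "MISSING"),
      hom_rate = {
        inf <- .data$call != "MISSING"
        hom <- .data$call %in% c("HOM_REF", "HOM_ALT") |
          (.data$call == "OTHER" & !is.na(.data$other_hom) & .data$other_hom)
        if (sum(inf) == 0) NA_real_ else sum(hom & inf) / sum(inf)
      },
      .groups = "drop"
    ) |>
    mutate(
      kept = !is.na(.data$hom_rate) & .data$hom_rate >= min_rate,
      reason = dplyr::case_when(
        .data$n_informative == 0 ~ "no_informative_loci",
        .data$hom_rate < min_rate ~ "low_homozygosity",
        TRUE ~ NA_character_
      )
    )
}

#' Flag RIL-specific loci
#'
#' A call whose allele matches neither founder allele (`OTHER`) at a
#' high-confidence locus is flagged RIL-specific, regardless of GQ and
#' whether homozygous or heterozygous. `MISSING` calls are never flagged.
#'
#' @param ril_calls Calls of RIL samples.
#' @param high_conf_loci Loci from [select_high_confidence_loci()].
#' @return Tibble `sample`, `chrom`, `pos`, `hom` (homozygous third allele).
#' @export
flag_ril_specific_loci <- function(ril_calls, high_conf_loci) {
  ril_calls |>
    inner_join(high_conf_loci, by = c("chrom", "pos")) |>
    filter(.data$call == "OTHER") |>
    mutate(hom = !is.na(.data$other_hom) & .data$other_hom) |>
    select("sample", "chrom", "pos", "hom")
}

#' Mask putative third-origin regions
#'
#' Flagged RIL-specific loci closer than `gap` bp are grouped into blocks;
#' a block with at least `min_loci` flagged loci of which at least
#' `min_hom` are homozygous becomes a masked third-origin region spanning
#' its first to last locus.
#'
#' @param flagged Output of [flag_ril_specific_loci()].
#' @param gap Grouping distance in bp (default 2.5 Mbp).
#' @param min_loci,min_hom Block thresholds (default 10 and 5).
#' @return Region tibble `sample`, `chrom`, `start`, `end`,
#'   `origin = "MASKED_THIRD"`.
#' @export
mask_third_origin <- function(flagged, gap = 2.5e6, min_loci = 10, min_hom = 5) {
  if (nrow(flagged) == 0) {
    return(tibble(sample = character(), chrom = character(),
                  start = numeric(), end = numeric(), origin = character()))
  }
  flagged |>
    arrange(.data$sample, .data$chrom, .data$pos) |>
    group_by(.data$sample, .data$chrom) |>
    mutate(block = cumsum(c(1, diff(.data$pos) >= gap))) |>
    group_by(.data$sample, .data$chrom, .data$block) |>
    summarise(start = min(.data$pos), end = max(.data$pos),
              n = n(), n_hom = sum(.data$hom), .groups = "drop") |>
    filter(.data$n >= min_loci, .data$n_hom >= min_hom) |>
    mutate(origin = "MASKED_THIRD") |>
    select("sample", "chrom", "start", "end", "origin")
}

#' Classify loci by a sliding 15-locus window
#'
#' Windows slide by one locus over the usable loci of a chromosome
#' (high-confidence loci with GQ >= `min_gq`, outside masked regions). A
#' window is labelled `MO17` when at least `mo17_min` of its loci are
#' homozygous for the Mo17 allele, `B73` when at least `b73_min` are
#' homozygous for the B73 allele, otherwise `AMBIGUOUS`. A locus survives
#' only if every window covering it carries a label that matches the locus's
#' own call; loci covered by any ambiguous or conflicting window are
#' dropped. Chromosomes with fewer usable loci than the window size are
#' entirely ambiguous (with a warning).
#'
#' @param ril_calls Calls of one or more RIL samples.
#' @param high_conf_loci High-confidence loci.
#' @param masked Masked regions from [mask_third_origin()] (may be empty).
#' @param window Window size in loci.
#' @param mo17_min,b73_min Window majority thresholds.
#' @param min_gq GQ filter applied before windowing.
#' @return Tibble of surviving loci `sample`, `chrom`, `pos`, `allele`
#'   (`B73` or `MO17`).
#' @export
classify_by_windows <- function(ril_calls, high_conf_loci, masked = NULL,
                                window = 15, mo17_min = 11, b73_min = 12,
                                min_gq = 10) {
  usable <- ril_calls |>
    inner_join(high_conf_loci, by = c("chrom", "pos")) |>
    filter(.data$gq >= min_gq, .data$call %in% c("HOM_REF", "HOM_ALT", "HET"))
  if (!is.null(masked) && nrow(masked) > 0) {
    usable <- usable |>
      left_join(masked |> select("sample", "chrom", "start", "end"),
                by = c("sample", "chrom"), relationship = "many-to-many") |>
      mutate(in_mask = !is.na(.data$start) & .data$pos >= .data$start &
               .data$pos <= .data$end) |>
      group_by(.data$sample, .data$chrom, .data$pos) |>
      summarise(call = first(.data$call), drop = any(.data$in_mask),
                .groups = "drop") |>
      filter(!.data$drop) |>
      select(-"drop")
  }
  usable <- usable |> arrange(.data$sample, .data$chrom, .data$pos)
  short <- usable |>
    count(.data$sample, .data$chrom) |>
    filter(.data$n < window)
  if (nrow(short) > 0) {
    warn(paste0(nrow(short), " sample-chromosome(s) with fewer than ",
                window, " usable loci: all their loci are ambiguous"))
  }
  usable |>
    group_by(.data$sample, .data$chrom) |>
    group_modify(function(df, key) window_survivors(df, window, mo17_min, b73_min)) |>
    ungroup()
}

window_survivors <- function(df, window, mo17_min, b73_min) {
  n <- nrow(df)
  if (n < window) return(df[0, c("pos", "call")] |> mutate(allele = character()))
  is_ref <- df$call == "HOM_REF"
  is_alt <- df$call == "HOM_ALT"
  cs_ref <- c(0, cumsum(is_ref))
  cs_alt <- c(0, cumsum(is_alt))
  nw <- n - window + 1
  w_ref <- cs_ref[(window + 1):(n + 1)] - cs_ref[1:nw]
  w_alt <- cs_alt[(window + 1):(n + 1)] - cs_alt[1:nw]
  w_lab <- ifelse(w_alt >= mo17_min, "MO17",
                  ifelse(w_ref >= b73_min, "B73", "AMBIGUOUS"))
  # locus i is covered by windows max(1, i-window+1) .. min(nw, i)
  keep <- logical(n)
  allele <- ifelse(is_ref, "B73", ifelse(is_alt, "MO17", NA_character_))
  for (i in seq_len(n)) {
    ws <- w_lab[max(1L, i - window + 1L):min(nw, i)]
    keep[i] <- !is.na(allele[i]) && all(ws == allele[i])
  }
  tibble(pos = df$pos[keep], call = df$call[keep], allele = allele[keep])
}

#' Merge surviving loci into same-allele blocks
#'
#' Successive loci carrying the same allele and less than `gap` bp apart
#' are grouped into one block; every block is retained as a classified
#' region spanning its first to last member locus (no extrapolation into
#' gaps). A single isolated locus forms a zero-length block.
#'
#' @param loci Survivors from [classify_by_windows()] (`sample`, `chrom`,
#'   `pos`, `allele`).
#' @param gap Maximum within-block distance in bp (default 0.5 Mbp).
#' @return Region tibble `sample`, `chrom`, `start`, `end`, `origin`.
#' @export
merge_allele_blocks <- function(loci, gap = 0.5e6) {
  if (nrow(loci) == 0) {
    return(tibble(sample = character(), chrom = character(),
                  start = numeric(), end = numeric(), origin = character()))
  }
  loci |>
    arrange(.data$sample, .data$chrom, .data$pos) |>
    group_by(.data$sample, .data$chrom) |>
    mutate(block = cumsum(c(1, diff(.data$pos) >= gap |
                              .data$allele[-1] != .data$allele[-n()]))) |>
    group_by(.data$sample, .data$chrom, .data$block) |>
    summarise(start = min(.data$pos), end = max(.data$pos),
              origin = first(.data$allele), .groups = "drop") |>
    select("sample", "chrom", "start", "end", "origin")
}

#' Exclude RILs dominated by third-origin regions
#'
#' A RIL is excluded when masked third-origin length exceeds 50% of its
#' total classified plus masked length (strict `>`); its backcross hybrids
#' are excluded with it.
#'
#' @param regions Classified regions (B73/MO17) per RIL sample.
#' @param masked Masked regions per RIL sample.
#' @param max_fraction Exclusion threshold.
#' @return Tibble `sample`, `masked_fraction`, `kept`.
#' @export
exclude_contaminated_rils <- function(regions, masked, max_fraction = 0.5) {
  cl <- regions |>
    group_by(.data$sample) |>
    summarise(classified_bp = sum(.data$end - .data$start + 1), .groups = "drop")
  mk <- masked |>
    group_by(.data$sample) |>
    summarise(masked_bp = sum(.data$end - .data$start + 1), .groups = "drop")
  dplyr::full_join(cl, mk, by = "sample") |>
    mutate(
      classified_bp = dplyr::coalesce(.data$classified_bp, 0),
      masked_bp = dplyr::coalesce(.data$masked_bp, 0),
      masked_fraction = .data$masked_bp /
        pmax(.data$classified_bp + .data$masked_bp, 1),
      kept = .data$masked_fraction <= max_fraction
    )
}

#' Classify RIL genomes into parental mosaics
#'
#' End-to-end wrapper: selects high-confidence founder loci, flags and masks
#' RIL-specific third-origin regions, applies the sliding-window filter,
#' merges surviving loci into B73/Mo17 blocks and excludes RILs whose
#' genomes are dominated by masked regions.
#'
#' @param calls,manifest Output of [simulate_genotype_calls()] or data read
#'   from VCF via [read_genotype_vcf()].
#' @inheritParams classify_by_windows
#' @inheritParams mask_third_origin
#' @param block_gap Same-allele block grouping distance (bp).
#' @return List with `regions` (B73/MO17 regions, `ril_id` column), `masked`
#'   (masked third-origin regions), `ril_status` (kept/excluded), and
#'   `high_conf_loci`.
#' @export
classify_ril_regions <- function(calls, manifest, window = 15, mo17_min = 11,
                                 b73_min = 12, min_gq = 10, mask_gap = 2.5e6,
                                 block_gap = 0.5e6) {
  hc <- select_high_confidence_loci(calls, manifest, min_gq = min_gq)
  ril_samples <- manifest |> filter(.data$type == "RIL")
  ril_calls <- calls |> inner_join(ril_samples |> select("sample", "ril_id"),
                                   by = "sample")
  flagged <- flag_ril_specific_loci(ril_calls, hc)
  masked <- mask_third_origin(flagged, gap = mask_gap)
  survivors <- classify_by_windows(ril_calls, hc, masked, window = window,
                                   mo17_min = mo17_min, b73_min = b73_min,
                                   min_gq = min_gq)
  regions <- merge_allele_blocks(survivors, gap = block_gap)
  status <- exclude_contaminated_rils(regions, masked)
  add_ril <- function(df) {
    df |> left_join(ril_samples |> select("sample", "ril_id"), by = "sample")
  }
  list(
    regions = add_ril(regions) |> filter(.data$sample %in%
                                           status$sample[status$kept]),
    masked = add_ril(masked),
    ril_status = add_ril(status),
    high_conf_loci = hc
  )
}

#' Annotate per-gene zygosity in a backcross hybrid
#'
#' A gene belongs to the classified region containing its annotated start
#' coordinate. In a B73 x RIL hybrid a gene inside a Mo17 region of the RIL
#' is heterozygous and inside a B73 region homozygous B73; mirrored for
#' Mo17 x RIL. Genes in masked regions are `MASKED`; genes overlapping no
#' region, or whose span straddles differently classified regions, are
#' `NO_INFO`.
#'
#' @param genes Gene table (`gene_id`, `chrom`, `start`, `end`).
#' @param regions Classified regions of one RIL (`chrom`, `start`, `end`,
#'   `origin` with B73/MO17), e.g. one `ril_id` slice of
#'   [classify_ril_regions()] output.
#' @param masked Masked regions of the same RIL (may be `NULL`).
#' @param cross `"B73xRIL"` or `"MO17xRIL"`.
#' @return Tibble `gene_id`, `zygosity` in
#'   `HET`, `HOM_B73`, `HOM_MO17`, `MASKED`, `NO_INFO`.
#' @export
annotate_gene_zygosity <- function(genes, regions, masked = NULL,
                                   cross = c("B73xRIL", "MO17xRIL")) {
  cross <- match.arg(cross)
  all_regions <- bind_rows(
    regions |> select("chrom", "start", "end", "origin"),
    if (!is.null(masked) && nrow(masked) > 0) {
      masked |> select("chrom", "start", "end", "origin")
    }
  )
  hit_at <- function(p_chrom, p) {
    i <- which(all_regions$chrom == p_chrom & all_regions$start <= p &
                 all_regions$end >= p)
    if (length(i) == 0) NA_character_ else all_regions$origin[i[1]]
  }
  zyg_of <- function(origin) {
    if (is.na(origin)) return("NO_INFO")
    if (origin == "MASKED_THIRD") return("MASKED")
    if (cross == "B73xRIL") {
      if (origin == "MO17") "HET" else "HOM_B73"
    } else {
      if (origin == "B73") "HET" else "HOM_MO17"
    }
  }
  straddle <- logical(nrow(genes))
  zyg <- character(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    o_start <- hit_at(genes$chrom[i], genes$start[i])
    o_end <- hit_at(genes$chrom[i], genes$end[i])
    if (!is.na(o_start) && !is.na(o_end) && o_start != o_end) {
      zyg[i] <- "NO_INFO"
      straddle[i] <- TRUE
    } else {
      zyg[i] <- zyg_of(o_start)
    }
  }
  if (any(straddle)) {
    warn(paste0(sum(straddle),
                " gene(s) straddle differently classified regions; set to NO_INFO"))
  }
  tibble(gene_id = genes$gene_id, zygosity = zyg)
}

#' Heterozygosity fraction of a backcross hybrid
#'
#' Total length of classified heterozygous regions divided by the total
#' length of all classified regions; masked third-origin regions and
#' regions without SNP information do not enter the denominator.
#'
#' @param regions Classified B73/MO17 regions of one RIL.
#' @param cross `"B73xRIL"` or `"MO17xRIL"`.
#' @return Proportion in `[0, 1]` (`NaN` when nothing is classified).
#' @export
heterozygosity_fraction <- function(regions, cross = c("B73xRIL", "MO17xRIL")) {
  cross <- match.arg(cross)
  het_origin <- if (cross == "B73xRIL") "MO17" else "B73"
  cl <- regions |> filter(.data$origin %in% c("B73", "MO17"))
  lens <- cl$end - cl$start + 1
  sum(lens[cl$origin == het_origin]) / sum(lens)
}
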