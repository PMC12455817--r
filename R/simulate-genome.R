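#' Describe a synthetic genome
#'
#' A genome specification holds the chromosome layout and the two coordinate
#' conventions used throughout the package: physical positions in bp (1-based,
#' closed intervals) and genetic positions in cM obtained from a linear
#' cM-per-Mbp map. The defaults describe a scaled-down mosaic genome suitable
#' for desk-scale simulation of an intermated RIL population.
#'
#' @param chromosomes A data frame with columns `chrom` and `length_bp`, or
#'   `NULL` for the default of 5 chromosomes of 50 Mbp.
#' @param marker_density Expected SNP loci per Mbp.
#' @param cm_per_mbp Genetic-map rate in cM per Mbp (linear map).
#' @return An object of class `genome_spec`.
#' @export
genome_spec <- function(chromosomes = NULL,
                        marker_density = 20,
                        cm_per_mbp = 2.5) {
  if (is.null(chromosomes)) {
    chromosomes <- tibble(
      chrom = paste0("chr", 1:5),
      length_bp = rep(50e6, 5)
    )
  }
  chromosomes <- as_tibble(chromosomes)
  stopifnot(all(c("chrom", "length_bp") %in% names(chromosomes)))
  if (any(chromosomes$length_bp <= 0)) {
    abort("all chromosome lengths must be > 0")
  }
  if (marker_density <= 0) abort("marker_density must be > 0")
  if (cm_per_mbp < 0) abort("cm_per_mbp must be >= 0")
  structure(
    list(
      chromosomes = chromosomes,
      marker_density = marker_density,
      cm_per_mbp = cm_per_mbp
    ),
    class = "genome_spec"
  )
}

#' @export
print.genome_spec <- function(x, ...) {
  cat("<genome_spec> ", nrow(x$chromosomes), " chromosomes, ",
      sum(x$chromosomes$length_bp) / 1e6, " Mbp total, ",
      x$marker_density, " loci/Mbp, ", x$cm_per_mbp, " cM/Mbp\n", sep = "")
  invisible(x)
}

#' Build a marker map for a synthetic genome
#'
#' Draws marker positions uniformly along each chromosome (count =
#' density x length, positions strictly increasing, 1-based bp) and assigns
#' genetic positions by the linear cM map.
#'
#' @param spec A [genome_spec()].
#' @param seed Integer seed; the map is a pure function of `(spec, seed)`.
#' @return A tibble with columns `locus_id`, `chrom`, `pos`, `cm`.
#' @export
build_marker_map <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "genome_spec"))
  withr_seed(seed)
  map <- purrr::pmap_dfr(spec$chromosomes, function(chrom, length_bp) {
    n <- max(1L, round(spec$marker_density * length_bp / 1e6))
    pos <- sort(sample.int(length_bp, n))
    tibble(chrom = chrom, pos = pos)
  })
  map |>
    mutate(
      cm = .data$pos / 1e6 * spec$cm_per_mbp,
      locus_id = paste0(.data$chrom, "_", .data$pos),
      .before = 1
    ) |>
    select("locus_id", "chrom", "pos", "cm")
}

# local RNG scope: restores .Random.seed on exit so simulator calls are pure
# functions of (inputs, seed) and do not disturb the caller's stream
withr_seed <- function(seed, env = parent.frame()) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  restore <- if (is.null(old)) {
    quote(invisible(NULL))
  } else {
    bquote(assign(".Random.seed", .(old), globalenv()))
  }
  do.call(on.exit, list(restore, TRUE), envir = env)
  set.seed(seed)
  invisible(NULL)
}

# A haplotype is list(brk = segment end positions (bp, last == L), orig =
# origins, one per segment). Segments are closed [prev_brk + 1, brk].
hap_const <- function(L, origin) list(brk = L, orig = origin)

# one meiosis: crossovers ~ Poisson(map length in Morgans), positions uniform
# (linear cM map => uniform in bp), no interference (Haldane), random start
# homolog
meiosis_gamete <- function(hapA, hapB, L_bp, L_morgan) {
  n_xo <- rpois(1L, L_morgan)
  xo <- if (n_xo > 0) sort(runif(n_xo, min = 1, max = L_bp - 1)) else numeric()
  cur <- sample(c(TRUE, FALSE), 1L)
  cuts <- c(floor(xo), L_bp)
  brk <- numeric(0)
  orig <- character(0)
  lo <- 0
  for (hi in cuts) {
    h <- if (cur) hapA else hapB
    keep <- which(h$brk > lo & c(0, h$brk[-length(h$brk)]) < hi)
    seg_end <- pmin(h$brk[keep], hi)
    brk <- c(brk, seg_end)
    orig <- c(orig, h$orig[keep])
    lo <- hi
    cur <- !cur
  }
  # merge adjacent same-origin segments
  keep <- c(orig[-1] != orig[-length(orig)], TRUE)
  list(brk = brk[keep], orig = orig[keep])
}

hap_to_segments <- function(hap) {
  start <- c(1, head(hap$brk, -1) + 1)
  tibble(start = start, end = hap$brk, origin = hap$orig)
}

#' Simulate an intermated RIL population
#'
#' Starting from the F1 of two founders (`B73` x `MO17`), a population is
#' intercrossed for `n_intermating_gens` generations (random pairs, one
#' gamete each) and then selfed for `n_selfing_gens` generations.
#' Homozygosity is idealized: after selfing a final gamete is drawn and
#' doubled, so every RIL is fully homozygous; genotype-call error downstream
#' supplies the residual-heterozygosity realism. Crossovers per chromosome
#' are Poisson with mean equal to the map length in Morgans (Haldane model,
#' no interference).
#'
#' @param spec A [genome_spec()].
#' @param n_rils Number of RILs (default 112, a typical study subset).
#' @param n_intermating_gens Generations of intercrossing (default 4).
#' @param n_selfing_gens Explicit selfing meioses before fixation (default 6).
#' @param seed Integer seed.
#' @return A tibble of mosaic segments: `ril_id`, `chrom`, `start`, `end`,
#'   `origin` (`B73` or `MO17`); segments tile each chromosome exactly.
#' @export
simulate_ril_population <- function(spec, n_rils = 112, n_intermating_gens = 4,
                                    n_selfing_gens = 6, seed = 1) {
  stopifnot(inherits(spec, "genome_spec"))
  if (n_rils < 1) abort("n_rils must be >= 1")
  withr_seed(seed)
  chroms <- spec$chromosomes
  out <- vector("list", nrow(chroms))
  for (ci in seq_len(nrow(chroms))) {
    L <- chroms$length_bp[ci]
    L_m <- L / 1e6 * spec$cm_per_mbp / 100  # Morgans
    f1 <- list(A = hap_const(L, "B73"), B = hap_const(L, "MO17"))
    pop <- rep(list(f1), max(n_rils, 2L))
    if (n_intermating_gens > 0) {
      for (g in seq_len(n_intermating_gens)) {
        pop <- lapply(seq_along(pop), function(i) {
          par <- sample(length(pop), 2L)
          list(
            A = meiosis_gamete(pop[[par[1]]]$A, pop[[par[1]]]$B, L, L_m),
            B = meiosis_gamete(pop[[par[2]]]$A, pop[[par[2]]]$B, L, L_m)
          )
        })
      }
    }
    rils <- lapply(seq_len(n_rils), function(i) {
      ind <- pop[[i]]
      if (n_selfing_gens > 0) {
        for (s in seq_len(n_selfing_gens)) {
          ind <- list(
            A = meiosis_gamete(ind$A, ind$B, L, L_m),
            B = meiosis_gamete(ind$A, ind$B, L, L_m)
          )
        }
      }
      meiosis_gamete(ind$A, ind$B, L, L_m)
    })
    out[[ci]] <- purrr::imap(rils, function(h, i) {
      hap_to_segments(h) |>
        mutate(ril_id = sprintf("RIL%03d", i), chrom = chroms$chrom[ci],
               .before = 1)
    }) |> bind_rows()
  }
  bind_rows(out) |>
    arrange(.data$ril_id, .data$chrom, .data$start)
}

#' Inject third-origin contamination into RIL mosaics
#'
#' Replaces, in a random subset of RILs, stretches of the genome with
#' segments of a third (non-founder) origin, emulating contamination from
#' other genotypes. The returned mosaics still tile every chromosome; the
#' `THIRD` segments are the ground-truth mask downstream recovery tests use.
#'
#' @param mosaics Mosaic tibble from [simulate_ril_population()].
#' @param spec The [genome_spec()] used to build `mosaics`.
#' @param fraction_contaminated_rils Fraction of RILs receiving contamination.
#' @param mean_segment_bp Mean contaminated segment length (exponential).
#' @param segments_per_ril Number of THIRD segments per contaminated RIL.
#' @param genome_fraction If not `NULL`, override `mean_segment_bp` so the
#'   contaminated segments cover about this fraction of the genome.
#' @param seed Integer seed.
#' @return Mosaic tibble with `THIRD` segments spliced in.
#' @export
inject_third_origin <- function(mosaics, spec, fraction_contaminated_rils = 0.05,
                                mean_segment_bp = 3e6, segments_per_ril = 1,
                                genome_fraction = NULL, seed = 1) {
  if (fraction_contaminated_rils < 0 || fraction_contaminated_rils > 1) {
    abort("fraction_contaminated_rils must be in [0, 1]")
  }
  if (fraction_contaminated_rils == 0) return(mosaics)
  withr_seed(seed)
  rils <- unique(mosaics$ril_id)
  n_cont <- round(fraction_contaminated_rils * length(rils))
  if (n_cont == 0) return(mosaics)
  contaminated <- sample(rils, n_cont)
  genome_bp <- sum(spec$chromosomes$length_bp)
  if (!is.null(genome_fraction)) {
    mean_segment_bp <- genome_fraction * genome_bp / segments_per_ril
  }
  extra <- purrr::map_dfr(contaminated, function(r) {
    purrr::map_dfr(seq_len(segments_per_ril), function(k) {
      ci <- sample.int(nrow(spec$chromosomes), 1L)
      L <- spec$chromosomes$length_bp[ci]
      len <- min(L, max(1, round(stats::rexp(1, 1 / mean_segment_bp))))
      start <- sample.int(max(1L, L - len + 1L), 1L)
      tibble(ril_id = r, chrom = spec$chromosomes$chrom[ci],
             start = start, end = start + len - 1, origin = "THIRD")
    })
  })
  splice_segments(mosaics, extra)
}

# overlay `new` segments on top of `base`, keeping the tiling exact
splice_segments <- function(base, new) {
  overlaid <- base |>
    group_by(.data$ril_id, .data$chrom) |>
    group_modify(function(df, key) {
      ins <- new |>
        filter(.data$ril_id == key$ril_id, .data$chrom == key$chrom)
      if (nrow(ins) == 0) return(df)
      for (i in seq_len(nrow(ins))) {
        df <- overlay_one(df, ins$start[i], ins$end[i], ins$origin[i])
      }
      df
    }) |>
    ungroup()
  overlaid |> arrange(.data$ril_id, .data$chrom, .data$start)
}

overlay_one <- function(segs, s, e, origin) {
  pieces <- list()
  for (i in seq_len(nrow(segs))) {
    a <- segs$start[i]; b <- segs$end[i]
    if (b < s || a > e) {
      pieces[[length(pieces) + 1]] <- segs[i, ]
    } else {
      if (a < s) {
        left <- segs[i, ]; left$end <- s - 1
        pieces[[length(pieces) + 1]] <- left
      }
      if (b > e) {
        right <- segs[i, ]; right$start <- e + 1
        pieces[[length(pieces) + 1]] <- right
      }
    }
  }
  newseg <- segs[1, ]
  newseg$start <- s; newseg$end <- e; newseg$origin <- origin
  pieces[[length(pieces) + 1]] <- newseg
  out <- bind_rows(pieces) |> arrange(.data$start)
  # merge adjacent same-origin
  out$grp <- cumsum(c(TRUE, out$origin[-1] != out$origin[-nrow(out)]))
  out |>
    group_by(.data$grp) |>
    summarise(start = min(.data$start), end = max(.data$end),
              origin = first(.data$origin), .groups = "drop") |>
    select(-"grp")
}

#' Look up the mosaic origin at given loci
#'
#' @param mosaics Mosaic tibble.
#' @param map Marker map tibble (`chrom`, `pos`).
#' @return Tibble `ril_id`, `chrom`, `pos`, `origin`.
#' @export
mosaic_origin_at <- function(mosaics, map) {
  mosaics |>
    inner_join(map |> select("chrom", "pos"), by = "chrom",
               relationship = "many-to-many") |>
    filter(.data$pos >= .data$start, .data$pos <= .data$end) |>
    select("ril_id", "chrom", "pos", "origin")
}

#' Simulate genotype calls for founders, RILs and backcross hybrids
#'
#' Emulates the output of a joint genotyping pipeline on RNA-seq data: a long
#' table of per-sample genotype calls with phred-scaled genotype qualities
#' (GQ). The B73 founder carries the reference allele at every marker and
#' Mo17 the alternate; `THIRD` mosaic segments emit alleles matching neither
#' founder (`OTHER` calls). Backcross hybrids are heterozygous wherever the
#' RIL origin differs from the recurrent parent. Calls are flipped to a
#' random wrong genotype with probability `error_rate`, dropped to `MISSING`
#' with probability `missing_rate`, and GQ is a two-component mixture: a
#' `low_fraction` of calls get GQ < 10, the rest GQ = `high`.
#'
#' @param mosaics Mosaic tibble (possibly with `THIRD` segments).
#' @param map Marker map from [build_marker_map()].
#' @param n_founder_reps Founder samples per founder (>= 3 for locus
#'   selection downstream).
#' @param gq_model List with `low_fraction` and `high`.
#' @param missing_rate,error_rate Per-call probabilities in `[0, 1]`.
#' @param third_hom_prob Probability that a RIL `OTHER` call is homozygous
#'   for the third allele (hybrids carry one founder allele, so their
#'   `OTHER` calls are heterozygous).
#' @param seed Integer seed.
#' @return List with `calls` (tibble `sample`, `chrom`, `pos`, `call`,
#'   `other_hom`, `gq`) and `manifest` (tibble `sample`, `type`, `ril_id`);
#'   `type` is one of `B73`, `MO17`, `RIL`, `B73xRIL`, `MO17xRIL`.
#' @export
simulate_genotype_calls <- function(mosaics, map, n_founder_reps = 3,
                                    gq_model = list(low_fraction = 0.05, high = 99),
                                    missing_rate = 0.02, error_rate = 0.006,
                                    third_hom_prob = 0.7, seed = 1) {
  if (error_rate < 0 || error_rate > 1) abort("error_rate must be in [0, 1]")
  if (missing_rate < 0 || missing_rate > 1) abort("missing_rate must be in [0, 1]")
  withr_seed(seed)
  rils <- unique(mosaics$ril_id)
  origin <- mosaic_origin_at(mosaics, map)

  true_one <- function(type, org) {
    switch(type,
      RIL = c(B73 = "HOM_REF", MO17 = "HOM_ALT", THIRD = "OTHER")[org],
      B73xRIL = c(B73 = "HOM_REF", MO17 = "HET", THIRD = "OTHER")[org],
      MO17xRIL = c(B73 = "HET", MO17 = "HOM_ALT", THIRD = "OTHER")[org]
    )
  }

  manifest <- bind_rows(
    tibble(sample = sprintf("B73_rep%d", seq_len(n_founder_reps)),
           type = "B73", ril_id = NA_character_),
    tibble(sample = sprintf("MO17_rep%d", seq_len(n_founder_reps)),
           type = "MO17", ril_id = NA_character_),
    tidyr::expand_grid(type = c("RIL", "B73xRIL", "MO17xRIL"), ril_id = rils) |>
      mutate(sample = paste0(.data$type, "_", .data$ril_id)) |>
      select("sample", "type", "ril_id")
  )

  founder_calls <- tidyr::expand_grid(
    manifest |> filter(.data$type %in% c("B73", "MO17")),
    map |> select("chrom", "pos")
  ) |>
    mutate(call = if_else(.data$type == "B73", "HOM_REF", "HOM_ALT"),
           other_hom = NA)

  line_calls <- manifest |>
    filter(!.data$type %in% c("B73", "MO17")) |>
    inner_join(origin, by = "ril_id", relationship = "many-to-many") |>
    mutate(
      call = unname(purrr::map2_chr(.data$type, .data$origin, true_one)),
      other_hom = if_else(.data$call == "OTHER",
                          if_else(.data$type == "RIL",
                                  runif(n()) < third_hom_prob, FALSE),
                          NA)
    ) |>
    select("sample", "type", "ril_id", "chrom", "pos", "call", "other_hom")

  calls <- bind_rows(founder_calls, line_calls)
  n <- nrow(calls)
  # genotype error: flip to a random different founder-space call
  flip <- runif(n) < error_rate & calls$call != "OTHER"
  if (any(flip)) {
    alt <- purrr::map_chr(calls$call[flip], function(cc) {
      sample(setdiff(c("HOM_REF", "HOM_ALT", "HET"), cc), 1L)
    })
    calls$call[flip] <- alt
  }
  calls$call[runif(n) < missing_rate] <- "MISSING"
  calls$gq <- ifelse(runif(n) < gq_model$low_fraction,
                     sample(0:9, n, replace = TRUE), gq_model$high)
  calls$gq[calls$call == "MISSING"] <- 0L
  list(
    calls = calls |> select("sample", "chrom", "pos", "call", "other_hom", "gq"),
    manifest = manifest
  )
}
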