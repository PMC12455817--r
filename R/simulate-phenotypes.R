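#' Build an alpha-design aeroponic experiment layout
#'
#' Lays out an incomplete-block (alpha) design: each block (biological
#' replicate) is split into batches grown in successive weeks; each batch
#' holds `systems_per_batch` aeroponic growth systems of `rows_per_system`
#' rows with `plants_per_row` planting sites. Three successive rows form a
#' triplet housing a RIL with its two backcross hybrids; each batch
#' additionally carries `ref_triplets_per_batch` reference triplets with the
#' founder inbreds and one reference hybrid. Triplets are randomized to
#' batches, systems and row slots independently within every block.
#'
#' @param ril_ids RIL identifiers; one triplet (RIL, B73xRIL, MO17xRIL) per
#'   RIL per block.
#' @param n_blocks,batches_per_block,systems_per_batch,rows_per_system,plants_per_row
#'   Layout dimensions (defaults: 3 blocks, 4 batches, 8 systems, 12 rows,
#'   8 plants).
#' @param ref_triplets_per_batch Reference triplets added to every batch.
#' @param seed Integer seed.
#' @return Design tibble with one row per plant: `block`, `batch`,
#'   `system`, `sys_row`, `plant`, `triplet`, `genotype`, `type`, `ril_id`,
#'   and unique nested factor labels `batch_id`, `system_id`, `triplet_id`,
#'   `row_id`.
#' @export
build_experimental_design <- function(ril_ids, n_blocks = 3,
                                      batches_per_block = 4,
                                      systems_per_batch = 8,
                                      rows_per_system = 12,
                                      plants_per_row = 8,
                                      ref_triplets_per_batch = 2,
                                      seed = 1) {
  triplets_per_system <- rows_per_system %/% 3
  capacity <- batches_per_block * systems_per_batch * triplets_per_system
  n_ril_triplets <- length(ril_ids)
  n_total <- n_ril_triplets + ref_triplets_per_batch * batches_per_block
  if (n_total > capacity) {
    abort(sprintf("design capacity exceeded: %d triplets > %d slots",
                  n_total, capacity))
  }
  withr_seed(seed)
  ref_content <- list(
    c("B73", "MO17", "B73xMO17"),
    c("B73", "MO17", "MO17xB73")
  )
  blocks <- purrr::map_dfr(seq_len(n_blocks), function(b) {
    # slots: (batch, system, triplet-within-system)
    slots <- tidyr::expand_grid(batch = seq_len(batches_per_block),
                                system = seq_len(systems_per_batch),
                                slot = seq_len(triplets_per_system))
    # reference triplets pinned per batch, RIL triplets randomized over rest
    refs <- tidyr::expand_grid(batch = seq_len(batches_per_block),
                               k = seq_len(ref_triplets_per_batch)) |>
      mutate(content = purrr::map(.data$k, function(k) {
        ref_content[[(k - 1) %% length(ref_content) + 1]]
      }),
      triplet = paste0("REF", .data$batch, "_", .data$k))
    ref_slots <- refs |>
      group_by(.data$batch) |>
      group_modify(function(df, key) {
        avail <- slots |> filter(.data$batch == key$batch)
        pick <- avail[sample.int(nrow(avail), nrow(df)), ]
        bind_cols(df, pick |> select("system", "slot"))
      }) |>
      ungroup()
    remaining <- anti_join(slots, ref_slots |> select("batch", "system", "slot"),
                           by = c("batch", "system", "slot"))
    ril_pick <- remaining[sample.int(nrow(remaining), n_ril_triplets), ]
    ril_tr <- ril_pick |>
      mutate(triplet = ril_ids,
             content = purrr::map(ril_ids, function(r) {
               sample(c(paste0("RIL_", r), paste0("B73xRIL_", r),
                        paste0("MO17xRIL_", r)))
             }))
    bind_rows(ref_slots |> select("batch", "system", "slot", "triplet", "content"),
              ril_tr) |>
      mutate(block = b)
  })
  long <- blocks |>
    mutate(row_in_triplet = list(1:3)) |>
    unnest(c("content", "row_in_triplet")) |>
    rename(genotype = "content") |>
    mutate(sys_row = (.data$slot - 1) * 3 + .data$row_in_triplet) |>
    tidyr::expand_grid(plant = seq_len(plants_per_row))
  long |>
    mutate(
      type = dplyr::case_when(
        .data$genotype %in% c("B73", "MO17") ~ .data$genotype,
        grepl("^B73xMO17|^MO17xB73", .data$genotype) ~ "REF_HYBRID",
        grepl("^RIL_", .data$genotype) ~ "RIL",
        grepl("^B73xRIL_", .data$genotype) ~ "B73xRIL",
        grepl("^MO17xRIL_", .data$genotype) ~ "MO17xRIL"
      ),
      ril_id = if_else(.data$type %in% c("RIL", "B73xRIL", "MO17xRIL"),
                       sub("^[^_]+_", "", .data$genotype), NA_character_),
      batch_id = paste0("b", .data$block, ".p", .data$batch),
      system_id = paste0(.data$batch_id, ".s", .data$system),
      triplet_id = paste0(.data$system_id, ".t", .data$slot),
      row_id = paste0(.data$triplet_id, ".r", .data$row_in_triplet)
    ) |>
    select("block", "batch", "system", "sys_row", "plant", "triplet",
           "genotype", "type", "ril_id", "batch_id", "system_id",
           "triplet_id", "row_id") |>
    arrange(.data$block, .data$batch, .data$system, .data$sys_row, .data$plant)
}

#' Generative model for phenotypes
#'
#' Holds every parameter of the trait-generating regression: per-parent
#' effects, block effects, the heterosis intercept, slopes on the four
#' SPE-pattern counts, and the design and genetic variance components.
#'
#' @param beta Named vector of parental genotype effects (one per parent
#'   appearing in the pedigree, including the founders).
#' @param block Vector of block effects (first is the reference 0).
#' @param phi Heterosis intercept (mean deviation of hybrids from
#'   mid-parent).
#' @param gamma Length-4 slopes on the SPE-pattern counts.
#' @param sigma2 Named list/vector of variance components: `batch`,
#'   `system`, `triplet`, `row`, `het` (hybrid deviation), `resid`.
#' @return Object of class `phenotype_gen_model`.
#' @export
phenotype_gen_model <- function(beta, block = c(0, 0, 0), phi = 1,
                                gamma = c(0.002, 0.002, 0.001, 0.001),
                                sigma2 = c(batch = 0.05, system = 0.05,
                                           triplet = 0.05, row = 0.05,
                                           het = 0.1, resid = 0.25)) {
  sigma2 <- unlist(sigma2)
  needed <- c("batch", "system", "triplet", "row", "het", "resid")
  stopifnot(all(needed %in% names(sigma2)))
  if (any(sigma2 < 0)) abort("variance components must be >= 0")
  if (length(gamma) != 4) abort("gamma must have length 4")
  structure(list(beta = beta, block = block, phi = phi, gamma = gamma,
                 sigma2 = sigma2[needed]),
            class = "phenotype_gen_model")
}

#' Simulate plant-level phenotypes from the generative model
#'
#' Parents receive their parental effect plus block and nested design
#' effects; hybrids additionally receive the mid-parent construction
#' (half of each parent's effect), the heterosis intercept, the SPE-count
#' regression part and a genotype-specific random heterosis deviation.
#' The ground-truth p_Het implied by the drawn SPE counts and variances is
#' returned for recovery tests.
#'
#' @param design From [build_experimental_design()].
#' @param gen_model A [phenotype_gen_model()].
#' @param spe_counts Tibble `genotype`, `sa`, `sb`, `sc`, `sd` with one row
#'   per hybrid genotype in the design.
#' @param seed Integer seed.
#' @return List: `phenotypes` (design + `value`), `true_p_het`,
#'   `true_sigma2_het`, `true_sigma2_g`, `hybrid_effects`.
#' @export
simulate_phenotypes <- function(design, gen_model, spe_counts, seed = 1) {
  stopifnot(inherits(gen_model, "phenotype_gen_model"))
  withr_seed(seed)
  hybrids <- design |>
    filter(.data$type %in% c("B73xRIL", "MO17xRIL", "REF_HYBRID")) |>
    distinct(.data$genotype)
  missing_counts <- setdiff(hybrids$genotype, spe_counts$genotype)
  if (length(missing_counts) > 0) {
    abort(paste0("SPE counts missing for hybrid(s): ",
                 paste(head(missing_counts, 3), collapse = ", ")))
  }
  s2 <- gen_model$sigma2
  draw <- function(ids, s) setNames(rnorm(length(ids), 0, sqrt(s)), ids)
  eff <- list(
    batch = draw(unique(design$batch_id), s2["batch"]),
    system = draw(unique(design$system_id), s2["system"]),
    triplet = draw(unique(design$triplet_id), s2["triplet"]),
    row = draw(unique(design$row_id), s2["row"])
  )
  g_het <- draw(hybrids$genotype, s2["het"])

  ped <- pedigree_from_design(design)
  pm <- ped |> filter(!is.na(.data$parent1))
  mid_beta <- setNames(
    0.5 * gen_model$beta[pm$parent1] + 0.5 * gen_model$beta[pm$parent2],
    pm$genotype
  )
  sc <- spe_counts
  gamma_part <- setNames(
    as.vector(as.matrix(sc[, c("sa", "sb", "sc", "sd")]) %*% gen_model$gamma),
    sc$genotype
  )
  is_hyb <- design$genotype %in% pm$genotype
  base <- numeric(nrow(design))
  base[!is_hyb] <- gen_model$beta[design$genotype[!is_hyb]]
  base[is_hyb] <- mid_beta[design$genotype[is_hyb]] + gen_model$phi +
    gamma_part[design$genotype[is_hyb]] + g_het[design$genotype[is_hyb]]
  value <- base +
    gen_model$block[design$block] +
    eff$batch[design$batch_id] + eff$system[design$system_id] +
    eff$triplet[design$triplet_id] + eff$row[design$row_id] +
    rnorm(nrow(design), 0, sqrt(s2["resid"]))

  v_gamma <- stats::var(gamma_part[hybrids$genotype])
  true_sigma2_g <- v_gamma + s2[["het"]]
  list(
    phenotypes = design |> mutate(value = unname(value)),
    true_p_het = if (true_sigma2_g > 0) 1 - s2[["het"]] / true_sigma2_g else NA_real_,
    true_sigma2_het = s2[["het"]],
    true_sigma2_g = unname(true_sigma2_g),
    hybrid_effects = g_het
  )
}

#' Pedigree implied by the design's genotype labels
#'
#' @param design Design tibble (or any tibble with `genotype` labels of the
#'   forms `B73`, `MO17`, `RIL_<id>`, `B73xRIL_<id>`, `MO17xRIL_<id>`,
#'   `B73xMO17`, `MO17xB73`).
#' @return Tibble `genotype`, `parent1`, `parent2` (`NA` for parents).
#' @export
pedigree_from_design <- function(design) {
  design |>
    distinct(.data$genotype) |>
    mutate(
      parent1 = dplyr::case_when(
        grepl("^B73x", .data$genotype) ~ "B73",
        grepl("^MO17x", .data$genotype) ~ "MO17",
        TRUE ~ NA_character_
      ),
      parent2 = dplyr::case_when(
        .data$genotype %in% c("B73xMO17") ~ "MO17",
        .data$genotype %in% c("MO17xB73") ~ "B73",
        grepl("^(B73|MO17)xRIL_", .data$genotype) ~
          sub("^(B73|MO17)x", "", .data$genotype),
        TRUE ~ NA_character_
      )
    )
}
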