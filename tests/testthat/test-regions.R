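test_that("high-confidence locus selection enforces the 90%/min-3 and GQ rules", {
  loci <- tibble::tibble(chrom = "chr1", pos = 1e6)
  man <- founder_manifest(10, 10)
  mk <- function(n_mo17_alt, n_mo17 = 10, n_b73_ref = 10, n_b73 = 10,
                 gq_mo17 = 99) {
    dplyr::bind_rows(
      tidyr::expand_grid(sample = sprintf("B73_rep%d", 1:n_b73), loci) |>
        dplyr::mutate(call = dplyr::if_else(dplyr::row_number() <= n_b73_ref,
                                            "HOM_REF", "HET")),
      tidyr::expand_grid(sample = sprintf("MO17_rep%d", 1:n_mo17), loci) |>
        dplyr::mutate(call = dplyr::if_else(dplyr::row_number() <= n_mo17_alt,
                                            "HOM_ALT", "HET"))
    ) |>
      dplyr::mutate(other_hom = NA, gq = gq_mo17)
  }
  # 9/10 = 90% HOM_ALT in Mo17, all B73 reference -> retained
  expect_equal(nrow(select_high_confidence_loci(mk(9), man)), 1)
  # 8/10 < 90% -> rejected
  expect_equal(nrow(select_high_confidence_loci(mk(8), man)), 0)
  # only 2 qualifying Mo17 calls, both HOM_ALT (100%) -> rejected (min 3)
  man2 <- founder_manifest(10, 2)
  two <- mk(2, n_mo17 = 2)
  expect_equal(nrow(select_high_confidence_loci(two, man2)), 0)
  # GQ 9 calls are excluded before counting: 3 of 10 Mo17 calls qualify
  gq_mixed <- mk(10) |>
    dplyr::mutate(gq = dplyr::if_else(grepl("MO17", sample) &
                                        sample > "MO17_rep3", 9L, 99L))
  expect_equal(nrow(select_high_confidence_loci(gq_mixed, man)), 1)
  expect_error(select_high_confidence_loci(mk(9),
                                           founder_manifest(0, 0)[0, ]),
               "founder")
})

test_that("sample homozygosity filter uses a strict 95% boundary", {
  loci <- tibble::tibble(chrom = "chr1", pos = as.numeric(1:100))
  mk_sample <- function(id, n_het) {
    tibble::tibble(sample = id, chrom = "chr1", pos = as.numeric(1:100),
                   call = c(rep("HET", n_het), rep("HOM_REF", 100 - n_het)),
                   other_hom = NA, gq = 99L)
  }
  calls <- dplyr::bind_rows(mk_sample("s96", 4), mk_sample("s94", 6),
                            mk_sample("s95", 5),
                            tibble::tibble(sample = "s_empty", chrom = "chr1",
                                           pos = as.numeric(1:100),
                                           call = "MISSING", other_hom = NA,
                                           gq = 0L))
  res <- filter_samples_by_homozygosity(calls, loci)
  got <- setNames(res$kept, res$sample)
  expect_true(got[["s96"]])
  expect_false(got[["s94"]])
  expect_true(got[["s95"]])   # exactly 0.95 is kept ("less than" is strict)
  expect_false(got[["s_empty"]])
  expect_equal(res$reason[res$sample == "s_empty"], "no_informative_loci")
})

test_that("RIL-specific flagging ignores GQ and founder alleles", {
  hc <- tibble::tibble(chrom = "chr1", pos = c(1e6, 2e6, 3e6))
  rc <- tibble::tibble(
    sample = "RIL_A", chrom = "chr1", pos = c(1e6, 2e6, 3e6),
    call = c("OTHER", "HOM_ALT", "MISSING"),
    other_hom = c(TRUE, NA, NA), gq = c(2L, 99L, 0L)
  )
  fl <- flag_ril_specific_loci(rc, hc)
  expect_equal(fl$pos, 1e6)   # OTHER flagged even at GQ 2
  expect_true(fl$hom)
})

test_that("third-origin masking applies the 2.5-Mbp grouping and 10/5 rule", {
  mk_flags <- function(n, n_hom, spacing = 0.2e6) {
    tibble::tibble(sample = "RIL_A", chrom = "chr1",
                   pos = 1e6 + spacing * (seq_len(n) - 1),
                   hom = seq_len(n) <= n_hom)
  }
  m1 <- mask_third_origin(mk_flags(10, 5))
  expect_equal(nrow(m1), 1)
  expect_equal(m1$start, 1e6)
  expect_equal(m1$end, 1e6 + 0.2e6 * 9)
  expect_equal(nrow(mask_third_origin(mk_flags(9, 9))), 0)
  expect_equal(nrow(mask_third_origin(mk_flags(10, 4))), 0)
  # loci >= 2.5 Mbp apart split into blocks that fail the count rule
  spread <- mk_flags(10, 10, spacing = 2.6e6)
  expect_equal(nrow(mask_third_origin(spread)), 0)
})

test_that("window classification uses 11/15 Mo17 and 12/15 B73 majorities", {
  hc <- tibble::tibble(chrom = "chr1", pos = as.numeric(1:15) * 1e5)
  mk <- function(calls) {
    tibble::tibble(sample = "RIL_A", chrom = "chr1",
                   pos = as.numeric(1:15) * 1e5, call = calls,
                   other_hom = NA, gq = 99L)
  }
  # 12 HOM_REF out of 15 -> B73 window; the 12 matching loci survive
  v12 <- mk(c(rep("HOM_REF", 12), rep("HOM_ALT", 3)))
  s12 <- classify_by_windows(v12, hc)
  expect_equal(sort(unique(s12$allele)), "B73")
  expect_equal(nrow(s12), 12)
  # 11 HOM_REF is ambiguous (B73 needs 12) -> everything dropped
  v11 <- mk(c(rep("HOM_REF", 11), rep("HOM_ALT", 4)))
  expect_equal(nrow(classify_by_windows(v11, hc)), 0)
  # 11 HOM_ALT -> Mo17 window
  a11 <- mk(c(rep("HOM_ALT", 11), rep("HOM_REF", 4)))
  s11 <- classify_by_windows(a11, hc)
  expect_equal(sort(unique(s11$allele)), "MO17")
  expect_equal(nrow(s11), 11)
  # fewer than 15 usable loci -> warning, all ambiguous
  short <- mk(rep("HOM_REF", 15))[1:10, ]
  expect_warning(out <- classify_by_windows(short, hc), "ambiguous")
  expect_equal(nrow(out), 0)
})

test_that("allele blocks split at 0.5 Mbp or allele changes", {
  loci <- tibble::tibble(
    sample = "RIL_A", chrom = "chr1",
    pos = c(1.0e6, 1.2e6, 1.9e6), allele = "B73"
  )
  b <- merge_allele_blocks(loci)
  expect_equal(nrow(b), 2)
  expect_equal(b$start, c(1.0e6, 1.9e6))
  expect_equal(b$end, c(1.2e6, 1.9e6))   # singleton = zero-length block
  alt <- loci |> dplyr::mutate(allele = c("B73", "MO17", "B73"),
                               pos = c(1.0e6, 1.1e6, 1.2e6))
  expect_equal(nrow(merge_allele_blocks(alt)), 3)
})

test_that("contamination exclusion uses a strict 50% boundary", {
  reg <- function(frac) {
    total <- 100e6
    list(
      regions = tibble::tibble(sample = "RIL_A", chrom = "chr1", start = 1,
                               end = (1 - frac) * total, origin = "B73"),
      masked = if (frac > 0) {
        tibble::tibble(sample = "RIL_A", chrom = "chr2", start = 1,
                       end = frac * total, origin = "MASKED_THIRD")
      } else {
        tibble::tibble(sample = character(), chrom = character(),
                       start = numeric(), end = numeric(),
                       origin = character())
      }
    )
  }
  ex <- function(frac) {
    r <- reg(frac)
    exclude_contaminated_rils(r$regions, r$masked)$kept
  }
  expect_false(ex(0.6))
  expect_true(ex(0.5))   # exactly 50% is kept (strict >)
  expect_true(ex(0))
})

test_that("gene zygosity mirrors between the two backcrosses", {
  regions <- tibble::tibble(
    chrom = "chr1", start = c(1, 10e6 + 1), end = c(10e6, 20e6),
    origin = c("MO17", "B73")
  )
  masked <- tibble::tibble(chrom = "chr1", start = 30e6, end = 32e6,
                           origin = "MASKED_THIRD")
  genes <- tibble::tibble(
    gene_id = c("g_mo17", "g_b73", "g_masked", "g_none", "g_straddle"),
    chrom = "chr1",
    start = c(5e6, 15e6, 31e6, 50e6, 9.9e6),
    end = c(5e6 + 1e3, 15e6 + 1e3, 31e6 + 1e3, 50e6 + 1e3, 10.2e6)
  )
  zb <- suppressWarnings(annotate_gene_zygosity(genes, regions, masked,
                                                "B73xRIL"))
  zm <- suppressWarnings(annotate_gene_zygosity(genes, regions, masked,
                                                "MO17xRIL"))
  gz <- function(z, g) z$zygosity[z$gene_id == g]
  expect_equal(gz(zb, "g_mo17"), "HET")
  expect_equal(gz(zm, "g_mo17"), "HOM_MO17")  # mirrored
  expect_equal(gz(zb, "g_b73"), "HOM_B73")
  expect_equal(gz(zm, "g_b73"), "HET")
  expect_equal(gz(zb, "g_masked"), "MASKED")
  expect_equal(gz(zb, "g_none"), "NO_INFO")
  expect_warning(annotate_gene_zygosity(genes, regions, masked, "B73xRIL"),
                 "straddle")
  expect_equal(gz(zb, "g_straddle"), "NO_INFO")
})

test_that("heterozygosity fraction excludes masked and uninformative length", {
  mk_reg <- function(mo17_mbp, b73_mbp) {
    tibble::tibble(
      chrom = "chr1",
      start = c(1, mo17_mbp * 1e6 + 1),
      end = c(mo17_mbp * 1e6, (mo17_mbp + b73_mbp) * 1e6),
      origin = c("MO17", "B73")
    )
  }
  expect_equal(heterozygosity_fraction(mk_reg(50, 50), "B73xRIL"), 0.5,
               tolerance = 1e-6)
  all_b73 <- tibble::tibble(chrom = "chr1", start = 1, end = 100e6,
                            origin = "B73")
  expect_equal(heterozygosity_fraction(all_b73, "B73xRIL"), 0)
  # 40 Mbp Mo17 + 40 Mbp B73 + 20 Mbp masked -> 40/80 by the denominator rule
  with_mask <- dplyr::bind_rows(
    mk_reg(40, 40),
    tibble::tibble(chrom = "chr1", start = 80e6 + 1, end = 100e6,
                   origin = "MASKED_THIRD")
  )
  expect_equal(heterozygosity_fraction(with_mask, "B73xRIL"), 0.5,
               tolerance = 1e-6)
})

test_that("classification recovers simulated mosaics and masks injected segments", {
  cr <- tiny_cross(n_rils = 8, seed = 77, error_rate = 0.006,
                   missing_rate = 0.02, low_gq = 0.05, third = 0.25)
  cls <- classify_ril_regions(cr$calls, cr$manifest)
  truth <- cr$mosaics
  # measure correctly assigned length over non-THIRD genome
  reg <- cls$regions
  correct <- 0; assigned <- 0
  for (i in seq_len(nrow(reg))) {
    tr <- truth |>
      dplyr::filter(ril_id == reg$ril_id[i], chrom == reg$chrom[i],
                    end >= reg$start[i], start <= reg$end[i])
    for (j in seq_len(nrow(tr))) {
      ov <- min(tr$end[j], reg$end[i]) - max(tr$start[j], reg$start[i]) + 1
      if (tr$origin[j] != "THIRD") {
        assigned <- assigned + ov
        if (tr$origin[j] == reg$origin[i]) correct <- correct + ov
      }
    }
  }
  expect_gt(correct / assigned, 0.99)
  # every injected THIRD segment >= 2 Mbp is covered by a mask
  big_third <- truth |>
    dplyr::filter(origin == "THIRD", end - start + 1 >= 2e6)
  if (nrow(big_third) > 0) {
    for (i in seq_len(nrow(big_third))) {
      hit <- cls$masked |>
        dplyr::filter(ril_id == big_third$ril_id[i],
                      chrom == big_third$chrom[i],
                      start <= big_third$end[i], end >= big_third$start[i])
      expect_gt(nrow(hit), 0)
    }
  }
})
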