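# small deterministic cross for scan tests
mk_cross <- function(n_ind = 120, n_mark = 40, chroms = c("chr1", "chr2"),
                     seed = 1, missing = 0) {
  withr::with_seed(seed, {
    map <- purrr::map_dfr(chroms, function(ch) {
      tibble::tibble(
        marker = paste0(ch, "_m", seq_len(n_mark)),
        chrom = ch,
        pos = seq(1e6, 40e6, length.out = n_mark),
        cm = seq(0, 100, length.out = n_mark)
      )
    })
    # simulate RIL genotypes marker by marker with ~5% recombination
    g <- matrix(NA_integer_, n_ind, nrow(map))
    for (ch in chroms) {
      idx <- which(map$chrom == ch)
      g[, idx[1]] <- sample(1:2, n_ind, TRUE)
      for (j in idx[-1]) {
        flip <- runif(n_ind) < 0.08
        g[, j] <- ifelse(flip, 3L - g[, j - 1], g[, j - 1])
      }
    }
    if (missing > 0) g[runif(length(g)) < missing] <- NA
    rownames(g) <- sprintf("ind%03d", seq_len(n_ind))
    colnames(g) <- map$marker
  })
  cross_geno(g, map, "rilself")
}

test_that("marker preparation applies the missingness and 1-cM thinning rules", {
  map <- tibble::tibble(marker = paste0("m", 1:10), chrom = "chr1",
                        pos = (1:10) * 2e6, cm = (1:10) * 5)
  set.seed(1)
  g <- matrix(sample(1:2, 80, TRUE), nrow = 8, ncol = 10,
              dimnames = list(paste0("i", 1:8), map$marker))
  g[1, 1:3] <- NA                               # 30% missing individual
  g[4:8, 3] <- NA                               # marker m3: 5/7 missing
  g[3, ] <- g[2, ]                              # duplicate individual
  cr <- cross_geno(g, map, "rilself")
  prep <- prepare_markers(cr, pseudo_step = NULL, min_cm = 1)
  expect_false("i1" %in% rownames(prep$geno))   # 25% > 19% missing
  expect_equal(sum(rownames(prep$geno) %in% c("i2", "i3")), 1)  # dedup
  expect_false("m3" %in% colnames(prep$geno))   # 5/7 > 60% missing marker
  # thinning: 0, 0.5, 1.2 cM -> keep {0, 1.2} by the greedy rule
  map2 <- tibble::tibble(marker = c("t1", "t2", "t3"), chrom = "chr1",
                         pos = c(1e6, 1.5e6, 2.2e6), cm = c(0, 0.5, 1.2))
  g2 <- matrix(1L, 4, 3, dimnames = list(paste0("j", 1:4), map2$marker))
  g2[2, ] <- 2L
  prep2 <- prepare_markers(cross_geno(g2, map2, "rilself"),
                           pseudo_step = NULL)
  expect_equal(colnames(prep2$geno), c("t1", "t3"))
  # pseudomarkers are interleaved on a 1-cM grid with interpolated bp
  prep3 <- prepare_markers(cross_geno(g2, map2, "rilself"), pseudo_step = 1)
  expect_true(any(is.na(prep3$grid$marker)))
  expect_false(is.unsorted(prep3$grid$cm))
})

test_that("HMM genotype probabilities are calibrated and conserved", {
  map <- tibble::tibble(marker = paste0("m", 1:3), chrom = "chr1",
                        pos = c(1e6, 2e6, 3e6), cm = c(0, 1, 2))
  g <- matrix(c(1L, 1L, 1L,
                2L, 2L, 2L,
                1L, NA, 1L), nrow = 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), map$marker))
  prep <- prepare_markers(cross_geno(g, map, "rilself"), pseudo_step = NULL,
                          max_ind_missing = 0.5)
  pr <- genotype_probabilities(prep, error_prob = 0)
  # fully observed, error 0 -> indicator probabilities
  expect_equal(unname(pr$prob["a", ]), c(0, 0, 0))
  expect_equal(unname(pr$prob["b", ]), c(1, 1, 1))
  # missing marker flanked by identical calls 1 cM away -> posterior > 0.99
  pr2 <- genotype_probabilities(prep, error_prob = 0.001)
  expect_lt(pr2$prob["c", 2], 0.01)
  # hand-computed forward-backward oracle for the missing middle marker
  r <- 0.5 * (1 - exp(-2 * 1 / 100)); R <- 2 * r / (1 + 2 * r)
  e <- 0.001
  states <- expand.grid(s1 = 1:2, s2 = 1:2, s3 = 1:2)
  joint <- apply(states, 1, function(s) {
    em <- function(st, obs) if (st == obs) 1 - e else e
    trans <- function(s_a, s_b) if (s_a == s_b) 1 - R else R
    0.5 * em(s[1], 1) * trans(s[1], s[2]) * 1 * trans(s[2], s[3]) *
      em(s[3], 1)
  })
  post2 <- sum(joint[states$s2 == 2]) / sum(joint)
  expect_equal(unname(pr2$prob["c", 2]), post2, tolerance = 1e-12)
  # probabilities sum to one everywhere by construction (P1 = 1 - P2)
  expect_true(all(pr2$prob >= 0 & pr2$prob <= 1))
})

test_that("Haley-Knott LOD agrees with per-position regression to 1e-8", {
  cr <- mk_cross(n_ind = 80, n_mark = 15, chroms = "chr1", seed = 5)
  prep <- prepare_markers(cr)
  pr <- genotype_probabilities(prep)
  n <- nrow(pr$prob)
  set.seed(6)
  y <- pr$prob[, 10] * 1.5 + rnorm(n)
  scan <- hk_scan(pr, y)
  oracle <- vapply(seq_len(ncol(pr$prob)), function(j) {
    fit <- lm(y ~ pr$prob[, j])
    rss1 <- sum(resid(fit)^2)
    rss0 <- sum((y - mean(y))^2)
    n / 2 * log10(rss0 / rss1)
  }, numeric(1))
  expect_lt(max(abs(scan$lod[, 1] - oracle)), 1e-8)
  # zero-variance phenotype -> flat zero curve
  expect_true(all(hk_scan(pr, rep(3, n))$lod == 0))
  # exact fit capped at the documented ceiling
  expect_equal(max(hk_scan(pr, pr$prob[, 10])$lod), 300)
})

test_that("permutation p-values are reproducible, monotone and calibrated", {
  cr <- mk_cross(n_ind = 60, n_mark = 12, chroms = "chr1", seed = 7)
  prep <- prepare_markers(cr)
  pr <- genotype_probabilities(prep)
  n <- nrow(pr$prob)
  set.seed(8)
  y <- cbind(null1 = rnorm(n), strong = pr$prob[, 5] * 3 + rnorm(n))
  p1 <- scan_permutations(pr, y, n_perm = 200, seed = 99)
  p2 <- scan_permutations(pr, y, n_perm = 200, seed = 99)
  expect_identical(p1$p_adj, p2$p_adj)
  expect_lt(p1$p_adj[p1$phenotype == "strong"], 0.01)
  # observed above all maxima reports below-resolution p
  expect_equal(p1$p_adj[2], 0.5 / 200)
  expect_warning(scan_permutations(pr, y[, 1], n_perm = 50, seed = 1),
                 "resolution")
  # p monotone non-increasing in observed LOD against shared maxima
  maxima <- attr(p1, "maxima")[, 1]
  lods <- seq(0, 5, by = 0.5)
  ps <- vapply(lods, function(L) mean(maxima >= L), numeric(1))
  expect_true(all(diff(ps) <= 0))
})

test_that("genome-wide null type-I error stays at the permutation alpha", {
  cr <- mk_cross(n_ind = 100, n_mark = 20, chroms = c("chr1", "chr2"),
                 seed = 9)
  prep <- prepare_markers(cr)
  pr <- genotype_probabilities(prep)
  set.seed(10)
  Y <- matrix(rnorm(nrow(pr$prob) * 120), nrow(pr$prob), 120)
  res <- scan_permutations(pr, Y, n_perm = 400, alpha = 0.01, seed = 11)
  # at alpha = 0.01 expect ~1.2 significant of 120; allow Poisson slack
  expect_lte(sum(res$significant), 6)
  # adjusted p approximately uniform under the null
  ks <- suppressWarnings(stats::ks.test(res$p_adj, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("peak finding separates maxima and reports 1.5-LOD intervals", {
  grid <- tibble::tibble(chrom = "chr1", cm = 0:20,
                         pos = (0:20) * 1e6 + 1, marker = NA_character_)
  mk_scan <- function(lod) {
    structure(list(lod = matrix(lod, ncol = 1,
                                dimnames = list(NULL, "g")),
                   grid = grid, n = 100),
              class = "eqtl_scan")
  }
  # monotone curve -> single boundary peak
  mono <- mk_scan(seq(0, 10, by = 0.5))
  pk <- find_peaks(mono, "g", threshold = 3)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$cm, 20)
  # two maxima with a deep valley -> two peaks
  two <- mk_scan(c(0:5 * 2, 4, 2, 1, 2, 4, 6:10, 10:7) * 1)
  pk2 <- find_peaks(two, "g", threshold = 3)
  expect_equal(nrow(pk2), 2)
  # support interval spans the region within 1.5 LOD of the peak
  bump <- mk_scan(c(rep(0, 5), 2, 4, 6, 4, 2, rep(0, 11)))
  pk3 <- find_peaks(bump, "g", threshold = 3)
  expect_equal(pk3$pos, 7e6 + 1)
  expect_equal(pk3$ci_lo, 6e6 + 1)   # lod 4 >= 6 - 1.5 fails at lod 2
  expect_equal(pk3$ci_hi, 8e6 + 1)
})

test_that("across-genes FDR matches direct Benjamini-Hochberg", {
  set.seed(12)
  p <- c(1e-6, 1e-4, 0.002, 0.04, 0.5, 1, 1, 0.03, 0.0005, 0.2,
         0.9, 0.07, 1e-5, 0.6, 0.015, 0.33, 0.08, 0.44, 0.0001, 0.91)
  peaks <- tibble::tibble(phenotype = paste0("g", 1:20), p_adj = p)
  out <- fdr_across_genes(peaks, n_genes_total = 500, fdr = 0.05)
  expect_equal(out$q, p.adjust(p, "BH", n = 500))
  # second peaks add to the effective n
  peaks2 <- dplyr::bind_rows(peaks,
                             tibble::tibble(phenotype = "g1", p_adj = 0.01))
  out2 <- fdr_across_genes(peaks2, n_genes_total = 500)
  expect_equal(out2$q, p.adjust(c(p, 0.01), "BH", n = 501))
  expect_true(all(fdr_across_genes(
    tibble::tibble(phenotype = "a", p_adj = 1), 10)$q == 1))
})

test_that("peak merging honors the 25-Mbp and CI-containment clauses", {
  mk_pk <- function(pos, lod, lo, hi, chrom = "chr1") {
    tibble::tibble(phenotype = "g", chrom = chrom, pos = pos, cm = pos / 1e6,
                   lod = lod, ci_lo = lo, ci_hi = hi)
  }
  # 30 Mbp apart, disjoint CIs -> both kept
  far <- dplyr::bind_rows(mk_pk(10e6, 8, 9e6, 11e6),
                          mk_pk(40e6, 6, 39e6, 41e6))
  expect_equal(nrow(merge_peaks(far)), 2)
  # 10 Mbp apart -> same eQTL, shorter CI wins
  near <- dplyr::bind_rows(mk_pk(10e6, 6, 5e6, 15e6),
                           mk_pk(20e6, 8, 18e6, 22e6))
  m <- merge_peaks(near)
  expect_equal(nrow(m), 1)
  expect_equal(m$pos, 20e6)
  # equal CI lengths -> higher LOD wins
  tie <- dplyr::bind_rows(mk_pk(10e6, 6, 9e6, 11e6),
                          mk_pk(12e6, 9, 11e6, 13e6))
  expect_equal(merge_peaks(tie)$lod, 9)
  # far apart but CI containment -> merged
  contain <- dplyr::bind_rows(mk_pk(10e6, 6, 5e6, 45e6),
                              mk_pk(40e6, 8, 39e6, 41e6))
  expect_equal(nrow(merge_peaks(contain)), 1)
  # different chromosomes -> kept apart
  chroms <- dplyr::bind_rows(mk_pk(10e6, 6, 9e6, 11e6),
                             mk_pk(10e6, 8, 9e6, 11e6, chrom = "chr2"))
  expect_equal(nrow(merge_peaks(chroms)), 2)
})

test_that("cis/trans classification uses distance, chromosome and CI clauses", {
  genes <- tibble::tibble(gene_id = "g", chrom = "chr1", start = 10e6)
  mk_pk <- function(chrom, pos, lo, hi) {
    tibble::tibble(phenotype = "g", chrom = chrom, pos = pos, cm = 1,
                   lod = 10, ci_lo = lo, ci_hi = hi)
  }
  cls <- function(p) classify_cis_trans(p, genes)$regulation
  expect_equal(cls(mk_pk("chr1", 11e6, 10.5e6, 11.5e6)), "cis")  # 1 Mbp
  expect_equal(cls(mk_pk("chr2", 10e6, 9e6, 11e6)), "trans")     # other chrom
  expect_equal(cls(mk_pk("chr1", 13e6, 9.5e6, 13.5e6)), "cis")   # CI spans
  expect_equal(cls(mk_pk("chr1", 13e6, 12.8e6, 13.5e6)), "trans")
})
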