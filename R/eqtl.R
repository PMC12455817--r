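#' Construct a cross genotype object
#'
#' Genotype codes are 1 (A/A, the B73 homozygote) and 2 (B/B, the Mo17
#' homozygote) for selfed RILs, or 1 (recurrent homozygote) and 2
#' (heterozygote) for a backcross; `NA` is missing.
#'
#' @param geno Individuals x markers integer matrix (1/2/NA) with
#'   dimnames.
#' @param map Tibble `marker`, `chrom`, `pos` (bp), `cm`; genetic
#'   positions non-decreasing within chromosome.
#' @param cross_type `"rilself"` or `"backcross"`.
#' @return Object of class `cross_geno`.
#' @export
cross_geno <- function(geno, map, cross_type = c("rilself", "backcross")) {
  cross_type <- match.arg(cross_type)
  stopifnot(is.matrix(geno), ncol(geno) == nrow(map))
  bad <- !geno %in% c(1L, 2L, NA)
  if (any(bad)) abort("genotype codes must be 1, 2 or NA")
  ok <- map |>
    group_by(.data$chrom) |>
    summarise(sorted = !is.unsorted(.data$cm), .groups = "drop")
  if (!all(ok$sorted)) abort("genetic positions must be non-decreasing")
  structure(list(geno = geno, map = as_tibble(map), cross_type = cross_type),
            class = "cross_geno")
}

#' Filter individuals and markers and insert a pseudomarker grid
#'
#' Drops individuals with more than 19% missing genotypes and duplicated
#' individuals, drops markers with more than 60% missing calls, thins
#' markers greedily so retained markers are at least 1 cM apart (keeping
#' the first marker of each run), and interleaves pseudomarkers at 1 cM
#' spacing with physical positions interpolated from the cM-to-bp map.
#'
#' @param cross A [cross_geno()].
#' @param max_ind_missing,max_marker_missing Missingness limits
#'   (strict `>` drops).
#' @param min_cm Marker thinning distance.
#' @param pseudo_step Pseudomarker spacing in cM (`NULL` to skip).
#' @return List of class `cross_prep`: `geno` (filtered), `grid` (tibble
#'   `chrom`, `cm`, `pos`, `marker` with `NA` for pseudomarkers),
#'   `cross_type`, `dropped` bookkeeping.
#' @export
prepare_markers <- function(cross, max_ind_missing = 0.19,
                            max_marker_missing = 0.6, min_cm = 1,
                            pseudo_step = 1) {
  stopifnot(inherits(cross, "cross_geno"))
  g <- cross$geno
  ind_miss <- rowMeans(is.na(g))
  keep_ind <- ind_miss <= max_ind_missing
  g <- g[keep_ind, , drop = FALSE]
  dup <- duplicated(apply(g, 1, paste, collapse = ","))
  g <- g[!dup, , drop = FALSE]
  mk_miss <- colMeans(is.na(g))
  keep_mk <- mk_miss <= max_marker_missing
  g <- g[, keep_mk, drop = FALSE]
  map <- cross$map[keep_mk, ]
  thin <- map |>
    group_by(.data$chrom) |>
    mutate(keep = greedy_thin(.data$cm, min_cm)) |>
    ungroup()
  g <- g[, thin$keep, drop = FALSE]
  map <- map[thin$keep, ]
  if (any(table(map$chrom) == 0) || nrow(map) == 0) {
    abort("chromosome(s) with no markers after filtering")
  }
  grid <- map |>
    group_by(.data$chrom) |>
    group_modify(function(df, key) pseudo_grid(df, pseudo_step)) |>
    ungroup() |>
    arrange(match(.data$chrom, unique(map$chrom)), .data$cm)
  structure(
    list(geno = g, grid = grid, cross_type = cross$cross_type,
         dropped = list(individuals = sum(!keep_ind) + sum(dup),
                        markers = sum(!keep_mk))),
    class = "cross_prep"
  )
}

greedy_thin <- function(cm, min_cm) {
  keep <- logical(length(cm))
  last <- -Inf
  for (i in seq_along(cm)) {
    if (cm[i] - last >= min_cm) {
      keep[i] <- TRUE
      last <- cm[i]
    }
  }
  keep
}

pseudo_grid <- function(df, pseudo_step) {
  base <- tibble(cm = df$cm, pos = df$pos, marker = df$marker)
  if (is.null(pseudo_step) || nrow(df) < 2) {
    return(base)
  }
  pseudo_cm <- setdiff(seq(min(df$cm), max(df$cm), by = pseudo_step), df$cm)
  if (length(pseudo_cm) == 0) return(base)
  pseudo_pos <- stats::approx(df$cm, df$pos, xout = pseudo_cm, rule = 2,
                              ties = "ordered")$y
  bind_rows(base, tibble(cm = pseudo_cm, pos = round(pseudo_pos),
                         marker = NA_character_)) |>
    arrange(.data$cm)
}

haldane_r <- function(d_cm) 0.5 * (1 - exp(-2 * d_cm / 100))

#' Hidden-Markov genotype probabilities on the marker grid
#'
#' Forward-backward over the positions of each chromosome with two hidden
#' states. Transition probabilities come from Haldane recombination
#' fractions of the inter-position distances, with the standard
#' map-expansion `R = 2r / (1 + 2r)` for RILs by selfing; emissions are
#' correct with probability `1 - error_prob`, and missing genotypes (and
#' pseudomarkers) are uninformative. Posterior probabilities sum to one at
#' every position.
#'
#' @param prep A [prepare_markers()] result.
#' @param error_prob Genotyping error probability.
#' @return List of class `geno_prob`: `prob` (individuals x grid-positions
#'   matrix of P(state 2)), `grid`, `cross_type`.
#' @export
genotype_probabilities <- function(prep, error_prob = 0.001) {
  stopifnot(inherits(prep, "cross_prep"))
  grid <- prep$grid
  n <- nrow(prep$geno)
  p2 <- matrix(NA_real_, n, nrow(grid),
               dimnames = list(rownames(prep$geno), NULL))
  marker_col <- match(grid$marker, colnames(prep$geno))
  for (ch in unique(grid$chrom)) {
    idx <- which(grid$chrom == ch)
    P <- length(idx)
    d <- diff(grid$cm[idx])
    r <- haldane_r(d)
    R <- if (prep$cross_type == "rilself") 2 * r / (1 + 2 * r) else r
    # emission likelihoods, n x P per state
    e1 <- matrix(1, n, P)
    e2 <- matrix(1, n, P)
    for (j in seq_len(P)) {
      mc <- marker_col[idx[j]]
      if (!is.na(mc)) {
        obs <- prep$geno[, mc]
        seen <- !is.na(obs)
        e1[seen, j] <- ifelse(obs[seen] == 1L, 1 - error_prob, error_prob)
        e2[seen, j] <- ifelse(obs[seen] == 2L, 1 - error_prob, error_prob)
      }
    }
    # forward
    a1 <- matrix(0, n, P); a2 <- matrix(0, n, P)
    a1[, 1] <- 0.5 * e1[, 1]; a2[, 1] <- 0.5 * e2[, 1]
    sc <- a1[, 1] + a2[, 1]
    a1[, 1] <- a1[, 1] / sc; a2[, 1] <- a2[, 1] / sc
    for (j in seq_len(P - 1)) {
      t1 <- a1[, j] * (1 - R[j]) + a2[, j] * R[j]
      t2 <- a1[, j] * R[j] + a2[, j] * (1 - R[j])
      a1[, j + 1] <- t1 * e1[, j + 1]
      a2[, j + 1] <- t2 * e2[, j + 1]
      sc <- a1[, j + 1] + a2[, j + 1]
      a1[, j + 1] <- a1[, j + 1] / sc
      a2[, j + 1] <- a2[, j + 1] / sc
    }
    # backward
    b1 <- matrix(1, n, P); b2 <- matrix(1, n, P)
    for (j in rev(seq_len(P - 1))) {
      u1 <- e1[, j + 1] * b1[, j + 1]
      u2 <- e2[, j + 1] * b2[, j + 1]
      b1[, j] <- (1 - R[j]) * u1 + R[j] * u2
      b2[, j] <- R[j] * u1 + (1 - R[j]) * u2
      sc <- b1[, j] + b2[, j]
      b1[, j] <- b1[, j] / sc
      b2[, j] <- b2[, j] / sc
    }
    g1 <- a1 * b1
    g2 <- a2 * b2
    p2[, idx] <- g2 / (g1 + g2)
  }
  structure(list(prob = p2, grid = grid, cross_type = prep$cross_type),
            class = "geno_prob")
}

#' Haley-Knott genome scan
#'
#' At every grid position the phenotype is regressed on the expected
#' genotype dosage (the posterior probability of the second genotype);
#' `LOD = (n/2) log10(RSS0 / RSS1)`. Exact fits are capped at LOD 300; a
#' phenotype with zero variance yields an all-zero curve.
#'
#' @param probs A [genotype_probabilities()] result.
#' @param pheno Numeric vector (one phenotype) or individuals x phenotypes
#'   matrix, rows matching the genotyped individuals.
#' @param lod_cap Ceiling for exact fits.
#' @return Object of class `eqtl_scan`: `lod` (positions x phenotypes
#'   matrix), `grid`, `n`.
#' @export
hk_scan <- function(probs, pheno, lod_cap = 300) {
  stopifnot(inherits(probs, "geno_prob"))
  Y <- as.matrix(pheno)
  D <- probs$prob
  n <- nrow(D)
  stopifnot(nrow(Y) == n)
  Dc <- sweep(D, 2, colMeans(D))
  Sdd <- colSums(Dc^2)
  Yc <- sweep(Y, 2, colMeans(Y))
  Syy <- colSums(Yc^2)
  Sxy <- crossprod(Dc, Yc)                       # positions x phenotypes
  expl <- Sxy^2 / ifelse(Sdd > 0, Sdd, Inf)
  rss1 <- pmax(sweep(-expl, 2, Syy, `+`), 0)
  lod <- matrix(0, nrow(Sxy), ncol(Sxy), dimnames = dimnames(Sxy))
  pos_var <- Syy > 0
  if (any(pos_var)) {
    lr <- sweep(log10(pmax(rss1[, pos_var, drop = FALSE], 1e-300)), 2,
                log10(Syy[pos_var]), function(a, b) b - a)
    lod[, pos_var] <- pmin(n / 2 * lr, lod_cap)
  }
  if (is.null(colnames(lod))) {
    colnames(lod) <- paste0("pheno", seq_len(ncol(lod)))
  }
  structure(list(lod = lod, grid = probs$grid, n = n), class = "eqtl_scan")
}

#' Permutation maxima and adjusted p-values for a scan
#'
#' Reshuffles each phenotype over individuals `n_perm` times, records the
#' genome-wide maximum LOD of every permutation, and reports the adjusted
#' p of each observed maximum as the fraction of permutation maxima at
#' least as large (observed maxima exceeding all permutations are reported
#' as `0.5 / n_perm`, i.e. below the `1 / n_perm` resolution). The
#' significance threshold at `alpha` is the `(1 - alpha)` quantile of the
#' maxima.
#'
#' @param probs A [genotype_probabilities()] result.
#' @param pheno Individuals x phenotypes matrix (or vector).
#' @param n_perm Number of permutations (the study default is 10,000;
#'   1,000 is adequate for testing).
#' @param alpha Genome-wide significance level.
#' @param seed Integer seed.
#' @return Tibble `phenotype`, `max_lod`, `p_adj`, `threshold`,
#'   `significant`; attribute `"maxima"` holds the permutation maxima
#'   matrix (n_perm x phenotypes).
#' @export
scan_permutations <- function(probs, pheno, n_perm = 1000, alpha = 0.001,
                              seed = 1) {
  if (n_perm < 100) warn("n_perm < 100 gives poor p-value resolution")
  Y <- as.matrix(pheno)
  if (is.null(colnames(Y))) colnames(Y) <- paste0("pheno", seq_len(ncol(Y)))
  withr_seed(seed)
  D <- probs$prob
  n <- nrow(D)
  Dc <- sweep(D, 2, colMeans(D))
  Sdd <- colSums(Dc^2)
  ok <- Sdd > 0
  obs <- hk_scan(probs, Y)
  obs_max <- apply(obs$lod, 2, max)
  maxima <- matrix(NA_real_, n_perm, ncol(Y),
                   dimnames = list(NULL, colnames(Y)))
  for (k in seq_len(ncol(Y))) {
    y <- Y[, k]
    Syy <- sum((y - mean(y))^2)
    if (Syy == 0) { maxima[, k] <- 0; next }
    Pm <- vapply(seq_len(n_perm), function(i) sample(y), numeric(n))
    Pc <- sweep(Pm, 2, colMeans(Pm))
    Sxy <- crossprod(Dc[, ok, drop = FALSE], Pc)   # positions x n_perm
    best <- apply(Sxy^2 / Sdd[ok], 2, max)
    rss1 <- pmax(Syy - best, 1e-300)
    maxima[, k] <- pmin(n / 2 * (log10(Syy) - log10(rss1)), 300)
  }
  p_adj <- vapply(seq_len(ncol(Y)), function(k) {
    cnt <- sum(maxima[, k] >= obs_max[k])
    if (cnt == 0) 0.5 / n_perm else cnt / n_perm
  }, numeric(1))
  thr <- apply(maxima, 2, quantile, probs = 1 - alpha, type = 7)
  out <- tibble(phenotype = colnames(Y), max_lod = unname(obs_max),
                p_adj = p_adj, threshold = unname(thr),
                significant = unname(obs_max >= thr))
  attr(out, "maxima") <- maxima
  out
}

#' Locate LOD peaks with 1.5-LOD support intervals
#'
#' Finds, per chromosome, maxima above the threshold that are separated by
#' a drop of at least `drop` LOD units; the support interval of a peak is
#' the contiguous region whose curve stays within `drop` of the peak,
#' expanded by one grid position on each side, reported in interpolated
#' physical coordinates. Plateau ties resolve to the lowest coordinate.
#'
#' @param scan An [hk_scan()] result.
#' @param phenotype Column of the scan to use.
#' @param threshold Minimum peak LOD.
#' @param drop Support-interval/peak-separation LOD drop.
#' @return Tibble `phenotype`, `chrom`, `pos`, `cm`, `lod`, `ci_lo`,
#'   `ci_hi` (bp).
#' @export
find_peaks <- function(scan, phenotype = 1, threshold, drop = 1.5) {
  stopifnot(inherits(scan, "eqtl_scan"))
  lodv <- scan$lod[, phenotype]
  grid <- scan$grid
  pname <- if (is.character(phenotype)) phenotype else colnames(scan$lod)[phenotype]
  out <- list()
  for (ch in unique(grid$chrom)) {
    idx <- which(grid$chrom == ch)
    lod <- lodv[idx]
    peaks_i <- chrom_peaks(lod, threshold, drop)
    for (pk in peaks_i) {
      lo <- pk
      while (lo > 1 && lod[lo - 1] >= lod[pk] - drop) lo <- lo - 1
      hi <- pk
      while (hi < length(lod) && lod[hi + 1] >= lod[pk] - drop) hi <- hi + 1
      # expand one position beyond the drop (standard LOD-interval practice)
      lo <- max(1L, lo - 1L)
      hi <- min(length(lod), hi + 1L)
      out[[length(out) + 1]] <- tibble(
        phenotype = pname, chrom = ch, pos = grid$pos[idx[pk]],
        cm = grid$cm[idx[pk]], lod = lod[pk],
        ci_lo = grid$pos[idx[lo]], ci_hi = grid$pos[idx[hi]]
      )
    }
  }
  if (length(out) == 0) {
    return(tibble(phenotype = character(), chrom = character(),
                  pos = numeric(), cm = numeric(), lod = numeric(),
                  ci_lo = numeric(), ci_hi = numeric()))
  }
  bind_rows(out) |> arrange(dplyr::desc(.data$lod))
}

chrom_peaks <- function(lod, threshold, drop) {
  above <- which(lod >= threshold)
  if (length(above) == 0) return(integer())
  runs <- split(above, cumsum(c(1, diff(above) != 1)))
  peaks <- integer()
  for (run in runs) {
    cur <- run[1]
    valley <- lod[run[1]]
    for (j in run[-1]) {
      valley <- min(valley, lod[j])
      if (lod[j] > lod[cur]) {
        if (lod[cur] - valley >= drop && lod[j] - valley >= drop) {
          peaks <- c(peaks, cur)
        }
        cur <- j
        valley <- lod[j]
      }
    }
    peaks <- c(peaks, cur)
  }
  sort(peaks)
}

#' FDR across genes for permutation-adjusted peak p-values
#'
#' Benjamini-Hochberg correction of the per-peak adjusted p-values with
#' the effective test count set to the total number of genes scanned plus
#' the number of second and further significant peaks.
#'
#' @param peaks Tibble with `phenotype` (gene) and `p_adj` per peak.
#' @param n_genes_total Total genes scanned (not just those with peaks).
#' @param fdr Retention threshold on q.
#' @return `peaks` with columns `q` and `retained`.
#' @export
fdr_across_genes <- function(peaks, n_genes_total, fdr = 0.001) {
  extra <- peaks |>
    count(.data$phenotype) |>
    summarise(extra = sum(pmax(.data$n - 1L, 0L))) |>
    pull(.data$extra)
  n_eff <- max(n_genes_total + extra, nrow(peaks))
  peaks |>
    mutate(q = p.adjust(.data$p_adj, method = "BH", n = n_eff),
           retained = .data$q <= fdr)
}

#' Merge eQTL peaks for the same gene across cross datasets
#'
#' Two peaks of one gene are distinct when they are at least 25 Mbp apart
#' or on different chromosomes and neither position lies inside the
#' other's support interval; otherwise they are the same eQTL and only the
#' peak with the shortest support interval (highest LOD on ties) is kept.
#'
#' @param peaks Tibble with `phenotype`, `chrom`, `pos`, `lod`, `ci_lo`,
#'   `ci_hi` (rows possibly from several datasets).
#' @param min_dist Distance beyond which peaks may be distinct.
#' @return Merged peak tibble.
#' @export
merge_peaks <- function(peaks, min_dist = 25e6) {
  same_eqtl <- function(a, b) {
    near <- a$chrom == b$chrom & abs(a$pos - b$pos) < min_dist
    inside <- a$chrom == b$chrom &
      ((a$pos >= b$ci_lo & a$pos <= b$ci_hi) |
         (b$pos >= a$ci_lo & b$pos <= a$ci_hi))
    near | inside
  }
  peaks |>
    group_by(.data$phenotype) |>
    group_modify(function(df, key) {
      m <- nrow(df)
      if (m < 2) return(df)
      grp <- seq_len(m)
      for (i in seq_len(m - 1)) {
        for (j in seq((i + 1), m)) {
          if (same_eqtl(df[i, ], df[j, ])) {
            grp[grp == grp[j]] <- grp[i]
          }
        }
      }
      df |>
        mutate(.grp = grp,
               .ci_len = .data$ci_hi - .data$ci_lo) |>
        group_by(.data$.grp) |>
        arrange(.data$.ci_len, dplyr::desc(.data$lod), .by_group = TRUE) |>
        slice(1) |>
        ungroup() |>
        select(-".grp", -".ci_len")
    }) |>
    ungroup()
}

#' Classify eQTL as cis- or trans-regulating
#'
#' A peak is cis when it lies within `cis_window` of its target gene's
#' start on the same chromosome, or when its support interval includes the
#' gene start; otherwise (including all peaks on other chromosomes) it is
#' trans.
#'
#' @param peaks Peak tibble with `phenotype` (gene id), `chrom`, `pos`,
#'   `ci_lo`, `ci_hi`.
#' @param genes Gene tibble `gene_id`, `chrom`, `start`.
#' @param cis_window Distance threshold in bp (default 2.5 Mbp).
#' @return `peaks` with columns `gene_chrom`, `gene_start`, `regulation`.
#' @export
classify_cis_trans <- function(peaks, genes, cis_window = 2.5e6) {
  peaks |>
    left_join(genes |> select(phenotype = "gene_id", gene_chrom = "chrom",
                              gene_start = "start"),
              by = "phenotype") |>
    mutate(regulation = if_else(
      .data$chrom == .data$gene_chrom &
        (abs(.data$pos - .data$gene_start) < cis_window |
           (.data$gene_start >= .data$ci_lo & .data$gene_start <= .data$ci_hi)),
      "cis", "trans"
    ))
}

#' Map expression QTL for many genes
#'
#' Full per-dataset scan: genotype probabilities, Haley-Knott regression,
#' permutation-adjusted significance, peak finding with support intervals
#' and gene-level FDR.
#'
#' @param cross A [cross_geno()].
#' @param pheno Individuals x genes expression matrix (e.g. genotype
#'   means), rows named like the cross individuals.
#' @param n_perm Permutations per gene.
#' @param alpha Genome-wide significance level per gene.
#' @param fdr Across-genes FDR threshold.
#' @param error_prob HMM genotyping error probability.
#' @param drop Support-interval LOD drop.
#' @param seed Integer seed.
#' @return Tibble of retained peaks: `phenotype`, `chrom`, `pos`, `cm`,
#'   `lod`, `ci_lo`, `ci_hi`, `p_adj`, `q`, `retained`.
#' @export
map_eqtl <- function(cross, pheno, n_perm = 1000, alpha = 0.001, fdr = 0.001,
                     error_prob = 0.001, drop = 1.5, seed = 1) {
  prep <- prepare_markers(cross)
  pheno <- as.matrix(pheno)
  pheno <- pheno[rownames(prep$geno), , drop = FALSE]
  probs <- genotype_probabilities(prep, error_prob = error_prob)
  scan <- hk_scan(probs, pheno)
  perms <- scan_permutations(probs, pheno, n_perm = n_perm, alpha = alpha,
                             seed = seed)
  sig <- perms |> filter(.data$significant)
  pk <- purrr::map_dfr(sig$phenotype, function(g) {
    find_peaks(scan, g, threshold = sig$threshold[sig$phenotype == g],
               drop = drop) |>
      mutate(p_adj = sig$p_adj[sig$phenotype == g])
  })
  if (nrow(pk) == 0) {
    return(tibble(phenotype = character(), chrom = character(),
                  pos = numeric(), cm = numeric(), lod = numeric(),
                  ci_lo = numeric(), ci_hi = numeric(), p_adj = numeric(),
                  q = numeric(), retained = logical()))
  }
  fdr_across_genes(pk, n_genes_total = ncol(pheno), fdr = fdr) |>
    filter(.data$retained)
}
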