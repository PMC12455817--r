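#' Fit the GC/length artifact smoother
#'
#' Fits a penalized additive smoother (generalized additive model, thin
#' plate splines, smoothness by GCV) of log mean count on GC fraction and
#' log gene length, to capture artifactual read-count differences across
#' genes. The exponentiated fit is the predictive count per gene.
#'
#' @param mean_counts Per-gene mean raw counts (length = number of genes).
#' @param gc GC fraction per gene.
#' @param log_length Log-transformed gene length per gene.
#' @param min_genes Minimum number of genes with nonzero counts.
#' @return Tibble `predictive` (positive predictive count per gene, in
#'   input order) with attribute `"fit"` carrying the mgcv fit (or `NULL`
#'   after a fallback).
#' @export
fit_artifact_smoother <- function(mean_counts, gc, log_length, min_genes = 50) {
  stopifnot(length(mean_counts) == length(gc),
            length(gc) == length(log_length))
  nz <- mean_counts > 0
  if (sum(nz) < min_genes) {
    abort(sprintf("need >= %d genes with nonzero counts, got %d",
                  min_genes, sum(nz)))
  }
  df <- tibble(y = log(mean_counts[nz]), gc = gc[nz], llen = log_length[nz])
  term_for <- function(x, name) {
    u <- length(unique(x))
    if (u < 2) NULL
    else if (u < 10) name
    else sprintf("s(%s, k = %d)", name, min(10L, u - 1L))
  }
  terms <- c(term_for(df$gc, "gc"), term_for(df$llen, "llen"))
  if (length(terms) == 0) {
    warn("constant GC and length: predictive count falls back to grand mean")
    pred <- rep(exp(mean(df$y)), length(mean_counts))
    out <- tibble(predictive = pred)
    attr(out, "fit") <- NULL
    return(out)
  }
  fml <- stats::as.formula(paste("y ~", paste(terms, collapse = " + ")))
  fit <- mgcv::gam(fml, data = df, method = "GCV.Cp")
  pred <- exp(as.numeric(stats::predict(
    fit, newdata = tibble(gc = gc, llen = log_length))))
  out <- tibble(predictive = pred)
  attr(out, "fit") <- fit
  out
}

#' Gene-specific normalization factors
#'
#' The inverse of the predictive count is the multiplicative gene-specific
#' normalization factor.
#'
#' @param predictive Positive predictive counts per gene.
#' @return Numeric factors, `1 / predictive`.
#' @export
gene_norm_factors <- function(predictive) {
  if (any(predictive <= 0)) abort("predictive counts must be positive")
  1 / predictive
}

#' Sample-wise TMM scale factors
#'
#' Trimmed mean of M-values: the reference sample is the library whose
#' upper-quartile count is closest to the mean upper quartile; log ratios
#' (M) are trimmed by 30% and average log expression (A) by 5%, and the
#' remaining M values are combined by inverse-variance weights. The
#' returned multiplicative per-sample factor is `1 / (library size x TMM
#' factor)` rescaled to geometric mean 1, so multiplying counts by it
#' equalizes effective library sizes; `ref_ratio` additionally reports the
#' factor relative to the reference sample (reference = 1, a doubled
#' library = 0.5).
#'
#' @param raw Genes x samples count matrix.
#' @return Tibble `sample`, `lib_size`, `tmm` (edgeR-convention TMM
#'   factor), `scale_factor`, `ref_ratio`.
#' @export
tmm_factors <- function(raw) {
  raw <- as.matrix(raw)
  lib <- colSums(raw)
  if (any(lib == 0)) abort("sample(s) with all-zero counts")
  expressed <- raw > 0
  if (ncol(raw) >= 2) {
    shared <- crossprod(expressed)
    diag(shared) <- NA
    if (any(shared == 0, na.rm = TRUE)) {
      abort("sample pair(s) share no expressed genes; cannot compute M values")
    }
  }
  nf <- edgeR::calcNormFactors(raw, method = "TMM")
  eff <- lib * nf
  inv <- 1 / eff
  scale_factor <- inv / exp(mean(log(inv)))
  uq <- apply(raw, 2, function(x) quantile(x, 0.75))
  ref <- which.min(abs(uq - mean(uq)))
  tibble(
    sample = colnames(raw) %||% as.character(seq_along(lib)),
    lib_size = unname(lib),
    tmm = unname(nf),
    scale_factor = unname(scale_factor),
    ref_ratio = unname(eff[ref] / eff)
  )
}

#' Normalize counts and average per genotype
#'
#' Each raw count is multiplied by the product of its gene-specific factor
#' and its sample scale factor.
#'
#' @param raw Genes x samples count matrix.
#' @param gene_factors Per-gene multiplicative factors
#'   ([gene_norm_factors()]).
#' @param sample_factors Per-sample factors (the `scale_factor` column of
#'   [tmm_factors()], in column order), or `NULL` for 1.
#' @return Normalized matrix of the same shape.
#' @export
normalize_counts <- function(raw, gene_factors = NULL, sample_factors = NULL) {
  raw <- as.matrix(raw)
  gene_factors <- gene_factors %||% rep(1, nrow(raw))
  sample_factors <- sample_factors %||% rep(1, ncol(raw))
  raw * gene_factors %o% sample_factors
}

#' Per-genotype mean expression
#'
#' @param normalized Genes x samples matrix.
#' @param samples Sample table mapping `sample` to `genotype`.
#' @return Genes x genotypes matrix of means over replicates.
#' @export
genotype_means <- function(normalized, samples) {
  stopifnot(all(colnames(normalized) %in% samples$sample))
  geno <- samples$genotype[match(colnames(normalized), samples$sample)]
  gl <- unique(geno)
  out <- vapply(gl, function(g) {
    rowMeans(normalized[, geno == g, drop = FALSE])
  }, numeric(nrow(normalized)))
  dimnames(out) <- list(rownames(normalized), gl)
  out
}

#' Gene-activity threshold
#'
#' The empirical 0.25 quantile (linear-interpolation convention, R type 7)
#' of the pooled nonzero genotype means.
#'
#' @param means Genes x genotypes matrix of mean normalized counts.
#' @param probs Quantile (default 0.25).
#' @return Scalar threshold tau.
#' @export
activity_threshold <- function(means, probs = 0.25) {
  nz <- means[means > 0]
  if (length(nz) == 0) abort("no nonzero genotype means; cannot set threshold")
  unname(quantile(nz, probs, type = 7))
}

#' Call gene activity
#'
#' A gene is active in a genotype when its mean normalized expression is
#' strictly greater than the threshold; ties and zeros are inactive.
#'
#' @param means Genes x genotypes mean matrix.
#' @param tau Threshold from [activity_threshold()].
#' @return Logical genes x genotypes matrix.
#' @export
call_activity <- function(means, tau) {
  means > tau
}

#' One-stop count normalization and activity calling
#'
#' Runs the artifact smoother, gene factors, TMM sample factors,
#' normalization, genotype means, threshold and activity calls.
#'
#' @param counts Genes x samples raw count matrix.
#' @param samples Sample table (`sample`, `genotype`).
#' @param genes Gene table (`gene_id`, `gc`, `length`) in row order of
#'   `counts`.
#' @param quantile_prob Activity-threshold quantile.
#' @return List of class `activity_call`: `activity`, `means`, `tau`,
#'   `gene_factors`, `sample_factors`, `normalized`.
#' @export
call_gene_activity <- function(counts, samples, genes, quantile_prob = 0.25) {
  sm <- fit_artifact_smoother(rowMeans(counts), genes$gc, log(genes$length))
  gf <- gene_norm_factors(sm$predictive)
  tf <- tmm_factors(counts)
  norm <- normalize_counts(counts, gf, tf$scale_factor)
  means <- genotype_means(norm, samples)
  tau <- activity_threshold(means, quantile_prob)
  structure(
    list(activity = call_activity(means, tau), means = means, tau = tau,
         gene_factors = gf, sample_factors = tf, normalized = norm),
    class = "activity_call"
  )
}
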