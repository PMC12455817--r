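# lean phenotype data: design + generative model + SPE counts in one call
sim_phet_data <- function(n_rils = 20, gamma = c(0.004, 0.004, 0.002, 0.002),
                          s2_het = 0.05, s2_design = 0.02, s2_resid = 0.1,
                          seed = 1, plants_per_row = 2) {
  ril_ids <- sprintf("R%02d", seq_len(n_rils))
  des <- build_experimental_design(ril_ids, plants_per_row = plants_per_row,
                                   seed = seed)
  des <- des[des$type %in% c("B73", "MO17", "RIL", "B73xRIL"), ]
  parents <- unique(des$genotype[des$type %in% c("B73", "MO17", "RIL")])
  withr::with_seed(seed + 1, {
    beta <- setNames(rnorm(length(parents), 10, 1), parents)
    hyb <- unique(des$genotype[des$type == "B73xRIL"])
    spe <- tibble::tibble(
      genotype = hyb,
      sa = rpois(length(hyb), 400), sb = rpois(length(hyb), 300),
      sc = rpois(length(hyb), 150), sd = rpois(length(hyb), 150)
    )
  })
  gm <- phenotype_gen_model(
    beta = beta, phi = 1, gamma = gamma,
    sigma2 = c(batch = s2_design, system = s2_design, triplet = s2_design,
               row = s2_design, het = s2_het, resid = s2_resid)
  )
  sim <- simulate_phenotypes(des, gm, spe, seed = seed + 2)
  list(design = des, sim = sim, spe = spe, gm = gm,
       records = sim$phenotypes, pedigree = pedigree_from_design(des))
}

test_that("trait transforms follow the sqrt(y + 0.5) rule and invert", {
  expect_equal(transform_trait(0, "root_tips"), sqrt(0.5), tolerance = 1e-6)
  expect_equal(transform_trait(0, "root_tips"), 0.70711, tolerance = 1e-4)
  expect_equal(transform_trait(0.5, "root_length"), 1.0)
  y <- c(0, 1.3, 27)
  expect_equal(inverse_transform_trait(transform_trait(y, "root_volume"),
                                       "root_volume"), y)
  expect_equal(transform_trait(y, "lateral_root_density"), y)
})

test_that("baseline model reduces to arithmetic means on balanced noiseless data", {
  des <- build_experimental_design(sprintf("R%02d", 1:4), plants_per_row = 2,
                                   seed = 3)
  gm <- phenotype_gen_model(
    beta = setNames(
      rep(10, length(unique(des$genotype))),
      unique(des$genotype)
    )[!grepl("x", unique(des$genotype)) | grepl("RIL_", unique(des$genotype))],
    phi = 0, gamma = rep(0, 4),
    sigma2 = c(batch = 0, system = 0, triplet = 0, row = 0, het = 0,
               resid = 1e-4)
  )
  # direct construction instead: tiny balanced records
  set.seed(4)
  recs <- tidyr::expand_grid(
    genotype = c("A", "B", "C"), block = 1:3, rep = 1:2
  ) |>
    dplyr::mutate(value = dplyr::case_when(genotype == "A" ~ 10,
                                           genotype == "B" ~ 12,
                                           genotype == "C" ~ 9) +
                    0.5 * (block - 2) + rnorm(18, 0, 1e-5))
  fit <- fit_baseline_model(recs)
  m <- tidy(fit)
  expect_equal(m$mean[m$genotype == "A"], 10, tolerance = 1e-4)
  expect_equal(m$mean[m$genotype == "B"], 12, tolerance = 1e-4)
  expect_equal(m$mean[m$genotype == "C"], 9, tolerance = 1e-4)
  expect_warning(fit_baseline_model(recs[recs$block == 1, ]), "block")
})

test_that("baseline model beats raw means under a batch effect", {
  errs <- purrr::map_dfr(1:25, function(i) {
    d <- sim_phet_data(n_rils = 6, gamma = rep(0, 4), s2_het = 0,
                       s2_design = 0.3, s2_resid = 0.05, seed = 100 + i)
    fit <- fit_baseline_model(d$records)
    truth <- d$gm$beta
    adj <- setNames(tidy(fit)$mean, tidy(fit)$genotype)[names(truth)]
    raw <- tapply(d$records$value, d$records$genotype,
                  mean)[names(truth)]
    blk <- mean(d$gm$block)
    tibble::tibble(adj_mse = mean((adj - truth - blk)^2, na.rm = TRUE),
                   raw_mse = mean((raw - truth - blk)^2, na.rm = TRUE))
  })
  expect_lt(mean(errs$adj_mse), mean(errs$raw_mse))
})

test_that("MPH and BPH percentages follow their definitions", {
  means <- tibble::tibble(genotype = c("H1", "H2", "H3", "P1", "P2"),
                          mean = c(15, 12, 8, 10, 6))
  ped <- tibble::tibble(genotype = c("H1", "H2", "H3"),
                        parent1 = c("P1", "P1", "P1"),
                        parent2 = c("P1", "P2", "P2"))
  h <- compute_heterosis(means, ped)
  expect_equal(h$mph_pct[h$genotype == "H1"], 50)   # H 15, MP 10
  expect_equal(h$bph_pct[h$genotype == "H1"], 50)
  expect_equal(h$mph_pct[h$genotype == "H2"], 50)   # H 12, MP 8, BP 10
  expect_equal(h$bph_pct[h$genotype == "H2"], 20)
  expect_equal(h$mph_pct[h$genotype == "H3"], 0)    # H equals mid-parent
})

test_that("covariate rows encode parents, hybrids, SPE counts and the z switch", {
  recs <- tibble::tibble(
    genotype = c("P1", "P2", "H"), block = c(1, 2, 3),
    value = c(1, 2, 3)
  )
  ped <- tibble::tibble(genotype = c("P1", "P2", "H"),
                        parent1 = c(NA, NA, "P1"), parent2 = c(NA, NA, "P2"))
  spe <- tibble::tibble(genotype = "H", sa = 10, sb = 20, sc = 30, sd = 40)
  cv <- build_heterosis_covariates(recs, ped, spe, mode = "MPH")
  expect_equal(cv$x_P1, c(1, 0, 0.5))
  expect_equal(cv$x_P2, c(0, 1, 0.5))
  expect_equal(cv$z, c(0, 0, 1))
  expect_equal(cv$sa, c(0, 0, 10))
  expect_equal(cv$sd, c(0, 0, 40))
  expect_equal(cv$blk2, c(0, 1, 0))
  expect_equal(cv$blk3, c(0, 0, 1))
  bp <- build_heterosis_covariates(recs, ped, spe, mode = "BPH",
                                   parent_means = c(P1 = 5, P2 = 9))
  expect_equal(bp$x_P1, c(1, 0, 0))
  expect_equal(bp$x_P2, c(0, 1, 1))   # better parent gets 1
  expect_error(build_heterosis_covariates(recs, ped, spe, mode = "BPH"),
               "parent_means")
})

test_that("full-model REML matches a brute-force restricted likelihood", {
  # two-component toy: hybrid deviation + residual only
  set.seed(7)
  n_par <- 8; n_hyb <- 12; reps <- 4
  parents <- paste0("P", seq_len(n_par))
  hybs <- paste0("H", seq_len(n_hyb))
  ped <- dplyr::bind_rows(
    tibble::tibble(genotype = parents, parent1 = NA, parent2 = NA),
    tibble::tibble(genotype = hybs,
                   parent1 = sample(parents, n_hyb, TRUE),
                   parent2 = sample(parents, n_hyb, TRUE))
  )
  beta <- setNames(rnorm(n_par, 10, 1), parents)
  g <- setNames(rnorm(n_hyb, 0, sqrt(0.3)), hybs)
  recs <- tidyr::expand_grid(genotype = c(parents, hybs),
                             rep = seq_len(reps)) |>
    dplyr::mutate(block = 1 + (rep %% 2))
  is_h <- recs$genotype %in% hybs
  mid <- function(gt) {
    i <- match(gt, ped$genotype)
    0.5 * beta[ped$parent1[i]] + 0.5 * beta[ped$parent2[i]]
  }
  recs$value <- ifelse(is_h, mid(recs$genotype) + 0.8 + g[recs$genotype],
                       beta[recs$genotype]) + rnorm(nrow(recs), 0, 0.5)
  spe <- tibble::tibble(genotype = hybs, sa = rpois(n_hyb, 100),
                        sb = 0, sc = 0, sd = 0)
  cv <- build_heterosis_covariates(recs, ped, spe, mode = "MPH")
  suppressWarnings(full <- fit_full_model(cv))

  # brute force: profile REML over (log s2_het, log s2_e)
  Xcols <- c(attr(cv, "parents"), attr(cv, "blocks"), "sa", "z")
  X <- as.matrix(cv[, Xcols])
  X <- X[, qr(X)$pivot[seq_len(qr(X)$rank)], drop = FALSE]
  Z <- outer(cv$genotype, hybs, "==") * cv$z
  y <- cv$value
  n <- length(y)
  reml_nll <- function(par) {
    s2h <- exp(par[1]); s2e <- exp(par[2])
    V <- s2h * tcrossprod(Z) + diag(s2e, n)
    ch <- chol(V)
    Vi <- chol2inv(ch)
    XtVi <- crossprod(X, Vi)
    XtViX <- XtVi %*% X
    b <- solve(XtViX, XtVi %*% y)
    r <- y - X %*% b
    as.numeric(2 * sum(log(diag(ch))) + determinant(XtViX)$modulus +
                 crossprod(r, Vi %*% r))
  }
  opt <- optim(c(log(0.3), log(0.25)), reml_nll, method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 2000))
  s2 <- exp(opt$par)
  expect_equal(full$sigma2_het, s2[1], tolerance = 1e-4)
  resid_var <- full$varcomp$variance[full$varcomp$component == "ResidualNA"]
  if (length(resid_var) == 0) {
    resid_var <- full$varcomp$variance[grepl("Residual",
                                             full$varcomp$component)]
  }
  expect_equal(resid_var, s2[2], tolerance = 1e-4)
})

test_that("p_Het arithmetic matches worked examples and boundary rules", {
  expect_equal(round(compute_p_het(0.232, 0.325), 2), 0.29)
  expect_equal(round(compute_p_het(0.205, 0.190), 2), -0.08)
  expect_equal(compute_p_het(0.5, 0.5), 0)
  expect_error(compute_p_het(0.1, 0), "undefined")
})

test_that("p_Het pipeline recovers strong and absent SPE signals", {
  # strong gamma, tiny residual hybrid variance -> high p_Het
  d_hi <- sim_phet_data(n_rils = 25, gamma = c(0.01, 0.01, 0.005, 0.005),
                        s2_het = 0.01, seed = 11)
  ph_hi <- suppressWarnings(phet(d_hi$records, d_hi$pedigree, d_hi$spe))
  expect_gt(ph_hi$p_het, 0.5)
  expect_gt(d_hi$sim$true_p_het, 0.8)
  # gamma = 0 -> sigma2_G ~ sigma2_Het, p_Het near 0
  d_0 <- sim_phet_data(n_rils = 25, gamma = rep(0, 4), s2_het = 0.1,
                       seed = 12)
  ph_0 <- suppressWarnings(phet(d_0$records, d_0$pedigree, d_0$spe))
  expect_lt(abs(ph_0$p_het), 0.25)
  # adding a constant shifts phi only
  recs_c <- d_0$records |> dplyr::mutate(value = value + 50)
  ph_c <- suppressWarnings(phet(recs_c, d_0$pedigree, d_0$spe))
  expect_equal(ph_c$sigma2_het, ph_0$sigma2_het, tolerance = 1e-3)
  expect_equal(ph_c$sigma2_g, ph_0$sigma2_g, tolerance = 1e-3)
  expect_equal(ph_c$p_het, ph_0$p_het, tolerance = 0.02)
  # both fits converge with non-negative variance components
  expect_true(all(ph_0$varcomp_full$variance >= 0))
  expect_true(all(ph_0$varcomp_null$variance >= 0))
})

test_that("shared-slope option collapses the four SPE slopes into one", {
  d <- sim_phet_data(n_rils = 15, seed = 21)
  ph <- suppressWarnings(phet(d$records, d$pedigree, d$spe,
                              shared_slope = TRUE))
  expect_equal(names(ph$gamma), "s_total")
  expect_true(is.finite(ph$p_het))
})
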