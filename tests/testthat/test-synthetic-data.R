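test_that("panel mechanism mix, implied ratios and degenerate mixes behave", {
  params <- cohort_params(n_subjects = 100, n_variants = 200, seed = 5)

  set.seed(5)
  null_panel <- simulate_panel(params, mix = c(null = 1))
  expect_true(all(null_panel$effect_remnant == 0))
  expect_true(all(null_panel$effect_ldl == 0))
  expect_true(all(null_panel$effect_lpa == 0))

  set.seed(6)
  panel <- simulate_panel(params, mix = c(receptor = 0.5, lipolysis = 0.5))
  counts <- table(panel$mechanism)
  # block-level multinomial draw: binomial spread around 100 per class
  expect_gt(counts[["receptor"]], 50)
  expect_gt(counts[["lipolysis"]], 50)

  # recompute the implied apoB : TRL/remnant-C ratio from the emitted specs
  ratio <- params$apob_per_particle *
    (panel$effect_remnant + panel$effect_ldl) /
    (params$chol_per_remnant * panel$effect_remnant)
  rec <- panel$mechanism == "receptor"
  lip <- panel$mechanism == "lipolysis"
  expect_true(all(ratio[rec] >= 0.9 & ratio[rec] <= 3.0))
  expect_true(all(ratio[lip] >= -0.75 & ratio[lip] <= 0.75))
  expect_equal(ratio[rec | lip], panel$implied_ratio[rec | lip])

  # at least one Lp(a) variant whenever its fraction is positive
  set.seed(7)
  p_small <- cohort_params(n_subjects = 100, n_variants = 10, seed = 7)
  lpa_panel <- simulate_panel(p_small, mix = c(null = 0.99, lpa = 0.01))
  expect_gte(sum(lpa_panel$mechanism == "lpa"), 1)

  expect_error(simulate_panel(params, mix = c(receptor = 0.7)),
               "sum to 1")
})

test_that("genotypes have target allele frequencies and block LD", {
  params <- cohort_params(n_subjects = 10000, n_variants = 25, seed = 31)
  set.seed(31)
  panel <- simulate_panel(params)
  G <- simulate_genotypes(panel, 10000, ld_rho = 0.9, seed = 32)
  expect_true(all(G %in% 0:2))

  # observed allele frequency within binomial bounds of the block MAF
  f_obs <- colMeans(G) / 2
  bound <- 3 * sqrt(panel$maf * (1 - panel$maf) / (2 * 10000))
  expect_true(all(abs(f_obs - panel$maf) < bound + 0.01))

  # adjacent dosage r^2 ~ ld_rho^2 = 0.81 within a block
  r2_adj <- unlist(lapply(split(seq_len(25), panel$ld_block), function(ix) {
    if (length(ix) < 2) return(NULL)
    diag(cor(G[, ix])[-1, -length(ix), drop = FALSE])^2
  }))
  expect_equal(mean(r2_adj), 0.81, tolerance = 0.05)

  # ld_rho = 0: within-block r^2 at the 1/(n-1) sampling floor
  G0 <- simulate_genotypes(panel, 10000, ld_rho = 0, seed = 33)
  r2_0 <- unlist(lapply(split(seq_len(25), panel$ld_block), function(ix) {
    cc <- cor(G0[, ix])^2
    cc[upper.tri(cc)]
  }))
  expect_lt(mean(r2_0), 5 / 10000)

  expect_error(simulate_genotypes(panel, 1), "at least 2")
})

test_that("identical params and seed reproduce the cohort bit for bit", {
  params <- cohort_params(n_subjects = 300, n_variants = 20, seed = 99)
  c1 <- simulate_cohort(params)
  c2 <- simulate_cohort(params)
  expect_identical(c1$genotypes, c2$genotypes)
  expect_identical(c1$subjects, c2$subjects)
  expect_identical(c1$panel, c2$panel)

  c3 <- simulate_cohort(cohort_params(n_subjects = 300, n_variants = 20,
                                      seed = 100))
  expect_false(identical(c1$genotypes, c3$genotypes))
  expect_identical(names(c1$subjects), names(c3$subjects))
})

test_that("phenotype SDs hit the configured population targets", {
  fx <- big_fixture()
  s <- fx$subjects
  expect_equal(sd(s$trl_remnant_c, na.rm = TRUE), 0.30, tolerance = 0.10)
  expect_equal(sd(s$ldl_c_direct), 0.82, tolerance = 0.10)
  expect_equal(sd(s$tg), 1.0, tolerance = 0.10)
  expect_equal(sd(s$apob), 0.23, tolerance = 0.10)
  # covariates centred on the reference profile
  expect_equal(mean(s$age), 56, tolerance = 1)
  expect_equal(mean(s$bmi), 26.32, tolerance = 0.5)
  expect_equal(mean(s$hdl_c), 1.435, tolerance = 0.05)
})

test_that("noiseless generative equations are exact", {
  # single receptor variant, no noise: per-allele apoB effect equals
  # apob_per_particle * (effect_remnant + effect_ldl) exactly
  params <- cohort_params(n_subjects = 600, n_variants = 1, block_size = 1,
                          noise_scale = 0, seed = 12)
  set.seed(12)
  panel <- simulate_panel(params, mix = c(receptor = 1))
  G <- simulate_genotypes(panel, 600, ld_rho = 0)
  s <- simulate_phenotypes(G, panel, params)
  d_apob <- diff(tapply(s$apob, G[, 1], mean))
  expected <- params$apob_per_particle *
    (panel$effect_remnant + panel$effect_ldl)
  expect_equal(unname(d_apob[1]), expected, tolerance = 1e-10)
  expect_equal(unname(d_apob[2]), expected, tolerance = 1e-10)

  # all-null panel with noise: trait variance equals the solved residual
  # variance, i.e. the configured SD target
  p0 <- cohort_params(n_subjects = 60000, n_variants = 5, seed = 13)
  set.seed(13)
  panel0 <- simulate_panel(p0, mix = c(null = 1))
  G0 <- simulate_genotypes(panel0, p0$n_subjects, p0$ld_rho)
  s0 <- simulate_phenotypes(G0, panel0, p0)
  expect_equal(sd(s0$ldl_c_direct), 0.82, tolerance = 0.05)
  expect_equal(sd(s0$apob), 0.23, tolerance = 0.05)
})

test_that("lipid composition identity holds up to assay noise", {
  fx <- big_fixture()
  s <- fx$subjects
  resid <- (s$tc - s$hdl_c - s$ldl_c_direct) -
    fx$params$chol_per_remnant * s$latent_remnant
  expect_equal(sd(resid), fx$params$assay_sd[["tc"]], tolerance = 0.15)
  expect_lt(abs(mean(resid)), 0.01)
})

test_that("apoB accounting: regression on the pools recovers the constant", {
  params <- cohort_params(n_subjects = 20000, n_variants = 30, seed = 55)
  co <- simulate_cohort(params)
  fit <- lm(apob ~ latent_remnant + latent_ldl, data = co$subjects)
  cf <- coef(summary(fit))
  expect_lt(abs(cf["latent_remnant", 1] - params$apob_per_particle),
            3 * cf["latent_remnant", 2] + 1e-3)
  expect_lt(abs(cf["latent_ldl", 1] - params$apob_per_particle),
            3 * cf["latent_ldl", 2] + 1e-3)
})

test_that("outcome process: censoring bound, rates, and null independence", {
  co <- small_cohort()
  s <- co$subjects
  expect_true(all(s$time_to_event_or_censor > 0))
  expect_true(all(s$time_to_event_or_censor <= 12))
  expect_true(mean(s$incident_event) > 0 && mean(s$incident_event) < 1)

  # beta_R = beta_L = 0: no association between outcome and any variant
  p0 <- cohort_params(n_subjects = 4000, n_variants = 100,
                      beta_remnant = 0, beta_ldl = 0, seed = 77)
  co0 <- simulate_cohort(p0)
  pvals <- apply(co0$genotypes, 2, function(g) {
    tab <- table(factor(g, levels = 0:2), co0$subjects$incident_event)
    suppressWarnings(stats::chisq.test(tab)$p.value)
  })
  expect_lte(sum(pvals < 0.01, na.rm = TRUE), 100 * 0.01 + 4)
})

test_that("Cox regression on the true pools recovers the hazard gradient", {
  params <- cohort_params(n_subjects = 20000, n_variants = 30,
                          beta_ldl = 0, seed = 88)
  co <- simulate_cohort(params)
  s <- dplyr::filter(co$subjects, !prevalent_ascvd)
  fit <- survival::coxph(
    survival::Surv(time_to_event_or_censor, incident_event) ~
      latent_remnant + age + sex, data = s, ties = "breslow")
  est <- coef(fit)[["latent_remnant"]]
  se <- sqrt(diag(vcov(fit)))[["latent_remnant"]]
  expect_lt(abs(est - params$beta_remnant), 2 * se)
})

test_that("statistical effect-ratio embedding holds at reference scale", {
  fx <- big_fixture()
  tab <- dplyr::inner_join(
    dplyr::select(fx$panel, variant_id, mechanism),
    cluster_assignments(orient_effects(fx$assoc, "minor_vs_major")),
    by = "variant_id")
  rec <- dplyr::filter(tab, mechanism == "receptor", !is.na(ratio))
  lip <- dplyr::filter(tab, mechanism == "lipolysis", !is.na(ratio))
  expect_gte(mean(rec$ratio >= 0.9 & rec$ratio <= 3.0), 0.90)
  expect_gte(mean(lip$ratio >= -0.75 & lip$ratio <= 0.75), 0.90)
})
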