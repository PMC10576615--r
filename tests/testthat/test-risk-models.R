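test_that("gene score arithmetic counts weighted apoB-raising alleles", {
  G <- rbind(c(0L, 2L), c(1L, 1L), c(2L, 0L))
  colnames(G) <- c("v1", "v2")
  oriented <- tibble::tibble(
    variant_id = c("v1", "v2"), orientation = "apob_raising",
    flipped = c(FALSE, TRUE), flag_zero_apob = FALSE,
    beta_apob = c(0.05, 0.02))
  sc <- build_gene_score(G, oriented)
  # v2 flipped: raising dosage = 2 - dosage
  expect_equal(sc$score, c(0.05 * 0 + 0.02 * 0,
                           0.05 * 1 + 0.02 * 1,
                           0.05 * 2 + 0.02 * 2))

  one <- build_gene_score(G, oriented[1, ])
  expect_equal(one$score, c(0, 0.05, 0.10))

  expect_error(build_gene_score(G[, 1, drop = FALSE], oriented),
               "missing from the genotype")
})

test_that("beta-weighted score is calibrated against measured apoB", {
  # calibration (slope ~ 1) holds for uncorrelated variants; residual LD
  # double-counts tagged effects, so the check uses an LD-free panel
  p <- cohort_params(n_subjects = 20000, n_variants = 60, block_size = 1,
                     ld_rho = 0, seed = 705)
  co <- simulate_cohort(p)
  s <- quiet(derive_lipids(co$subjects))
  assoc <- quiet(assoc_scan_traits(
    s, co$genotypes, c("ldl_c_direct", "trl_remnant_c", "apob", "lpa")))
  sel <- select_variants(assoc, co$genotypes, tier = 3)
  oar <- quiet(orient_effects(
    dplyr::filter(assoc, variant_id %in% sel$variant_id), "apob_raising"))
  sc <- build_gene_score(co$genotypes, oar)
  fit <- lm(s$apob ~ sc$score)
  expect_equal(unname(coef(fit)[2]), 1, tolerance = 0.1)
})

test_that("decile summaries show the cluster-specific lipid signatures", {
  fx <- big_fixture()
  ids1 <- fx$clusters$variant_id[fx$clusters$cluster == "1"]
  ids2 <- fx$clusters$variant_id[fx$clusters$cluster == "2"]
  s1 <- build_gene_score(fx$genotypes, fx$oriented_ar, ids1)
  s2 <- build_gene_score(fx$genotypes, fx$oriented_ar, ids2)
  d1 <- decile_summary(fx$subjects, s1$score)
  d2 <- decile_summary(fx$subjects, s2$score)

  expect_equal(d1$decile, 1:10)
  expect_true(all(abs(d1$n - nrow(fx$subjects) / 10) <= 1))
  # mean apoB strictly increases across deciles of either score
  expect_true(all(diff(d1$mean_apob) > 0))
  expect_true(all(diff(d2$mean_apob) > 0))

  span <- function(x) x[10] - x[1]
  # receptor-like score: LDL-C and TRL/remnant-C both rise, TG much less
  # (in SD units) -- receptor variants touch TG only through the remnant
  # pool they clear
  expect_gt(span(d1$mean_ldl_c), 2 * abs(span(d1$mean_tg)) *
              (sd(fx$subjects$ldl_c_direct) / sd(fx$subjects$tg)))
  expect_gt(span(d1$mean_trl_remnant_c), 0)
  # lipolysis-like score: TG and TRL/remnant-C rise steeply, LDL-C weakly
  expect_gt(span(d2$mean_tg) / sd(fx$subjects$tg),
            2 * span(d2$mean_ldl_c) / sd(fx$subjects$ldl_c_direct))

  # null score: flat trait means
  set.seed(701)
  d0 <- decile_summary(fx$subjects, rnorm(nrow(fx$subjects)))
  expect_lt(abs(span(d0$mean_apob)), 0.02)
})

test_that("decile Cox hazards: structure, reference and null calibration", {
  fx <- big_fixture()
  ids2 <- fx$clusters$variant_id[fx$clusters$cluster == "2"]
  s2 <- build_gene_score(fx$genotypes, fx$oriented_ar, ids2)
  hz <- quiet(decile_hazards(fx$subjects, s2$score))
  tab <- tidy(hz)
  expect_equal(tab$hr[1], 1)
  expect_equal(tab$se_log_hr[1], 0)
  expect_equal(nrow(tab), 10)
  expect_true(all(tab$ci_low[-1] <= tab$hr[-1] & tab$hr[-1] <=
                    tab$ci_high[-1]))

  # null scores: decile HR CIs cover 1 almost everywhere
  set.seed(702)
  cover <- replicate(5, {
    hz0 <- quiet(decile_hazards(fx$subjects, rnorm(nrow(fx$subjects))))
    t0 <- hz0$table[-1, ]
    mean(t0$ci_low <= 1 & 1 <= t0$ci_high)
  })
  expect_gte(mean(cover), 0.9)
})

test_that("Cox fits agree with a brute-force partial-likelihood oracle", {
  set.seed(703)
  n <- 200
  x1 <- rnorm(n)
  x2 <- rbinom(n, 1, 0.5)
  t_ev <- rexp(n, rate = 0.05 * exp(0.5 * x1 + 0.3 * x2))
  time <- pmin(t_ev, 12)
  status <- as.integer(t_ev <= 12)
  fit <- survival::coxph(survival::Surv(time, status) ~ x1 + x2,
                         ties = "breslow")
  oracle <- oracle_cox(time, status, cbind(x1, x2))
  expect_equal(unname(coef(fit)), oracle, tolerance = 1e-6)
})

test_that("hazard scaling per 10 mg/dL apoB and its invariances", {
  # exactly linear decile log-HRs with slope 1 per g/L -> HR = exp(0.1)
  means <- tibble::tibble(decile = 1:10,
                          mean_apob = seq(0.9, 1.2, length.out = 10))
  tab <- tibble::tibble(
    decile = 1:10,
    log_hr = 1.0 * (means$mean_apob - means$mean_apob[1]),
    se_log_hr = c(0, rep(0.05, 9)))
  out <- hr_per_10mg_dl(tab, means)
  expect_equal(out$hr_per_10mg_dl, exp(0.1), tolerance = 1e-9)
  expect_equal(out$slope_per_g_l, 1.0, tolerance = 1e-9)

  # zero slope -> HR 1
  out0 <- hr_per_10mg_dl(dplyr::mutate(tab, log_hr = 0 * log_hr), means)
  expect_equal(out0$hr_per_10mg_dl, 1, tolerance = 1e-9)

  # invariance to the reference decile: shifting all log-HRs by a constant
  # leaves the slope unchanged
  shifted <- dplyr::mutate(tab, log_hr = log_hr - log_hr[5])
  out_s <- hr_per_10mg_dl(shifted, means)
  expect_equal(out_s$slope_per_g_l, out$slope_per_g_l, tolerance = 1e-9)
})

test_that("cluster interaction test: nulls, symmetry and combined model", {
  means <- tibble::tibble(decile = 1:10,
                          mean_apob = seq(0.9, 1.2, length.out = 10))
  set.seed(706)
  jitter10 <- c(0, rnorm(9, 0, 0.02))
  mk <- function(slope, se = 0.05) tibble::tibble(
    decile = 1:10,
    log_hr = slope * (means$mean_apob - means$mean_apob[1]) + jitter10,
    se_log_hr = c(0, rep(se, 9)))

  # identical inputs: interaction estimate 0, p ~ 1
  it0 <- interaction_test(mk(1), means, mk(1), means)
  expect_equal(it0$interaction$estimate, 0, tolerance = 1e-9)
  expect_gt(it0$interaction$p, 0.99)

  # swapping cluster labels flips the sign, same p
  it_a <- interaction_test(mk(1), means, mk(2.2), means)
  it_b <- interaction_test(mk(2.2), means, mk(1), means)
  expect_equal(it_a$interaction$estimate, -it_b$interaction$estimate,
               tolerance = 1e-9)
  expect_equal(it_a$interaction$p, it_b$interaction$p, tolerance = 1e-9)

  # combined Cox model reports one HR per score
  fx <- big_fixture()
  ids1 <- fx$clusters$variant_id[fx$clusters$cluster == "1"]
  ids2 <- fx$clusters$variant_id[fx$clusters$cluster == "2"]
  s1 <- build_gene_score(fx$genotypes, fx$oriented_ar, ids1)$score
  s2 <- build_gene_score(fx$genotypes, fx$oriented_ar, ids2)$score
  hz1 <- quiet(decile_hazards(fx$subjects, s1))
  hz2 <- quiet(decile_hazards(fx$subjects, s2))
  d1 <- decile_summary(fx$subjects, s1)
  d2 <- decile_summary(fx$subjects, s2)
  it <- interaction_test(hz1, d1, hz2, d2, fx$subjects, s1, s2)
  expect_equal(nrow(it$combined), 2)
  expect_true(all(it$combined$hr_per_10mg_dl > 0))
})

test_that("observational Cox recovers the remnant-vs-LDL hazard ordering", {
  fx <- big_fixture()
  obs <- observational_cox(fx$subjects)
  hr_trl <- obs$hr[obs$exposure == "trl_remnant_c"]
  hr_ldl <- obs$hr[obs$exposure == "ldl_c_direct"]
  expect_gt(hr_trl, hr_ldl)

  # swapping exposure order permutes rows, not values
  obs2 <- observational_cox(fx$subjects,
                            exposures = c("trl_remnant_c", "ldl_c_direct"))
  expect_equal(sort(obs$hr), sort(obs2$hr), tolerance = 1e-9)

  # zero-effect generator: both CIs cover 1
  p0 <- cohort_params(n_subjects = 6000, n_variants = 20,
                      beta_remnant = 0, beta_ldl = 0, seed = 704)
  co0 <- simulate_cohort(p0)
  s0 <- quiet(derive_lipids(co0$subjects))
  obs0 <- observational_cox(s0)
  expect_true(all(obs0$ci_low <= 1 & 1 <= obs0$ci_high))
})

test_that("ratio spline: normalisation, winsorisation and glance", {
  s <- small_cohort()$subjects
  sp <- quiet(ratio_spline(s))
  # curve equals 1 at the reference ratio by construction
  ref_hr <- approx(sp$curve$ratio, sp$curve$hr, xout = sp$reference_ratio)$y
  expect_equal(ref_hr, 1, tolerance = 1e-3)
  expect_true(sp$p_spline >= 0 && sp$p_spline <= 1)
  gl <- glance(sp)
  expect_false(gl$include_hdl)
  expect_gt(gl$log_hr_range, 0)

  # winsorisation message on extreme outliers
  s2 <- s
  s2$trl_remnant_c[1] <- 50
  expect_message(ratio_spline(s2), "winsorised")
})
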