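#' Parameters for a synthetic lipid-genetics cohort
#'
#' Bundles every constant the cohort generator needs: the mapping from latent
#' lipoprotein particle pools to measured lipids, population SD targets for
#' the derived traits, the block-LD genotype model, and the censored
#' event-time process.  Defaults emulate a UK-Biobank-like population:
#' TRL/remnant-C SD 0.30 mmol/L, LDL-C SD 0.82 mmol/L, TG SD 1.0 mmol/L,
#' apoB SD 0.23 g/L, a 12-year follow-up with administrative censoring, and a
#' per-particle hazard gradient that is higher for remnant particles than for
#' LDL particles.
#'
#' Two latent pools drive the lipid panel: `R` (TRL/remnant particles) and
#' `L` (LDL particles), in arbitrary particle units.  Cholesterol per
#' particle-unit is `chol_per_remnant` for remnants and `chol_per_ldl` for
#' LDL; because remnants carry more cholesterol per particle the former must
#' exceed the latter.  apoB counts particles: `apob = apob_per_particle *
#' (R + L) + assay noise`.  Residual (environmental) variances are solved
#' internally so that the derived traits hit `sd_targets`, given the genetic
#' variance implied by the variant panel; `noise_scale = 0` switches every
#' noise source off, making the generative equations exact (useful for
#' closed-form checks).
#'
#' @param n_subjects Number of subjects.
#' @param n_variants Number of variants in the panel.
#' @param block_size Variants per LD block.
#' @param ld_rho Adjacent-variant allele correlation within a block, in
#'   `[0, 1)`.
#' @param maf_range Range the per-block minor allele frequency is drawn from.
#' @param chol_per_remnant,chol_per_ldl mmol/L cholesterol per particle-unit.
#' @param apob_per_particle g/L apoB per particle-unit.
#' @param tg_per_remnant mmol/L TG per remnant particle-unit.
#' @param tg_baseline Baseline TG (mmol/L) not attributable to the remnant
#'   pool.
#' @param mean_remnant,mean_ldl Cohort mean latent pool sizes (particle
#'   units).
#' @param sd_targets Named vector of target marginal SDs for
#'   `trl_remnant_c`, `ldl_c`, `tg` (mmol/L) and `apob` (g/L).
#' @param h2_remnant,h2_ldl Fraction of each pool's variance explained by the
#'   variant panel.
#' @param assay_sd Named vector of assay noise SDs for `tc`, `ldl`, `apob`
#'   (trait units).
#' @param hdl_mean Mean HDL-C (mmol/L); the default is the reference value
#'   used by the spline models.
#' @param hdl_sd Marginal HDL-C SD (mmol/L).
#' @param hdl_remnant_slope mmol/L HDL-C change per mmol/L remnant
#'   cholesterol; negative by default, emulating cholesteryl-ester transfer
#'   from HDL to TRL during remnant formation, which leaves HDL-C
#'   anti-correlated with TG and remnant cholesterol.
#' @param receptor_gamma_range Range of the LDL:remnant particle effect ratio
#'   `gamma = effect_ldl / effect_remnant` for receptor-class variants.
#'   Together with `apob_per_particle / chol_per_remnant` this pins the
#'   implied apoB:TRL/remnant-C effect-size ratio inside `[0.9, 3.0]`.
#' @param lipolysis_gamma_range Same for lipolysis-class variants; keeps the
#'   implied ratio inside `[-0.75, 0.75]`.
#' @param lpa_effect_mean Mean Lp(a) effect (mg/dL per minor allele) for
#'   Lp(a)-class variants.
#' @param lpa_chol_frac Fraction of Lp(a) mass counted as cholesterol by the
#'   direct LDL-C assay (so Lp(a)-raising variants show an LDL-C
#'   association, as in real panels, and exercise the exclusion filter).
#' @param baseline_hazard Baseline yearly event rate of the exponential
#'   incident-event process.
#' @param beta_remnant,beta_ldl Log-hazard per remnant / LDL particle-unit
#'   (both must be non-negative).
#' @param hazard_age,hazard_male Log-hazard per year of age (centred at 56)
#'   and for male sex.
#' @param prevalent_intercept Logit intercept of the independent
#'   prevalent-disease draw.
#' @param follow_up_years Administrative censoring time (years).
#' @param noise_scale Multiplier on all solved noise SDs (0 = noiseless).
#' @param truncation_floor Small positive floor applied to lipid values.
#' @param max_truncated_frac Error if more than this fraction of subjects is
#'   floored in any lipid.
#' @param seed Integer seed for the whole cohort simulation.
#'
#' @return A list of class `cohort_params`.
#' @export
#' @examples
#' p <- cohort_params(n_subjects = 500, n_variants = 30, seed = 1)
#' str(p[c("n_subjects", "sd_targets")])
cohort_params <- function(n_subjects = 20000,
                          n_variants = 150,
                          block_size = 5,
                          ld_rho = 0.4,
                          maf_range = c(0.05, 0.5),
                          chol_per_remnant = 1.0,
                          chol_per_ldl = 0.88,
                          apob_per_particle = 0.22,
                          tg_per_remnant = 2.66,
                          tg_baseline = 0.3,
                          mean_remnant = 0.6,
                          mean_ldl = 4.0,
                          sd_targets = c(trl_remnant_c = 0.30, ldl_c = 0.82,
                                         tg = 1.0, apob = 0.23),
                          h2_remnant = 0.3,
                          h2_ldl = 0.3,
                          assay_sd = c(tc = 0.05, ldl = 0.18, apob = NA_real_),
                          hdl_mean = 1.435,
                          hdl_sd = 0.33,
                          hdl_remnant_slope = -0.7,
                          receptor_gamma_range = c(5.5, 8.5),
                          lipolysis_gamma_range = c(-0.3, 0.5),
                          lpa_effect_mean = 15,
                          lpa_chol_frac = 0.3,
                          baseline_hazard = 0.004,
                          beta_remnant = 0.41,
                          beta_ldl = 0.16,
                          hazard_age = 0.06,
                          hazard_male = 0.4,
                          prevalent_intercept = qlogis(0.05),
                          follow_up_years = 12,
                          noise_scale = 1,
                          truncation_floor = 0.01,
                          max_truncated_frac = 0.01,
                          seed = 1L) {
  assert_that(n_subjects >= 2, "`n_subjects` must be at least 2")
  assert_that(n_variants >= 1, "`n_variants` must be positive")
  assert_that(ld_rho >= 0 && ld_rho < 1, "`ld_rho` must be in [0, 1)")
  assert_that(all(maf_range > 0) && all(maf_range <= 0.5) &&
                maf_range[1] <= maf_range[2],
              "`maf_range` must be within (0, 0.5]")
  assert_that(chol_per_remnant / apob_per_particle >
                chol_per_ldl / apob_per_particle,
              "remnants must carry more cholesterol per apoB than LDL")
  assert_that(beta_remnant >= 0 && beta_ldl >= 0,
              "hazard gradients must be non-negative")
  assert_that(all(sd_targets > 0), "all SD targets must be positive")
  assert_that(follow_up_years > 0, "`follow_up_years` must be positive")
  assert_that(noise_scale >= 0, "`noise_scale` must be non-negative")
  needed <- c("trl_remnant_c", "ldl_c", "tg", "apob")
  assert_that(all(needed %in% names(sd_targets)),
              "`sd_targets` must name trl_remnant_c, ldl_c, tg and apob")
  structure(
    list(
      n_subjects = as.integer(n_subjects), n_variants = as.integer(n_variants),
      block_size = as.integer(block_size), ld_rho = ld_rho,
      maf_range = maf_range,
      chol_per_remnant = chol_per_remnant, chol_per_ldl = chol_per_ldl,
      apob_per_particle = apob_per_particle,
      tg_per_remnant = tg_per_remnant, tg_baseline = tg_baseline,
      mean_remnant = mean_remnant, mean_ldl = mean_ldl,
      sd_targets = sd_targets, h2_remnant = h2_remnant, h2_ldl = h2_ldl,
      assay_sd = assay_sd, hdl_mean = hdl_mean, hdl_sd = hdl_sd,
      hdl_remnant_slope = hdl_remnant_slope,
      receptor_gamma_range = receptor_gamma_range,
      lipolysis_gamma_range = lipolysis_gamma_range,
      lpa_effect_mean = lpa_effect_mean, lpa_chol_frac = lpa_chol_frac,
      baseline_hazard = baseline_hazard,
      beta_remnant = beta_remnant, beta_ldl = beta_ldl,
      hazard_age = hazard_age, hazard_male = hazard_male,
      prevalent_intercept = prevalent_intercept,
      follow_up_years = follow_up_years, noise_scale = noise_scale,
      truncation_floor = truncation_floor,
      max_truncated_frac = max_truncated_frac,
      seed = as.integer(seed)
    ),
    class = "cohort_params"
  )
}

#' Simulate a variant panel with receptor-like and lipolysis-like classes
#'
#' Draws `n_variants` variant specifications carrying per-minor-allele effects
#' on the latent remnant and LDL particle pools.  Receptor-class variants
#' affect both pools concordantly (LDL:remnant particle effect ratio drawn
#' from `params$receptor_gamma_range`), so their implied apoB:TRL/remnant-C
#' effect-size ratio lies in `[0.9, 3.0]`.  Lipolysis-class variants act
#' mainly on the remnant pool, with implied ratios in `[-0.75, 0.75]`.
#' Lp(a)-class variants carry an Lp(a) effect and no lipid effect; null
#' variants carry no effect at all.  Class effect vectors are rescaled so the
#' panel's genetic variance equals `h2_remnant` / `h2_ldl` of the pool
#' variance targets (accounting for within-block LD covariance).
#'
#' @param params A [cohort_params()] object.
#' @param mix Named fractions over `receptor`, `lipolysis`, `lpa`, `null`;
#'   must sum to 1.  Class counts are multinomial draws, except that at least
#'   one `lpa` variant is guaranteed whenever its fraction is positive.
#' @param seed Optional integer seed; `NULL` continues the current RNG
#'   stream.
#'
#' @return A tibble (the variant panel) with columns `variant_id`,
#'   `minor_allele`, `major_allele`, `maf`, `ld_block`, `mechanism`,
#'   `effect_remnant`, `effect_ldl`, `effect_lpa` and `implied_ratio` (the
#'   apoB:TRL/remnant-C effect-size ratio implied by the generative
#'   constants; `NA` for variants without a remnant effect).
#' @export
simulate_panel <- function(params,
                           mix = c(receptor = 0.35, lipolysis = 0.35,
                                   lpa = 0.05, null = 0.25),
                           seed = NULL) {
  stopifnot(inherits(params, "cohort_params"))
  if (!is.null(seed)) set.seed(seed)
  classes <- c("receptor", "lipolysis", "lpa", "null")
  mix <- mix[intersect(classes, names(mix))]
  assert_that(length(mix) > 0 && all(mix >= 0) && abs(sum(mix) - 1) < 1e-8,
              "`mix` fractions must be non-negative and sum to 1")
  m <- params$n_variants
  assert_that(m > 0, "cannot simulate a zero-variant panel")
  full_mix <- setNames(numeric(4), classes)
  full_mix[names(mix)] <- mix

  # a mechanism is a property of a locus: the whole LD block shares it, so
  # null blocks are genuinely null rather than proxies of causal neighbours
  n_blocks <- ceiling(m / params$block_size)
  ld_block <- rep(seq_len(n_blocks), each = params$block_size)[seq_len(m)]
  block_mech <- sample(classes, n_blocks, replace = TRUE, prob = full_mix)
  if (full_mix[["lpa"]] > 0 && !any(block_mech == "lpa")) {
    block_mech[sample.int(n_blocks, 1)] <- "lpa"
  }
  mechanism <- block_mech[ld_block]
  block_maf <- runif(n_blocks, params$maf_range[1], params$maf_range[2])
  maf <- block_maf[ld_block]

  alleles <- c("A", "C", "G", "T")
  minor <- sample(alleles, m, replace = TRUE)
  major <- vapply(minor, function(a) sample(setdiff(alleles, a), 1), "")

  effect_remnant <- numeric(m)
  effect_ldl <- numeric(m)
  effect_lpa <- numeric(m)
  gamma <- numeric(m)

  is_rec <- mechanism == "receptor"
  is_lip <- mechanism == "lipolysis"
  is_lpa <- mechanism == "lpa"

  # raw magnitude shapes: a floor plus a mild gamma tail, so every causal
  # variant is well detectable at cohort scale (keeping realised effect-size
  # ratios close to the implied ones) while a few are stronger
  # (PCSK9/LPL-like)
  raw_shape <- function(k) (0.8 + rgamma(k, shape = 1.2, scale = 0.35)) *
    sample(c(-1, 1), k, replace = TRUE)

  pool_var_targets <- .pool_variance_targets(params)

  if (any(is_rec)) {
    gamma[is_rec] <- runif(sum(is_rec), params$receptor_gamma_range[1],
                           params$receptor_gamma_range[2])
    raw <- raw_shape(sum(is_rec))
    # scale receptor class to meet the LDL-pool genetic variance budget
    vl <- .genetic_variance(gamma[is_rec] * raw, maf[is_rec],
                            ld_block[is_rec], params$ld_rho)
    scl <- sqrt(params$h2_ldl * pool_var_targets["ldl"] / vl)
    effect_remnant[is_rec] <- scl * raw
    effect_ldl[is_rec] <- gamma[is_rec] * scl * raw
  }
  rec_r_var <- .genetic_variance(effect_remnant, maf, ld_block, params$ld_rho)

  if (any(is_lip)) {
    gamma[is_lip] <- runif(sum(is_lip), params$lipolysis_gamma_range[1],
                           params$lipolysis_gamma_range[2])
    raw <- raw_shape(sum(is_lip))
    budget <- max(params$h2_remnant * pool_var_targets["remnant"] - rec_r_var,
                  0.05 * params$h2_remnant * pool_var_targets["remnant"])
    vr <- .genetic_variance(raw, maf[is_lip], ld_block[is_lip], params$ld_rho)
    scl <- sqrt(budget / vr)
    effect_remnant[is_lip] <- scl * raw
    effect_ldl[is_lip] <- gamma[is_lip] * scl * raw
  }

  if (any(is_lpa)) {
    effect_lpa[is_lpa] <- rgamma(sum(is_lpa), shape = 2,
                                 scale = params$lpa_effect_mean / 2)
  }

  implied_ratio <- ifelse(
    abs(effect_remnant) > 0,
    params$apob_per_particle * (effect_remnant + effect_ldl) /
      (params$chol_per_remnant * effect_remnant),
    NA_real_
  )
  bad_rec <- is_rec & (implied_ratio < 0.9 | implied_ratio > 3.0)
  bad_lip <- is_lip & (implied_ratio < -0.75 | implied_ratio > 0.75)
  assert_that(!any(bad_rec, na.rm = TRUE) && !any(bad_lip, na.rm = TRUE),
              paste("generator constants place implied effect-size ratios",
                    "outside the cluster intervals; adjust gamma ranges or",
                    "apob_per_particle/chol_per_remnant"))

  tibble::tibble(
    variant_id = sprintf("rs%06d", seq_len(m)),
    minor_allele = minor, major_allele = unname(major),
    maf = maf, ld_block = ld_block,
    mechanism = factor(mechanism, levels = classes),
    effect_remnant = effect_remnant,
    effect_ldl = effect_ldl,
    effect_lpa = effect_lpa,
    implied_ratio = implied_ratio
  )
}

# pool-variance targets in particle units, net of assay noise on the
# measured scale
.pool_variance_targets <- function(params) {
  sdt <- params$sd_targets
  asd <- params$assay_sd
  ns2 <- params$noise_scale^2
  v_rem <- (sdt[["trl_remnant_c"]]^2 - ns2 * asd[["tc"]]^2) /
    params$chol_per_remnant^2
  v_ldl <- (sdt[["ldl_c"]]^2 - ns2 * asd[["ldl"]]^2) / params$chol_per_ldl^2
  assert_that(v_rem > 0 && v_ldl > 0,
              "assay noise SDs exceed the trait SD targets")
  c(remnant = v_rem, ldl = v_ldl)
}

# expected genetic variance e' C e, C the HWE dosage covariance with
# within-block AR-style correlation rho^|i-j|
.genetic_variance <- function(effects, maf, ld_block, ld_rho) {
  total <- 0
  for (b in unique(ld_block)) {
    idx <- which(ld_block == b)
    e <- effects[idx]
    if (all(e == 0)) next
    p <- maf[idx][1]
    v <- 2 * p * (1 - p)
    d <- abs(outer(seq_along(idx), seq_along(idx), "-"))
    C <- v * ld_rho^d
    total <- total + drop(crossprod(e, C %*% e))
  }
  total
}

#' Simulate genotype dosages with block LD
#'
#' Generates two haplotypes per subject and sums them into 0/1/2 minor-allele
#' dosage counts.  Within an LD block, haplotype alleles follow a Markov
#' copy-with-refresh chain: each allele is copied from its left neighbour
#' with probability `ld_rho` and redrawn at the block frequency otherwise,
#' which makes the allele-level (and hence dosage) correlation between
#' adjacent variants exactly `ld_rho` while preserving the marginal allele
#' frequency.  Blocks are mutually independent.
#'
#' @param panel A panel tibble from [simulate_panel()].
#' @param n_subjects Number of subjects.
#' @param ld_rho Adjacent-variant allele correlation in `[0, 1)`.
#' @param seed Optional integer seed; `NULL` continues the RNG stream.
#'
#' @return An integer matrix (subjects x variants) with variant ids as column
#'   names.
#' @export
simulate_genotypes <- function(panel, n_subjects, ld_rho = 0.4, seed = NULL) {
  assert_that(n_subjects >= 2, "`n_subjects` must be at least 2")
  assert_that(ld_rho >= 0 && ld_rho < 1, "`ld_rho` must be in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  m <- nrow(panel)
  G <- matrix(0L, nrow = n_subjects, ncol = m,
              dimnames = list(NULL, panel$variant_id))
  for (b in unique(panel$ld_block)) {
    idx <- which(panel$ld_block == b)
    p <- panel$maf[idx][1]
    for (hap in 1:2) {
      H <- matrix(0L, n_subjects, length(idx))
      H[, 1] <- rbinom(n_subjects, 1L, p)
      if (length(idx) > 1) {
        for (k in 2:length(idx)) {
          copy <- runif(n_subjects) < ld_rho
          H[, k] <- ifelse(copy, H[, k - 1], rbinom(n_subjects, 1L, p))
        }
      }
      G[, idx] <- G[, idx] + H
    }
  }
  storage.mode(G) <- "integer"
  G
}

#' Simulate lipid phenotypes and covariates from genotypes
#'
#' Builds the latent remnant and LDL particle pools as baseline plus the
#' centred genetic contribution plus residual noise, then maps pools to the
#' measured lipid panel: TG and the remnant pool share a multiplicative
#' log-normal residual (keeping both positive and right-skewed, as in real
#' cohorts), LDL gets an additive Gaussian residual, apoB counts particles,
#' and total cholesterol is assembled as LDL-C + remnant cholesterol + HDL-C
#' plus assay noise, so that non-HDL-C minus LDL-C recovers the latent
#' remnant cholesterol up to the configured assay SD.  Residual variances are
#' solved so the derived TRL/remnant-C, LDL-C, TG and apoB SDs hit
#' `params$sd_targets`.  Covariates (age, sex, BMI, SBP, HbA1c, five genetic
#' PCs) are nuisance draws centred on the reference values used by the
#' hazard models.
#'
#' @param genotypes Dosage matrix from [simulate_genotypes()].
#' @param panel The matching panel tibble.
#' @param params A [cohort_params()] object.
#' @param seed Optional integer seed; `NULL` continues the RNG stream.
#'
#' @return A subject tibble with identifiers, covariates, measured lipids
#'   (`tc`, `hdl_c`, `ldl_c_direct`, `tg` in mmol/L; `apob` in g/L; `lpa` in
#'   mg/dL) and the latent pools `latent_remnant`, `latent_ldl` (particle
#'   units) retained as oracle columns for parameter-recovery checks.
#' @export
simulate_phenotypes <- function(genotypes, panel, params, seed = NULL) {
  stopifnot(inherits(params, "cohort_params"))
  assert_that(ncol(genotypes) == nrow(panel),
              "genotype columns must match panel rows")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(genotypes)
  ns <- params$noise_scale

  Gc <- sweep(genotypes, 2, 2 * panel$maf)
  gR <- drop(Gc %*% panel$effect_remnant)
  gL <- drop(Gc %*% panel$effect_ldl)
  g_lpa <- drop(genotypes %*% panel$effect_lpa)

  pool_targets <- .pool_variance_targets(params)
  var_gR <- .genetic_variance(panel$effect_remnant, panel$maf,
                              panel$ld_block, params$ld_rho)
  var_gL <- .genetic_variance(panel$effect_ldl, panel$maf,
                              panel$ld_block, params$ld_rho)
  assert_that(var_gR <= pool_targets[["remnant"]] + .eps,
              "remnant-pool genetic variance exceeds its SD target")
  assert_that(var_gL <= pool_targets[["ldl"]] + .eps,
              "LDL-pool genetic variance exceeds its SD target")

  # remnant pool: multiplicative log-normal residual (mean-one)
  muR <- params$mean_remnant
  sig2_R <- log((pool_targets[["remnant"]] + muR^2) / (var_gR + muR^2))
  sig_R <- ns * sqrt(max(sig2_R, 0))
  R <- (muR + gR) * exp(rnorm(n, 0, max(sig_R, 0)) - sig_R^2 / 2)

  # LDL pool: additive Gaussian residual; the Lp(a) cholesterol picked up
  # by the direct assay (below) is budgeted out of the residual so measured
  # LDL-C still hits its SD target
  muL <- params$mean_ldl
  var_lpa <- .genetic_variance(panel$effect_lpa, panel$maf, panel$ld_block,
                               params$ld_rho) + ns^2 * 0.8 * 25^2
  lpa_ldl_var <- (params$lpa_chol_frac / 38.67)^2 * var_lpa /
    params$chol_per_ldl^2
  sig_L <- ns * sqrt(max(pool_targets[["ldl"]] - var_gL - lpa_ldl_var, 0))
  L <- muL + gL + rnorm(n, 0, max(sig_L, 0))

  n_trunc <- sum(R < 0) + sum(L < 0)
  R <- pmax(R, params$truncation_floor)
  L <- pmax(L, params$truncation_floor)

  # TG shares the remnant pool plus its own multiplicative residual
  tgA_mean <- params$tg_baseline + params$tg_per_remnant * muR
  tgA_var <- params$tg_per_remnant^2 * pool_targets[["remnant"]]
  sig2_TG <- log((params$sd_targets[["tg"]]^2 + tgA_mean^2) /
                   (tgA_var + tgA_mean^2))
  sig_TG <- ns * sqrt(max(sig2_TG, 0))
  tg <- (params$tg_baseline + params$tg_per_remnant * R) *
    exp(rnorm(n, 0, max(sig_TG, 0)) - sig_TG^2 / 2)

  # apoB counts particles; assay noise solved against the SD target unless
  # given explicitly
  cov_gRL <- .genetic_covariance(panel, params$ld_rho)
  apob_lat_var <- params$apob_per_particle^2 *
    (pool_targets[["remnant"]] + pool_targets[["ldl"]] - lpa_ldl_var +
       2 * cov_gRL)
  apob_assay <- params$assay_sd[["apob"]]
  if (is.na(apob_assay)) {
    apob_assay <- sqrt(max(params$sd_targets[["apob"]]^2 - apob_lat_var,
                           1e-6))
  }
  apob <- params$apob_per_particle * (R + L) + rnorm(n, 0, ns * apob_assay)

  lpa <- g_lpa + ns * rgamma(n, shape = 0.8, scale = 25)

  # the direct LDL-C assay counts part of the Lp(a) particle's cholesterol
  ldl_c_direct <- params$chol_per_ldl * L +
    params$lpa_chol_frac * lpa / 38.67 +
    rnorm(n, 0, ns * params$assay_sd[["ldl"]])

  hdl_coupling <- params$hdl_remnant_slope * params$chol_per_remnant
  sig_H <- sqrt(max(params$hdl_sd^2 -
                      hdl_coupling^2 * pool_targets[["remnant"]], 0))
  hdl_c <- params$hdl_mean + hdl_coupling * (R - muR) +
    rnorm(n, 0, ns * sig_H)

  tc <- ldl_c_direct + params$chol_per_remnant * R + hdl_c +
    rnorm(n, 0, ns * params$assay_sd[["tc"]])

  lipids <- list(tg = tg, apob = apob, ldl_c_direct = ldl_c_direct,
                 hdl_c = hdl_c, lpa = lpa)
  floors <- vapply(lipids, function(x) sum(x < 0), 0)
  n_trunc <- n_trunc + sum(floors)
  if (n_trunc > params$max_truncated_frac * n * (length(lipids) + 2)) {
    abort_bad_arg(sprintf(
      "%d values fell below the positivity floor (> %.1f%% allowance)",
      n_trunc, 100 * params$max_truncated_frac))
  }
  lipids <- lapply(lipids, pmax, params$truncation_floor)

  u <- runif(n, pnorm((40 - 56) / 8), pnorm((70 - 56) / 8))
  age <- 56 + 8 * qnorm(u)
  sex <- factor(ifelse(runif(n) < 0.5, "male", "female"),
                levels = c("female", "male"))

  tibble::tibble(
    subject_id = sprintf("S%07d", seq_len(n)),
    age = age, sex = sex,
    bmi = pmax(rnorm(n, 26.32, 4), 15),
    sbp = rnorm(n, 137, 18),
    hba1c = pmax(rnorm(n, 34.8, 6), 15),
    pc1 = rnorm(n), pc2 = rnorm(n), pc3 = rnorm(n),
    pc4 = rnorm(n), pc5 = rnorm(n),
    lipid_lowering = FALSE,
    tc = tc, hdl_c = lipids$hdl_c, ldl_c_direct = lipids$ldl_c_direct,
    tg = lipids$tg, apob = lipids$apob, lpa = lipids$lpa,
    latent_remnant = R, latent_ldl = L,
    n_truncated = n_trunc
  )
}

# genetic covariance between remnant and LDL pools, with block LD
.genetic_covariance <- function(panel, ld_rho) {
  total <- 0
  for (b in unique(panel$ld_block)) {
    idx <- which(panel$ld_block == b)
    eR <- panel$effect_remnant[idx]
    eL <- panel$effect_ldl[idx]
    if (all(eR == 0) || all(eL == 0)) next
    p <- panel$maf[idx][1]
    d <- abs(outer(seq_along(idx), seq_along(idx), "-"))
    C <- 2 * p * (1 - p) * ld_rho^d
    total <- total + drop(crossprod(eR, C %*% eL))
  }
  total
}

#' Simulate prevalent and incident ASCVD outcomes
#'
#' Incident events follow an exponential time-to-event process with
#' log-hazard `log(baseline_hazard) + beta_remnant * (R - mean_R) +
#' beta_ldl * (L - mean_L) + age and sex terms`, administratively censored at
#' `follow_up_years`.  Prevalent disease is an independent logistic draw with
#' the same linear predictor, so the combined prevalent-or-incident binary
#' outcome has (approximately, on the rare-disease scale) the same per-pool
#' log-odds gradients.
#'
#' @param subjects Subject tibble from [simulate_phenotypes()] (must carry
#'   the latent pool columns).
#' @param params A [cohort_params()] object.
#' @param seed Optional integer seed; `NULL` continues the RNG stream.
#'
#' @return `subjects` with `prevalent_ascvd`, `incident_event` (logical) and
#'   `time_to_event_or_censor` (years, in `(0, follow_up_years]`) appended.
#' @export
simulate_outcomes <- function(subjects, params, seed = NULL) {
  stopifnot(inherits(params, "cohort_params"))
  assert_that(all(c("latent_remnant", "latent_ldl") %in% names(subjects)),
              "`subjects` must carry the latent pool columns")
  assert_that(is.finite(params$beta_remnant) && is.finite(params$beta_ldl),
              "hazard gradients must be finite")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(subjects)
  lp <- params$beta_remnant * (subjects$latent_remnant - params$mean_remnant) +
    params$beta_ldl * (subjects$latent_ldl - params$mean_ldl) +
    params$hazard_age * (subjects$age - 56) +
    params$hazard_male * (subjects$sex == "male")

  prevalent <- runif(n) < plogis(params$prevalent_intercept + lp)
  t_event <- rexp(n, rate = params$baseline_hazard * exp(lp))
  incident <- t_event <= params$follow_up_years
  time <- pmin(t_event, params$follow_up_years)
  frac <- mean(incident)
  assert_that(frac > 0 && frac < 1,
              "incident event fraction degenerate under this configuration")
  dplyr::mutate(subjects,
                prevalent_ascvd = prevalent,
                incident_event = incident,
                time_to_event_or_censor = time)
}

#' Simulate a complete cohort (panel, genotypes, subjects, outcomes)
#'
#' Convenience wrapper running [simulate_panel()], [simulate_genotypes()],
#' [simulate_phenotypes()] and [simulate_outcomes()] under the single seed in
#' `params`; identical `params` (including seed) give bit-identical output.
#'
#' @inheritParams simulate_panel
#' @return A list with elements `panel`, `genotypes`, `subjects` and
#'   `params`.
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_params(n_subjects = 300, n_variants = 20,
#'                                         seed = 7))
#' dim(cohort$genotypes)
simulate_cohort <- function(params,
                            mix = c(receptor = 0.35, lipolysis = 0.35,
                                    lpa = 0.05, null = 0.25)) {
  set.seed(params$seed)
  panel <- simulate_panel(params, mix)
  genotypes <- simulate_genotypes(panel, params$n_subjects, params$ld_rho)
  subjects <- simulate_phenotypes(genotypes, panel, params)
  subjects <- simulate_outcomes(subjects, params)
  list(panel = panel, genotypes = genotypes, subjects = subjects,
       params = params)
}
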