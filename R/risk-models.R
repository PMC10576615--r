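#' Per-subject polygenic apoB-raising-allele score
#'
#' `score_i = sum_j w_j * d_ij`, where `d_ij` counts the apoB-raising allele
#' (the minor-allele dosage, or `2 - dosage` for variants whose minor allele
#' lowers apoB) and `w_j` is the apoB effect size in g/L per raising allele.
#' Because the weights are in apoB units the score is a predicted apoB, so a
#' regression of measured apoB on the score has slope ~ 1.
#'
#' @param genotypes Dosage matrix (minor-allele counts).
#' @param oriented Output of [orient_effects()] in `apob_raising` mode; its
#'   `beta_apob` (>= 0) are the weights and `flipped` marks variants whose
#'   raising allele is the major one.
#' @param variants Optional subset of variant ids (e.g. one cluster).
#' @return Tibble `subject_id` (row index when the matrix is unnamed) and
#'   `score`.
#' @export
build_gene_score <- function(genotypes, oriented, variants = NULL) {
  assert_that(identical(unique(oriented$orientation), "apob_raising"),
              "`oriented` must be in apob_raising orientation")
  tab <- oriented
  if (!is.null(variants)) {
    tab <- dplyr::filter(tab, .data$variant_id %in% variants)
  }
  missing <- setdiff(tab$variant_id, colnames(genotypes))
  assert_that(length(missing) == 0,
              paste("variants missing from the genotype matrix:",
                    paste(head(missing, 5), collapse = ", ")))
  G <- genotypes[, tab$variant_id, drop = FALSE]
  storage.mode(G) <- "double"
  # count the raising allele
  G[, tab$flipped] <- 2 - G[, tab$flipped, drop = FALSE]
  w <- tab$beta_apob
  assert_that(all(w >= 0), "weights must be non-negative after orientation")
  tibble::tibble(
    subject_id = rownames(genotypes) %||% seq_len(nrow(G)),
    score = drop(G %*% w)
  )
}

#' Decile summary of a gene score
#'
#' Cuts the score into deciles (rank-based, ties resolved by record order)
#' and reports per-decile means of measured apoB, TG, TRL/remnant-C and
#' LDL-C.
#'
#' @param subjects Subject tibble with derived lipids (see
#'   [derive_lipids()]).
#' @param score Numeric score vector aligned with `subjects`.
#' @return Tibble with `decile`, `n`, `mean_score`, `mean_apob`, `mean_tg`,
#'   `mean_trl_remnant_c`, `mean_ldl_c`.
#' @export
decile_summary <- function(subjects, score) {
  assert_that(nrow(subjects) == length(score),
              "`score` must align with `subjects`")
  assert_that(nrow(subjects) >= 10, "need at least 10 subjects")
  dplyr::mutate(subjects, .score = score,
                decile = dplyr::ntile(score, 10)) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_score = mean(.data$.score),
      mean_apob = mean(.data$apob, na.rm = TRUE),
      mean_tg = mean(.data$tg, na.rm = TRUE),
      mean_trl_remnant_c = mean(.data$trl_remnant_c, na.rm = TRUE),
      mean_ldl_c = mean(.data$ldl_c_direct, na.rm = TRUE),
      .by = "decile") |>
    dplyr::arrange(.data$decile)
}

#' Per-decile Cox hazard ratios for incident events
#'
#' Restricts to subjects free of prevalent disease, fits a Cox proportional
#' hazards model (Breslow ties by default) with decile indicators (decile 1
#' is the reference) adjusted for age and sex, and reports per-decile hazard
#' ratios with 95% CIs.  Deciles with no events are flagged (their CI is
#' unbounded).
#'
#' @param subjects Subject tibble with outcome columns.
#' @param score Numeric score vector aligned with `subjects`.
#' @param covariates Adjustment covariates (default age, sex).
#' @param ties Tie handling passed to [survival::coxph()] (default
#'   `"breslow"`; `"efron"` available).
#' @return Object of class `decile_hazards`: `table` (decile, n, events,
#'   hr, ci_low, ci_high, se_log_hr), the `fit`, and the decile index.
#' @export
decile_hazards <- function(subjects, score, covariates = c("age", "sex"),
                           ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  assert_that(nrow(subjects) == length(score),
              "`score` must align with `subjects`")
  dat <- dplyr::mutate(subjects, .score = score) |>
    dplyr::filter(!.data$prevalent_ascvd) |>
    dplyr::mutate(decile = dplyr::ntile(.data$.score, 10))
  dat$decile_f <- factor(dat$decile, levels = 1:10)
  f <- stats::as.formula(paste(
    "survival::Surv(time_to_event_or_censor, incident_event) ~ decile_f +",
    paste(covariates, collapse = " + ")))
  fit <- survival::coxph(f, data = dat, ties = ties)
  cf <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  dn <- paste0("decile_f", 2:10)
  log_hr <- c(0, cf[dn])
  se_log <- c(0, se[dn])
  counts <- dat |>
    dplyr::summarise(n = dplyr::n(), events = sum(.data$incident_event),
                     .by = "decile") |>
    dplyr::arrange(.data$decile)
  n_dec <- counts$n[match(1:10, counts$decile)]
  ev_dec <- counts$events[match(1:10, counts$decile)]
  tab <- tibble::tibble(
    decile = 1:10,
    n = n_dec,
    events = ev_dec,
    log_hr = unname(log_hr), se_log_hr = unname(se_log),
    hr = exp(log_hr),
    ci_low = exp(log_hr - qnorm(0.975) * se_log),
    ci_high = exp(log_hr + qnorm(0.975) * se_log),
    zero_events = dplyr::coalesce(ev_dec, 0L) == 0
  )
  if (any(tab$zero_events)) {
    message("decile_hazards: decile(s) with zero events flagged; their ",
            "hazard ratios are unidentified")
  }
  structure(list(table = tab, fit = fit, decile = dat$decile, ties = ties),
            class = "decile_hazards")
}

#' @export
print.decile_hazards <- function(x, ...) {
  cat("<decile_hazards>\n")
  print(as.data.frame(x$table[, c("decile", "n", "events", "hr",
                                  "ci_low", "ci_high")]), digits = 3)
  invisible(x)
}

#' @rdname decile_hazards
#' @param x A `decile_hazards` object.
#' @param ... Unused.
#' @method tidy decile_hazards
#' @export
tidy.decile_hazards <- function(x, ...) x$table

#' Hazard ratio per 10 mg/dL apoB from decile results
#'
#' Inverse-variance-weighted linear regression (with intercept, so the
#' result does not depend on which decile is the reference) of decile
#' log-hazard-ratios on decile mean apoB (g/L); the slope `b` is scaled to
#' `HR = exp(0.1 * b)` per 10 mg/dL (0.1 g/L) with a delta-method CI.  The
#' reference decile (SE 0) and any non-finite decile is excluded from the
#' regression.
#'
#' @param hz A [decile_hazards()] result (or its `table`).
#' @param decile_means A [decile_summary()] table supplying `mean_apob` per
#'   decile.
#' @return Tibble `hr_per_10mg_dl`, `ci_low`, `ci_high`, `slope_per_g_l`,
#'   `se_slope`, `n_deciles`.
#' @export
hr_per_10mg_dl <- function(hz, decile_means) {
  tab <- if (inherits(hz, "decile_hazards")) hz$table else hz
  d <- dplyr::inner_join(tab, decile_means[, c("decile", "mean_apob")],
                         by = "decile") |>
    dplyr::filter(is.finite(.data$log_hr), is.finite(.data$se_log_hr),
                  .data$se_log_hr > 0)
  assert_that(nrow(d) >= 3, "need at least 3 deciles with finite hazard")
  w <- 1 / d$se_log_hr^2
  fit <- lm(log_hr ~ mean_apob, data = d, weights = w)
  b <- coef(fit)[["mean_apob"]]
  se_b <- sqrt(vcov(fit)["mean_apob", "mean_apob"])
  tibble::tibble(
    hr_per_10mg_dl = exp(0.1 * b),
    ci_low = exp(0.1 * (b - qnorm(0.975) * se_b)),
    ci_high = exp(0.1 * (b + qnorm(0.975) * se_b)),
    slope_per_g_l = b, se_slope = se_b, n_deciles = nrow(d)
  )
}

#' Test for a difference in apoB-risk slope between clusters
#'
#' Stacks the two clusters' decile points and fits a weighted regression of
#' decile log-HR on mean apoB, a cluster indicator and their interaction;
#' the Wald p-value of the interaction term tests whether the apoB-risk
#' gradient differs between clusters.  Optionally also fits a combined Cox
#' model on the whole (event-free-at-baseline) cohort with both polygenic
#' scores as continuous covariates.
#'
#' @param hz1,hz2 [decile_hazards()] results for clusters 1 and 2.
#' @param means1,means2 Matching [decile_summary()] tables.
#' @param subjects,score1,score2 Optional: subject tibble plus the two
#'   per-subject scores; when all are supplied a combined Cox model is
#'   fitted and per-10mg/dL HRs for both scores reported.
#' @return List with `interaction` (estimate, se, z, p) and (optionally)
#'   `combined` (per-score HR per 10 mg/dL).
#' @export
interaction_test <- function(hz1, means1, hz2, means2,
                             subjects = NULL, score1 = NULL, score2 = NULL) {
  get_pts <- function(hz, means, label) {
    tab <- if (inherits(hz, "decile_hazards")) hz$table else hz
    dplyr::inner_join(tab, means[, c("decile", "mean_apob")],
                      by = "decile") |>
      dplyr::filter(is.finite(.data$log_hr), .data$se_log_hr > 0) |>
      dplyr::mutate(cluster = label)
  }
  d <- dplyr::bind_rows(get_pts(hz1, means1, 0), get_pts(hz2, means2, 1))
  w <- 1 / d$se_log_hr^2
  fit <- lm(log_hr ~ mean_apob * cluster, data = d, weights = w)
  est <- coef(fit)[["mean_apob:cluster"]]
  se <- sqrt(vcov(fit)["mean_apob:cluster", "mean_apob:cluster"])
  z <- est / se
  out <- list(interaction = tibble::tibble(
    estimate = est, se = se, z = z, p = 2 * pnorm(-abs(z))))

  if (!is.null(subjects) && !is.null(score1) && !is.null(score2)) {
    dat <- dplyr::mutate(subjects, s1 = score1, s2 = score2) |>
      dplyr::filter(!.data$prevalent_ascvd)
    fit2 <- survival::coxph(
      survival::Surv(time_to_event_or_censor, incident_event) ~
        s1 + s2 + age + sex,
      data = dat, ties = "breslow")
    cf <- coef(fit2)[c("s1", "s2")]
    se2 <- sqrt(diag(vcov(fit2))[c("s1", "s2")])
    out$combined <- tibble::tibble(
      score = c("cluster1", "cluster2"),
      hr_per_10mg_dl = exp(0.1 * cf),
      ci_low = exp(0.1 * (cf - qnorm(0.975) * se2)),
      ci_high = exp(0.1 * (cf + qnorm(0.975) * se2))
    )
  }
  out
}

#' Observational Cox model for lipid exposures
#'
#' Joint Cox proportional hazards fit of incident events (subjects free of
#' prevalent disease) on one or more lipid exposures, reporting hazard
#' ratios per 1.0 mmol/L with 95% CIs.  Warns when the exposures are highly
#' collinear.
#'
#' @param subjects Subject tibble with derived lipids and outcome columns.
#' @param exposures Exposure column names (default LDL-C and
#'   TRL/remnant-C).
#' @param covariates Additional adjustment columns (default age, sex).
#' @param ties Cox tie handling (default Breslow).
#' @return Tibble `exposure`, `hr`, `ci_low`, `ci_high`, `log_hr`, `se`,
#'   `p`, with the `coxph` fit attached as attribute `fit`.
#' @export
observational_cox <- function(subjects,
                              exposures = c("ldl_c_direct", "trl_remnant_c"),
                              covariates = c("age", "sex"),
                              ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  dat <- dplyr::filter(subjects, !.data$prevalent_ascvd)
  dat <- dat[complete.cases(dat[, c(exposures, covariates)]), ]
  if (length(exposures) > 1) {
    cc <- cor(dat[, exposures])
    if (any(abs(cc[upper.tri(cc)]) > 0.95)) {
      warning("exposures are highly collinear (|r| > 0.95)", call. = FALSE)
    }
  }
  f <- stats::as.formula(paste(
    "survival::Surv(time_to_event_or_censor, incident_event) ~",
    paste(c(exposures, covariates), collapse = " + ")))
  fit <- survival::coxph(f, data = dat, ties = ties)
  cf <- coef(fit)[exposures]
  se <- sqrt(diag(vcov(fit))[exposures])
  out <- tibble::tibble(
    exposure = exposures, log_hr = unname(cf), se = unname(se),
    hr = exp(unname(cf)),
    ci_low = exp(unname(cf - qnorm(0.975) * se)),
    ci_high = exp(unname(cf + qnorm(0.975) * se)),
    p = 2 * pnorm(-abs(unname(cf / se)))
  )
  attr(out, "fit") <- fit
  out
}

#' Reference covariate values for spline hazard curves
#'
#' The covariate profile the fitted ratio-spline curves are normalised to.
#' @return Named list.
#' @export
spline_reference <- function() {
  list(apob = 1.066, sex = "female", bmi = 26.32, age = 56, sbp = 137,
       hba1c = 34.8, hdl_c = 1.435)
}

#' Cox spline model for a lipid ratio exposure
#'
#' Fits incident events on a restricted cubic spline (natural cubic spline,
#' 4 knots at the 5/35/65/95% quantiles) of an exposure ratio such as
#' TG : LDL-C or TRL/remnant-C : LDL-C, controlling for apoB, sex, BMI,
#' age, systolic BP and HbA1c, optionally further adjusted for HDL-C.
#' Extreme ratios are winsorised at configurable quantiles before fitting.
#' The fitted curve is the hazard ratio along a ratio grid, normalised to 1
#' at the reference ratio (the cohort median by default); because the model
#' is linear in the covariates the curve is invariant to the covariate
#' profile.  The spline term is tested with a Wald chi-square on all spline
#' coefficients.
#'
#' @param subjects Subject tibble with derived lipids and outcomes.
#' @param numerator,denominator Ratio component columns (denominator must
#'   be positive).
#' @param include_hdl Adjust for HDL-C as well (default FALSE).
#' @param covariates Adjustment columns.
#' @param knot_quantiles Four quantiles for the spline knots.
#' @param winsor_quantiles Ratio winsorisation quantiles.
#' @param reference_ratio Ratio value where the curve equals 1 (default:
#'   cohort median).
#' @param grid_n Number of curve grid points.
#' @param ties Cox tie handling.
#' @return Object of class `ratio_spline`: `curve` (tibble `ratio`, `hr`),
#'   `p_spline`, `fit`, `reference_ratio`, `include_hdl`, `n`, `events`.
#' @export
ratio_spline <- function(subjects, numerator = "trl_remnant_c",
                         denominator = "ldl_c_direct",
                         include_hdl = FALSE,
                         covariates = c("apob", "sex", "bmi", "age", "sbp",
                                        "hba1c"),
                         knot_quantiles = c(0.05, 0.35, 0.65, 0.95),
                         winsor_quantiles = c(0.001, 0.999),
                         reference_ratio = NULL,
                         grid_n = 100,
                         ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  if (include_hdl) covariates <- union(covariates, "hdl_c")
  dat <- dplyr::filter(subjects, !.data$prevalent_ascvd,
                       !is.na(.data[[numerator]]),
                       !is.na(.data[[denominator]]),
                       .data[[denominator]] > 0)
  dat$ratio <- dat[[numerator]] / dat[[denominator]]
  lim <- quantile(dat$ratio, winsor_quantiles)
  n_wins <- sum(dat$ratio < lim[1] | dat$ratio > lim[2])
  if (n_wins > 0) {
    message(sprintf("ratio_spline: winsorised %d extreme ratio value(s)",
                    n_wins))
  }
  dat$ratio <- pmin(pmax(dat$ratio, lim[1]), lim[2])

  kq <- quantile(dat$ratio, knot_quantiles)
  basis <- splines::ns(dat$ratio, knots = kq[2:3],
                       Boundary.knots = kq[c(1, 4)])
  X <- cbind(basis, stats::model.matrix(
    ~ . - 1, data = as.data.frame(dat[, covariates, drop = FALSE])))
  spline_idx <- seq_len(ncol(basis))
  fit <- survival::coxph(
    survival::Surv(dat$time_to_event_or_censor, dat$incident_event) ~ X,
    ties = ties)

  cf <- coef(fit)[spline_idx]
  V <- vcov(fit)[spline_idx, spline_idx, drop = FALSE]
  stat <- drop(crossprod(cf, solve(V, cf)))
  p_spline <- pchisq(stat, df = length(cf), lower.tail = FALSE)

  ref <- reference_ratio %||% median(dat$ratio)
  grid <- seq(quantile(dat$ratio, 0.01), quantile(dat$ratio, 0.99),
              length.out = grid_n)
  pb <- predict(basis, grid)
  rb <- predict(basis, ref)
  lp <- drop((pb - matrix(rb, nrow(pb), ncol(pb), byrow = TRUE)) %*% cf)
  curve <- tibble::tibble(ratio = grid, hr = exp(lp))

  structure(list(curve = curve, p_spline = p_spline, fit = fit,
                 reference_ratio = ref, include_hdl = include_hdl,
                 n = nrow(dat), events = sum(dat$incident_event),
                 exposure = paste(numerator, "/", denominator)),
            class = "ratio_spline")
}

#' @export
print.ratio_spline <- function(x, ...) {
  cat(sprintf("<ratio_spline: %s%s, n = %d, events = %d, p = %.3g>\n",
              x$exposure, if (x$include_hdl) " + HDL-C" else "",
              x$n, x$events, x$p_spline))
  invisible(x)
}

#' @rdname ratio_spline
#' @param x A `ratio_spline` object.
#' @param ... Unused.
#' @method glance ratio_spline
#' @export
glance.ratio_spline <- function(x, ...) {
  tibble::tibble(exposure = x$exposure, include_hdl = x$include_hdl,
                 n = x$n, events = x$events, p_spline = x$p_spline,
                 reference_ratio = x$reference_ratio,
                 log_hr_range = diff(range(log(x$curve$hr))))
}
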