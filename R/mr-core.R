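#' Assemble summary statistics for Mendelian randomisation
#'
#' Bundles variant-exposure effects (one column per exposure), their SEs,
#' and variant-outcome log-odds effects with SEs.  Variants are assumed
#' mutually independent (i.e. the set has been LD-pruned).
#'
#' @param b_exp Numeric matrix (variants x exposures) of per-allele exposure
#'   effects, or a vector for a single exposure.
#' @param se_exp Matching matrix/vector of exposure SEs.
#' @param b_out Vector of per-allele outcome log-odds effects.
#' @param se_out Vector of positive outcome SEs.
#' @param snps Optional variant ids.
#' @param exposures Optional exposure names (defaults to `b_exp` column
#'   names).
#' @return An object of class `mr_input`.
#' @export
mr_input <- function(b_exp, se_exp, b_out, se_out, snps = NULL,
                     exposures = NULL) {
  B <- as.matrix(b_exp)
  S <- as.matrix(se_exp)
  assert_that(nrow(B) == length(b_out) && nrow(B) == length(se_out),
              "dimensions of exposure and outcome statistics disagree")
  assert_that(!anyNA(B) && !anyNA(b_out) && !anyNA(se_out),
              "mr_input does not accept missing cells")
  assert_that(all(se_out > 0), "outcome SEs must be positive")
  exposures <- exposures %||% colnames(B) %||%
    paste0("exposure", seq_len(ncol(B)))
  colnames(B) <- exposures
  snps <- snps %||% sprintf("snp%d", seq_len(nrow(B)))
  structure(list(B = B, S = S, b_out = b_out, se_out = se_out, snps = snps,
                 exposures = exposures),
            class = "mr_input")
}

# weighted least squares core shared by IVW and Egger
.mr_wls <- function(X, y, w, random_effects = TRUE) {
  XtW <- t(X * w)
  V <- solve(XtW %*% X)
  theta <- drop(V %*% (XtW %*% y))
  resid <- y - drop(X %*% theta)
  df <- length(y) - ncol(X)
  dispersion <- if (df > 0) sum(w * resid^2) / df else NA_real_
  infl <- if (random_effects && is.finite(dispersion)) {
    max(1, sqrt(dispersion))
  } else 1
  se <- sqrt(diag(V)) * infl
  list(theta = theta, se = se, dispersion = dispersion, df = df)
}

.mr_estimates_tbl <- function(exposures, theta, se) {
  theta <- unname(theta)
  se <- unname(se)
  z <- theta / se
  tibble::tibble(
    exposure = exposures,
    theta = theta, se = se,
    or_per_unit = exp(theta),
    ci_low = exp(theta - qnorm(0.975) * se),
    ci_high = exp(theta + qnorm(0.975) * se),
    p = 2 * pnorm(-abs(z))
  )
}

#' Inverse-variance-weighted Mendelian randomisation
#'
#' Weighted least-squares regression of variant-outcome effects on
#' variant-exposure effects with weights `1/se_out^2` and no intercept:
#' univariable when `b_exp` has one column, multivariable otherwise.  All
#' variants are treated as valid instruments.  By default the SEs carry a
#' multiplicative random-effects inflation `max(1, sqrt(dispersion))`;
#' p-values use the normal approximation.
#'
#' @param input An [mr_input()].
#' @param intercept Add a free intercept (used internally by
#'   [egger_fit()]).
#' @param random_effects Apply the multiplicative SE inflation (default
#'   TRUE); `FALSE` gives the fixed-effect model.
#' @return An object of class `mr_fit`; see [tidy.mr_fit()] /
#'   [glance.mr_fit()].
#' @export
ivw_fit <- function(input, intercept = FALSE, random_effects = TRUE) {
  stopifnot(inherits(input, "mr_input"))
  K <- ncol(input$B) + as.integer(intercept)
  assert_that(nrow(input$B) >= K,
              "need at least as many variants as free parameters")
  X <- if (intercept) cbind(`(intercept)` = 1, input$B) else input$B
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort_bad_arg(paste("collinear exposures:", paste(bad, collapse = ", ")))
  }
  w <- 1 / input$se_out^2
  fit <- .mr_wls(X, input$b_out, w, random_effects)
  est <- .mr_estimates_tbl(colnames(X), fit$theta, fit$se)
  intercept_row <- NULL
  if (intercept) {
    intercept_row <- est[1, ]
    est <- est[-1, ]
  }
  structure(list(estimates = est, intercept = intercept_row,
                 method = if (intercept) "egger" else "ivw",
                 n_snps = nrow(input$B), dispersion = fit$dispersion,
                 random_effects = random_effects),
            class = "mr_fit")
}

#' MR-Egger regression
#'
#' IVW with a free intercept; a non-zero intercept indicates directional
#' pleiotropy and the slope(s) remain the causal estimates.  Because Egger
#' regression is orientation dependent, effects are first oriented so that
#' each variant's effect on the first exposure is positive.
#'
#' @param input An [mr_input()].
#' @param random_effects Multiplicative SE inflation (default TRUE).
#' @return An `mr_fit` whose `intercept` element carries the pleiotropy
#'   intercept estimate and test.
#' @export
egger_fit <- function(input, random_effects = TRUE) {
  stopifnot(inherits(input, "mr_input"))
  assert_that(nrow(input$B) >= ncol(input$B) + 1,
              "Egger regression needs variants >= exposures + 1")
  flip <- ifelse(input$B[, 1] < 0, -1, 1)
  oriented <- mr_input(input$B * flip, input$S, input$b_out * flip,
                       input$se_out, input$snps, input$exposures)
  ivw_fit(oriented, intercept = TRUE, random_effects = random_effects)
}

#' Contamination-mixture Mendelian randomisation
#'
#' Univariable estimator that accommodates invalid instruments: each
#' variant's ratio estimate `by/bx` is modelled as either valid
#' (Normal(theta, se)) or invalid (Normal(0, psi)); a profile likelihood
#' over a theta grid picks the causal estimate, a likelihood-ratio 95% CI
#' and the valid-variant assignment at the optimum.
#'
#' @param bx,sx Variant-exposure effects and SEs (single exposure).
#' @param by,sy Variant-outcome effects and SEs.
#' @param psi SD of the invalid-estimate distribution; default 1.5 x SD of
#'   the ratio estimates.
#' @param grid_n Number of grid points (default 500) spanning +/- 4 pooled
#'   SEs around the IVW point.
#' @param bx_tol Variants with `|bx|` below this are dropped (ratio
#'   undefined); default `1e-8`.
#' @param exposure Optional exposure label.
#' @return An `mr_fit` with `valid` (logical, per retained variant) and
#'   `snps` elements; the CI is likelihood-based.
#' @export
conmix_fit <- function(bx, sx, by, sy, psi = NULL, grid_n = 500,
                       bx_tol = 1e-8, exposure = "exposure") {
  keep <- abs(bx) >= bx_tol
  if (!all(keep)) {
    message(sprintf("conmix_fit: dropped %d variant(s) with |bx| < tol",
                    sum(!keep)))
  }
  bx <- bx[keep]; by <- by[keep]; sy <- sy[keep]
  J <- length(bx)
  assert_that(J >= 1, "no usable variants")
  ratio <- by / bx
  se_r <- sy / abs(bx)
  if (is.null(psi)) psi <- 1.5 * if (J > 1) sd(ratio) else se_r
  if (!is.finite(psi) || psi <= 0) psi <- max(se_r)

  w <- 1 / se_r^2
  ivw_point <- sum(w * ratio) / sum(w)
  pooled_se <- sqrt(1 / sum(w))
  ll_invalid <- dnorm(ratio, 0, psi, log = TRUE)
  profile_ll <- function(g) {
    colSums(pmax(outer(ratio, g, function(r, th)
      dnorm(r, th, se_r, log = TRUE)), ll_invalid))
  }
  # coarse pass over the whole ratio range (outliers can pull the IVW
  # point far from the contamination-mixture optimum), then a fine grid
  # of grid_n points spanning +/- 4 pooled SEs around the coarse optimum
  span <- 2 * max(se_r)
  coarse <- seq(min(ratio) - span, max(ratio) + span, length.out = grid_n)
  best_coarse <- coarse[which.max(profile_ll(coarse))]
  fine <- seq(best_coarse - 4 * pooled_se, best_coarse + 4 * pooled_se,
              length.out = grid_n)
  grid <- sort(unique(c(coarse, fine)))
  ll_valid <- outer(ratio, grid, function(r, th) dnorm(r, th, se_r, log = TRUE))
  ll <- colSums(pmax(ll_valid, ll_invalid))
  best <- which.max(ll)
  theta <- grid[best]
  valid <- ll_valid[, best] >= ll_invalid
  inside <- ll >= ll[best] - qchisq(0.95, 1) / 2
  ci <- range(grid[inside])
  se_eff <- sum(valid / se_r^2)^(-0.5)

  est <- tibble::tibble(
    exposure = exposure, theta = theta, se = se_eff,
    or_per_unit = exp(theta), ci_low = exp(ci[1]), ci_high = exp(ci[2]),
    p = 2 * pnorm(-abs(theta / se_eff))
  )
  structure(list(estimates = est, intercept = NULL, method = "conmix",
                 n_snps = J, dispersion = NA_real_, psi = psi,
                 valid = valid, snps = which(keep), grid = grid,
                 loglik = ll),
            class = "mr_fit")
}

#' @export
print.mr_fit <- function(x, ...) {
  cat(sprintf("<mr_fit: %s, %d variants>\n", x$method, x$n_snps))
  print(as.data.frame(x$estimates), digits = 4)
  if (!is.null(x$intercept)) {
    cat(sprintf("Egger intercept: %.4f (p = %.3g)\n",
                x$intercept$theta, x$intercept$p))
  }
  invisible(x)
}

#' Tidy a Mendelian randomisation fit
#'
#' @param x An `mr_fit`.
#' @param ... Unused.
#' @return Tibble with one row per exposure: log-odds `theta`, `se`,
#'   per-unit OR with 95% CI and p-value, plus the method label.
#' @method tidy mr_fit
#' @export
tidy.mr_fit <- function(x, ...) {
  dplyr::mutate(x$estimates, method = x$method, .before = 1)
}

#' One-line summary of a Mendelian randomisation fit
#'
#' @param x An `mr_fit`.
#' @param ... Unused.
#' @return Tibble with `method`, `n_snps`, `dispersion`, and for Egger fits
#'   the intercept and its p-value.
#' @method glance mr_fit
#' @export
glance.mr_fit <- function(x, ...) {
  tibble::tibble(
    method = x$method, n_snps = x$n_snps, dispersion = x$dispersion,
    egger_intercept = if (!is.null(x$intercept)) x$intercept$theta else
      NA_real_,
    egger_intercept_p = if (!is.null(x$intercept)) x$intercept$p else
      NA_real_
  )
}

#' Per-unit and per-SD odds-ratio report
#'
#' Joins fitted estimates with a population SD table and adds per-SD odds
#' ratios (`or_per_unit^sd`, CIs transformed monotonically).  Values are
#' full precision; use `digits` only when printing.
#'
#' @param fits An `mr_fit` or list of them.
#' @param sd_tbl An [sd_table()]; `trait` must cover every exposure.
#' @param exposure_traits Optional named character vector mapping exposure
#'   names to `sd_tbl` traits (defaults to identity).
#' @return Tibble: exposure, method, n_snps, or_unit, ci_low, ci_high,
#'   or_sd, or_sd_low, or_sd_high, p.
#' @export
report_estimates <- function(fits, sd_tbl, exposure_traits = NULL) {
  if (inherits(fits, "mr_fit")) fits <- list(fits)
  tab <- purrr::map_dfr(fits, function(f) {
    dplyr::mutate(tidy(f), n_snps = f$n_snps)
  })
  map <- exposure_traits %||% setNames(tab$exposure, tab$exposure)
  tab$trait <- unname(map[tab$exposure])
  missing_sd <- setdiff(tab$trait, sd_tbl$trait)
  assert_that(length(missing_sd) == 0,
              paste("no SD available for:", paste(missing_sd, collapse = ", ")))
  tab |>
    dplyr::left_join(sd_tbl[, c("trait", "sd")], by = "trait") |>
    dplyr::transmute(
      exposure = .data$exposure, method = .data$method,
      n_snps = .data$n_snps,
      or_unit = .data$or_per_unit,
      ci_low = .data$ci_low, ci_high = .data$ci_high,
      or_sd = or_per_sd(.data$or_per_unit, .data$sd),
      or_sd_low = or_per_sd(.data$ci_low, .data$sd),
      or_sd_high = or_per_sd(.data$ci_high, .data$sd),
      p = .data$p
    )
}
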