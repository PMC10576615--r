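# intercept-only design when no covariates are requested
.covariate_matrix <- function(subjects, covariates) {
  if (length(covariates) == 0) {
    return(matrix(1, nrow(subjects), 1,
                  dimnames = list(NULL, "(Intercept)")))
  }
  stats::model.matrix(
    ~ ., data = as.data.frame(subjects[, covariates, drop = FALSE]))
}

#' Default covariate set for association scans
#'
#' Age, sex and the first five genetic principal components.
#' @return Character vector of covariate column names.
#' @export
assoc_covariates <- function() c("age", "sex", paste0("pc", 1:5))

#' Per-variant association scan
#'
#' Regresses a trait on minor-allele dosage, one variant at a time, adjusted
#' for covariates.  Quantitative traits use exact ordinary least squares via
#' covariate projection (Frisch-Waugh), with the two-sided p-value from the
#' t distribution.  Binary traits use logistic regression: by default the
#' null-model score-test one-step estimator (the standard large-cohort GWAS
#' device — fit covariates once, then score each variant), or exact
#' per-variant `glm` with `method = "glm"`.
#'
#' Monomorphic genotype columns are reported with `beta = 0`, `p = 1` and
#' `monomorphic = TRUE`.  Records with missing trait or covariate values are
#' dropped listwise (message emitted).
#'
#' @param subjects Subject tibble carrying the trait and covariate columns.
#' @param genotypes Dosage matrix (subjects x variants), rows aligned with
#'   `subjects`.
#' @param trait Name of the trait column; logical or 0/1 traits are scanned
#'   as binary.
#' @param covariates Character vector of covariate column names; factors are
#'   expanded to dummies.
#' @param method For binary traits: `"score"` (default) or `"glm"`.
#' @return An association tibble: `variant_id`, `trait`, `beta`, `se`, `p`,
#'   `n`, `n_het`, `eaf` (coded-allele frequency), `maf`, `monomorphic`.
#' @export
assoc_scan <- function(subjects, genotypes, trait,
                       covariates = assoc_covariates(),
                       method = c("score", "glm")) {
  method <- match.arg(method)
  assert_that(trait %in% names(subjects),
              sprintf("trait column `%s` not found", trait))
  assert_that(all(covariates %in% names(subjects)),
              "missing covariate columns")
  assert_that(nrow(subjects) == nrow(genotypes),
              "`subjects` and `genotypes` must have matching rows")

  y_raw <- subjects[[trait]]
  X <- .covariate_matrix(subjects, covariates)
  keep <- !is.na(y_raw) & complete.cases(subjects[, covariates, drop = FALSE])
  if (!all(keep)) {
    message(sprintf("assoc_scan: dropped %d record(s) with missing values",
                    sum(!keep)))
    y_raw <- y_raw[keep]
    X <- X[keep, , drop = FALSE]
    genotypes <- genotypes[keep, , drop = FALSE]
  }
  n <- length(y_raw)
  binary <- is.logical(y_raw) ||
    (is.numeric(y_raw) && all(y_raw %in% c(0, 1)))
  y <- as.numeric(y_raw)

  G <- genotypes
  storage.mode(G) <- "double"
  eaf <- colMeans(G) / 2
  maf <- pmin(eaf, 1 - eaf)
  n_het <- colSums(G == 1)
  col_var <- colMeans(G^2) - colMeans(G)^2
  mono <- col_var < .eps

  if (!binary) {
    qrX <- qr(X)
    Gr <- G - qr.fitted(qrX, G)
    yr <- y - qr.fitted(qrX, y)
    gg <- colSums(Gr^2)
    gy <- drop(crossprod(Gr, yr))
    beta <- ifelse(gg > .eps, gy / gg, 0)
    rss0 <- sum(yr^2)
    df <- n - ncol(X) - 1
    rss <- pmax(rss0 - beta^2 * gg, 0)
    se <- sqrt(rss / df / pmax(gg, .eps))
    tval <- ifelse(gg > .eps, beta / se, 0)
    p <- 2 * pt(-abs(tval), df)
  } else if (method == "score") {
    null_fit <- glm.fit(X, y, family = binomial())
    mu <- null_fit$fitted.values
    w <- mu * (1 - mu)
    XtWX <- crossprod(X, X * w)
    XtWG <- crossprod(X, G * w)
    Gw <- G - X %*% solve(XtWX, XtWG)
    info <- colSums(w * Gw^2)
    U <- drop(crossprod(Gw, y - mu))
    beta <- ifelse(info > .eps, U / info, 0)
    se <- 1 / sqrt(pmax(info, .eps))
    p <- 2 * pnorm(-abs(ifelse(info > .eps, beta / se, 0)))
  } else {
    res <- apply(G, 2, function(g) {
      if (length(unique(g)) == 1L) return(c(0, NA, 1))
      fit <- glm.fit(cbind(g, X), y, family = binomial())
      cf <- fit$coefficients[1]
      # covariance from the final IRLS weights
      w <- fit$weights
      V <- solve(crossprod(cbind(g, X), cbind(g, X) * w))
      se <- sqrt(V[1, 1])
      c(cf, se, 2 * pnorm(-abs(cf / se)))
    })
    beta <- res[1, ]
    se <- res[2, ]
    p <- res[3, ]
  }

  beta[mono] <- 0
  p[mono] <- 1
  se[mono] <- NA_real_

  tibble::tibble(
    variant_id = colnames(genotypes) %||% sprintf("v%d", seq_len(ncol(G))),
    trait = trait, beta = unname(beta), se = unname(se), p = unname(p),
    n = n, n_het = unname(as.integer(n_het)), eaf = unname(eaf),
    maf = unname(maf), monomorphic = unname(mono)
  )
}

#' Scan several traits at once
#'
#' Equivalent to running [assoc_scan()] per trait and binding the rows, but
#' quantitative traits sharing a missing-data pattern reuse one covariate
#' projection of the genotype matrix, which is substantially faster on wide
#' cohorts.
#'
#' @inheritParams assoc_scan
#' @param traits Character vector of trait column names.
#' @return Long association tibble (one row per variant x trait).
#' @export
assoc_scan_traits <- function(subjects, genotypes, traits,
                              covariates = assoc_covariates(),
                              method = c("score", "glm")) {
  method <- match.arg(method)
  is_quant <- vapply(traits, function(tr) {
    y <- subjects[[tr]]
    !(is.logical(y) || (is.numeric(y) && all(y %in% c(0, 1, NA))))
  }, TRUE)
  cc_cov <- complete.cases(subjects[, covariates, drop = FALSE])
  pattern <- vapply(traits, function(tr) {
    paste(which(is.na(subjects[[tr]]) | !cc_cov), collapse = ",")
  }, "")

  out <- vector("list", length(traits))
  for (pat in unique(pattern[is_quant])) {
    idx <- which(is_quant & pattern == pat)
    if (length(idx) < 2) next
    out[idx] <- .scan_quant_shared(subjects, genotypes, traits[idx],
                                   covariates)
  }
  for (i in seq_along(traits)) {
    if (is.null(out[[i]])) {
      out[[i]] <- assoc_scan(subjects, genotypes, traits[i], covariates,
                             method)
    }
  }
  dplyr::bind_rows(out)
}

# one covariate projection shared across quantitative traits with the same
# missingness pattern; numerically identical to per-trait assoc_scan
.scan_quant_shared <- function(subjects, genotypes, traits, covariates) {
  keep <- complete.cases(subjects[, c(traits, covariates), drop = FALSE])
  if (!all(keep)) {
    message(sprintf("assoc_scan: dropped %d record(s) with missing values",
                    sum(!keep)))
  }
  X <- .covariate_matrix(subjects[keep, , drop = FALSE], covariates)
  G <- genotypes[keep, , drop = FALSE]
  storage.mode(G) <- "double"
  n <- nrow(G)
  eaf <- colMeans(G) / 2
  maf <- pmin(eaf, 1 - eaf)
  n_het <- colSums(G == 1)
  mono <- (colMeans(G^2) - colMeans(G)^2) < .eps

  qrX <- qr(X)
  Gr <- G - qr.fitted(qrX, G)
  gg <- colSums(Gr^2)
  df <- n - ncol(X) - 1
  ids <- colnames(genotypes) %||% sprintf("v%d", seq_len(ncol(G)))

  lapply(traits, function(tr) {
    y <- as.numeric(subjects[[tr]][keep])
    yr <- y - qr.fitted(qrX, y)
    gy <- drop(crossprod(Gr, yr))
    beta <- ifelse(gg > .eps, gy / gg, 0)
    rss <- pmax(sum(yr^2) - beta^2 * gg, 0)
    se <- sqrt(rss / df / pmax(gg, .eps))
    tval <- ifelse(gg > .eps, beta / se, 0)
    p <- 2 * pt(-abs(tval), df)
    beta[mono] <- 0
    p[mono] <- 1
    se[mono] <- NA_real_
    tibble::tibble(variant_id = ids, trait = tr, beta = unname(beta),
                   se = unname(se), p = unname(p), n = n,
                   n_het = unname(as.integer(n_het)), eaf = unname(eaf),
                   maf = unname(maf), monomorphic = unname(mono))
  })
}

.tier_thresholds <- c(`1` = 1e-21, `2` = 1e-12, `3` = 5e-8)

#' Tiered significance filter
#'
#' Keeps variants associated with LDL-C and/or TRL/remnant-C below the
#' tier's p-value threshold (tier 1: 1e-21; tier 2: 1e-12; tier 3: 5e-8);
#' "and/or" means the union, i.e. the minimum of the two trait p-values is
#' compared with the threshold.
#'
#' @param assoc Long association tibble containing scans for both traits.
#' @param tier 1, 2 or 3.
#' @param traits The two trait labels forming the union.
#' @return Tibble with `variant_id`, `p_min` and `tier` for retained
#'   variants.
#' @export
tier_filter <- function(assoc, tier = 3,
                        traits = c("ldl_c_direct", "trl_remnant_c")) {
  assert_that(as.character(tier) %in% names(.tier_thresholds),
              "`tier` must be 1, 2 or 3")
  assert_that(all(traits %in% assoc$trait),
              "association scans for both traits are required")
  thr <- .tier_thresholds[[as.character(tier)]]
  assoc |>
    dplyr::filter(.data$trait %in% traits) |>
    dplyr::summarise(p_min = min(.data$p), .by = "variant_id") |>
    dplyr::filter(.data$p_min < thr) |>
    dplyr::mutate(tier = as.integer(tier))
}

#' Combined LDL-C / TRL-remnant-C effect magnitude
#'
#' `sqrt(beta_ldl^2 + beta_trl^2)`: the tie-break statistic used during LD
#' pruning.
#'
#' @param beta_ldl,beta_trl Effect sizes (any consistent units).
#' @return Non-negative magnitude.
#' @export
#' @examples
#' combined_effect_size(0.3, 0.4) # 0.5
combined_effect_size <- function(beta_ldl, beta_trl) {
  assert_that(all(is.finite(beta_ldl)) && all(is.finite(beta_trl)),
              "effect sizes must be finite")
  sqrt(beta_ldl^2 + beta_trl^2)
}

#' Greedy LD pruning
#'
#' Removes linkage-disequilibrium redundancy from a candidate set: variants
#' are visited in decreasing order of combined effect size (ties broken by
#' variant id) and accepted only if their squared dosage correlation with
#' every previously accepted variant is below `r2_threshold`.  This realises
#' the pairwise rule "keep the variant with the larger combined effect"
#' deterministically.
#'
#' @param genotypes Dosage matrix containing the candidate columns.
#' @param candidates Character vector of candidate variant ids.
#' @param effect Named numeric vector of combined effect sizes (see
#'   [combined_effect_size()]) covering the candidates.
#' @param r2_threshold Retained pairs must have r^2 strictly below this
#'   (default 0.3).
#' @return Character vector of retained variant ids.
#' @export
ld_prune <- function(genotypes, candidates, effect, r2_threshold = 0.3) {
  assert_that(all(candidates %in% colnames(genotypes)),
              "genotype columns missing for some candidates")
  assert_that(all(candidates %in% names(effect)),
              "`effect` must cover all candidates")
  ord <- candidates[order(-effect[candidates], candidates)]
  G <- genotypes[, ord, drop = FALSE]
  storage.mode(G) <- "double"
  poly <- (colMeans(G^2) - colMeans(G)^2) >= .eps
  ord <- ord[poly]
  if (length(ord) == 0) return(character(0))
  r2 <- suppressWarnings(cor(G[, poly, drop = FALSE]))^2
  r2[is.na(r2)] <- 0
  kept_idx <- integer(0)
  for (i in seq_along(ord)) {
    if (length(kept_idx) == 0 ||
        all(r2[i, kept_idx] < r2_threshold)) {
      kept_idx <- c(kept_idx, i)
    }
  }
  ord[kept_idx]
}

#' Minor-allele-frequency and heterozygote-count filter
#'
#' Keeps variants with MAF strictly above `maf_threshold` and at least
#' `het_threshold` heterozygous subjects.  The full-scale heterozygote rule
#' (1000 carriers in a reference cohort of 354,104) is rescaled to the
#' analysis sample size by default so the filter stays meaningful at smaller
#' scale; pass `het_threshold` explicitly to fix it.
#'
#' @param assoc Association tibble (any single trait) carrying `maf`,
#'   `n_het` and `n`.
#' @param maf_threshold Exclusive lower MAF bound (default 0.01).
#' @param het_threshold Inclusive minimum heterozygote count; default
#'   `round(1000 * n / 354104)`, floored at 1.
#' @return Tibble of retained `variant_id` rows with `maf` and `n_het`.
#' @export
maf_het_filter <- function(assoc, maf_threshold = 0.01,
                           het_threshold = NULL) {
  if (is.null(het_threshold)) {
    het_threshold <- max(1, round(1000 * max(assoc$n) / 354104))
  }
  assoc |>
    dplyr::distinct(.data$variant_id, .keep_all = TRUE) |>
    dplyr::filter(.data$maf > maf_threshold,
                  .data$n_het >= het_threshold) |>
    dplyr::select("variant_id", "maf", "n_het")
}

#' Lipoprotein(a) exclusion filter
#'
#' Applies the Holm step-down adjustment to the candidates' Lp(a) scan
#' p-values and EXCLUDES variants whose adjusted p is below `alpha`; the
#' multiplicity family is the candidate set entering the filter.
#'
#' @param assoc_lpa Association tibble for the Lp(a) trait, restricted to
#'   the candidate set.
#' @param alpha Exclusion level (default 0.05).
#' @return `assoc_lpa` with `p_holm` and logical `excluded` appended.
#' @export
lpa_exclusion_filter <- function(assoc_lpa, alpha = 0.05) {
  dplyr::mutate(assoc_lpa,
                p_holm = p.adjust(.data$p, method = "holm"),
                excluded = .data$p_holm < alpha)
}

#' Tiered variant selection pipeline
#'
#' Runs the full selection procedure on long association scans: tier filter
#' (LDL-C and/or TRL/remnant-C union) -> MAF / heterozygote filter -> greedy
#' LD pruning (largest combined effect retained) -> Lp(a) Holm exclusion.
#' The stage order follows the procedure's description; pruning before the
#' Lp(a) filter keeps the Holm family equal to the pruned candidate list.
#'
#' @param assoc Long association tibble with scans for the two lipid traits
#'   and (optionally) `lpa`.
#' @param genotypes Dosage matrix for r^2 computation.
#' @param tier 1, 2 or 3.
#' @param traits The two union traits.
#' @param r2_threshold,maf_threshold,het_threshold,alpha Stage thresholds.
#' @return Tibble of selected variants: `variant_id`, `p_min`,
#'   `combined_effect`.
#' @export
select_variants <- function(assoc, genotypes, tier = 3,
                            traits = c("ldl_c_direct", "trl_remnant_c"),
                            r2_threshold = 0.3, maf_threshold = 0.01,
                            het_threshold = NULL, alpha = 0.05) {
  sel <- tier_filter(assoc, tier, traits)
  kept <- maf_het_filter(dplyr::filter(assoc, .data$trait == traits[1]),
                         maf_threshold, het_threshold)
  sel <- dplyr::semi_join(sel, kept, by = "variant_id")

  eff <- assoc |>
    dplyr::filter(.data$trait %in% traits,
                  .data$variant_id %in% sel$variant_id) |>
    tidyr::pivot_wider(id_cols = "variant_id", names_from = "trait",
                       values_from = "beta") |>
    dplyr::mutate(combined = combined_effect_size(.data[[traits[1]]],
                                                  .data[[traits[2]]]))
  effect <- setNames(eff$combined, eff$variant_id)
  pruned <- ld_prune(genotypes, sel$variant_id, effect, r2_threshold)
  sel <- dplyr::filter(sel, .data$variant_id %in% pruned)

  if ("lpa" %in% assoc$trait) {
    lpa <- assoc |>
      dplyr::filter(.data$trait == "lpa",
                    .data$variant_id %in% sel$variant_id) |>
      lpa_exclusion_filter(alpha)
    sel <- dplyr::filter(sel,
                         .data$variant_id %in% lpa$variant_id[!lpa$excluded])
  }
  dplyr::left_join(sel,
                   tibble::tibble(variant_id = names(effect),
                                  combined_effect = unname(effect)),
                   by = "variant_id")
}
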