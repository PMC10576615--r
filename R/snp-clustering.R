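#' Orient per-variant effects
#'
#' Reshapes a long association table (one row per variant x trait) into one
#' row per variant with `beta_<trait>` / `se_<trait>` columns, under one of
#' two allele-orientation conventions: `minor_vs_major` keeps effects as
#' estimated for the minor allele; `apob_raising` flips the sign of every
#' trait effect for variants whose minor-allele apoB effect is negative, so
#' the exposure allele is the apoB-raising one.  Variants with an apoB
#' effect of exactly zero keep the minor-allele orientation and are flagged.
#'
#' @param assoc Long association tibble including an `apob` scan.
#' @param mode `"minor_vs_major"` (default) or `"apob_raising"`.
#' @return Wide tibble with `variant_id`, `orientation`, `flipped`,
#'   `flag_zero_apob` and per-trait `beta_*` / `se_*` columns.
#' @export
orient_effects <- function(assoc,
                           mode = c("minor_vs_major", "apob_raising")) {
  mode <- match.arg(mode)
  assert_that("apob" %in% assoc$trait, "an apoB scan is required")
  wide <- assoc |>
    dplyr::select("variant_id", "trait", "beta", "se") |>
    tidyr::pivot_wider(names_from = "trait", values_from = c("beta", "se"))
  flip <- rep(1, nrow(wide))
  flag0 <- wide$beta_apob == 0
  if (mode == "apob_raising") {
    flip <- ifelse(wide$beta_apob < 0, -1, 1)
    if (any(flag0)) {
      message(sprintf(
        "orient_effects: %d variant(s) with zero apoB effect kept in %s",
        sum(flag0), "minor-allele orientation"))
    }
  }
  beta_cols <- grep("^beta_", names(wide), value = TRUE)
  wide[beta_cols] <- lapply(wide[beta_cols], function(b) b * flip)
  dplyr::mutate(wide, orientation = mode, flipped = flip == -1,
                flag_zero_apob = flag0, .after = "variant_id")
}

#' apoB : TRL/remnant-C effect-size ratio
#'
#' Per-variant ratio of the apoB effect (g/L per minor allele) to the
#' TRL/remnant-C effect (mmol/L per minor allele), in minor-vs-major
#' orientation.  When the denominator is smaller in magnitude than
#' `min_denominator` the ratio is undefined (`NA`) and the variant will be
#' left unassigned: a quotient over a near-zero, noise-level denominator
#' carries no information.
#'
#' @param beta_apob apoB effects, g/L per allele.
#' @param beta_trl TRL/remnant-C effects, mmol/L per allele.
#' @param min_denominator Scalar or per-variant vector; the recommended
#'   default is one standard error of `beta_trl`.
#' @return Numeric vector of ratios (`NA` where undefined).
#' @export
#' @examples
#' effect_ratio(0.045, 0.03) # 1.5
effect_ratio <- function(beta_apob, beta_trl, min_denominator = 0) {
  ifelse(abs(beta_trl) >= pmax(min_denominator, .Machine$double.xmin),
         beta_apob / beta_trl, NA_real_)
}

#' Assign variants to effect-ratio clusters
#'
#' Closed-interval rule on the apoB : TRL/remnant-C effect-size ratio:
#' ratios in `[0.9, 3.0]` go to cluster 1 (receptor-pathway-like: concordant
#' remnant, LDL and apoB effects), ratios in `[-0.75, 0.75]` to cluster 2
#' (lipolysis-pathway-like: remnant/TG effects with little apoB change);
#' anything else — including undefined ratios — is unassigned.
#'
#' @param ratio Numeric vector of effect-size ratios (`NA` = undefined).
#' @param cluster1,cluster2 Interval bounds (closed).
#' @return Factor with levels `"1"`, `"2"`, `"unassigned"`.
#' @export
#' @examples
#' assign_cluster(c(1.50, 0.29, 0.8, NA))
assign_cluster <- function(ratio, cluster1 = c(0.9, 3.0),
                           cluster2 = c(-0.75, 0.75)) {
  out <- dplyr::case_when(
    !is.na(ratio) & ratio >= cluster1[1] & ratio <= cluster1[2] ~ "1",
    !is.na(ratio) & ratio >= cluster2[1] & ratio <= cluster2[2] ~ "2",
    .default = "unassigned"
  )
  factor(out, levels = c("1", "2", "unassigned"))
}

#' Cluster assignments for an oriented effect table
#'
#' Convenience wrapper: computes per-variant effect-size ratios (guarding
#' the denominator at one SE of the TRL/remnant-C effect by default) and
#' applies the interval rule.
#'
#' @param oriented Output of [orient_effects()] in `minor_vs_major` mode,
#'   with `beta_apob` and `beta_trl_remnant_c` columns.
#' @param min_denominator `NULL` (default: one SE of the TRL/remnant-C
#'   effect) or a numeric guard.
#' @inheritParams assign_cluster
#' @return Tibble `variant_id`, `ratio`, `cluster`.
#' @export
cluster_assignments <- function(oriented, min_denominator = NULL,
                                cluster1 = c(0.9, 3.0),
                                cluster2 = c(-0.75, 0.75)) {
  need <- c("beta_apob", "beta_trl_remnant_c", "se_trl_remnant_c")
  assert_that(all(need %in% names(oriented)),
              "need apoB and TRL/remnant-C effect columns")
  guard <- min_denominator %||% oriented$se_trl_remnant_c
  ratio <- effect_ratio(oriented$beta_apob, oriented$beta_trl_remnant_c,
                        guard)
  tibble::tibble(variant_id = oriented$variant_id, ratio = ratio,
                 cluster = assign_cluster(ratio, cluster1, cluster2))
}

#' Frequency distribution of effect-size ratios
#'
#' Bins the defined ratios over a fixed range (empty bins preserved) and
#' reports a descriptive bimodality summary: the two highest local modes
#' and the antimode (lowest bin) between them.  The cluster boundaries
#' remain the fixed printed intervals; the histogram is for inspection
#' only.
#'
#' @param ratios Numeric vector (NAs dropped); at least 20 defined values.
#' @param bin_width Bin width (default 0.1).
#' @param range Histogram range; values outside are clipped into the edge
#'   bins.
#' @return Object of class `ratio_histogram`: list with `bins` (tibble
#'   `mid`, `count`) and `summary` (modes/antimode).  Has an
#'   [ggplot2::autoplot()] method.
#' @export
ratio_histogram <- function(ratios, bin_width = 0.1, range = c(-2, 4)) {
  r <- ratios[!is.na(ratios)]
  assert_that(length(r) >= 20,
              "at least 20 defined ratios are required")
  r <- pmin(pmax(r, range[1]), range[2])
  breaks <- seq(range[1], range[2] + bin_width, by = bin_width)
  bin <- cut(r, breaks, include.lowest = TRUE, right = FALSE)
  counts <- as.integer(table(bin))
  mids <- head(breaks, -1) + bin_width / 2

  n <- length(counts)
  is_max <- vapply(seq_len(n), function(i) {
    left <- if (i > 1) counts[i - 1] else -Inf
    right <- if (i < n) counts[i + 1] else -Inf
    counts[i] > 0 && counts[i] >= left && counts[i] >= right &&
      (counts[i] > left || counts[i] > right)
  }, TRUE)
  peaks <- order(-counts * is_max)[1:2]
  peaks <- peaks[is_max[peaks] & counts[peaks] > 0]
  modes <- sort(mids[peaks])
  antimode <- NA_real_
  bimodal <- length(modes) == 2
  if (bimodal) {
    between <- which(mids > modes[1] & mids < modes[2])
    if (length(between) > 0) {
      antimode <- mids[between[which.min(counts[between])]]
    } else {
      bimodal <- FALSE
    }
  }
  structure(list(
    bins = tibble::tibble(mid = mids, count = counts),
    summary = list(modes = modes, antimode = antimode, bimodal = bimodal,
                   n = length(r))
  ), class = "ratio_histogram")
}

#' @export
print.ratio_histogram <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<ratio_histogram: %d ratios, %s>\n", s$n,
              if (s$bimodal) sprintf("modes at %.2f and %.2f, antimode %.2f",
                                     s$modes[1], s$modes[2], s$antimode)
              else "unimodal"))
  invisible(x)
}

#' Per-cluster Mendelian randomisation on apoB
#'
#' Univariable MR of the ASCVD outcome on apoB within each effect-ratio
#' cluster, in apoB-raising orientation, by both the IVW and the
#' contamination-mixture methods, with odds ratios per population SD of
#' apoB.  When both clusters are present, the cluster-2 vs cluster-1
#' log-OR difference (IVW) is tested with a z-test.
#'
#' @param oriented Output of [orient_effects()] in `apob_raising` mode,
#'   carrying `beta_apob` / `se_apob`.
#' @param outcome_assoc Association tibble of the (combined
#'   prevalent+incident) binary outcome, minor-allele orientation; effects
#'   are re-oriented consistently with `oriented$flipped`.
#' @param clusters Tibble from [cluster_assignments()].
#' @param sd_apob Population SD of apoB in g/L (default 0.23), or a value
#'   estimated from the cohort.
#' @param min_snps Minimum variants per cluster (default 3).
#' @return Object of class `cluster_mr`: `estimates` tibble (cluster,
#'   method, n_snps, or_sd and CI), fits, and `comparison` (z, p for the
#'   IVW log-OR difference; NA when a single cluster).
#' @export
cluster_mr <- function(oriented, outcome_assoc, clusters, sd_apob = 0.23,
                       min_snps = 3) {
  assert_that(identical(unique(oriented$orientation), "apob_raising"),
              "`oriented` must be in apob_raising orientation")
  dat <- oriented |>
    dplyr::inner_join(clusters, by = "variant_id") |>
    dplyr::inner_join(
      dplyr::select(outcome_assoc, "variant_id",
                    b_out = "beta", se_out = "se"),
      by = "variant_id") |>
    dplyr::mutate(b_out = .data$b_out * ifelse(.data$flipped, -1, 1)) |>
    dplyr::filter(.data$cluster %in% c("1", "2"))

  fit_one <- function(d) {
    inp <- mr_input(d$beta_apob, d$se_apob, d$b_out, d$se_out,
                    snps = d$variant_id, exposures = "apob")
    list(ivw = ivw_fit(inp),
         conmix = conmix_fit(d$beta_apob, d$se_apob, d$b_out, d$se_out,
                             exposure = "apob"))
  }
  present <- as.character(unique(dat$cluster))
  present <- present[vapply(present,
                            function(cl) sum(dat$cluster == cl) >= min_snps,
                            TRUE)]
  assert_that(length(present) > 0,
              sprintf("no cluster with at least %d variants", min_snps))
  fits <- lapply(setNames(present, present),
                 function(cl) fit_one(dat[dat$cluster == cl, ]))

  estimates <- purrr::map_dfr(present, function(cl) {
    purrr::map_dfr(fits[[cl]], function(f) {
      e <- f$estimates
      tibble::tibble(cluster = cl, method = f$method, n_snps = f$n_snps,
                     theta = e$theta, se = e$se,
                     or_sd = or_per_sd(e$or_per_unit, sd_apob),
                     or_sd_low = or_per_sd(e$ci_low, sd_apob),
                     or_sd_high = or_per_sd(e$ci_high, sd_apob),
                     p = e$p)
    })
  })

  comparison <- tibble::tibble(z = NA_real_, p = NA_real_,
                               note = "single cluster: not applicable")
  if (all(c("1", "2") %in% present)) {
    e1 <- fits[["1"]]$ivw$estimates
    e2 <- fits[["2"]]$ivw$estimates
    z <- (e2$theta - e1$theta) / sqrt(e1$se^2 + e2$se^2)
    comparison <- tibble::tibble(z = z, p = 2 * pnorm(-abs(z)),
                                 note = "cluster 2 minus cluster 1 (IVW)")
  }
  structure(list(estimates = estimates, fits = fits,
                 comparison = comparison, sd_apob = sd_apob),
            class = "cluster_mr")
}

#' @export
print.cluster_mr <- function(x, ...) {
  cat("<cluster_mr>\n")
  print(as.data.frame(x$estimates), digits = 4)
  if (is.finite(x$comparison$z)) {
    cat(sprintf("cluster 2 vs 1: z = %.2f, p = %.3g\n",
                x$comparison$z, x$comparison$p))
  }
  invisible(x)
}

#' @rdname cluster_mr
#' @param x A `cluster_mr` object.
#' @param ... Unused.
#' @method tidy cluster_mr
#' @export
tidy.cluster_mr <- function(x, ...) x$estimates
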