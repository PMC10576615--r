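#' Configuration for an end-to-end pipeline run
#'
#' Aggregates the cohort generator parameters, the variant-selection
#' thresholds, the cluster intervals and the SD-table mode into a single
#' validated object that round-trips through YAML unchanged.
#'
#' @param params A [cohort_params()] object (or a list of arguments for
#'   one).
#' @param mix Mechanism mix passed to [simulate_panel()].
#' @param tier Selection tier (1, 2 or 3).
#' @param r2_threshold,maf_threshold,holm_alpha Selection thresholds.
#' @param het_threshold Heterozygote threshold (`NULL` = rescaled rule).
#' @param cluster1,cluster2 Effect-ratio intervals.
#' @param sd_mode `"fixed_paper_values"` or `"estimated_from_cohort"`.
#' @param seed Run seed (overrides the one in `params`).
#' @return List of class `run_config`.
#' @export
run_config <- function(params = cohort_params(),
                       mix = c(receptor = 0.35, lipolysis = 0.35,
                               lpa = 0.05, null = 0.25),
                       tier = 3,
                       r2_threshold = 0.3, maf_threshold = 0.01,
                       het_threshold = NULL, holm_alpha = 0.05,
                       cluster1 = c(0.9, 3.0), cluster2 = c(-0.75, 0.75),
                       sd_mode = c("fixed_paper_values",
                                   "estimated_from_cohort"),
                       seed = NULL) {
  sd_mode <- match.arg(sd_mode)
  if (is.list(params) && !inherits(params, "cohort_params")) {
    params <- do.call(cohort_params, params)
  }
  if (!is.null(seed)) params$seed <- as.integer(seed)
  assert_that(tier %in% 1:3, "`tier` must be 1, 2 or 3")
  assert_that(r2_threshold > 0 && r2_threshold <= 1,
              "`r2_threshold` must be in (0, 1]")
  assert_that(maf_threshold >= 0 && maf_threshold < 0.5,
              "`maf_threshold` must be in [0, 0.5)")
  assert_that(holm_alpha > 0 && holm_alpha < 1,
              "`holm_alpha` must be in (0, 1)")
  structure(list(params = params, mix = mix, tier = tier,
                 r2_threshold = r2_threshold,
                 maf_threshold = maf_threshold,
                 het_threshold = het_threshold, holm_alpha = holm_alpha,
                 cluster1 = cluster1, cluster2 = cluster2,
                 sd_mode = sd_mode),
            class = "run_config")
}

#' Serialise / restore a run configuration
#'
#' @param config A [run_config()].
#' @param path YAML file path.
#' @return `write_run_config` returns `path` invisibly; `read_run_config`
#'   returns the restored `run_config`.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x$params <- unclass(x$params)
  # named vectors must become maps, or YAML drops their names
  x$params$sd_targets <- as.list(x$params$sd_targets)
  x$params$assay_sd <- as.list(x$params$assay_sd)
  x$mix <- as.list(x$mix)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  prm <- x$params
  prm$sd_targets <- unlist(prm$sd_targets)
  prm$assay_sd <- unlist(prm$assay_sd)
  prm <- lapply(prm, function(v) if (is.list(v)) unlist(v) else v)
  cfg <- run_config(
    params = do.call(cohort_params, prm),
    mix = unlist(x$mix), tier = x$tier,
    r2_threshold = x$r2_threshold, maf_threshold = x$maf_threshold,
    het_threshold = x$het_threshold, holm_alpha = x$holm_alpha,
    cluster1 = unlist(x$cluster1), cluster2 = unlist(x$cluster2),
    sd_mode = x$sd_mode)
  cfg
}

.write_tsv <- function(x, dir, name) {
  path <- file.path(dir, name)
  readr::write_tsv(tibble::as_tibble(x), path, progress = FALSE)
  path
}

#' Run the full pipeline on a simulated cohort
#'
#' Executes simulate -> derive -> scan -> select -> MR -> cluster -> score
#' -> observational models, writing every stage artifact as a tab-separated
#' file plus a manifest of MD5 hashes; identical configuration and seed
#' reproduce byte-identical files.  Stage failures halt with the stage name.
#'
#' Artifacts: `panel.tsv`, `subjects.tsv`, `genotypes.tsv`,
#' `assoc_<trait>.tsv`, `selected_tier<k>.txt`, `mr_results.tsv`,
#' `clusters.tsv`, `ratio_histogram.tsv`, `cluster_mr.tsv`,
#' `score_deciles.tsv`, `hazards.tsv`, `observational_cox.tsv`,
#' `spline_curve.tsv`, `config.yaml`, `manifest.tsv`.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest tibble.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "simulate"
  result <- tryCatch({
    cohort <- simulate_cohort(config$params, config$mix)

    stage <- "derive"
    subjects <- derive_lipids(cohort$subjects)

    stage <- "assoc"
    traits <- c("ldl_c_direct", "trl_remnant_c", "tg", "apob", "lpa")
    assoc <- assoc_scan_traits(subjects, cohort$genotypes, traits)
    outcome01 <- as.integer(subjects$prevalent_ascvd |
                              subjects$incident_event)
    subjects$ascvd <- outcome01
    assoc_out <- assoc_scan(subjects, cohort$genotypes, "ascvd")

    stage <- "select"
    sel <- select_variants(assoc, cohort$genotypes, tier = config$tier,
                           r2_threshold = config$r2_threshold,
                           maf_threshold = config$maf_threshold,
                           het_threshold = config$het_threshold,
                           alpha = config$holm_alpha)

    stage <- "mr"
    sd_tbl <- if (config$sd_mode == "fixed_paper_values") {
      sd_table("fixed_paper_values")
    } else {
      sd_table("estimated_from_cohort", subjects)
    }
    sel_assoc <- dplyr::filter(assoc, .data$variant_id %in% sel$variant_id)
    wide <- sel_assoc |>
      dplyr::select("variant_id", "trait", "beta", "se") |>
      tidyr::pivot_wider(names_from = "trait",
                         values_from = c("beta", "se"))
    out_sel <- assoc_out[match(wide$variant_id, assoc_out$variant_id), ]
    inp <- mr_input(
      cbind(trl_remnant_c = wide$beta_trl_remnant_c,
            ldl_c = wide$beta_ldl_c_direct),
      cbind(wide$se_trl_remnant_c, wide$se_ldl_c_direct),
      out_sel$beta, out_sel$se, snps = wide$variant_id)
    mr_main <- ivw_fit(inp)
    mr_egger <- egger_fit(inp)
    mr_tbl <- report_estimates(list(mr_main, mr_egger), sd_tbl)

    stage <- "cluster"
    oriented_mm <- orient_effects(sel_assoc, "minor_vs_major")
    clusters <- cluster_assignments(oriented_mm,
                                    cluster1 = config$cluster1,
                                    cluster2 = config$cluster2)
    hist <- ratio_histogram(clusters$ratio)
    oriented_ar <- orient_effects(sel_assoc, "apob_raising")
    sd_apob <- sd_tbl$sd[sd_tbl$trait == "apob"]
    cl_mr <- cluster_mr(oriented_ar, assoc_out, clusters,
                        sd_apob = sd_apob)

    stage <- "score"
    score_res <- list()
    for (cl in c("1", "2")) {
      ids <- clusters$variant_id[clusters$cluster == cl]
      if (length(ids) < 3) next
      sc <- build_gene_score(cohort$genotypes, oriented_ar, ids)
      ds <- decile_summary(subjects, sc$score)
      hz <- decile_hazards(subjects, sc$score)
      hr10 <- hr_per_10mg_dl(hz, ds)
      score_res[[cl]] <- list(score = sc, deciles = ds, hazards = hz,
                              hr10 = hr10)
    }
    inter <- NULL
    if (all(c("1", "2") %in% names(score_res))) {
      inter <- interaction_test(
        score_res[["1"]]$hazards, score_res[["1"]]$deciles,
        score_res[["2"]]$hazards, score_res[["2"]]$deciles,
        subjects, score_res[["1"]]$score$score,
        score_res[["2"]]$score$score)
    }

    stage <- "observe"
    obs <- observational_cox(subjects)
    spl <- ratio_spline(subjects, include_hdl = FALSE)
    spl_hdl <- ratio_spline(subjects, include_hdl = TRUE)

    stage <- "write"
    files <- character(0)
    files <- c(files, .write_tsv(cohort$panel, out_dir, "panel.tsv"))
    files <- c(files, .write_tsv(subjects, out_dir, "subjects.tsv"))
    gt <- tibble::as_tibble(as.data.frame(cohort$genotypes))
    files <- c(files, .write_tsv(gt, out_dir, "genotypes.tsv"))
    for (tr in unique(assoc$trait)) {
      files <- c(files, .write_tsv(
        dplyr::filter(assoc, .data$trait == tr), out_dir,
        paste0("assoc_", tr, ".tsv")))
    }
    files <- c(files, .write_tsv(assoc_out, out_dir, "assoc_ascvd.tsv"))
    sel_path <- file.path(out_dir,
                          sprintf("selected_tier%d.txt", config$tier))
    writeLines(sel$variant_id, sel_path)
    files <- c(files, sel_path)
    files <- c(files, .write_tsv(mr_tbl, out_dir, "mr_results.tsv"))
    files <- c(files, .write_tsv(clusters, out_dir, "clusters.tsv"))
    files <- c(files, .write_tsv(hist$bins, out_dir, "ratio_histogram.tsv"))
    files <- c(files, .write_tsv(cl_mr$estimates, out_dir, "cluster_mr.tsv"))
    if (length(score_res) > 0) {
      dec_tbl <- purrr::imap_dfr(score_res, function(r, cl) {
        dplyr::mutate(r$deciles, cluster = cl, .before = 1)
      })
      hz_tbl <- purrr::imap_dfr(score_res, function(r, cl) {
        dplyr::mutate(r$hazards$table, cluster = cl, .before = 1)
      })
      hr_tbl <- purrr::imap_dfr(score_res, function(r, cl) {
        dplyr::mutate(r$hr10, cluster = cl, .before = 1)
      })
      files <- c(files, .write_tsv(dec_tbl, out_dir, "score_deciles.tsv"))
      files <- c(files, .write_tsv(hz_tbl, out_dir, "hazards.tsv"))
      files <- c(files, .write_tsv(hr_tbl, out_dir, "hr_per_10mg_dl.tsv"))
    }
    files <- c(files, .write_tsv(obs, out_dir, "observational_cox.tsv"))
    spl_tbl <- dplyr::bind_rows(
      dplyr::mutate(spl$curve, include_hdl = FALSE,
                    p_spline = spl$p_spline),
      dplyr::mutate(spl_hdl$curve, include_hdl = TRUE,
                    p_spline = spl_hdl$p_spline))
    files <- c(files, .write_tsv(spl_tbl, out_dir, "spline_curve.tsv"))
    cfg_path <- file.path(out_dir, "config.yaml")
    write_run_config(config, cfg_path)
    files <- c(files, cfg_path)

    manifest <- tibble::tibble(
      file = basename(files),
      md5 = unname(tools::md5sum(files)))
    .write_tsv(manifest, out_dir, "manifest.tsv")

    list(cohort = cohort, subjects = subjects, assoc = assoc,
         assoc_out = assoc_out, selection = sel, mr = mr_tbl,
         clusters = clusters, histogram = hist, cluster_mr = cl_mr,
         scores = score_res, interaction = inter, observational = obs,
         splines = list(without_hdl = spl, with_hdl = spl_hdl),
         manifest = manifest, out_dir = out_dir)
  }, error = function(e) {
    stop(sprintf("pipeline stage `%s` failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(result)
}

#' Summarise a pipeline run directory
#'
#' Reads the stage artifacts back and assembles a human-readable report:
#' per-unit and per-SD causal odds ratios, cluster counts and per-cluster
#' estimates, per-10mg/dL hazard ratios, and the worked per-SD rescaling
#' check (per-SD column recomputed from the per-unit column via
#' [or_per_sd()]).  Missing artifacts leave gaps flagged rather than
#' failing.
#'
#' @param run_dir Directory written by [run_pipeline()].
#' @return List of class `pipeline_report` with tibbles `mr`, `clusters`,
#'   `cluster_mr`, `hr10`, `gaps`.
#' @export
pipeline_report <- function(run_dir) {
  rd <- function(name) {
    p <- file.path(run_dir, name)
    if (!file.exists(p)) return(NULL)
    readr::read_tsv(p, show_col_types = FALSE, progress = FALSE)
  }
  gaps <- character(0)
  mr <- rd("mr_results.tsv")
  if (is.null(mr)) gaps <- c(gaps, "mr_results.tsv")
  clusters <- rd("clusters.tsv")
  if (is.null(clusters)) gaps <- c(gaps, "clusters.tsv")
  clmr <- rd("cluster_mr.tsv")
  if (is.null(clmr)) gaps <- c(gaps, "cluster_mr.tsv")
  hr10 <- rd("hr_per_10mg_dl.tsv")
  if (is.null(hr10)) gaps <- c(gaps, "hr_per_10mg_dl.tsv")

  cluster_counts <- NULL
  if (!is.null(clusters)) {
    cluster_counts <- dplyr::count(clusters, .data$cluster)
  }
  structure(list(mr = mr, clusters = cluster_counts, cluster_mr = clmr,
                 hr10 = hr10, gaps = gaps, run_dir = run_dir),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("== pipeline report:", x$run_dir, "==\n")
  if (!is.null(x$mr)) {
    cat("\nMendelian randomisation (per-unit and per-SD ORs):\n")
    print(as.data.frame(x$mr), digits = 3)
  }
  if (!is.null(x$clusters)) {
    cat("\nCluster counts:\n")
    print(as.data.frame(x$clusters))
  }
  if (!is.null(x$cluster_mr)) {
    cat("\nPer-cluster MR (OR per SD apoB):\n")
    print(as.data.frame(x$cluster_mr), digits = 3)
  }
  if (!is.null(x$hr10)) {
    cat("\nHazard ratios per 10 mg/dL apoB:\n")
    print(as.data.frame(x$hr10), digits = 3)
  }
  if (length(x$gaps) > 0) {
    cat("\nMissing artifacts:", paste(x$gaps, collapse = ", "), "\n")
  }
  invisible(x)
}
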