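#' Non-HDL cholesterol
#'
#' Total cholesterol minus HDL cholesterol, both in mmol/L.  Pure
#' arithmetic; negative results (possible under assay noise) are returned
#' as-is so callers can flag rather than silently clamp — [derive_lipids()]
#' does exactly that.
#'
#' @param tc,hdl_c Numeric vectors, mmol/L, non-negative.
#' @return `tc - hdl_c` (mmol/L).
#' @export
#' @examples
#' non_hdl_c(5.0, 1.4)
non_hdl_c <- function(tc, hdl_c) {
  assert_that(all(tc >= 0, na.rm = TRUE) && all(hdl_c >= 0, na.rm = TRUE),
              "cholesterol inputs must be non-negative")
  tc - hdl_c
}

#' TRL/remnant cholesterol
#'
#' Cholesterol carried in triglyceride-rich-lipoprotein remnants,
#' operationalised as non-HDL-C minus directly measured LDL-C (mmol/L).
#' Negative values arise from accumulated assay error and are returned
#' unclamped; [derive_lipids()] flags and excludes them.
#'
#' @param non_hdl_c,ldl_c_direct Numeric vectors, mmol/L, non-negative.
#' @return `non_hdl_c - ldl_c_direct` (mmol/L).
#' @export
#' @examples
#' trl_remnant_c(3.6, 3.0)
trl_remnant_c <- function(non_hdl_c, ldl_c_direct) {
  assert_that(all(non_hdl_c >= 0, na.rm = TRUE) &&
                all(ldl_c_direct >= 0, na.rm = TRUE),
              "cholesterol inputs must be non-negative")
  non_hdl_c - ldl_c_direct
}

#' Sampson-equation VLDL cholesterol
#'
#' Two-variable estimate of VLDL cholesterol from TG and non-HDL-C.
#' Constants table (transcribed from the published equation, which works in
#' mg/dL):
#'
#' | constant | value | role |
#' |---|---|---|
#' | `1/8.56` | TG term | mg/dL VLDL-C per mg/dL TG |
#' | `1/2140` | interaction | per (mg/dL TG x mg/dL non-HDL-C) |
#' | `-1/16100` | TG^2 term | curvature at high TG |
#' | `38.67` | mg/dL per mmol/L | cholesterol unit conversion |
#' | `88.57` | mg/dL per mmol/L | triglyceride unit conversion |
#'
#' Inputs and output here are mmol/L; the conversion happens internally.
#' The published equation was derived for TG up to 800 mg/dL (9.04 mmol/L);
#' above that the function warns and computes anyway.  Output is floored at
#' zero.
#'
#' @param tg Triglyceride, mmol/L.
#' @param non_hdl_c Non-HDL cholesterol, mmol/L.
#' @return Estimated VLDL-C, mmol/L.
#' @export
#' @examples
#' vldl_c_sampson(1.5, 3.6)
vldl_c_sampson <- function(tg, non_hdl_c) {
  assert_that(all(tg >= 0, na.rm = TRUE) && all(non_hdl_c >= 0, na.rm = TRUE),
              "inputs must be non-negative")
  if (any(tg > 9.04, na.rm = TRUE)) {
    warning("TG above the equation's 9.04 mmol/L (800 mg/dL) validity range",
            call. = FALSE)
  }
  tg_mg <- tg * 88.57
  nh_mg <- non_hdl_c * 38.67
  vldl_mg <- tg_mg / 8.56 + tg_mg * nh_mg / 2140 - tg_mg^2 / 16100
  pmax(vldl_mg / 38.67, 0)
}

#' Rescale an odds ratio from per-unit to per-SD
#'
#' Converts an odds ratio expressed per 1.0 unit of an exposure into an odds
#' ratio per population SD of that exposure: `OR_sd = exp(sd * log(OR_unit))
#' = OR_unit^sd`.  The inverse rescaling is `or_per_sd(x, 1/sd)`.  No
#' rounding is applied; presentation rounding (2 dp in the reported tables)
#' is the caller's concern.
#'
#' @param or_per_unit Positive odds ratio per 1.0 exposure unit.
#' @param sd Positive population SD in the same unit.
#' @return Odds ratio per SD.
#' @export
#' @examples
#' round(or_per_sd(1.82, 0.30), 2) # 1.20
or_per_sd <- function(or_per_unit, sd) {
  assert_that(all(or_per_unit > 0, na.rm = TRUE),
              "`or_per_unit` must be positive")
  assert_that(all(sd > 0, na.rm = TRUE), "`sd` must be positive")
  exp(sd * log(or_per_unit))
}

#' Convert apoB between g/L and mg/dL
#'
#' 1 g/L = 100 mg/dL exactly.
#'
#' @param value Numeric apoB values.
#' @param from Unit of `value`: `"g/L"` or `"mg/dL"`.
#' @return `value` in the other unit.
#' @export
#' @examples
#' convert_apob_units(1.066, from = "g/L") # 106.6 mg/dL
convert_apob_units <- function(value, from = c("g/L", "mg/dL")) {
  from <- match.arg(from)
  assert_that(all(is.finite(value) | is.na(value)), "`value` must be finite")
  if (from == "g/L") value * 100 else value / 100
}

#' Population SD table for exposure rescaling
#'
#' Either the fixed reference values used for reproducing published-scale
#' per-SD odds ratios (TRL/remnant-C 0.30 mmol/L, LDL-C 0.82 mmol/L, TG
#' 1.0 mmol/L, apoB 0.23 g/L, VLDL-C 0.43 mmol/L) or SDs recomputed from an
#' analysis cohort.
#'
#' @param mode `"fixed_paper_values"` or `"estimated_from_cohort"`.
#' @param subjects Subject tibble with derived lipid columns (required for
#'   cohort mode; see [derive_lipids()]).
#' @return A tibble with columns `trait`, `sd`, `mode`.
#' @export
sd_table <- function(mode = c("fixed_paper_values", "estimated_from_cohort"),
                     subjects = NULL) {
  mode <- match.arg(mode)
  if (mode == "fixed_paper_values") {
    out <- tibble::tibble(
      trait = c("trl_remnant_c", "ldl_c", "tg", "apob", "vldl_c"),
      sd = c(0.30, 0.82, 1.0, 0.23, 0.43)
    )
  } else {
    assert_that(!is.null(subjects), "cohort mode needs `subjects`")
    cols <- c(trl_remnant_c = "trl_remnant_c", ldl_c = "ldl_c_direct",
              tg = "tg", apob = "apob", vldl_c = "vldl_c")
    present <- cols[cols %in% names(subjects)]
    out <- tibble::tibble(
      trait = names(present),
      sd = unname(vapply(present,
                         function(cl) sd(subjects[[cl]], na.rm = TRUE), 0))
    )
  }
  assert_that(all(out$sd > 0), "all SDs must be positive")
  out$mode <- mode
  out
}

#' Append derived lipid columns to a subject table
#'
#' Computes non-HDL-C, TRL/remnant-C and Sampson VLDL-C and appends them,
#' flagging (rather than clamping) records whose derived concentrations come
#' out negative under assay noise: flagged values are set `NA` so that
#' downstream analyses using that trait exclude the record, and the flag
#' columns `flag_non_hdl_c` / `flag_trl_remnant_c` record why.
#'
#' @param subjects Tibble with `tc`, `hdl_c`, `ldl_c_direct`, `tg` columns
#'   (mmol/L).
#' @return `subjects` with `non_hdl_c`, `trl_remnant_c`, `vldl_c`,
#'   `flag_non_hdl_c`, `flag_trl_remnant_c` appended.  The number of flagged
#'   records is reported via message.
#' @export
#' @examples
#' derive_lipids(tibble::tibble(tc = 5, hdl_c = 1.4, ldl_c_direct = 3,
#'                              tg = 1.2))
derive_lipids <- function(subjects) {
  need <- c("tc", "hdl_c", "ldl_c_direct", "tg")
  assert_that(all(need %in% names(subjects)),
              "`subjects` must have tc, hdl_c, ldl_c_direct and tg columns")
  nh <- non_hdl_c(subjects$tc, subjects$hdl_c)
  flag_nh <- !is.na(nh) & nh < 0
  nh[flag_nh] <- NA_real_
  trl <- trl_remnant_c(ifelse(is.na(nh), 0, nh), subjects$ldl_c_direct)
  trl[is.na(nh)] <- NA_real_
  flag_trl <- !is.na(trl) & trl < 0
  trl[flag_trl] <- NA_real_
  vldl <- vldl_c_sampson(subjects$tg, ifelse(is.na(nh), 0, nh))
  vldl[is.na(nh)] <- NA_real_
  n_flag <- sum(flag_nh) + sum(flag_trl)
  if (n_flag > 0) {
    message(sprintf("derive_lipids: flagged %d record(s) with negative %s",
                    n_flag, "derived cholesterol (excluded downstream)"))
  }
  dplyr::mutate(subjects,
                non_hdl_c = nh,
                trl_remnant_c = trl,
                vldl_c = vldl,
                flag_non_hdl_c = flag_nh,
                flag_trl_remnant_c = flag_trl)
}
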