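# Shared fixtures and independent oracles for the test suite.
# Large fixtures are built once per test run and cached in this environment.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

quiet <- function(expr) suppressWarnings(suppressMessages(expr))

# a mid-sized cohort shared by several module tests
small_cohort <- function() {
  cached("small_cohort", function() {
    co <- simulate_cohort(cohort_params(n_subjects = 4000, n_variants = 40,
                                        seed = 421))
    co$subjects <- quiet(derive_lipids(co$subjects))
    co
  })
}

# the reference-scale cohort (n = 50,000) used for the statistical-embedding
# and classification-recovery properties, with scans and selection attached
big_fixture <- function() {
  cached("big_fixture", function() {
    params <- cohort_params(n_subjects = 50000, n_variants = 150, seed = 2024)
    co <- simulate_cohort(params)
    subjects <- quiet(derive_lipids(co$subjects))
    subjects$ascvd <- as.integer(subjects$prevalent_ascvd |
                                   subjects$incident_event)
    assoc <- quiet(assoc_scan_traits(
      subjects, co$genotypes,
      c("ldl_c_direct", "trl_remnant_c", "tg", "apob", "lpa")))
    assoc_out <- quiet(assoc_scan(subjects, co$genotypes, "ascvd"))
    selection <- quiet(select_variants(assoc, co$genotypes, tier = 3))
    sel_assoc <- dplyr::filter(assoc,
                               variant_id %in% selection$variant_id)
    oriented_mm <- orient_effects(sel_assoc, "minor_vs_major")
    oriented_ar <- quiet(orient_effects(sel_assoc, "apob_raising"))
    clusters <- cluster_assignments(oriented_mm)
    list(params = params, panel = co$panel, genotypes = co$genotypes,
         subjects = subjects, assoc = assoc, assoc_out = assoc_out,
         selection = selection, sel_assoc = sel_assoc,
         oriented_mm = oriented_mm, oriented_ar = oriented_ar,
         clusters = clusters)
  })
}

# --- independent oracles ---------------------------------------------------

# weighted-normal-equations oracle for IVW (explicit matrix algebra,
# independent of the package's WLS path)
oracle_ivw <- function(B, b_out, se_out) {
  W <- diag(1 / se_out^2)
  XtWX <- t(B) %*% W %*% B
  theta <- solve(XtWX, t(B) %*% W %*% b_out)
  resid <- b_out - B %*% theta
  disp <- sum((resid / se_out)^2) / (length(b_out) - ncol(B))
  se <- sqrt(diag(solve(XtWX))) * max(1, sqrt(disp))
  list(theta = drop(theta), se = se)
}

# brute-force Breslow partial-likelihood maximiser for Cox regression
oracle_cox <- function(time, status, X) {
  X <- as.matrix(X)
  negll <- function(beta) {
    eta <- drop(X %*% beta)
    ord <- order(time)
    eta <- eta[ord]; st <- status[ord]
    # Breslow: risk set = subjects with time >= t_i
    rev_cumsum <- rev(cumsum(rev(exp(eta))))
    -sum(st * (eta - log(rev_cumsum)))
  }
  optim(rep(0, ncol(X)), negll, method = "BFGS",
        control = list(reltol = 1e-12))$par
}

# Holm step-down adjustment computed by hand
oracle_holm <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- pmin(cummax((n - seq_len(n) + 1) * p[o]), 1)
  out <- numeric(n)
  out[o] <- adj
  out
}
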