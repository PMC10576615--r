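test_that("association scan is exact OLS and calibrated under the null", {
  set.seed(301)
  n <- 1000
  G <- matrix(rbinom(n * 500, 2, 0.3), n, 500,
              dimnames = list(NULL, sprintf("v%03d", 1:500)))
  subj <- tibble::tibble(
    y = rnorm(n), age = rnorm(n, 56, 8),
    sex = factor(sample(c("female", "male"), n, TRUE)),
    pc1 = rnorm(n), pc2 = rnorm(n), pc3 = rnorm(n), pc4 = rnorm(n),
    pc5 = rnorm(n))
  res <- assoc_scan(subj, G, "y")
  # null p-values uniform (Kolmogorov-Smirnov)
  expect_gt(stats::ks.test(res$p, "punif")$p.value, 0.01)

  # agreement with lm() on a handful of variants
  for (j in c(1, 100, 499)) {
    fit <- lm(y ~ G[, j] + age + sex + pc1 + pc2 + pc3 + pc4 + pc5,
              data = subj)
    cf <- coef(summary(fit))[2, ]
    expect_equal(res$beta[j], unname(cf[1]), tolerance = 1e-10)
    expect_equal(res$se[j], unname(cf[2]), tolerance = 1e-10)
  }

  # single causal variant, noiseless trait: slope recovered exactly
  subj$y2 <- 0.25 * G[, 7]
  res2 <- assoc_scan(subj, G[, 1:20], "y2", covariates = character(0))
  expect_equal(res2$beta[7], 0.25, tolerance = 1e-12)

  # monomorphic column flagged with beta 0 and p 1
  G[, 3] <- 0L
  res3 <- assoc_scan(subj, G[, 1:5], "y", covariates = character(0))
  expect_true(res3$monomorphic[3])
  expect_equal(res3$beta[3], 0)
  expect_equal(res3$p[3], 1)
})

test_that("planted-slope coverage of the scan estimator", {
  set.seed(302)
  hits <- 0
  reps <- 60
  n <- 5000
  b_true <- 0.1 * 0.82
  for (r in seq_len(reps)) {
    g <- rbinom(n, 2, 0.3)
    y <- b_true * g + rnorm(n, 0, 0.82)
    subj <- tibble::tibble(y = y)
    res <- assoc_scan(subj, matrix(g, ncol = 1,
                                   dimnames = list(NULL, "v1")),
                      "y", covariates = character(0))
    hits <- hits + (abs(res$beta - b_true) <= 2 * res$se)
  }
  expect_gte(hits / reps, 0.9)
})

test_that("binary score scan matches exact per-variant logistic regression", {
  set.seed(303)
  n <- 3000
  G <- matrix(rbinom(n * 10, 2, 0.3), n, 10,
              dimnames = list(NULL, sprintf("v%02d", 1:10)))
  lp <- -2.2 + 0.4 * G[, 4] + 0.02 * rnorm(n)
  subj <- tibble::tibble(y = rbinom(n, 1, plogis(lp)), age = rnorm(n, 56, 8),
                         sex = factor(sample(c("female", "male"), n, TRUE)))
  covs <- c("age", "sex")
  sc <- assoc_scan(subj, G, "y", covariates = covs, method = "score")
  ex <- assoc_scan(subj, G, "y", covariates = covs, method = "glm")
  expect_equal(sc$beta, ex$beta, tolerance = 0.05)
  expect_equal(sc$se, ex$se, tolerance = 0.05)
  # the planted effect is detected by both
  expect_lt(sc$p[4], 0.01)
  expect_lt(ex$p[4], 0.01)
})

test_that("tier thresholds bracket and nest correctly", {
  assoc <- tibble::tibble(
    variant_id = rep(c("a", "b", "c"), 2),
    trait = rep(c("ldl_c_direct", "trl_remnant_c"), each = 3),
    p = c(1e-22, 1e-13, 1e-9, 0.5, 0.5, 1e-9),
    beta = 0.1, se = 0.01, n = 1000, n_het = 500, eaf = 0.3, maf = 0.3,
    monomorphic = FALSE)
  t1 <- tier_filter(assoc, 1)$variant_id
  t2 <- tier_filter(assoc, 2)$variant_id
  t3 <- tier_filter(assoc, 3)$variant_id
  expect_setequal(t1, "a")                     # only p < 1e-21
  expect_setequal(t2, c("a", "b"))             # p < 1e-12
  expect_setequal(t3, c("a", "b", "c"))        # union "and/or" at 5e-8
  expect_true(all(t1 %in% t2) && all(t2 %in% t3))
})

test_that("combined effect size is the Euclidean magnitude", {
  expect_equal(combined_effect_size(0.3, 0.4), 0.5)
  expect_equal(combined_effect_size(0, 0), 0)
  expect_equal(combined_effect_size(-0.3, 0.4), 0.5)
  expect_error(combined_effect_size(NA, 1), "finite")
})

test_that("greedy LD pruning keeps the larger combined effect", {
  set.seed(304)
  n <- 2000
  # two perfectly correlated variants + one independent
  g1 <- rbinom(n, 2, 0.3)
  g3 <- rbinom(n, 2, 0.4)
  G <- cbind(a = g1, b = g1, c = g3)
  eff <- c(a = 0.5, b = 0.2, c = 0.1)
  expect_setequal(ld_prune(G, c("a", "b", "c"), eff), c("a", "c"))

  # three mutually independent variants all kept
  G2 <- cbind(a = rbinom(n, 2, 0.3), b = rbinom(n, 2, 0.3),
              c = rbinom(n, 2, 0.3))
  expect_setequal(ld_prune(G2, c("a", "b", "c"), eff), c("a", "b", "c"))

  # chain A-B r2 = 0.5, B-C r2 = 0.5, A-C = 0, effects A > C > B -> {A, C}
  # (hand-traced greedy: A accepted; C independent of A accepted; B
  # conflicts with both and is dropped)
  z <- matrix(rnorm(n * 3), n, 3)
  la <- z[, 1]
  lc <- z[, 3]
  lb <- sqrt(0.5) * (la + lc)
  G3 <- cbind(A = la, B = lb, C = lc)
  eff3 <- c(A = 0.9, B = 0.1, C = 0.5)
  expect_setequal(ld_prune(G3, c("A", "B", "C"), eff3, r2_threshold = 0.3),
                  c("A", "C"))

  # pairwise invariant: no retained pair with r^2 >= threshold
  fx <- big_fixture()
  kept <- fx$selection$variant_id
  cc <- cor(fx$genotypes[, kept])^2
  diag(cc) <- 0
  expect_lt(max(cc), 0.3)
})

test_that("MAF and heterozygote filters use the stated boundaries", {
  assoc <- tibble::tibble(
    variant_id = c("a", "b", "c", "d"),
    trait = "ldl_c_direct",
    beta = 0.1, se = 0.01, p = 1e-9,
    n = 354104, n_het = c(5000, 999, 1000, 5000),
    eaf = c(0.005, 0.3, 0.3, 0.3), maf = c(0.005, 0.3, 0.3, 0.3),
    monomorphic = FALSE)
  kept <- maf_het_filter(assoc, het_threshold = 1000)$variant_id
  expect_false("a" %in% kept)  # maf below 0.01
  expect_false("b" %in% kept)  # 999 heterozygotes, rule is "at least 1000"
  expect_true("c" %in% kept)   # boundary inclusive
  expect_true("d" %in% kept)

  # rescaled default threshold at reduced n
  assoc$n <- 35410
  kept2 <- maf_het_filter(assoc)$variant_id
  expect_true(all(c("b", "c", "d") %in% kept2))
})

test_that("Holm Lp(a) exclusion matches the hand-computed adjustment", {
  assoc_lpa <- tibble::tibble(
    variant_id = c("a", "b", "c"), trait = "lpa",
    beta = 1, se = 0.1, p = c(1e-10, 0.2, 0.9),
    n = 1000, n_het = 400, eaf = 0.3, maf = 0.3, monomorphic = FALSE)
  out <- lpa_exclusion_filter(assoc_lpa)
  expect_equal(out$p_holm, oracle_holm(assoc_lpa$p))
  expect_equal(out$p_holm, c(3e-10, 0.4, 0.9))
  expect_identical(out$excluded, c(TRUE, FALSE, FALSE))

  all_null <- dplyr::mutate(assoc_lpa, p = 1.0)
  expect_false(any(lpa_exclusion_filter(all_null)$excluded))
})

test_that("planted Lp(a) variants are excluded by the full selection", {
  fx <- big_fixture()
  lpa_ids <- fx$panel$variant_id[fx$panel$mechanism == "lpa"]
  in_tier3 <- lpa_ids[lpa_ids %in% tier_filter(fx$assoc, 3)$variant_id]
  expect_gte(length(in_tier3), 1)
  expect_false(any(in_tier3 %in% fx$selection$variant_id))
})

test_that("maf/het and tier filters commute", {
  fx <- big_fixture()
  assoc <- fx$assoc
  tier_first <- tier_filter(assoc, 3)$variant_id
  tier_first <- intersect(
    tier_first,
    maf_het_filter(dplyr::filter(assoc,
                                 trait == "ldl_c_direct"))$variant_id)
  maf_first <- maf_het_filter(dplyr::filter(assoc,
                                            trait == "ldl_c_direct"))
  maf_first <- intersect(
    tier_filter(dplyr::semi_join(assoc, maf_first, by = "variant_id"),
                3)$variant_id,
    maf_first$variant_id)
  expect_setequal(tier_first, maf_first)
})

test_that("null-mechanism variants essentially never reach tier 3", {
  fx <- big_fixture()
  null_ids <- fx$panel$variant_id[fx$panel$mechanism == "null"]
  t3 <- tier_filter(fx$assoc, 3)$variant_id
  expect_lte(sum(null_ids %in% t3), 1)
})
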