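test_that("the Nagelkerke rescaling matches direct formula evaluation", {
  # frozen oracle triple: (1 - e^-0.2) / (1 - e^-1)
  expect_equal(nagelkerke_r2(-100, -80, 200),
               (1 - exp(-0.2)) / (1 - exp(-1)), tolerance = 1e-12)
  expect_equal(nagelkerke_r2(-50, -50, 80), 0)
  # saturated model attains 1
  expect_equal(nagelkerke_r2(-60, 0, 100), 1, tolerance = 1e-12)
  set.seed(20)
  for (i in 1:25) {
    n <- sample(20:500, 1)
    ll0 <- -runif(1, 10, 200)
    ll1 <- ll0 + runif(1, 0, -ll0)
    direct <- (1 - exp(2 * (ll0 - ll1) / n)) / (1 - exp(2 * ll0 / n))
    expect_equal(nagelkerke_r2(ll0, ll1, n), direct, tolerance = 1e-12)
  }
  expect_error(nagelkerke_r2(-10, -11, 50), class = "chronoprs_nesting_error")
})

test_that("a constant score contributes an increment of exactly zero", {
  x <- small_cohort(seed = 30, n_cases = 80, n_controls = 80)
  const <- chronoprs:::new_grps(x$grps$individual_id,
                                rep(1.7, nrow(x$grps)), 0.05, 1L, FALSE)
  expect_identical(
    incremental_nkr2(x$cohort$phenotypes, const, x$cohort$covariates), 0)
})

test_that("the increment matches an independent Newton-Raphson refit", {
  for (s in 31:33) {
    x <- small_cohort(seed = s, n_cases = 100, n_controls = 100)
    inc <- incremental_nkr2(x$cohort$phenotypes, x$grps, x$cohort$covariates)
    des <- chronoprs:::build_cc_design(x$cohort$phenotypes, x$grps,
                                       x$cohort$covariates)
    oracle <- oracle_incremental_nkr2(des$y, des$x_null, des$x_full)
    expect_equal(inc, oracle, tolerance = 1e-8)
  }
})

test_that("the increment is invariant to affine rescaling of the score", {
  x <- small_cohort(seed = 34, n_cases = 90, n_controls = 90)
  g2 <- chronoprs:::new_grps(x$grps$individual_id,
                             5 - 3 * x$grps$score, 0.05, 1L, FALSE)
  expect_equal(incremental_nkr2(x$cohort$phenotypes, x$grps,
                                x$cohort$covariates),
               incremental_nkr2(x$cohort$phenotypes, g2,
                                x$cohort$covariates),
               tolerance = 1e-10)
})

test_that("chronicity filters enumerate the expected ids", {
  ph <- toy_pheno(n_inpatient = c(3, 12, 11, 40, 12))
  ids <- apply_chronicity_filter(ph, chronicity_filter("n_inpatient", 12))
  expect_setequal(ids, ph$individual_id[c(2, 4, 5)])
  expect_length(apply_chronicity_filter(ph, chronicity_filter("n_inpatient", 0)),
                5)
  expect_error(chronicity_filter("n_admissions", 5),
               class = "chronoprs_validation_error")
  expect_error(chronicity_filter("n_total", -1),
               class = "chronoprs_config_error")
  # controls are never selected
  ph$case_status[2] <- 0L
  expect_setequal(apply_chronicity_filter(ph,
                                          chronicity_filter("n_inpatient", 12)),
                  ph$individual_id[c(4, 5)])
  # the four conventional above-average thresholds
  filt <- default_chronicity_filters()
  expect_equal(vapply(filt, `[[`, "", "marker"), chronicity_markers())
  expect_equal(vapply(filt, `[[`, 0, "threshold"), c(27, 12, 19, 640))
})

test_that("a filter retaining every case gives p_perm = 1", {
  x <- small_cohort(seed = 35, n_cases = 40, n_controls = 40)
  r <- permutation_enrichment_test(x$cohort$phenotypes, x$grps,
                                   x$cohort$covariates,
                                   chronicity_filter("n_total", 0),
                                   n_perm = 25, seed = 2)
  expect_equal(r$n_selected_cases, 40)
  expect_true(all(abs(r$perm_values - r$observed_nkr2) < 1e-12))
  expect_equal(r$p_perm, 1)
})

test_that("Monte-Carlo p agrees with exhaustive subset enumeration", {
  x <- small_cohort(seed = 36, n_cases = 6, n_controls = 30)
  ph <- x$cohort$phenotypes
  # hospitalization length is continuous (no ties), so a threshold at the
  # third-largest value selects exactly 3 of the 6 cases
  thr <- sort(ph$hosp_length_days[ph$case_status == 1], decreasing = TRUE)[3]
  filt <- chronicity_filter("hosp_length_days", thr)
  expect_length(apply_chronicity_filter(ph, filt), 3)

  des <- chronoprs:::build_cc_design(ph, x$grps, x$cohort$covariates)
  ctrl <- which(des$y == 0)
  case_ids <- des$ids[des$y == 1]
  stat <- function(sub) {
    rows <- c(which(des$ids %in% sub & des$y == 1), ctrl)
    chronoprs:::inc_nkr2_core(des$y[rows], des$x_null[rows, , drop = FALSE],
                              des$x_full[rows, , drop = FALSE])
  }
  obs <- stat(apply_chronicity_filter(ph, filt))
  all_vals <- apply(combn(case_ids, 3), 2, stat)
  expect_length(all_vals, 20)
  p_exact <- mean(all_vals >= obs - 1e-12)

  n_perm <- 2000
  r <- permutation_enrichment_test(ph, x$grps, x$cohort$covariates, filt,
                                   n_perm = n_perm, seed = 3)
  expected <- (1 + n_perm * p_exact) / (n_perm + 1)
  se <- sqrt(p_exact * (1 - p_exact) / n_perm)
  expect_lt(abs(r$p_perm - expected), 3 * se + 1e-6)
})

test_that("permutation draws are seeded and bounded away from zero", {
  x <- small_cohort(seed = 37, n_cases = 60, n_controls = 60)
  filt <- chronicity_filter("n_inpatient", 12)
  r1 <- permutation_enrichment_test(x$cohort$phenotypes, x$grps,
                                    x$cohort$covariates, filt,
                                    n_perm = 40, seed = 7)
  r2 <- permutation_enrichment_test(x$cohort$phenotypes, x$grps,
                                    x$cohort$covariates, filt,
                                    n_perm = 40, seed = 7)
  r3 <- permutation_enrichment_test(x$cohort$phenotypes, x$grps,
                                    x$cohort$covariates, filt,
                                    n_perm = 40, seed = 8)
  expect_identical(r1$perm_values, r2$perm_values)
  expect_false(identical(r1$perm_values, r3$perm_values))
  expect_length(r1$perm_values, 40)
  expect_gte(r1$p_perm, 1 / 41)
  expect_lte(r1$p_perm, 1)
  expect_error(permutation_enrichment_test(x$cohort$phenotypes, x$grps,
                                           x$cohort$covariates, filt,
                                           n_perm = 0),
               class = "chronoprs_config_error")
  expect_error(permutation_enrichment_test(
    x$cohort$phenotypes, x$grps, x$cohort$covariates,
    chronicity_filter("n_total", 1e9), n_perm = 10),
    class = "chronoprs_empty_filter_error")
})

test_that("relabelling every sex negates the gap and keeps its p-value", {
  x <- small_cohort(seed = 38, n_cases = 120, n_controls = 120)
  r1 <- sex_prediction_gap_test(x$cohort$phenotypes, x$grps,
                                x$cohort$covariates, n_perm = 30, seed = 4)
  ph_sw <- x$cohort$phenotypes
  ph_sw$sex <- ifelse(ph_sw$sex == "F", "M", "F")
  r2 <- sex_prediction_gap_test(ph_sw, x$grps, x$cohort$covariates,
                                n_perm = 30, seed = 4)
  expect_equal(r1$observed_gap, -r2$observed_gap, tolerance = 1e-10)
  expect_equal(r1$nkr2_male, r2$nkr2_female, tolerance = 1e-10)
  expect_gte(r1$p_perm, 1 / 31)

  ph_m <- x$cohort$phenotypes
  ph_m$sex[ph_m$case_status == 1] <- "M"
  expect_error(sex_prediction_gap_test(ph_m, x$grps, x$cohort$covariates,
                                       n_perm = 10),
               class = "chronoprs_input_error")
})

test_that("sex-permuted gaps have the same two-sided p after relabelling", {
  x <- small_cohort(seed = 39, n_cases = 100, n_controls = 100)
  r1 <- sex_prediction_gap_test(x$cohort$phenotypes, x$grps,
                                x$cohort$covariates, n_perm = 60, seed = 5)
  ph_sw <- x$cohort$phenotypes
  ph_sw$sex <- ifelse(ph_sw$sex == "F", "M", "F")
  r2 <- sex_prediction_gap_test(ph_sw, x$grps, x$cohort$covariates,
                                n_perm = 60, seed = 5)
  # permuted labels are drawn identically, so each permuted gap flips sign
  expect_equal(r1$perm_values, -r2$perm_values, tolerance = 1e-10)
  expect_equal(r1$p_perm, r2$p_perm, tolerance = 1e-12)
})
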