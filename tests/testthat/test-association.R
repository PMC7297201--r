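test_that("the outcome transform matches a hand-computed 3-row oracle", {
  ph <- toy_pheno(n_inpatient = c(0, 9, 99), follow_up = c(1, 1, 1))
  out <- make_outcome(ph, "n_inpatient")
  manual <- log1p(c(0, 9, 99))          # 0, log 10, log 100
  manual <- (manual - mean(manual)) / sd(manual)
  expect_equal(out$value, manual, tolerance = 1e-12)
  expect_equal(mean(out$value), 0, tolerance = 1e-12)
  expect_equal(sd(out$value), 1, tolerance = 1e-12)
  expect_equal(attr(out, "marker"), "n_inpatient")

  # raw_z skips the rate/log step
  ph2 <- toy_pheno(n_total = c(1, 2, 3), follow_up = c(1, 2, 4))
  raw <- make_outcome(ph2, "n_total", transform = "raw_z")
  expect_equal(raw$value, scale(c(1, 2, 3))[, 1], tolerance = 1e-12)
})

test_that("degenerate and invalid outcomes raise typed errors", {
  ph <- toy_pheno(n_total = rep(10, 4), follow_up = rep(5, 4))
  expect_error(make_outcome(ph, "n_total"),
               class = "chronoprs_degenerate_outcome_error")
  ph2 <- toy_pheno(n_total = c(1, 5, 9), follow_up = c(1, 0, -2))
  err <- tryCatch(make_outcome(ph2, "n_total"), error = identity)
  expect_s3_class(err, "chronoprs_validation_error")
  expect_match(conditionMessage(err), "ind_00002")
  expect_error(make_outcome(ph, "n_admissions"), class = "chronoprs_input_error")
  # the admissible markers are exactly the four phenotype columns
  expect_setequal(chronicity_markers(),
                  c("n_total", "n_inpatient", "n_outpatient",
                    "hosp_length_days"))
})

test_that("regressing the score on itself returns slope one", {
  set.seed(10)
  ids <- sprintf("i%03d", 1:30)
  sc <- scale(rnorm(30))[, 1]
  g <- chronoprs:::new_grps(ids, sc, 0.05, 10L, TRUE)
  out <- tibble::tibble(individual_id = ids, value = sc)
  attr(out, "marker") <- "n_total"
  fit <- fit_case_only(out, g, covars = NULL, pheno = NULL)
  expect_equal(fit$B, 1, tolerance = 1e-10)
  expect_lt(fit$P, 1e-10)
  expect_equal(fit$n, 30L)
})

test_that("coefficients match the normal-equations oracle on a 12-row design", {
  set.seed(11)
  n <- 12
  ids <- sprintf("i%03d", 1:n)
  d <- data.frame(score = rnorm(n), pc_1 = rnorm(n), pc_2 = rnorm(n),
                  age = rnorm(n, 30, 5),
                  sexM = rep(c(0, 1), 6), batch2 = rep(c(0, 0, 1), 4))
  y <- 0.4 * d$score + 0.2 * d$pc_1 - 0.1 * d$pc_2 + 0.05 * d$age +
    0.3 * d$sexM - 0.2 * d$batch2 + rnorm(n, 0, 0.5)
  y <- (y - mean(y)) / sd(y)

  g <- chronoprs:::new_grps(ids, d$score, 0.05, 5L, TRUE)
  covars <- tibble::tibble(individual_id = ids, pc_1 = d$pc_1, pc_2 = d$pc_2,
                           batch = ifelse(d$batch2 == 1, "batch_2", "batch_1"))
  pheno <- toy_pheno(sex = ifelse(d$sexM == 1, "M", "F"),
                     case_status = rep(1L, n), ids = ids)
  pheno$age_at_diagnosis <- d$age
  out <- tibble::tibble(individual_id = ids, value = y)
  attr(out, "marker") <- "n_total"
  fit <- fit_case_only(out, g, covars, pheno, stratum = "all")

  x <- cbind(1, d$score, d$pc_1, d$pc_2, d$batch2, d$age, d$sexM)
  bhat <- solve(t(x) %*% x, t(x) %*% y)
  resid <- y - x %*% bhat
  s2 <- sum(resid^2) / (n - ncol(x))
  se <- sqrt(diag(s2 * solve(t(x) %*% x)))
  expect_equal(fit$B, bhat[2], tolerance = 1e-10)
  expect_equal(fit$se, se[2], tolerance = 1e-10)
})

test_that("case-only regression recovers a simulated slope", {
  set.seed(12)
  reps <- 30; n <- 500; b <- 0.3
  est <- replicate(reps, {
    ids <- sprintf("i%04d", 1:n)
    sc <- scale(rnorm(n))[, 1]
    pc1 <- rnorm(n)
    y <- b * sc + 0.3 * pc1 + rnorm(n, 0, 1)
    g <- chronoprs:::new_grps(ids, sc, 0.05, 10L, TRUE)
    covars <- tibble::tibble(individual_id = ids, pc_1 = pc1)
    out <- tibble::tibble(individual_id = ids, value = y)
    attr(out, "marker") <- "n_total"
    fit_case_only(out, g, covars, pheno = NULL)$B
  })
  mc_se <- sd(est) / sqrt(reps)
  expect_lt(abs(mean(est) - b), 3 * mc_se + 1e-12)
})

test_that("an exact sexwise-slope construction yields the exact interaction", {
  n <- 40
  ids <- sprintf("i%03d", 1:n)
  sex <- rep(c("F", "M"), each = n / 2)
  set.seed(13)
  sc <- rnorm(n)
  y <- ifelse(sex == "F", 0.5, 1.0) * sc      # noiseless
  g <- chronoprs:::new_grps(ids, sc, 0.05, 10L, TRUE)
  pheno <- toy_pheno(sex = sex, case_status = rep(1L, n), ids = ids)
  pheno$age_at_diagnosis <- 20 + seq_len(n)   # varying, but with zero effect
  out <- tibble::tibble(individual_id = ids, value = y)
  attr(out, "marker") <- "n_total"
  fit <- fit_interaction(out, g, covars = NULL, pheno = pheno)
  expect_equal(fit$B, 0.5, tolerance = 1e-10)
})

test_that("swapping the sex reference negates the interaction coefficient", {
  x <- small_cohort(seed = 14, n_cases = 150, n_controls = 20)
  out <- make_outcome(x$cohort$phenotypes, "n_inpatient")
  f1 <- fit_interaction(out, x$grps, x$cohort$covariates,
                        x$cohort$phenotypes, sex_ref = "F")
  f2 <- fit_interaction(out, x$grps, x$cohort$covariates,
                        x$cohort$phenotypes, sex_ref = "M")
  expect_equal(f1$B, -f2$B, tolerance = 1e-10)
  expect_equal(f1$P, f2$P, tolerance = 1e-10)
  # single-sex samples cannot support an interaction
  ph_f <- x$cohort$phenotypes
  ph_f$sex <- "F"
  expect_error(fit_interaction(out, x$grps, x$cohort$covariates, ph_f),
               class = "chronoprs_input_error")
})

test_that("results are invariant to row and covariate-column order", {
  x <- small_cohort(seed = 15, n_cases = 120, n_controls = 20)
  out <- make_outcome(x$cohort$phenotypes, "n_total")
  covars <- x$cohort$covariates
  fit1 <- fit_case_only(out, x$grps, covars, x$cohort$phenotypes, "all")

  set.seed(16)
  perm <- sample(nrow(out))
  out2 <- out[perm, ]
  attr(out2, "marker") <- "n_total"
  covars2 <- covars[sample(nrow(covars)),
                    c("individual_id", "batch",
                      rev(grep("^pc_", names(covars), value = TRUE)))]
  fit2 <- fit_case_only(out2, x$grps, covars2, x$cohort$phenotypes, "all")
  expect_equal(fit1$B, fit2$B, tolerance = 1e-10)
  expect_equal(fit1$se, fit2$se, tolerance = 1e-10)
  expect_equal(fit1$P, fit2$P, tolerance = 1e-10)
})

test_that("sex strata partition the case set", {
  x <- small_cohort(seed = 17, n_cases = 130, n_controls = 20)
  out <- make_outcome(x$cohort$phenotypes, "hosp_length_days")
  n_all <- fit_case_only(out, x$grps, x$cohort$covariates,
                         x$cohort$phenotypes, "all")$n
  n_f <- fit_case_only(out, x$grps, x$cohort$covariates,
                       x$cohort$phenotypes, "female")$n
  n_m <- fit_case_only(out, x$grps, x$cohort$covariates,
                       x$cohort$phenotypes, "male")$n
  expect_equal(n_f + n_m, n_all)
})

test_that("a rank-deficient design names the aliased column", {
  set.seed(18)
  n <- 25
  ids <- sprintf("i%03d", 1:n)
  sc <- rnorm(n)
  covars <- tibble::tibble(individual_id = ids, pc_1 = rnorm(n))
  covars$pc_2 <- 2 * covars$pc_1           # exactly collinear
  g <- chronoprs:::new_grps(ids, sc, 0.05, 10L, TRUE)
  out <- tibble::tibble(individual_id = ids, value = rnorm(n))
  attr(out, "marker") <- "n_total"
  err <- tryCatch(fit_case_only(out, g, covars, pheno = NULL),
                  error = identity)
  expect_s3_class(err, "chronoprs_collinearity_error")
  expect_match(conditionMessage(err), "pc_2")
})
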