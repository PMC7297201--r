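#' Nagelkerke pseudo-R-squared from two nested log-likelihoods
#'
#' Cox-Snell R-squared `1 - exp(2 (ll_null - ll_full) / n)` rescaled by its
#' attainable maximum `1 - exp(2 ll_null / n)`, so a saturated model reaches
#' 1.
#'
#' @param ll_null,ll_full log-likelihoods of the nested null and full models
#'   (`ll_full >= ll_null` up to 1e-8).
#' @param n sample size.
#' @return The Nagelkerke pseudo-R-squared in \[0, 1\].
#' @examples
#' nagelkerke_r2(-100, -80, 200)
#' @export
nagelkerke_r2 <- function(ll_null, ll_full, n) {
  stopifnot(is.numeric(ll_null), is.numeric(ll_full), length(n) == 1, n >= 1)
  if (any(ll_full < ll_null - 1e-8)) {
    chk_stop("ll_full < ll_null: models are not nested (or fits did not converge)",
             "chronoprs_nesting_error")
  }
  cs <- 1 - exp(2 * (ll_null - ll_full) / n)
  cs_max <- 1 - exp(2 * ll_null / n)
  ifelse(cs_max <= 0, 0, pmin(pmax(cs / cs_max, 0), 1))
}

# Bernoulli log-likelihood of a fitted logistic model.
#' @noRd
logistic_ll <- function(y, x) {
  fit <- suppressWarnings(glm.fit(x, y, family = binomial(),
                                  control = stats::glm.control(maxit = 100)))
  mu <- fit$fitted.values
  separated <- any(mu < 1e-8 | mu > 1 - 1e-8)
  if (separated) {
    # the ML estimate diverges but the log-likelihood plateaus at its
    # supremum, which is what the pseudo-R2 needs; report, do not abort
    rlang::warn("fitted probabilities numerically 0 or 1: complete or quasi-complete separation",
                class = "chronoprs_separation_warning",
                .frequency = "once",
                .frequency_id = "chronoprs_separation_warning")
  } else if (!fit$converged) {
    chk_stop(sprintf("logistic fit did not converge after %d IRLS iterations",
                     fit$iter),
             "chronoprs_optimizer_error", iterations = fit$iter)
  }
  sum(dbinom(y, 1, mu, log = TRUE))
}

# Fast core: incremental Nagelkerke R2 of X_full over X_null, both measured
# against the intercept-only model.
#' @noRd
inc_nkr2_core <- function(y, x_null, x_full, detail = FALSE) {
  n <- length(y)
  q <- mean(y)
  ll_int <- if (q %in% c(0, 1)) 0 else n * (q * log(q) + (1 - q) * log(1 - q))
  ll_null <- logistic_ll(y, x_null)
  ll_full <- logistic_ll(y, x_full)
  nk_null <- nagelkerke_r2(ll_int, max(ll_null, ll_int), n)
  nk_full <- nagelkerke_r2(ll_int, max(ll_full, ll_int), n)
  if (detail) {
    list(increment = nk_full - nk_null, nkr2_full = nk_full,
         nkr2_null = nk_null, n = n)
  } else {
    nk_full - nk_null
  }
}

# Design matrices for the case-control logistic models over all individuals.
# Null model: intercept + PCs (+ batch indicators if requested); full model
# additionally carries the score.
#' @noRd
build_cc_design <- function(pheno, grps, covars, include_batch = FALSE) {
  ids <- pheno$individual_id
  sc <- grps$score[match(ids, grps$individual_id)]
  if (anyNA(sc)) {
    chk_stop("some phenotype individuals have no GRPS value",
             "chronoprs_input_error")
  }
  i <- match(ids, covars$individual_id)
  pc_cols <- grep("^pc_", names(covars), value = TRUE)
  x_null <- cbind(`(Intercept)` = 1,
                  as.matrix(covars[i, pc_cols, drop = FALSE]))
  if (include_batch && "batch" %in% names(covars)) {
    b <- factor(covars$batch[i])
    if (nlevels(b) > 1) {
      x_null <- cbind(x_null, stats::model.matrix(~b)[, -1, drop = FALSE])
    }
  }
  list(ids = ids, y = as.integer(pheno$case_status),
       sex = pheno$sex,
       x_null = x_null, x_full = cbind(x_null, score = sc))
}

#' Incremental Nagelkerke R-squared of the GRPS over principal components
#'
#' Fits logistic case-control models `case ~ PCs` (null) and
#' `case ~ PCs + GRPS` (full) by maximum likelihood on the selected cases
#' together with all controls, and returns the difference of their Nagelkerke
#' pseudo-R-squared values, each measured against the intercept-only model.
#' A score that is constant over the analysis sample contributes an increment
#' of exactly 0 (the aliased term is dropped by the fitter).
#'
#' @param pheno phenotype table (`individual_id`, `case_status`, ...).
#' @param grps a `grps` object covering all individuals.
#' @param covars covariate table with `pc_*` columns (and `batch`).
#' @param case_ids subset of case ids to retain; `NULL` keeps all cases.
#'   Controls are never filtered.
#' @param include_batch also adjust the case-control models for batch
#'   indicators (default `FALSE`: the null model is PCs only).
#' @param detail return a list with `increment`, `nkr2_full`, `nkr2_null`,
#'   `n` instead of the bare increment.
#' @return The incremental Nagelkerke R-squared (or the detail list).
#' @export
incremental_nkr2 <- function(pheno, grps, covars, case_ids = NULL,
                             include_batch = FALSE, detail = FALSE) {
  des <- build_cc_design(pheno, grps, covars, include_batch)
  keep <- des$y == 0L
  if (is.null(case_ids)) {
    keep <- keep | des$y == 1L
  } else {
    if (!all(case_ids %in% des$ids[des$y == 1L])) {
      chk_stop("`case_ids` must be a subset of case identifiers",
               "chronoprs_input_error")
    }
    keep <- keep | des$ids %in% case_ids
  }
  inc_nkr2_core(des$y[keep], des$x_null[keep, , drop = FALSE],
                des$x_full[keep, , drop = FALSE], detail = detail)
}

#' Chronicity filters for case enrichment
#'
#' A filter keeps cases whose marker value is at or above an inclusive
#' threshold. The conventional above-average thresholds are 27 total
#' contacts, 12 inpatient contacts, 19 outpatient contacts, and 640
#' hospitalization days; [default_chronicity_filters()] returns these four.
#'
#' @param marker one of [chronicity_markers()].
#' @param threshold inclusive lower bound (count or days), >= 0.
#' @return A `chronicity_filter` object.
#' @export
chronicity_filter <- function(marker, threshold) {
  if (!marker %in% chronicity_markers()) {
    chk_stop(sprintf("unknown chronicity marker `%s`", marker),
             "chronoprs_validation_error")
  }
  assert_scalar_number(threshold, "threshold", lower = 0)
  structure(list(marker = marker, threshold = threshold),
            class = "chronicity_filter")
}

#' @rdname chronicity_filter
#' @export
default_chronicity_filters <- function() {
  list(chronicity_filter("n_total", 27),
       chronicity_filter("n_inpatient", 12),
       chronicity_filter("n_outpatient", 19),
       chronicity_filter("hosp_length_days", 640))
}

#' Apply a chronicity filter to the cases of a phenotype table
#'
#' @param pheno phenotype table.
#' @param filter a [chronicity_filter()].
#' @return Character vector of case ids with `marker >= threshold`. Controls
#'   are never filtered.
#' @export
apply_chronicity_filter <- function(pheno, filter) {
  stopifnot(inherits(filter, "chronicity_filter"))
  cases <- pheno[pheno$case_status == 1L, , drop = FALSE]
  if (nrow(cases) == 0) {
    chk_stop("no cases present", "chronoprs_input_error")
  }
  x <- cases[[filter$marker]]
  cases$individual_id[!is.na(x) & x >= filter$threshold]
}

#' Matched-subsample permutation test of chronicity enrichment
#'
#' Measures whether restricting cases to a chronicity-enriched subset changes
#' the GRPS's incremental Nagelkerke R-squared relative to random case subsets
#' of the same size. The observed statistic is [incremental_nkr2()] on the
#' filtered cases plus all controls; the null distribution is built by
#' repeatedly drawing, uniformly without replacement, a case subset matching
#' the filtered count and recomputing the statistic. The empirical p-value
#' uses the add-one convention `(1 + #\{perm >= obs\}) / (n_perm + 1)` (never
#' exactly zero); the default alternative is one-sided improvement.
#'
#' @inheritParams incremental_nkr2
#' @param filter a [chronicity_filter()].
#' @param n_perm number of permutation draws (>= 1); 1000 is conventional.
#' @param seed integer seed; fully determines the draws.
#' @param alternative `"greater"` (default), `"less"`, or `"two.sided"`.
#' @return An `enrichment_result`: list with `filter`, `n_selected_cases`,
#'   `observed_nkr2` (incremental, filtered subsample), `baseline_nkr2`
#'   (incremental, all cases), `observed_full_model_nkr2`, `perm_values`,
#'   `p_perm`, `n_perm`, `seed`, `alternative`.
#' @export
permutation_enrichment_test <- function(pheno, grps, covars, filter,
                                        n_perm = 1000, seed = 1,
                                        alternative = c("greater", "less", "two.sided"),
                                        include_batch = FALSE) {
  alternative <- match.arg(alternative)
  assert_scalar_number(n_perm, "n_perm", lower = 1, integerish = TRUE)
  selected <- apply_chronicity_filter(pheno, filter)
  if (!length(selected)) {
    chk_stop(sprintf("chronicity filter (%s >= %g) selects no cases",
                     filter$marker, filter$threshold),
             "chronoprs_empty_filter_error")
  }
  des <- build_cc_design(pheno, grps, covars, include_batch)
  ctrl_rows <- which(des$y == 0L)
  case_ids <- des$ids[des$y == 1L]
  k <- length(selected)

  stat_for <- function(sub_ids) {
    rows <- c(which(des$ids %in% sub_ids & des$y == 1L), ctrl_rows)
    inc_nkr2_core(des$y[rows], des$x_null[rows, , drop = FALSE],
                  des$x_full[rows, , drop = FALSE], detail = TRUE)
  }
  obs <- stat_for(selected)
  perm_values <- with_seed(substream_seed(seed, "enrichment-perm"), {
    vapply(seq_len(n_perm), function(i) {
      stat_for(sample(case_ids, k, replace = FALSE))$increment
    }, numeric(1))
  })
  structure(list(
    filter = filter, n_selected_cases = k,
    observed_nkr2 = obs$increment,
    observed_full_model_nkr2 = obs$nkr2_full,
    baseline_nkr2 = incremental_nkr2(pheno, grps, covars,
                                     include_batch = include_batch),
    perm_values = perm_values,
    p_perm = empirical_p(obs$increment, perm_values, alternative),
    n_perm = as.integer(n_perm), seed = as.integer(seed),
    alternative = alternative
  ), class = "enrichment_result")
}

#' @noRd
empirical_p <- function(observed, perm, alternative) {
  n <- length(perm)
  p_ge <- (1 + sum(perm >= observed)) / (n + 1)
  p_le <- (1 + sum(perm <= observed)) / (n + 1)
  switch(alternative,
         greater = p_ge,
         less = p_le,
         two.sided = min(1, 2 * min(p_ge, p_le)))
}

#' Sex prediction-gap permutation test
#'
#' The observed statistic is the male-minus-female difference in the GRPS's
#' incremental Nagelkerke R-squared, each sex analysed with its own cases and
#' controls. The null distribution permutes sex labels across all individuals
#' (case status untouched) and recomputes the gap; the p-value is two-sided
#' with the add-one convention.
#'
#' @inheritParams permutation_enrichment_test
#' @return An `enrichment_result` with `statistic = "sex_gap"`,
#'   `observed_gap`, `nkr2_male`, `nkr2_female` (incremental, per sex),
#'   `perm_values`, `p_perm`, `n_perm`, `seed`.
#' @export
sex_prediction_gap_test <- function(pheno, grps, covars, n_perm = 1000,
                                    seed = 1, include_batch = FALSE) {
  assert_scalar_number(n_perm, "n_perm", lower = 1, integerish = TRUE)
  des <- build_cc_design(pheno, grps, covars, include_batch)
  for (s in c("F", "M")) {
    if (!any(des$y == 1L & des$sex == s) || !any(des$y == 0L & des$sex == s)) {
      chk_stop(sprintf("sex stratum %s lacks cases or controls", s),
               "chronoprs_input_error")
    }
  }
  gap_for <- function(sex_labels, detail = FALSE) {
    inc <- lapply(c(M = "M", F = "F"), function(s) {
      rows <- which(sex_labels == s)
      inc_nkr2_core(des$y[rows], des$x_null[rows, , drop = FALSE],
                    des$x_full[rows, , drop = FALSE], detail = TRUE)
    })
    if (detail) inc else inc$M$increment - inc$F$increment
  }
  obs <- gap_for(des$sex, detail = TRUE)
  observed <- obs$M$increment - obs$F$increment
  perm_values <- with_seed(substream_seed(seed, "sexgap-perm"), {
    vapply(seq_len(n_perm), function(i) gap_for(sample(des$sex)), numeric(1))
  })
  p <- (1 + sum(abs(perm_values) >= abs(observed))) / (n_perm + 1)
  structure(list(
    statistic = "sex_gap", observed_gap = observed,
    nkr2_male = obs$M$increment, nkr2_female = obs$F$increment,
    nkr2_male_full_model = obs$M$nkr2_full,
    nkr2_female_full_model = obs$F$nkr2_full,
    n_male = obs$M$n, n_female = obs$F$n,
    perm_values = perm_values, p_perm = p,
    n_perm = as.integer(n_perm), seed = as.integer(seed),
    alternative = "two.sided"
  ), class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  if (!is.null(x$statistic) && x$statistic == "sex_gap") {
    cat(sprintf("<enrichment_result: sex gap> male NkR2=%.4f, female NkR2=%.4f, gap=%.4f, p_perm=%.4g (%d perms)\n",
                x$nkr2_male, x$nkr2_female, x$observed_gap, x$p_perm, x$n_perm))
  } else {
    cat(sprintf("<enrichment_result: %s >= %g> n_cases=%d, incremental NkR2=%.4f (baseline %.4f), p_perm=%.4g (%d perms, %s)\n",
                x$filter$marker, x$filter$threshold, x$n_selected_cases,
                x$observed_nkr2, x$baseline_nkr2, x$p_perm, x$n_perm,
                x$alternative))
  }
  invisible(x)
}
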