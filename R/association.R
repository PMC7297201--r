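#' Build a transformed case-only chronicity outcome
#'
#' Chronicity markers are accumulated over unequal follow-up, so the default
#' outcome is the annualized rate `marker / follow_up_years`, tamed with
#' `log1p` (the markers are heavily right-skewed, with sd exceeding the mean),
#' then z-scored across cases. `transform = "raw_z"` skips the rate and log
#' steps and simply z-scores the raw marker.
#'
#' @param pheno phenotype table (see [simulate_cohort()]); only rows with
#'   `case_status == 1` are used.
#' @param marker one of [chronicity_markers()].
#' @param transform `"rate_log1p_z"` (default) or `"raw_z"`.
#'
#' @return An `outcome_vector`: tibble with `individual_id` and `value`
#'   (mean 0, sd 1 across cases), with attributes `marker` and `transform`.
#' @export
make_outcome <- function(pheno, marker,
                         transform = c("rate_log1p_z", "raw_z")) {
  transform <- match.arg(transform)
  if (!marker %in% chronicity_markers()) {
    chk_stop(sprintf("unknown chronicity marker `%s`; expected one of %s",
                     marker, paste(chronicity_markers(), collapse = ", ")),
             "chronoprs_input_error")
  }
  cases <- pheno[pheno$case_status == 1L, , drop = FALSE]
  if (nrow(cases) == 0) {
    chk_stop("no cases in phenotype table", "chronoprs_input_error")
  }
  bad_fu <- cases$individual_id[!is.finite(cases$follow_up_years) |
                                  cases$follow_up_years <= 0]
  if (transform == "rate_log1p_z" && length(bad_fu)) {
    chk_stop(paste0("nonpositive or missing follow-up for case(s): ",
                    paste(head(bad_fu, 5), collapse = ", "),
                    if (length(bad_fu) > 5) sprintf(" (+%d more)", length(bad_fu) - 5) else ""),
             "chronoprs_validation_error", ids = bad_fu)
  }
  x <- cases[[marker]]
  if (anyNA(x) || any(x < 0)) {
    chk_stop(sprintf("marker `%s` missing or negative for some cases", marker),
             "chronoprs_validation_error")
  }
  val <- switch(transform,
                rate_log1p_z = log1p(x / cases$follow_up_years),
                raw_z = x)
  s <- sd(val)
  if (!is.finite(s) || s == 0) {
    chk_stop(sprintf("outcome `%s` has zero variance after transform (degenerate outcome)",
                     marker),
             "chronoprs_degenerate_outcome_error")
  }
  out <- tibble::tibble(individual_id = cases$individual_id,
                        value = (val - mean(val)) / s)
  attr(out, "marker") <- marker
  attr(out, "transform") <- transform
  class(out) <- c("outcome_vector", class(out))
  out
}

# Assemble the case-only model frame: outcome value, score, PCs, batch,
# age at diagnosis, sex, restricted to the outcome's individuals.
#' @noRd
case_model_frame <- function(outcome, grps, covars, pheno) {
  d <- data.frame(individual_id = outcome$individual_id,
                  value = outcome$value, stringsAsFactors = FALSE)
  d$score <- grps$score[match(d$individual_id, grps$individual_id)]
  if (anyNA(d$score)) {
    chk_stop("some outcome individuals have no GRPS value",
             "chronoprs_input_error")
  }
  if (!is.null(covars)) {
    i <- match(d$individual_id, covars$individual_id)
    pc_cols <- grep("^pc_", names(covars), value = TRUE)
    for (pc in pc_cols) d[[pc]] <- covars[[pc]][i]
    if ("batch" %in% names(covars)) d$batch <- factor(covars$batch[i])
  }
  if (!is.null(pheno)) {
    i <- match(d$individual_id, pheno$individual_id)
    d$sex <- factor(pheno$sex[i], levels = c("F", "M"))
    d$age_at_diagnosis <- pheno$age_at_diagnosis[i]
  }
  d
}

#' @noRd
rhs_terms <- function(d, include_sex) {
  terms <- "score"
  terms <- c(terms, grep("^pc_", names(d), value = TRUE))
  if (!is.null(d$batch) && nlevels(droplevels(d$batch)) > 1) {
    terms <- c(terms, "batch")
  }
  if (!is.null(d$age_at_diagnosis) && !anyNA(d$age_at_diagnosis)) {
    terms <- c(terms, "age_at_diagnosis")
  }
  if (include_sex && !is.null(d$sex) && nlevels(droplevels(d$sex)) > 1) {
    terms <- c(terms, "sex")
  }
  terms
}

#' @noRd
check_full_rank <- function(fit) {
  co <- coef(fit)
  if (anyNA(co)) {
    chk_stop(paste0("rank-deficient design; aliased column(s): ",
                    paste(names(co)[is.na(co)], collapse = ", ")),
             "chronoprs_collinearity_error")
  }
  invisible(fit)
}

#' Case-only association of a chronicity outcome with the GRPS
#'
#' Ordinary least squares of the transformed outcome on the standardized GRPS
#' with adjustment for ancestry principal components, genotyping batch
#' (indicator-coded, first batch as reference), age at diagnosis, and — in the
#' unstratified model — sex. In sex-stratified fits the sex term is removed.
#'
#' @param outcome an `outcome_vector` from [make_outcome()].
#' @param grps a (standardized) `grps` object.
#' @param covars covariate table with `pc_*` columns and `batch`, or `NULL`
#'   for an unadjusted fit.
#' @param pheno phenotype table providing `sex` and `age_at_diagnosis`, or
#'   `NULL` (then `stratum` must be `"all"` and no age/sex adjustment is
#'   done).
#' @param stratum `"all"`, `"female"`, or `"male"`.
#'
#' @return One-row tibble: `outcome`, `stratum`, `term` (`"GRPS"`), `B`
#'   (coefficient per SD of score), `se`, `P` (two-sided), `n`.
#' @export
fit_case_only <- function(outcome, grps, covars = NULL, pheno = NULL,
                          stratum = c("all", "female", "male")) {
  stratum <- match.arg(stratum)
  if (stratum != "all" && is.null(pheno)) {
    chk_stop("sex-stratified fits require `pheno` (sex information)",
             "chronoprs_input_error")
  }
  d <- case_model_frame(outcome, grps, covars, pheno)
  if (stratum != "all") {
    d <- d[!is.na(d$sex) & d$sex == c(female = "F", male = "M")[[stratum]], ,
           drop = FALSE]
  }
  terms <- rhs_terms(d, include_sex = stratum == "all")
  if (nrow(d) < length(terms) + 2) {
    chk_stop("too few cases for the requested model", "chronoprs_input_error")
  }
  fit <- lm(stats::reformulate(terms, response = "value"), data = d)
  check_full_rank(fit)
  sm <- summary(fit)$coefficients
  tibble::tibble(outcome = attr(outcome, "marker") %||% "outcome",
                 stratum = stratum, term = "GRPS",
                 B = sm["score", 1], se = sm["score", 2], P = sm["score", 4],
                 n = nrow(d))
}

#' GRPS-by-sex interaction on a chronicity outcome
#'
#' Adds a GRPS x sex product term to the case-only model (main effects of
#' score and sex retained, covariates as in [fit_case_only()]) and reports the
#' product term.
#'
#' @inheritParams fit_case_only
#' @param sex_ref reference sex level (`"F"` default); the interaction
#'   coefficient is the male-minus-female difference in score slope when the
#'   reference is `"F"`.
#' @return One-row tibble: `outcome`, `stratum` (`"interaction"`), `term`
#'   (`"GRPS:sex"`), `B`, `se`, `P`, `n`.
#' @export
fit_interaction <- function(outcome, grps, covars = NULL, pheno = NULL,
                            sex_ref = c("F", "M")) {
  sex_ref <- match.arg(sex_ref)
  if (is.null(pheno)) {
    chk_stop("interaction fits require `pheno` (sex information)",
             "chronoprs_input_error")
  }
  d <- case_model_frame(outcome, grps, covars, pheno)
  d$sex <- stats::relevel(d$sex, ref = sex_ref)
  if (nlevels(droplevels(d$sex)) < 2) {
    chk_stop("both sexes must be present among cases for an interaction model",
             "chronoprs_input_error")
  }
  terms <- c(rhs_terms(d, include_sex = FALSE), "sex", "score:sex")
  fit <- lm(stats::reformulate(terms, response = "value"), data = d)
  check_full_rank(fit)
  sm <- summary(fit)$coefficients
  row <- grep("^score:sex", rownames(sm))
  tibble::tibble(outcome = attr(outcome, "marker") %||% "outcome",
                 stratum = "interaction", term = "GRPS:sex",
                 B = sm[row, 1], se = sm[row, 2], P = sm[row, 4],
                 n = nrow(d))
}
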