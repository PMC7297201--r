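#' Simulation configuration for the discovery GWAS and target cohort
#'
#' Builds the configuration object consumed by [simulate_summary_stats()] and
#' [simulate_cohort()]. The default (`preset = "paper"`) is calibrated to an
#' ascertained schizophrenia case-control sample: 2,457 cases and 2,702
#' controls with a 897F/1560M case and 1286F/1416M control sex split, case
#' chronicity marker means of roughly 27 total contacts, 11.5 inpatient
#' contacts, 19 outpatient contacts and 642 hospitalization days, follow-up of
#' 22 years (sd 8.2), and age at diagnosis around 28 years. The `"test"`
#' preset is a scaled-down configuration for fast simulation studies.
#'
#' Chronicity markers are coupled to the standardized genetic liability value
#' through log-linear links: counts are negative binomial with log-mean
#' `a + b * g` (plus a sex shift where configured) and hospitalization length
#' is log-normal likewise. By default the outpatient-contact slope is zero, so
#' outpatient contacts carry no genetic signal, while total contacts,
#' inpatient contacts and hospitalization length do.
#'
#' @param preset `"paper"` (full-size calibrated defaults) or `"test"`
#'   (scaled down for simulation studies).
#' @param ... named overrides of any configuration field, e.g.
#'   `n_cases = 500` or `female_noise_inflation = 1`.
#'
#' @return A list of class `sim_config` with fields:
#' \describe{
#'   \item{n_variants}{number of independent variants in the discovery panel}
#'   \item{maf_range}{minor-allele-frequency range, in (0, 0.5]}
#'   \item{h2_liability}{liability variance attributable to the panel, in
#'     \[0, 1\] (a SNP-heritability-like quantity, not twin heritability)}
#'   \item{prevalence}{per-sex lifetime prevalence determining the liability
#'     threshold}
#'   \item{n_discovery}{discovery GWAS sample size (sets the effect-estimate
#'     standard errors)}
#'   \item{n_cases, n_controls}{ascertained target-sample sizes}
#'   \item{prop_female_cases, prop_female_controls}{sex composition}
#'   \item{chronicity_links}{per-marker list of intercept `a`, slope `b` on
#'     the standardized genetic value, and dispersion (`size` for counts,
#'     `sdlog` for length)}
#'   \item{sex_effects}{additive log-scale shifts: `hosp_length_male` applied
#'     to males, `n_outpatient_female` applied to females}
#'   \item{female_noise_inflation}{multiplier >= 1 on the female environmental
#'     liability variance}
#'   \item{n_pcs, n_batches}{covariate structure}
#'   \item{followup_mean_years, followup_sd_years, age_mean, age_sd}{case
#'     follow-up and age-at-diagnosis truncated-normal parameters}
#'   \item{missing_rate}{uniform genotype missingness rate}
#'   \item{draw_budget}{hard cap on individuals drawn during rejection
#'     sampling}
#'   \item{seed}{default master seed}
#' }
#'
#' @examples
#' cfg <- sim_config(preset = "test", n_cases = 100, n_controls = 100)
#' cfg$n_cases
#' @export
sim_config <- function(preset = c("paper", "test"), ...) {
  preset <- match.arg(preset)
  cfg <- list(
    preset = preset,
    n_variants = 1500L,
    maf_range = c(0.05, 0.5),
    h2_liability = 0.25,
    prevalence = 0.01,
    n_discovery = 6000L,
    n_cases = 2457L,
    n_controls = 2702L,
    prop_female_cases = 897 / 2457,
    prop_female_controls = 1286 / 2702,
    chronicity_links = list(
      n_total          = list(a = 2.962, b = 0.25, size = 0.9),
      n_inpatient      = list(a = 2.128, b = 0.25, size = 0.8),
      n_outpatient     = list(a = 2.876, b = 0.00, size = 0.6),
      hosp_length_days = list(a = 5.317, b = 0.25, sdlog = 1.065)
    ),
    sex_effects = list(
      hosp_length_male = log(712.69 / 509.33),
      n_outpatient_female = log(17.23 / 15.18)
    ),
    female_noise_inflation = 2.0,
    n_pcs = 10L,
    n_batches = 6L,
    followup_mean_years = 22,
    followup_sd_years = 8.22,
    age_mean = 28,
    age_sd = 7,
    missing_rate = 0,
    draw_budget = 1e7,
    seed = 1L
  )
  if (preset == "test") {
    cfg <- modifyList(cfg, list(
      n_variants = 200L, n_discovery = 4000L,
      n_cases = 300L, n_controls = 300L,
      prevalence = 0.05, n_pcs = 4L, n_batches = 3L
    ))
  }
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad) || is.null(names(dots)) || any(names(dots) == "")) {
      chk_stop(paste0("unknown configuration field(s): ",
                      paste(bad, collapse = ", ")),
               "chronoprs_config_error")
    }
    cfg <- modifyList(cfg, dots)
  }
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' @noRd
validate_sim_config <- function(cfg) {
  assert_scalar_number(cfg$n_variants, "n_variants", lower = 1, integerish = TRUE)
  if (!is.numeric(cfg$maf_range) || length(cfg$maf_range) != 2 ||
      cfg$maf_range[1] <= 0 || cfg$maf_range[2] > 0.5 ||
      cfg$maf_range[1] > cfg$maf_range[2]) {
    chk_stop("invalid configuration field `maf_range`: must be an increasing pair in (0, 0.5]",
             "chronoprs_config_error", field = "maf_range")
  }
  assert_scalar_number(cfg$h2_liability, "h2_liability", 0, 1)
  assert_scalar_number(cfg$prevalence, "prevalence", 0, 1,
                       closed_lower = FALSE, closed_upper = FALSE)
  assert_scalar_number(cfg$n_discovery, "n_discovery", lower = 1, integerish = TRUE)
  assert_scalar_number(cfg$n_cases, "n_cases", lower = 0, integerish = TRUE)
  assert_scalar_number(cfg$n_controls, "n_controls", lower = 0, integerish = TRUE)
  if (cfg$n_cases + cfg$n_controls < 1) {
    chk_stop("invalid configuration: n_cases + n_controls must be positive",
             "chronoprs_config_error", field = "n_cases")
  }
  assert_scalar_number(cfg$prop_female_cases, "prop_female_cases", 0, 1)
  assert_scalar_number(cfg$prop_female_controls, "prop_female_controls", 0, 1)
  assert_scalar_number(cfg$female_noise_inflation, "female_noise_inflation", lower = 1)
  assert_scalar_number(cfg$n_pcs, "n_pcs", lower = 1, integerish = TRUE)
  assert_scalar_number(cfg$n_batches, "n_batches", lower = 1, integerish = TRUE)
  assert_scalar_number(cfg$followup_mean_years, "followup_mean_years", lower = 0,
                       closed_lower = FALSE)
  assert_scalar_number(cfg$followup_sd_years, "followup_sd_years", lower = 0,
                       closed_lower = FALSE)
  assert_scalar_number(cfg$age_mean, "age_mean", lower = 0, closed_lower = FALSE)
  assert_scalar_number(cfg$age_sd, "age_sd", lower = 0, closed_lower = FALSE)
  assert_scalar_number(cfg$missing_rate, "missing_rate", 0, 1, closed_upper = FALSE)
  assert_scalar_number(cfg$draw_budget, "draw_budget", lower = 1)
  assert_scalar_number(cfg$seed, "seed", integerish = TRUE)
  for (m in chronicity_markers()) {
    lk <- cfg$chronicity_links[[m]]
    if (is.null(lk)) {
      chk_stop(sprintf("invalid configuration field `chronicity_links`: missing marker `%s`", m),
               "chronoprs_config_error", field = "chronicity_links")
    }
    assert_scalar_number(lk$a, paste0("chronicity_links$", m, "$a"))
    assert_scalar_number(lk$b, paste0("chronicity_links$", m, "$b"))
    disp <- if (m == "hosp_length_days") lk$sdlog else lk$size
    assert_scalar_number(disp, paste0("chronicity_links$", m, "$dispersion"),
                         lower = 0, closed_lower = FALSE)
  }
  invisible(cfg)
}

#' The four chronicity marker names
#'
#' Total health-care contacts, inpatient contacts, outpatient contacts, and
#' cumulative hospitalization length in days.
#'
#' @return Character vector of the four marker column names in
#'   the phenotype table.
#' @export
chronicity_markers <- function() {
  c("n_total", "n_inpatient", "n_outpatient", "hosp_length_days")
}

#' Read / write a simulation configuration as YAML
#'
#' @param path file path.
#' @param config a [sim_config()] object.
#' @return `read_sim_config()` returns a validated `sim_config`;
#'   `write_sim_config()` returns `path` invisibly.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  preset <- raw$preset %||% "paper"
  raw$preset <- NULL
  if (!is.null(raw$maf_range)) raw$maf_range <- as.numeric(raw$maf_range)
  do.call(sim_config, c(list(preset = preset), raw))
}

#' @rdname read_sim_config
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config preset=%s> %d variants, h2=%.2f, prevalence=%.3f, %d cases / %d controls\n",
              x$preset, x$n_variants, x$h2_liability, x$prevalence,
              x$n_cases, x$n_controls))
  invisible(x)
}
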