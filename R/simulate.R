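#' Simulate discovery GWAS summary statistics
#'
#' Draws an independent variant panel with allele frequencies uniform over
#' `config$maf_range` and per-variant true effects on the standardized-genotype
#' scale with total liability variance `config$h2_liability`. The reported
#' (estimated) effect is the true per-allele effect plus Gaussian estimation
#' noise with standard error `1 / sqrt(2 p (1-p) n_discovery)`, and the
#' p-value is the two-sided Wald p of estimate/se. Variants are unlinked: no
#' LD structure is simulated, mirroring a clumped discovery panel.
#'
#' @param config a [sim_config()] object.
#' @param seed integer master seed; defaults to `config$seed`. All
#'   randomness is drawn from a dedicated sub-stream so the same seed in
#'   [simulate_cohort()] yields independent draws.
#'
#' @return A tibble with one row per variant: `variant_id`, `effect_allele`,
#'   `other_allele`, `effect_size` (estimated per-allele effect, the scoring
#'   weight), `p_value`, `effect_allele_freq`, `se`, and `true_effect` (the
#'   latent standardized-scale effect used by [simulate_cohort()]).
#' @examples
#' ss <- simulate_summary_stats(sim_config(preset = "test"), seed = 1)
#' head(ss)
#' @export
simulate_summary_stats <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  m <- as.integer(config$n_variants)
  with_seed(substream_seed(seed, "sumstats"), {
    maf <- runif(m, config$maf_range[1], config$maf_range[2])
    bases <- c("A", "C", "G", "T")
    ea <- sample(bases, m, replace = TRUE)
    oa <- vapply(ea, function(b) sample(setdiff(bases, b), 1L), character(1))
    # true effects on the standardized-genotype scale; total variance h2
    beta_std <- if (config$h2_liability > 0) {
      rnorm(m, 0, sqrt(config$h2_liability / m))
    } else {
      rep(0, m)
    }
    scale <- sqrt(2 * maf * (1 - maf))
    beta_allele <- beta_std / scale
    se <- 1 / (scale * sqrt(config$n_discovery))
    est <- beta_allele + rnorm(m, 0, se)
    p <- pmax(2 * pnorm(-abs(est / se)), .Machine$double.xmin)
    tibble::tibble(
      variant_id = sprintf("var_%05d", seq_len(m)),
      effect_allele = unname(ea),
      other_allele = unname(oa),
      effect_size = est,
      p_value = p,
      effect_allele_freq = maf,
      se = se,
      true_effect = beta_std
    )
  })
}

#' Simulate an ascertained case-control cohort under the liability-threshold model
#'
#' Genotype dosages are drawn binomially at each variant's frequency
#' (Hardy-Weinberg). Liability is the sum of true standardized effects on
#' standardized dosages plus a Gaussian environmental term with variance
#' `1 - h2_liability`, inflated by `female_noise_inflation` for females. An
#' individual is a case when liability exceeds the upper-`prevalence`
#' quantile of their sex's liability distribution; the quantile is sex-specific
#' so each sex's case fraction equals `prevalence` even when the female
#' environmental variance is inflated. With `ascertain = TRUE` (default),
#' rejection sampling continues until the configured case/control counts and
#' sex composition are reached, under a hard `draw_budget`.
#'
#' For cases, chronicity markers follow the configured log-linear links on the
#' population-standardized genetic value: counts are negative binomial,
#' hospitalization length is log-normal, with additive log-scale sex shifts
#' where configured. Follow-up years and age at diagnosis are truncated-normal
#' (left-truncated at zero). Principal components are standard normal noise
#' and batch is uniform categorical.
#'
#' @param config a [sim_config()] object.
#' @param sumstats output of [simulate_summary_stats()]; must carry
#'   `true_effect`.
#' @param seed integer master seed; defaults to `config$seed`.
#' @param ascertain if `FALSE`, a population sample of
#'   `n_cases + n_controls` individuals is drawn without rejection (case
#'   status still assigned by the liability threshold); used to check
#'   prevalence calibration.
#'
#' @return A list of class `cohort` with elements
#'   \describe{
#'     \item{genotypes}{a `genotype_matrix`: integer dosage matrix
#'       (individuals x variants, counting the effect allele) plus variant
#'       metadata}
#'     \item{phenotypes}{tibble: `individual_id`, `case_status`, `sex`,
#'       `age_at_diagnosis`, `follow_up_years`, and the four chronicity
#'       markers (`NA` for controls)}
#'     \item{covariates}{tibble: `individual_id`, `pc_1..pc_K`, `batch`}
#'     \item{genetic_value}{per-individual population-standardized genetic
#'       liability value (simulator truth, for calibration checks)}
#'     \item{liability}{per-individual total latent liability (simulator
#'       truth)}
#'   }
#' @examples
#' cfg <- sim_config(preset = "test", n_cases = 50, n_controls = 50)
#' ss <- simulate_summary_stats(cfg, seed = 1)
#' coh <- simulate_cohort(cfg, ss, seed = 1)
#' table(coh$phenotypes$case_status, coh$phenotypes$sex)
#' @export
simulate_cohort <- function(config, sumstats, seed = config$seed,
                            ascertain = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  if (is.null(sumstats$true_effect)) {
    chk_stop("`sumstats` must carry a `true_effect` column (simulator output)",
             "chronoprs_input_error")
  }
  m <- nrow(sumstats)
  maf <- sumstats$effect_allele_freq
  beta_std <- sumstats$true_effect
  scale <- sqrt(2 * maf * (1 - maf))
  beta_allele <- beta_std / scale
  g_offset <- sum(2 * maf * beta_allele)
  vg <- sum(beta_std^2)            # realized genetic liability variance
  ve <- c(F = (1 - config$h2_liability) * config$female_noise_inflation,
          M = (1 - config$h2_liability))
  thr <- qnorm(1 - config$prevalence) * sqrt(vg + ve)  # per-sex threshold

  draws <- with_seed(substream_seed(seed, "genotypes"), {
    if (ascertain) {
      n_case_f <- round(config$n_cases * config$prop_female_cases)
      n_ctrl_f <- round(config$n_controls * config$prop_female_controls)
      targets <- list(
        F = c(case = n_case_f, control = n_ctrl_f),
        M = c(case = config$n_cases - n_case_f,
              control = config$n_controls - n_ctrl_f)
      )
      sample_cell_rejection(targets, maf, beta_allele, g_offset, ve, thr,
                            config$draw_budget)
    } else {
      sample_population(config, maf, beta_allele, g_offset, ve, thr)
    }
  })

  n <- nrow(draws$dosages)
  ids <- sprintf("ind_%05d", seq_len(n))
  gstd <- if (vg > 0) draws$gval / sqrt(vg) else rep(0, n)

  pheno <- with_seed(substream_seed(seed, "phenotypes"), {
    simulate_phenotypes(config, ids, draws$case, draws$sex, gstd)
  })
  covars <- with_seed(substream_seed(seed, "covariates"), {
    pcs <- matrix(rnorm(n * config$n_pcs), nrow = n,
                  dimnames = list(NULL, paste0("pc_", seq_len(config$n_pcs))))
    tibble::tibble(
      individual_id = ids,
      tibble::as_tibble(pcs),
      batch = paste0("batch_", sample.int(config$n_batches, n, replace = TRUE))
    )
  })

  dos <- draws$dosages
  if (config$missing_rate > 0) {
    dos <- with_seed(substream_seed(seed, "missingness"), {
      miss <- runif(length(dos)) < config$missing_rate
      dos[miss] <- NA_integer_
      dos
    })
  }
  dimnames(dos) <- list(ids, sumstats$variant_id)
  geno <- new_genotype_matrix(
    dos,
    tibble::tibble(variant_id = sumstats$variant_id,
                   counted_allele = sumstats$effect_allele,
                   other_allele = sumstats$other_allele)
  )
  structure(list(genotypes = geno, phenotypes = pheno, covariates = covars,
                 genetic_value = setNames(gstd, ids),
                 liability = setNames(draws$liab, ids)),
            class = "cohort")
}

# Rejection sampling per sex cell until the case/control targets are met.
#' @noRd
sample_cell_rejection <- function(targets, maf, beta_allele, g_offset, ve,
                                  thr, draw_budget) {
  m <- length(maf)
  total_target <- sum(unlist(targets))
  kept_dos <- matrix(0L, nrow = total_target, ncol = m)
  kept_gval <- numeric(total_target)
  kept_liab <- numeric(total_target)
  kept_case <- integer(total_target)
  kept_sex <- character(total_target)
  row <- 0L
  drawn_total <- 0
  chunk_size <- max(1000L, min(20000L, ceiling(2e7 / m)))
  for (sex in c("F", "M")) {
    need <- targets[[sex]]
    if (sum(need) == 0) next
    got <- c(case = 0L, control = 0L)
    while (any(got < need)) {
      if (drawn_total >= draw_budget) {
        chk_stop(sprintf(
          "rejection-sampling draw budget (%g individuals) exhausted before reaching targets; prevalence may be too extreme",
          draw_budget), "chronoprs_sampling_budget_error")
      }
      nb <- as.integer(min(chunk_size, draw_budget - drawn_total))
      drawn_total <- drawn_total + nb
      dos <- matrix(rbinom(nb * m, 2L, rep(maf, each = nb)), nrow = nb)
      gval <- as.numeric(dos %*% beta_allele) - g_offset
      liab <- gval + rnorm(nb, 0, sqrt(ve[[sex]]))
      is_case <- liab > thr[[sex]]
      for (status in c("case", "control")) {
        want <- need[[status]] - got[[status]]
        if (want <= 0) next
        idx <- which(if (status == "case") is_case else !is_case)
        idx <- head(idx, want)
        if (!length(idx)) next
        rows <- row + seq_along(idx)
        kept_dos[rows, ] <- dos[idx, , drop = FALSE]
        kept_gval[rows] <- gval[idx]
        kept_liab[rows] <- liab[idx]
        kept_case[rows] <- as.integer(status == "case")
        kept_sex[rows] <- sex
        row <- row + length(idx)
        got[[status]] <- got[[status]] + length(idx)
      }
    }
  }
  ord <- order(-kept_case, kept_sex)   # cases first (F then M), then controls
  list(dosages = kept_dos[ord, , drop = FALSE], gval = kept_gval[ord],
       liab = kept_liab[ord], case = kept_case[ord], sex = kept_sex[ord])
}

#' @noRd
sample_population <- function(config, maf, beta_allele, g_offset, ve, thr) {
  n <- as.integer(config$n_cases + config$n_controls)
  m <- length(maf)
  pf <- (config$n_cases * config$prop_female_cases +
           config$n_controls * config$prop_female_controls) /
    (config$n_cases + config$n_controls)
  sex <- ifelse(runif(n) < pf, "F", "M")
  dos <- matrix(rbinom(n * m, 2L, rep(maf, each = n)), nrow = n)
  gval <- as.numeric(dos %*% beta_allele) - g_offset
  liab <- gval + rnorm(n, 0, sqrt(ve[sex]))
  list(dosages = dos, gval = gval, liab = liab,
       case = as.integer(liab > thr[sex]), sex = sex)
}

#' @noRd
rtruncnorm_pos <- function(n, mean, sd) {
  lo <- pnorm(0, mean, sd)
  qnorm(lo + runif(n) * (1 - lo), mean, sd)
}

#' @noRd
simulate_phenotypes <- function(config, ids, case, sex, gstd) {
  n <- length(ids)
  idx_case <- which(case == 1L)
  nc <- length(idx_case)
  out <- tibble::tibble(
    individual_id = ids,
    case_status = as.integer(case),
    sex = sex,
    age_at_diagnosis = NA_real_,
    follow_up_years = NA_real_,
    n_total = NA_real_, n_inpatient = NA_real_, n_outpatient = NA_real_,
    hosp_length_days = NA_real_
  )
  if (nc == 0) return(out)
  g <- gstd[idx_case]
  sx <- sex[idx_case]
  shift <- function(marker) {
    s <- rep(0, nc)
    if (marker == "hosp_length_days") {
      s[sx == "M"] <- config$sex_effects$hosp_length_male %||% 0
    } else if (marker == "n_outpatient") {
      s[sx == "F"] <- config$sex_effects$n_outpatient_female %||% 0
    }
    s
  }
  for (marker in c("n_total", "n_inpatient", "n_outpatient")) {
    lk <- config$chronicity_links[[marker]]
    mu <- exp(lk$a + shift(marker) + lk$b * g)
    out[[marker]][idx_case] <- rnbinom(nc, size = lk$size, mu = mu)
  }
  lk <- config$chronicity_links$hosp_length_days
  out$hosp_length_days[idx_case] <-
    rlnorm(nc, meanlog = lk$a + shift("hosp_length_days") + lk$b * g,
           sdlog = lk$sdlog)
  out$follow_up_years[idx_case] <-
    rtruncnorm_pos(nc, config$followup_mean_years, config$followup_sd_years)
  out$age_at_diagnosis[idx_case] <-
    rtruncnorm_pos(nc, config$age_mean, config$age_sd)
  out
}

#' @noRd
new_genotype_matrix <- function(dosages, variants) {
  stopifnot(is.matrix(dosages), ncol(dosages) == nrow(variants))
  structure(list(dosages = dosages, variants = variants),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d individuals x %d variants (%.2f%% missing)\n",
              nrow(x$dosages), ncol(x$dosages),
              100 * mean(is.na(x$dosages))))
  invisible(x)
}
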