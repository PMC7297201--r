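# Shared fixture builders and independent oracles. Everything is generated
# in code under fixed seeds; no data files.

# non-palindromic allele pairs so alignment keeps everything by default
toy_sumstats <- function(m, seed = 1, betas = NULL, pvals = NULL) {
  set.seed(seed)
  pairs <- list(c("A", "C"), c("A", "G"), c("T", "C"), c("T", "G"))
  al <- pairs[sample.int(4, m, replace = TRUE)]
  tibble::tibble(
    variant_id = sprintf("var_%05d", seq_len(m)),
    effect_allele = vapply(al, `[`, "", 1L),
    other_allele = vapply(al, `[`, "", 2L),
    effect_size = betas %||% rnorm(m, 0, 0.1),
    p_value = pvals %||% runif(m),
    effect_allele_freq = runif(m, 0.05, 0.5)
  )
}

toy_genotypes <- function(sumstats, n, seed = 1, missing = 0) {
  set.seed(seed)
  m <- nrow(sumstats)
  dos <- matrix(rbinom(n * m, 2L, rep(sumstats$effect_allele_freq, each = n)),
                nrow = n,
                dimnames = list(sprintf("ind_%05d", seq_len(n)),
                                sumstats$variant_id))
  if (missing > 0) dos[runif(length(dos)) < missing] <- NA_integer_
  chronoprs:::new_genotype_matrix(
    dos,
    tibble::tibble(variant_id = sumstats$variant_id,
                   counted_allele = sumstats$effect_allele,
                   other_allele = sumstats$other_allele))
}

# nested-loop scoring oracle, deliberately naive
brute_force_scores <- function(dosages, betas, pvals, pt) {
  n <- nrow(dosages)
  scores <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (j in seq_len(ncol(dosages))) {
      if (pvals[j] < pt) s <- s + betas[j] * dosages[i, j]
    }
    scores[i] <- s
  }
  scores
}

# hand-rolled Newton-Raphson logistic ML, independent of glm.fit
oracle_logistic_ll <- function(y, x, tol = 1e-12, max_iter = 200) {
  qrx <- qr(x)
  x <- x[, qrx$pivot[seq_len(qrx$rank)], drop = FALSE]
  beta <- rep(0, ncol(x))
  for (it in seq_len(max_iter)) {
    eta <- drop(x %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    grad <- crossprod(x, y - mu)
    hess <- crossprod(x * w, x)
    step <- solve(hess, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  eta <- drop(x %*% beta)
  sum(y * eta - log1p(exp(eta)))
}

oracle_incremental_nkr2 <- function(y, x_null, x_full) {
  n <- length(y)
  q <- mean(y)
  ll_int <- n * (q * log(q) + (1 - q) * log(1 - q))
  nk <- function(ll0, ll1) {
    (1 - exp(2 * (ll0 - ll1) / n)) / (1 - exp(2 * ll0 / n))
  }
  nk(ll_int, oracle_logistic_ll(y, x_full)) -
    nk(ll_int, oracle_logistic_ll(y, x_null))
}

# small cohort with real score-phenotype coupling, for enrichment tests
small_cohort <- function(seed = 1, n_cases = 120, n_controls = 120, ...) {
  cfg <- sim_config(preset = "test", n_cases = n_cases,
                    n_controls = n_controls, ...)
  ss <- simulate_summary_stats(cfg, seed = seed)
  coh <- simulate_cohort(cfg, ss, seed = seed)
  panel <- align_variants(coh$genotypes, ss, drop_ambiguous = FALSE)
  grps <- standardize_grps(compute_grps(panel, ss, pt = 0.05))
  list(cfg = cfg, sumstats = ss, cohort = coh, panel = panel, grps = grps)
}

# hand-built phenotype table (cases unless stated otherwise)
toy_pheno <- function(n_total = NULL, n_inpatient = NULL, n_outpatient = NULL,
                      hosp_length_days = NULL, follow_up = NULL, sex = NULL,
                      case_status = NULL, ids = NULL) {
  n <- max(lengths(list(n_total, n_inpatient, n_outpatient, hosp_length_days,
                        follow_up, sex, case_status, ids)))
  tibble::tibble(
    individual_id = ids %||% sprintf("ind_%05d", seq_len(n)),
    case_status = case_status %||% rep(1L, n),
    sex = sex %||% rep(c("F", "M"), length.out = n),
    age_at_diagnosis = rep(30, n),
    follow_up_years = follow_up %||% rep(10, n),
    n_total = n_total %||% rep(0, n),
    n_inpatient = n_inpatient %||% rep(0, n),
    n_outpatient = n_outpatient %||% rep(0, n),
    hosp_length_days = hosp_length_days %||% rep(0, n)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# chronicity links with every slope zeroed (complete phenotype null)
null_links <- function(cfg = sim_config()) {
  lapply(cfg$chronicity_links, function(lk) { lk$b <- 0; lk })
}
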