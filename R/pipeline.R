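#' Run the full simulate-score-associate-enrich pipeline
#'
#' Orchestrates all stages under one master seed: simulates discovery summary
#' statistics and the ascertained cohort, aligns and scores at each p-value
#' threshold, fits the case-only chronicity models (all four markers at every
#' threshold, plus sex-stratified and interaction models at the primary
#' threshold), runs the four chronicity-enrichment permutation tests and the
#' sex prediction-gap test, and assembles report tables: a case descriptives
#' table (marker by sex, mean and sd), an association table, and an
#' enrichment table.
#'
#' @param config a [sim_config()] object.
#' @param seed master seed; defaults to `config$seed`. Identical
#'   `(config, seed)` reruns produce byte-identical output files.
#' @param pt_thresholds p-value thresholds to score; the conventional set is
#'   0.05, 0.1, 0.01.
#' @param primary_pt the threshold used for stratified models and
#'   enrichment tests (0.05: the threshold with the most explanatory power in
#'   large discovery GWAS).
#' @param n_perm permutation draws per enrichment/sex-gap test.
#' @param transform outcome transform passed to [make_outcome()].
#' @param include_batch adjust the case-control logistic models for batch
#'   (the case-only linear models always adjust for batch).
#' @param out_dir if non-`NULL`, report tables, simulated data and a
#'   permutation-distribution JSON sidecar are written there, each headed by
#'   a `# config_hash=..., seed=...` comment.
#' @param verbose log stage progress and timings.
#'
#' @return A `report_bundle`: list with `descriptives`, `association`,
#'   `enrichment` (tibbles), `enrichment_results` / `sex_gap` (full objects),
#'   `data` (the simulated cohort and scores) and `metadata`.
#' @export
run_pipeline <- function(config, seed = config$seed,
                         pt_thresholds = c(0.05, 0.1, 0.01),
                         primary_pt = 0.05, n_perm = 1000,
                         transform = "rate_log1p_z",
                         include_batch = FALSE,
                         out_dir = NULL, verbose = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  if (!primary_pt %in% pt_thresholds) {
    pt_thresholds <- c(primary_pt, pt_thresholds)
  }
  timings <- list()
  say <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e) {
      chk_stop(sprintf("pipeline stage `%s` failed: %s", name,
                       conditionMessage(e)),
               "chronoprs_pipeline_error", stage = name, parent = e)
    })
    timings[[name]] <<- proc.time()[["elapsed"]] - t0
    say("stage %-12s done in %.2fs", name, timings[[name]])
    res
  }

  say("pipeline seed %d (config hash %s)", as.integer(seed),
      config_hash(config))
  sumstats <- stage("simulate", simulate_summary_stats(config, seed))
  cohort <- stage("cohort", simulate_cohort(config, sumstats, seed))
  pheno <- cohort$phenotypes
  covars <- cohort$covariates

  # simulated genotypes are on the discovery strand by construction, so
  # palindromic variants are unambiguous here and kept
  panel <- stage("align",
                 align_variants(cohort$genotypes, sumstats,
                                drop_ambiguous = FALSE))
  scores <- stage("score", {
    lapply(setNames(pt_thresholds, paste0("pt_", pt_thresholds)), function(pt) {
      standardize_grps(compute_grps(panel, sumstats, pt = pt))
    })
  })
  primary <- scores[[paste0("pt_", primary_pt)]]

  descriptives <- stage("describe", describe_chronicity(pheno))

  association <- stage("associate", {
    rows <- list()
    for (marker in chronicity_markers()) {
      outc <- make_outcome(pheno, marker, transform = transform)
      for (pt in pt_thresholds) {
        rows[[length(rows) + 1L]] <- cbind(
          pt = pt,
          fit_case_only(outc, scores[[paste0("pt_", pt)]], covars, pheno,
                        stratum = "all"))
      }
      for (st in c("female", "male")) {
        rows[[length(rows) + 1L]] <- cbind(
          pt = primary_pt,
          fit_case_only(outc, primary, covars, pheno, stratum = st))
      }
      rows[[length(rows) + 1L]] <- cbind(
        pt = primary_pt, fit_interaction(outc, primary, covars, pheno))
    }
    tibble::as_tibble(do.call(rbind, rows))
  })

  enrich_results <- stage("enrich", {
    lapply(default_chronicity_filters(), function(f) {
      permutation_enrichment_test(pheno, primary, covars, f,
                                  n_perm = n_perm,
                                  seed = substream_seed(seed, f$marker),
                                  include_batch = include_batch)
    })
  })
  sex_gap <- stage("sexgap", {
    sex_prediction_gap_test(pheno, primary, covars, n_perm = n_perm,
                            seed = substream_seed(seed, "sexgap"),
                            include_batch = include_batch)
  })
  enrichment <- enrichment_table(enrich_results, sex_gap)

  bundle <- structure(list(
    descriptives = descriptives,
    association = association,
    enrichment = enrichment,
    enrichment_results = enrich_results,
    sex_gap = sex_gap,
    data = list(sumstats = sumstats, cohort = cohort, scores = scores),
    metadata = list(config = config, config_hash = config_hash(config),
                    seed = as.integer(seed), n_perm = as.integer(n_perm),
                    primary_pt = primary_pt,
                    package_version = as.character(utils::packageVersion("chronoprs")),
                    timings = timings)
  ), class = "report_bundle")

  if (!is.null(out_dir)) {
    stage("write", write_report_bundle(bundle, out_dir))
  }
  bundle
}

#' Case chronicity descriptives by sex
#'
#' Mean and sd of each chronicity marker among cases, overall and per sex.
#'
#' @param pheno phenotype table.
#' @return Tibble: one row per marker with `mean_total`, `sd_total`,
#'   `mean_female`, `sd_female`, `mean_male`, `sd_male`.
#' @export
describe_chronicity <- function(pheno) {
  cases <- pheno[pheno$case_status == 1L, , drop = FALSE]
  one <- function(marker) {
    x <- cases[[marker]]
    f <- x[cases$sex == "F"]; m <- x[cases$sex == "M"]
    tibble::tibble(marker = marker,
                   mean_total = mean(x), sd_total = sd(x),
                   mean_female = mean(f), sd_female = sd(f),
                   mean_male = mean(m), sd_male = sd(m))
  }
  do.call(rbind, lapply(chronicity_markers(), one))
}

#' @noRd
enrichment_table <- function(enrich_results, sex_gap) {
  rows <- lapply(enrich_results, function(r) {
    tibble::tibble(subsample = r$filter$marker,
                   threshold = r$filter$threshold,
                   n_selected_cases = r$n_selected_cases,
                   nkr2_incremental = r$observed_nkr2,
                   nkr2_full_model = r$observed_full_model_nkr2,
                   baseline_incremental = r$baseline_nkr2,
                   p_perm = r$p_perm)
  })
  sexrows <- tibble::tibble(
    subsample = c("females", "males"),
    threshold = NA_real_,
    n_selected_cases = NA_integer_,
    nkr2_incremental = c(sex_gap$nkr2_female, sex_gap$nkr2_male),
    nkr2_full_model = c(sex_gap$nkr2_female_full_model,
                        sex_gap$nkr2_male_full_model),
    baseline_incremental = NA_real_,
    p_perm = sex_gap$p_perm
  )
  rbind(do.call(rbind, rows), sexrows)
}

#' Write a report bundle to disk
#'
#' Writes `descriptives.tsv`, `association.tsv`, `enrichment.tsv`, the
#' simulated inputs (`summary_stats.tsv`, `phenotypes.tsv`,
#' `covariates.tsv`, per-threshold `scores_pt*.tsv`), `config.yaml`, and
#' `permutations.json` (permutation distributions and seeds). Every
#' tab-delimited file is headed by a `# config_hash=..., seed=...` comment.
#'
#' @param bundle a `report_bundle` from [run_pipeline()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report_bundle <- function(bundle, out_dir) {
  stopifnot(inherits(bundle, "report_bundle"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cmt <- tsv_header_comment(bundle$metadata$config, bundle$metadata$seed)
  p <- function(f) file.path(out_dir, f)
  write_tsv_commented(bundle$descriptives, p("descriptives.tsv"), cmt)
  write_tsv_commented(bundle$association, p("association.tsv"), cmt)
  write_tsv_commented(bundle$enrichment, p("enrichment.tsv"), cmt)
  write_summary_stats(bundle$data$sumstats, p("summary_stats.tsv"),
                      include_truth = TRUE, comment = cmt)
  write_phenotypes(bundle$data$cohort$phenotypes, p("phenotypes.tsv"), cmt)
  write_covariates(bundle$data$cohort$covariates, p("covariates.tsv"), cmt)
  for (nm in names(bundle$data$scores)) {
    write_scores(bundle$data$scores[[nm]], p(paste0("scores_", nm, ".tsv")),
                 cmt)
  }
  write_sim_config(bundle$metadata$config, p("config.yaml"))
  perms <- c(
    lapply(bundle$enrichment_results, function(r) {
      list(marker = r$filter$marker, threshold = r$filter$threshold,
           seed = r$seed, p_perm = r$p_perm, perm_values = r$perm_values)
    }),
    list(sex_gap = list(seed = bundle$sex_gap$seed,
                        p_perm = bundle$sex_gap$p_perm,
                        observed_gap = bundle$sex_gap$observed_gap,
                        perm_values = bundle$sex_gap$perm_values))
  )
  names(perms)[seq_along(bundle$enrichment_results)] <-
    vapply(bundle$enrichment_results, function(r) r$filter$marker, "")
  jsonlite::write_json(
    list(config_hash = bundle$metadata$config_hash,
         seed = bundle$metadata$seed, permutations = perms),
    p("permutations.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf("<report_bundle> seed %d, config hash %s\n",
              x$metadata$seed, x$metadata$config_hash))
  cat("\nCase chronicity descriptives:\n")
  print(as.data.frame(x$descriptives), digits = 4)
  cat("\nEnrichment (incremental Nagelkerke R2, primary threshold):\n")
  print(as.data.frame(x$enrichment), digits = 4)
  invisible(x)
}
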