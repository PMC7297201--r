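#' Align target genotypes to discovery summary statistics
#'
#' Matches variants by identifier and harmonizes the counted allele to the
#' summary-statistic effect allele. Each genotype variant receives exactly one
#' action: `keep` (counted allele already the effect allele), `flip` (alleles
#' swapped; dosage recoded as `2 - g`), or `drop` with a reason
#' (`"no-summary-stat"`, `"allele-mismatch"`, or `"strand-ambiguous"` for A/T
#' and C/G palindromic pairs when `drop_ambiguous` is set).
#'
#' @param genotypes a `genotype_matrix` (see [simulate_cohort()] or
#'   [read_dosages()]).
#' @param sumstats summary-statistic table with `variant_id`,
#'   `effect_allele`, `other_allele`.
#' @param drop_ambiguous drop strand-ambiguous (palindromic) variants.
#'   Default `TRUE`: without strand information an A/T or C/G variant cannot
#'   be unambiguously oriented.
#'
#' @return An `aligned_panel`: list with `dosages` (recoded matrix counting
#'   the effect allele, kept variants only), `variants` (metadata for kept
#'   variants), `actions` (one row per genotype variant: `variant_id`,
#'   `action`, `reason`), and `counts` (named keep/flip/drop totals).
#' @export
align_variants <- function(genotypes, sumstats, drop_ambiguous = TRUE) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (ncol(genotypes$dosages) == 0 || nrow(sumstats) == 0) {
    chk_stop("empty genotype matrix or summary-statistic table",
             "chronoprs_input_error")
  }
  gv <- genotypes$variants
  idx <- match(gv$variant_id, sumstats$variant_id)
  action <- rep("drop", nrow(gv))
  reason <- rep(NA_character_, nrow(gv))
  matched <- !is.na(idx)
  reason[!matched] <- "no-summary-stat"

  ea <- sumstats$effect_allele[idx]
  oa <- sumstats$other_allele[idx]
  pal <- paste0(pmin(gv$counted_allele, gv$other_allele),
                pmax(gv$counted_allele, gv$other_allele)) %in% c("AT", "CG")
  same <- matched & gv$counted_allele == ea & gv$other_allele == oa
  swap <- matched & gv$counted_allele == oa & gv$other_allele == ea
  if (drop_ambiguous) {
    amb <- matched & pal & (same | swap)
    reason[amb] <- "strand-ambiguous"
    same <- same & !amb
    swap <- swap & !amb
  }
  mism <- matched & !same & !swap & is.na(reason)
  reason[mism] <- "allele-mismatch"
  action[same] <- "keep"
  action[swap] <- "flip"

  keep_idx <- which(action != "drop")
  if (!length(keep_idx)) {
    chk_stop("no variants survive allele alignment (empty panel)",
             "chronoprs_empty_panel_error")
  }
  dos <- genotypes$dosages[, keep_idx, drop = FALSE]
  flip_cols <- which(action[keep_idx] == "flip")
  if (length(flip_cols)) {
    dos[, flip_cols] <- 2 - dos[, flip_cols, drop = FALSE]
  }
  variants <- tibble::tibble(
    variant_id = gv$variant_id[keep_idx],
    effect_allele = ea[keep_idx],
    other_allele = oa[keep_idx],
    action = action[keep_idx]
  )
  structure(list(
    dosages = dos,
    variants = variants,
    actions = tibble::tibble(variant_id = gv$variant_id, action = action,
                             reason = reason),
    counts = c(keep = sum(action == "keep"), flip = sum(action == "flip"),
               drop = sum(action == "drop"))
  ), class = "aligned_panel")
}

#' @export
print.aligned_panel <- function(x, ...) {
  cat(sprintf("<aligned_panel> %d individuals x %d variants (keep %d, flip %d, drop %d)\n",
              nrow(x$dosages), ncol(x$dosages),
              x$counts[["keep"]], x$counts[["flip"]], x$counts[["drop"]]))
  invisible(x)
}

#' Compute the genomic risk profile score (GRPS)
#'
#' Forms the weighted allele sum `score_i = sum_j beta_j * dosage_ij` over the
#' variants whose discovery p-value falls strictly below the threshold `pt`.
#' Missing dosages are mean-imputed as twice the target-sample effect-allele
#' frequency at that variant (no external reference panel required).
#'
#' @param panel an `aligned_panel` from [align_variants()].
#' @param sumstats summary-statistic table carrying `effect_size` and
#'   `p_value` for the panel's variants.
#' @param pt p-value threshold in (0, 1]; variants with `p_value < pt` are
#'   scored. 0.05 is the conventional primary threshold.
#' @param missing_policy `"impute_freq"` (default; impute `2 * eaf` from the
#'   target sample) or `"fail"` (error on any missing dosage).
#'
#' @return A `grps` object: tibble with `individual_id` and `score`, plus
#'   attributes `pt`, `n_variants_used`, and `standardized = FALSE`.
#' @examples
#' cfg <- sim_config(preset = "test", n_cases = 30, n_controls = 30)
#' ss <- simulate_summary_stats(cfg, seed = 2)
#' coh <- simulate_cohort(cfg, ss, seed = 2)
#' panel <- align_variants(coh$genotypes, ss)
#' g <- compute_grps(panel, ss, pt = 0.05)
#' attr(g, "n_variants_used")
#' @export
compute_grps <- function(panel, sumstats, pt = 0.05,
                         missing_policy = c("impute_freq", "fail")) {
  stopifnot(inherits(panel, "aligned_panel"))
  missing_policy <- match.arg(missing_policy)
  if (!is.numeric(pt) || length(pt) != 1 || pt <= 0 || pt > 1) {
    chk_stop("`pt` must be a single p-value threshold in (0, 1]",
             "chronoprs_input_error")
  }
  idx <- match(panel$variants$variant_id, sumstats$variant_id)
  if (anyNA(idx)) {
    chk_stop("panel contains variants absent from `sumstats`",
             "chronoprs_input_error")
  }
  use <- which(sumstats$p_value[idx] < pt)
  if (!length(use)) {
    chk_stop(sprintf("no variants pass the p-value threshold pt=%g", pt),
             "chronoprs_empty_threshold_error")
  }
  dos <- panel$dosages[, use, drop = FALSE]
  beta <- sumstats$effect_size[idx][use]
  if (anyNA(dos)) {
    if (missing_policy == "fail") {
      chk_stop("missing dosages present and missing_policy = \"fail\"",
               "chronoprs_input_error")
    }
    eaf <- colMeans(dos, na.rm = TRUE) / 2
    if (anyNA(eaf)) {
      chk_stop("a selected variant has no observed dosages; cannot impute its frequency",
               "chronoprs_input_error")
    }
    na_idx <- which(is.na(dos), arr.ind = TRUE)
    dos[na_idx] <- 2 * eaf[na_idx[, 2]]
  }
  score <- as.numeric(dos %*% beta)
  new_grps(rownames(panel$dosages) %||% paste0("ind_", seq_along(score)),
           score, pt = pt, n_variants_used = length(use),
           standardized = FALSE)
}

#' @noRd
new_grps <- function(ids, score, pt, n_variants_used, standardized) {
  out <- tibble::tibble(individual_id = ids, score = score)
  attr(out, "pt") <- pt
  attr(out, "n_variants_used") <- n_variants_used
  attr(out, "standardized") <- standardized
  class(out) <- c("grps", class(out))
  out
}

#' Standardize a GRPS vector
#'
#' Z-scores the score within the analysis sample so regression coefficients
#' are per standard deviation of the score.
#'
#' @param scores a `grps` object from [compute_grps()].
#' @return The z-scored `grps` with the `standardized` attribute set.
#' @export
standardize_grps <- function(scores) {
  stopifnot(inherits(scores, "grps"))
  if (nrow(scores) < 2) {
    chk_stop("need at least 2 individuals to standardize a score",
             "chronoprs_input_error")
  }
  s <- sd(scores$score)
  if (!is.finite(s) || s == 0) {
    chk_stop("score has zero variance; cannot standardize (degenerate score)",
             "chronoprs_degenerate_score_error")
  }
  new_grps(scores$individual_id, (scores$score - mean(scores$score)) / s,
           pt = attr(scores, "pt"),
           n_variants_used = attr(scores, "n_variants_used"),
           standardized = TRUE)
}

#' @export
print.grps <- function(x, ...) {
  cat(sprintf("<grps> %d individuals, pt=%g, %d variants used%s\n",
              nrow(x), attr(x, "pt"), attr(x, "n_variants_used"),
              if (isTRUE(attr(x, "standardized"))) ", standardized" else ""))
  NextMethod()
}
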