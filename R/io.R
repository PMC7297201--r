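#' Read and write the tab-delimited interchange formats
#'
#' Summary statistics travel as a tab-delimited table with header
#' `variant_id, effect_allele, other_allele, beta, p, eaf`; dosages as a
#' matrix with the individual id in the first column and one column per
#' variant, headed `variant_id:counted_allele:other_allele`; phenotypes,
#' covariates and scores as plain tab-delimited tables with headers. Lines
#' starting with `#` are ignored on read.
#'
#' @param x object to write ([simulate_summary_stats()] output, a
#'   `genotype_matrix`, a phenotype/covariate tibble, or a `grps`).
#' @param path file path.
#' @param include_truth also write the simulator-only `true_effect` and `se`
#'   columns.
#' @param comment optional `#`-prefixed header line(s).
#' @return Readers return tibbles (or a `genotype_matrix`); writers return
#'   `path` invisibly.
#' @name chronoprs-io
NULL

#' @rdname chronoprs-io
#' @export
write_summary_stats <- function(x, path, include_truth = FALSE,
                                comment = NULL) {
  out <- data.frame(variant_id = x$variant_id,
                    effect_allele = x$effect_allele,
                    other_allele = x$other_allele,
                    beta = x$effect_size, p = x$p_value,
                    eaf = x$effect_allele_freq)
  if (include_truth) {
    out$se <- x$se
    out$true_effect <- x$true_effect
  }
  write_tsv_commented(out, path, comment)
}

#' @rdname chronoprs-io
#' @export
read_summary_stats <- function(path) {
  d <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("variant_id", "effect_allele", "other_allele", "beta", "p", "eaf")
  if (!all(need %in% names(d))) {
    chk_stop(paste0("summary-statistic file missing column(s): ",
                    paste(setdiff(need, names(d)), collapse = ", ")),
             "chronoprs_io_error")
  }
  out <- tibble::tibble(variant_id = as.character(d$variant_id),
                        effect_allele = d$effect_allele,
                        other_allele = d$other_allele,
                        effect_size = d$beta, p_value = d$p,
                        effect_allele_freq = d$eaf)
  if ("se" %in% names(d)) out$se <- d$se
  if ("true_effect" %in% names(d)) out$true_effect <- d$true_effect
  out
}

#' @rdname chronoprs-io
#' @export
write_dosages <- function(x, path, comment = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  hdr <- paste(x$variants$variant_id, x$variants$counted_allele,
               x$variants$other_allele, sep = ":")
  d <- data.frame(individual_id = rownames(x$dosages), x$dosages,
                  check.names = FALSE, row.names = NULL)
  names(d) <- c("individual_id", hdr)
  write_tsv_commented(d, path, comment)
}

#' @rdname chronoprs-io
#' @export
read_dosages <- function(path) {
  d <- read.delim(path, comment.char = "#", check.names = FALSE,
                  stringsAsFactors = FALSE)
  ids <- as.character(d[[1]])
  mat <- as.matrix(d[, -1, drop = FALSE])
  parts <- strsplit(colnames(mat), ":", fixed = TRUE)
  if (any(lengths(parts) != 3)) {
    chk_stop("dosage column headers must be `variant_id:counted_allele:other_allele`",
             "chronoprs_io_error")
  }
  variants <- tibble::tibble(
    variant_id = vapply(parts, `[`, "", 1L),
    counted_allele = vapply(parts, `[`, "", 2L),
    other_allele = vapply(parts, `[`, "", 3L)
  )
  dimnames(mat) <- list(ids, variants$variant_id)
  new_genotype_matrix(mat, variants)
}

#' @rdname chronoprs-io
#' @export
write_phenotypes <- function(x, path, comment = NULL) {
  write_tsv_commented(x, path, comment)
}

#' @rdname chronoprs-io
#' @export
read_phenotypes <- function(path) {
  d <- tibble::as_tibble(read.delim(path, comment.char = "#",
                                    stringsAsFactors = FALSE))
  d$individual_id <- as.character(d$individual_id)
  d
}

#' @rdname chronoprs-io
#' @export
write_covariates <- write_phenotypes

#' @rdname chronoprs-io
#' @export
read_covariates <- read_phenotypes

#' @rdname chronoprs-io
#' @export
write_scores <- function(x, path, comment = NULL) {
  stopifnot(inherits(x, "grps"))
  write_tsv_commented(
    data.frame(individual_id = x$individual_id, score = x$score,
               pt = attr(x, "pt")),
    path, comment)
}

#' @rdname chronoprs-io
#' @export
read_scores <- function(path) {
  d <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  new_grps(as.character(d$individual_id), d$score, pt = d$pt[1],
           n_variants_used = NA_integer_, standardized = FALSE)
}
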