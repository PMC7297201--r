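#' @noRd
chk_stop <- function(msg, class, ...) {
  rlang::abort(msg, class = c(class, "chronoprs_error"), ...)
}

#' @noRd
assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 integerish = FALSE, closed_lower = TRUE,
                                 closed_upper = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (closed_lower) x >= lower else x > lower) &&
    (if (closed_upper) x <= upper else x < upper) &&
    (!integerish || abs(x - round(x)) < 1e-8)
  if (!ok) {
    chk_stop(sprintf("invalid configuration field `%s`: %s", name,
                     paste(format(x), collapse = ", ")),
             "chronoprs_config_error", field = name)
  }
  invisible(x)
}

# Deterministic per-stage sub-seeds derived from one master seed, so that e.g.
# enlarging the variant panel does not shift the phenotype random stream.
# Values kept strictly below 2^31.
#' @noRd
substream_seed <- function(seed, stage) {
  stopifnot(length(stage) == 1L, is.character(stage))
  h <- 97
  for (b in utf8ToInt(stage)) {
    # all intermediates stay below 2^53, so the double arithmetic is exact
    h <- (bitwXor(as.integer(h), b) * 1664525 + 1013904223) %% 2147483563
  }
  as.integer((as.numeric(seed) %% 2147483563 * 40014 + h) %% 2147483563 + 1)
}

# Run `expr` under a local RNG state seeded by `seed`; the caller's RNG state
# is untouched.
#' @noRd
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' @noRd
config_hash <- function(config) {
  rlang::hash(config[setdiff(names(config), "preset")])
}

#' @noRd
tsv_header_comment <- function(config, seed) {
  sprintf("# config_hash=%s, seed=%d", config_hash(config), as.integer(seed))
}

# Write a tab-delimited table with a `# config_hash=..., seed=...` first line.
#' @noRd
write_tsv_commented <- function(x, path, comment = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(comment, con)
  write.table(as.data.frame(x), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
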