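# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so library calls never perturb user RNG.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)

warn_fmt <- function(...) warning(sprintf(...), call. = FALSE)

# Label-aware conformity check: both objects must carry the same subject
# labels in the same order. Positional agreement alone is not trusted.
check_subjects <- function(a, b, what_a, what_b) {
  if (is.null(a) || is.null(b)) {
    stop_fmt("subject labels missing when aligning %s with %s", what_a, what_b)
  }
  if (length(a) != length(b) || !all(a == b)) {
    stop_fmt("subject order of %s does not match %s", what_a, what_b)
  }
  invisible(TRUE)
}

# Deterministic TSV writer used for all tabular outputs: fixed quoting and
# number formatting so repeated runs are byte-identical.
write_tsv_det <- function(df, path, row_names = FALSE) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) {
    out <- sprintf("%.17g", x)
    out[is.na(x)] <- "NA"
    out
  })
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = row_names, col.names = TRUE)
  invisible(path)
}
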