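# Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG state
#'
#' Sets the seed, runs `expr`, and restores the caller's `.Random.seed`, so
#' seeded operations never perturb the global RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# Consistent number formatting for all TSV output: 6-decimal floats, plain
# integers, everything else as-is.
fmt_num <- function(x) {
  if (is.double(x)) sprintf("%.6f", x) else as.character(x)
}

write_tsv_fixed <- function(df, path) {
  out <- vapply(df, fmt_num, character(nrow(df)))
  if (nrow(df) == 1L) out <- matrix(out, nrow = 1L, dimnames = list(NULL, names(df)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df) > 0L)
    writeLines(apply(out, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

stop_format <- function(...) {
  stop(sprintf(...), call. = FALSE)
}
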