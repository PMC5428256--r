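# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the RNG seeded at `seed`, then restores the caller's
#' RNG state, so seeded generators do not perturb surrounding simulations.
#' With `seed = NULL` the current RNG stream is used unchanged.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1) # materialise a RNG state so it can be restored
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  code
}

# Derive a reproducible sub-stream seed from a master seed, staying inside
# 32-bit integer range.
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 97 + offset) %% 2147483647L)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_range <- function(x, name) {
  if (length(x) != 2L || !is.numeric(x) || anyNA(x) || x[1] > x[2])
    stopf("'%s' must be a numeric (low, high) pair with low <= high", name)
  invisible(x)
}

check_number <- function(x, name, min = -Inf) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min)
    stopf("'%s' must be a single number >= %s", name, min)
  invisible(x)
}

# Columns required in a data.frame, with a helpful error naming the absentee.
check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L)
    stopf("%s is missing column(s): %s", what, paste(missing, collapse = ", "))
  invisible(df)
}
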