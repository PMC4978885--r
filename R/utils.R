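# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr with a temporary RNG state seeded at `seed`; the caller's
# RNG state is untouched.  All simulators route their randomness through
# this so a fixed seed gives byte-identical output.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

assert_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < min || x > max)
    stop(sprintf("'%s' must be a single number in [%s, %s]", name,
                 format(min), format(max)), call. = FALSE)
  invisible(x)
}

# standard error of the mean
se_mean <- function(x) {
  if (length(x) < 2) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

is_reads_df <- function(x) {
  is.data.frame(x) && all(c("read_id", "bases") %in% names(x))
}

check_reads_df <- function(x, name = "reads") {
  if (!is_reads_df(x))
    stop(sprintf("'%s' must be a data.frame with columns read_id and bases",
                 name), call. = FALSE)
  if (anyDuplicated(x$read_id))
    stop(sprintf("'%s' has duplicated read_id values", name), call. = FALSE)
  invisible(x)
}
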