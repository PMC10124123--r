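#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the RNG seed for the duration of `expr` and restores the caller's
#' RNG state afterwards, so simulation helpers never leak randomness into
#' (or depend on) the global stream.
#'
#' @param seed integer scalar seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic stream of sub-seeds derived from a base seed; keeps every
# derived seed a positive 32-bit integer.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + index * 16807) %% 2147483629 + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_mixcount <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "mixcount_error")))
}

# truncated normal via rejection (bounds always within a few sd of the mean
# for the size distributions used here, so rejection is cheap)
rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (n == 0L) return(numeric(0))
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    x <- rnorm(length(need), mean, sd)
    ok <- x >= lower & x <= upper
    out[need[ok]] <- x[ok]
    need <- need[!ok]
  }
  out
}
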