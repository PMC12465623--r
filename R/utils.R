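# Internal helpers shared across modules.

#' Stop with a classed condition
#' @noRd
abort <- function(msg, class) {
  stop(structure(
    class = c(class, "emgait_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' Evaluate an expression under a given seed, restoring the RNG state
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Nearest odd integer >= 3
#' @noRd
odd_window <- function(k) {
  k <- max(3L, as.integer(round(k)))
  if (k %% 2L == 0L) k + 1L else k
}

#' Linear resampling of a vector to a target length
#' @noRd
resample_to <- function(x, n_out) {
  if (length(x) == n_out) return(as.numeric(x))
  approx(seq_along(x), x, xout = seq(1, length(x), length.out = n_out))$y
}

#' Check a scalar is a finite number
#' @noRd
is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
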