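#' Round half away from zero
#'
#' Presentation-layer rounding used for all reported percentages: exact halves
#' round away from zero (81.25 -> 81.3, -4.755 -> -4.8), unlike [base::round()]
#' which rounds halves to even. Intermediates are always kept at full
#' precision; this is applied only when a number is reported.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the RNG seeded to `seed`, then restores the caller's RNG
#' state, so that generators are deterministic without clobbering the session
#' stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Derive a child seed below 2^31 from a base seed and a stream label.
child_seed <- function(seed, stream) {
  (as.numeric(seed) * 48271 + as.numeric(stream) * 16807) %% 2147483629 + 1
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Minimal-overhead tibble constructor for hot inner loops (no recycling,
# no name repair); all columns must already have equal length.
fast_tb <- function(...) {
  l <- list(...)
  tibble::new_tibble(l, nrow = if (length(l)) length(l[[1L]]) else 0L)
}
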