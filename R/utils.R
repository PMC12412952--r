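## Internal helpers shared across modules.

#' Derive a per-stream seed from a root seed
#'
#' All randomness in the package flows from a single root seed. Each
#' stochastic stage draws from its own stream, derived deterministically so
#' that, e.g., regenerating the taxa table does not perturb the core survey.
#' Streams: 1 core survey, 2 dPCR wells, 3 spiking experiment, 4 taxa table,
#' 5 nutrients, 6 rarefaction, 7 permutation tests.
#'
#' @param seed integer root seed.
#' @param stream integer stream index (>= 0).
#' @return An integer seed, strictly below 2^31.
#' @keywords internal
streamSeed <- function(seed, stream = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  (abs(as.integer(seed)) + as.integer(stream) * 1000003L) %% 2147483629L
}

## Trapezoidal quadrature on irregular knots.
trapzIntegral <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L, !is.unsorted(x))
  sum(diff(x) * (y[-length(y)] + y[-1L]) / 2)
}

## stop() with a consistent prefix naming the violated condition.
failIf <- function(cond, msg) {
  if (isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

isCount <- function(x) is.numeric(x) && all(is.finite(x)) && all(x >= 0) &&
  all(abs(x - round(x)) < 1e-8)
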