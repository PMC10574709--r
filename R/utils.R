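# Internal helpers shared across modules.

#' Derive a child seed from a master seed and a stream name
#'
#' All randomness in the package flows from a single integer seed.  Stages and
#' samples obtain their own reproducible streams by hashing a descriptive key
#' together with the master seed, so toggling one stage never shifts the draws
#' of another.
#'
#' @param seed master integer seed.
#' @param ... character or integer key components identifying the stream.
#' @return an integer in \[0, 2^31 - 2\] suitable for `set.seed()`.
#' @export
derive_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  # polynomial rolling hash mod a Mersenne prime; stays well inside 32-bit
  m <- 2147483647
  h <- 0
  for (cp in utf8ToInt(key)) h <- (h * 131 + cp) %% m
  as.integer(h)
}

# Exact integral of the piecewise-linear interpolant of (x, y) from x[1] to
# each value in `at`.  `at` must lie within range(x); x strictly increasing.
trapz_cum_at <- function(x, y, at) {
  if (any(at < x[1] - 1e-12) || any(at > x[length(x)] + 1e-12)) {
    stop("integration bound outside the spectrum grid")
  }
  at <- pmin(pmax(at, x[1]), x[length(x)])
  dx <- diff(x)
  Fg <- c(0, cumsum(dx * (y[-length(y)] + y[-1]) / 2))
  idx <- findInterval(at, x, rightmost.closed = TRUE)
  frac <- (at - x[idx]) / dx[pmin(idx, length(dx))]
  frac[idx >= length(x)] <- 0
  yat <- y[idx] + frac * (y[pmin(idx + 1, length(y))] - y[idx])
  Fg[idx] + (at - x[idx]) * (y[idx] + yat) / 2
}

# Lorentzian (Cauchy) line shape parameterized by peak height and
# half-width-at-half-maximum, the standard model of an NMR resonance.
lorentzian <- function(ppm, center, hwhm, height) {
  height * hwhm^2 / ((ppm - center)^2 + hwhm^2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
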