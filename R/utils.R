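## Small shared helpers.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Wilson score interval for a binomial proportion
#'
#' @param x number of successes.
#' @param n number of trials.
#' @param conf confidence level.
#' @return named numeric: \code{estimate}, \code{lower}, \code{upper}.
#' @examples
#' wilsonInterval(140, 200)
#' @export
wilsonInterval <- function(x, n, conf = 0.95) {
  stopifnot(n >= 1, x >= 0, x <= n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(estimate = p, lower = max(0, centre - half), upper = min(1, centre + half))
}

## Lognormal meanlog/sdlog from an arithmetic mean and coefficient of
## variation (the scale on which enrichment spread is specified).
lognormalParams <- function(mean, cv) {
  stopifnot(mean > 0, cv >= 0)
  s2 <- log(1 + cv^2)
  list(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

## Deterministic fan-out of one global seed into per-component seeds,
## kept below .Machine$integer.max.
fanOutSeeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

## Geometric mean of strictly positive values.
geoMean <- function(x) exp(mean(log(x)))
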