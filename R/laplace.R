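#' The Laplace impulse law, parameterized by its standard deviation
#'
#' The random velocity changes of the model follow a Laplace
#' (double-exponential) law
#' \deqn{p(q) = \frac{1}{\sqrt{2\sigma^2}}
#'       \exp\!\left(-\sqrt{\frac{2(q-\bar q)^2}{\sigma^2}}\right)}
#' written in terms of its mean \eqn{\bar q} and standard deviation
#' \eqn{\sigma} (the conventional scale parameter is \eqn{b = \sigma/\sqrt2}).
#' `dlaplace_sd`, `plaplace_sd` and `qlaplace_sd` are the density, CDF and
#' quantile function; `rlaplace_sd` draws by inversion of the CDF, so a fixed
#' seed reproduces the sample sequence exactly (and matches the draws used
#' inside the compiled simulator).
#'
#' @param q,p,n Evaluation points, probabilities, or sample count.
#' @param q_bar Mean of the law (cm/s in model use).
#' @param sigma Standard deviation, must be > 0.
#' @return Density values, probabilities, quantiles, or a numeric sample.
#' @examples
#' dlaplace_sd(0, 0, 1)       # 1/sqrt(2)
#' sd(rlaplace_sd(1e4, 0, 1.25))
#' @export
dlaplace_sd <- function(q, q_bar = 0, sigma = 1) {
  stopifnot(sigma > 0)
  exp(-sqrt(2) * abs(q - q_bar) / sigma) / (sqrt(2) * sigma)
}

#' @rdname dlaplace_sd
#' @export
plaplace_sd <- function(q, q_bar = 0, sigma = 1) {
  stopifnot(sigma > 0)
  z <- (q - q_bar) / (sigma / sqrt(2))
  ifelse(z < 0, 0.5 * exp(z), 1 - 0.5 * exp(-z))
}

#' @rdname dlaplace_sd
#' @export
qlaplace_sd <- function(p, q_bar = 0, sigma = 1) {
  stopifnot(sigma >= 0, all(p >= 0 & p <= 1))
  u <- p - 0.5
  s <- ifelse(u < 0, -1, 1)
  q_bar - (sigma / sqrt(2)) * s * log(1 - 2 * abs(u))
}

#' @rdname dlaplace_sd
#' @export
rlaplace_sd <- function(n, q_bar = 0, sigma = 1) {
  stopifnot(n >= 1)
  qlaplace_sd(stats::runif(n), q_bar, sigma)
}

#' Maximum-likelihood fit of the Laplace impulse law
#'
#' The exact MLE for a Laplace sample: location is the sample median (the
#' midpoint of the two central order statistics for even counts) and the
#' scale is the mean absolute deviation about the median, so that the fitted
#' standard deviation is \eqn{\sigma = \sqrt2\, b}.
#'
#' @param x Numeric sample of velocity changes.
#' @param min_n Minimum number of samples required.
#' @return An object of class `laplace_fit`: list with `q_bar`, `sigma`, `n`,
#'   and `degenerate` (`TRUE` when the sample has zero spread, in which case
#'   `sigma` is 0 and a warning is issued).
#' @examples
#' fit_laplace(c(0, 0, 0, 2)) # q_bar 0, sigma sqrt(2)*0.5
#' @export
fit_laplace <- function(x, min_n = 2L) {
  x <- x[is.finite(x)]
  if (length(x) < min_n)
    stop("insufficient data for Laplace fit: ", length(x), " samples (need ",
         min_n, ")", call. = FALSE)
  m <- stats::median(x)
  b <- mean(abs(x - m))
  degenerate <- b == 0
  if (degenerate)
    warning("degenerate Laplace fit: sample has zero spread", call. = FALSE)
  structure(list(q_bar = m, sigma = sqrt(2) * b, n = length(x),
                 degenerate = degenerate),
            class = "laplace_fit")
}

#' @export
print.laplace_fit <- function(x, ...) {
  cat(sprintf("Laplace fit: q_bar = %.4g, sigma = %.4g (n = %d)%s\n",
              x$q_bar, x$sigma, x$n,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}
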