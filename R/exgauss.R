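#' The Ex-Gaussian distribution
#'
#' Density, distribution function, quantile function and random generation
#' for the Ex-Gaussian (exponentially modified Gaussian) distribution: the
#' sum of a Normal(mu, sigma) and an independent Exponential with mean nu.
#' This is the standard right-skewed model for reaction times; `mu` and
#' `sigma` describe the Gaussian component (seconds), `nu` the mean of the
#' exponential tail (seconds).
#'
#' The log-density is evaluated on the log scale throughout,
#' \deqn{\log f(x) = -\log\nu + (\mu-x)/\nu + \sigma^2/(2\nu^2) +
#'   \log\Phi\!\left(\frac{x-\mu}{\sigma} - \frac{\sigma}{\nu}\right),}
#' using `pnorm(log.p = TRUE)` so that it does not overflow when
#' \eqn{\nu \ll \sigma}, where the naive product form fails.
#'
#' @param x,q vector of quantiles.
#' @param p vector of probabilities.
#' @param n number of draws.
#' @param mu Gaussian location (seconds).
#' @param sigma Gaussian standard deviation, > 0.
#' @param nu mean of the exponential component, > 0.
#' @param log,log.p logical; return log-density / log-probability.
#' @return `dexgauss` the (log-)density, `pexgauss` the cdf, `qexgauss`
#'   quantiles, `rexgauss` random draws.
#' @examples
#' dexgauss(1.2, mu = 1, sigma = 0.2, nu = 0.5)
#' qexgauss(0.5, mu = 1, sigma = 0.2, nu = 0.5)  # the median
#' @export
dexgauss <- function(x, mu = 0, sigma = 1, nu = 1, log = FALSE) {
  stopifnot(all(sigma > 0), all(nu > 0))
  v <- (x - mu) / sigma
  z <- v - sigma / nu
  out <- -base::log(nu) + (mu - x) / nu + sigma^2 / (2 * nu^2) +
    stats::pnorm(z, log.p = TRUE)
  # For z << 0 the two huge terms above cancel; substitute the Mills-ratio
  # asymptotic expansion of log Phi(z), in which the cancellation is exact:
  # log f = log phi(v) - log nu - log(-z) + log(1 - 1/z^2 + 3/z^4)
  ext <- which(z < -1e4)
  if (length(ext)) {
    ze <- z[ext]
    ve <- if (length(v) == 1) v else v[ext]
    out[ext] <- stats::dnorm(ve, log = TRUE) -
      (if (length(nu) == 1) base::log(nu) else base::log(nu[ext])) -
      base::log(-ze) + log1p(-1 / ze^2 + 3 / ze^4)
  }
  if (log) out else exp(out)
}

#' @rdname dexgauss
#' @export
pexgauss <- function(q, mu = 0, sigma = 1, nu = 1, log.p = FALSE) {
  stopifnot(all(sigma > 0), all(nu > 0))
  v <- (q - mu) / sigma
  z <- v - sigma / nu
  # F(q) = Phi(v) - exp((mu-q)/nu + sigma^2/(2 nu^2) + log Phi(z))
  a <- (mu - q) / nu + sigma^2 / (2 * nu^2) + stats::pnorm(z, log.p = TRUE)
  p <- stats::pnorm(v) - exp(a)
  p <- pmin(pmax(p, 0), 1)
  if (log.p) base::log(p) else p
}

#' @rdname dexgauss
#' @export
qexgauss <- function(p, mu = 0, sigma = 1, nu = 1) {
  stopifnot(all(p > 0), all(p < 1), sigma > 0, nu > 0)
  vapply(p, function(pp) {
    lo <- mu - 10 * sigma
    hi <- mu + 10 * (sigma + nu)
    while (pexgauss(hi, mu, sigma, nu) < pp) hi <- hi + 5 * (sigma + nu)
    stats::uniroot(function(x) pexgauss(x, mu, sigma, nu) - pp,
                   c(lo, hi), tol = 1e-10)$root
  }, numeric(1))
}

#' @rdname dexgauss
#' @export
rexgauss <- function(n, mu = 0, sigma = 1, nu = 1) {
  stopifnot(sigma > 0, nu > 0)
  stats::rnorm(n, mu, sigma) + stats::rexp(n, rate = 1 / nu)
}

# Per-observation score of the Ex-Gaussian log-density, natural scale.
# Columns (mu, sigma, nu). h = phi(z)/Phi(z) is computed on the log scale
# (inverse Mills ratio) so it stays finite for z << 0.
exgauss_score <- function(x, mu, sigma, nu) {
  z <- (x - mu) / sigma - sigma / nu
  h <- exp(stats::dnorm(z, log = TRUE) - stats::pnorm(z, log.p = TRUE))
  d_mu <- 1 / nu - h / sigma
  d_sigma <- sigma / nu^2 - h * ((x - mu) / sigma^2 + 1 / nu)
  d_nu <- -1 / nu - (mu - x) / nu^2 - sigma^2 / nu^3 + h * sigma / nu^2
  cbind(mu = d_mu, sigma = d_sigma, nu = d_nu)
}
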