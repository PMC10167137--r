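#' The generalized beta type 1 distribution
#'
#' Log-density of the four-parameter generalized beta type 1 (GB1)
#' distribution on the open unit interval, in the location/scale/shape
#' parameterization common in distributional regression: `mu` (location)
#' and `sigma` (scale) in (0,1), `nu` and `tau` (shapes) positive. With
#' \eqn{a = \mu(1-\sigma^2)/\sigma^2} and
#' \eqn{b = (1-\mu)(1-\sigma^2)/\sigma^2},
#' \deqn{f(y) = \frac{\tau \nu^b y^{\tau a - 1} (1-y^\tau)^{b-1}}
#'   {B(a,b)\,\{\nu + (1-\nu) y^\tau\}^{a+b}}, \qquad 0 < y < 1.}
#' At `nu = tau = 1` this reduces exactly to the Beta(a, b) density, so the
#' family nests the Beta; `mu` is then the Beta mean and
#' `var = mu (1 - mu) sigma^2`. Used here for accuracy rates (which must be
#' squeezed off the boundary first, see [squeeze_unit()]).
#'
#' @param x vector of values strictly inside (0, 1).
#' @param mu,sigma location and scale, both in (0, 1).
#' @param nu,tau positive shape parameters.
#' @param log logical; return the log-density.
#' @return numeric vector of (log-)density values.
#' @examples
#' # Beta(2, 2) is nested at mu = .5, sigma = 1/sqrt(5), nu = tau = 1
#' dgb1(0.5, 0.5, 1 / sqrt(5), 1, 1, log = TRUE)
#' dbeta(0.5, 2, 2, log = TRUE)
#' @export
dgb1 <- function(x, mu, sigma, nu, tau, log = FALSE) {
  if (any(x <= 0) || any(x >= 1))
    stop("dgb1: x must lie strictly inside (0, 1); squeeze boundary values first")
  stopifnot(mu > 0, mu < 1, sigma > 0, sigma < 1, nu > 0, tau > 0)
  a <- mu * (1 - sigma^2) / sigma^2
  b <- (1 - mu) * (1 - sigma^2) / sigma^2
  xt <- x^tau
  out <- base::log(tau) + b * base::log(nu) + (tau * a - 1) * base::log(x) +
    (b - 1) * log1p(-xt) - lbeta(a, b) - (a + b) * base::log(nu + (1 - nu) * xt)
  if (log) out else exp(out)
}

# Per-observation score of the GB1 log-density, natural scale, columns
# (mu, sigma, nu, tau). Derivatives flow through a, b via the chain rule.
gb1_score <- function(x, mu, sigma, nu, tau) {
  a <- mu * (1 - sigma^2) / sigma^2
  b <- (1 - mu) * (1 - sigma^2) / sigma^2
  xt <- x^tau
  lx <- base::log(x)
  den <- nu + (1 - nu) * xt
  dab <- digamma(a + b)
  dl_da <- tau * lx - digamma(a) + dab - base::log(den)
  dl_db <- base::log(nu) + log1p(-xt) - digamma(b) + dab - base::log(den)
  r <- (1 - sigma^2) / sigma^2
  d_mu <- r * (dl_da - dl_db)
  d_sigma <- (-2 / sigma^3) * (mu * dl_da + (1 - mu) * dl_db)
  d_nu <- b / nu - (a + b) * (1 - xt) / den
  d_tau <- 1 / tau + a * lx - (b - 1) * xt * lx / (1 - xt) -
    (a + b) * (1 - nu) * xt * lx / den
  cbind(mu = d_mu, sigma = d_sigma, nu = d_nu, tau = d_tau)
}

#' Squeeze unit-interval values off the boundary
#'
#' Maps values in the closed unit interval into the open interval by the
#' affine compression `v * (1 - 2 * eps) + eps`, so 0 -> eps, 1 -> 1 - eps
#' and 0.5 is a fixed point. Needed before fitting boundary-free families
#' such as GB1 to accuracy rates, where 100% accuracies occur routinely.
#'
#' @param values numeric vector in `[0, 1]`.
#' @param epsilon compression margin, in (0, 0.5). Default 0.005.
#' @return numeric vector in `(0, 1)`, strictly monotone in the input.
#' @export
squeeze_unit <- function(values, epsilon = 0.005) {
  if (!is.numeric(epsilon) || length(epsilon) != 1 || epsilon <= 0 || epsilon >= 0.5)
    stop("squeeze_unit: epsilon must be a single number in (0, 0.5)")
  if (any(values < 0 | values > 1, na.rm = TRUE))
    stop("squeeze_unit: values must lie in [0, 1]")
  values * (1 - 2 * epsilon) + epsilon
}
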