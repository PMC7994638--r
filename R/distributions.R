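#' Gamma log-density in mean / standard-deviation parameterization
#'
#' Movement HMMs parameterize the step-length distribution by its mean and
#' standard deviation rather than shape and rate; the conversion is
#' `shape = (mu/sigma)^2`, `rate = mu/sigma^2`.
#'
#' @param x step length (m), strictly positive.
#' @param mu mean (m), positive.
#' @param sigma standard deviation (m), positive.
#' @param log return log-density (default `TRUE`).
#' @return (log-)density values.
#' @examples
#' dgamma_musd(11.4, 11.4, 7.38)
#' @export
dgamma_musd <- function(x, mu, sigma, log = TRUE) {
  stopifnot(all(mu > 0), all(sigma > 0))
  if (any(x <= 0, na.rm = TRUE)) {
    stop("zero or negative step lengths; enable the zero-mass option ",
         "(`zero_mass = TRUE` in `fit_hmm()`) to model exact zeros")
  }
  stats::dgamma(x, shape = (mu / sigma)^2, rate = mu / sigma^2, log = log)
}

#' Convert mean/SD gamma parameters to shape and rate
#' @param mu,sigma mean and standard deviation (positive).
#' @return list with `shape` and `rate`.
#' @export
gamma_shape_rate <- function(mu, sigma) {
  list(shape = (mu / sigma)^2, rate = mu / sigma^2)
}

#' Wrapped-Cauchy log-density
#'
#' Density on `(-pi, pi]`:
#' `f(phi) = (1/2pi) (1 - rho^2) / (1 + rho^2 - 2 rho cos(phi - mu))`.
#' `rho = 0` is the circular uniform; `rho -> 1` concentrates at `mu`.
#'
#' @param x angle (radians).
#' @param mu angular mean (radians).
#' @param rho concentration in `[0, 1)`.
#' @param log return log-density (default `TRUE`).
#' @return (log-)density values.
#' @export
dwcauchy <- function(x, mu, rho, log = TRUE) {
  if (any(rho < 0 | rho >= 1)) stop("rho must lie in [0, 1)")
  ld <- log1p(-rho^2) - log(2 * pi) -
    log(1 + rho^2 - 2 * rho * cos(x - mu))
  if (log) ld else exp(ld)
}

#' Draw wrapped-Cauchy random angles
#'
#' Samples a linear Cauchy with scale `-log(rho)` and wraps it to
#' `(-pi, pi]`; the wrapped variable has concentration `rho` exactly.
#'
#' @param n number of draws.
#' @param mu angular mean (radians).
#' @param rho concentration in `[0, 1)`; `0` gives circular uniform draws.
#' @return angles in `(-pi, pi]`.
#' @export
rwcauchy <- function(n, mu = 0, rho = 0) {
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  if (rho == 0) {
    th <- stats::runif(n, -pi, pi)
  } else {
    th <- stats::rcauchy(n, location = mu, scale = -log(rho))
  }
  wrap_angle(th)
}

#' Wrap angles to (-pi, pi]
#'
#' The boundary convention keeps `pi` (an exact reversal) rather than `-pi`.
#'
#' @param x angles (radians).
#' @return wrapped angles in `(-pi, pi]`.
#' @export
wrap_angle <- function(x) {
  y <- x - 2 * pi * floor((x + pi) / (2 * pi))
  # floor maps pi to -pi; put the boundary back at +pi
  y[y <= -pi + .Machine$double.eps * 4 & !is.na(y)] <- pi
  y
}

#' Circular mean of angles
#'
#' `atan2(mean(sin x), mean(cos x))`, in `(-pi, pi]`.
#'
#' @param x angles (radians); `NA`s dropped.
#' @return circular mean (radians).
#' @export
circular_mean <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  wrap_angle(atan2(mean(sin(x)), mean(cos(x))))
}
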