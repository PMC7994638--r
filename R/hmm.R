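#' Construct movement-HMM parameters
#'
#' A `K`-state hidden Markov model for movement data with gamma step-length
#' emissions (mean `mu`, SD `sigma`), wrapped-Cauchy turning-angle emissions
#' (angular mean `muphi`, concentration `rho`), an initial state
#' distribution `delta`, and a time-of-day-dependent transition model: each
#' off-diagonal transition logit is `eta_ij(h) = z(h) . beta_ij` with the
#' diagonal as reference, where `z(h)` is `(1, cos(2 pi h/24), sin(2 pi
#' h/24))` for the default first-order cosinor, `(1, h)` for `tod =
#' "linear"`, or `1` for `tod = "none"`.
#'
#' @param mu,sigma gamma step mean and SD per state (m), positive.
#' @param muphi,rho wrapped-Cauchy angular mean (radians, `(-pi, pi]`) and
#'   concentration (`[0, 1)`) per state.
#' @param tbeta transition coefficient matrix, `K(K-1)` rows (ordered pairs
#'   `(1,2), (1,3), ..., (2,1), ...`, diagonal skipped) by `p` columns;
#'   defaults to intercepts -2 with no diel effect.
#' @param delta initial state distribution; defaults to uniform.
#' @param tod time-of-day covariate form: `"cosinor"`, `"linear"`, `"none"`.
#' @param zmass optional per-state point mass at zero step length.
#' @return object of class `hmm_params`.
#' @export
hmm_params <- function(mu, sigma, muphi = NULL, rho = NULL, tbeta = NULL,
                       delta = NULL, tod = c("cosinor", "linear", "none"),
                       zmass = NULL) {
  tod <- match.arg(tod)
  K <- length(mu)
  stopifnot(K >= 1, K <= 16, length(sigma) == K, all(mu > 0), all(sigma > 0))
  if (is.null(muphi)) muphi <- rep(0, K)
  if (is.null(rho)) rho <- rep(0, K)
  stopifnot(length(muphi) == K, length(rho) == K,
            all(rho >= 0), all(rho < 1))
  p <- tod_ncol(tod)
  if (is.null(tbeta)) {
    tbeta <- matrix(0, K * (K - 1), p)
    if (K > 1) tbeta[, 1] <- -2
  }
  tbeta <- as.matrix(tbeta)
  stopifnot(nrow(tbeta) == K * (K - 1), ncol(tbeta) == p)
  if (is.null(delta)) delta <- rep(1 / K, K)
  stopifnot(length(delta) == K, all(delta >= 0),
            abs(sum(delta) - 1) < 1e-8)
  if (!is.null(zmass)) stopifnot(length(zmass) == K, all(zmass >= 0),
                                 all(zmass < 1))
  structure(list(K = K, mu = mu, sigma = sigma,
                 muphi = wrap_angle(muphi), rho = rho,
                 tbeta = tbeta, delta = delta / sum(delta), tod = tod,
                 zmass = zmass),
            class = "hmm_params")
}

tod_ncol <- function(tod) switch(tod, cosinor = 3L, linear = 2L, none = 1L)

tod_design <- function(hour, tod) {
  switch(tod,
         cosinor = cbind(1, cos(2 * pi * hour / 24), sin(2 * pi * hour / 24)),
         linear = cbind(1, hour),
         none = matrix(1, length(hour), 1))
}

# index of ordered pair (i, j), i != j, in the tbeta row layout
pair_index <- function(i, j, K) (i - 1L) * (K - 1L) + j - (j > i)

#' Transition probability matrix at a given hour
#'
#' Row-wise multinomial logit with the diagonal as reference; rows sum to 1
#' and the matrix is 24-h periodic in `hour`.
#'
#' @param params `hmm_params` object.
#' @param hour hour of day (single value, any real; used modulo 24).
#' @return `K x K` stochastic matrix.
#' @export
transition_matrix <- function(params, hour) {
  K <- params$K
  if (K == 1) return(matrix(1, 1, 1))
  z <- drop(tod_design(hour %% 24, params$tod))
  eta <- matrix(0, K, K)
  for (i in 1:K) for (j in 1:K) if (i != j)
    eta[i, j] <- sum(params$tbeta[pair_index(i, j, K), ] * z)
  ex <- exp(eta)
  diag(ex) <- 1
  ex / rowSums(ex)
}

# package a step-series data frame for the C++ likelihood core
prepare_hmm_data <- function(steps, tod) {
  stopifnot(all(c("step_m", "turn_rad", "hour", "burst") %in% names(steps)))
  l <- steps$step_m
  if (any(!is.finite(l)) || any(l < 0)) stop("non-finite or negative steps")
  hasangle <- as.integer(!is.na(steps$turn_rad))
  phi <- ifelse(hasangle == 1, steps$turn_rad, 0)
  hu <- unique(steps$hour)
  list(l = l, logl = ifelse(l > 0, log(l), 0),
       cosphi = cos(phi), sinphi = sin(phi), hasangle = hasangle,
       newburst = as.integer(c(TRUE, diff(as.integer(factor(steps$burst))) != 0)),
       hidx = match(steps$hour, hu) - 1L, Z = tod_design(hu, tod))
}

#' Forward-algorithm log-likelihood of a step series under an HMM
#'
#' Scaled forward recursion; the initial distribution is applied at the
#' start of every burst, and the turning-angle term is omitted where the
#' angle is missing (the first step of each burst).
#'
#' @param params `hmm_params` object.
#' @param steps step-series data frame (see [compute_steps()]).
#' @return log-likelihood (scalar); `-Inf` if the likelihood degenerates.
#' @export
forward_loglik <- function(params, steps) {
  d <- prepare_hmm_data(steps, params$tod)
  if (any(d$l == 0) && is.null(params$zmass)) {
    stop("zero step lengths present; fit with zero_mass = TRUE")
  }
  nll <- hmm_nll_cpp(params$mu, params$sigma, params$muphi, params$rho,
                     if (is.null(params$zmass)) rep(0, params$K) else params$zmass,
                     !is.null(params$zmass),
                     params$tbeta, params$delta,
                     d$l, d$logl, d$cosphi, d$sinphi, d$hasangle,
                     d$newburst, d$hidx, d$Z)
  if (nll >= 1e10) -Inf else -nll
}

# ---- working-scale parameterization -------------------------------------

# order: log mu (K), log sigma (K), muphi unconstrained-periodic (K),
# logit rho (K), [logit zmass (K)], tbeta (K(K-1)*p), delta logits (K-1)
pack_working <- function(params) {
  w <- c(log(params$mu), log(params$sigma), params$muphi,
         stats::qlogis(pmin(pmax(params$rho, 1e-6), 1 - 1e-6)))
  if (!is.null(params$zmass))
    w <- c(w, stats::qlogis(pmin(pmax(params$zmass, 1e-6), 1 - 1e-6)))
  w <- c(w, as.vector(params$tbeta))
  if (params$K > 1) w <- c(w, log(params$delta[-1] / params$delta[1]))
  w
}

unpack_working <- function(w, K, tod, zero_mass) {
  p <- tod_ncol(tod)
  i <- 0L
  take <- function(n) {
    if (n == 0) return(numeric(0))
    v <- w[(i + 1):(i + n)]; i <<- i + n; v
  }
  mu <- exp(take(K)); sigma <- exp(take(K))
  muphi <- wrap_angle(take(K)); rho <- stats::plogis(take(K))
  zmass <- if (zero_mass) stats::plogis(take(K)) else NULL
  tbeta <- matrix(take(K * (K - 1) * p), K * (K - 1), p)
  delta <- if (K > 1) { d <- c(0, take(K - 1)); exp(d) / sum(exp(d)) } else 1
  structure(list(K = K, mu = mu, sigma = sigma, muphi = muphi, rho = rho,
                 tbeta = tbeta, delta = delta, tod = tod, zmass = zmass),
            class = "hmm_params")
}

n_working <- function(K, tod, zero_mass)
  4L * K + (if (zero_mass) K else 0L) + K * (K - 1L) * tod_ncol(tod) +
  (K - 1L)

# permute state labels; ord[new] = old
relabel_params <- function(params, ord) {
  K <- params$K
  tb <- params$tbeta
  for (i in 1:K) for (j in 1:K) if (i != j)
    tb[pair_index(i, j, K), ] <- params$tbeta[pair_index(ord[i], ord[j], K), ]
  hmm_params(params$mu[ord], params$sigma[ord], params$muphi[ord],
             params$rho[ord], tb, params$delta[ord] / sum(params$delta[ord]),
             params$tod, params$zmass[ord])
}

# quantile-anchored random starting values (one draw)
random_start <- function(K, steps, tod, zero_mass) {
  probs <- switch(as.character(K), "1" = 0.5, "2" = c(0.3, 0.85),
                  "3" = c(0.25, 0.5, 0.9), seq(0.2, 0.9, length.out = K))
  anchors <- stats::quantile(steps$step_m[steps$step_m > 0], probs,
                             names = FALSE)
  mu <- sort(anchors * exp(stats::runif(K, -log(3), log(3))))
  sigma <- mu * stats::runif(K, 0.5, 1.5)
  muphi <- sample(c(0, pi), K, replace = TRUE)
  rho <- stats::runif(K, 0.05, 0.9)
  p <- tod_ncol(tod)
  tbeta <- matrix(0, K * (K - 1), p)
  if (K > 1) tbeta[, 1] <- stats::runif(K * (K - 1), -2, -1)
  hmm_params(mu, sigma, muphi, rho, tbeta, rep(1 / K, K), tod,
             zmass = if (zero_mass) rep(0.01, K) else NULL)
}

#' Fit a movement HMM by direct likelihood maximization
#'
#' Maximizes the forward log-likelihood over a working-scale
#' parameterization (log means and SDs, logit concentrations, periodic
#' angular means, unconstrained transition coefficients, multinomial-logit
#' initial distribution) with BFGS and forward-difference gradients, from
#' `n_starts` randomly drawn starting values (gamma means log-uniform within
#' a factor of 3 of quantile anchors of the observed steps, SDs 0.5-1.5
#' times the drawn mean, concentrations uniform on (0.05, 0.9), angular
#' means drawn from {0, pi}, transition intercepts uniform on (-2, -1)).
#' The best converged start is returned with states relabeled by ascending
#' gamma mean, so state 1 is always the shortest-step (resting-like) state.
#'
#' @param steps step-series data frame (see [compute_steps()]).
#' @param K number of states.
#' @param n_starts number of random starting values (default 25).
#' @param seed optional integer seed; the fit is bit-reproducible given it.
#' @param tod time-of-day covariate form on the transition logits.
#' @param zero_mass model exact-zero steps with a per-state point mass.
#' @param maxit,reltol BFGS control.
#' @param starts optional list of `hmm_params` starting values overriding the
#'   random draws.
#' @return object of class `hmm_fit`: `params`, `logL`, `n_par`, `AIC`,
#'   `n_obs`, per-start diagnostics in `starts_diag`.
#' @export
fit_hmm <- function(steps, K, n_starts = 25, seed = NULL,
                    tod = c("cosinor", "linear", "none"), zero_mass = FALSE,
                    maxit = 500, reltol = 1e-8, starts = NULL) {
  tod <- match.arg(tod)
  if (!is.null(seed)) set.seed(seed)
  d <- prepare_hmm_data(steps, tod)
  if (any(d$l == 0) && !zero_mass) {
    stop("zero step lengths present; refit with zero_mass = TRUE")
  }
  zm <- rep(0, K)
  obj <- function(w) {
    pp <- unpack_working(w, K, tod, zero_mass)
    hmm_nll_cpp(pp$mu, pp$sigma, pp$muphi, pp$rho,
                if (zero_mass) pp$zmass else zm, zero_mass,
                pp$tbeta, pp$delta, d$l, d$logl, d$cosphi, d$sinphi,
                d$hasangle, d$newburst, d$hidx, d$Z)
  }
  grad <- function(w) {
    f0 <- obj(w)
    vapply(seq_along(w), function(i) {
      h <- 1e-6 * max(1, abs(w[i]))
      wi <- w; wi[i] <- wi[i] + h
      (obj(wi) - f0) / h
    }, numeric(1))
  }
  if (is.null(starts)) {
    starts <- replicate(n_starts, random_start(K, steps, tod, zero_mass),
                        simplify = FALSE)
  }
  diag_df <- data.frame(start = seq_along(starts), logL = NA_real_,
                        convergence = NA_integer_)
  best <- NULL
  for (s in seq_along(starts)) {
    w0 <- pack_working(starts[[s]])
    res <- tryCatch(
      stats::optim(w0, obj, grad, method = "BFGS",
                   control = list(maxit = maxit, reltol = reltol)),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$value) || res$value >= 1e9) next
    diag_df$logL[s] <- -res$value
    diag_df$convergence[s] <- res$convergence
    # reject degenerate optima: a gamma spiking on single observations
    # (sigma -> 0) or a turn distribution collapsing to a point (rho -> 1)
    # makes the mixture likelihood unbounded without describing the data
    cand <- unpack_working(res$par, K, tod, zero_mass)
    if (any(cand$sigma < 1e-4 * stats::median(d$l)) ||
        any(cand$rho > 0.999)) {
      diag_df$convergence[s] <- 2L
      next
    }
    if (res$convergence == 0 &&
        (is.null(best) || res$value < best$value)) best <- res
  }
  if (is.null(best)) {
    stop("no HMM start converged; per-start diagnostics:\n",
         paste(utils::capture.output(print(diag_df)), collapse = "\n"))
  }
  params <- unpack_working(best$par, K, tod, zero_mass)
  params <- relabel_params(params, order(params$mu))
  n_par <- n_working(K, tod, zero_mass)
  logL <- -best$value
  structure(list(params = params, logL = logL, n_par = n_par,
                 AIC = -2 * logL + 2 * n_par, K = K, tod = tod,
                 n_obs = length(d$l), n_starts = length(starts),
                 starts_diag = diag_df, seed = seed),
            class = "hmm_fit")
}

#' @export
print.hmm_fit <- function(x, ...) {
  cat(sprintf("%d-state movement HMM (tod = %s): logL = %.3f, AIC = %.3f\n",
              x$K, x$tod, x$logL, x$AIC))
  cat(sprintf("  %d observations, %d/%d starts converged\n", x$n_obs,
              sum(x$starts_diag$convergence == 0, na.rm = TRUE), x$n_starts))
  tab <- with(x$params, data.frame(state = 1:K, mu = mu, sigma = sigma,
                                   muphi = muphi, rho = rho))
  print(tab, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Akaike information criterion of an HMM fit
#' @param fit `hmm_fit` object.
#' @return `-2 logL + 2 k`.
#' @export
aic_hmm <- function(fit) -2 * fit$logL + 2 * fit$n_par

#' Select the most parsimonious HMM by AIC
#'
#' @param fits list of `hmm_fit` objects for the same data with different
#'   numbers of states. Ties are broken toward fewer states.
#' @return the minimum-AIC fit.
#' @export
select_states <- function(fits) {
  a <- vapply(fits, aic_hmm, numeric(1))
  k <- vapply(fits, function(f) f$K, numeric(1))
  fits[[order(a, k)[1]]]
}

# T x K log-density matrix of the observations under each state
logdens_matrix <- function(params, steps) {
  K <- params$K
  l <- steps$step_m
  out <- matrix(0, length(l), K)
  for (k in 1:K) {
    if (!is.null(params$zmass)) {
      ld <- ifelse(l == 0, log(params$zmass[k]),
                   log1p(-params$zmass[k]) +
                     dgamma_musd(pmax(l, .Machine$double.xmin),
                                 params$mu[k], params$sigma[k]))
    } else {
      ld <- dgamma_musd(l, params$mu[k], params$sigma[k])
    }
    ang <- !is.na(steps$turn_rad)
    ld[ang] <- ld[ang] + dwcauchy(steps$turn_rad[ang], params$muphi[k],
                                  params$rho[k])
    out[, k] <- ld
  }
  out
}

#' Viterbi decoding of the most likely state sequence
#'
#' Log-space dynamic programming per burst; the initial distribution is
#' applied at each burst start and ties are broken toward the lowest state
#' index. With states labeled by ascending step mean, 1/2/3 read as
#' resting/foraging/traveling.
#'
#' @param params `hmm_params` object (or an `hmm_fit`, whose parameters are
#'   used).
#' @param steps step-series data frame.
#' @return integer vector of decoded states, aligned to the rows of `steps`.
#' @export
viterbi <- function(params, steps) {
  if (inherits(params, "hmm_fit")) params <- params$params
  K <- params$K
  ld <- logdens_matrix(params, steps)
  if (K == 1) return(rep(1L, nrow(steps)))
  out <- integer(nrow(steps))
  lG <- function(h) log(transition_matrix(params, h))
  for (b in split(seq_len(nrow(steps)), steps$burst)) {
    n <- length(b)
    v <- matrix(-Inf, n, K)
    bp <- matrix(0L, n, K)
    v[1, ] <- log(params$delta) + ld[b[1], ]
    for (t in seq_len(n)[-1]) {
      G <- lG(steps$hour[b[t]])
      for (k in 1:K) {
        cand <- v[t - 1, ] + G[, k]
        bp[t, k] <- which.max(cand)
        v[t, k] <- cand[bp[t, k]] + ld[b[t], k]
      }
    }
    path <- integer(n)
    path[n] <- which.max(v[n, ])
    for (t in rev(seq_len(n - 1))) path[t] <- bp[t + 1, path[t + 1]]
    out[b] <- path
  }
  out
}

#' Serialize an HMM fit to a structured text (JSON) file
#' @param fit `hmm_fit` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hmm_fit <- function(fit, path) {
  x <- list(K = fit$K, tod = fit$tod, logL = fit$logL, n_par = fit$n_par,
            AIC = fit$AIC, n_obs = fit$n_obs, n_starts = fit$n_starts,
            seed = fit$seed,
            params = fit$params[c("mu", "sigma", "muphi", "rho", "delta")],
            tbeta = as.data.frame(fit$params$tbeta),
            zmass = fit$params$zmass,
            starts_diag = fit$starts_diag)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
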