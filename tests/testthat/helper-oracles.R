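# Independent brute-force oracles and small builders used across tests.
# These deliberately re-derive quantities with naive algorithms (exhaustive
# path enumeration, direct quadrature, pair counting) and never call the
# package's fast paths.

# build a step-series data frame directly
make_steps <- function(l, phi, hour = rep(0, length(l)),
                       burst = rep(1L, length(l)), id = "t1") {
  data.frame(animal_id = id, burst = burst, t = Sys.time() + seq_along(l),
             x = 0, y = 0, step_m = l, turn_rad = phi, hour = hour,
             season = "low_forage", stringsAsFactors = FALSE)
}

# joint log-probability of one complete state path (single burst)
path_logprob <- function(params, steps, path) {
  K <- params$K
  lp <- log(params$delta[path[1]])
  for (t in seq_along(path)) {
    lp <- lp + dgamma_musd(steps$step_m[t], params$mu[path[t]],
                           params$sigma[path[t]])
    if (!is.na(steps$turn_rad[t])) {
      lp <- lp + dwcauchy(steps$turn_rad[t], params$muphi[path[t]],
                          params$rho[path[t]])
    }
    if (t > 1) {
      G <- transition_matrix(params, steps$hour[t])
      lp <- lp + log(G[path[t - 1], path[t]])
    }
  }
  lp
}

# exhaustive-path forward log-likelihood (per burst, summed)
forward_loglik_brute <- function(params, steps) {
  tot <- 0
  for (b in split(steps, steps$burst)) {
    Tt <- nrow(b)
    paths <- as.matrix(expand.grid(rep(list(seq_len(params$K)), Tt)))
    lps <- apply(paths, 1, function(p) path_logprob(params, b, p))
    m <- max(lps)
    tot <- tot + m + log(sum(exp(lps - m)))
  }
  tot
}

# exhaustive-path Viterbi (single burst), ties to the lowest path by
# lexicographic order of expand.grid (first index varies fastest)
viterbi_brute <- function(params, steps) {
  Tt <- nrow(steps)
  paths <- as.matrix(expand.grid(rep(list(seq_len(params$K)), Tt)))
  lps <- apply(paths, 1, function(p) path_logprob(params, steps, p))
  unname(paths[which.max(lps), ])
}

# random valid HMM parameters for property tests
rand_hmm_params <- function(K, tod = "cosinor") {
  p <- switch(tod, cosinor = 3, linear = 2, none = 1)
  hmm_params(mu = sort(exp(runif(K, log(5), log(400)))),
             sigma = exp(runif(K, log(4), log(200))),
             muphi = runif(K, -pi, pi),
             rho = runif(K, 0, 0.9),
             tbeta = matrix(rnorm(K * (K - 1) * p, -1, 0.7), K * (K - 1), p),
             delta = {d <- runif(K, 0.2, 1); d / sum(d)},
             tod = tod)
}

# random small step series (steps positive, first angle NA)
rand_steps <- function(Tt, burst = rep(1L, Tt)) {
  phi <- runif(Tt, -pi, pi)
  phi[!duplicated(burst)] <- NA
  make_steps(l = rexp(Tt, 1 / 50) + 1, phi = phi,
             hour = sample(0:23, Tt, replace = TRUE), burst = burst)
}

# brute-force nearest-target distance raster (cell-center metric)
brute_distance_raster <- function(class_raster, code) {
  m <- class_raster$values
  tg <- which(m == code, arr.ind = TRUE)
  out <- matrix(NA_real_, nrow(m), ncol(m))
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    out[i, j] <- sqrt(min((tg[, 1] - i)^2 + (tg[, 2] - j)^2))
  }
  out * class_raster$cell
}

# bounding-box polygon of a region (for nesting checks)
region_bbox_poly <- function(region) {
  bb <- stateRSF:::region_bbox(region)
  mcp(cbind(bb[c(1, 2, 2, 1)], bb[c(3, 3, 4, 4)]))
}

# shoelace area of an open ring (re-derived for round-trip checks)
ring_area_test <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1)
  abs(sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2]) / 2)
}

# AUC by exhaustive pair counting (ties half)
auc_pairs <- function(scores, labels) {
  s1 <- scores[labels == 1]
  s0 <- scores[labels == 0]
  tot <- 0
  for (a in s1) for (b in s0) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(s1) * length(s0))
}

# simulate a used-available design directly from the logistic model
sim_design <- function(n, beta, tau = 0, n_groups = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- length(beta) - 1
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- paste0("v", seq_len(p))
  g <- rep_len(sprintf("g%02d", seq_len(n_groups)), n)
  b <- rnorm(n_groups, 0, tau)
  eta <- beta[1] + X %*% beta[-1] +
    b[match(g, sprintf("g%02d", seq_len(n_groups)))]
  y <- rbinom(n, 1, plogis(eta))
  df <- data.frame(y = y, group = g, X)
  used <- df[df$y == 1, ]
  avail <- df[df$y == 0, ]
  ua_design(used[colnames(X)], avail[colnames(X)], colnames(X),
            group_used = used$group, group_available = avail$group)
}

# direct numerical integration of the random-intercept marginal likelihood
glmm_loglik_integrate <- function(beta, tau, y, X, group) {
  X <- as.matrix(X)
  eta0 <- beta[1] + X %*% beta[-1]
  tot <- 0
  for (g in unique(group)) {
    i <- group == g
    f <- function(b) {
      vapply(b, function(bb) {
        p <- plogis(eta0[i] + bb)
        exp(sum(dbinom(y[i], 1, p, log = TRUE))) * dnorm(bb, 0, tau)
      }, numeric(1))
    }
    tot <- tot + log(integrate(f, -Inf, Inf, rel.tol = 1e-12)$value)
  }
  tot
}
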