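test_that("single-state likelihood collapses to independent sums", {
  set.seed(21)
  st <- rand_steps(60)
  p1 <- hmm_params(mu = 40, sigma = 30, muphi = 0.5, rho = 0.4, tod = "none")
  direct <- sum(dgamma_musd(st$step_m, 40, 30)) +
    sum(dwcauchy(st$turn_rad[-1], 0.5, 0.4))
  expect_equal(forward_loglik(p1, st), direct, tolerance = 1e-10)
})

test_that("forward likelihood matches exhaustive path enumeration", {
  set.seed(31)
  for (rep in 1:25) {
    K <- sample(2:3, 1)
    Tt <- sample(3:8, 1)
    pars <- rand_hmm_params(K)
    st <- rand_steps(Tt)
    expect_equal(forward_loglik(pars, st), forward_loglik_brute(pars, st),
                 tolerance = 1e-10)
  }
})

test_that("likelihood is invariant to state relabeling and burst order", {
  set.seed(41)
  pars <- rand_hmm_params(3)
  st <- rand_steps(30, burst = rep(1:3, each = 10))
  ll <- forward_loglik(pars, st)

  ord <- c(3, 1, 2)
  pperm <- stateRSF:::relabel_params(pars, ord)
  expect_equal(forward_loglik(pperm, st), ll, tolerance = 1e-9)

  st2 <- st[order(match(st$burst, c(2, 3, 1)), st$t), ]
  expect_equal(forward_loglik(pars, st2), ll, tolerance = 1e-9)

  # multi-burst likelihood = sum of single-burst likelihoods
  parts <- vapply(split(st, st$burst), function(b) forward_loglik(pars, b),
                  numeric(1))
  expect_equal(sum(parts), ll, tolerance = 1e-9)
})

test_that("viterbi matches exhaustive argmax and trivial cases", {
  set.seed(51)
  st <- rand_steps(6)
  p1 <- hmm_params(mu = 40, sigma = 30, tod = "none")
  expect_equal(viterbi(p1, st), rep(1L, 6))

  for (rep in 1:25) {
    K <- sample(2:3, 1)
    Tt <- sample(3:8, 1)
    pars <- rand_hmm_params(K)
    stt <- rand_steps(Tt)
    expect_equal(viterbi(pars, stt), viterbi_brute(pars, stt))
  }
})

test_that("viterbi recovers well-separated generating states", {
  set.seed(61)
  tb <- matrix(c(log(0.05 / 0.95), log(0.05 / 0.95)), 2, 1)
  pars <- hmm_params(mu = c(10, 400), sigma = c(8, 300),
                     muphi = c(3.1, 0), rho = c(0.4, 0.7),
                     tbeta = tb, tod = "none")
  tr <- simulate_track(pars, 2000)
  acc <- mean(viterbi(pars, tr$steps) == tr$states)
  expect_gte(acc, 0.95)
})

test_that("AIC arithmetic, parsimony tie-break and inert-parameter penalty", {
  f1 <- structure(list(logL = -100, n_par = 10, K = 2), class = "hmm_fit")
  expect_equal(aic_hmm(f1), 220)
  f2 <- structure(list(logL = -100, n_par = 12, K = 3), class = "hmm_fit")
  expect_equal(select_states(list(f2, f1))$K, 2)
  # one inert parameter at equal logL costs exactly +2 AIC
  expect_equal(aic_hmm(structure(list(logL = -100, n_par = 11),
                                 class = "hmm_fit")) - aic_hmm(f1), 2)
  # equal AIC ties break toward fewer states
  f3 <- structure(list(logL = -99, n_par = 11, K = 3), class = "hmm_fit")
  expect_equal(aic_hmm(f3), aic_hmm(f1))
  expect_equal(select_states(list(f3, f1))$K, 2)
})

test_that("parameter count follows the emission/transition/delta bookkeeping", {
  expect_equal(stateRSF:::n_working(3, "cosinor", FALSE), 3 * 4 + 18 + 2)
  expect_equal(stateRSF:::n_working(2, "cosinor", FALSE), 2 * 4 + 6 + 1)
  expect_equal(stateRSF:::n_working(3, "none", FALSE), 3 * 4 + 6 + 2)
  expect_equal(stateRSF:::n_working(3, "cosinor", TRUE), 3 * 5 + 18 + 2)
  expect_equal(stateRSF:::n_working(1, "cosinor", FALSE), 4)
})

test_that("K = 1 fit matches direct independent MLE of the two distributions", {
  set.seed(71)
  p1 <- hmm_params(mu = 60, sigma = 45, muphi = 2.5, rho = 0.45, tod = "none")
  tr <- simulate_track(p1, 800)
  fit <- fit_hmm(tr$steps, K = 1, n_starts = 3, seed = 5, tod = "none")
  # independent oracle: separate 2-parameter optimizations per distribution
  g_nll <- function(p) -sum(dgamma_musd(tr$steps$step_m, exp(p[1]), exp(p[2])))
  g_hat <- exp(optim(log(c(50, 50)), g_nll)$par)
  phi <- tr$steps$turn_rad[-1]
  w_nll <- function(p) -sum(dwcauchy(phi, p[1], plogis(p[2])))
  w_opt <- optim(c(2, 0), w_nll)$par
  expect_equal(fit$params$mu, g_hat[1], tolerance = 1e-3)
  expect_equal(fit$params$sigma, g_hat[2], tolerance = 1e-3)
  expect_equal(fit$params$muphi, w_opt[1], tolerance = 1e-3)
  expect_equal(fit$params$rho, plogis(w_opt[2]), tolerance = 1e-3)
  expect_equal(fit$logL, -(g_nll(log(g_hat)) + w_nll(w_opt)), tolerance = 1e-4)
})

test_that("fitting is deterministic under a fixed seed", {
  set.seed(81)
  pars <- hmm_params(mu = c(15, 250), sigma = c(12, 200), muphi = c(3, 0),
                     rho = c(0.4, 0.7), tod = "none",
                     tbeta = matrix(log(1 / 9), 2, 1))
  tr <- simulate_track(pars, 500)
  f1 <- fit_hmm(tr$steps, 2, n_starts = 3, seed = 99, tod = "none")
  f2 <- fit_hmm(tr$steps, 2, n_starts = 3, seed = 99, tod = "none")
  expect_identical(f1$params, f2$params)
  expect_identical(f1$logL, f2$logL)
})

test_that("2-state fit recovers simulated parameters and labels by step mean", {
  set.seed(83)
  pars <- hmm_params(mu = c(20, 300), sigma = c(15, 240), muphi = c(3.1, 0),
                     rho = c(0.35, 0.7), tod = "none",
                     tbeta = matrix(log(0.15 / 0.85), 2, 1))
  sims <- lapply(1:4, function(i) simulate_track(pars, 800))
  steps <- do.call(rbind, lapply(seq_along(sims), function(i) {
    s <- sims[[i]]$steps; s$burst <- i; s
  }))
  fit <- fit_hmm(steps, 2, n_starts = 5, seed = 7, tod = "none")
  expect_lt(abs(fit$params$mu[1] - 20) / 20, 0.10)
  expect_lt(abs(fit$params$mu[2] - 300) / 300, 0.10)
  expect_true(all(diff(fit$params$mu) > 0))
  G <- transition_matrix(fit$params, 12)
  expect_equal(G[1, 1], 0.85, tolerance = 0.05)
  # AIC prefers 2 states over 1 for clearly bimodal data
  fit1 <- fit_hmm(steps, 1, n_starts = 2, seed = 7, tod = "none")
  expect_lt(aic_hmm(fit), aic_hmm(fit1))
})

test_that("zero steps error by default and are modeled under zero_mass", {
  set.seed(85)
  st <- rand_steps(50)
  st$step_m[c(4, 30)] <- 0
  p <- hmm_params(mu = 50, sigma = 40, tod = "none")
  expect_error(forward_loglik(p, st), "zero_mass")
  expect_error(fit_hmm(st, 1, n_starts = 2, seed = 1, tod = "none"),
               "zero_mass")
  fitz <- fit_hmm(st, 1, n_starts = 3, seed = 1, tod = "none",
                  zero_mass = TRUE)
  expect_equal(fitz$params$zmass, 2 / 50, tolerance = 0.02)
  expect_equal(fitz$n_par, 5)
})

test_that("serialized fits round-trip the key quantities", {
  set.seed(87)
  pars <- hmm_params(mu = c(15, 250), sigma = c(12, 200), tod = "none",
                     tbeta = matrix(log(1 / 9), 2, 1))
  tr <- simulate_track(pars, 300)
  fit <- fit_hmm(tr$steps, 2, n_starts = 2, seed = 3, tod = "none")
  path <- tempfile(fileext = ".json")
  write_hmm_fit(fit, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$logL, fit$logL, tolerance = 1e-10)
  expect_equal(back$AIC, fit$AIC, tolerance = 1e-10)
  expect_equal(back$params$mu, fit$params$mu, tolerance = 1e-10)
})
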