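test_that("intercept-only logistic fit recovers the log odds of the class ratio", {
  used <- data.frame(id = seq_len(300))
  avail <- data.frame(id = seq_len(700))
  des <- ua_design(used, avail, character(0))
  fit <- fit_logistic(des)
  expect_equal(unname(fit$coef[1]), log(3 / 7), tolerance = 1e-8)
})

test_that("logistic RSF recovers simulated coefficients within 3 SEs", {
  des <- sim_design(20000, beta = c(-1, 0.8, -0.5), seed = 31)
  fit <- fit_logistic(des)
  # covariates are re-standardized inside the design; compare on that scale
  for (v in c("v1", "v2")) {
    btrue <- c(v1 = 0.8, v2 = -0.5)[[v]] * des$stats$sd[des$stats$column == v]
    expect_lt(abs(fit$coef[[v]] - btrue) / fit$se[[v]], 3)
  }
})

test_that("duplicated covariate columns raise an aliasing error", {
  set.seed(32)
  u <- data.frame(a = rnorm(50), b = rnorm(50))
  u$c <- u$a
  a <- data.frame(a = rnorm(80), b = rnorm(80))
  a$c <- a$a
  des <- ua_design(u, a, c("a", "b", "c"))
  expect_error(fit_logistic(des), "alias")
})

test_that("Wald CIs of the logistic fit cover the truth at nominal rate", {
  set.seed(33)
  cover <- 0L
  reps <- 200
  for (r in seq_len(reps)) {
    des <- sim_design(400, beta = c(-0.5, 0.6))
    f <- fit_logistic(des)
    btrue <- 0.6 * des$stats$sd[des$stats$column == "v1"]
    ci <- f$coef[["v1"]] + c(-1.96, 1.96) * f$se[["v1"]]
    cover <- cover + (ci[1] <= btrue && btrue <= ci[2])
  }
  expect_gte(cover / reps, 0.92)
  expect_lte(cover / reps, 0.98)
})

test_that("GLMM marginal likelihood matches direct numerical integration", {
  set.seed(34)
  n <- 150
  X <- matrix(rnorm(n), n, 1)
  g <- rep_len(sprintf("g%d", 1:5), n)
  y <- rbinom(n, 1, plogis(-0.3 + 0.7 * X[, 1] +
                             rnorm(5, 0, 0.8)[match(g, sprintf("g%d", 1:5))]))
  for (pars in list(list(beta = c(-0.3, 0.7), tau = 0.8),
                    list(beta = c(0.1, -0.4), tau = 0.3),
                    list(beta = c(0, 0), tau = 1.5))) {
    ll_agh <- glmm_marginal_loglik(pars$beta, pars$tau, y, X, g, nodes = 25)
    ll_int <- glmm_loglik_integrate(pars$beta, pars$tau, y, X, g)
    expect_equal(ll_agh, ll_int, tolerance = 1e-6)
  }
  # accuracy improves (or stays) as nodes double
  err <- vapply(c(3, 6, 12, 24), function(nd)
    abs(glmm_marginal_loglik(c(-0.3, 0.7), 0.8, y, X, g, nodes = nd) -
          glmm_loglik_integrate(c(-0.3, 0.7), 0.8, y, X, g)), numeric(1))
  expect_true(all(diff(err) <= 1e-8))
})

test_that("mixed fit agrees with the plain GLM when tau = 0 and recovers tau = 1", {
  des0 <- sim_design(4000, beta = c(-0.6, 0.5), tau = 0, n_groups = 20,
                     seed = 36)
  fg <- fit_logistic(des0)
  fm <- fit_logistic_mixed(des0, nAGQ = 9)
  expect_lte(fm$tau, 0.05)
  expect_lt(abs(fm$coef[["v1"]] - fg$coef[["v1"]]), 1e-2)

  des1 <- sim_design(20000, beta = c(-0.5, 0.5), tau = 1, n_groups = 40,
                     seed = 37)
  fm1 <- fit_logistic_mixed(des1, nAGQ = 9)
  expect_gte(fm1$tau, 0.6)
  expect_lte(fm1$tau, 1.4)
  # glmer's AGH log-likelihood agrees with our own quadrature at its optimum
  dat <- des1$data
  ll <- glmm_marginal_loglik(fm1$coef, fm1$tau, dat$y,
                             as.matrix(dat["v1"]), dat$group, nodes = 40)
  expect_equal(ll, fm1$logLik, tolerance = 1e-4)
})

test_that("odds back-transformation reproduces per-increment percent changes", {
  # beta chosen so exp(100 * beta_raw) = 0.77: a 23% decrease per 100 m
  s <- 350
  beta_raw <- log(0.77) / 100
  fit <- structure(list(
    coef = c(`(Intercept)` = 0, d_bottomland = beta_raw * s),
    se = c(`(Intercept)` = 0.1, d_bottomland = 0.01),
    design = structure(list(
      covariates = "d_bottomland",
      stats = data.frame(column = "d_bottomland", mean = 500, sd = s)),
      class = "ua_design")), class = "rsf_glm")
  rep1 <- odds_per_increment(fit)
  expect_equal(rep1$or, 0.77, tolerance = 1e-12)
  expect_equal(rep1$increment, 100)

  fit$coef[2] <- log(0.946) / 100 * s
  expect_equal(odds_per_increment(fit)$or, 0.946, tolerance = 1e-12)

  # zero coefficient: OR 1, non-significant
  fit$coef[2] <- 0
  r0 <- odds_per_increment(fit)
  expect_equal(r0$or, 1)
  expect_false(r0$significant)
  expect_lt(r0$ci_low, 1)
  expect_gt(r0$ci_high, 1)

  # canopy uses 10-unit increments
  fitc <- fit
  fitc$coef <- c(`(Intercept)` = 0, canopy = 0.2)
  fitc$se <- c(`(Intercept)` = 0.1, canopy = 0.02)
  fitc$design$covariates <- "canopy"
  fitc$design$stats <- data.frame(column = "canopy", mean = 60, sd = 20)
  rc <- odds_per_increment(fitc)
  expect_equal(rc$increment, 10)
  expect_equal(rc$or, exp(0.2 / 20 * 10))
  expect_true(rc$significant)
})

test_that("rank AUC matches pair counting, is transform-invariant, handles ties", {
  expect_equal(auc_rank(c(0.9, 0.4, 0.5, 0.1), c(1, 1, 0, 0)), 0.75)
  expect_equal(auc_rank(c(5, 4, 3, 2), c(1, 1, 0, 0)), 1)
  expect_equal(auc_rank(rep(1, 10), rep(c(1, 0), 5)), 0.5)
  expect_error(auc_rank(1:4, rep(1, 4)), "both classes")

  set.seed(38)
  for (r in 1:20) {
    n <- sample(10:40, 1)
    sc <- sample(round(rnorm(n), 1))      # induces ties
    lb <- rbinom(n, 1, 0.5)
    if (length(unique(lb)) < 2) next
    expect_equal(auc_rank(sc, lb), auc_pairs(sc, lb))
    expect_equal(auc_rank(exp(3 * sc), lb), auc_rank(sc, lb))
  }
})

test_that("rank AUC agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(39)
  sc <- rnorm(300)
  lb <- rbinom(300, 1, plogis(sc))
  a1 <- auc_rank(sc, lb)
  a2 <- as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE)))
  expect_equal(a1, a2, tolerance = 1e-12)
})

test_that("standardized and raw covariates give identical fitted probabilities", {
  set.seed(40)
  n <- 800
  u <- data.frame(d_pine = rexp(n, 1 / 300), canopy = runif(n, 0, 100))
  a <- data.frame(d_pine = rexp(2 * n, 1 / 200), canopy = runif(2 * n, 0, 100))
  des <- ua_design(u, a, c("d_pine", "canopy"))
  fs <- fit_logistic(des)
  raw <- rbind(cbind(y = 1, u), cbind(y = 0, a))
  fr <- glm(y ~ d_pine + canopy, family = binomial(), data = raw)
  expect_equal(unname(fitted(fs$fit)), unname(fitted(fr)), tolerance = 1e-8)
  # coefficients related exactly through the standardization statistics
  expect_equal(unname(fs$coef[["d_pine"]] / des$stats$sd[1]),
               unname(coef(fr)[["d_pine"]]), tolerance = 1e-6)
})
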