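test_that("synthetic landscape honors mixing weights and is seed-reproducible", {
  land <- make_landscape(extent = 15000, cell = 30, seed = 51)
  cls <- land$class$values
  w <- land$weights
  for (k in seq_along(w)) {
    expect_lt(abs(mean(cls == k) - w[k]), 0.05)
  }
  expect_true(all(land$canopy$values >= 0 & land$canopy$values <= 100))
  expect_gte(length(land$streams), 1)

  land2 <- make_landscape(extent = 15000, cell = 30, seed = 51)
  expect_identical(land$class$values, land2$class$values)
  expect_identical(land$canopy$values, land2$canopy$values)

  # single-class degenerate weights
  land1 <- make_landscape(extent = 3000, cell = 30,
                          weights = c(upland_pine = 1, bottomland_hardwood = 0,
                                      shrub_herb = 0, upland_hardwood = 0,
                                      developed = 0, other = 0), seed = 5)
  expect_true(all(land1$class$values == 1))
})

test_that("simulated tracks follow the generating states and geometry", {
  # identity transition matrix: the chain never leaves its initial state
  pfix <- hmm_params(mu = c(10, 50, 200), sigma = c(8, 40, 160),
                     tbeta = matrix(c(rep(-30, 6), rep(0, 12)), 6, 3),
                     delta = c(1, 0, 0))
  tr <- simulate_track(pfix, 300, seed = 52)
  expect_true(all(tr$states == 1))

  # near-unit concentration at 0 turns gives a near-straight path
  pstr <- hmm_params(mu = 100, sigma = 20, muphi = 0, rho = 0.999,
                     tod = "none")
  trs <- simulate_track(pstr, 400, seed = 53)
  net <- sqrt(diff(range(trs$fixes$x))^2 + diff(range(trs$fixes$y))^2)
  expect_gte(net / sum(trs$steps$step_m), 0.95)

  # law of large numbers: per-state mean steps near the generating means
  p3 <- pig_hmm_params("female", "low_forage",
                       tbeta = pig_transition_beta(diel = FALSE))
  big <- simulate_track(p3, 1e5, seed = 54)
  for (k in 1:3) {
    m <- mean(big$steps$step_m[big$states == k])
    expect_lt(abs(m - p3$mu[k]) / p3$mu[k], 0.02)
  }

  # determinism
  t1 <- simulate_track(p3, 200, seed = 55)
  t2 <- simulate_track(p3, 200, seed = 55)
  expect_identical(t1$fixes, t2$fixes)
})

test_that("step series from simulated fixes match the generated steps", {
  p3 <- pig_hmm_params("male", "high_forage")
  tr <- simulate_track(p3, 400, start = c(5000, 5000), seed = 56)
  tr$fixes$burst <- 1L
  st <- compute_steps(tr$fixes)
  expect_equal(st$step_m, tr$steps$step_m, tolerance = 1e-9)
  expect_equal(st$turn_rad[-1], tr$steps$turn_rad[-1], tolerance = 1e-9)
  expect_equal(st$hour, tr$steps$hour)
})

test_that("rsf point simulator: uniform null, selection direction, determinism", {
  land <- make_landscape(extent = 6000, cell = 30, seed = 57)
  stack <- covariate_stack(land)
  region <- mcp(cbind(c(500, 5500, 5500, 500), c(500, 500, 5500, 5500)))

  # null case: beta = 0 gives uniform points (chi-square on quadrants)
  pts0 <- simulate_rsf_points(c(d_stream = 0), stack, region,
                              n_used = 2500, n_animals = 4, seed = 58)
  qx <- pts0$x > 3000; qy <- pts0$y > 3000
  tab <- table(qx, qy)
  expect_gt(chisq.test(tab)$p.value, 0.01)

  # strong avoidance of streams: used nearer streams than available
  ptsn <- simulate_rsf_points(c(d_stream = -1.5), stack, region,
                              n_used = 500, n_animals = 4, seed = 59)
  avail <- grid_sample(region, spacing = 90)
  avail_cov <- extract_covariates(avail, stack["d_stream"])
  used_raw <- unstandardize_covariates(ptsn["d_stream"], attr(ptsn, "stats"))
  expect_lt(median(used_raw$d_stream), median(avail_cov$d_stream))

  p1 <- simulate_rsf_points(c(canopy = 0.5), stack, region, n_used = 200,
                            n_animals = 2, seed = 60)
  p2 <- simulate_rsf_points(c(canopy = 0.5), stack, region, n_used = 200,
                            n_animals = 2, seed = 60)
  expect_identical(p1, p2)
})

test_that("full closure: simulate, fit, decode recovers most true states", {
  set.seed(61)
  truth <- pig_hmm_params("female", "low_forage",
                          tbeta = pig_transition_beta(diel = FALSE))
  sims <- lapply(1:6, function(i) simulate_track(truth, 500))
  steps <- do.call(rbind, lapply(seq_along(sims), function(i) {
    s <- sims[[i]]$steps; s$burst <- i; s
  }))
  fit <- fit_hmm(steps, 3, n_starts = 6, seed = 62, tod = "none")
  dec <- viterbi(fit, steps)
  expect_gte(mean(dec == steps$state), 0.90)
})

test_that("end-to-end rsf recovery: known coefficients within 3 SEs", {
  land <- make_landscape(extent = 6000, cell = 30, seed = 63)
  stack <- covariate_stack(land)
  region <- mcp(cbind(c(300, 5700, 5700, 300), c(300, 300, 5700, 5700)))
  beta <- c(d_bottomland = -0.6, canopy = 0.4)
  used <- simulate_rsf_points(beta, stack, region, n_used = 60,
                              n_animals = 25, tau = 0.5, seed = 64)
  avail <- grid_sample(region, spacing = 90)
  avail_cov <- extract_covariates(avail, stack[names(beta)])
  # points carry standardized covariates; move them back to natural units
  used_raw <- unstandardize_covariates(used[names(beta)], attr(used, "stats"))
  used_raw$animal_id <- used$animal_id
  des <- ua_design(used_raw, avail_cov, names(beta))
  fit <- fit_logistic_mixed(des, nAGQ = 9)
  sim_stats <- attr(used, "stats")
  for (v in names(beta)) {
    # translate the generating coefficient to the design's standardized scale
    btrue <- beta[[v]] / sim_stats$sd[sim_stats$column == v] *
      des$stats$sd[des$stats$column == v]
    expect_lt(abs(fit$coef[[v]] - btrue) / fit$se[[v]], 3)
  }
})
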