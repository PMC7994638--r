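#' Default 3-state movement parameters for wild pigs
#'
#' Emission parameters (gamma step mean/SD in meters, wrapped-Cauchy angular
#' mean in radians) representative of wild pig (*Sus scrofa*) telemetry in
#' the southeastern United States, by sex and forage season. States are
#' ordered resting, foraging, traveling. Step means range from ~10 m
#' (resting) to ~420 m (traveling males in the high-forage season); resting
#' and foraging turn angles concentrate near a full reversal (pi), traveling
#' near 0. Turn-angle concentrations are not part of the published state
#' summaries and default to 0.40/0.30/0.75.
#'
#' @param sex `"female"` or `"male"`.
#' @param season `"low_forage"` (January-April) or `"high_forage"`
#'   (May-December).
#' @param rho per-state wrapped-Cauchy concentrations.
#' @param tbeta optional transition coefficient matrix; default
#'   [pig_transition_beta()].
#' @param tod time-of-day covariate form for the transition model.
#' @return `hmm_params` object.
#' @export
pig_hmm_params <- function(sex = c("female", "male"),
                           season = c("low_forage", "high_forage"),
                           rho = c(0.40, 0.30, 0.75),
                           tbeta = NULL,
                           tod = c("cosinor", "linear", "none")) {
  sex <- match.arg(sex)
  season <- match.arg(season)
  tod <- match.arg(tod)
  em <- switch(paste(sex, season, sep = "."),
    female.low_forage = list(mu = c(11.40, 37.70, 244.30),
                             sigma = c(7.38, 23.24, 220.97),
                             muphi = c(3.14, 3.11, 0.001)),
    female.high_forage = list(mu = c(19.25, 67.29, 276.62),
                              sigma = c(13.08, 48.32, 227.91),
                              muphi = c(-3.11, 3.14, 0.07)),
    male.low_forage = list(mu = c(9.68, 33.00, 398.43),
                           sigma = c(6.31, 23.11, 385.81),
                           muphi = c(-3.12, -3.12, -0.04)),
    male.high_forage = list(mu = c(14.27, 52.46, 420.70),
                            sigma = c(9.56, 34.67, 406.12),
                            muphi = c(3.11, 3.13, 0.02)))
  if (is.null(tbeta)) tbeta <- pig_transition_beta(tod = tod)
  hmm_params(em$mu, em$sigma, em$muphi, rho, tbeta, tod = tod)
}

#' Default transition coefficients for simulated pig movement
#'
#' Intercepts give a diagonally dominant hourly transition matrix (staying
#' probability 0.8, each switch 0.1 when `diel = FALSE`). With `diel =
#' TRUE`, cosinor terms modulate the switch probabilities over the 24-h
#' clock (more traveling at night, more resting by day), emulating the diel
#' activity structure of free-ranging pigs.
#'
#' @param K number of states (default 3).
#' @param diel add cosinor modulation (default `TRUE`).
#' @param tod covariate form (must be `"cosinor"` for `diel = TRUE`).
#' @return transition coefficient matrix, `K(K-1)` rows.
#' @export
pig_transition_beta <- function(K = 3, diel = TRUE,
                                tod = c("cosinor", "linear", "none")) {
  tod <- match.arg(tod)
  p <- tod_ncol(tod)
  tb <- matrix(0, K * (K - 1), p)
  tb[, 1] <- log(0.1 / 0.8)
  if (diel && tod == "cosinor" && K == 3) {
    # rows: (1,2) (1,3) (2,1) (2,3) (3,1) (3,2)
    # cos(2 pi h/24) peaks at midnight: entries into traveling peak at
    # night, entries into resting peak in the day
    tb[, 2] <- c(-0.3, 0.8, 0.5, 0.6, -0.8, -0.2)
    tb[, 3] <- c(0.2, 0.3, -0.2, 0.1, -0.3, 0.0)
  }
  tb
}

#' Simulate a movement track from an HMM
#'
#' States follow the initial distribution and the hour-dependent transition
#' matrix; each step draws its length from the state's gamma and its
#' turning angle from the state's wrapped Cauchy; the position advances by
#' heading accumulation (first heading uniform, thereafter `heading +
#' turn`). The first step of the track has no turning angle, mirroring real
#' step series.
#'
#' @param params `hmm_params`.
#' @param n_steps number of steps (the track has `n_steps + 1` fixes).
#' @param start start coordinates `c(x, y)`.
#' @param t0 POSIXct time of the first fix.
#' @param interval fix interval, seconds (default 3600).
#' @param animal_id id string for the output.
#' @param seed optional seed.
#' @return list with `fixes` (data frame `animal_id`, `t`, `x`, `y`),
#'   `states` (true state per step), `steps` (the step series as from
#'   [compute_steps()] with the true state attached).
#' @export
simulate_track <- function(params, n_steps, start = c(0, 0),
                           t0 = as.POSIXct("2015-06-01 00:00:00", tz = "UTC"),
                           interval = 3600, animal_id = "sim1", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  K <- params$K
  t <- t0 + (0:n_steps) * interval
  hour <- clock_hour(t)
  states <- integer(n_steps)
  states[1] <- sample.int(K, 1, prob = params$delta)
  for (s in seq_len(n_steps)[-1]) {
    G <- transition_matrix(params, hour[s])
    states[s] <- sample.int(K, 1, prob = G[states[s - 1], ])
  }
  sr <- gamma_shape_rate(params$mu, params$sigma)
  len <- stats::rgamma(n_steps, shape = sr$shape[states],
                       rate = sr$rate[states])
  turn <- c(NA_real_, vapply(seq_len(n_steps)[-1], function(s)
    rwcauchy(1, params$muphi[states[s]], params$rho[states[s]]),
    numeric(1)))
  heading <- numeric(n_steps)
  heading[1] <- stats::runif(1, -pi, pi)
  for (s in seq_len(n_steps)[-1]) heading[s] <- heading[s - 1] + turn[s]
  x <- start[1] + c(0, cumsum(len * cos(heading)))
  y <- start[2] + c(0, cumsum(len * sin(heading)))
  fixes <- data.frame(animal_id = animal_id, t = t, x = x, y = y,
                      stringsAsFactors = FALSE)
  steps <- data.frame(animal_id = animal_id, burst = 1L, t = t[-(n_steps + 1)],
                      x = x[-(n_steps + 1)], y = y[-(n_steps + 1)],
                      step_m = len, turn_rad = turn,
                      hour = hour[-(n_steps + 1)],
                      season = assign_season(t[-(n_steps + 1)]),
                      state = states, stringsAsFactors = FALSE)
  list(fixes = fixes, states = states, steps = steps)
}

#' Simulate a multi-animal telemetry study
#'
#' One track per animal per sex, drawn from the sex- and season-specific
#' default movement parameters. Track start positions scatter uniformly
#' over a square so that home ranges tile the landscape.
#'
#' @param n_per_sex animals per sex (default 8).
#' @param n_steps steps per track.
#' @param season `"low_forage"` or `"high_forage"`; sets both the emission
#'   defaults and the simulated calendar window.
#' @param extent side length (m) of the square the start positions scatter
#'   over.
#' @param margin minimum distance (m) of start positions from the extent
#'   edge.
#' @param interval fix interval (s).
#' @param diel include diel transition modulation.
#' @param rho per-state turn concentrations.
#' @param seed optional seed.
#' @return list with `fixes` (all animals bound together, with `sex`),
#'   `steps` (with true `state`), `truth` (the generating `hmm_params` per
#'   sex).
#' @export
simulate_study <- function(n_per_sex = 8, n_steps = 500,
                           season = c("low_forage", "high_forage"),
                           extent = 15000, margin = 2000, interval = 3600,
                           diel = TRUE, rho = c(0.40, 0.30, 0.75),
                           seed = NULL) {
  season <- match.arg(season)
  if (!is.null(seed)) set.seed(seed)
  t0 <- as.POSIXct(if (season == "low_forage") "2015-02-01 00:00:00"
                   else "2015-06-01 00:00:00", tz = "UTC")
  fixes <- list()
  steps <- list()
  truth <- list()
  b_off <- 0L
  for (sex in c("female", "male")) {
    pars <- pig_hmm_params(sex, season, rho = rho,
                           tbeta = pig_transition_beta(diel = diel))
    truth[[sex]] <- pars
    for (a in seq_len(n_per_sex)) {
      id <- sprintf("%s%02d", substr(sex, 1, 1), a)
      st <- c(stats::runif(1, margin, extent - margin),
              stats::runif(1, margin, extent - margin))
      tr <- simulate_track(pars, n_steps, start = st, t0 = t0,
                           interval = interval, animal_id = id)
      tr$fixes$sex <- sex
      tr$steps$sex <- sex
      tr$steps$burst <- b_off + 1L
      b_off <- b_off + 1L
      fixes[[id]] <- tr$fixes
      steps[[id]] <- tr$steps
    }
  }
  list(fixes = do.call(rbind, fixes), steps = do.call(rbind, steps),
       truth = truth)
}

# smoothed standard-normal random field via FFT convolution with a
# Gaussian kernel (periodic boundary), rescaled to unit variance
gaussian_field <- function(nr, nc, scale_cells) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  gx <- c(0:(floor(nc / 2)), -((ceiling(nc / 2) - 1):1))
  gy <- c(0:(floor(nr / 2)), -((ceiling(nr / 2) - 1):1))
  kern <- outer(exp(-gy^2 / (2 * scale_cells^2)),
                exp(-gx^2 / (2 * scale_cells^2)))
  sm <- Re(stats::fft(stats::fft(z) * stats::fft(kern / sum(kern)),
                      inverse = TRUE)) / (nr * nc)
  (sm - mean(sm)) / stats::sd(sm)
}

# meandering polyline across the extent, as a persistent random walk
random_polyline <- function(extent, step = 300, jitter = 0.25) {
  horizontal <- stats::runif(1) < 0.5
  pos <- c(if (horizontal) 0 else stats::runif(1, 0, extent),
           if (horizontal) stats::runif(1, 0, extent) else 0)
  ang <- if (horizontal) 0 else pi / 2
  pts <- list(pos)
  repeat {
    ang <- ang + stats::rnorm(1, 0, jitter)
    pos <- pos + step * c(cos(ang), sin(ang))
    pts[[length(pts) + 1]] <- pos
    if (any(pos < 0) || any(pos > extent)) break
  }
  m <- do.call(rbind, pts)
  colnames(m) <- c("x", "y")
  m
}

#' Generate a synthetic heterogeneous landscape
#'
#' Class raster from a smoothed Gaussian random field thresholded at the
#' mixing weights' quantiles (contiguous patches with exactly the requested
#' class proportions), stream and road networks as meandering polylines,
#' and a percent-canopy raster from a second smoothed field rescaled to
#' [0, 100] and elevated inside forested classes. Default composition
#' emulates a southeastern US pine-dominated industrial forest: ~50% upland
#' pine, 25% bottomland hardwood, 10% shrub/herbaceous, 8% upland hardwood,
#' and the rest developed and other.
#'
#' @param extent side length (m); must be a multiple of `cell`.
#' @param cell cell size (m), default 30.
#' @param weights class mixing weights in the order of
#'   [landcover_classes()]; must sum to 1.
#' @param patch_scale patch correlation scale (m).
#' @param n_streams,n_primary,n_secondary numbers of polylines.
#' @param canopy_scale canopy field correlation scale (m).
#' @param seed optional seed.
#' @return landscape list: `class` and `canopy` (`grid_raster`s), `streams`,
#'   `roads_primary`, `roads_secondary` (lists of polylines), `extent`,
#'   `cell`.
#' @export
make_landscape <- function(extent = 15000, cell = 30,
                           weights = c(upland_pine = 0.50,
                                       bottomland_hardwood = 0.25,
                                       shrub_herb = 0.10,
                                       upland_hardwood = 0.08,
                                       developed = 0.04, other = 0.03),
                           patch_scale = 600, canopy_scale = 900,
                           n_streams = 4, n_primary = 2, n_secondary = 4,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(abs(sum(weights) - 1) < 1e-8, extent %% cell == 0)
  n <- as.integer(extent / cell)
  fld <- gaussian_field(n, n, patch_scale / cell)
  br <- stats::quantile(fld, cumsum(weights), names = FALSE)
  cls <- matrix(findInterval(fld, br[-length(br)], left.open = TRUE) + 1L,
                n, n)
  # guarantee every class is present even on degenerate draws
  cls[cls > length(weights)] <- length(weights)
  origin <- c(0, extent)
  class_r <- grid_raster(cls, origin, cell)
  can <- gaussian_field(n, n, canopy_scale / cell)
  can <- (can - min(can)) / (max(can) - min(can)) * 100
  forested <- cls %in% which(names(weights) %in%
                               c("upland_pine", "bottomland_hardwood",
                                 "upland_hardwood"))
  can[forested] <- pmin(100, can[forested] + 25)
  canopy_r <- grid_raster(matrix(can, n, n), origin, cell)
  list(class = class_r, canopy = canopy_r,
       streams = replicate(n_streams, random_polyline(extent),
                           simplify = FALSE),
       roads_primary = replicate(n_primary, random_polyline(extent, jitter = 0.05),
                                 simplify = FALSE),
       roads_secondary = replicate(n_secondary, random_polyline(extent, jitter = 0.15),
                                   simplify = FALSE),
       extent = extent, cell = cell, weights = weights)
}

#' Simulate used points from a known resource selection function
#'
#' Rejection sampling: uniform proposals in the region are accepted with
#' probability proportional to `exp(beta' x(s) + b_animal)` where `x(s)`
#' are the *standardized* covariates at the proposal and `b_animal ~
#' N(0, tau^2)` is a per-animal intercept. With a fixed number of used
#' points per animal the intercept cancels from the accepted spatial
#' pattern; it is retained for designs where per-animal sample sizes vary.
#'
#' @param beta named coefficient vector on the standardized covariate scale;
#'   names must match columns produced by `stack`.
#' @param stack named list of covariate `grid_raster`s.
#' @param region `region_polygon` or `region_mask` to sample within.
#' @param n_used used points per animal.
#' @param n_animals number of animals.
#' @param tau random-intercept SD (default 0).
#' @param stats optional standardization statistics (as from
#'   [standardize_covariates()]); defaults to the mean/SD of each raster
#'   over the region's bounding box.
#' @param max_tries proposals drawn per batch before checking the
#'   acceptance-rate guard (error below 1e-4).
#' @param seed optional seed.
#' @return data frame `animal_id`, `x`, `y` plus the standardized covariate
#'   columns; attribute `b_animal` holds the simulated intercepts and
#'   `stats` the standardization used.
#' @export
simulate_rsf_points <- function(beta, stack, region, n_used = 50,
                                n_animals = 10, tau = 0, stats = NULL,
                                max_tries = 2e6, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(names(beta) %in% names(stack)), tau >= 0)
  bb <- region_bbox(region)
  if (is.null(stats)) {
    vals <- lapply(names(beta), function(nm) as.numeric(stack[[nm]]$values))
    stats <- data.frame(column = names(beta),
                        mean = vapply(vals, mean, numeric(1)),
                        sd = vapply(vals, stats::sd, numeric(1)))
  }
  # upper bound of the linear predictor over the region for the envelope
  zmax <- sum(vapply(names(beta), function(nm) {
    z <- (range(stack[[nm]]$values, na.rm = TRUE) -
            stats$mean[stats$column == nm]) / stats$sd[stats$column == nm]
    max(beta[[nm]] * z)
  }, numeric(1)))
  b_animal <- stats::rnorm(n_animals, 0, tau)
  out <- list()
  for (a in seq_len(n_animals)) {
    got <- 0L
    acc <- list()
    tried <- 0L
    while (got < n_used) {
      m <- max(4L * n_used, 1000L)
      px <- stats::runif(m, bb[1], bb[2])
      py <- stats::runif(m, bb[3], bb[4])
      inside <- point_in_region(region, px, py)
      px <- px[inside]; py <- py[inside]
      if (length(px)) {
        zz <- vapply(names(beta), function(nm)
          (raster_lookup(stack[[nm]], px, py) -
             stats$mean[stats$column == nm]) / stats$sd[stats$column == nm],
          numeric(length(px)))
        zz <- matrix(zz, ncol = length(beta))
        eta <- drop(zz %*% unlist(beta))
        keep <- !is.na(eta) &
          stats::runif(length(eta)) < exp(eta - zmax)
        if (any(keep)) {
          df <- data.frame(animal_id = sprintf("a%02d", a),
                           x = px[keep], y = py[keep])
          df <- cbind(df, as.data.frame(zz[keep, , drop = FALSE],
                                        col.names = names(beta)))
          names(df)[-(1:3)] <- names(beta)
          acc[[length(acc) + 1]] <- df
          got <- got + sum(keep)
        }
      }
      tried <- tried + m
      if (tried > max_tries && got < max(1, 1e-4 * tried)) {
        stop("acceptance rate below 1e-4; rescale beta or enlarge region")
      }
      if (tried > 50 * max_tries) stop("rejection sampling did not finish")
    }
    df <- do.call(rbind, acc)[seq_len(n_used), , drop = FALSE]
    out[[a]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "b_animal") <- b_animal
  attr(res, "stats") <- stats
  res
}
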