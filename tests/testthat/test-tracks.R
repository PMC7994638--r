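ts0 <- as.POSIXct("2015-02-01 00:00:00", tz = "UTC")

write_fix_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE)
  path
}

test_that("parse_fixes reads well-formed tables and reports bad rows", {
  p <- write_fix_csv(data.frame(
    animal_id = "a1", timestamp = format(ts0 + 0:2 * 3600, "%Y-%m-%dT%H:%M:%SZ"),
    x = c(0, 10, 20), y = 0))
  fx <- parse_fixes(p)
  expect_equal(nrow(fx), 3)
  expect_s3_class(fx$t, "POSIXct")
  expect_equal(fx$x, c(0, 10, 20))

  p2 <- write_fix_csv(data.frame(animal_id = "a1", timestamp = "2015-01-01 00:00:00",
                                 x = 1))
  expect_error(parse_fixes(p2), "y")

  p3 <- write_fix_csv(data.frame(
    animal_id = "a1",
    timestamp = c("2015-01-01 00:00:00", "not-a-date", "2015-01-01 02:00:00"),
    x = 0, y = 0))
  expect_warning(fx3 <- parse_fixes(p3), "rejected 1")
  expect_equal(nrow(fx3), 2)
  expect_equal(attr(fx3, "rejected"), 2L)
})

test_that("clean_track drops the first 48 h half-open, duplicates, post-mortality", {
  fx <- data.frame(animal_id = "a1", t = ts0 + 0:99 * 3600,
                   x = rnorm(100), y = rnorm(100))
  tr <- clean_track(fx, deploy_time = ts0)
  expect_equal(nrow(tr), 52)                 # fix at exactly +48 h retained
  expect_equal(min(tr$t), ts0 + 48 * 3600)
  expect_equal(unname(attr(tr, "removed")["pre_48h"]), 48)

  fx2 <- fx[c(1, 1, 2:100), ]
  tr2 <- clean_track(fx2, deploy_time = ts0 - 72 * 3600)
  expect_equal(unname(attr(tr2, "removed")["duplicates"]), 1)
  expect_equal(nrow(tr2), 100)

  tr3 <- clean_track(fx, deploy_time = ts0 - 72 * 3600,
                     mortality_time = fx$t[80])
  expect_equal(nrow(tr3), 79)                # fixes 80..100 dropped
  expect_equal(unname(attr(tr3, "removed")["post_mortality"]), 21)

  # empty result is a zero-row track, not an error
  tr4 <- clean_track(fx[1:3, ], deploy_time = ts0)
  expect_equal(nrow(tr4), 0)
})

test_that("cleaning is idempotent", {
  set.seed(4)
  fx <- data.frame(animal_id = "a1",
                   t = ts0 + sort(sample(0:200, 120)) * 3600,
                   x = rnorm(120), y = rnorm(120))
  fx <- fx[c(1:120, 17, 33), ]
  c1 <- clean_track(fx, deploy_time = ts0)
  c2 <- clean_track(c1, deploy_time = ts0)
  expect_equal(c2$t, c1$t)
  expect_equal(c2$x, c1$x)
})

test_that("regularize thins 30-min data and splits on gaps", {
  fx30 <- data.frame(animal_id = "a1", t = ts0 + 0:9 * 1800, x = 1:10, y = 0)
  b <- regularize(fx30)
  expect_equal(nrow(b), 5)
  expect_equal(unique(b$burst), 1L)
  expect_equal(as.numeric(diff(b$t), units = "secs"), rep(3600, 4))

  t_gap <- ts0 + c(0:4, 7:11) * 3600   # one 3-h gap mid-track
  fxg <- data.frame(animal_id = "a1", t = t_gap, x = seq_along(t_gap), y = 0)
  bg <- regularize(fxg)
  expect_equal(length(unique(bg$burst)), 2)

  # 2-fix fragment after splitting is discarded and counted
  t_frag <- ts0 + c(0:4, 10, 11) * 3600
  fxf <- data.frame(animal_id = "a1", t = t_frag, x = seq_along(t_frag), y = 0)
  bf <- regularize(fxf)
  expect_equal(length(unique(bf$burst)), 1)
  expect_equal(attr(bf, "discarded"), 1L)
})

test_that("assign_season partitions the calendar at April/May", {
  expect_equal(assign_season(as.POSIXct("2014-04-30 23:00:00", tz = "UTC")),
               "low_forage")
  expect_equal(assign_season(as.POSIXct("2014-05-01 00:00:00", tz = "UTC")),
               "high_forage")
  expect_equal(assign_season(as.POSIXct("2014-12-15 12:00:00", tz = "UTC")),
               "high_forage")
  months <- as.POSIXct(sprintf("2014-%02d-15 00:00:00", 1:12), tz = "UTC")
  s <- assign_season(months)
  expect_true(all(s %in% c("low_forage", "high_forage")))
  expect_equal(sum(s == "low_forage"), 4)
})

test_that("compute_steps derives lengths, signed wrapped angles and hours", {
  mk <- function(xy) data.frame(animal_id = "a1", t = ts0 + 0:(nrow(xy) - 1) * 3600,
                                x = xy[, 1], y = xy[, 2], burst = 1L)
  st <- compute_steps(mk(cbind(c(0, 100, 200), 0)))
  expect_equal(st$step_m, c(100, 100))
  expect_equal(st$turn_rad, c(NA, 0))

  # exact reversal gives +pi, not -pi
  st2 <- compute_steps(mk(cbind(c(0, 100, 0), 0)))
  expect_equal(st2$turn_rad[2], pi)

  # right-angle left turn is +pi/2 (counterclockwise positive)
  st3 <- compute_steps(mk(cbind(c(0, 100, 100), c(0, 0, 100))))
  expect_equal(st3$turn_rad[2], pi / 2)
  expect_equal(st3$hour, c(0, 1))
  expect_error(compute_steps(mk(cbind(c(0, 1), c(0, 0)))), "fewer than 3")
})

test_that("step/turn counts and rigid-motion invariance hold per burst", {
  set.seed(11)
  n <- 40
  xy <- cbind(cumsum(rnorm(n, 0, 50)), cumsum(rnorm(n, 0, 50)))
  b <- data.frame(animal_id = "a1", t = ts0 + 0:(n - 1) * 3600,
                  x = xy[, 1], y = xy[, 2], burst = 1L)
  st <- compute_steps(b)
  expect_equal(nrow(st), n - 1)
  expect_equal(sum(!is.na(st$turn_rad)), n - 2)

  th <- 0.83
  Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  xyr <- sweep(xy %*% t(Rm), 2, c(-500, 1200), "+")
  br <- b; br$x <- xyr[, 1]; br$y <- xyr[, 2]
  str <- compute_steps(br)
  expect_equal(str$step_m, st$step_m, tolerance = 1e-10)
  expect_equal(str$turn_rad, st$turn_rad, tolerance = 1e-8)
})

test_that("preprocess_fixes chains cleaning, regularization and steps", {
  set.seed(2)
  fx <- rbind(
    data.frame(animal_id = "a1", t = ts0 + 0:199 * 3600,
               x = cumsum(rnorm(200, 0, 30)), y = cumsum(rnorm(200, 0, 30))),
    data.frame(animal_id = "a2", t = ts0 + 0:149 * 3600,
               x = cumsum(rnorm(150, 0, 30)), y = cumsum(rnorm(150, 0, 30))))
  st <- preprocess_fixes(fx)
  expect_equal(sort(unique(st$animal_id)), c("a1", "a2"))
  # each animal loses 48 fixes to the deployment screen, steps = fixes - 1
  expect_equal(sum(st$animal_id == "a1"), 200 - 48 - 1)
  expect_equal(sum(st$animal_id == "a2"), 150 - 48 - 1)
  expect_false(any(duplicated(paste(st$animal_id, st$t))))
})
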