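test_that("parameter sampling is seeded-deterministic and honours priors", {
  cfg <- sim_config(seed = 77)
  p1 <- sample_bird_parameters(cfg)
  p2 <- sample_bird_parameters(cfg)
  expect_identical(as.data.frame(p1), as.data.frame(p2))
  expect_equal(nrow(p1), sum(cfg$birds_per_round))

  # degenerate prior pins the parameter exactly
  pfix <- sample_bird_parameters(cfg, bird_priors(sigma_mean = 2, sigma_sd = 0))
  expect_true(all(pfix$sigma == 2))

  # invalid prior bounds are a configuration error
  expect_error(bird_priors(rho_max = 1.2), "rho_max")
  expect_error(bird_priors(sigma_sd = -1), "non-negative")

  # Monte-Carlo: the sample mean of the trend intercept tracks its prior
  cfg1k <- sim_config(n_rounds = 1, birds_per_round = 1000, seed = 3)
  pr <- bird_priors()
  pp <- sample_bird_parameters(cfg1k, pr)
  se <- pr$a_sd / sqrt(1000)
  expect_lt(abs(mean(pp$a) - pr$a_mean), 3 * se)
})

test_that("daily activity targets follow the trend plus AR(1) deviations", {
  set.seed(1)
  # noise-free: exactly on the truncated line
  expect_equal(simulate_daily_activity_targets(5, -0.2, 0, 0, 1:30),
               pmax(0, 5 - 0.2 * (1:30)))
  expect_equal(simulate_daily_activity_targets(20, 0, 0, 0, 1:5), rep(20, 5))

  # white noise: sample lag-1 autocorrelation within 0.01 of zero
  e0 <- ar1_deviations(1e5, 2, 0)
  expect_lt(abs(cor(e0[-1], e0[-length(e0)])), 0.01)
  expect_equal(sd(e0), 2, tolerance = 0.02)

  # AR(1): within 0.02 of rho, marginal SD preserved
  e6 <- ar1_deviations(1e5, 2, 0.6)
  expect_equal(cor(e6[-1], e6[-length(e6)]), 0.6, tolerance = 0.02)
  expect_equal(sd(e6), 2, tolerance = 0.03)
})

test_that("within-day simulation round-trips the target DADM through kinematics", {
  g <- build_antenna_grid()
  set.seed(55)
  # worked case: target 20 m/h recovers within 10%
  day <- simulate_bird_day(20, 0.5, g, sample_period_s = 30)
  ev <- day$events[sec_of_day >= 25200 & sec_of_day < 82800]
  ev[, segment := 1L]
  dadm <- daily_average_distance(daily_distance(ev, g), 57600)
  expect_gte(dadm, 18); expect_lte(dadm, 22)

  # calibration sweep: >= 95% of days within 10% for targets in [2, 40]
  targets <- rep(seq(2, 40, length.out = 20), each = 5)
  rel_err <- vapply(targets, function(tg) {
    d <- simulate_bird_day(tg, runif(1), g, sample_period_s = 60)
    e <- d$events[sec_of_day >= 25200 & sec_of_day < 82800]
    e[, segment := 1L]
    abs(daily_average_distance(daily_distance(e, g), 57600) - tg) / tg
  }, numeric(1))
  expect_gte(mean(rel_err <= 0.10), 0.95)

  # target 0: a single antenna all day, zero distance downstream
  d0 <- simulate_bird_day(0, 0.5, g, sample_period_s = 30)
  expect_equal(length(unique(d0$events$antenna)), 1)

  # unachievable target errors out
  expect_error(simulate_bird_day(5000, 0.5, g), "exceeds")
})

test_that("movement is suppressed during dark periods", {
  g <- build_antenna_grid()
  set.seed(9)
  day <- simulate_bird_day(25, 0.5, g, emit = "minutes")
  dark_min <- c(1:180, 301:420, 1381:1440)      # 00-03, 05-07, 23-24
  light_min <- 421:1380                          # 07-23
  rate_dark <- mean(day$minute_moves[dark_min])
  rate_light <- mean(day$minute_moves[light_min])
  expect_lt(rate_dark, 0.15 * rate_light)
})

test_that("bout regularity maps monotonically to daily sample entropy", {
  g <- build_antenna_grid()
  set.seed(202)
  ent <- vapply(c(0.05, 0.5, 0.95), function(reg) {
    mean(vapply(1:60, function(i) {
      d <- simulate_bird_day(20, reg, g, emit = "minutes")
      cls <- minute_moves_to_classes(d$minute_moves)
      brute_sampen(cls$class, r = 0.2 * sd(cls$class))
    }, numeric(1)), na.rm = TRUE)
  }, numeric(1))
  expect_true(ent[1] > ent[2] && ent[2] > ent[3])
})

test_that("weight tables linearise growth and respect rounding precision", {
  wt <- simulate_weights(40, 70, 0, weigh_days = c(0, 7, 14, 21, 28, 35),
                         start_precision = 1, precision = 1)
  expect_equal(wt$weight_g[wt$age_days == 35], 2490)  # 40 + 70*35
  wt5 <- simulate_weights(40, 70, 0, weigh_days = c(0, 35),
                          start_precision = 2, precision = 5)
  expect_equal(wt5$weight_g[2] %% 5, 0)
  expect_error(simulate_weights(40, -10, 0, weigh_days = c(0, 35)),
               "negative")

  # noise off, growth decoupled from activity: identical ADG for birds
  # differing only in sigma
  cfg <- sim_config(n_rounds = 1, birds_per_round = 20, seed = 4)
  pr0 <- bird_priors(adg_noise_sd = 0, beta_rmse = 0, w0_sd = 0)
  params <- sample_bird_parameters(cfg, pr0)
  gr <- simulate_growth(params, pr0)
  expect_equal(length(unique(gr$truth$adg_true)), 1)
  expect_gt(sd(params$sigma), 0)

  # ADG recomputed from written (rounded) weights matches truth up to
  # rounding: |error| <= (5/2 + 1/2) / (end - start)
  params5 <- sample_bird_parameters(cfg, bird_priors(adg_noise_sd = 0))
  gr5 <- simulate_growth(params5, bird_priors(adg_noise_sd = 0),
                         start_precision = 1, precision = 5)
  g5 <- growth_records(gr5$weights)
  m <- merge(g5, gr5$truth, by = "bird_id")
  expect_true(all(abs(m$adg - m$adg_true) <= 3 / (m$end_age - m$start_age)))
})

test_that("growth coefficients are recoverable by regression on sigma", {
  cfg <- sim_config(n_rounds = 1, birds_per_round = 500, seed = 12)
  pr <- bird_priors(beta_rmse = -1.0, adg_noise_sd = 5)
  params <- sample_bird_parameters(cfg, pr)
  gr <- simulate_growth(params, pr)
  slope <- brute_ols_slope(params$sigma, gr$truth$adg_true)
  expect_gt(slope, -1.2); expect_lt(slope, -0.8)
})

test_that("generated datasets are byte-identical under a fixed seed", {
  cfg <- sim_config(n_rounds = 1, birds_per_round = 2, sim_age_max = 3,
                    end_ages = 8, sample_period_s = 120, seed = 31,
                    gap_rate_per_day = 0.5)
  d1 <- file.path(tempdir(), "fixA"); d2 <- file.path(tempdir(), "fixB")
  generate_dataset(cfg, bird_priors(), d1)
  generate_dataset(cfg, bird_priors(), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = paste("file", f))
  }
})

test_that("fixture round trip: bird-day bookkeeping and gap-free logs", {
  cfg <- sim_config(n_rounds = 1, birds_per_round = 3, sim_age_max = 5,
                    end_ages = 30, sample_period_s = 60, seed = 41,
                    gap_rate_per_day = 0)
  dir <- file.path(tempdir(), "fixC")
  ds <- generate_dataset(cfg, bird_priors(), dir)
  g <- build_antenna_grid()
  rec <- read_rfid_log(file.path(dir, "rfid_round1.csv"), grid = g)
  gaps <- find_group_gaps(rec)
  # zero gap rate: no detectable group gap beyond the handling windows
  hw <- ds$windows
  expect_lte(nrow(gaps), nrow(hw))
  if (nrow(gaps) > 0) {
    # any detected silence must overlap a handling window (the last
    # keep-alive before handling can precede it by up to one period)
    hs <- as.POSIXct(hw$start, tz = "UTC", format = "%Y-%m-%dT%H:%M:%S")
    he <- as.POSIXct(hw$end, tz = "UTC", format = "%Y-%m-%dT%H:%M:%S")
    overlaps <- vapply(seq_len(nrow(gaps)), function(i) {
      any(gaps$start[i] < he & gaps$end[i] > hs)
    }, logical(1))
    expect_true(all(overlaps))
  }
  rounds <- data.frame(round_id = 1, start_date = as.character(cfg$round_start_dates[1]),
                       start_age = cfg$start_ages[1], end_age = cfg$end_ages[1])
  st <- clip_to_light_period(rec, gaps, rounds)
  # birds x simulated days, no fully-gapped days
  expect_equal(nrow(st$bird_days), 3 * 5)
  expect_equal(sum(st$bird_days$missing), 0)
})
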