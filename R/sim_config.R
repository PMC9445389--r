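#' Simulation configuration
#'
#' Describes a simulated multi-round tracking study: pen and antenna
#' geometry, round structure (number of birds, start/end ages), lighting
#' schedule, recording behaviour and sensor-gap model. Defaults mirror
#' the study conditions the pipeline targets: a 1.8 x 2.6 m pen with a
#' 5 x 6 antenna grid, five consecutive rounds of 78-82 male birds
#' starting at age 0 or 1 and ending at 33-36 days, dark periods
#' 23:00-03:00 and 05:00-07:00, and weekly weighings.
#'
#' @param n_rounds number of production rounds.
#' @param birds_per_round birds at round start (recycled to `n_rounds`).
#' @param start_ages,end_ages bird age (days) at round start / end
#'   (recycled).
#' @param pen_w,pen_l pen width and length in metres.
#' @param grid_cols,grid_rows antenna grid dimensions
#'   (`grid_cols * grid_rows` antennas).
#' @param dark_periods list of clock intervals with lights off (movement
#'   is suppressed); must be disjoint and within 00:00-24:00.
#' @param light_period the analysis light period (activity window).
#' @param seed integer RNG seed; all simulator randomness derives from
#'   it.
#' @param sample_period_s keep-alive registration period in seconds. At
#'   the nominal 1 s every second is sampled; larger values thin the
#'   keep-alive stream (every antenna switch is always emitted, so
#'   distances are unaffected) and keep test fixtures small.
#' @param sim_age_max last age (days) for which RFID days are generated
#'   (default 16; the analysis window ends at age 15). Weights span the
#'   full round regardless.
#' @param gap_rate_per_day expected group-level sensor gaps per day,
#'   per round (recycled; the first round defaults to a gap-ridden
#'   sensor, the rest to rare gaps).
#' @param gap_duration_s range (seconds) of uniform gap durations.
#' @param handling_start,handling_minutes start clock time and duration
#'   of the handling (weighing) exclusion window on weigh days.
#' @param weigh_interval_days days between weighings (default 7).
#' @param start_weight_precision_g start-weight rounding precision per
#'   round, grams (recycled).
#' @param weight_precision_g rounding precision of later weights
#'   (default 5 g).
#' @param dark_move_factor multiplier on the movement rate during dark
#'   periods (default 0.05: birds are relatively inactive in the dark).
#' @param bout_mean_active_min,bout_mean_inactive_min mean duration
#'   (minutes) of active / inactive bouts of the two-state within-day
#'   movement process.
#' @param round_start_dates optional Date vector (one per round); the
#'   default spaces rounds 7 weeks apart starting 2021-01-05.
#' @param removed_birds bird ids scripted for exclusion before analysis
#'   (sexing errors, deaths, density removals); they are simulated but
#'   flagged in the metadata.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_rounds = 5,
                       birds_per_round = c(80, 82, 82, 78, 80),
                       start_ages = c(1, 0, 0, 1, 1),
                       end_ages = c(36, 33, 35, 35, 33),
                       pen_w = 1.8, pen_l = 2.6,
                       grid_cols = 5, grid_rows = 6,
                       dark_periods = list(c("00:00", "03:00"),
                                           c("05:00", "07:00"),
                                           c("23:00", "24:00")),
                       light_period = c("07:00", "23:00"),
                       seed = 1L,
                       sample_period_s = 1,
                       sim_age_max = 16,
                       gap_rate_per_day = c(3, 0.2, 0.2, 0.2, 0.2),
                       gap_duration_s = c(330, 1500),
                       handling_start = "09:00",
                       handling_minutes = 30,
                       weigh_interval_days = 7,
                       start_weight_precision_g = c(2, 1, 2, 1, 1),
                       weight_precision_g = 5,
                       dark_move_factor = 0.05,
                       bout_mean_active_min = 5,
                       bout_mean_inactive_min = 5,
                       round_start_dates = NULL,
                       removed_birds = character()) {
  stopifnot(n_rounds >= 1, grid_cols >= 1, grid_rows >= 1,
            pen_w > 0, pen_l > 0, sample_period_s >= 1,
            weigh_interval_days >= 1, sim_age_max >= 1)
  rec <- function(v) rep_len(v, n_rounds)
  birds_per_round <- rec(birds_per_round)
  start_ages <- rec(start_ages); end_ages <- rec(end_ages)
  gap_rate_per_day <- rec(gap_rate_per_day)
  start_weight_precision_g <- rec(start_weight_precision_g)
  if (any(birds_per_round < 1)) stop("birds_per_round must be positive")
  if (any(end_ages <= start_ages)) stop("end age must exceed start age")
  dark <- clock_intervals(dark_periods)  # validates disjointness
  lp <- parse_clock(light_period)
  if (interval_overlap_s(lp[1], lp[2], dark) > 0)
    stop("light_period overlaps a dark period")
  if (is.null(round_start_dates)) {
    round_start_dates <- as.Date("2021-01-05") + 49 * (seq_len(n_rounds) - 1)
  } else {
    round_start_dates <- as.Date(round_start_dates)
    stopifnot(length(round_start_dates) == n_rounds)
  }
  structure(list(
    n_rounds = n_rounds, birds_per_round = birds_per_round,
    start_ages = start_ages, end_ages = end_ages,
    pen_w = pen_w, pen_l = pen_l,
    grid_cols = grid_cols, grid_rows = grid_rows,
    dark_periods = dark, light_period = light_period,
    seed = as.integer(seed), sample_period_s = sample_period_s,
    sim_age_max = sim_age_max,
    gap_rate_per_day = gap_rate_per_day, gap_duration_s = gap_duration_s,
    handling_start = handling_start, handling_minutes = handling_minutes,
    weigh_interval_days = weigh_interval_days,
    start_weight_precision_g = start_weight_precision_g,
    weight_precision_g = weight_precision_g,
    dark_move_factor = dark_move_factor,
    bout_mean_active_min = bout_mean_active_min,
    bout_mean_inactive_min = bout_mean_inactive_min,
    round_start_dates = round_start_dates,
    removed_birds = removed_birds
  ), class = "sim_config")
}

#' Priors of the per-bird generating parameters
#'
#' Each simulated bird follows a declining linear daily-activity trend
#' `a + b * age` (m/h) with AR(1) day-to-day deviations of marginal SD
#' `sigma` and lag-1 correlation `rho`, a within-day bout regularity
#' `reg` in \[0, 1\], a start weight `w0` (g), and a true average daily
#' gain `ADG = beta0 + beta_sw * w0 + beta_rmse * sigma + noise` that
#' couples growth (weakly, negatively) to activity variability. Default
#' means put cohort-level mean distance near 20 m/h, trend-residual RMSE
#' near 3.6 m/h and ADG near 77 g/day.
#'
#' Setting an `_sd` to zero fixes the parameter at its mean.
#'
#' @param a_mean,a_sd trend intercept prior, m/h (normal, truncated
#'   below at 1).
#' @param b_mean,b_sd trend slope prior, m/h/day (normal; typically
#'   negative).
#' @param sigma_mean,sigma_sd,sigma_min deviation SD prior, m/h (normal
#'   truncated below at `sigma_min`).
#' @param rho_mean,rho_sd,rho_max deviation lag-1 autocorrelation prior
#'   (normal clamped to `[-rho_max, rho_max]`, `rho_max < 1`).
#' @param reg_shape1,reg_shape2 Beta prior of the bout regularity.
#' @param w0_mean,w0_sd start-weight prior, g.
#' @param beta0,beta_sw,beta_rmse growth coefficients (g/day intercept,
#'   per gram of start weight, per m/h of deviation SD).
#' @param adg_noise_sd residual SD of true ADG, g/day.
#' @return a validated list of class `bird_priors`.
#' @export
bird_priors <- function(a_mean = 26, a_sd = 4.5,
                        b_mean = -0.8, b_sd = 0.25,
                        sigma_mean = 3.9, sigma_sd = 1.6, sigma_min = 0.3,
                        rho_mean = 0.15, rho_sd = 0.2, rho_max = 0.9,
                        reg_shape1 = 2, reg_shape2 = 2,
                        w0_mean = 42, w0_sd = 3,
                        beta0 = 64.5, beta_sw = 0.41, beta_rmse = -1.08,
                        adg_noise_sd = 9) {
  if (rho_max >= 1 || rho_max < 0)
    stop("rho_max must lie in [0, 1): |rho| < 1 is required")
  if (abs(rho_mean) >= 1) stop("rho_mean must have absolute value < 1")
  if (any(c(a_sd, b_sd, sigma_sd, rho_sd, w0_sd, adg_noise_sd) < 0))
    stop("prior standard deviations must be non-negative")
  if (sigma_min < 0) stop("sigma_min must be non-negative (SDs cannot be negative)")
  if (reg_shape1 <= 0 || reg_shape2 <= 0) stop("Beta shapes must be positive")
  structure(list(a_mean = a_mean, a_sd = a_sd, b_mean = b_mean, b_sd = b_sd,
                 sigma_mean = sigma_mean, sigma_sd = sigma_sd,
                 sigma_min = sigma_min,
                 rho_mean = rho_mean, rho_sd = rho_sd, rho_max = rho_max,
                 reg_shape1 = reg_shape1, reg_shape2 = reg_shape2,
                 w0_mean = w0_mean, w0_sd = w0_sd,
                 beta0 = beta0, beta_sw = beta_sw, beta_rmse = beta_rmse,
                 adg_noise_sd = adg_noise_sd),
            class = "bird_priors")
}

#' Draw per-bird generating parameters
#'
#' Seeds the RNG from `config$seed` and draws one parameter set per bird
#' from the priors; identical config and priors always give identical
#' draws.
#'
#' @param config a [sim_config()].
#' @param priors a [bird_priors()].
#' @return data.table with one row per bird: `bird_id`, `round_id`,
#'   `start_age`, `end_age`, `a`, `b`, `sigma`, `rho`, `reg`, `w0`.
#'   The priors are attached as attribute `priors`.
#' @export
sample_bird_parameters <- function(config, priors = bird_priors()) {
  stopifnot(inherits(config, "sim_config"), inherits(priors, "bird_priors"))
  set.seed(config$seed)
  rows <- lapply(seq_len(config$n_rounds), function(r) {
    nb <- config$birds_per_round[r]
    data.table(
      bird_id = sprintf("R%dB%03d", r, seq_len(nb)),
      round_id = r,
      start_age = config$start_ages[r],
      end_age = config$end_ages[r],
      a = pmax(1, rnorm(nb, priors$a_mean, priors$a_sd)),
      b = rnorm(nb, priors$b_mean, priors$b_sd),
      sigma = pmax(priors$sigma_min, rnorm(nb, priors$sigma_mean, priors$sigma_sd)),
      rho = pmin(priors$rho_max,
                 pmax(-priors$rho_max, rnorm(nb, priors$rho_mean, priors$rho_sd))),
      reg = stats::rbeta(nb, priors$reg_shape1, priors$reg_shape2),
      w0 = pmax(30, rnorm(nb, priors$w0_mean, priors$w0_sd))
    )
  })
  out <- rbindlist(rows)
  setattr(out, "priors", priors)
  out[]
}
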