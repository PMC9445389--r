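# Cohort generator at the daily-series level: simulates each bird's daily
# activity targets and pushes them through the descriptor operations,
# optionally attaching entropy from fast-path within-day simulations.
# Used by the recovery and type-I tests, where the antenna-level round
# trip (validated separately) would only add runtime.
sim_descriptor_cohort <- function(n, sigma, rho = 0, reg = 0.5,
                                  days = 1:15, ent_days = 0,
                                  ent_target = 20,
                                  priors = bird_priors(),
                                  grid = build_antenna_grid()) {
  sigma <- rep_len(sigma, n); rho <- rep_len(rho, n); reg <- rep_len(reg, n)
  a <- pmax(1, rnorm(n, priors$a_mean, priors$a_sd))
  b <- rnorm(n, priors$b_mean, priors$b_sd)
  rows <- lapply(seq_len(n), function(j) {
    dadm <- simulate_daily_activity_targets(a[j], b[j], sigma[j], rho[j], days)
    fit <- fit_individual_trend(days, dadm)
    ent <- if (ent_days > 0) {
      mean(vapply(seq_len(ent_days), function(d) {
        day <- simulate_bird_day(ent_target, reg[j], grid, emit = "minutes")
        cls <- minute_moves_to_classes(day$minute_moves)
        sample_entropy(cls$class, r = 0.2 * sd(cls$class))
      }, numeric(1)), na.rm = TRUE)
    } else NA_real_
    data.table::data.table(
      md = mean_distance(dadm),
      skew = activity_skewness(dadm),
      rmse = activity_rmse(fit),
      ac = lag1_autocorrelation(fit),
      ent = ent)
  })
  out <- data.table::rbindlist(rows)
  out[, `:=`(bird_id = sprintf("B%04d", seq_len(n)),
             sigma = sigma, rho = rho, reg = reg, a = a, b = b)]
  out[]
}

# small end-to-end simulation config for pipeline tests
tiny_sim_config <- function(seed = 101, ...) {
  sim_config(n_rounds = 2, birds_per_round = 5, start_ages = c(1, 0),
             end_ages = c(36, 33), sample_period_s = 60,
             gap_rate_per_day = c(2, 0.1), seed = seed, ...)
}
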