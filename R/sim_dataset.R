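#' Simulate a bird's weekly weight table
#'
#' Growth is linearised around the true average daily gain:
#' `W(d) = w0 + adg_true * (d - start_age)`, evaluated at the weigh
#' days. The start weight is rounded to `start_precision` grams and all
#' later weights to `precision` grams (weighing-scale resolution).
#'
#' @param w0 start weight, g.
#' @param adg_true true average daily gain, g/day.
#' @param start_age age at the first weighing, days.
#' @param weigh_days ages (days) at which the bird is weighed; must
#'   include `start_age` and the final age.
#' @param start_precision,precision rounding precision, g.
#' @return data.table `age_days`, `weight_g`.
#' @export
simulate_weights <- function(w0, adg_true, start_age, weigh_days,
                             start_precision = 1, precision = 5) {
  stopifnot(start_age %in% weigh_days)
  w <- w0 + adg_true * (weigh_days - start_age)
  if (any(w < 0)) stop("negative generated weight: ADG/start weight inconsistent")
  rounded <- ifelse(weigh_days == start_age,
                    round(w / start_precision) * start_precision,
                    round(w / precision) * precision)
  data.table(age_days = as.integer(weigh_days), weight_g = rounded)
}

# true ADG from the growth coefficients of the priors
true_adg <- function(priors, w0, sigma) {
  priors$beta0 + priors$beta_sw * w0 + priors$beta_rmse * sigma +
    rnorm(length(w0), 0, priors$adg_noise_sd)
}

#' Simulate growth (true ADG and weekly weight tables) for a cohort
#'
#' Draws each bird's true average daily gain from the priors' growth
#' model, `ADG = beta0 + beta_sw * w0 + beta_rmse * sigma + noise`, and
#' writes out its weekly weight table via [simulate_weights()].
#'
#' @param params bird parameter table from [sample_bird_parameters()]
#'   (columns `bird_id`, `round_id`, `start_age`, `end_age`, `sigma`,
#'   `w0`).
#' @param priors a [bird_priors()].
#' @param weigh_interval_days days between weighings (default 7; the
#'   final age is always included).
#' @param start_precision,precision weight rounding precisions, g.
#' @return list with `weights` (data.table `bird_id`, `round_id`,
#'   `age_days`, `weight_g`) and `truth` (data.table `bird_id`,
#'   `adg_true`).
#' @export
simulate_growth <- function(params, priors, weigh_interval_days = 7,
                            start_precision = 1, precision = 5) {
  p <- as.data.table(params)
  adg <- true_adg(priors, p$w0, p$sigma)
  wl <- lapply(seq_len(nrow(p)), function(j) {
    weigh_ages <- sort(unique(c(seq(p$start_age[j], p$end_age[j],
                                    by = weigh_interval_days),
                                p$end_age[j])))
    wt <- simulate_weights(p$w0[j], adg[j], p$start_age[j], weigh_ages,
                           start_precision = start_precision,
                           precision = precision)
    wt[, `:=`(bird_id = p$bird_id[j], round_id = p$round_id[j])]
  })
  weights <- rbindlist(wl)
  setcolorder(weights, c("bird_id", "round_id", "age_days", "weight_g"))
  list(weights = weights, truth = data.table(bird_id = p$bird_id,
                                             adg_true = adg))
}

# preformatted "HH:MM:SS" lookup for all 86400 seconds of a day
tod_strings <- function() {
  s <- 0:86399
  sprintf("%02d:%02d:%02d", s %/% 3600, (s %% 3600) %/% 60, s %% 60)
}

#' Generate a complete simulated study on disk
#'
#' Simulates every round of a tracking study -- per-bird RFID
#' registration logs over the antenna grid, group-level sensor gaps,
#' handling windows on weigh days (during which no registrations are
#' recorded), and weekly weight tables -- and writes the fixture in the
#' pipeline's external file formats together with the generating ground
#' truth.
#'
#' Files written to `dir`: `rfid_round<r>.csv` (timestamp, tag_id,
#' antenna_id), `weights.csv` (bird_id, round_id, age_days, weight_g),
#' `rounds.json` (round table and key config), `windows.csv` (known
#' handling exclusion windows), `sim_truth.csv` (per-bird generating
#' parameters and true ADG; synthetic ground truth, not an analysis
#' input) and `gaps_truth.csv` (injected sensor gaps, ditto).
#'
#' Note on size: at the nominal 1 s keep-alive period a full-scale study
#' is tens of gigabytes of text; test-scale runs should reduce
#' `birds_per_round` and raise `sample_period_s` (switch registrations
#' are always emitted, so distances are unaffected).
#'
#' @param config a [sim_config()].
#' @param priors a [bird_priors()].
#' @param dir output directory (created if needed).
#' @return (invisibly) list with file `paths`, the `truth` table, the
#'   `rounds` metadata and the handling `windows`.
#' @export
generate_dataset <- function(config, priors = bird_priors(), dir) {
  stopifnot(inherits(config, "sim_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  grid <- build_antenna_grid(config$grid_cols, config$grid_rows,
                             config$pen_w, config$pen_l)
  params <- sample_bird_parameters(config, priors)  # seeds the RNG
  tod <- tod_strings()
  hs <- parse_clock(config$handling_start)
  he <- hs + 60 * config$handling_minutes

  rounds_meta <- data.frame(
    round_id = seq_len(config$n_rounds),
    start_date = config$round_start_dates,
    start_age = config$start_ages,
    end_age = config$end_ages,
    n_birds = config$birds_per_round
  )

  weights_list <- list()
  truth_list <- list()
  windows_list <- list()
  gaps_list <- list()
  log_paths <- character(config$n_rounds)

  for (r in seq_len(config$n_rounds)) {
    pr <- params[round_id == r]
    start_age <- config$start_ages[r]
    end_age <- config$end_ages[r]
    ages_sim <- start_age:min(end_age, config$sim_age_max)
    dates <- config$round_start_dates[r] + (ages_sim - start_age)
    weigh_ages <- sort(unique(c(seq(start_age, end_age,
                                    by = config$weigh_interval_days),
                                end_age)))

    # --- RFID events for every bird-day
    rec_list <- vector("list", nrow(pr) * length(ages_sim))
    ri <- 0L
    for (j in seq_len(nrow(pr))) {
      targets <- simulate_daily_activity_targets(
        pr$a[j], pr$b[j], pr$sigma[j], pr$rho[j], ages_sim)
      ant <- sample.int(nrow(grid), 1)
      for (k in seq_along(ages_sim)) {
        day <- simulate_bird_day(
          targets[k], pr$reg[j], grid,
          dark = config$dark_periods, light_period = config$light_period,
          sample_period_s = config$sample_period_s,
          dark_move_factor = config$dark_move_factor,
          mean_active = config$bout_mean_active_min,
          mean_inactive = config$bout_mean_inactive_min,
          start_antenna = ant)
        ant <- day$end_antenna
        ri <- ri + 1L
        rec_list[[ri]] <- data.table(date_i = k,
                                     sec_of_day = day$events$sec_of_day,
                                     tag_id = pr$bird_id[j],
                                     antenna = day$events$antenna)
      }
    }
    ev <- rbindlist(rec_list)

    # --- handling windows on weigh days (birds out of the pen)
    weigh_k <- which(ages_sim %in% weigh_ages)
    if (length(weigh_k) > 0) {
      ev <- ev[!(date_i %in% weigh_k & sec_of_day >= hs & sec_of_day < he)]
      windows_list[[r]] <- data.frame(
        round_id = r,
        start = paste0(as.character(dates[weigh_k]), "T", tod[hs + 1]),
        end = paste0(as.character(dates[weigh_k]), "T", tod[he + 1]),
        reason = "handling")
    }

    # --- group-level sensor gaps
    n_gaps <- rpois(length(ages_sim), config$gap_rate_per_day[r])
    for (k in seq_along(ages_sim)) {
      if (n_gaps[k] == 0) next
      dur <- runif(n_gaps[k], config$gap_duration_s[1],
                   config$gap_duration_s[2])
      gs <- runif(n_gaps[k], 0, 86400 - dur)
      for (g in seq_len(n_gaps[k])) {
        ev <- ev[!(date_i == k & sec_of_day > gs[g] &
                     sec_of_day < gs[g] + dur[g])]
        gaps_list[[length(gaps_list) + 1L]] <- data.frame(
          round_id = r, date = as.character(dates[k]),
          start_s = gs[g], end_s = gs[g] + dur[g])
      }
    }

    setorder(ev, date_i, sec_of_day, tag_id)
    out <- data.table(
      timestamp = paste0(as.character(dates[ev$date_i]), "T",
                         tod[ev$sec_of_day + 1L]),
      tag_id = ev$tag_id,
      antenna_id = ev$antenna)
    log_paths[r] <- file.path(dir, sprintf("rfid_round%d.csv", r))
    fwrite(out, log_paths[r])

    # --- weights and ground truth
    gr <- simulate_growth(pr, priors,
                          weigh_interval_days = config$weigh_interval_days,
                          start_precision = config$start_weight_precision_g[r],
                          precision = config$weight_precision_g)
    weights_list[[length(weights_list) + 1L]] <- gr$weights
    truth_list[[r]] <- data.table(pr, adg_true = gr$truth$adg_true,
                                  removed = pr$bird_id %in% config$removed_birds)
  }

  weights <- rbindlist(weights_list)
  setcolorder(weights, c("bird_id", "round_id", "age_days", "weight_g"))
  truth <- rbindlist(truth_list)
  windows <- if (length(windows_list)) do.call(rbind, windows_list) else
    data.frame(round_id = integer(), start = character(),
               end = character(), reason = character())
  gaps <- if (length(gaps_list)) do.call(rbind, gaps_list) else
    data.frame(round_id = integer(), date = character(),
               start_s = numeric(), end_s = numeric())

  paths <- list(
    logs = log_paths,
    weights = file.path(dir, "weights.csv"),
    rounds = file.path(dir, "rounds.json"),
    windows = file.path(dir, "windows.csv"),
    truth = file.path(dir, "sim_truth.csv"),
    gaps = file.path(dir, "gaps_truth.csv")
  )
  fwrite(weights, paths$weights)
  rounds_out <- rounds_meta
  rounds_out$start_date <- as.character(rounds_out$start_date)
  jsonlite::write_json(list(
    rounds = rounds_out,
    seed = config$seed,
    light_period = config$light_period,
    sample_period_s = config$sample_period_s,
    removed_birds = config$removed_birds
  ), paths$rounds, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  fwrite(as.data.table(windows), paths$windows)
  fwrite(truth, paths$truth)
  fwrite(as.data.table(gaps), paths$gaps)

  invisible(list(paths = paths, truth = truth, rounds = rounds_meta,
                 windows = windows, gaps = gaps))
}
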