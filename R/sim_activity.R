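#' AR(1) day-to-day activity deviations
#'
#' Stationary first-order autoregressive noise with marginal standard
#' deviation `sigma` and lag-1 correlation `rho`: the first value is
#' drawn from the stationary distribution `N(0, sigma^2)` and subsequent
#' values follow `e[t] = rho * e[t-1] + N(0, sigma^2 (1 - rho^2))`.
#'
#' @param n number of days.
#' @param sigma marginal SD (>= 0).
#' @param rho lag-1 correlation, `|rho| < 1`.
#' @return numeric vector of length `n`.
#' @export
ar1_deviations <- function(n, sigma, rho) {
  stopifnot(n >= 1, sigma >= 0, abs(rho) < 1)
  if (sigma == 0) return(numeric(n))
  e <- numeric(n)
  innov_sd <- sigma * sqrt(1 - rho^2)
  e[1] <- rnorm(1, 0, sigma)
  if (n > 1) {
    z <- rnorm(n - 1, 0, innov_sd)
    for (t in 2:n) e[t] <- rho * e[t - 1] + z[t - 1]
  }
  e
}

#' Daily activity targets of one bird
#'
#' The target daily average distance moved per hour over a range of
#' ages: a linear (typically declining) trend plus stationary AR(1)
#' deviations, truncated at zero since activity cannot be negative:
#' `target[d] = max(0, a + b * d + e[d])`.
#'
#' @param a,b trend intercept (m/h) and slope (m/h/day).
#' @param sigma,rho deviation marginal SD and lag-1 correlation.
#' @param days integer vector of ages (days), non-empty.
#' @return numeric vector of target DADM values (m/h), one per day.
#' @export
simulate_daily_activity_targets <- function(a, b, sigma, rho, days) {
  stopifnot(length(days) >= 1)
  pmax(0, a + b * days + ar1_deviations(length(days), sigma, rho))
}

#' Two-state bout process over the minutes of a day
#'
#' Alternating active/inactive bouts whose durations interpolate between
#' a fixed period (`reg = 1`: rigidly periodic cycling) and a geometric
#' distribution (`reg = 0`: memoryless switching):
#' `duration = max(1, round(reg * mu + (1 - reg) * G))` with
#' `G ~ 1 + Geom(1/mu)` (mean `mu` for every `reg`). The initial state
#' is drawn at random.
#'
#' @param n_min number of minutes (1440 for a day).
#' @param reg regularity in \[0, 1\].
#' @param mean_active,mean_inactive mean bout durations, minutes.
#' @return logical vector, `TRUE` = active minute.
#' @export
simulate_bout_states <- function(n_min, reg, mean_active = 5,
                                 mean_inactive = 5) {
  stopifnot(reg >= 0, reg <= 1, mean_active >= 1, mean_inactive >= 1)
  n_bouts <- ceiling(2 * n_min / min(mean_active, mean_inactive)) + 20
  state0 <- runif(1) < 0.5
  states <- rep(c(state0, !state0), length.out = n_bouts)
  mu <- ifelse(states, mean_active, mean_inactive)
  g <- 1 + rgeom(n_bouts, prob = 1 / mu)
  dur <- pmax(1, round(reg * mu + (1 - reg) * g))
  out <- rep(states, times = dur)
  while (length(out) < n_min) {  # extremely unlikely top-up
    extra <- simulate_bout_states(n_min, reg, mean_active, mean_inactive)
    out <- c(out, extra)
  }
  out[seq_len(n_min)]
}

# distribute `total` items over slots with relative weights `w`
# (largest-remainder style via cumulative rounding; exact total)
distribute_counts <- function(total, w) {
  if (length(w) == 0 || total <= 0 || sum(w) <= 0)
    return(integer(length(w)))
  cum <- cumsum(w / sum(w)) * total
  diff(c(0L, round(cum)))
}

#' Simulate one bird-day of movement over the antenna grid
#'
#' Realises a day of pen movement consistent with a target daily average
#' distance moved per hour: a two-state bout process determines active
#' minutes, the calibrated number of antenna hops
#' `round(target * light_hours / mean_step)` is spread evenly over the
#' active seconds of the analysis light period (the same per-second rate
#' applies in any other lit interval, and `dark_move_factor` times it
#' during dark periods), and each hop moves the bird to a uniformly
#' chosen 4-connected neighbouring antenna. Registrations are emitted at
#' every hop plus a keep-alive sample every `sample_period_s` seconds,
#' so centre-to-centre distance reconstruction is exact at any
#' keep-alive rate.
#'
#' @param target target DADM over the light period, m/h (>= 0).
#' @param reg bout regularity in \[0, 1\].
#' @param grid an [build_antenna_grid()] object.
#' @param dark matrix of dark clock intervals (see [clock_intervals()]).
#' @param light_period analysis light period clock times.
#' @param sample_period_s keep-alive period, seconds.
#' @param dark_move_factor movement-rate multiplier in the dark.
#' @param mean_active,mean_inactive bout duration means, minutes.
#' @param start_antenna antenna at 00:00 (default random).
#' @param emit `"events"` for the full registration stream or
#'   `"minutes"` for the fast path that stops after move scheduling
#'   (identical minute-level activity, no walk or event table).
#' @return list with `minute_moves` (integer vector, hops per minute of
#'   the day), `events` (data.table `sec_of_day`, `antenna`; `NULL` for
#'   the fast path), `end_antenna`, `n_moves_light`.
#' @export
simulate_bird_day <- function(target, reg, grid,
                              dark = clock_intervals(list(
                                c("00:00", "03:00"), c("05:00", "07:00"),
                                c("23:00", "24:00"))),
                              light_period = c("07:00", "23:00"),
                              sample_period_s = 1,
                              dark_move_factor = 0.05,
                              mean_active = 5, mean_inactive = 5,
                              start_antenna = NULL,
                              emit = c("events", "minutes")) {
  emit <- match.arg(emit)
  stopifnot(target >= 0)
  lp <- parse_clock(light_period)
  n_min <- 1440L
  if (is.null(start_antenna)) start_antenna <- sample.int(nrow(grid), 1)

  active <- simulate_bout_states(n_min, reg, mean_active, mean_inactive)
  minute_start <- (seq_len(n_min) - 1L) * 60
  is_dark <- in_intervals(minute_start, dark)
  in_lp <- minute_start >= lp[1] & minute_start < lp[2]

  lp_active <- which(active & in_lp & !is_dark)
  lit_active <- which(active & !in_lp & !is_dark)
  dark_active <- which(active & is_dark)

  d_bar <- as.numeric(mean_step_distance(grid))
  lp_hours <- (lp[2] - lp[1]) / 3600
  n_moves_light <- if (target == 0 || d_bar == 0) 0L else
    as.integer(round(target * lp_hours / d_bar))
  if (n_moves_light > 60 * length(lp_active))
    stop(sprintf(
      "target DADM %.1f m/h exceeds the movement achievable on this grid/day",
      target))

  minute_moves <- integer(n_min)
  minute_moves[lp_active] <- distribute_counts(n_moves_light,
                                               rep(1, length(lp_active)))
  if (n_moves_light > 0 && length(lp_active) > 0) {
    rate_per_min <- n_moves_light / length(lp_active)
    minute_moves[lit_active] <- distribute_counts(
      round(rate_per_min * length(lit_active)), rep(1, length(lit_active)))
    minute_moves[dark_active] <- distribute_counts(
      round(rate_per_min * dark_move_factor * length(dark_active)),
      rep(1, length(dark_active)))
  }

  if (emit == "minutes") {
    return(list(minute_moves = minute_moves, events = NULL,
                end_antenna = start_antenna, n_moves_light = n_moves_light))
  }

  # hop seconds: evenly spaced within each minute
  mv_min <- which(minute_moves > 0)
  k <- minute_moves[mv_min]
  move_sec <- unlist(lapply(seq_along(mv_min), function(i) {
    (mv_min[i] - 1L) * 60 + floor(60 * (seq_len(k[i]) - 0.5) / k[i])
  }), use.names = FALSE)
  M <- length(move_sec)

  # uniform-neighbour random walk (4-connected)
  nb <- neighbour_list(grid)
  path <- integer(M)
  cur <- start_antenna
  if (M > 0) {
    u <- runif(M)
    for (i in seq_len(M)) {
      nbs <- nb[[cur]]
      cur <- nbs[1L + floor(u[i] * length(nbs))]
      path[i] <- cur
    }
  }

  ka_sec <- seq(0, 86399, by = sample_period_s)
  ka_sec <- ka_sec[!(ka_sec %in% move_sec)]
  ka_ant <- if (M > 0) {
    idx <- findInterval(ka_sec, move_sec)
    c(start_antenna, path)[idx + 1L]
  } else rep(start_antenna, length(ka_sec))

  events <- data.table(sec_of_day = c(ka_sec, move_sec),
                       antenna = c(ka_ant, path))
  setorder(events, sec_of_day)
  list(minute_moves = minute_moves, events = events,
       end_antenna = cur, n_moves_light = n_moves_light)
}

# 4-connected neighbours of every antenna (row-major grid numbering)
neighbour_list <- function(grid) {
  nc <- attr(grid, "cols"); nr <- attr(grid, "rows")
  lapply(seq_len(nc * nr), function(a) {
    c0 <- (a - 1L) %% nc + 1L
    r0 <- (a - 1L) %/% nc + 1L
    out <- integer(0)
    if (c0 > 1)  out <- c(out, a - 1L)
    if (c0 < nc) out <- c(out, a + 1L)
    if (r0 > 1)  out <- c(out, a - nc)
    if (r0 < nr) out <- c(out, a + nc)
    out
  })
}

#' One bird-day of RFID registrations with timestamps
#'
#' Wraps [simulate_bird_day()] into a timestamped registration table
#' matching the on-disk RFID log layout.
#'
#' @param date calendar date of the day.
#' @param tag_id the bird's tag identifier.
#' @inheritParams simulate_bird_day
#' @param ... passed on to [simulate_bird_day()].
#' @return list with `records` (data.table `time`, `tag_id`, `antenna`),
#'   `minute_moves`, `end_antenna`.
#' @export
simulate_rfid_day <- function(date, tag_id, target, reg, grid, ...) {
  day <- simulate_bird_day(target, reg, grid, ...)
  t0 <- as.POSIXct(paste(as.character(date), "00:00:00"), tz = "UTC")
  rec <- data.table(time = t0 + day$events$sec_of_day,
                    tag_id = tag_id,
                    antenna = day$events$antenna)
  list(records = rec, minute_moves = day$minute_moves,
       end_antenna = day$end_antenna)
}

#' Quarter-hour activity classes implied by per-minute hop counts
#'
#' Fast-path counterpart of [minute_activity_classes()]: every antenna
#' hop is an antenna switch, so a minute is active exactly when at least
#' one hop falls in it.
#'
#' @param minute_moves integer vector of hops per minute of the day
#'   (from [simulate_bird_day()]).
#' @param light_period analysis light period.
#' @param bin_min bin width, minutes.
#' @param class_bounds class cut-offs (see [minute_activity_classes()]).
#' @return data.table `bin`, `active_min`, `class`, `complete` (TRUE).
#' @export
minute_moves_to_classes <- function(minute_moves,
                                    light_period = c("07:00", "23:00"),
                                    bin_min = 15, class_bounds = c(2, 4, 7)) {
  lp <- parse_clock(light_period) / 60
  mins <- (lp[1] + 1):lp[2]  # 1-based minute indices within the light period
  act <- minute_moves[mins] > 0
  n_bins <- length(mins) / bin_min
  bins <- rep(seq_len(n_bins), each = bin_min)
  active_min <- as.integer(tapply(act, bins, sum))
  data.table(bin = seq_len(n_bins), active_min = active_min,
             class = classify_counts(active_min, class_bounds),
             complete = TRUE)
}
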