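#' Build the antenna grid of the pen floor
#'
#' The pen floor is tiled by `cols x rows` rectangular RFID antennas; the
#' centre point of each antenna approximates the position of any bird
#' registered on it. Antennas are numbered row-major (antenna 1 at column
#' 1, row 1), with centre coordinates
#' `((c - 1/2) * pen_w / cols, (r - 1/2) * pen_l / rows)`.
#'
#' The default is the 5 x 6 grid of a 1.8 m x 2.6 m pen (30 antennas of
#' 0.36 m x 0.4333 m, close to the physical 32 x 41 cm antenna size).
#'
#' @param cols,rows number of antenna columns / rows (positive integers).
#' @param pen_w,pen_l pen width (x, metres, spanned by columns) and length
#'   (y, metres, spanned by rows).
#' @return an object of class `antenna_grid`: a data.frame with columns
#'   `antenna`, `col`, `row`, `x`, `y` and attributes `cols`, `rows`,
#'   `pen_w`, `pen_l`.
#' @examples
#' g <- build_antenna_grid()
#' head(g)
#' @export
build_antenna_grid <- function(cols = 5, rows = 6, pen_w = 1.8, pen_l = 2.6) {
  if (cols < 1 || rows < 1) stop("grid must have at least one antenna")
  if (pen_w <= 0 || pen_l <= 0) stop("pen dimensions must be positive")
  col <- rep(seq_len(cols), times = rows)
  row <- rep(seq_len(rows), each = cols)
  g <- data.frame(
    antenna = seq_len(cols * rows),
    col = col, row = row,
    x = (col - 0.5) * pen_w / cols,
    y = (row - 0.5) * pen_l / rows
  )
  structure(g, class = c("antenna_grid", "data.frame"),
            cols = cols, rows = rows, pen_w = pen_w, pen_l = pen_l)
}

#' @export
print.antenna_grid <- function(x, ...) {
  cat(sprintf("<antenna_grid> %d x %d antennas, pen %.2f x %.2f m\n",
              attr(x, "cols"), attr(x, "rows"),
              attr(x, "pen_w"), attr(x, "pen_l")))
  print.data.frame(head(as.data.frame(x), 6), ...)
  if (nrow(x) > 6) cat("...", nrow(x) - 6, "more antennas\n")
  invisible(x)
}

# centre-to-centre step sizes of the grid
grid_steps <- function(grid) {
  c(dx = attr(grid, "pen_w") / attr(grid, "cols"),
    dy = attr(grid, "pen_l") / attr(grid, "rows"))
}

# mean edge length of the 4-connected antenna graph under the stationary
# distribution of a uniform-neighbour random walk (stationary mass is
# proportional to degree, so this is the unweighted mean over undirected
# edges); used to calibrate simulated movement
mean_step_distance <- function(grid) {
  s <- grid_steps(grid)
  nc <- attr(grid, "cols"); nr <- attr(grid, "rows")
  n_h <- nr * (nc - 1)  # horizontal edges
  n_v <- nc * (nr - 1)  # vertical edges
  if (n_h + n_v == 0) return(0)
  (n_h * s["dx"] + n_v * s["dy"]) / (n_h + n_v)
}

#' Total distance moved in one bird-day of registrations
#'
#' Sums the Euclidean distances between the centre points of consecutively
#' registered antennas. Consecutive registrations on the same antenna
#' contribute zero. Pairs of registrations that straddle an exclusion
#' window (different `segment`) do not contribute: movement during
#' unobserved intervals is unknowable.
#'
#' @param events data.frame of one bird-day's time-ordered registrations
#'   with at least a column `antenna`; an optional `segment` column (as
#'   produced by [clip_to_light_period()]) breaks the sequence at
#'   exclusion windows.
#' @param grid an [build_antenna_grid()] object.
#' @return total distance moved, metres.
#' @examples
#' g <- build_antenna_grid()
#' daily_distance(data.frame(antenna = c(1, 2, 7)), g)
#' @export
daily_distance <- function(events, grid) {
  a <- events$antenna
  if (length(a) < 2) return(0)
  if (anyNA(a) || any(a < 1 | a > nrow(grid)))
    stop("event references unknown antenna id")
  seg <- if (!is.null(events$segment)) events$segment else rep(1L, length(a))
  dx <- diff(grid$x[a])
  dy <- diff(grid$y[a])
  keep <- diff(seg) == 0
  sum(sqrt(dx[keep]^2 + dy[keep]^2))
}

#' Daily average distance moved per hour (DADM)
#'
#' Normalises a day's total distance by the effective recorded duration,
#' so days with excluded intervals (weighing, sensor gaps) remain
#' comparable: `DADM = total_m / (effective_seconds / 3600)`.
#'
#' @param total_m total distance moved in the day (metres).
#' @param effective_seconds seconds actually recorded within the analysis
#'   light period. Non-positive durations yield `NA` (the day is missing),
#'   not an error.
#' @return DADM in metres per hour (vectorised).
#' @examples
#' daily_average_distance(32, 57600)  # full 16 h light period -> 2 m/h
#' daily_average_distance(30, 54000)  # 1 h excluded, same rate
#' @export
daily_average_distance <- function(total_m, effective_seconds) {
  out <- ifelse(effective_seconds > 0, total_m / (effective_seconds / 3600),
                NA_real_)
  as.numeric(out)
}

#' Per-bird-day activity series from clipped registration streams
#'
#' Applies [daily_distance()] and [daily_average_distance()] to every
#' bird-day delivered by [clip_to_light_period()].
#'
#' @param streams the list returned by [clip_to_light_period()] (elements
#'   `events` and `bird_days`).
#' @param grid an [build_antenna_grid()] object.
#' @return data.table with columns `bird_id`, `round_id`, `age_days`,
#'   `distance_m`, `effective_seconds`, `dadm` (`NA` when the day is
#'   missing), one row per bird-day.
#' @export
daily_activity_series <- function(streams, grid) {
  ev <- as.data.table(streams$events)
  bd <- as.data.table(streams$bird_days)
  if (nrow(ev) > 0) {
    dist <- ev[, .(distance_m = daily_distance(.SD, grid)),
               by = .(bird_id, age_days), .SDcols = c("antenna", "segment")]
    bd <- merge(bd, dist, by = c("bird_id", "age_days"), all.x = TRUE)
  } else {
    bd[, distance_m := NA_real_]
  }
  bd[is.na(distance_m) & effective_seconds > 0, distance_m := 0]
  bd[, dadm := daily_average_distance(distance_m, effective_seconds)]
  setcolorder(bd, c("bird_id", "round_id", "age_days", "distance_m",
                    "effective_seconds", "dadm"))
  bd[]
}
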