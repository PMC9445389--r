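#' Read an RFID registration log
#'
#' Registration logs are delimited text with one row per registration:
#' a timestamp (ISO-8601, 1-second resolution), the tag identifier and the
#' antenna at which the tag was registered. The recording frequency is
#' nominally one sample per second per tag; two registrations within the
#' same second occur at antenna switches and are both retained.
#'
#' @param file path to the log file.
#' @param delim field delimiter (default comma).
#' @param tz timezone of the timestamps (default `"UTC"`).
#' @param grid optional [build_antenna_grid()]; when given, antenna ids are
#'   validated against it and offenders reported.
#' @return a `data.table` with columns `time` (POSIXct), `tag_id`
#'   (character), `antenna` (integer), sorted by time (stable, so
#'   same-second switch pairs keep their order).
#' @export
read_rfid_log <- function(file, delim = ",", tz = "UTC", grid = NULL) {
  dt <- data.table::fread(file, sep = delim, header = TRUE,
                          colClasses = list(character = 1:2))
  if (nrow(dt) == 0) {
    return(data.table(time = as.POSIXct(character(), tz = tz),
                      tag_id = character(), antenna = integer()))
  }
  if (ncol(dt) < 3) stop("RFID log must have columns timestamp, tag_id, antenna_id")
  setnames(dt, 1:3, c("time_raw", "tag_id", "antenna_raw"))
  tm <- parse_iso_times(dt$time_raw, tz)
  if (anyNA(tm)) {
    bad <- which(is.na(tm))
    stop("malformed timestamp in RFID log at data row(s): ",
         paste(head(bad, 5), collapse = ", "),
         if (length(bad) > 5) " ..." else "")
  }
  ant <- suppressWarnings(as.integer(dt$antenna_raw))
  if (anyNA(ant)) {
    bad <- which(is.na(ant))
    stop("malformed antenna id at data row(s): ",
         paste(head(bad, 5), collapse = ", "))
  }
  if (!is.null(grid)) {
    unknown <- setdiff(unique(ant), grid$antenna)
    if (length(unknown) > 0)
      stop("unknown antenna id(s) in log: ", paste(sort(unknown), collapse = ", "))
  }
  out <- data.table(time = tm, tag_id = dt$tag_id, antenna = ant)
  setorder(out, time)  # stable radix sort: ties keep file order
  out[]
}

#' @keywords internal
#' @noRd
# vectorised ISO-8601 parser: fast path splits "YYYY-MM-DD[T ]HH:MM:SS"
# into a per-unique-date lookup plus integer second-of-day arithmetic;
# anything else falls back to as.POSIXct
parse_iso_times <- function(x, tz = "UTC") {
  iso <- grepl("^\\d{4}-\\d{2}-\\d{2}[T ]\\d{2}:\\d{2}:\\d{2}$", x)
  if (all(iso)) {
    dstr <- substr(x, 1, 10)
    ud <- unique(dstr)
    day0 <- as.POSIXct(paste(ud, "00:00:00"), tz = tz,
                       format = "%Y-%m-%d %H:%M:%S")
    base <- as.numeric(day0)[match(dstr, ud)]
    sec <- 3600 * as.integer(substr(x, 12, 13)) +
             60 * as.integer(substr(x, 15, 16)) +
                  as.integer(substr(x, 18, 19))
    sec[sec < 0 | sec > 86399] <- NA_integer_
    return(as.POSIXct(base + sec, origin = "1970-01-01", tz = tz))
  }
  # slow path: per-format parsing returns NA (not an error) for bad rows,
  # so the caller can report offending line numbers
  out <- as.POSIXct(x, tz = tz, format = "%Y-%m-%dT%H:%M:%OS")
  alt <- as.POSIXct(x, tz = tz, format = "%Y-%m-%d %H:%M:%OS")
  out[is.na(out)] <- alt[is.na(out)]
  out
}

#' Detect group-level recording gaps
#'
#' A group-level gap is a maximal interval in which no registrations were
#' recorded for *any* tag, longer than the threshold (sensor downtime).
#' The boundary case is kept: only silences *strictly longer* than
#' `threshold_s` become exclusion windows. Windows span the silent
#' interval exactly (from the last registration before to the first
#' after). A single bird's silence while others register is never a gap.
#'
#' @param records registration table as from [read_rfid_log()] (must be
#'   time-sorted).
#' @param threshold_s silence threshold in seconds; the default 300 s
#'   implements the "more than five consecutive minutes" rule.
#' @return a data.frame of exclusion windows: `start`, `end` (POSIXct),
#'   `reason = "group_gap"`; zero rows when traffic is continuous.
#' @export
find_group_gaps <- function(records, threshold_s = 300) {
  empty <- data.frame(start = as.POSIXct(character()),
                      end = as.POSIXct(character()),
                      reason = character())
  if (nrow(records) < 2) return(empty)
  tm <- records$time
  d <- as.numeric(diff(tm), units = "secs")
  i <- which(d > threshold_s)
  if (length(i) == 0) return(empty)
  data.frame(start = tm[i], end = tm[i + 1L],
             reason = rep("group_gap", length(i)))
}

#' Normalize exclusion windows
#'
#' Sorts windows by start and merges any that overlap or touch, so that
#' downstream overlap arithmetic never double-counts. Reasons of merged
#' windows are concatenated.
#'
#' @param windows data.frame with POSIXct `start`, `end` and a `reason`
#'   column; `NULL` or zero rows allowed.
#' @return normalized data.frame of disjoint windows sorted by start.
#' @export
normalize_windows <- function(windows) {
  if (is.null(windows) || nrow(windows) == 0) {
    return(data.frame(start = as.POSIXct(character()),
                      end = as.POSIXct(character()),
                      reason = character()))
  }
  stopifnot(all(windows$start < windows$end))
  w <- windows[order(windows$start), , drop = FALSE]
  start <- w$start[1]; end <- w$end[1]; reason <- w$reason[1]
  out <- list()
  if (nrow(w) > 1) {
    for (k in 2:nrow(w)) {
      if (w$start[k] <= end) {  # overlap or touch: merge
        if (w$end[k] > end) end <- w$end[k]
        if (!grepl(w$reason[k], reason, fixed = TRUE))
          reason <- paste(reason, w$reason[k], sep = "+")
      } else {
        out[[length(out) + 1L]] <- data.frame(start = start, end = end,
                                              reason = reason)
        start <- w$start[k]; end <- w$end[k]; reason <- w$reason[k]
      }
    }
  }
  out[[length(out) + 1L]] <- data.frame(start = start, end = end,
                                        reason = reason)
  do.call(rbind, out)
}

#' Clip registrations to the analysis light period and exclusion windows
#'
#' Restricts a round's registration stream to the main light period
#' (default 07:00-23:00, the window over which all activity descriptors
#' are defined), removes events inside exclusion windows, keys each event
#' by the bird's age in days (from round metadata, so rounds starting at
#' age 0 and age 1 align), and computes the effective recorded duration of
#' every bird-day. Events separated by an exclusion window receive
#' different `segment` ids so that distance accumulation breaks there.
#'
#' @param records registration table as from [read_rfid_log()].
#' @param windows exclusion windows (group gaps, handling, custom);
#'   normalized internally. `NULL` for none.
#' @param rounds round metadata: data.frame with columns `round_id`,
#'   `start_date` (Date or ISO string: the date at which birds were
#'   `start_age` days old), `start_age`, `end_age`.
#' @param light_period length-2 clock times, default `c("07:00", "23:00")`.
#' @return a list with
#'   \describe{
#'     \item{events}{data.table `bird_id`, `round_id`, `age_days`, `time`,
#'       `sec_of_day`, `antenna`, `segment`, events kept.}
#'     \item{bird_days}{data.table `bird_id`, `round_id`, `age_days`,
#'       `date`, `effective_seconds`, `missing`; one row per bird and per
#'       calendar day spanned by the round's records. Days whose light
#'       period is fully excluded have `effective_seconds = 0` and
#'       `missing = TRUE`.}
#'   }
#'   Attributes `events_in`, `events_kept`, `events_removed` support
#'   conservation checks.
#' @export
clip_to_light_period <- function(records, windows = NULL, rounds,
                                 light_period = c("07:00", "23:00")) {
  lp <- parse_clock(light_period)
  stopifnot(length(lp) == 2, lp[1] < lp[2])
  rounds <- as.data.frame(rounds)
  rounds$start_date <- as.Date(rounds$start_date)
  win <- normalize_windows(windows)

  ev <- as.data.table(records)
  n_in <- nrow(ev)
  tz <- if (n_in > 0) attr(ev$time, "tzone") else "UTC"
  if (is.null(tz) || !nzchar(tz)) tz <- "UTC"

  # map calendar dates to (round, age)
  date_map <- do.call(rbind, lapply(seq_len(nrow(rounds)), function(i) {
    r <- rounds[i, ]
    ages <- r$start_age:r$end_age
    data.frame(date = r$start_date + (ages - r$start_age),
               round_id = r$round_id, age_days = ages)
  }))

  if (n_in > 0) {
    # fast day split on epoch seconds (timestamps are fixed-offset; use UTC
    # or a DST-free zone for logs)
    tnum <- as.numeric(ev$time)
    midnight1 <- as.numeric(as.POSIXct(
      paste(as.Date(ev$time[1], tz = tz), "00:00:00"), tz = tz))
    off <- midnight1 %% 86400  # UTC offset of the zone, seconds
    dayn <- floor((tnum - off) / 86400)
    ev[, date := as.Date(dayn, origin = "1970-01-01")]
    ev[, sec_of_day := tnum - off - 86400 * dayn]
    mi <- match(ev$date, date_map$date)
    if (anyNA(mi)) {
      stop("round metadata missing for date(s): ",
           paste(head(unique(ev$date[is.na(mi)]), 5), collapse = ", "))
    }
    ev[, round_id := date_map$round_id[mi]]
    ev[, age_days := date_map$age_days[mi]]
    keep <- ev$sec_of_day >= lp[1] & ev$sec_of_day < lp[2]
    if (nrow(win) > 0) {
      for (k in seq_len(nrow(win)))
        keep <- keep & !(ev$time > win$start[k] & ev$time < win$end[k])
    }
    kept <- ev[keep]
    if (nrow(win) > 0) {
      kept[, segment := findInterval(as.numeric(time), as.numeric(win$end)) + 1L]
    } else {
      kept[, segment := 1L]
    }
    setnames(kept, "tag_id", "bird_id")
    kept <- kept[, .(bird_id, round_id, age_days, time, sec_of_day,
                     antenna, segment)]
    setorder(kept, bird_id, time)
  } else {
    kept <- data.table(bird_id = character(), round_id = integer(),
                       age_days = integer(),
                       time = as.POSIXct(character(), tz = tz),
                       sec_of_day = numeric(), antenna = integer(),
                       segment = integer())
  }

  # bird-day bookkeeping: birds and dates observed per round
  if (n_in > 0) {
    obs <- ev[, .(round_id = round_id[1]), by = date]
    span <- obs[, .(first = min(date), last = max(date)), by = round_id]
    bd_list <- lapply(seq_len(nrow(span)), function(i) {
      rid <- span$round_id[i]
      dates <- seq(span$first[i], span$last[i], by = "day")
      birds <- sort(unique(ev[round_id == rid, tag_id]))
      CJ(bird_id = birds, date = dates)[, round_id := rid]
    })
    bd <- rbindlist(bd_list)
    mi <- match(bd$date, date_map$date)
    bd[, age_days := date_map$age_days[mi]]
    day0 <- as.POSIXct(as.character(bd$date), tz = tz)
    eff <- vapply(seq_len(nrow(bd)), function(i) {
      a1 <- as.numeric(day0[i]) + lp[1]
      a2 <- as.numeric(day0[i]) + lp[2]
      ov <- if (nrow(win) > 0) {
        sum(pmax(0, pmin(a2, as.numeric(win$end)) -
                      pmax(a1, as.numeric(win$start))))
      } else 0
      (lp[2] - lp[1]) - ov
    }, numeric(1))
    bd[, effective_seconds := eff]
    bd[, missing := effective_seconds <= 0]
    setcolorder(bd, c("bird_id", "round_id", "age_days", "date",
                      "effective_seconds", "missing"))
    setorder(bd, round_id, bird_id, age_days)
  } else {
    bd <- data.table(bird_id = character(), round_id = integer(),
                     age_days = integer(), date = as.Date(character()),
                     effective_seconds = numeric(), missing = logical())
  }

  structure(list(events = kept, bird_days = bd),
            events_in = n_in, events_kept = nrow(kept),
            events_removed = n_in - nrow(kept))
}
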