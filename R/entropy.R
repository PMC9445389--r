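#' Sample entropy (SampEn)
#'
#' Measures the (ir)regularity of a short time series by template
#' matching: `SampEn = -ln(A/B)` where `B` counts unordered pairs of
#' distinct length-`m` templates whose Chebyshev distance is at most `r`,
#' and `A` the same for length `m + 1`. Self-matches are excluded. Low
#' values indicate regularity, high values randomness.
#'
#' Template counting: the length-`m` templates start at positions
#' `1 .. N - m` and the length-`m + 1` templates at `1 .. N - m - 1`.
#' For a strictly alternating two-symbol series of length 64 with `m = 2`
#' this yields `B = 930`, `A = 900`, `SampEn = -ln(900/930)`.
#'
#' Because the length-`m + 1` template set has one member fewer than the
#' length-`m` set, a perfectly regular (e.g. constant) series attains a
#' small positive floor `ln((N - m)/(N - m - 2))` (about 0.033 at
#' `N = 64`, `m = 2`) rather than exactly zero; this finite-size offset
#' is a property of the counting convention and is identical for every
#' fully self-similar series.
#'
#' @param x numeric series (e.g. the 64 quarter-hour activity classes of
#'   one day).
#' @param m embedding (template) length, default 2.
#' @param r matching tolerance, default `0.2 * sd(x)`.
#' @return SampEn (non-negative), `NA` when `A` or `B` is zero
#'   (undefined).
#' @examples
#' sample_entropy(rep(3, 64))              # regularity floor ~ 0.033
#' sample_entropy(rep(c(1, 2), 32), r = 0.1)
#' @export
sample_entropy <- function(x, m = 2, r = 0.2 * sd(x)) {
  x <- as.numeric(x)
  N <- length(x)
  if (N <= m + 1) return(NA_real_)
  if (is.na(r)) return(NA_real_)
  B <- count_template_pairs(x, m, N - m, r)
  A <- count_template_pairs(x, m + 1, N - m - 1, r)
  if (A == 0 || B == 0) return(NA_real_)
  -log(A / B)
}

# pairs (i < j) among templates x[i .. i+len-1], i = 1..n_t, with
# Chebyshev distance <= r
count_template_pairs <- function(x, len, n_t, r) {
  if (n_t < 2) return(0)
  idx <- seq_len(n_t)
  D <- matrix(0, n_t, n_t)
  for (k in 0:(len - 1)) {
    v <- x[idx + k]
    D <- pmax(D, abs(outer(v, v, "-")))
  }
  sum(D[upper.tri(D)] <= r)
}

#' Quarter-hour activity classes of one bird-day
#'
#' For every minute of the analysis light period it is determined whether
#' the bird registered on a *different* antenna than its immediately
#' preceding registration (an antenna switch). Per 15-minute bin, the
#' number of such active minutes (0-15) is counted and categorised into
#' four classes: 1 = very inactive (0-2 min), 2 = inactive (3-4 min),
#' 3 = active (5-7 min), 4 = very active (8-15 min). The 64 classes of a
#' complete day form the series on which daily sample entropy is
#' computed.
#'
#' @param events one bird-day's registrations: data.frame with
#'   `sec_of_day` and `antenna` (and optionally `segment`; switches are
#'   never counted across exclusion-window boundaries), time-ordered.
#' @param effective_seconds the day's effective recorded light-period
#'   duration; the day is complete only if it equals the full light
#'   period (no bin overlaps an exclusion window).
#' @param light_period clock times, default `c("07:00", "23:00")`.
#' @param bin_min bin width in minutes (default 15).
#' @param class_bounds upper count bounds of classes 1..3 (default
#'   `c(2, 4, 7)`, the quantile-derived cut-offs; see
#'   [derive_class_bounds()] for recomputing them on new data).
#' @return data.table with one row per bin: `bin`, `active_min`, `class`,
#'   `complete` (constant flag column).
#' @export
minute_activity_classes <- function(events, effective_seconds = NULL,
                                    light_period = c("07:00", "23:00"),
                                    bin_min = 15, class_bounds = c(2, 4, 7)) {
  lp <- parse_clock(light_period)
  n_min <- (lp[2] - lp[1]) / 60
  stopifnot(n_min %% bin_min == 0)
  n_bins <- as.integer(n_min / bin_min)

  sec <- events$sec_of_day
  ant <- events$antenna
  seg <- if (!is.null(events$segment)) events$segment else rep(1L, length(ant))
  if (length(ant) >= 2) {
    switch <- c(FALSE, ant[-1] != ant[-length(ant)] &
                       seg[-1] == seg[-length(seg)])
  } else {
    switch <- rep(FALSE, length(ant))
  }
  in_lp <- sec >= lp[1] & sec < lp[2]
  sw_min <- unique((sec[switch & in_lp] - lp[1]) %/% 60)

  minute_active <- rep(FALSE, n_min)
  minute_active[sw_min + 1] <- TRUE
  bins <- rep(seq_len(n_bins), each = bin_min)
  active_min <- as.integer(tapply(minute_active, bins, sum))

  complete <- if (is.null(effective_seconds)) TRUE
              else isTRUE(effective_seconds >= lp[2] - lp[1])
  data.table(bin = seq_len(n_bins),
             active_min = active_min,
             class = classify_counts(active_min, class_bounds),
             complete = complete)
}

# map active-minute counts to ordinal classes 1..4
classify_counts <- function(counts, bounds = c(2, 4, 7)) {
  stopifnot(length(bounds) == 3, !is.unsorted(bounds))
  1L + (counts > bounds[1]) + (counts > bounds[2]) + (counts > bounds[3])
}

#' Data-driven class bounds from observed active-minute counts
#'
#' Recomputes the three class cut-offs as the quartiles of the observed
#' per-bin active-minute counts (rounded down to integer counts), for use
#' on datasets whose activity distribution differs from the default
#' bounds.
#'
#' @param counts integer vector of per-bin active-minute counts pooled
#'   over birds and days.
#' @return integer vector of three upper bounds for classes 1..3.
#' @export
derive_class_bounds <- function(counts) {
  q <- floor(quantile(counts, c(0.25, 0.5, 0.75), names = FALSE))
  q <- cummax(q)
  as.integer(q)
}

#' Mean daily sample entropy of a bird (ENT)
#'
#' Computes the daily SampEn of each *complete* day's quarter-hour class
#' series (tolerance `r = r_factor * SD` of that day's series) and
#' averages over days. Days with missing data are excluded; a bird with
#' no complete days gets a missing value.
#'
#' @param class_days data.frame of one bird's class series: columns
#'   `age_days`, `bin`, `class`, `complete` (rows of
#'   [minute_activity_classes()] over days).
#' @param m embedding length (default 2).
#' @param r_factor tolerance factor (default 0.2).
#' @return ENT (mean daily SampEn) or `NA`.
#' @export
bird_entropy <- function(class_days, m = 2, r_factor = 0.2) {
  cd <- as.data.table(class_days)[complete == TRUE]
  if (nrow(cd) == 0) return(NA_real_)
  daily <- cd[, .(sampen = {
    s <- class[order(bin)]
    sample_entropy(s, m = m, r = r_factor * sd(s))
  }), by = age_days]
  if (all(is.na(daily$sampen))) return(NA_real_)
  mean(daily$sampen, na.rm = TRUE)
}
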