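#' Average daily gain (ADG)
#'
#' `ADG = (end weight - start weight) / (end age - start age)`, in grams
#' per day. Using ADG rather than end weight corrects for unequal round
#' lengths.
#'
#' @param start_weight,end_weight weights in grams (non-negative).
#' @param start_age,end_age ages in days, `end_age > start_age`.
#' @return ADG in g/day (vectorised).
#' @examples
#' average_daily_gain(42, 2562, 0, 35)  # 72 g/day
#' @export
average_daily_gain <- function(start_weight, end_weight, start_age, end_age) {
  if (any(end_age <= start_age)) stop("end_age must exceed start_age")
  if (any(start_weight < 0 | end_weight < 0)) stop("weights must be non-negative")
  (end_weight - start_weight) / (end_age - start_age)
}

#' Build per-bird growth records from a weight table
#'
#' Extracts each bird's first and last weighing from the weekly weight
#' table and computes ADG over the full production period.
#'
#' @param weights data.frame with columns `bird_id`, `age_days`,
#'   `weight_g` (weekly weighings including the start and final day).
#' @param rounds round metadata with `round_id`, `start_age`, `end_age`;
#'   either `weights` carries a `round_id` column or a single round is
#'   assumed.
#' @return data.table: `bird_id`, `round_id`, `start_weight`,
#'   `end_weight`, `start_age`, `end_age`, `adg`.
#' @export
growth_records <- function(weights, rounds = NULL) {
  w <- as.data.table(weights)
  if (!"round_id" %in% names(w)) w[, round_id := 1L]
  g <- w[order(age_days), .(
    start_weight = weight_g[1], end_weight = weight_g[.N],
    start_age = age_days[1], end_age = age_days[.N],
    round_id = round_id[1]
  ), by = bird_id]
  if (!is.null(rounds)) {
    rr <- as.data.frame(rounds)
    mi <- match(g$round_id, rr$round_id)
    if (anyNA(mi)) stop("round metadata missing for round(s): ",
                        paste(unique(g$round_id[is.na(mi)]), collapse = ", "))
    bad <- g$start_age != rr$start_age[mi] | g$end_age != rr$end_age[mi]
    if (any(bad))
      warning(sum(bad), " bird(s) lack weighings at the round's start/end age")
  }
  g[, adg := average_daily_gain(start_weight, end_weight, start_age, end_age)]
  setcolorder(g, c("bird_id", "round_id", "start_weight", "end_weight",
                   "start_age", "end_age", "adg"))
  setorder(g, round_id, bird_id)
  g[]
}

#' Row-wise ADG outlier removal
#'
#' Birds whose ADG deviates more than `k` standard deviations from their
#' round's mean (mean and SD computed within round, including the
#' candidate) are removed entirely from the data -- row-wise removal, so
#' the bird disappears from every downstream table.
#'
#' @param growth growth table as from [growth_records()].
#' @param k threshold multiplier (default 4).
#' @return list with `kept` (filtered growth table) and `removed`
#'   (removal report: `bird_id`, `round_id`, `adg`).
#' @export
adg_outlier_filter <- function(growth, k = 4) {
  g <- as.data.table(growth)
  mask <- flag_outliers(g$adg, g$round_id, k = k)
  list(kept = g[!mask], removed = g[mask, .(bird_id, round_id, adg)])
}

#' ADG quartile groups
#'
#' Labels the lower and upper quartiles of birds by ADG, pooled across
#' rounds: `low` for ADG at or below the 25th percentile, `high` for ADG
#' at or above the 75th percentile, `mid` otherwise. Percentiles use
#' linear interpolation between order statistics ([stats::quantile()]
#' type 7). Ties at the thresholds are inclusive on both tails; the
#' degenerate all-equal case is flagged with a warning.
#'
#' @param growth growth table with an `adg` column.
#' @return the table with an added `quartile` column (factor
#'   low/mid/high); thresholds in attributes `q_low`, `q_high`.
#' @export
adg_quartile_groups <- function(growth) {
  g <- as.data.table(growth)
  if (nrow(g) < 8) stop("at least 8 birds are needed for quartile groups")
  qs <- quantile(g$adg, c(0.25, 0.75), names = FALSE, na.rm = TRUE)
  lab <- ifelse(g$adg <= qs[1], "low", ifelse(g$adg >= qs[2], "high", "mid"))
  if (qs[1] == qs[2])
    warning("degenerate ADG quartiles: thresholds coincide; ",
            "every tied bird falls in both tails")
  g[, quartile := factor(lab, levels = c("low", "mid", "high"))]
  setattr(g, "q_low", qs[1])
  setattr(g, "q_high", qs[2])
  g[]
}
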