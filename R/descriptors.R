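#' Mean distance moved (MD)
#'
#' Arithmetic mean of the daily average distance moved per hour over the
#' two-week analysis window, excluding missing days.
#'
#' @param dadm numeric vector of daily DADM values (m/h), `NA` = missing
#'   day.
#' @return MD in m/h, or `NA` if every day is missing.
#' @export
mean_distance <- function(dadm) {
  if (all(is.na(dadm))) return(NA_real_)
  mean(dadm, na.rm = TRUE)
}

#' Skewness of daily activity (Skew)
#'
#' Skewness of the distribution of a bird's daily DADM values, computed as
#' the b1 moment-ratio variant (third central moment over the cube of the
#' n-1-denominator standard deviation), the default of
#' [e1071::skewness()]. Missing days are excluded; birds with fewer than
#' `min_days` observed days, or zero variance, get a missing value.
#'
#' @param dadm numeric vector of daily DADM values, `NA` = missing.
#' @param min_days minimum number of observed days (default 3).
#' @return skewness (unitless) or `NA`.
#' @export
activity_skewness <- function(dadm, min_days = 3) {
  x <- dadm[!is.na(dadm)]
  if (length(x) < min_days) return(NA_real_)
  if (sd(x) == 0) return(NA_real_)
  as.numeric(e1071::skewness(x, type = 3))
}

#' Per-bird linear activity trend
#'
#' Fits the bird's own ordinary least squares line of DADM on age in days,
#' the expected generally declining activity trend. Residuals (observed
#' minus predicted) are indexed by age; missing days are simply absent.
#'
#' @param age_days integer ages (days).
#' @param dadm DADM values aligned with `age_days`, `NA` = missing.
#' @param min_days minimum observed days for a fit (default 3).
#' @return a list of class `trend_fit` with `slope`, `intercept`,
#'   `residuals` (named by age), `fitted`, `n`; or `NULL` when fewer than
#'   `min_days` days are observed.
#' @export
fit_individual_trend <- function(age_days, dadm, min_days = 3) {
  ok <- !is.na(dadm) & !is.na(age_days)
  x <- as.numeric(age_days[ok]); y <- as.numeric(dadm[ok])
  if (length(y) < min_days || length(unique(x)) < 2) return(NULL)
  f <- lm.fit(cbind(1, x), y)
  res <- setNames(as.numeric(f$residuals), as.character(x))
  structure(list(slope = unname(f$coefficients[2]),
                 intercept = unname(f$coefficients[1]),
                 residuals = res,
                 fitted = setNames(as.numeric(f$fitted.values),
                                   as.character(x)),
                 n = length(y)),
            class = "trend_fit")
}

#' Trend-residual RMSE of activity
#'
#' Root mean square of the residuals around the bird's own linear
#' activity trend, with divisor `n` (the number of observed days), an
#' index of day-to-day variability of activity:
#' `RMSE = sqrt(mean(residual^2))`.
#'
#' @param fit a [fit_individual_trend()] result (or `NULL`).
#' @return RMSE in m/h, or `NA` when the fit is missing.
#' @export
activity_rmse <- function(fit) {
  if (is.null(fit)) return(NA_real_)
  sqrt(mean(fit$residuals^2))
}

#' Lag-1 autocorrelation of activity deviations (AC)
#'
#' Pearson correlation between residuals from the bird's activity trend on
#' consecutive ages: only complete pairs, i.e. ages `d` where both day `d`
#' and day `d + 1` were observed, enter the calculation. Values near zero
#' indicate deviations that do not persist from one day to the next.
#'
#' @param fit a [fit_individual_trend()] result (or `NULL`).
#' @param min_pairs minimum number of consecutive-age residual pairs
#'   (default 3).
#' @return AC in `[-1, 1]`, or `NA` (too few pairs, zero variance, or
#'   missing fit).
#' @export
lag1_autocorrelation <- function(fit, min_pairs = 3) {
  if (is.null(fit)) return(NA_real_)
  ages <- as.integer(names(fit$residuals))
  i <- match(ages + 1L, ages)
  ok <- !is.na(i)
  if (sum(ok) < min_pairs) return(NA_real_)
  r0 <- fit$residuals[ok]
  r1 <- fit$residuals[i[ok]]
  if (sd(r0) == 0 || sd(r1) == 0) return(NA_real_)
  as.numeric(cor(r0, r1))
}

#' Flag within-group outliers at k standard deviations
#'
#' A value is an outlier when its absolute deviation from its group's mean
#' exceeds `k` times the group's standard deviation (n-1 denominator),
#' both computed *including* the candidate value. Groups are recording
#' rounds; flagged descriptor values are set to missing cell-wise by the
#' caller.
#'
#' @param x numeric values (`NA` allowed and never flagged).
#' @param group grouping vector (round), same length as `x`.
#' @param k threshold multiplier (default 4).
#' @return logical mask, `TRUE` = outlier.
#' @export
flag_outliers <- function(x, group = rep(1L, length(x)), k = 4) {
  out <- rep(FALSE, length(x))
  for (g in unique(group)) {
    i <- which(group == g & !is.na(x))
    if (length(i) < 2) next
    m <- mean(x[i]); s <- sd(x[i])
    if (s == 0) next
    out[i] <- abs(x[i] - m) > k * s
  }
  out
}

#' Per-bird descriptor table
#'
#' Computes the five activity descriptors for every bird from its daily
#' activity series (ages restricted to the analysis window) and, when
#' minute-level class series are supplied, the entropy descriptor; then
#' applies the within-round k-SD outlier rule cell-wise to each
#' descriptor column.
#'
#' @param daily data.frame/data.table with columns `bird_id`, `round_id`,
#'   `age_days`, `dadm` (`NA` = missing day); already restricted to the
#'   analysis age window by the caller (or use `max_age`).
#' @param class_days optional data.frame as from
#'   [minute_activity_classes()] rows pooled over birds and days (columns
#'   `bird_id`, `age_days`, `bin`, `active_min`, `class`, `complete`),
#'   used for ENT.
#' @param max_age upper age bound of the analysis window (default 15,
#'   inclusive).
#' @param min_days minimum observed days for Skew and the trend fit.
#' @param min_pairs minimum consecutive-age residual pairs for AC.
#' @param entropy_m,entropy_r_factor sample entropy parameters: embedding
#'   length and tolerance factor (r = factor x SD of the day's class
#'   series).
#' @param ent_exclude_rounds rounds whose ENT is set missing wholesale
#'   (systemic recording problems).
#' @param outlier_k within-round outlier threshold in SDs; `Inf` disables
#'   masking.
#' @return data.table, one row per bird: `bird_id`, `round_id`, `n_days`,
#'   `md`, `skew`, `rmse`, `ac`, `ent`.
#' @export
compute_descriptors <- function(daily, class_days = NULL, max_age = 15,
                                min_days = 3, min_pairs = 3,
                                entropy_m = 2, entropy_r_factor = 0.2,
                                ent_exclude_rounds = integer(),
                                outlier_k = 4) {
  d <- as.data.table(daily)[age_days <= max_age]
  per_bird <- d[, {
    fit <- fit_individual_trend(age_days, dadm, min_days = min_days)
    .(round_id = round_id[1],
      n_days = sum(!is.na(dadm)),
      md = mean_distance(dadm),
      skew = activity_skewness(dadm, min_days = min_days),
      rmse = activity_rmse(fit),
      ac = lag1_autocorrelation(fit, min_pairs = min_pairs))
  }, by = bird_id]

  if (!is.null(class_days)) {
    cd <- as.data.table(class_days)[age_days <= max_age]
    ent <- cd[, .(ent = bird_entropy(.SD, m = entropy_m,
                                     r_factor = entropy_r_factor)),
              by = bird_id]
    per_bird <- merge(per_bird, ent, by = "bird_id", all.x = TRUE)
  } else {
    per_bird[, ent := NA_real_]
  }
  per_bird[round_id %in% ent_exclude_rounds, ent := NA_real_]

  if (is.finite(outlier_k)) {
    for (col in c("md", "skew", "rmse", "ac", "ent")) {
      mask <- flag_outliers(per_bird[[col]], per_bird$round_id, k = outlier_k)
      if (any(mask)) per_bird[mask, (col) := NA_real_]
    }
  }
  setorder(per_bird, round_id, bird_id)
  per_bird[]
}
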