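fake_fit <- function(residuals, ages = seq_along(residuals)) {
  structure(list(slope = 0, intercept = 0,
                 residuals = setNames(residuals, as.character(ages)),
                 n = length(residuals)),
            class = "trend_fit")
}

test_that("mean distance excludes missing days", {
  expect_equal(mean_distance(c(10, 20, 30)), 20)
  expect_equal(mean_distance(c(10, NA, 30)), 20)
  expect_true(is.na(mean_distance(c(NA_real_, NA_real_))))
})

test_that("skewness is the b1 moment-ratio variant with minimum-data rules", {
  expect_equal(activity_skewness(c(1, 2, 3)), 0)
  # worked case: m3 = 6, s = 2 (n-1 denominator), b1 = m3/s^3 = 0.75;
  # cross-checked against the moment formula below
  x <- c(1, 1, 1, 5)
  m3 <- mean((x - mean(x))^3)
  expect_equal(activity_skewness(x), m3 / sd(x)^3)
  expect_equal(activity_skewness(x), 0.75)
  expect_true(is.na(activity_skewness(c(2, 2, 2, 2))))  # zero variance
  expect_true(is.na(activity_skewness(c(1, 5))))        # too few days
  expect_true(is.na(activity_skewness(c(1, NA, 5, NA))))
})

test_that("individual trend fit matches closed-form OLS", {
  # exact line: residuals all zero
  ages <- 1:10
  f0 <- fit_individual_trend(ages, 5 - 0.2 * ages)
  expect_equal(unname(f0$residuals), rep(0, 10))
  expect_equal(f0$slope, -0.2)

  f <- fit_individual_trend(c(1, 2, 3), c(1, 3, 2))
  expect_equal(f$slope, 0.5)
  expect_equal(f$slope, brute_ols_slope(c(1, 2, 3), c(1, 3, 2)))
  expect_equal(f$intercept, 1.0)
  expect_equal(unname(f$residuals), c(-0.5, 1.0, -0.5))

  # shift equivariance: constant offset moves the intercept only
  fc <- fit_individual_trend(c(1, 2, 3), c(1, 3, 2) + 7)
  expect_equal(fc$intercept, 8.0)
  expect_equal(fc$residuals, f$residuals)

  # missing days are simply absent; too few days -> no fit
  fm <- fit_individual_trend(1:5, c(1, NA, 3, NA, 2))
  expect_equal(fm$n, 3)
  expect_null(fit_individual_trend(1:5, c(1, NA, NA, NA, 2)))
})

test_that("activity RMSE uses divisor n", {
  expect_equal(activity_rmse(fake_fit(rep(0, 5))), 0)
  expect_equal(activity_rmse(fake_fit(c(-0.5, 1.0, -0.5))), sqrt(1.5 / 3))
  expect_equal(activity_rmse(fake_fit(c(1, -1, 1, -1))), 1)
  expect_true(is.na(activity_rmse(NULL)))
})

test_that("lag-1 autocorrelation uses consecutive-age complete pairs only", {
  # perfect alternation -> -1
  expect_equal(lag1_autocorrelation(fake_fit(c(1, -1, 1, -1, 1))), -1)

  # iid residuals: AC near zero
  set.seed(99)
  ages <- 1:10000
  f <- fit_individual_trend(ages, rnorm(10000))
  expect_lt(abs(lag1_autocorrelation(f)), 0.05)

  # ages (1,2,4,5): only two consecutive pairs -> missing
  expect_true(is.na(lag1_autocorrelation(fake_fit(c(1, -1, 1, -1),
                                                  ages = c(1, 2, 4, 5)))))
  expect_true(is.na(lag1_autocorrelation(NULL)))
})

test_that("minute classes: switch detection, bin counts and class bounds", {
  # class boundaries: 0-2 / 3-4 / 5-7 / 8-15 active minutes
  expect_equal(broileract:::classify_counts(c(0, 2, 3, 4, 5, 6, 7, 8, 15)),
               c(1L, 1L, 2L, 2L, 3L, 3L, 3L, 4L, 4L))

  # bird that never changes antenna: all counts 0, all classes 1
  ev0 <- data.frame(sec_of_day = seq(25200, 82799, by = 30), antenna = 4)
  c0 <- minute_activity_classes(ev0, effective_seconds = 57600)
  expect_equal(nrow(c0), 64)
  expect_true(all(c0$active_min == 0))
  expect_true(all(c0$class == 1L))
  expect_true(all(c0$complete))

  # six switch minutes in the first 15-min bin -> count 6, class 3;
  # each switch minute hops 1 -> 2 -> 1 within the minute so no switch
  # leaks into the next minute
  sw_min <- c(0, 2, 4, 6, 8, 10)
  hop <- data.frame(
    sec_of_day = as.vector(rbind(25200 + 60 * sw_min + 1,
                                 25200 + 60 * sw_min + 2)),
    antenna = rep(c(2, 1), times = length(sw_min)))
  ev <- rbind(data.frame(sec_of_day = seq(25200, 82799, by = 60), antenna = 1),
              hop)
  ev <- ev[order(ev$sec_of_day), ]
  cc <- minute_activity_classes(ev, effective_seconds = 57600)
  expect_equal(cc$active_min[1], 6)
  expect_equal(cc$class[1], 3L)
  expect_true(all(cc$active_min[-1] == 0))

  # incomplete day flagged, not dropped
  ci <- minute_activity_classes(ev0, effective_seconds = 50000)
  expect_false(any(ci$complete))
})

test_that("sample entropy matches closed forms and behaves with randomness", {
  # a constant series sits at the counting convention's regularity floor
  # ln((N-m)/(N-m-2)): all templates match at both lengths, but the
  # length-(m+1) template set has one member fewer
  expect_equal(sample_entropy(rep(3, 64), r = 0.2),
               -log(choose(61, 2) / choose(62, 2)))
  expect_equal(sample_entropy(rep(3, 64), r = 0.2),
               brute_sampen(rep(3, 64), r = 0.2))
  expect_equal(sample_entropy(rep(c(1, 2), 32), m = 2, r = 0.1),
               -log(900 / 930))
  # short series undefined
  expect_true(is.na(sample_entropy(c(1, 2, 1), m = 2)))
  # iid classes are less regular than strict alternation
  set.seed(4)
  r_alt <- sample_entropy(rep(c(1, 2), 32), r = 0.1)
  r_iid <- mean(replicate(50, {
    s <- sample(1:4, 64, replace = TRUE)
    sample_entropy(s, r = 0.2 * sd(s))
  }), na.rm = TRUE)
  expect_gt(r_iid, r_alt)
})

test_that("bird entropy averages complete days only", {
  mk_day <- function(age, cls, complete = TRUE) {
    data.table::data.table(age_days = age, bin = seq_along(cls), class = cls,
                           complete = complete)
  }
  set.seed(8)
  s1 <- sample(1:4, 64, replace = TRUE)
  s2 <- sample(1:4, 64, replace = TRUE)
  e1 <- sample_entropy(s1, r = 0.2 * sd(s1))
  e2 <- sample_entropy(s2, r = 0.2 * sd(s2))
  cd <- rbind(mk_day(1, s1), mk_day(2, s2))
  expect_equal(bird_entropy(cd), mean(c(e1, e2)))
  # an incomplete third day does not contribute
  cd3 <- rbind(cd, mk_day(3, sample(1:4, 64, TRUE), complete = FALSE))
  expect_equal(bird_entropy(cd3), mean(c(e1, e2)))
  expect_true(is.na(bird_entropy(mk_day(1, s1, complete = FALSE))))
})

test_that("k-SD outlier rule computed including the candidate (masking-aware)", {
  expect_equal(flag_outliers(rep(7, 20)), rep(FALSE, 20))
  # 100 values at 10 plus one at 1000: SD ~ 98.5, 4 SD ~ 394 < 980 -> flagged
  x <- c(rep(10, 100), 1000)
  expect_equal(which(flag_outliers(x)), 101L)
  # 9 values at 10 plus one at 1000: the outlier inflates the SD enough to
  # mask itself (4 SD ~ 1252 > 891) -> nothing flagged
  y <- c(rep(10, 9), 1000)
  expect_equal(sum(flag_outliers(y)), 0)
  # grouping: flags computed within rounds
  g <- rep(1:2, each = 101)
  xx <- c(x, rep(1000, 100), 10)
  expect_equal(which(flag_outliers(xx, g)), c(101L, 202L))
  # NAs never flagged
  expect_equal(sum(flag_outliers(c(x, NA), rep(1, 102))), 1)
})

test_that("adding a missing day never changes MD or Skew", {
  set.seed(21)
  for (i in 1:20) {
    x <- rnorm(10, 20, 4)
    xm <- append(x, NA_real_, after = sample(0:10, 1))
    expect_equal(mean_distance(xm), mean_distance(x))
    expect_equal(activity_skewness(xm), activity_skewness(x))
  }
})

test_that("descriptor table integrates trend, entropy, and outlier masking", {
  # enough pen mates that the within-round 4-SD rule can flag one extreme
  # bird despite it inflating the round SD itself
  daily <- data.table::CJ(bird_id = sprintf("B%02d", 1:25), age_days = 1:10)
  set.seed(5)
  daily[, round_id := 1L]
  daily[, dadm := pmax(0, 22 - 0.5 * age_days + rnorm(.N, 0, 2))]
  daily[bird_id == "B25", dadm := dadm + 500]
  desc <- compute_descriptors(daily, outlier_k = 4)
  expect_equal(nrow(desc), 25)
  expect_true(all(c("md", "skew", "rmse", "ac", "ent") %in% names(desc)))
  expect_true(is.na(desc[bird_id == "B25", md]))   # masked cell-wise
  expect_false(is.na(desc[bird_id == "B25", rmse]))
  # ent missing without class data
  expect_true(all(is.na(desc$ent)))
})
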