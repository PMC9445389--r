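test_that("Kendall tau-b handles ties and matches cor.test", {
  expect_equal(kendall_tau_b(1:3, 1:3)$tau, 1)
  expect_equal(kendall_tau_b(1:3, 3:1)$tau, -1)
  # pair-count case: C = 1, D = 0, one tie on each side
  expect_equal(kendall_tau_b(c(1, 1, 2), c(1, 2, 2))$tau, 0.5)
  # degenerate input gives a missing result, not an error
  expect_true(is.na(kendall_tau_b(rep(1, 5), 1:5)$tau))
  expect_equal(kendall_tau_b(c(1, NA, 2, 3), c(1, 2, NA, 3))$n, 2)

  set.seed(14)
  for (i in 1:25) {
    n <- sample(10:60, 1)
    x <- sample(1:8, n, replace = TRUE)
    y <- x * sample(c(-1, 1), 1) + sample(1:4, n, replace = TRUE)
    kt <- kendall_tau_b(x, y)
    expect_equal(kt$tau, unname(cor(x, y, method = "kendall")))
    ct <- suppressWarnings(cor.test(x, y, method = "kendall"))
    expect_equal(kt$z, unname(ct$statistic))
    expect_equal(kt$p, ct$p.value)
  }
})

test_that("tau-b symmetries and monotone-transform invariance", {
  set.seed(15)
  for (i in 1:20) {
    n <- sample(8:40, 1)
    x <- sample(1:6, n, replace = TRUE); y <- sample(1:6, n, replace = TRUE)
    if (min(x) == max(x) || min(y) == max(y)) next
    t0 <- kendall_tau_b(x, y)$tau
    expect_equal(kendall_tau_b(y, x)$tau, t0)
    expect_equal(kendall_tau_b(x, -y)$tau, -t0)
    expect_equal(kendall_tau_b(exp(x), y^3)$tau, t0)  # strictly monotone
  }
})

test_that("bootstrap CI is seeded, powerful, and roughly calibrated", {
  set.seed(16)
  x <- rnorm(500); y <- 0.8 * x + rnorm(500, 0, 0.5)
  ci1 <- bootstrap_tau_ci(x, y, B = 200, seed = 9)
  ci2 <- bootstrap_tau_ci(x, y, B = 200, seed = 9)
  expect_identical(ci1, ci2)
  expect_gt(ci1$lower, 0)  # strong correlation: CI excludes 0
  tau <- kendall_tau_b(x, y)$tau
  expect_lte(ci1$lower, tau); expect_gte(ci1$upper, tau)

  # coverage under independence: percentile CI covers 0 about 95% of the
  # time (scaled-down replication)
  set.seed(17)
  cover <- mean(vapply(1:150, function(i) {
    a <- rnorm(40); b <- rnorm(40)
    ci <- bootstrap_tau_ci(a, b, B = 200)
    ci$lower <= 0 && ci$upper >= 0
  }, logical(1)))
  expect_gte(cover, 0.90); expect_lte(cover, 0.99)
})

test_that("Wilcoxon rank-sum statistic and identities", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$W, 0)
  expect_equal(wilcoxon_rank_sum(c(4, 5, 6), c(1, 2, 3))$W, 9)
  expect_equal(wilcoxon_rank_sum(rep(2, 4), rep(2, 6))$p, 1)
  set.seed(18)
  for (i in 1:30) {
    na <- sample(3:30, 1); nb <- sample(3:30, 1)
    a <- sample(1:10, na, replace = TRUE); b <- sample(1:10, nb, replace = TRUE)
    expect_equal(wilcoxon_rank_sum(a, b)$W + wilcoxon_rank_sum(b, a)$W,
                 na * nb)
    expect_equal(wilcoxon_rank_sum(a, b)$W,
                 unname(suppressWarnings(wilcox.test(a, b)$statistic)))
  }
})

make_model_cohort <- function(n = 240, seed = 1, beta_rmse = -1,
                              round_fx = c(-2, 1, 2, -1)) {
  set.seed(seed)
  cohort <- sim_descriptor_cohort(n, sigma = pmax(0.3, rnorm(n, 3.9, 1.6)),
                                  ent_days = 0)
  cohort[, ent := rnorm(n, 1.16, 0.09)]  # entropy-scale noise stand-in
  cohort[, round_id := rep(2:5, length.out = n)]
  cohort[, start_weight := pmax(30, rnorm(n, 42, 3))]
  cohort[, adg := 60 + round_fx[round_id - 1] + 0.4 * start_weight +
           beta_rmse * sigma + rnorm(n, 0, 5)]
  cohort
}

test_that("ADG model: sum-to-zero rounds, Type-I table, recovery", {
  co <- make_model_cohort(seed = 21)
  fit <- fit_adg_model(co, include_rounds = 2:5)
  # the full set of round effects always sums to zero
  if (!is.null(fit$round_effects))
    expect_equal(sum(fit$round_effects), 0, tolerance = 1e-10)
  # the true activity-variability effect is retained and near -1/0.93
  expect_true("rmse" %in% fit$terms)
  est <- fit$coefficients["rmse", "Estimate"]
  expect_lt(abs(est - (-1)), 0.5)
  expect_lte(fit$adj_r_squared, fit$r_squared)

  # structure with only Round + SW + RMSE: 3 round contrasts + 2 slopes
  # + intercept
  fit2 <- fit_adg_model(co, candidates = c("round_id", "start_weight", "rmse"),
                        include_rounds = 2:5, stage2 = FALSE, alpha = 1)
  expect_equal(nrow(fit2$coefficients), 6)
  expect_equal(rownames(fit2$anova)[1:3],
               c("round_id", "start_weight", "rmse"))
  expect_equal(sum(fit2$round_effects), 0, tolerance = 1e-10)

  # rank deficiency is reported with the aliased term
  co2 <- data.table::copy(co)[, skew := rmse]
  expect_error(fit_adg_model(co2, candidates = c("rmse", "skew"),
                             alpha = 1, stage2 = FALSE),
               "alias|deficien")
})

test_that("backward selection drops null terms and respects marginality", {
  co <- make_model_cohort(seed = 22, beta_rmse = 0)
  fit <- fit_adg_model(co, include_rounds = 2:5)
  # start weight (a real effect) is kept
  expect_true("start_weight" %in% fit$terms)
  # no interaction without both parents
  inter <- grep(":", fit$terms, value = TRUE)
  for (tm in inter) {
    parents <- strsplit(tm, ":", fixed = TRUE)[[1]]
    expect_true(all(parents %in% fit$terms))
  }
  # the selection trace records every drop
  expect_true(all(fit$trace$action %in% c("drop", "add")))
})

test_that("AIC criterion is available as an alternative", {
  co <- make_model_cohort(seed = 23)
  fit <- fit_adg_model(co, include_rounds = 2:5, criterion = "AIC",
                       stage2 = FALSE)
  expect_true("rmse" %in% fit$terms)
})

test_that("per-descriptor correlation table uses pairwise-complete data", {
  co <- make_model_cohort(seed = 24)
  co[1:40, ent := NA_real_]
  tbl <- descriptor_adg_correlations(co, B = 100, seed = 2)
  expect_equal(tbl$descriptor, c("md", "skew", "rmse", "ac", "ent"))
  expect_equal(tbl$n[tbl$descriptor == "ent"], nrow(co) - 40)
  expect_true(all(tbl$ci_lower <= tbl$tau & tbl$tau <= tbl$ci_upper))
  # rmse truly correlates with adg here
  expect_lt(tbl$p[tbl$descriptor == "rmse"], 0.05)
})

test_that("24-hour and light-period distances are strongly rank-correlated", {
  g <- build_antenna_grid()
  set.seed(25)
  d24 <- numeric(40); dlp <- numeric(40)
  for (i in 1:40) {
    day <- simulate_bird_day(runif(1, 5, 35), runif(1), g,
                             sample_period_s = 120)
    ev <- day$events; ev[, segment := 1L]
    d24[i] <- daily_distance(ev, g)
    dlp[i] <- daily_distance(ev[sec_of_day >= 25200 & sec_of_day < 82800], g)
  }
  expect_gt(kendall_tau_b(d24, dlp)$tau, 0.9)
})
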