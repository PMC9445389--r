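#' Kendall rank correlation tau-b with tie-corrected test
#'
#' Kendall's tau-b for paired observations with ties:
#' `tau_b = (C - D) / sqrt((n0 - n1)(n0 - n2))` where `C`/`D` are the
#' concordant/discordant pair counts, `n0 = n(n-1)/2` and `n1`, `n2` are
#' the tied-pair counts within `x` and `y`. The z statistic uses the
#' standard tie-corrected normal approximation for the variance of
#' `S = C - D`, with a two-sided p-value. Pairs with a missing value on
#' either side are dropped.
#'
#' @param x,y paired numeric vectors.
#' @return list with `tau`, `z`, `p`, `n` (pairs used) and `S`
#'   (`C - D`); `tau` is `NA` (with `z`, `p` `NA`) when fewer than 3
#'   complete pairs remain or either side has zero variance.
#' @examples
#' kendall_tau_b(c(1, 1, 2), c(1, 2, 2))$tau  # 0.5
#' @export
kendall_tau_b <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- as.numeric(x[ok]); y <- as.numeric(y[ok])
  n <- length(x)
  na_result <- list(tau = NA_real_, z = NA_real_, p = NA_real_, n = n,
                    S = NA_real_)
  if (n < 3) return(na_result)
  if (min(x) == max(x) || min(y) == max(y)) return(na_result)

  dx <- sign(outer(x, x, "-"))
  dy <- sign(outer(y, y, "-"))
  up <- upper.tri(dx)
  S <- sum(dx[up] * dy[up])  # C - D

  t <- as.numeric(table(x)); u <- as.numeric(table(y))
  n0 <- n * (n - 1) / 2
  n1 <- sum(t * (t - 1) / 2); n2 <- sum(u * (u - 1) / 2)
  tau <- S / sqrt((n0 - n1) * (n0 - n2))

  v0 <- n * (n - 1) * (2 * n + 5)
  vt <- sum(t * (t - 1) * (2 * t + 5)); vu <- sum(u * (u - 1) * (2 * u + 5))
  v1 <- sum(t * (t - 1)) * sum(u * (u - 1)) / (2 * n * (n - 1))
  v2 <- sum(t * (t - 1) * (t - 2)) * sum(u * (u - 1) * (u - 2)) /
        (9 * n * (n - 1) * (n - 2))
  var_s <- (v0 - vt - vu) / 18 + v1 + v2
  z <- S / sqrt(var_s)
  list(tau = tau, z = z, p = 2 * pnorm(-abs(z)), n = n, S = S)
}

#' Bootstrap percentile confidence interval for Kendall's tau-b
#'
#' Resamples the observation pairs with replacement `B` times, recomputes
#' tau-b on each resample and returns the percentile interval. Degenerate
#' resamples (zero variance on either side) are redrawn; their count is
#' reported.
#'
#' @param x,y paired numeric vectors (missing pairs dropped).
#' @param B number of bootstrap resamples (default 1000).
#' @param level confidence level (default 0.95).
#' @param seed optional integer seed for reproducible intervals.
#' @return list with `lower`, `upper`, `level`, `B`, `redraws`.
#' @export
bootstrap_tau_ci <- function(x, y, B = 1000, level = 0.95, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ok <- complete.cases(x, y)
  x <- as.numeric(x[ok]); y <- as.numeric(y[ok])
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs for a bootstrap CI")
  taus <- numeric(B)
  redraws <- 0L
  for (b in seq_len(B)) {
    repeat {
      i <- sample.int(n, n, replace = TRUE)
      if (min(x[i]) != max(x[i]) && min(y[i]) != max(y[i])) break
      redraws <- redraws + 1L
      if (redraws > 100 * B) stop("too many degenerate bootstrap resamples")
    }
    taus[b] <- kendall_tau_b(x[i], y[i])$tau
  }
  a <- (1 - level) / 2
  ci <- quantile(taus, c(a, 1 - a), names = FALSE)
  list(lower = ci[1], upper = ci[2], level = level, B = B, redraws = redraws)
}

#' Wilcoxon rank-sum comparison of two groups
#'
#' Mann-Whitney-Wilcoxon test between two independent groups, as used to
#' compare activity descriptors between the low- and high-ADG quartile
#' groups. The statistic is `W = (rank sum of group a) - n_a(n_a + 1)/2`
#' (so `W + W' = n_a * n_b`); the p-value is exact for small untied
#' samples and uses the tie-corrected normal approximation otherwise.
#'
#' @param a,b numeric vectors (missing values dropped).
#' @return list with `W`, `p`, `n_a`, `n_b`.
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$W  # 0
#' @export
wilcoxon_rank_sum <- function(a, b) {
  a <- as.numeric(a[!is.na(a)]); b <- as.numeric(b[!is.na(b)])
  if (length(a) == 0 || length(b) == 0) stop("both groups must be non-empty")
  n_a <- length(a); n_b <- length(b)
  r <- rank(c(a, b))
  W <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  pooled <- c(a, b)
  if (min(pooled) == max(pooled)) {
    p <- 1
  } else {
    p <- suppressWarnings(wilcox.test(a, b)$p.value)
  }
  list(W = W, p = p, n_a = n_a, n_b = n_b)
}

#' Rank correlations between activity descriptors and ADG
#'
#' Computes, per descriptor, the pairwise-complete Kendall tau-b with
#' ADG, its tie-corrected z and p, and a seeded bootstrap percentile CI
#' -- one row per descriptor, mirroring the structure of a correlation
#' results table.
#'
#' @param tbl merged per-bird table containing `adg` and the descriptor
#'   columns.
#' @param descriptors descriptor column names (default the five activity
#'   descriptors).
#' @param B,level,seed bootstrap settings (see [bootstrap_tau_ci()]).
#' @return data.frame: `descriptor`, `tau`, `ci_lower`, `ci_upper`, `z`,
#'   `p`, `n`.
#' @export
descriptor_adg_correlations <- function(tbl,
                                        descriptors = c("md", "skew", "rmse",
                                                        "ac", "ent"),
                                        B = 1000, level = 0.95, seed = NULL) {
  rows <- lapply(seq_along(descriptors), function(k) {
    d <- descriptors[k]
    xv <- tbl[[d]]; yv <- tbl$adg
    kt <- kendall_tau_b(xv, yv)
    ci <- if (!is.na(kt$tau)) {
      s <- if (is.null(seed)) NULL else seed + k
      bootstrap_tau_ci(xv, yv, B = B, level = level, seed = s)
    } else list(lower = NA_real_, upper = NA_real_)
    data.frame(descriptor = d, tau = kt$tau, ci_lower = ci$lower,
               ci_upper = ci$upper, z = kt$z, p = kt$p, n = kt$n)
  })
  do.call(rbind, rows)
}

#' Compare descriptors between ADG quartile groups
#'
#' Wilcoxon rank-sum tests of each activity descriptor between the low-
#' and high-ADG quartile groups.
#'
#' @param tbl merged per-bird table with a `quartile` column (from
#'   [adg_quartile_groups()]) and descriptor columns.
#' @param descriptors descriptor column names.
#' @return data.frame: `descriptor`, `mean_low`, `mean_high`, `W`, `p`,
#'   `n_low`, `n_high`.
#' @export
compare_quartile_groups <- function(tbl,
                                    descriptors = c("md", "skew", "rmse",
                                                    "ac", "ent")) {
  lo <- tbl[tbl$quartile == "low", , drop = FALSE]
  hi <- tbl[tbl$quartile == "high", , drop = FALSE]
  rows <- lapply(descriptors, function(d) {
    a <- lo[[d]][!is.na(lo[[d]])]
    b <- hi[[d]][!is.na(hi[[d]])]
    if (length(a) == 0 || length(b) == 0) {
      return(data.frame(descriptor = d, mean_low = NA_real_,
                        mean_high = NA_real_, W = NA_real_, p = NA_real_,
                        n_low = length(a), n_high = length(b)))
    }
    wt <- wilcoxon_rank_sum(a, b)
    data.frame(descriptor = d, mean_low = mean(a), mean_high = mean(b),
               W = wt$W, p = wt$p, n_low = wt$n_a, n_high = wt$n_b)
  })
  do.call(rbind, rows)
}
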