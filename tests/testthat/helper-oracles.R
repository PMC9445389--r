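# Independent brute-force oracles, deliberately written as literal loops
# so they share no code with the package implementations.

# sample entropy by explicit template-pair counting:
# B over length-m templates starting at 1..N-m, A over length-(m+1)
# templates starting at 1..N-m-1, Chebyshev distance <= r, i < j pairs
brute_sampen <- function(x, m = 2, r) {
  N <- length(x)
  count_pairs <- function(len, n_t) {
    cnt <- 0L
    if (n_t < 2) return(cnt)
    for (i in 1:(n_t - 1)) {
      for (j in (i + 1):n_t) {
        d <- 0
        for (k in 0:(len - 1)) {
          dk <- abs(x[i + k] - x[j + k])
          if (dk > d) d <- dk
        }
        if (d <= r) cnt <- cnt + 1L
      }
    }
    cnt
  }
  B <- count_pairs(m, N - m)
  A <- count_pairs(m + 1, N - m - 1)
  if (A == 0 || B == 0) return(NA_real_)
  -log(A / B)
}

# Kendall tau-b by explicit concordant/discordant/tie pair counting
brute_tau <- function(x, y) {
  n <- length(x)
  C <- 0; D <- 0; tied_x <- 0; tied_y <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      a <- x[i] - x[j]; b <- y[i] - y[j]
      if (a == 0) tied_x <- tied_x + 1
      if (b == 0) tied_y <- tied_y + 1
      if (a != 0 && b != 0) {
        if (a * b > 0) C <- C + 1 else D <- D + 1
      }
    }
  }
  n0 <- n * (n - 1) / 2
  (C - D) / sqrt((n0 - tied_x) * (n0 - tied_y))
}

# ordinary least squares slope by the closed-form covariance ratio
brute_ols_slope <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}
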