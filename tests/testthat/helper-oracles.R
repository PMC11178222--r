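# Independent brute-force oracles used to cross-check the package's
# implementations. Deliberately naive: plain loops and closed forms.

ols_oracle <- function(x, y) {
  n <- length(x)
  xbar <- sum(x) / n
  ybar <- sum(y) / n
  sxy <- 0; sxx <- 0
  for (i in seq_len(n)) {
    sxy <- sxy + (x[i] - xbar) * (y[i] - ybar)
    sxx <- sxx + (x[i] - xbar)^2
  }
  slope <- sxy / sxx
  intercept <- ybar - slope * xbar
  sse <- 0; sst <- 0
  for (i in seq_len(n)) {
    sse <- sse + (y[i] - intercept - slope * x[i])^2
    sst <- sst + (y[i] - ybar)^2
  }
  list(slope = slope, intercept = intercept,
       r_squared = if (sst == 0) 1 else 1 - sse / sst)
}

rmsre_oracle <- function(x, x_hat) {
  acc <- 0
  for (i in seq_along(x)) {
    m <- (x[i] + x_hat[i]) / 2
    acc <- acc + ((x[i] - x_hat[i]) / m)^2
  }
  sqrt(acc / length(x))
}

reldiff_oracle <- function(x, x_hat) {
  out <- numeric(length(x))
  for (i in seq_along(x))
    out[i] <- 100 * abs(x[i] - x_hat[i]) / ((x[i] + x_hat[i]) / 2)
  out
}

# Type-7 percentile by hand: h = (n - 1) p + 1, linear interpolation.
percentile_oracle <- function(v, p) {
  v <- sort(v)
  n <- length(v)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  v[lo] + (h - lo) * (v[hi] - v[lo])
}

iqr_oracle <- function(v) {
  q1 <- percentile_oracle(v, 0.25)
  q3 <- percentile_oracle(v, 0.75)
  iqr <- q3 - q1
  keep <- v >= q1 - 1.5 * iqr & v <= q3 + 1.5 * iqr
  list(kept = v[keep], removed = v[!keep],
       fences = c(q1 - 1.5 * iqr, q3 + 1.5 * iqr))
}

# Direct (untruncated) Gaussian-kernel density on a grid.
kde_oracle <- function(samples, grid, bandwidth) {
  vapply(grid, function(g) mean(dnorm(g - samples, sd = bandwidth)),
         numeric(1))
}

# Grid argmax of the oracle density inside a window.
kde_mode_oracle <- function(samples, grid, bandwidth, window) {
  inside <- grid >= window[1] & grid <= window[2]
  d <- kde_oracle(samples, grid[inside], bandwidth)
  grid[inside][which.max(d)]
}
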