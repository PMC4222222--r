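# Independent brute-force oracles, deliberately written as plain loops so
# they share no code path with the package implementation.

# Exhaustive exponent grid with the scale constant profiled at each point.
oracle_grid_beta <- function(icv, voi, lower = 0, upper = 3, step = 1e-3) {
  x <- icv / 1500                      # crude rescale, absorbed into alpha
  best <- list(sse = Inf, beta = NA_real_, alpha = NA_real_)
  for (b in seq(lower, upper, by = step)) {
    w <- x^b
    a <- sum(voi * w) / sum(w * w)
    sse <- sum((voi - a * w)^2)
    if (sse < best$sse)
      best <- list(sse = sse, beta = b, alpha = a / 1500^b)
  }
  best
}

# OLS residuals straight from the normal equations.
oracle_ols_residuals <- function(X, y) {
  beta <- solve(t(X) %*% X, t(X) %*% y)
  as.numeric(y - X %*% beta)
}

# Double-loop leave-one-out: refit with `fitfun(x, y)` (returning a
# prediction function) without point i, predict point i, square, sum.
oracle_loocv <- function(x, y, fitfun) {
  total <- 0
  for (i in seq_along(x)) {
    pred <- fitfun(x[-i], y[-i])
    total <- total + (y[i] - pred(x[i]))^2
  }
  total
}
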