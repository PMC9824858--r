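# Independent brute-force oracles, kept deliberately literal (two-pass
# formulas, explicit loops) so they share no code with the implementation.

# segment variance: mean-centred sum of squares over s[i..j], divisor j - i
seg_var_oracle <- function(s, i, j) {
  x <- s[i:j]
  m <- sum(x) / length(x)
  acc <- 0
  for (v in x) acc <- acc + (v - m)^2
  acc / (j - i)
}

# literal evaluation of the two-segment log-variance criterion at every
# admissible merge point, with the same variance floor as the package
brute_aic <- function(s, variant = "inclusive") {
  N <- length(s)
  eps <- 1e-12 * max(abs(s))^2
  ks <- 2:(N - 2)
  vapply(ks, function(k) {
    vl <- max(seg_var_oracle(s, 1, k), eps)
    vr <- max(seg_var_oracle(s, k + 1, N), eps)
    coef_r <- if (variant == "inclusive") N - k + 1 else N - k - 1
    k * log(vl) + coef_r * log(vr)
  }, 1.0)
}

# M applications of the forward first difference, one loop per application
iter_diff_oracle <- function(x, M) {
  for (m in seq_len(M)) {
    y <- numeric(length(x) - 1L)
    for (i in seq_along(y)) y[i] <- x[i + 1L] - x[i]
    x <- y
  }
  x
}

# quadratic least squares through the normal equations
quad_fit_oracle <- function(theta, v) {
  X <- cbind(1, theta, theta^2)
  solve(t(X) %*% X, t(X) %*% v)[, 1L]
}

# textbook Pearson correlation
pearson_oracle <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# default synthetic A-scan used across picker tests
default_sim <- function(seed, ...) {
  simulate_ascan(ascan_spec(seed = seed, ...))
}
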