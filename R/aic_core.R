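#' Segment variance of a sampled signal
#'
#' Variance of the segment `s[i..j]` as used by the AIC change-point
#' criterion: the mean-centred sum of squares divided by `j - i`. Note the
#' divisor is the segment length minus one written as `j - i`, not
#' `j - i + 1`.
#'
#' @param s Numeric vector.
#' @param i,j Segment bounds, `1 <= i < j <= length(s)`.
#'
#' @return A single non-negative number.
#' @export
#' @examples
#' segment_variance(c(1, -1), 1, 2)   # 2
segment_variance <- function(s, i, j) {
  if (i >= j) stop("segment bounds must satisfy i < j (got i=", i, ", j=", j, ")")
  if (i < 1 || j > length(s)) stop("segment bounds outside the signal")
  x <- s[i:j]
  sum((x - mean(x))^2) / (j - i)
}

#' Classical AIC arrival-time curve
#'
#' Computes the two-segment log-variance criterion
#' `AIC(k) = k * log var(s[1..k]) + (N - k + 1) * log var(s[k+1..N])`
#' over all admissible merge points `k` in `[2, N - 2]`; each side of the
#' split keeps at least two samples so both variances are defined. The
#' global minimum of this curve separates the high-energy transmit burst
#' from what follows; in heterogeneous stems that junction is generally
#' *not* the primary echo (see [pick_primary_echo()]).
#'
#' Variances below a relative floor of `1e-12 * max(|s|)^2` are clamped to
#' the floor before the (natural) logarithm, so near-silent spans do not
#' produce `-Inf`. The printed form of the second coefficient, `N - k + 1`,
#' is the default; `variant = "maeda"` uses the common alternative
#' `N - k - 1`. Either choice shifts the curve without materially moving
#' its minimum.
#'
#' @param trace An [ultrasonic_trace] or bare numeric vector (at least 16
#'   samples).
#' @param variant `"inclusive"` (default, coefficient `N - k + 1`) or `"maeda"`
#'   (`N - k - 1`).
#'
#' @return An object of class `aic_curve`: list with `values` (one per
#'   admissible `k`), `k_min`, `k_max`, `trace_id`, `variant`.
#' @seealso [classic_min_pick()], [extract_tail()]
#' @export
#' @examples
#' tr <- c(rnorm(100, sd = 1), rnorm(100, sd = 0.05))
#' curve <- aic_curve(tr)
#' classic_min_pick(curve)   # close to 100
aic_curve <- function(trace, variant = c("inclusive", "maeda")) {
  variant <- match.arg(variant)
  trace <- as_trace(trace)
  s <- trace$samples
  N <- length(s)
  if (N < 16L) stop("aic_curve needs at least 16 samples")
  if (max(abs(s - s[1L])) == 0) {
    stop("degenerate trace (zero variance everywhere)")
  }

  # cumulative-sum evaluation; centring the whole trace first leaves every
  # segment variance unchanged but keeps the sums well conditioned
  sc <- s - mean(s)
  cs <- cumsum(sc)
  css <- cumsum(sc^2)
  ks <- 2:(N - 2L)

  var_left <- (css[ks] - cs[ks]^2 / ks) / (ks - 1)
  sum_r <- cs[N] - cs[ks]
  ssq_r <- css[N] - css[ks]
  var_right <- (ssq_r - sum_r^2 / (N - ks)) / (N - ks - 1)

  eps <- 1e-12 * max(abs(s))^2
  var_left <- pmax(var_left, eps)
  var_right <- pmax(var_right, eps)

  coef_r <- if (variant == "inclusive") N - ks + 1 else N - ks - 1
  values <- ks * log(var_left) + coef_r * log(var_right)

  structure(
    list(values = values, k_min = 2L, k_max = N - 2L,
         trace_id = trace$trace_id, variant = variant),
    class = "aic_curve"
  )
}

#' @export
print.aic_curve <- function(x, ...) {
  cat("<aic_curve> ", x$trace_id, "  (variant: ", x$variant, ")\n", sep = "")
  cat(sprintf("  k range : [%d, %d]  (%d points)\n", x$k_min, x$k_max,
              length(x$values)))
  cat(sprintf("  minimum : %.4g at k = %d\n", min(x$values),
              classic_min_pick(x)))
  invisible(x)
}

#' Classical AIC pick: position of the global minimum
#'
#' Returns the merge point `k` attaining the global minimum of an AIC
#' curve, the earliest such `k` on ties (first-arrival convention).
#'
#' @param curve An [aic_curve].
#'
#' @return Integer sample index.
#' @export
classic_min_pick <- function(curve) {
  stopifnot(inherits(curve, "aic_curve"))
  curve$k_min + which.min(curve$values) - 1L
}
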