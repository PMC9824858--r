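#' Configuration of the hybrid differential AIC picker
#'
#' @param diff_order Order `M` of the iterated forward difference applied to
#'   the AIC tail (default 4).
#' @param envelope_exponent Positive odd exponent of the signed envelope
#'   (default 3); odd so the sign of the differential is preserved.
#' @param mixing_mode How the normalised envelope is recombined with the AIC
#'   tail: `"shifted"` (default) multiplies the envelope by
#'   `aicseg - max(aicseg)`, which reproduces the sign structure of the
#'   plain product for the usual negative-valued AIC curves while staying
#'   invariant under amplitude scaling of the trace; `"literal"` is the
#'   plain elementwise product `envelope * aicseg`.
#' @param onset_offset Integer correction added to the raw argmax (default
#'   0; the raw pick sits 0--2 samples after the true onset on synthetic
#'   benchmarks, so no correction is applied by default).
#'
#' @return An object of class `hybrid_config`.
#' @export
hybrid_config <- function(diff_order = 4L, envelope_exponent = 3L,
                          mixing_mode = c("shifted", "literal"),
                          onset_offset = 0L) {
  mixing_mode <- match.arg(mixing_mode)
  diff_order <- as.integer(diff_order)
  envelope_exponent <- as.integer(envelope_exponent)
  if (diff_order < 1L) stop("diff_order must be >= 1")
  if (envelope_exponent < 1L || envelope_exponent %% 2L == 0L) {
    stop("envelope_exponent must be a positive odd integer")
  }
  structure(
    list(diff_order = diff_order, envelope_exponent = envelope_exponent,
         mixing_mode = mixing_mode, onset_offset = as.integer(onset_offset)),
    class = "hybrid_config"
  )
}

#' Extract the AIC tail after the global minimum
#'
#' Cuts the AIC curve from the position of its global minimum (earliest on
#' ties) to the last admissible merge point. All later stages of the hybrid
#' picker operate on this tail, in a coordinate frame that starts at the
#' minimum.
#'
#' @param curve An [aic_curve].
#'
#' @return A list with `index` (sample index of the AIC minimum) and
#'   `aicseg` (curve values from the minimum to the end).
#' @export
extract_tail <- function(curve) {
  stopifnot(inherits(curve, "aic_curve"))
  pos <- which.min(curve$values)
  list(index = curve$k_min + pos - 1L,
       aicseg = curve$values[pos:length(curve$values)])
}

#' M-th order forward difference
#'
#' Iterated forward first difference: each application maps `x` to
#' `x[i+1] - x[i]`, shortening the sequence by one; `M` applications
#' annihilate any polynomial trend of degree below `M` while turning a kink
#' in the input into a localised spike.
#'
#' @param x Numeric vector, longer than `M`.
#' @param M Positive integer difference order.
#'
#' @return Numeric vector of length `length(x) - M`.
#' @export
#' @examples
#' m_order_difference(c(1, 2, 4, 8), 2)   # c(1, 2)
m_order_difference <- function(x, M) {
  M <- as.integer(M)
  if (M < 1L) stop("difference order must be >= 1")
  if (M >= length(x)) {
    stop("difference order ", M, " too large for a sequence of length ",
         length(x))
  }
  diff(x, differences = M)
}

#' Signed envelope of the differential AIC
#'
#' Raises the differential to an odd power (default cube) and divides by
#' the maximum absolute value, so the output keeps the sign of its input,
#' lies in `[-1, 1]`, and attains magnitude 1 at the strongest excursion.
#' The odd power sharpens genuine spikes relative to low-level ripple --
#' this is the interference suppression at the heart of the hybrid picker.
#'
#' @param d Numeric vector, not identically zero.
#' @param exponent Positive odd integer (default 3).
#'
#' @return Numeric vector of the same length as `d` with `max(|.|) == 1`.
#' @export
signed_envelope <- function(d, exponent = 3L) {
  if (exponent < 1L || exponent %% 2L == 0L) {
    stop("envelope exponent must be a positive odd integer")
  }
  if (all(d == 0)) stop("flat differential")
  p <- d^exponent
  p / max(abs(p))
}

#' Mix the envelope back into the AIC tail
#'
#' Recombines the normalised envelope with the AIC tail so that the echo
#' onset becomes the global maximum. In `"literal"` mode this is the plain
#' elementwise product. In `"shifted"` mode (the default used by
#' [pick_primary_echo()]) the tail is first shifted by its maximum:
#' `envelope * (aicseg - max(aicseg))`. Because the shifted tail is
#' non-positive, a negative envelope spike at the echo dip maps to a large
#' positive peak -- the same sign structure the plain product has when the
#' AIC values are negative -- while the result no longer depends on the
#' overall amplitude scale of the trace.
#'
#' @param envelope Numeric vector; if shorter than `aicseg` it is padded
#'   with trailing zeros (the difference stage shortens the sequence).
#' @param aicseg Numeric vector, the AIC tail.
#' @param mode `"shifted"` or `"literal"`.
#'
#' @return Numeric vector the length of `aicseg`.
#' @export
mixed_aic <- function(envelope, aicseg, mode = c("shifted", "literal")) {
  mode <- match.arg(mode)
  if (length(envelope) > length(aicseg)) {
    stop("envelope longer than AIC tail (", length(envelope), " > ",
         length(aicseg), ")")
  }
  if (length(envelope) < length(aicseg)) {
    envelope <- c(envelope, rep(0, length(aicseg) - length(envelope)))
  }
  switch(mode,
    literal = envelope * aicseg,
    shifted = envelope * (aicseg - max(aicseg))
  )
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("in stage '%s': %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}

#' All intermediate curves of the hybrid picker
#'
#' Runs the full pipeline -- AIC curve, tail extraction, M-th order
#' difference, signed envelope, mixing -- and returns every intermediate
#' sequence in a common coordinate frame starting at the AIC minimum. The
#' difference and envelope are zero-padded at the tail end to the length of
#' `aicseg`.
#'
#' @param trace An [ultrasonic_trace] or numeric vector.
#' @param config A [hybrid_config].
#'
#' @return An object of class `hybrid_curves`: list with `index` (sample
#'   index of the AIC minimum, the frame origin), `aicseg`, `diff`,
#'   `envelope`, `mixed`, `aic` (the full curve) and `trace_id`.
#' @export
hybrid_curves <- function(trace, config = hybrid_config()) {
  stopifnot(inherits(config, "hybrid_config"))
  trace <- as_trace(trace)
  M <- config$diff_order

  curve <- with_stage("aic_curve", aic_curve(trace))
  tail <- with_stage("extract_tail", {
    t0 <- extract_tail(curve)
    if (length(t0$aicseg) < 2L * (M + 1L)) {
      stop("echo window too short (", length(t0$aicseg),
           " samples after the AIC minimum, need >= ", 2L * (M + 1L), ")")
    }
    t0
  })
  d <- with_stage("m_order_difference", m_order_difference(tail$aicseg, M))
  env <- with_stage("signed_envelope",
                    signed_envelope(d, config$envelope_exponent))
  mixed <- with_stage("mixed_aic",
                      mixed_aic(env, tail$aicseg, config$mixing_mode))

  pad <- rep(0, length(tail$aicseg) - length(d))
  structure(
    list(index = tail$index, aicseg = tail$aicseg, diff = c(d, pad),
         envelope = c(env, pad), mixed = mixed, aic = curve,
         trace_id = trace$trace_id, config = config),
    class = "hybrid_curves"
  )
}

#' @export
print.hybrid_curves <- function(x, ...) {
  cat("<hybrid_curves> ", x$trace_id, "\n", sep = "")
  cat(sprintf("  AIC minimum at sample %d; tail of %d samples\n",
              x$index, length(x$aicseg)))
  cat(sprintf("  mixed-curve peak %.4g at sample %d\n", max(x$mixed),
              x$index + which.max(x$mixed) - 1L))
  invisible(x)
}

#' Pick the primary echo with the hybrid differential AIC
#'
#' The classical AIC minimum of a stem A-scan marks the junction between
#' the transmit burst and the noise-drowned span, not the primary echo.
#' The hybrid picker therefore keeps only the AIC tail after that minimum,
#' applies an M-th order forward difference (which turns the slope change
#' at the echo onset into a spike), sharpens and normalises it with a
#' signed odd-power envelope, mixes the envelope back into the tail, and
#' reports the position of the resulting global maximum (earliest on ties)
#' as the primary-echo onset.
#'
#' @inheritParams hybrid_curves
#'
#' @return An [echo_pick].
#' @export
#' @examples
#' sim <- simulate_ascan(ascan_spec(seed = 1))
#' pick_primary_echo(sim$trace)   # onset near sample 153
pick_primary_echo <- function(trace, config = hybrid_config()) {
  trace <- as_trace(trace)
  hc <- hybrid_curves(trace, config)
  p <- which.max(hc$mixed)
  onset <- hc$index + p - 1L + config$onset_offset
  echo_pick(onset_index = onset,
            classic_min_index = hc$index,
            mixed_peak_value = max(hc$mixed),
            trace_id = trace$trace_id,
            n_samples = length(trace$samples))
}
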