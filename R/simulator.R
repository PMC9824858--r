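# run expr with a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specification of a synthetic three-segment A-scan
#'
#' Describes a simulated pulse-echo record with the canonical structure of
#' a stem measurement: a strong transmit burst, a span where the ultrasound
#' is drowned by noise, and the primary echo. All three segments carry
#' additive white Gaussian noise of standard deviation `noise_sigma`; the
#' drowned span additionally carries a sub-noise sinusoid at
#' `drowned_snr_db`, so it vanishes with the noise in the noise-free limit.
#'
#' Signal-to-noise ratios are stated at the carrier peak: a sinusoid of
#' amplitude `A` on noise of standard deviation `sigma` has
#' `SNR = 10*log10(A^2 / (2*sigma^2))` dB.
#'
#' The transmit burst decays slowly (`decay_rate`, per sample) so its
#' variance stays well above the noise up to the burst/noise junction;
#' the echo wavelet decays fast (`echo_decay_rate`), concentrating its
#' energy at the onset the way a heavily attenuated reflection does.
#'
#' @param n_samples Record length (default 200; one printed time unit =
#'   100 samples).
#' @param burst_end Last sample of the transmit burst (default 100).
#' @param echo_onset First sample of the primary echo (default 153).
#' @param carrier_cycles_per_sample Carrier frequency in cycles per sample
#'   (default 0.1, i.e. 1 MHz sampled at 10 MHz).
#' @param burst_amplitude,echo_amplitude Peak amplitudes of the two
#'   wavelets (defaults 1 and 0.4).
#' @param drowned_snr_db Peak SNR of the sub-noise sinusoid in the drowned
#'   span, in dB (default -6).
#' @param noise_sigma Noise standard deviation (default 0.01).
#' @param decay_rate Exponential amplitude decay of the transmit burst,
#'   per sample (default 0.005).
#' @param echo_decay_rate Exponential amplitude decay of the echo wavelet
#'   (default 0.5).
#' @param seed Integer RNG seed; the same spec always generates the same
#'   trace.
#'
#' @return An object of class `ascan_spec`.
#' @seealso [simulate_ascan()], [simulate_table1_suite()]
#' @export
ascan_spec <- function(n_samples = 200L, burst_end = 100L, echo_onset = 153L,
                       carrier_cycles_per_sample = 0.1,
                       burst_amplitude = 1, echo_amplitude = 0.4,
                       drowned_snr_db = -6, noise_sigma = 0.01,
                       decay_rate = 0.005, echo_decay_rate = 0.5,
                       seed = 1L) {
  n_samples <- as.integer(n_samples)
  burst_end <- as.integer(burst_end)
  echo_onset <- as.integer(echo_onset)
  if (n_samples < 16L) stop("n_samples must be >= 16")
  if (!(1L < burst_end && burst_end < echo_onset && echo_onset <= n_samples)) {
    stop("segment boundaries must satisfy 1 < burst_end < echo_onset <= ",
         "n_samples (got ", burst_end, ", ", echo_onset, ", ", n_samples, ")")
  }
  if (echo_onset - burst_end < 2L) {
    stop("the drowned span needs at least one sample between burst_end and ",
         "echo_onset")
  }
  if (burst_amplitude <= 0 || echo_amplitude <= 0) {
    stop("amplitudes must be positive")
  }
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (decay_rate < 0 || echo_decay_rate < 0) stop("decay rates must be >= 0")
  if (carrier_cycles_per_sample <= 0) stop("carrier frequency must be positive")
  structure(
    list(n_samples = n_samples, burst_end = burst_end, echo_onset = echo_onset,
         carrier_cycles_per_sample = carrier_cycles_per_sample,
         burst_amplitude = burst_amplitude, echo_amplitude = echo_amplitude,
         drowned_snr_db = drowned_snr_db, noise_sigma = noise_sigma,
         decay_rate = decay_rate, echo_decay_rate = echo_decay_rate,
         seed = as.integer(seed)),
    class = "ascan_spec"
  )
}

#' Sinusoid amplitude for a requested peak SNR
#'
#' Inverts the peak-SNR convention used throughout the simulator:
#' `A = sigma * sqrt(2 * 10^(snr_db / 10))`.
#'
#' @param snr_db Peak signal-to-noise ratio in dB.
#' @param noise_sigma Noise standard deviation.
#' @return The sinusoid amplitude.
#' @export
echo_amplitude_for_snr <- function(snr_db, noise_sigma) {
  noise_sigma * sqrt(2 * 10^(snr_db / 10))
}

# deterministic part of the trace (no noise), used by simulate_ascan
ascan_deterministic <- function(spec) {
  n <- spec$n_samples
  f <- spec$carrier_cycles_per_sample
  s <- numeric(n)

  i1 <- seq_len(spec$burst_end)
  t1 <- i1 - 1
  s[i1] <- spec$burst_amplitude * exp(-spec$decay_rate * t1) *
    sin(2 * pi * f * t1)

  i2 <- (spec$burst_end + 1L):(spec$echo_onset - 1L)
  a2 <- echo_amplitude_for_snr(spec$drowned_snr_db, spec$noise_sigma)
  t2 <- i2 - i2[1L]
  s[i2] <- a2 * sin(2 * pi * f * t2)

  i3 <- spec$echo_onset:n
  t3 <- i3 - spec$echo_onset
  s[i3] <- spec$echo_amplitude * exp(-spec$echo_decay_rate * t3) *
    sin(2 * pi * f * t3)
  s
}

#' Simulate one A-scan with ground truth
#'
#' Generates the three-segment trace described by an [ascan_spec]:
#' burst, drowned span, primary echo, each with additive white Gaussian
#' noise. The same spec (including its seed) always produces a
#' bit-identical trace.
#'
#' @param spec An [ascan_spec].
#' @param trace_id Optional label; defaults to `"sim_seed<seed>"`.
#'
#' @return A list with `trace` (an [ultrasonic_trace]) and `truth` (class
#'   `simulation_truth`: `echo_onset`, `burst_end` and the generating
#'   `spec`).
#' @export
#' @examples
#' sim <- simulate_ascan(ascan_spec(seed = 42))
#' sim$truth$echo_onset   # 153
simulate_ascan <- function(spec, trace_id = NULL) {
  stopifnot(inherits(spec, "ascan_spec"))
  if (is.null(trace_id)) trace_id <- paste0("sim_seed", spec$seed)
  det <- ascan_deterministic(spec)
  noise <- with_seed(spec$seed, stats::rnorm(spec$n_samples, 0, spec$noise_sigma))
  trace <- ultrasonic_trace(det + noise, trace_id = trace_id)
  truth <- structure(
    list(echo_onset = spec$echo_onset, burst_end = spec$burst_end, spec = spec),
    class = "simulation_truth"
  )
  list(trace = trace, truth = truth)
}

#' Simulate the nine-signal benchmark suite
#'
#' Generates the 3 x 3 design used to benchmark the hybrid picker: three
#' echo-onset positions crossed with three echo SNR levels of decreasing
#' quality. For onset `o` the burst ends at `o - 52`, preserving the
#' 52-sample drowned span of the default record, and the record runs 47
#' samples past the onset. Signals are ordered onset-major (signals 1-3
#' share the first onset), each triplet from the highest SNR down.
#'
#' The suite is a pure function of its arguments: per-trace seeds are
#' derived deterministically from `seed`.
#'
#' @param onsets Three echo-onset sample indices (default
#'   `c(153, 253, 351)`).
#' @param snr_levels_db Three decreasing peak-SNR levels for the echo, in
#'   dB (default `c(30, 27, 24)`, calibrated so the spread of pick errors
#'   brackets the 0-8 sample spread of the reference benchmark).
#' @param seed Integer master seed.
#' @param noise_sigma Noise standard deviation shared by all traces.
#'
#' @return A list of 9 elements, each a `list(trace, truth)` as returned by
#'   [simulate_ascan()]; trace ids are `table1_1` .. `table1_9`.
#' @export
simulate_table1_suite <- function(onsets = c(153L, 253L, 351L),
                                  snr_levels_db = c(30, 27, 24),
                                  seed = 1L, noise_sigma = 0.01) {
  if (length(onsets) != 3L) stop("need exactly 3 onset positions")
  if (length(snr_levels_db) != 3L || is.unsorted(rev(snr_levels_db))) {
    stop("need exactly 3 decreasing SNR levels")
  }
  out <- vector("list", 9L)
  i <- 0L
  for (o in as.integer(onsets)) {
    for (snr in snr_levels_db) {
      i <- i + 1L
      sub_seed <- (as.numeric(seed) * 1009 + i * 9973) %% 2147483647
      spec <- ascan_spec(
        n_samples = o + 47L, burst_end = o - 52L, echo_onset = o,
        echo_amplitude = echo_amplitude_for_snr(snr, noise_sigma),
        noise_sigma = noise_sigma, seed = as.integer(sub_seed)
      )
      out[[i]] <- simulate_ascan(spec, trace_id = paste0("table1_", i))
    }
  }
  out
}
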