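#' Transducer specification
#'
#' Describes the single-element pulse-echo transducer used by the RF
#' simulator. The emitted pulse is modelled as a Gabor pulse: a cosine at the
#' centre frequency under a Gaussian envelope whose width is set by the
#' fractional bandwidth (full width of the amplitude spectrum at half
#' maximum, i.e. -6 dB, divided by the centre frequency).
#'
#' @param center_frequency centre frequency f0 in Hz (default 50 MHz).
#' @param fractional_bandwidth -6 dB fractional bandwidth in (0, 1]
#'   (default 0.5).
#' @param sampling_rate digitizer sampling rate in Hz (default 400 MHz).
#'   Must be at least `4 * center_frequency` (Nyquist margin).
#' @param pulse_amplitude peak envelope amplitude of the emitted pulse,
#'   arbitrary units (default 1).
#' @return an object of class `"transducer_spec"`.
#' @examples
#' tx <- transducer_spec()
#' tx
#' @export
transducer_spec <- function(center_frequency = 50e6,
                            fractional_bandwidth = 0.5,
                            sampling_rate = 400e6,
                            pulse_amplitude = 1) {
  check_number(center_frequency, "center_frequency", lower = 0,
               strict_lower = TRUE)
  check_number(fractional_bandwidth, "fractional_bandwidth", lower = 0,
               upper = 1, strict_lower = TRUE)
  check_number(sampling_rate, "sampling_rate", lower = 0, strict_lower = TRUE)
  check_number(pulse_amplitude, "pulse_amplitude")
  if (sampling_rate < 4 * center_frequency) {
    stop("sampling_rate must be at least 4 x center_frequency",
         call. = FALSE)
  }
  structure(
    list(center_frequency = center_frequency,
         fractional_bandwidth = fractional_bandwidth,
         sampling_rate = sampling_rate,
         pulse_amplitude = pulse_amplitude),
    class = "transducer_spec"
  )
}

#' @export
print.transducer_spec <- function(x, ...) {
  cat(sprintf(
    "<transducer_spec> f0 = %.1f MHz, bw = %.0f%%, fs = %.0f MHz, A = %g\n",
    x$center_frequency / 1e6, 100 * x$fractional_bandwidth,
    x$sampling_rate / 1e6, x$pulse_amplitude))
  invisible(x)
}

# Gaussian envelope time constant (s) of the Gabor pulse:
# amplitude spectrum exp(-(f - f0)^2 / (2 sf^2)) with
# 2 * sf * sqrt(2 log 2) = bw * f0  and  sigma_t = 1 / (2 pi sf).
gabor_sigma <- function(tx) {
  sqrt(2 * log(2)) / (pi * tx$fractional_bandwidth * tx$center_frequency)
}

# Gabor pulse sampled at times t (s), centred at 0.
gabor_pulse <- function(t, tx, amplitude = tx$pulse_amplitude) {
  s <- gabor_sigma(tx)
  amplitude * exp(-t^2 / (2 * s^2)) * cos(2 * pi * tx$center_frequency * t)
}

# Closed-form peak-to-peak amplitude of the Gabor pulse: maximum A at t = 0,
# minimum ~ -A * exp(-1 / (8 f0^2 sigma^2)) half a carrier period away.
gabor_peak_to_peak <- function(tx, amplitude = tx$pulse_amplitude) {
  s <- gabor_sigma(tx)
  abs(amplitude) * (1 + exp(-1 / (8 * tx$center_frequency^2 * s^2)))
}

# Pulse length (s): full width of the Gaussian envelope at 1/10 maximum.
gabor_pulse_length <- function(tx) {
  2 * gabor_sigma(tx) * sqrt(2 * log(10))
}

#' RF scan container
#'
#' Bundles a grid of RF A-lines with the acquisition metadata needed to
#' convert echo times into distances: sampling rate, sound speed in the
#' coupling medium (saline) and in cartilage. Samples are assumed to start
#' at time zero (transducer face).
#'
#' @param rf numeric matrix, one A-line per row (`m` lines x `n` samples),
#'   `n >= 64`.
#' @param positions numeric matrix `m x 2` of lateral line positions in mm.
#' @param sampling_rate sampling rate in Hz.
#' @param c_medium sound speed in the coupling medium, m/s.
#' @param c_cartilage sound speed in cartilage, m/s (NA for reference traces).
#' @param meta optional named list of extra metadata (e.g. simulation flags).
#' @return an object of class `"rf_scan"`.
#' @export
rf_scan <- function(rf, positions, sampling_rate, c_medium = 1520,
                    c_cartilage = NA_real_, meta = list()) {
  if (!is.matrix(rf)) rf <- matrix(rf, nrow = 1)
  if (!is.numeric(rf) || !all(is.finite(rf))) {
    stop("`rf` must be a finite numeric matrix", call. = FALSE)
  }
  if (nrow(rf) < 1 || ncol(rf) < 64) {
    stop("`rf` must have >= 1 line and >= 64 samples", call. = FALSE)
  }
  if (!is.matrix(positions)) positions <- matrix(positions, ncol = 2)
  if (nrow(positions) != nrow(rf) || ncol(positions) != 2) {
    stop("`positions` must be an m x 2 matrix matching `rf`", call. = FALSE)
  }
  check_number(sampling_rate, "sampling_rate", lower = 0, strict_lower = TRUE)
  check_number(c_medium, "c_medium", lower = 0, strict_lower = TRUE)
  structure(
    list(rf = rf, positions = positions, sampling_rate = sampling_rate,
         c_medium = c_medium, c_cartilage = c_cartilage, meta = meta),
    class = "rf_scan"
  )
}

#' @export
print.rf_scan <- function(x, ...) {
  cat(sprintf("<rf_scan> %d line(s) x %d samples @ %.0f MHz, c_medium = %g m/s\n",
              nrow(x$rf), ncol(x$rf), x$sampling_rate / 1e6, x$c_medium))
  invisible(x)
}

#' Simulate the perfect-reflector reference trace
#'
#' One noiseless A-line containing a single Gabor pulse returned from a flat
#' rigid target at the given standoff. Its peak-to-peak amplitude is the
#' reference `A_ref` against which reflection coefficients are expressed.
#'
#' @param tx a [transducer_spec()].
#' @param standoff_mm distance transducer to reflector, mm (default 10).
#' @param c_medium sound speed in the coupling medium, m/s (default 1520).
#' @param n_samples trace length; default is just past the echo plus a pulse
#'   margin, rounded up to a multiple of 32 (minimum 64).
#' @return an [rf_scan()] with a single line.
#' @examples
#' ref <- simulate_reference(transducer_spec())
#' max(ref$rf) - min(ref$rf)  # ~ A_ref
#' @export
simulate_reference <- function(tx, standoff_mm = 10, c_medium = 1520,
                               n_samples = NULL) {
  stopifnot(inherits(tx, "transducer_spec"))
  check_number(standoff_mm, "standoff_mm", lower = 0, strict_lower = TRUE)
  t_echo <- 2 * (standoff_mm * 1e-3) / c_medium
  if (is.null(n_samples)) {
    n_samples <- ceiling((t_echo + 10 * gabor_sigma(tx)) * tx$sampling_rate)
    n_samples <- max(64L, as.integer(32 * ceiling(n_samples / 32)))
  }
  t <- (seq_len(n_samples) - 1) / tx$sampling_rate
  line <- gabor_pulse(t - t_echo, tx)
  rf_scan(matrix(line, nrow = 1), matrix(c(0, 0), ncol = 2),
          sampling_rate = tx$sampling_rate, c_medium = c_medium,
          meta = list(kind = "reference", standoff_mm = standoff_mm))
}
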