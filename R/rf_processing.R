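#' Signal envelope via the analytic signal
#'
#' Magnitude of the analytic signal (Hilbert transform method): the FFT of
#' the line has its negative frequencies zeroed and positive frequencies
#' doubled; the modulus of the inverse transform is the envelope.
#'
#' @param x finite numeric vector, length >= 4.
#' @return nonnegative envelope vector of the same length.
#' @examples
#' t <- seq(0, 1, length.out = 256)
#' env <- envelope(sin(2 * pi * 32 * t))
#' range(env[32:224])  # ~ 1 over the burst interior
#' @export
envelope <- function(x) {
  if (!is.numeric(x) || length(x) < 4 || !all(is.finite(x))) {
    stop("`x` must be a finite numeric vector of length >= 4", call. = FALSE)
  }
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(fft(fft(x) * h, inverse = TRUE) / n)
}

#' Echo-detection configuration
#'
#' @param threshold_factor candidate peaks must exceed this multiple of the
#'   noise floor (median envelope over the leading noise window); default 4.
#' @param min_surface_frac additional absolute floor as a fraction of the
#'   reference envelope maximum (default 0.02).
#' @param noise_window number of leading samples used to estimate the noise
#'   floor; default `min(512, n %/% 8)` at run time.
#' @param surface_gate_s optional `c(min, max)` time gate (s) for the
#'   surface echo; default: everything after the noise window.
#' @param dead_time_s minimum delay between surface and interface echoes;
#'   default: one pulse length (reference envelope full width at 1/10
#'   maximum), so the surface tail is not read as the interface.
#' @param max_tof_s maximum surface-to-interface time-of-flight searched;
#'   default: to the end of the trace.
#' @param upsample integer band-limited upsampling factor used when reading
#'   peak-to-peak amplitudes off the raw RF (default 8; removes
#'   sampling-phase ripple at a few samples per carrier period).
#' @param band_frac out-of-band noise rejection: scan and reference lines
#'   are band-pass filtered to the frequency support where the reference
#'   amplitude spectrum exceeds this fraction of its maximum (default
#'   0.05). Identical filtering of echo and reference leaves amplitude
#'   ratios unchanged. Set 0 to disable.
#' @return an object of class `"detection_config"`.
#' @export
detection_config <- function(threshold_factor = 4, min_surface_frac = 0.02,
                             noise_window = NULL, surface_gate_s = NULL,
                             dead_time_s = NULL, max_tof_s = NULL,
                             upsample = 8, band_frac = 0.05) {
  check_number(threshold_factor, "threshold_factor", lower = 0)
  check_number(min_surface_frac, "min_surface_frac", lower = 0, upper = 1)
  if (!is.null(noise_window)) check_count(noise_window, "noise_window", 8L)
  if (!is.null(surface_gate_s)) {
    stopifnot(length(surface_gate_s) == 2, surface_gate_s[1] <
                surface_gate_s[2])
  }
  if (!is.null(dead_time_s)) check_number(dead_time_s, "dead_time_s",
                                          lower = 0)
  if (!is.null(max_tof_s)) check_number(max_tof_s, "max_tof_s", lower = 0,
                                        strict_lower = TRUE)
  upsample <- check_count(upsample, "upsample", 1L)
  check_number(band_frac, "band_frac", lower = 0, upper = 1)
  structure(
    list(threshold_factor = threshold_factor,
         min_surface_frac = min_surface_frac, noise_window = noise_window,
         surface_gate_s = surface_gate_s, dead_time_s = dead_time_s,
         max_tof_s = max_tof_s, upsample = upsample,
         band_frac = band_frac),
    class = "detection_config"
  )
}

# sub-sample refinement of an envelope peak by a log-parabolic fit (exact
# for a Gaussian envelope); returns the fractional index
refine_peak <- function(env, i) {
  n <- length(env)
  if (i <= 1 || i >= n) return(i)
  y <- env[(i - 1):(i + 1)]
  if (any(y <= 0)) return(i)
  ly <- log(y)
  den <- ly[1] - 2 * ly[2] + ly[3]
  if (den >= 0) return(i)
  i + 0.5 * (ly[1] - ly[3]) / den
}

# band-limited upsampling by zero-padding the FFT
upsample_fft <- function(x, k) {
  if (k <= 1) return(x)
  n <- length(x)
  X <- fft(x)
  m <- n * k
  Y <- complex(length.out = m)
  if (n %% 2 == 0) {
    half <- n / 2
    Y[seq_len(half)] <- X[seq_len(half)]
    Y[half + 1] <- X[half + 1] / 2        # split the Nyquist bin
    Y[m - half + 1] <- X[half + 1] / 2
    if (half >= 2) Y[(m - half + 2):m] <- X[(half + 2):n]
  } else {
    half <- (n - 1) / 2
    Y[seq_len(half + 1)] <- X[seq_len(half + 1)]
    if (half >= 1) Y[(m - half + 1):m] <- X[(half + 2):n]
  }
  Re(fft(Y, inverse = TRUE)) / n
}

# zero-phase band-pass by zeroing FFT bins outside [f1, f2] Hz
bandpass_fft <- function(x, f1, f2, fs) {
  n <- length(x)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)                  # fold to |frequency|
  X <- fft(x)
  X[f < f1 | f > f2] <- 0
  Re(fft(X, inverse = TRUE) / n)
}

# frequency support (Hz) where the reference amplitude spectrum exceeds
# frac of its maximum
reference_band <- function(ref_line, fs, frac) {
  n <- length(ref_line)
  spec <- Mod(fft(ref_line))[seq_len(floor(n / 2) + 1)]
  f <- (seq_along(spec) - 1) * fs / n
  keep <- which(spec >= frac * max(spec))
  c(f[min(keep)], f[max(keep)])
}

# peak-to-peak of raw RF within +/- pulse_len samples of index i,
# measured on a band-limited upsampled copy of the window
peak_to_peak <- function(rf_line, i, half_window, k) {
  lo <- max(1L, i - half_window)
  hi <- min(length(rf_line), i + half_window)
  seg <- rf_line[lo:hi]
  if (k > 1 && length(seg) >= 8) seg <- upsample_fft(seg, k)
  max(seg) - min(seg)
}

#' Detect surface and interface echoes on every A-line
#'
#' Per line, the surface echo is the first envelope local maximum above
#' threshold (4 x the noise floor estimated from the leading pre-surface
#' samples, and at least `min_surface_frac` of the reference envelope
#' maximum); the interface echo is the largest envelope maximum in the
#' window from one dead time after the surface up to the maximum
#' time-of-flight. Echo times are envelope peaks refined by log-parabolic
#' interpolation; amplitudes are the peak-to-peak of the raw RF within one
#' pulse length of the peak. Lines where detection fails are flagged
#' invalid and excluded downstream.
#'
#' @param scan an [rf_scan()] of the specimen.
#' @param ref an [rf_scan()] with the single perfect-reflector line;
#'   must share the scan's sampling rate.
#' @param cfg a [detection_config()].
#' @return an object of class `"echo_features"`: a data frame with one row
#'   per line (`d_um`, `tof_s`, `amp_surface`, `amp_interface`,
#'   `valid_surface`, `valid_interface`, echo times) and attributes
#'   `a_ref`, `pulse_length_s`, `c_medium`, `c_cartilage`,
#'   `n_invalid_surface`, `n_invalid_interface`.
#' @examples
#' tx <- transducer_spec()
#' sim <- simulate_rf_scan(cartilage_phantom_spec(n_lines = 4, seed = 1), tx)
#' feats <- detect_echoes(sim$scan, simulate_reference(tx))
#' feats$d_um
#' @export
detect_echoes <- function(scan, ref, cfg = detection_config()) {
  stopifnot(inherits(scan, "rf_scan"), inherits(ref, "rf_scan"),
            inherits(cfg, "detection_config"))
  if (!isTRUE(all.equal(scan$sampling_rate, ref$sampling_rate))) {
    stop("scan and reference must share the sampling rate", call. = FALSE)
  }
  fs <- scan$sampling_rate

  ref_line <- ref$rf[1, ]
  band <- NULL
  if (cfg$band_frac > 0 && any(ref_line != 0)) {
    band <- reference_band(ref_line, fs, cfg$band_frac)
    ref_line <- bandpass_fft(ref_line, band[1], band[2], fs)
  }
  ref_env <- envelope(ref_line)
  ref_peak <- which.max(ref_env)
  if (max(ref_env) <= 0) stop("reference amplitude is zero", call. = FALSE)
  # contiguous run around the reference peak above 1/10 of the maximum
  # defines the pulse length
  above <- ref_env >= max(ref_env) / 10
  lo <- ref_peak
  while (lo > 1 && above[lo - 1]) lo <- lo - 1
  hi <- ref_peak
  while (hi < length(above) && above[hi + 1]) hi <- hi + 1
  pulse_samples <- max(3L, hi - lo + 1L)
  pulse_length_s <- pulse_samples / fs
  a_ref <- peak_to_peak(ref_line, ref_peak, pulse_samples, cfg$upsample)
  if (a_ref <= 0) stop("reference peak-to-peak amplitude is zero",
                       call. = FALSE)

  n <- ncol(scan$rf)
  m <- nrow(scan$rf)
  nw <- if (is.null(cfg$noise_window)) min(512L, n %/% 8L) else
    min(cfg$noise_window, n %/% 2L)
  dead <- if (is.null(cfg$dead_time_s)) pulse_length_s else cfg$dead_time_s
  dead_samp <- round(dead * fs)

  out <- data.frame(
    line = seq_len(m),
    x_mm = scan$positions[, 1], y_mm = scan$positions[, 2],
    t_surface_s = NA_real_, d_um = NA_real_, amp_surface = NA_real_,
    t_interface_s = NA_real_, tof_s = NA_real_, amp_interface = NA_real_,
    valid_surface = FALSE, valid_interface = FALSE
  )

  for (i in seq_len(m)) {
    line <- scan$rf[i, ]
    if (!is.null(band)) line <- bandpass_fft(line, band[1], band[2], fs)
    env <- envelope(line)
    noise_floor <- median(env[seq_len(nw)])
    thr <- max(cfg$threshold_factor * noise_floor,
               cfg$min_surface_frac * max(ref_env))
    gate <- if (is.null(cfg$surface_gate_s)) c(nw + 1L, n) else
      pmax(1L, pmin(n, round(cfg$surface_gate_s * fs) + 1L))
    # surface echo: first threshold crossing in the gate, localized as the
    # envelope maximum within one pulse length of the crossing (robust to
    # noise micro-maxima on the rising flank)
    in_gate <- gate[1]:gate[2]
    cross <- in_gate[which(env[in_gate] > thr)[1]]
    if (is.na(cross)) next
    seg <- cross:min(n, cross + pulse_samples)
    ps <- seg[which.max(env[seg])]
    ts <- (refine_peak(env, ps) - 1) / fs
    out$t_surface_s[i] <- ts
    out$d_um[i] <- scan$c_medium * ts / 2 * 1e6
    out$amp_surface[i] <- peak_to_peak(line, ps, pulse_samples, cfg$upsample)
    out$valid_surface[i] <- TRUE

    w_lo <- ps + dead_samp
    w_hi <- if (is.null(cfg$max_tof_s)) n else
      min(n, ps + round(cfg$max_tof_s * fs))
    if (w_lo + 1L > w_hi) next
    win <- (w_lo + 1L):w_hi
    pi_ <- win[which.max(env[win])]
    if (env[pi_] <= thr) next
    ti <- (refine_peak(env, pi_) - 1) / fs
    out$t_interface_s[i] <- ti
    out$tof_s[i] <- ti - ts
    out$amp_interface[i] <- peak_to_peak(line, pi_, pulse_samples,
                                         cfg$upsample)
    out$valid_interface[i] <- TRUE
  }

  n_bad_s <- sum(!out$valid_surface)
  n_bad_i <- sum(!out$valid_interface)
  if (n_bad_s > m / 2) {
    stop(sprintf("echo detection failed on %d of %d lines", n_bad_s, m),
         call. = FALSE)
  }
  structure(out,
            class = c("echo_features", "data.frame"),
            a_ref = a_ref, pulse_length_s = pulse_length_s,
            sampling_rate = fs, c_medium = scan$c_medium,
            c_cartilage = scan$c_cartilage,
            n_invalid_surface = n_bad_s, n_invalid_interface = n_bad_i)
}

#' @export
print.echo_features <- function(x, ...) {
  cat(sprintf(
    "<echo_features> %d lines (%d surface-valid, %d interface-valid), A_ref = %.4g\n",
    nrow(x), sum(x$valid_surface), sum(x$valid_interface), attr(x, "a_ref")))
  NextMethod()
}
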