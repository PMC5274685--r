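#' Cartilage phantom specification
#'
#' Parameters of the two-interface cartilage phantom scanned by the RF
#' simulator: a saline--cartilage surface whose local standoff varies from
#' line to line (surface roughness) and a cartilage--subchondral-bone
#' interface one cartilage thickness deeper. Amplitudes are expressed as
#' pressure-reflection coefficients relative to a perfect reflector.
#'
#' Defaults emulate a 100-line raster over a 0.3 mm x 0.3 mm region of
#' intact articular cartilage: a smooth surface (roughness SD 5 um), a thin
#' cartilage layer (0.30 mm), a weak surface reflection (r = 0.10) and a
#' stronger bone interface (r = 0.30) attenuated on the round trip through
#' cartilage (2 dB/cm/MHz at the carrier frequency).
#'
#' @param n_lines number of A-lines (default 100, scanned as a near-square
#'   raster over the region of interest).
#' @param roi_extent lateral scan extent, mm x mm (default `c(0.3, 0.3)`).
#' @param standoff_mean mean transducer-to-surface distance, mm (default 10).
#' @param surface_roughness_sd SD of the per-line surface distance, um.
#' @param thickness_mean mean cartilage thickness, mm.
#' @param thickness_sd SD of the per-line local thickness, um.
#' @param r_surface surface pressure-reflection coefficient in \[0, 1\].
#' @param r_interface cartilage-bone interface reflection coefficient in
#'   \[0, 1\].
#' @param attenuation cartilage attenuation, dB cm^-1 MHz^-1, applied at the
#'   carrier frequency on the round trip through the layer.
#' @param c_medium sound speed in saline, m/s (default 1520).
#' @param c_cartilage sound speed in cartilage, m/s (default 1675).
#' @param noise_sd additive white-noise SD as a fraction of the reference
#'   peak-to-peak amplitude (default 0.002, an averaged acquisition).
#' @param seed integer seed for reproducible draws, or `NULL`.
#' @return an object of class `"cartilage_phantom_spec"`.
#' @export
cartilage_phantom_spec <- function(n_lines = 100,
                                   roi_extent = c(0.3, 0.3),
                                   standoff_mean = 10,
                                   surface_roughness_sd = 5,
                                   thickness_mean = 0.30,
                                   thickness_sd = 15,
                                   r_surface = 0.10,
                                   r_interface = 0.30,
                                   attenuation = 2,
                                   c_medium = 1520,
                                   c_cartilage = 1675,
                                   noise_sd = 0.002,
                                   seed = NULL) {
  n_lines <- check_count(n_lines, "n_lines", lower = 1L)
  stopifnot(length(roi_extent) == 2, all(roi_extent > 0))
  check_number(standoff_mean, "standoff_mean", lower = 0, strict_lower = TRUE)
  check_number(surface_roughness_sd, "surface_roughness_sd", lower = 0)
  check_number(thickness_mean, "thickness_mean", lower = 0,
               strict_lower = TRUE)
  check_number(thickness_sd, "thickness_sd", lower = 0)
  check_number(r_surface, "r_surface", lower = 0, upper = 1)
  check_number(r_interface, "r_interface", lower = 0, upper = 1)
  check_number(attenuation, "attenuation", lower = 0)
  check_number(c_medium, "c_medium", lower = 0, strict_lower = TRUE)
  check_number(c_cartilage, "c_cartilage", lower = 0, strict_lower = TRUE)
  check_number(noise_sd, "noise_sd", lower = 0)
  structure(
    list(n_lines = n_lines, roi_extent = roi_extent,
         standoff_mean = standoff_mean,
         surface_roughness_sd = surface_roughness_sd,
         thickness_mean = thickness_mean, thickness_sd = thickness_sd,
         r_surface = r_surface, r_interface = r_interface,
         attenuation = attenuation, c_medium = c_medium,
         c_cartilage = c_cartilage, noise_sd = noise_sd, seed = seed),
    class = "cartilage_phantom_spec"
  )
}

# near-square raster of n points over roi_extent (mm), centred on 0
raster_positions <- function(n, roi_extent) {
  nx <- ceiling(sqrt(n))
  ny <- ceiling(n / nx)
  gx <- if (nx > 1) seq(-roi_extent[1] / 2, roi_extent[1] / 2,
                        length.out = nx) else 0
  gy <- if (ny > 1) seq(-roi_extent[2] / 2, roi_extent[2] / 2,
                        length.out = ny) else 0
  g <- expand.grid(x = gx, y = gy)
  m <- as.matrix(g[seq_len(n), , drop = FALSE])
  dimnames(m) <- NULL
  m
}

# per-line latent truths of the phantom; used by simulate_rf_scan and by
# distributional tests of the generator
draw_phantom_truth <- function(p) {
  d_um <- rnorm(p$n_lines, p$standoff_mean * 1000, p$surface_roughness_sd)
  h_mm <- rnorm(p$n_lines, p$thickness_mean, p$thickness_sd / 1000)
  redraws <- 0L
  while (any(bad <- h_mm <= 0)) {
    redraws <- redraws + sum(bad)
    h_mm[bad] <- rnorm(sum(bad), p$thickness_mean, p$thickness_sd / 1000)
  }
  list(d_um = d_um, h_mm = h_mm, redraws = redraws)
}

#' Simulate an RF scan of the cartilage phantom
#'
#' For each line `i` the surface distance `d_i` and local thickness `h_i`
#' are drawn from the phantom's Normal laws (non-positive thickness draws
#' are redrawn and counted). The line is the sum of a surface echo at delay
#' `2 d_i / c_medium` with amplitude `r_surface * A_ref`, an interface echo
#' an additional `2 h_i / c_cartilage` later with amplitude
#' `r_interface * (1 - r_surface^2) * A_ref` reduced by the round-trip
#' attenuation at the carrier frequency, and white Gaussian noise.
#'
#' @param p a [cartilage_phantom_spec()].
#' @param tx a [transducer_spec()].
#' @return a list with components `scan` (an [rf_scan()]; its `meta` records
#'   the overlap warning flag and the thickness redraw count) and `truth`
#'   (class `"ground_truth"`: per-line `d_um`, `h_mm` and amplitude ratios,
#'   plus the scalar parameter values they imply).
#' @examples
#' sim <- simulate_rf_scan(cartilage_phantom_spec(seed = 1), transducer_spec())
#' sim$truth$uri_um  # realized surface roughness
#' @export
simulate_rf_scan <- function(p, tx) {
  stopifnot(inherits(p, "cartilage_phantom_spec"),
            inherits(tx, "transducer_spec"))
  with_seed(p$seed, {
    truth <- draw_phantom_truth(p)
    t_surf <- 2 * (truth$d_um * 1e-6) / p$c_medium
    t_intf <- t_surf + 2 * (truth$h_mm * 1e-3) / p$c_cartilage

    a_ref <- gabor_peak_to_peak(tx)
    # round-trip attenuation at f0: alpha [dB/cm/MHz] * 2h [cm] * f0 [MHz]
    atten_db <- p$attenuation * 2 * (truth$h_mm / 10) *
      (tx$center_frequency / 1e6)
    ratio_surf <- rep(p$r_surface, p$n_lines)
    ratio_intf <- p$r_interface * (1 - p$r_surface^2) * 10^(-atten_db / 20)

    sigma <- gabor_sigma(tx)
    n_samples <- ceiling((max(t_intf) + 10 * sigma) * tx$sampling_rate)
    n_samples <- max(64L, as.integer(32 * ceiling(n_samples / 32)))
    t <- (seq_len(n_samples) - 1) / tx$sampling_rate

    rf <- matrix(0, nrow = p$n_lines, ncol = n_samples)
    for (i in seq_len(p$n_lines)) {
      rf[i, ] <- gabor_pulse(t - t_surf[i], tx, ratio_surf[i] *
                               tx$pulse_amplitude) +
        gabor_pulse(t - t_intf[i], tx, ratio_intf[i] * tx$pulse_amplitude)
    }
    if (p$noise_sd > 0) {
      rf <- rf + matrix(rnorm(length(rf), 0, p$noise_sd * a_ref),
                        nrow = p$n_lines)
    }

    overlap <- any(t_intf - t_surf < gabor_pulse_length(tx))
    if (overlap) {
      warning("surface and interface echoes overlap within one pulse length",
              call. = FALSE)
    }

    gt <- structure(
      list(d_um = truth$d_um, h_mm = truth$h_mm,
           ratio_surface = ratio_surf, ratio_interface = ratio_intf,
           uri_um = sqrt(mean((truth$d_um - mean(truth$d_um))^2)),
           rc1_pct = 100 * p$r_surface,
           rc2_pct = 100 * mean(ratio_intf),
           h_mm_mean = mean(truth$h_mm),
           thickness_redraws = truth$redraws),
      class = "ground_truth"
    )
    scan <- rf_scan(rf, raster_positions(p$n_lines, p$roi_extent),
                    sampling_rate = tx$sampling_rate, c_medium = p$c_medium,
                    c_cartilage = p$c_cartilage,
                    meta = list(kind = "cartilage_phantom",
                                overlap_warning = overlap,
                                thickness_redraws = truth$redraws,
                                seed = p$seed))
    list(scan = scan, truth = gt)
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "<ground_truth> %d lines: URI %.2f um, RC1 %.1f%%, RC2 %.1f%%, h %.3f mm\n",
    length(x$d_um), x$uri_um, x$rc1_pct, x$rc2_pct, x$h_mm_mean))
  invisible(x)
}
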