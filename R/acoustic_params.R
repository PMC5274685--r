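#' Ultrasound roughness index (URI)
#'
#' Population standard deviation of the per-line transducer-to-surface
#' distances:
#' `URI = sqrt( (1/m) * sum_i (d_i - mean(d))^2 )`,
#' with `m` the number of valid lines. The population (1/m) normalization is
#' used, not 1/(m-1).
#'
#' @param d_um numeric vector of valid surface distances, um. Non-finite
#'   entries are dropped with a message.
#' @return URI in um.
#' @examples
#' compute_uri(c(10, 12, 14))  # sqrt(8/3)
#' @export
compute_uri <- function(d_um) {
  d_um <- drop_invalid(d_um, "d_um")
  if (length(d_um) < 2) {
    stop("URI needs at least 2 valid surface distances", call. = FALSE)
  }
  sqrt(mean((d_um - mean(d_um))^2))
}

#' Surface reflection coefficient (RC1)
#'
#' Mean per-line peak-to-peak surface-echo amplitude as a percentage of the
#' perfect-reflector amplitude: `RC1 = (1/m) * sum_i (A_i / A_ref) * 100`.
#'
#' @param a numeric vector of valid surface-echo peak-to-peak amplitudes.
#' @param a_ref reference (perfect reflector) peak-to-peak amplitude, > 0.
#' @return RC1 in percent.
#' @examples
#' compute_rc1(c(0.2, 0.4), 1)  # 30
#' @export
compute_rc1 <- function(a, a_ref) {
  check_number(a_ref, "a_ref", lower = 0, strict_lower = TRUE)
  a <- drop_invalid(a, "a")
  if (length(a) < 1) stop("RC1 needs at least 1 valid amplitude",
                          call. = FALSE)
  mean(a / a_ref) * 100
}

#' Cartilage-bone interface reflection coefficient (RC2)
#'
#' Same form as [compute_rc1()] applied to the interface-echo amplitudes.
#' No attenuation or transmission correction is applied: RC2 is the
#' uncorrected apparent reflection at the interface, so with attenuating
#' cartilage it underestimates the true interface reflectivity by design.
#'
#' @inheritParams compute_rc1
#' @param a numeric vector of valid interface-echo peak-to-peak amplitudes.
#' @return RC2 in percent.
#' @export
compute_rc2 <- function(a, a_ref) {
  compute_rc1(a, a_ref)
}

#' Mean cartilage thickness from time-of-flight
#'
#' `h = (1/m) * sum_i c_cartilage * TOF_i / 2`, the per-line thickness
#' averaged over valid lines, using an assumed constant sound speed in
#' cartilage.
#'
#' @param tof_s numeric vector of valid surface-to-interface
#'   times-of-flight, s. All valid values must be positive.
#' @param c_cartilage sound speed in cartilage, m/s (default 1675).
#' @return thickness in mm.
#' @examples
#' compute_thickness(2e-6, 1675)  # 1.675 mm
#' @export
compute_thickness <- function(tof_s, c_cartilage = 1675) {
  check_number(c_cartilage, "c_cartilage", lower = 0, strict_lower = TRUE)
  tof_s <- drop_invalid(tof_s, "tof_s")
  if (length(tof_s) < 1) stop("thickness needs at least 1 valid TOF",
                              call. = FALSE)
  if (any(tof_s <= 0)) {
    stop("non-positive TOF among valid lines", call. = FALSE)
  }
  mean(c_cartilage * tof_s / 2) * 1e3
}

drop_invalid <- function(x, name) {
  if (!is.numeric(x)) stop(sprintf("`%s` must be numeric", name),
                           call. = FALSE)
  bad <- !is.finite(x)
  if (any(bad)) {
    message(sprintf("dropping %d non-finite value(s) from `%s`", sum(bad),
                    name))
  }
  x[!bad]
}

#' Acoustic parameter panel from detected echoes
#'
#' Applies [compute_uri()], [compute_rc1()], [compute_rc2()] and
#' [compute_thickness()] to the valid lines of an `echo_features` table.
#' The effective `m` of each formula is the number of lines valid for that
#' echo, so the surface and interface counts may differ.
#'
#' @param features an `echo_features` object from [detect_echoes()].
#' @param c_cartilage sound speed used for thickness, m/s; default: the
#'   value recorded in the scan metadata, falling back to 1675.
#' @return a one-row data frame of class `"acoustic_params"` with columns
#'   `URI_um`, `RC1_pct`, `RC2_pct`, `h_mm`, `m_valid_surface`,
#'   `m_valid_interface`.
#' @export
acoustic_params <- function(features, c_cartilage = NULL) {
  stopifnot(inherits(features, "echo_features"))
  if (is.null(c_cartilage)) {
    c_cartilage <- attr(features, "c_cartilage")
    if (is.null(c_cartilage) || !is.finite(c_cartilage)) c_cartilage <- 1675
  }
  a_ref <- attr(features, "a_ref")
  s <- features$valid_surface
  j <- features$valid_interface
  res <- data.frame(
    URI_um = compute_uri(features$d_um[s]),
    RC1_pct = compute_rc1(features$amp_surface[s], a_ref),
    RC2_pct = if (any(j)) compute_rc2(features$amp_interface[j], a_ref)
              else NA_real_,
    h_mm = if (any(j)) compute_thickness(features$tof_s[j], c_cartilage)
           else NA_real_,
    m_valid_surface = sum(s),
    m_valid_interface = sum(j)
  )
  class(res) <- c("acoustic_params", "data.frame")
  res
}
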