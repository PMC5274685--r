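test_that("envelope handles degenerate and analytic inputs", {
  expect_identical(envelope(numeric(64)), numeric(64))
  expect_error(envelope(c(1, NA, 3, 4)), "finite")
  expect_error(envelope(c(1, 2)), "length")
  # pure cosine burst: envelope ~ amplitude over the interior
  t <- seq(0, 1, length.out = 512)
  x <- 0.7 * cos(2 * pi * 50 * t)
  env <- envelope(x)
  expect_equal(mean(env[100:400]), 0.7, tolerance = 1e-3)
})

test_that("envelope of a Gabor pulse peaks at the pulse centre", {
  tx <- default_tx()
  fs <- tx$sampling_rate
  t <- (0:1023) / fs
  center <- 512 / fs
  line <- cartiqus:::gabor_pulse(t - center, tx)
  env <- envelope(line)
  expect_lte(abs(which.max(env) - 513), 1)
})

test_that("noiseless echoes are localized to within one sample of truth", {
  tx <- default_tx()
  p <- cartilage_phantom_spec(n_lines = 25, noise_sd = 0, seed = 2)
  sim <- simulate_rf_scan(p, tx)
  ref <- simulate_reference(tx)
  feats <- detect_echoes(sim$scan, ref)
  expect_true(all(feats$valid_surface), all(feats$valid_interface))
  # one sample period <-> 1.9 um in saline, 2.1 um in cartilage
  d_tol_um <- p$c_medium / tx$sampling_rate / 2 * 1e6
  expect_lt(max(abs(feats$d_um - sim$truth$d_um)), d_tol_um)
  tof_true <- 2 * (sim$truth$h_mm * 1e-3) / p$c_cartilage
  expect_lt(max(abs(feats$tof_s - tof_true)), 1 / tx$sampling_rate)
})

test_that("amplitude ratios recover configured reflectivities", {
  tx <- default_tx()
  # attenuation off and transmission-corrected r_interface so that the
  # interface echo is exactly 5% of the reference
  p <- cartilage_phantom_spec(n_lines = 16, noise_sd = 0, attenuation = 0,
                              r_surface = 0.1,
                              r_interface = 0.05 / (1 - 0.1^2), seed = 4)
  sim <- simulate_rf_scan(p, tx)
  feats <- detect_echoes(sim$scan, simulate_reference(tx))
  a_ref <- attr(feats, "a_ref")
  expect_equal(mean(feats$amp_surface) / a_ref, 0.10, tolerance = 0.01)
  expect_equal(mean(feats$amp_interface) / a_ref, 0.05, tolerance = 0.01)
})

test_that("an all-noise line is flagged invalid without an exception", {
  tx <- default_tx()
  sim <- simulate_rf_scan(fast_phantom(n_lines = 9, seed = 6), tx)
  rf <- sim$scan$rf
  set.seed(1)
  rf[5, ] <- rnorm(ncol(rf), 0, 1e-4)
  scan <- rf_scan(rf, sim$scan$positions, sim$scan$sampling_rate,
                  sim$scan$c_medium, sim$scan$c_cartilage)
  feats <- detect_echoes(scan, simulate_reference(tx, standoff_mm = 2))
  expect_false(feats$valid_surface[5])
  expect_true(all(feats$valid_surface[-5]))
  expect_identical(attr(feats, "n_invalid_surface"), 1L)
})

test_that("detection fails hard when most lines are invalid", {
  tx <- default_tx()
  set.seed(8)
  rf <- matrix(rnorm(4 * 2048, 0, 1e-4), nrow = 4)
  scan <- rf_scan(rf, matrix(0, 4, 2), tx$sampling_rate)
  ref <- simulate_reference(tx, standoff_mm = 2)
  expect_error(detect_echoes(scan, ref), "failed on")
})

test_that("a zero reference is rejected", {
  tx <- default_tx()
  sim <- simulate_rf_scan(fast_phantom(n_lines = 4, seed = 9), tx)
  zero_ref <- rf_scan(matrix(0, 1, 512), matrix(0, 1, 2), tx$sampling_rate)
  expect_error(detect_echoes(sim$scan, zero_ref), "reference")
})

test_that("amplitude ratios and geometry are scale-invariant", {
  tx <- default_tx()
  sim <- simulate_rf_scan(fast_phantom(n_lines = 9, seed = 10), tx)
  ref <- simulate_reference(tx, standoff_mm = 2)
  f1 <- detect_echoes(sim$scan, ref)
  scan2 <- sim$scan
  scan2$rf <- scan2$rf * 37.5
  ref2 <- ref
  ref2$rf <- ref2$rf * 37.5
  f2 <- detect_echoes(scan2, ref2)
  expect_equal(f2$amp_surface / attr(f2, "a_ref"),
               f1$amp_surface / attr(f1, "a_ref"), tolerance = 1e-12)
  expect_equal(f2$d_um, f1$d_um, tolerance = 1e-12)
  expect_equal(f2$tof_s, f1$tof_s, tolerance = 1e-12)
})

test_that("delaying a line shifts detected times by exactly k samples", {
  tx <- default_tx()
  # noiseless: truncating the trace tail to insert the delay must not
  # perturb the band-filtered waveform
  sim <- simulate_rf_scan(fast_phantom(n_lines = 4, noise_sd = 0, seed = 11),
                          tx)
  ref <- simulate_reference(tx, standoff_mm = 2)
  f1 <- detect_echoes(sim$scan, ref)
  k <- 40L
  n <- ncol(sim$scan$rf)
  scan2 <- sim$scan
  scan2$rf <- cbind(matrix(0, nrow(scan2$rf), k),
                    scan2$rf[, seq_len(n - k), drop = FALSE])
  f2 <- detect_echoes(scan2, ref)
  expect_equal(f2$t_surface_s, f1$t_surface_s + k / tx$sampling_rate,
               tolerance = 1e-9)
  expect_equal(f2$tof_s, f1$tof_s, tolerance = 1e-9)
})
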