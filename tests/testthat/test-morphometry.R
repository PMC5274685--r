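plate_vol <- function(t = 5, p = 25, d = c(50, 50, 50)) {
  generate_trabecular_phantom(trabecular_phantom_spec(
    "parallel_plates", volume_shape = d,
    geometry = list(thickness_vox = t, period_vox = p)))
}

test_that("BV/TV is exact voxel counting", {
  solid <- generate_trabecular_phantom(
    trabecular_phantom_spec("solid", volume_shape = c(8, 8, 8)))
  expect_identical(compute_bvtv(solid), 1)
  half <- trabecular_volume(digital_slab_z(16, 1, 8))
  expect_identical(compute_bvtv(half), 0.5)
  expect_identical(compute_bvtv(plate_vol()), 0.2)
})

test_that("an explicit VOI mask restricts BV/TV", {
  arr <- digital_slab_z(16, 1, 8)
  mask <- array(FALSE, dim = c(16, 16, 16))
  mask[, , 1:8] <- TRUE                 # VOI entirely inside the slab
  expect_identical(compute_bvtv(trabecular_volume(arr, mask = mask)), 1)
})

test_that("local thickness recovers analytic phantom values within a voxel", {
  v <- plate_vol()
  expect_lte(abs(compute_local_thickness(v, "foreground") / 0.012 - 5),
             1 + 1e-9)
  expect_lte(abs(compute_local_thickness(v, "background") / 0.012 - 20), 1)
  slab <- trabecular_volume(digital_slab_z(32, 11, 20))
  expect_lte(abs(compute_local_thickness(slab, "foreground") / 0.012 - 10), 1)
  cyl <- trabecular_volume(digital_cylinder_z(48, 16, 10.3))
  expect_lte(abs(compute_local_thickness(cyl, "foreground") / 0.012 - 20.6),
             1)
})

test_that("thickness of an empty or space-filling phase is rejected", {
  solid <- generate_trabecular_phantom(
    trabecular_phantom_spec("solid", volume_shape = c(8, 8, 8)))
  expect_error(compute_local_thickness(solid, "background"), "empty")
  expect_error(compute_local_thickness(solid, "foreground"), "fills")
})

test_that("Tb.N approximates the inverse plate period and scales with it", {
  v25 <- plate_vol(t = 5, p = 25, d = c(50, 50, 50))
  expect_equal(compute_tbn(v25), 1 / (25 * 0.012), tolerance = 0.05)
  v50 <- plate_vol(t = 5, p = 50, d = c(50, 50, 100))
  expect_equal(compute_tbn(v50) / compute_tbn(v25), 0.5, tolerance = 0.1)
  # plate-model variant is BV/TV over the measured plate thickness
  expect_equal(compute_tbn(v25, method = "plate"),
               compute_bvtv(v25) /
                 compute_local_thickness(v25, "foreground"))
})

test_that("Euler characteristic matches hand counts and the set oracle", {
  a <- array(FALSE, c(3, 3, 3)); a[2, 2, 2] <- TRUE
  expect_identical(euler_characteristic(a), 1L)
  b <- array(FALSE, c(4, 4, 4)); b[2, 2, 2] <- TRUE; b[3, 3, 3] <- TRUE
  expect_identical(euler_characteristic(b), 1L)   # corner touch, 26-conn
  torus <- generate_trabecular_phantom(trabecular_phantom_spec(
    "torus", volume_shape = c(32, 32, 16),
    geometry = list(major_vox = 9, minor_vox = 3)))
  expect_identical(euler_characteristic(torus$voxels), 0L)
  for (s in 1:5) {
    set.seed(s)
    r <- array(stats::runif(8^3) > 0.7, dim = c(8, 8, 8))
    expect_identical(euler_characteristic(r), as.integer(oracle_euler(r)))
  }
})

test_that("connectivity density counts independent loops per volume", {
  solid <- generate_trabecular_phantom(
    trabecular_phantom_spec("solid", volume_shape = c(8, 8, 8)))
  expect_identical(compute_connd(solid), 0)
  torus <- generate_trabecular_phantom(trabecular_phantom_spec(
    "torus", volume_shape = c(64, 64, 64),
    geometry = list(major_vox = 16, minor_vox = 6)))
  expect_equal(compute_connd(torus), 1 / (64^3 * 0.012^3))
  # cubic rod lattice: nl lines per axis -> beta1 = E - V + 1 on the
  # intersection graph
  lattice <- generate_trabecular_phantom(trabecular_phantom_spec(
    "rod_lattice", volume_shape = c(48, 48, 48),
    geometry = list(radius_vox = 2.5, cell_vox = 16)))
  nl <- 3
  beta1 <- 3 * nl^2 * (nl - 1) - nl^3 + 1
  expect_equal(compute_connd(lattice), beta1 / (48^3 * 0.012^3))
})

test_that("enclosed cavities do not masquerade as connectivity", {
  a <- array(TRUE, c(8, 8, 8))
  a[4:5, 4:5, 4:5] <- FALSE             # sealed cavity: beta2 = 1
  expect_identical(compute_connd(trabecular_volume(a)), 0)
})

test_that("multiple components fall back to the largest with a message", {
  a <- array(FALSE, c(12, 12, 12))
  a[2:5, 2:5, 2:5] <- TRUE
  a[8:10, 8:10, 8:10] <- TRUE
  expect_message(val <- compute_connd(trabecular_volume(a)), "largest")
  expect_identical(val, 0)
})

test_that("SMI discriminates plate, rod and sphere", {
  expect_lt(abs(compute_smi(trabecular_volume(digital_sphere(64, 20))) - 4),
            0.3)
  expect_lt(abs(compute_smi(trabecular_volume(
    digital_cylinder_z(64, 64, 10))) - 3), 0.3)
  plate <- array(FALSE, c(64, 64, 64)); plate[, , 29:36] <- TRUE
  expect_lt(abs(compute_smi(trabecular_volume(plate))), 0.3)
  solid <- array(TRUE, c(8, 8, 8))
  expect_error(compute_smi(trabecular_volume(solid)), "interface")
})

test_that("SMI increases monotonically along a plate-to-rod morph", {
  widths <- c(64, 32, 16, 8)
  smi <- vapply(widths, function(w) {
    compute_smi(trabecular_volume(digital_box_rod_x(64, w, 8)))
  }, numeric(1))
  expect_true(all(diff(smi) > 0))
  expect_lt(smi[1], 0.3)                # full-width slab is a plate
})

test_that("the full panel runs and respects its invariants", {
  v <- generate_trabecular_phantom(trabecular_phantom_spec(
    "rod_lattice", volume_shape = c(48, 48, 48),
    geometry = list(radius_vox = 2.5, cell_vox = 16,
                    offset_vox = c(0.2, -0.3, 0.1))))
  res <- compute_morphometry(v)
  expect_true(res$BV_TV > 0 && res$BV_TV < 1)
  expect_gt(res$Tb_Th, 0)
  expect_gt(res$Tb_Sp, res$Tb_Th)       # sparse lattice
  expect_gt(res$Conn_D, 0)
  expect_gt(res$SMI, 2)                 # rod-like structure
  expect_equal(res$Tb_N, 1 / (res$Tb_Th + res$Tb_Sp))
})

test_that("phantom geometry that exceeds the volume is rejected", {
  expect_error(generate_trabecular_phantom(trabecular_phantom_spec(
    "parallel_plates", volume_shape = c(16, 16, 16),
    geometry = list(thickness_vox = 5, period_vox = 20))), "exceeds")
  expect_error(generate_trabecular_phantom(trabecular_phantom_spec(
    "torus", volume_shape = c(16, 16, 16),
    geometry = list(major_vox = 9, minor_vox = 3))), "exceeds")
  expect_error(generate_trabecular_phantom(trabecular_phantom_spec(
    "rod_lattice", volume_shape = c(16, 16, 16),
    geometry = list(radius_vox = 5, cell_vox = 9))), "exceeds")
})
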