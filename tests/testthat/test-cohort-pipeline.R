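# small-but-complete study configuration used to keep end-to-end tests fast:
# short standoff (2 mm), 16 lines per scan, 32^3 bone volumes
small_config <- function(seed = 1, n_per_group = 3, ...) {
  pipeline_config(
    cohort = cohort_spec(
      n_per_group = n_per_group,
      sites = list(MTP = fast_phantom(n_lines = 16),
                   LTP = fast_phantom(n_lines = 16,
                                      thickness_mean = 0.28)),
      bone = trabecular_phantom_spec(
        "rod_lattice", volume_shape = c(32, 32, 32),
        geometry = list(radius_vox = 2.5, cell_vox = 16))),
    seed = seed, ...)
}

test_that("a cohort has the right shape and is reproducible", {
  cs <- cohort_spec(n_per_group = 7)
  cs_small <- cohort_spec(
    n_per_group = 2,
    sites = list(MTP = fast_phantom(n_lines = 9)),
    ovx_effects = list(MTP = c(surface_roughness_sd = 3),
                       bone = c(radius_vox = 1)),
    bone = trabecular_phantom_spec(
      "rod_lattice", volume_shape = c(32, 32, 32),
      geometry = list(radius_vox = 2.5, cell_vox = 16)),
    seed = 5)
  co <- generate_cohort(cs_small)
  expect_identical(nrow(co$manifest), 4L)
  expect_identical(sort(unique(co$manifest$group)), c("OVX", "sham"))
  co2 <- generate_cohort(cs_small)
  expect_identical(co$specimens$S01$sites$MTP$scan$rf,
                   co2$specimens$S01$sites$MTP$scan$rf)
  expect_identical(co$specimens$S03$volume$voxels,
                   co2$specimens$S03$volume$voxels)
  # default study size: 14 specimens
  expect_identical(2L * cs$n_per_group, 14L)
})

test_that("unit multipliers leave both groups identically distributed", {
  cs <- cohort_spec(
    ovx_effects = list(MTP = c(surface_roughness_sd = 1),
                       LTP = c(surface_roughness_sd = 1),
                       bone = c(radius_vox = 1)),
    animal_cv = c(surface_roughness_sd = 0, r_surface = 0,
                  thickness_mean = 0, r_interface = 0, radius_vox = 0),
    seed = 6)
  set.seed(6)
  lat <- cartiqus:::draw_cohort_parameters(cs)
  tab <- lat$sites$MTP
  for (p in c("surface_roughness_sd", "r_surface", "thickness_mean")) {
    expect_identical(tab[[p]][tab$group == "sham"],
                     tab[[p]][tab$group == "OVX"])
  }
})

test_that("the end-to-end pipeline recovers thickness and reflectivity", {
  # per-specimen relative recovery error, averaged over several seeded
  # cohorts, must stay below 2% for h (vs realized mean thickness) and for
  # RC1 (vs configured r_surface * 100)
  tx <- default_tx()
  h_err <- c()
  rc1_err <- c()
  for (seed in 1:6) {
    cs <- cohort_spec(
      n_per_group = 2,
      sites = list(MTP = fast_phantom(n_lines = 25)),
      ovx_effects = list(MTP = c(thickness_mean = 0.7, r_surface = 0.6),
                         bone = c(radius_vox = 1)),
      bone = trabecular_phantom_spec(
        "rod_lattice", volume_shape = c(32, 32, 32),
        geometry = list(radius_vox = 2.5, cell_vox = 16)),
      seed = seed)
    co <- generate_cohort(cs, tx)
    for (id in co$manifest$specimen_id) {
      sp <- co$specimens[[id]]
      feats <- detect_echoes(sp$sites$MTP$scan, co$reference)
      ap <- acoustic_params(feats)
      h_err <- c(h_err, abs(ap$h_mm - sp$sites$MTP$truth$h_mm_mean) /
                   sp$sites$MTP$truth$h_mm_mean)
      rc1_true <- sp$params$sites$MTP$r_surface * 100
      rc1_err <- c(rc1_err, abs(ap$RC1_pct - rc1_true) / rc1_true)
    }
  }
  expect_lt(mean(h_err), 0.02)
  expect_lt(mean(rc1_err), 0.02)
})

test_that("run_study produces a coherent, reproducible report bundle", {
  cfg <- small_config(seed = 2)
  rep1 <- run_study(cfg)
  expect_s3_class(rep1$comparisons, "group_comparison")
  expect_identical(nrow(rep1$parameters), 6L)
  expect_setequal(
    rep1$comparisons$parameter,
    c(paste0(rep(c("URI", "RC1", "RC2", "h"), 2), "_",
             rep(c("MTP", "LTP"), each = 4)),
      c("BV_TV", "Tb_N", "Tb_Th", "Tb_Sp", "Conn_D", "SMI")))
  expect_true(all(rep1$comparisons$method %in% c("exact", "degenerate")))
  rep2 <- run_study(cfg)
  expect_identical(rep1$comparisons$p_value, rep2$comparisons$p_value)
  expect_identical(rep1$config_hash, rep2$config_hash)
})

test_that("run_study writes stamped tables and a run manifest", {
  out <- file.path(tempdir(), "cartiqus-study")
  on.exit(unlink(out, recursive = TRUE), add = TRUE)
  cfg <- small_config(seed = 3, output_dir = out)
  rep <- run_study(cfg)
  for (f in c("acoustic.csv", "morphometry.csv", "comparisons.csv",
              "run_manifest.json")) {
    expect_true(file.exists(file.path(out, f)))
  }
  cmp <- utils::read.csv(file.path(out, "comparisons.csv"))
  expect_true(all(cmp$seed == 3))
  expect_true(all(cmp$config_hash == rep$config_hash))
  man <- jsonlite::read_json(file.path(out, "run_manifest.json"),
                             simplifyVector = TRUE)
  expect_identical(man$seed, 3L)
  expect_identical(man$config_hash, rep$config_hash)
})
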