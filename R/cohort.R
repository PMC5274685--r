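#' Two-group cohort specification
#'
#' Describes a sham/OVX study: per-site baseline cartilage phantoms
#' (medial and lateral tibial plateau by default), one trabecular bone
#' phantom, multiplicative OVX effect sizes per parameter and site, and
#' between-animal biological variability (lognormal, unit mean, given CV).
#'
#' Default effects mirror an early estrogen-deficiency pattern: a rougher
#' surface (x3) and thinner cartilage (x0.7) at both sites, a weaker
#' surface reflection (x0.6) at the medial site only, and no bone effect.
#'
#' @param n_per_group specimens per group (default 7).
#' @param sites named list of baseline [cartilage_phantom_spec()]s, one per
#'   scanned site.
#' @param bone baseline [trabecular_phantom_spec()] (default: a rod
#'   lattice at 12 um voxels).
#' @param ovx_effects named list: one numeric vector of multipliers per
#'   site (names among `surface_roughness_sd`, `r_surface`,
#'   `thickness_mean`, `r_interface`) plus `bone` (names among
#'   `radius_vox`).
#' @param animal_cv named numeric vector of between-animal coefficients of
#'   variation for the same parameters.
#' @param seed integer seed.
#' @return an object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_per_group = 7,
                        sites = list(
                          MTP = cartilage_phantom_spec(),
                          LTP = cartilage_phantom_spec(thickness_mean = 0.28)
                        ),
                        bone = trabecular_phantom_spec(
                          "rod_lattice", voxel_size_um = 12,
                          volume_shape = c(48, 48, 48),
                          geometry = list(radius_vox = 2.5, cell_vox = 16)),
                        ovx_effects = list(
                          MTP = c(surface_roughness_sd = 3, r_surface = 0.6,
                                  thickness_mean = 0.7, r_interface = 1),
                          LTP = c(surface_roughness_sd = 3, r_surface = 1,
                                  thickness_mean = 0.7, r_interface = 1),
                          bone = c(radius_vox = 1)
                        ),
                        animal_cv = c(surface_roughness_sd = 0.2,
                                      r_surface = 0.1,
                                      thickness_mean = 0.1,
                                      r_interface = 0.15,
                                      radius_vox = 0.05),
                        seed = 1) {
  n_per_group <- check_count(n_per_group, "n_per_group", lower = 2L)
  stopifnot(length(sites) >= 1, !is.null(names(sites)))
  for (s in sites) stopifnot(inherits(s, "cartilage_phantom_spec"))
  stopifnot(inherits(bone, "trabecular_phantom_spec"))
  stopifnot(all(names(sites) %in% names(ovx_effects)))
  for (e in ovx_effects) stopifnot(all(e > 0))
  stopifnot(all(animal_cv >= 0))
  structure(list(n_per_group = n_per_group, sites = sites, bone = bone,
                 ovx_effects = ovx_effects, animal_cv = animal_cv,
                 seed = seed),
            class = "cohort_spec")
}

# unit-mean lognormal factor with coefficient of variation cv
lognormal_factor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(rnorm(n, -sdlog^2 / 2, sdlog))
}

# per-animal latent parameter draws for one cohort: baseline values times
# animal factors, times OVX effects for the OVX group. Returns a list of
# per-site parameter data frames plus bone parameters. Used by
# generate_cohort and by null-distribution studies of the comparison stage.
draw_cohort_parameters <- function(cs) {
  n_tot <- 2L * cs$n_per_group
  group <- rep(c("sham", "OVX"), each = cs$n_per_group)
  pars <- c("surface_roughness_sd", "r_surface", "thickness_mean",
            "r_interface")
  site_tabs <- lapply(names(cs$sites), function(sn) {
    base <- cs$sites[[sn]]
    eff <- cs$ovx_effects[[sn]]
    tab <- data.frame(specimen = seq_len(n_tot), group = group)
    for (p in pars) {
      cv <- if (p %in% names(cs$animal_cv)) cs$animal_cv[[p]] else 0
      mult <- ifelse(group == "OVX",
                     if (p %in% names(eff)) eff[[p]] else 1, 1)
      val <- base[[p]] * lognormal_factor(n_tot, cv) * mult
      if (p %in% c("r_surface", "r_interface")) val <- pmin(val, 1)
      tab[[p]] <- val
    }
    tab
  })
  names(site_tabs) <- names(cs$sites)
  cv_r <- if ("radius_vox" %in% names(cs$animal_cv))
    cs$animal_cv[["radius_vox"]] else 0
  eff_r <- if ("radius_vox" %in% names(cs$ovx_effects$bone))
    cs$ovx_effects$bone[["radius_vox"]] else 1
  bone_tab <- data.frame(
    specimen = seq_len(n_tot), group = group,
    radius_vox = cs$bone$geometry$radius_vox *
      lognormal_factor(n_tot, cv_r) * ifelse(group == "OVX", eff_r, 1))
  list(sites = site_tabs, bone = bone_tab, group = group)
}

#' Generate a two-group synthetic cohort
#'
#' Draws per-animal latent parameters (between-animal lognormal
#' variability, OVX effect multipliers for the OVX group), then simulates
#' one RF scan per site and one trabecular volume per specimen, plus a
#' shared perfect-reflector reference. Everything is seeded and
#' reproducible; the full ground truth is kept with each specimen.
#'
#' @param cs a [cohort_spec()].
#' @param tx a [transducer_spec()].
#' @param dir optional output directory; when given, scans, volumes and a
#'   `manifest.csv` (specimen_id, group, per-site rf paths, volume path)
#'   are written with [write_rf_scan()] / [write_volume()].
#' @return a list of class `"cohort"`: `manifest` (data frame),
#'   `specimens` (per specimen: `sites` with `scan`+`truth`, `volume`,
#'   `params`), `reference`, `seed`.
#' @export
generate_cohort <- function(cs, tx = transducer_spec(), dir = NULL) {
  stopifnot(inherits(cs, "cohort_spec"), inherits(tx, "transducer_spec"))
  with_seed(cs$seed, {
    lat <- draw_cohort_parameters(cs)
    n_tot <- 2L * cs$n_per_group
    ids <- sprintf("S%02d", seq_len(n_tot))
    reference <- simulate_reference(
      tx, standoff_mm = cs$sites[[1]]$standoff_mean,
      c_medium = cs$sites[[1]]$c_medium)

    specimens <- vector("list", n_tot)
    names(specimens) <- ids
    for (i in seq_len(n_tot)) {
      site_out <- list()
      for (sn in names(cs$sites)) {
        p <- cs$sites[[sn]]
        row <- lat$sites[[sn]][i, ]
        p$surface_roughness_sd <- row$surface_roughness_sd
        p$r_surface <- row$r_surface
        p$thickness_mean <- row$thickness_mean
        p$r_interface <- row$r_interface
        p$seed <- draw_seed()
        site_out[[sn]] <- simulate_rf_scan(p, tx)
      }
      bs <- cs$bone
      bs$geometry$radius_vox <- lat$bone$radius_vox[i]
      if (bs$shape_kind == "rod_lattice") {
        # sub-voxel positioning of the specimen relative to the scan grid
        bs$geometry$offset_vox <- stats::runif(3, -0.5, 0.5)
      }
      bs$seed <- draw_seed()
      vol <- generate_trabecular_phantom(bs)
      specimens[[i]] <- list(
        sites = site_out, volume = vol,
        params = list(sites = lapply(lat$sites, function(t) t[i, ]),
                      bone = lat$bone[i, ]))
    }
    manifest <- data.frame(specimen_id = ids, group = lat$group,
                           stringsAsFactors = FALSE)
    cohort <- structure(list(manifest = manifest, specimens = specimens,
                             reference = reference, seed = cs$seed),
                        class = "cohort")
    if (!is.null(dir)) write_cohort(cohort, dir)
    cohort
  })
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d specimens (%s), %d site(s) each, seed = %s\n",
              nrow(x$manifest),
              paste(table(x$manifest$group), names(table(x$manifest$group)),
                    collapse = " + "),
              length(x$specimens[[1]]$sites),
              format(x$seed)))
  invisible(x)
}
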