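#' Binary trabecular volume
#'
#' A binary 3D voxel array (TRUE = mineralized bone) at an isotropic voxel
#' size, with an optional volume-of-interest mask restricting volume-based
#' metrics (BV/TV, densities). Structural metrics (thickness, separation,
#' connectivity, SMI) are computed on the full array.
#'
#' @param voxels logical (or 0/1 numeric) 3D array.
#' @param voxel_size_um isotropic voxel size in um (default 12).
#' @param mask optional logical array of the same dimensions.
#' @return an object of class `"trabecular_volume"`.
#' @export
trabecular_volume <- function(voxels, voxel_size_um = 12, mask = NULL) {
  if (!is.array(voxels) || length(dim(voxels)) != 3) {
    stop("`voxels` must be a 3D array", call. = FALSE)
  }
  storage.mode(voxels) <- "logical"
  if (anyNA(voxels)) stop("`voxels` must not contain NA", call. = FALSE)
  check_number(voxel_size_um, "voxel_size_um", lower = 0,
               strict_lower = TRUE)
  if (!is.null(mask)) {
    if (!is.array(mask) || !identical(dim(mask), dim(voxels))) {
      stop("`mask` must match the voxel array dimensions", call. = FALSE)
    }
    storage.mode(mask) <- "logical"
  }
  structure(list(voxels = voxels, voxel_size_um = voxel_size_um,
                 mask = mask),
            class = "trabecular_volume")
}

#' @export
print.trabecular_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<trabecular_volume> %d x %d x %d @ %g um, BV/TV = %.3f\n",
              d[1], d[2], d[3], x$voxel_size_um, mean(x$voxels)))
  invisible(x)
}

#' Trabecular phantom specification
#'
#' Parametric binary volumes with analytically known morphometry, standing
#' in for segmented micro-CT scans. Shapes:
#' \describe{
#'   \item{`parallel_plates`}{plates normal to z, `thickness_vox` thick with
#'     period `period_vox`: BV/TV = t/p, Tb.Th = t, Tb.Sp = p - t,
#'     Tb.N = 1/p (in voxel units).}
#'   \item{`rod_lattice`}{cylindrical rods of radius `radius_vox` along all
#'     three axes on a cubic lattice with cell size `cell_vox`; optional
#'     `offset_vox` (length 3) shifts the lattice by sub-voxel amounts,
#'     modelling specimen positioning relative to the scan grid.}
#'   \item{`solid`}{every voxel filled (BV/TV = 1).}
#'   \item{`torus`}{a voxelized torus (`major_vox`, `minor_vox`): one
#'     independent loop, Euler characteristic 0.}
#'   \item{`custom`}{a user-supplied array in `geometry$voxels`.}
#' }
#'
#' @param shape_kind one of `"parallel_plates"`, `"rod_lattice"`, `"solid"`,
#'   `"torus"`, `"custom"`.
#' @param voxel_size_um isotropic voxel size, um (default 12).
#' @param volume_shape integer vector of 3 voxel counts (default 64^3).
#' @param geometry named list of shape parameters in voxel units (see
#'   Details).
#' @param seed integer seed (reserved for randomized custom shapes).
#' @return an object of class `"trabecular_phantom_spec"`.
#' @export
trabecular_phantom_spec <- function(shape_kind, voxel_size_um = 12,
                                    volume_shape = c(64, 64, 64),
                                    geometry = list(), seed = NULL) {
  shape_kind <- match.arg(shape_kind, c("parallel_plates", "rod_lattice",
                                        "solid", "torus", "custom"))
  check_number(voxel_size_um, "voxel_size_um", lower = 0,
               strict_lower = TRUE)
  stopifnot(length(volume_shape) == 3, all(volume_shape >= 4))
  structure(list(shape_kind = shape_kind, voxel_size_um = voxel_size_um,
                 volume_shape = as.integer(volume_shape),
                 geometry = geometry, seed = seed),
            class = "trabecular_phantom_spec")
}

#' Generate a trabecular phantom volume
#'
#' @param s a [trabecular_phantom_spec()].
#' @return a [trabecular_volume()].
#' @examples
#' spec <- trabecular_phantom_spec("parallel_plates",
#'   volume_shape = c(25, 25, 50),
#'   geometry = list(thickness_vox = 5, period_vox = 25))
#' v <- generate_trabecular_phantom(spec)
#' compute_bvtv(v)  # 0.2
#' @export
generate_trabecular_phantom <- function(s) {
  stopifnot(inherits(s, "trabecular_phantom_spec"))
  d <- s$volume_shape
  g <- s$geometry
  # voxel-centre coordinates in voxel units
  cx <- seq_len(d[1]) - 0.5
  cy <- seq_len(d[2]) - 0.5
  cz <- seq_len(d[3]) - 0.5
  vox <- switch(
    s$shape_kind,
    solid = array(TRUE, dim = d),
    parallel_plates = {
      t_ <- check_count(g$thickness_vox, "geometry$thickness_vox", 1L)
      p <- check_count(g$period_vox, "geometry$period_vox", 2L)
      if (t_ >= p || p > d[3]) {
        stop("plate geometry exceeds the volume", call. = FALSE)
      }
      slab <- ((seq_len(d[3]) - 1L) %% p) < t_
      array(rep(slab, each = d[1] * d[2]), dim = d)
    },
    rod_lattice = {
      r <- g$radius_vox
      a <- g$cell_vox
      check_number(r, "geometry$radius_vox", lower = 0, strict_lower = TRUE)
      check_number(a, "geometry$cell_vox", lower = 0, strict_lower = TRUE)
      if (2 * r >= a || a > min(d)) {
        stop("rod geometry exceeds the volume", call. = FALSE)
      }
      off <- g$offset_vox
      if (is.null(off)) off <- c(0, 0, 0)
      stopifnot(length(off) == 3, all(abs(off) < a / 2))
      # distance of coordinate u to the nearest lattice line at
      # a/2 + offset + k*a (sub-voxel offsets model specimen positioning
      # relative to the scan grid)
      lat <- function(u, n, o) {
        centers <- seq(a / 2 + o, n - a / 2 + o + 1e-9, by = a)
        vapply(u, function(ui) min(abs(ui - centers)), numeric(1))
      }
      dx <- lat(cx, d[1], off[1])
      dy <- lat(cy, d[2], off[2])
      dz <- lat(cz, d[3], off[3])
      rx2 <- outer(dy^2, dz^2, "+")          # rods along x: (y,z) distance
      ry2 <- outer(dx^2, dz^2, "+")          # rods along y
      rz2 <- outer(dx^2, dy^2, "+")          # rods along z
      r2 <- r^2
      vox_x <- aperm(array(rx2 <= r2, dim = c(d[2], d[3], d[1])), c(3, 1, 2))
      vox_y <- aperm(array(ry2 <= r2, dim = c(d[1], d[3], d[2])), c(1, 3, 2))
      vox_z <- array(rz2 <= r2, dim = d)
      vox_x | vox_y | vox_z
    },
    torus = {
      R <- g$major_vox
      r <- g$minor_vox
      check_number(R, "geometry$major_vox", lower = 0, strict_lower = TRUE)
      check_number(r, "geometry$minor_vox", lower = 0, strict_lower = TRUE)
      if (2 * (R + r) >= min(d[1], d[2]) || 2 * r >= d[3]) {
        stop("torus geometry exceeds the volume", call. = FALSE)
      }
      ox <- cx - d[1] / 2
      oy <- cy - d[2] / 2
      oz <- cz - d[3] / 2
      ring <- outer(ox^2, oy^2, "+")
      vox <- array(FALSE, dim = d)
      for (k in seq_len(d[3])) {
        vox[, , k] <- (sqrt(ring) - R)^2 + oz[k]^2 <= r^2
      }
      vox
    },
    custom = {
      if (is.null(g$voxels)) stop("custom shape needs geometry$voxels",
                                  call. = FALSE)
      v <- g$voxels
      if (!identical(dim(v), as.integer(d))) {
        stop("geometry$voxels dimensions must match volume_shape",
             call. = FALSE)
      }
      v
    }
  )
  trabecular_volume(vox, s$voxel_size_um)
}
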