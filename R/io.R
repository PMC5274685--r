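#' Write an RF scan container
#'
#' Writes the scan as a small hierarchical plain-text container: a
#' directory with `rf.csv` (one row per line), `positions.csv`, optionally
#' `reference.csv`, and a `meta.json` sidecar carrying the acquisition
#' attributes (sampling rate, sound speeds, dimensions).
#'
#' @param scan an [rf_scan()].
#' @param path directory to create/fill.
#' @param reference optional single-line [rf_scan()] stored alongside.
#' @return `path`, invisibly.
#' @export
write_rf_scan <- function(scan, path, reference = NULL) {
  stopifnot(inherits(scan, "rf_scan"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(data.table::as.data.table(scan$rf),
                     file.path(path, "rf.csv"))
  data.table::fwrite(data.table::as.data.table(scan$positions),
                     file.path(path, "positions.csv"))
  if (!is.null(reference)) {
    stopifnot(inherits(reference, "rf_scan"))
    data.table::fwrite(data.table::as.data.table(reference$rf),
                       file.path(path, "reference.csv"))
  }
  meta <- list(sampling_rate_hz = scan$sampling_rate,
               c_medium = scan$c_medium,
               c_cartilage = scan$c_cartilage,
               n_lines = nrow(scan$rf), n_samples = ncol(scan$rf),
               extra = scan$meta)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read an RF scan container written by [write_rf_scan()]
#'
#' @param path container directory.
#' @return a list with `scan` and (if stored) `reference`, both
#'   [rf_scan()]s.
#' @export
read_rf_scan <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  rf <- as.matrix(data.table::fread(file.path(path, "rf.csv")))
  dimnames(rf) <- NULL
  pos <- as.matrix(data.table::fread(file.path(path, "positions.csv")))
  dimnames(pos) <- NULL
  cc <- meta$c_cartilage
  if (is.null(cc)) cc <- NA_real_
  scan <- rf_scan(rf, pos, as.numeric(meta$sampling_rate_hz),
                  as.numeric(meta$c_medium), as.numeric(cc),
                  meta = if (is.null(meta$extra)) list() else meta$extra)
  ref_file <- file.path(path, "reference.csv")
  reference <- NULL
  if (file.exists(ref_file)) {
    ref_rf <- as.matrix(data.table::fread(ref_file))
    dimnames(ref_rf) <- NULL
    reference <- rf_scan(ref_rf, matrix(c(0, 0), ncol = 2),
                         as.numeric(meta$sampling_rate_hz),
                         as.numeric(meta$c_medium))
  }
  list(scan = scan, reference = reference)
}

#' Write a binary volume as stacked TIFF
#'
#' One 8-bit page per z-slice plus a JSON sidecar (`<path>.json`) with the
#' voxel size, since TIFF tags do not carry it portably.
#'
#' @param v a [trabecular_volume()].
#' @param path output file (`.tif`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "trabecular_volume"))
  d <- dim(v$voxels)
  slices <- lapply(seq_len(d[3]), function(k) {
    m <- matrix(as.numeric(v$voxels[, , k]), nrow = d[1])
    m  # values in {0,1}, stored as 8-bit
  })
  tiff::writeTIFF(slices, path, bits.per.sample = 8L)
  jsonlite::write_json(
    list(voxel_size_um = v$voxel_size_um, dims = d),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a stacked-TIFF binary volume written by [write_volume()]
#'
#' @param path the `.tif` file.
#' @param voxel_size_um voxel size override; default: from the JSON
#'   sidecar, else 12.
#' @return a [trabecular_volume()].
#' @export
read_volume <- function(path, voxel_size_um = NULL) {
  slices <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(slices)) slices <- list(slices)
  d <- c(dim(slices[[1]]), length(slices))
  arr <- array(FALSE, dim = d)
  for (k in seq_along(slices)) arr[, , k] <- slices[[k]] > 0.5
  if (is.null(voxel_size_um)) {
    sidecar <- paste0(path, ".json")
    voxel_size_um <- if (file.exists(sidecar)) {
      jsonlite::read_json(sidecar, simplifyVector = TRUE)$voxel_size_um
    } else 12
  }
  trabecular_volume(arr, as.numeric(voxel_size_um))
}

# write all cohort artifacts + manifest.csv under dir
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- cohort$manifest
  site_names <- names(cohort$specimens[[1]]$sites)
  for (sn in site_names) man[[paste0("rf_path_", sn)]] <- NA_character_
  man$volume_path <- NA_character_
  for (i in seq_len(nrow(man))) {
    id <- man$specimen_id[i]
    sp <- cohort$specimens[[id]]
    for (sn in site_names) {
      p <- file.path(dir, sprintf("%s_%s_rf", id, sn))
      write_rf_scan(sp$sites[[sn]]$scan, p, reference = cohort$reference)
      man[[paste0("rf_path_", sn)]][i] <- p
    }
    vp <- file.path(dir, sprintf("%s_volume.tif", id))
    write_volume(sp$volume, vp)
    man$volume_path[i] <- vp
  }
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}
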