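#' Write an echo series as NIfTI magnitude/phase volumes with a sidecar
#'
#' Writes `<prefix>_mag.nii.gz` and `<prefix>_phase.nii.gz` (4-D, echo as
#' the fourth axis) plus `<prefix>.yaml` holding echo times (ms), scanner
#' name and field strength (T).
#'
#' @param series An `echo_series`.
#' @param prefix Output path prefix.
#' @param voxel_size Optional length-3 voxel dimensions (mm) recorded in
#'   the NIfTI header.
#' @return Invisibly, the three paths written.
#' @export
write_echo_series <- function(series, prefix, voxel_size = NULL) {
  if (!inherits(series, "echo_series")) stop("series must be an echo_series")
  paths <- c(magnitude = paste0(prefix, "_mag.nii.gz"),
             phase = paste0(prefix, "_phase.nii.gz"),
             sidecar = paste0(prefix, ".yaml"))
  mag <- abs(series$data)
  ph <- Arg(series$data)
  to_nifti <- function(arr) {
    if (is.null(voxel_size)) RNifti::asNifti(arr)
    else RNifti::asNifti(arr, pixdim = c(voxel_size, 1))
  }
  RNifti::writeNifti(to_nifti(mag), paths[["magnitude"]])
  RNifti::writeNifti(to_nifti(ph), paths[["phase"]])
  yaml::write_yaml(list(echo_times_ms = as.list(series$echo_times),
                        scanner = series$scanner_name,
                        field_strength_t = series$field_strength),
                   paths[["sidecar"]])
  invisible(paths)
}

#' Read a 4-D multi-echo stack into an echo series
#'
#' Accepts either a magnitude/phase NIfTI pair or a real/imaginary pair,
#' plus a YAML sidecar providing echo times (ms) and field strength (T).
#' The two input routes yield identical complex data for the same
#' underlying acquisition.
#'
#' @param magnitude,phase Paths to the magnitude and phase volumes, or
#' @param real,imaginary paths to real/imaginary volumes (supply one pair).
#' @param sidecar Path to the YAML sidecar.
#' @return An `echo_series`; the NIfTI header of the first input is
#'   attached as attribute `reference_header` so outputs can preserve the
#'   grid and affine.
#' @export
read_echo_stack <- function(magnitude = NULL, phase = NULL,
                            real = NULL, imaginary = NULL, sidecar) {
  meta <- yaml::read_yaml(sidecar)
  te <- as.numeric(unlist(meta$echo_times_ms))
  if (length(te) < 3) stop("sidecar must list at least 3 echo times (ms)")
  b0 <- if (!is.null(meta$field_strength_t)) as.numeric(meta$field_strength_t)
        else NA_real_

  if (!is.null(magnitude) && !is.null(phase)) {
    m <- RNifti::readNifti(magnitude)
    p <- RNifti::readNifti(phase)
    hdr <- m
    data <- array(as.numeric(m) * exp(1i * as.numeric(p)), dim = dim(m))
  } else if (!is.null(real) && !is.null(imaginary)) {
    re <- RNifti::readNifti(real)
    im <- RNifti::readNifti(imaginary)
    hdr <- re
    data <- array(complex(real = as.numeric(re), imaginary = as.numeric(im)),
                  dim = dim(re))
  } else {
    stop("supply either magnitude+phase or real+imaginary paths")
  }
  if (length(dim(data)) != 4L)
    stop("input must be a 4-D volume with echo as the fourth axis")
  if (dim(data)[4] != length(te))
    stop(sprintf("sidecar lists %d echo times but the volume has %d echoes",
                 length(te), dim(data)[4]))
  series <- new_echo_series(data, te,
                            scanner_name = if (!is.null(meta$scanner)) meta$scanner else "",
                            field_strength = b0,
                            provenance = paste("read from", sidecar))
  attr(series, "reference_header") <- RNifti::niftiHeader(hdr)
  series
}

#' Write a fat-water map set as NIfTI volumes
#'
#' @param maps A `fat_water_maps` object.
#' @param prefix Output path prefix; writes `<prefix>_water.nii.gz`,
#'   `_fat.nii.gz`, `_ff.nii.gz` and `_fieldmap.nii.gz`.
#' @return Invisibly, the paths written.
#' @export
write_fat_water_maps <- function(maps, prefix) {
  if (!inherits(maps, "fat_water_maps")) stop("maps must be fat_water_maps")
  paths <- c(water = paste0(prefix, "_water.nii.gz"),
             fat = paste0(prefix, "_fat.nii.gz"),
             ff = paste0(prefix, "_ff.nii.gz"),
             fieldmap = paste0(prefix, "_fieldmap.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(maps$water), paths[["water"]])
  RNifti::writeNifti(RNifti::asNifti(maps$fat), paths[["fat"]])
  ff <- maps$fat_fraction; ff[is.na(ff)] <- 0
  RNifti::writeNifti(RNifti::asNifti(ff), paths[["ff"]])
  RNifti::writeNifti(RNifti::asNifti(maps$field_map), paths[["fieldmap"]])
  invisible(paths)
}

#' Write a per-breast density table as CSV
#'
#' @param records Data frame with columns `subject_id`, `side`, `scanner`,
#'   `magdensity_percent` (and optionally `n_voxels`).
#' @param path Output CSV path.
#' @export
write_density_table <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Read a per-breast density table from CSV
#'
#' Tolerates alternate column layouts via `column_map`, which maps the
#' canonical names to the file's column names.
#'
#' @param path CSV path.
#' @param column_map Named character vector with entries `subject_id`,
#'   `side`, `scanner`, `magdensity_percent` giving the file's column
#'   names; defaults to the canonical names.
#' @return Data frame with the canonical columns.
#' @export
read_density_table <- function(path,
                               column_map = c(subject_id = "subject_id",
                                              side = "side",
                                              scanner = "scanner",
                                              magdensity_percent = "magdensity_percent")) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "side", "scanner", "magdensity_percent")
  missing_map <- setdiff(need, names(column_map))
  if (length(missing_map))
    stop("column_map must name: ", paste(missing_map, collapse = ", "))
  absent <- setdiff(unname(column_map[need]), names(raw))
  if (length(absent))
    stop("columns not found in ", path, ": ", paste(absent, collapse = ", "))
  out <- data.frame(subject_id = as.character(raw[[column_map[["subject_id"]]]]),
                    side = as.character(raw[[column_map[["side"]]]]),
                    scanner = as.character(raw[[column_map[["scanner"]]]]),
                    magdensity_percent = as.numeric(raw[[column_map[["magdensity_percent"]]]]),
                    stringsAsFactors = FALSE)
  if (!all(out$side %in% c("L", "R")))
    stop("side column must contain only 'L' and 'R'")
  out
}

#' Write a study report bundle as JSON
#'
#' @param report A `study_report`.
#' @param path Output JSON path.
#' @export
write_report_json <- function(report, path) {
  if (!inherits(report, "study_report")) stop("report must be a study_report")
  payload <- list(
    comparisons = lapply(c(report$pre, report$post), function(r)
      unclass(r)[c("former", "latter", "n", "mean_delta", "t_stat",
                   "p_value", "pearson_r", "ba_bias", "ba_loa_low",
                   "ba_loa_high")]),
    calibration_models = lapply(attr(report$calibrated, "models"), function(m)
      unclass(m)[c("slope", "intercept", "n_train", "fold",
                   "source_scanner", "target_scanner")])
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
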