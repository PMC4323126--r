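# NIfTI + JSON-sidecar I/O. On disk a series is a NIfTI volume ordered
# (x, y, t) -- frames along the last axis -- with an adjacent ".json" sidecar
# holding times_s, pixel_spacing_mm and series_role. In memory frames are
# (y, x, t), so axes are permuted on the way through.

sidecar_path <- function(path) {
  base <- sub("\\.nii(\\.gz)?$", "", path)
  paste0(base, ".json")
}

resolve_series_path <- function(path, series_role) {
  if (dir.exists(path))
    path <- file.path(path, paste0(series_role, ".nii.gz"))
  path
}

#' Read a dynamic series from NIfTI + JSON sidecar
#'
#' @param path Path to a `.nii`/`.nii.gz` volume, `(x, y, t)` or `(x, y)` for
#'   a single frame.
#' @param sidecar Path to the JSON sidecar; defaults to `path` with the NIfTI
#'   extension replaced by `.json`. Required keys: `times_s`,
#'   `pixel_spacing_mm`, `series_role`.
#' @return A validated [dynamic_series()].
#' @export
read_series <- function(path, sidecar = sidecar_path(path)) {
  if (!file.exists(path)) stop("series file not found: ", path)
  if (!file.exists(sidecar)) stop("missing sidecar: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  for (key in c("times_s", "pixel_spacing_mm", "series_role"))
    if (is.null(meta[[key]])) stop("sidecar missing key '", key, "': ", sidecar)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 2L) arr <- array(arr, c(dim(arr), 1L))
  if (length(dim(arr)) != 3L)
    stop("expected a 2D or 3D NIfTI volume, got ", length(dim(arr)), "D: ", path)
  frames <- aperm(arr, c(2, 1, 3))  # (x,y,t) on disk -> (y,x,t) in memory
  dynamic_series(frames, meta$times_s, meta$pixel_spacing_mm, meta$series_role)
}

#' Write a dynamic series to NIfTI + JSON sidecar
#'
#' Inverse of [read_series()]: reading the written files reproduces values,
#' times and spacing. If `path` is an existing directory the file is named
#' `<series_role>.nii.gz` inside it.
#'
#' @param series A valid [dynamic_series()].
#' @param path Output `.nii`/`.nii.gz` path or an existing directory.
#' @return The path written, invisibly.
#' @export
write_series <- function(series, path) {
  if (!inherits(series, "dynamic_series")) stop("series must be a dynamic_series")
  # re-validate so stale objects with e.g. NaN frames are refused
  series <- dynamic_series(series$frames, series$times_s,
                           series$pixel_spacing_mm, series$series_role)
  path <- resolve_series_path(path, series$series_role)
  arr <- aperm(series$frames, c(2, 1, 3))
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = "double"), path)
  jsonlite::write_json(
    list(times_s = series$times_s,
         pixel_spacing_mm = series$pixel_spacing_mm,
         series_role = series$series_role),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a binary ROI mask from NIfTI
#'
#' @param path NIfTI file with values in `{0, 1}`; any non-zero value is
#'   treated as inside the region.
#' @param label Mask label: `"myocardium"`, `"body"` or `"blood_pool"`.
#' @param reference Optional `dynamic_series` whose frame shape the mask must
#'   match.
#' @return An [roi_mask()].
#' @export
read_mask <- function(path, label, reference = NULL) {
  if (!file.exists(path)) stop("mask file not found: ", path)
  arr <- as.array(RNifti::readNifti(path))
  if (length(dim(arr)) == 3L && dim(arr)[3] == 1L) arr <- arr[, , 1]
  if (length(dim(arr)) != 2L) stop("mask must be a single 2D image: ", path)
  m <- roi_mask(t(arr) != 0, label)  # (x,y) on disk -> (y,x)
  if (!is.null(reference)) check_mask_shape(m, frame_shape(reference), "mask")
  m
}

#' Write a binary ROI mask to NIfTI
#'
#' @param mask An [roi_mask()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_mask <- function(mask, path) {
  if (!inherits(mask, "roi_mask")) stop("mask must be an roi_mask")
  arr <- t(mask$mask * 1)
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = "uint8"), path)
  invisible(path)
}

#' Export a time curve as two-column CSV
#'
#' @param curve A [concentration_curve()] or a plain numeric vector with a
#'   `times_s` attribute supplied via `times_s`.
#' @param path Output CSV path (columns `time_s`, `value`).
#' @param times_s Times when `curve` is a plain vector.
#' @return The path, invisibly.
#' @export
write_curve_csv <- function(curve, path, times_s = NULL) {
  if (inherits(curve, "concentration_curve")) {
    df <- data.frame(time_s = curve$times_s, value = curve$values)
  } else {
    df <- data.frame(time_s = times_s, value = as.double(curve))
  }
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
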