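# Core domain containers. All images are numeric matrices indexed [row = y
# from top, col = x from left], 1-based; dynamic series are ny x nx x nt
# arrays with the frame index last. Constructors validate every invariant and
# either return a well-formed object or fail with a message naming the
# violated constraint.

SERIES_ROLES <- c("perfusion", "aif", "pd")
MASK_LABELS <- c("myocardium", "body", "blood_pool")

#' Dynamic image series
#'
#' A time-ordered stack of 2D frames with per-frame acquisition times: the
#' central object of the perfusion pipeline. One frame is acquired per
#' heartbeat over roughly 60 heartbeats in a typical first-pass study.
#'
#' @param frames Numeric `ny x nx` matrix (single frame) or `ny x nx x nt`
#'   array; all values must be finite and non-negative.
#' @param times_s Numeric vector of per-frame acquisition times in seconds,
#'   strictly increasing, one per frame.
#' @param pixel_spacing_mm Length-2 numeric `(dy, dx)` pixel spacing.
#' @param series_role One of `"perfusion"`, `"aif"`, `"pd"`.
#' @return An object of class `dynamic_series` with fields `frames`,
#'   `times_s`, `pixel_spacing_mm`, `series_role`.
#' @export
dynamic_series <- function(frames, times_s, pixel_spacing_mm = c(1, 1),
                           series_role = "perfusion") {
  if (is.matrix(frames)) frames <- array(frames, dim = c(dim(frames), 1L))
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("frames must be a 2D matrix or a 3D (y, x, t) array")
  frames <- array(as.double(frames), dim = dim(frames))
  nt <- dim(frames)[3]
  if (nt < 1L) stop("frame count must be >= 1")
  times_s <- as.double(times_s)
  if (length(times_s) != nt)
    stop("times_s length (", length(times_s), ") does not match frame count (", nt, ")")
  if (nt > 1L && any(diff(times_s) <= 0))
    stop("times not strictly increasing")
  if (!all(is.finite(frames)))
    stop("frames contain non-finite intensities")
  if (any(frames < 0))
    stop("frames contain negative intensities")
  pixel_spacing_mm <- as.double(pixel_spacing_mm)
  if (length(pixel_spacing_mm) != 2L || any(!is.finite(pixel_spacing_mm)) ||
      any(pixel_spacing_mm <= 0))
    stop("pixel_spacing_mm must be two positive numbers (dy, dx)")
  series_role <- match.arg(series_role, SERIES_ROLES)
  structure(
    list(frames = frames, times_s = times_s,
         pixel_spacing_mm = pixel_spacing_mm, series_role = series_role),
    class = "dynamic_series"
  )
}

#' @export
print.dynamic_series <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<dynamic_series> %s: %d x %d px, %d frame(s), t = [%g, %g] s\n",
              x$series_role, d[1], d[2], d[3],
              x$times_s[1], x$times_s[length(x$times_s)]))
  invisible(x)
}

n_frames <- function(series) dim(series$frames)[3]

frame_shape <- function(series) dim(series$frames)[1:2]

get_frame <- function(series, i) series$frames[, , i]

#' Replace the frame stack of a series, keeping times and metadata
#' @noRd
with_frames <- function(series, frames) {
  dynamic_series(frames, series$times_s, series$pixel_spacing_mm,
                 series$series_role)
}

#' Binary region-of-interest mask
#'
#' @param mask Logical or 0/1 numeric matrix; any non-zero value is treated
#'   as inside the region.
#' @param label One of `"myocardium"`, `"body"`, `"blood_pool"`.
#' @return An object of class `roi_mask` with a logical `mask` and `label`.
#' @export
roi_mask <- function(mask, label) {
  if (!is.matrix(mask)) stop("mask must be a 2D matrix")
  if (is.numeric(mask)) {
    if (!all(is.finite(mask))) stop("mask contains non-finite values")
    mask <- mask != 0
  }
  if (!is.logical(mask)) stop("mask must be logical or numeric 0/1")
  label <- match.arg(label, MASK_LABELS)
  structure(list(mask = mask, label = label), class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %s: %d x %d px, %d inside\n", x$label,
              nrow(x$mask), ncol(x$mask), sum(x$mask)))
  invisible(x)
}

check_mask_shape <- function(mask, shape, what = "mask") {
  if (!identical(dim(mask$mask), as.integer(shape)))
    stop(what, " shape (", paste(dim(mask$mask), collapse = "x"),
         ") does not match image shape (", paste(shape, collapse = "x"), ")")
  invisible(TRUE)
}

#' Multiplicative surface-coil bias field
#'
#' A smooth, strictly positive 2D gain estimate. The field is stored with
#' unit mean over a normalization mask (the myocardium by default) so that
#' dividing a series by it does not rescale mean myocardial signal.
#'
#' @param field Strictly positive numeric matrix.
#' @param normalization_mask_label Label of the mask over which the field has
#'   unit mean.
#' @param normalization_mask Optional `roi_mask` used to verify the unit-mean
#'   invariant (checked to 1e-9 when supplied).
#' @return Object of class `bias_field`.
#' @export
bias_field <- function(field, normalization_mask_label = "myocardium",
                       normalization_mask = NULL) {
  if (!is.matrix(field)) stop("bias field must be a 2D matrix")
  field <- matrix(as.double(field), nrow(field), ncol(field))
  if (!all(is.finite(field))) stop("bias field contains non-finite values")
  if (any(field <= 0)) stop("bias field must be strictly positive everywhere")
  normalization_mask_label <- match.arg(normalization_mask_label, MASK_LABELS)
  if (!is.null(normalization_mask)) {
    check_mask_shape(normalization_mask, dim(field), "normalization mask")
    mu <- mean(field[normalization_mask$mask])
    if (abs(mu - 1) > 1e-9)
      stop("bias field mean over normalization mask is ", format(mu),
           ", not 1 within 1e-9")
  }
  structure(list(field = field,
                 normalization_mask_label = normalization_mask_label),
            class = "bias_field")
}

#' Contrast concentration time course
#'
#' Arterial input or tissue contrast concentration over time, in mmol/L or
#' any consistent linear concentration scale.
#'
#' @param values Numeric concentration samples.
#' @param times_s Strictly increasing sample times in seconds.
#' @param foot_index Optional 1-based index of contrast arrival.
#' @return Object of class `concentration_curve`.
#' @export
concentration_curve <- function(values, times_s, foot_index = NULL) {
  values <- as.double(values)
  times_s <- as.double(times_s)
  if (length(values) != length(times_s))
    stop("values and times_s must have equal length")
  if (length(times_s) > 1L && any(diff(times_s) <= 0))
    stop("times not strictly increasing")
  if (!all(is.finite(values))) stop("values contain non-finite entries")
  if (!is.null(foot_index)) {
    foot_index <- as.integer(foot_index)
    if (foot_index < 1L || foot_index > length(values))
      stop("foot_index out of range")
  }
  structure(list(values = values, times_s = times_s, foot_index = foot_index),
            class = "concentration_curve")
}

#' Pixel-wise myocardial blood flow map
#'
#' Flow estimates in mL/min/g over the myocardial mask with per-pixel fit
#' diagnostics. Pixels outside the mask are `NA` in every field.
#'
#' @param mbf Numeric matrix of flow estimates, `NA` outside the mask,
#'   non-negative wherever `converged` is `TRUE`.
#' @param fit_rss Matrix of per-pixel residual sums of squares.
#' @param converged Logical matrix of per-pixel convergence flags.
#' @param mask The myocardial `roi_mask` the map is defined over.
#' @return Object of class `mbf_map_result`.
#' @export
new_mbf_map <- function(mbf, fit_rss, converged, mask) {
  stopifnot(is.matrix(mbf), is.matrix(fit_rss), is.matrix(converged))
  check_mask_shape(mask, dim(mbf), "myocardial mask")
  inside <- mask$mask
  if (!identical(which(is.na(mbf)), which(!inside)))
    stop("mbf must be NA exactly on the complement of the myocardial mask")
  bad <- inside & converged & (is.na(mbf) | mbf < 0)
  if (any(bad, na.rm = TRUE)) stop("mbf must be >= 0 where converged")
  structure(list(mbf = mbf, fit_rss = fit_rss, converged = converged,
                 mask = mask),
            class = "mbf_map_result")
}

#' @export
print.mbf_map_result <- function(x, ...) {
  v <- x$mbf[x$mask$mask & x$converged]
  cat(sprintf(
    "<mbf_map_result> %d myocardial px, %d converged, MBF %.2f +/- %.2f mL/min/g\n",
    sum(x$mask$mask), sum(x$converged, na.rm = TRUE), mean(v), sd(v)))
  invisible(x)
}

#' AHA sector labels over the myocardial mask
#'
#' Six 60-degree angular sectors in the clockwise mid-ventricular order
#' anterior (1), anterolateral (2), inferolateral (3), inferior (4),
#' inferoseptum (5), anteroseptum (6), anchored at the anterior RV
#' insertion point.
#'
#' @param labels Integer matrix, values 1..6 over the myocardium and `NA`
#'   outside.
#' @param rv_insertion_angle_deg Display angle of the anterior RV insertion
#'   point, degrees clockwise from the vertical (anterior-up) direction.
#' @return Object of class `segment_labels`.
#' @export
segment_labels <- function(labels, rv_insertion_angle_deg) {
  if (!is.matrix(labels)) stop("labels must be a 2D matrix")
  vals <- labels[!is.na(labels)]
  if (length(vals) == 0L) stop("labels has no labelled pixels")
  if (!all(vals %in% 1:6)) stop("labels must take values 1..6 over the mask")
  structure(list(labels = labels,
                 rv_insertion_angle_deg = as.double(rv_insertion_angle_deg)),
            class = "segment_labels")
}

SECTOR_NAMES <- c("anterior", "anterolateral", "inferolateral",
                  "inferior", "inferoseptum", "anteroseptum")
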