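# Surface-coil intensity correction (SCIC). The receive-coil gain is
# approximated by an ordinary-least-squares third-order 2D polynomial fit to
# the signal of similar-intensity tissue (myocardium + intensity-banded body
# pixels) in a reference image: either the proton-density-weighted frame
# (PD-SCIC) or a pre-contrast saturation-prepared SSFP frame (SSFP-SCIC).
# The fitted surface, normalized to unit myocardial mean, is divided out of
# the perfusion series. The no-correction arm applies baseline normalization
# only.

norm_coord <- function(i, n) if (n > 1) 2 * (i - 1) / (n - 1) - 1 else 0 * i

poly_exponents <- function(order) {
  ex <- expand.grid(i = 0:order, j = 0:order)
  ex <- ex[ex$i + ex$j <= order, ]
  # fixed order: by total degree, then descending x exponent
  ex[order(ex$i + ex$j, -ex$i), ]
}

poly_design <- function(xn, yn, order) {
  ex <- poly_exponents(order)
  X <- matrix(0, length(xn), nrow(ex))
  for (k in seq_len(nrow(ex))) X[, k] <- xn^ex$i[k] * yn^ex$j[k]
  colnames(X) <- paste0("x", ex$i, "y", ex$j)
  X
}

poly_design_3 <- function(xn, yn) poly_design(xn, yn, 3L)

#' Construct the body fitting mask by intensity banding
#'
#' Keeps body-outline pixels whose reference intensity lies within a band
#' around the myocardial median, excluding tissue markedly brighter (fat) or
#' darker (lung) than myocardium, and removes myocardial pixels from the
#' result.
#'
#' @param reference 2D reference frame.
#' @param myo_mask Myocardial [roi_mask()].
#' @param body_outline Body-outline [roi_mask()]; may contain the myocardium.
#' @param lo_frac,hi_frac Band limits as fractions of the myocardial median
#'   intensity; `0 < lo_frac < 1 < hi_frac`.
#' @return A `"body"`-labelled [roi_mask()].
#' @export
build_body_mask <- function(reference, myo_mask, body_outline,
                            lo_frac = 0.5, hi_frac = 2.0) {
  stopifnot(is.matrix(reference))
  check_mask_shape(myo_mask, dim(reference), "myocardial mask")
  check_mask_shape(body_outline, dim(reference), "body outline")
  if (!(lo_frac > 0 && lo_frac < 1 && hi_frac > 1))
    stop("need 0 < lo_frac < 1 < hi_frac")
  m <- median(reference[myo_mask$mask])
  keep <- body_outline$mask & !myo_mask$mask &
    reference >= lo_frac * m & reference <= hi_frac * m
  if (!any(keep)) stop("body mask empty after intensity banding")
  roi_mask(keep, "body")
}

#' Fit the surface-coil bias field by polynomial surface fit
#'
#' Ordinary least squares of `sum_{i+j<=order} c_ij x^i y^j` (coordinates
#' affinely normalized to `[-1, 1]^2`) to reference intensities over the
#' union of the myocardial and body masks. The fitted surface is evaluated
#' on the full grid, floored at `1e-3` of its mask-union mean to prevent
#' amplification where the extrapolated fit dips toward zero, and normalized
#' to unit mean over the myocardium.
#'
#' @param reference 2D reference frame (non-negative intensities).
#' @param myo_mask,body_mask [roi_mask()]s defining the fitted pixels.
#' @param order Polynomial order (default 3, i.e. 10 coefficients).
#' @return `list(fit, bias)`: a `surface_fit` (fields `coefficients`,
#'   `coord_transform`, `rms_residual`, `order`) and a [bias_field()] with
#'   unit myocardial mean.
#' @export
fit_bias_surface <- function(reference, myo_mask, body_mask, order = 3L) {
  stopifnot(is.matrix(reference))
  if (any(reference < 0)) stop("reference intensities must be >= 0")
  check_mask_shape(myo_mask, dim(reference), "myocardial mask")
  check_mask_shape(body_mask, dim(reference), "body mask")
  fitted_mask <- myo_mask$mask | body_mask$mask
  n_terms <- nrow(poly_exponents(order))
  if (sum(fitted_mask) < max(10L, n_terms))
    stop("fewer than ", max(10L, n_terms), " usable pixels for the surface fit")
  ny <- nrow(reference); nx <- ncol(reference)
  idx <- which(fitted_mask, arr.ind = TRUE)
  X <- poly_design(norm_coord(idx[, 2], nx), norm_coord(idx[, 1], ny), order)
  z <- reference[fitted_mask]
  qr_x <- qr(X)
  if (qr_x$rank < n_terms)
    stop("rank-deficient surface fit: degenerate mask geometry")
  coef <- qr.coef(qr_x, z)
  resid <- z - X %*% coef
  rms <- sqrt(mean(resid^2))
  all_idx <- which(matrix(TRUE, ny, nx), arr.ind = TRUE)
  Xfull <- poly_design(norm_coord(all_idx[, 2], nx),
                       norm_coord(all_idx[, 1], ny), order)
  surface <- matrix(Xfull %*% coef, ny, nx)
  eps <- 1e-3 * mean(surface[fitted_mask])
  if (eps <= 0) stop("fitted surface non-positive over the fitted masks")
  surface <- pmax(surface, eps)
  field <- surface / mean(surface[myo_mask$mask])
  fit <- structure(list(coefficients = as.vector(coef),
                        coord_transform = list(ny = ny, nx = nx),
                        rms_residual = rms, order = order),
                   class = "surface_fit")
  list(fit = fit,
       bias = bias_field(field, "myocardium", normalization_mask = myo_mask))
}

#' Divide a series by a bias field
#'
#' Pixel-wise division of every frame by the field; times and metadata are
#' unchanged.
#'
#' @param series A [dynamic_series()].
#' @param bias A [bias_field()] of matching shape.
#' @return The corrected [dynamic_series()].
#' @export
apply_scic <- function(series, bias) {
  if (!identical(dim(bias$field), dim(series$frames)[1:2]))
    stop("bias field shape does not match series frames")
  with_frames(series, series$frames / as.vector(bias$field))
}

#' Baseline normalization
#'
#' Divides the whole series by the mean myocardial intensity of the first
#' `n_baseline` (pre-contrast) frames.
#'
#' @param series A [dynamic_series()].
#' @param myo_mask Myocardial [roi_mask()].
#' @param n_baseline Number of leading baseline frames (>= 1, < series
#'   length).
#' @return `list(series, scale)`: the normalized series and the scalar
#'   divided out.
#' @export
baseline_normalize <- function(series, myo_mask, n_baseline = 4L) {
  check_mask_shape(myo_mask, frame_shape(series), "myocardial mask")
  nt <- n_frames(series)
  if (n_baseline < 1L || n_baseline >= nt)
    stop("n_baseline must be >= 1 and < number of frames")
  s <- mean(vapply(seq_len(n_baseline),
                   function(i) mean(get_frame(series, i)[myo_mask$mask]),
                   numeric(1)))
  if (s <= 0) stop("non-positive baseline scale")
  list(series = with_frames(series, series$frames / s), scale = s)
}

#' Run one surface-coil intensity correction mode
#'
#' Dispatches the three comparison arms: `"pd"` fits the bias surface on the
#' proton-density frame, `"ssfp"` on a pre-contrast saturation-prepared
#' frame of the perfusion series (the first baseline frame by default), and
#' `"none"` applies baseline normalization only. The fitted modes divide out
#' the bias field and then baseline-normalize.
#'
#' @param mode `"pd"`, `"ssfp"` or `"none"`.
#' @param perfusion Perfusion [dynamic_series()].
#' @param pd Proton-density [dynamic_series()] (required for `"pd"`).
#' @param masks `list(myocardium =, body =)` of [roi_mask()]s; `body` is the
#'   traced body outline.
#' @param n_baseline Baseline frames for normalization.
#' @param lo_frac,hi_frac Intensity band for [build_body_mask()].
#' @param order Surface-fit polynomial order.
#' @param ssfp_ref_frame Index of the reference frame for `"ssfp"`.
#' @param details If `TRUE` return a list with the corrected series plus the
#'   bias field, surface fit, fitting masks, reference images and baseline
#'   scale; otherwise just the corrected [dynamic_series()].
#' @return See `details`.
#' @export
run_scic <- function(mode, perfusion, pd = NULL, masks, n_baseline = 4L,
                     lo_frac = 0.5, hi_frac = 2.0, order = 3L,
                     ssfp_ref_frame = 1L, details = FALSE) {
  mode <- match.arg(mode, c("none", "pd", "ssfp"))
  myo <- masks$myocardium
  reference <- bias <- fit <- body_mask <- ref_corrected <- NULL
  if (mode == "pd") {
    if (is.null(pd)) stop("PD-SCIC requires a proton-density frame")
    reference <- get_frame(pd, 1L)
  } else if (mode == "ssfp") {
    if (ssfp_ref_frame < 1L || ssfp_ref_frame > n_frames(perfusion))
      stop("ssfp_ref_frame out of range")
    if (ssfp_ref_frame > n_baseline)
      stop("SSFP reference frame must be a pre-contrast baseline frame")
    reference <- get_frame(perfusion, ssfp_ref_frame)
  }
  corrected <- perfusion
  if (!is.null(reference)) {
    body_mask <- build_body_mask(reference, myo, masks$body, lo_frac, hi_frac)
    fb <- fit_bias_surface(reference, myo, body_mask, order)
    fit <- fb$fit; bias <- fb$bias
    corrected <- apply_scic(perfusion, bias)
    ref_corrected <- reference / bias$field
  }
  bn <- baseline_normalize(corrected, myo, n_baseline)
  if (!details) return(bn$series)
  list(series = bn$series, scale = bn$scale, mode = mode, bias = bias,
       fit = fit, body_mask = body_mask, reference = reference,
       reference_corrected = ref_corrected)
}
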