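# Tracer-kinetic quantification: curve extraction, contrast-arrival (foot)
# detection, linear signal-to-concentration conversion, and pixel-wise MBF
# estimation by Fermi-model-constrained deconvolution of the arterial input
# function. The Fermi impulse retention function is the standard constrained
# model for first-pass cardiac MR; flow is read out as the impulse-response
# initial height, converted to mL/min/g assuming myocardial density
# 1.05 g/mL.

#' Fermi impulse-response parameters
#'
#' @param amp Impulse-response amplitude, per-second scale (>= 0).
#' @param k_per_s Decay sharpness (> 0).
#' @param w_s Shoulder width, seconds (>= 0).
#' @param delay_s Tissue-vs-AIF bolus arrival delay, seconds (>= 0).
#' @return Object of class `fermi_params`.
#' @export
fermi_params <- function(amp, k_per_s, w_s, delay_s = 0) {
  if (amp < 0) stop("amp must be >= 0")
  if (k_per_s <= 0) stop("k_per_s must be > 0")
  if (w_s < 0) stop("w_s must be >= 0")
  if (delay_s < 0) stop("delay_s must be >= 0")
  structure(list(amp = amp, k_per_s = k_per_s, w_s = w_s, delay_s = delay_s),
            class = "fermi_params")
}

#' Deconvolution fit configuration
#'
#' Bounds, coarse initialization grid, multistart count and convergence
#' control for the per-pixel Fermi fits, plus the flow units constant
#' (per-second impulse height to mL/min/g: x60, tissue density 1.05 g/mL).
#' Multistart is deterministic: the `multistart` best cells of the coarse
#' grid seed independent Nelder-Mead refinements; ties are broken by lowest
#' residual, then lowest delay.
#'
#' @param bounds Named list of `c(lower, upper)` for `amp`, `k_per_s`,
#'   `w_s`, `delay_s`.
#' @param max_iterations Nelder-Mead iteration cap per start.
#' @param multistart Number of grid-seeded starts (>= 1).
#' @param tol Relative convergence tolerance on the residual sum of squares.
#' @param flow_unit_constant Multiplier from per-second impulse height to
#'   mL/min/g.
#' @param fit_window_s First-pass fit window: only frames up to this many
#'   seconds past the detected contrast foot enter the least-squares fit
#'   (the classical restriction of Fermi deconvolution to the first pass;
#'   also keeps the long washout tail from dominating the residual).
#'   `Inf` fits the whole series.
#' @param k_grid,w_grid,delay_grid Coarse initialization grids.
#' @return Object of class `fit_config`.
#' @export
fit_config <- function(bounds = list(amp = c(0, 0.5), k_per_s = c(0.02, 5),
                                     w_s = c(0, 30), delay_s = c(0, 10)),
                       max_iterations = 400L, multistart = 6L, tol = 1e-12,
                       flow_unit_constant = 60 / 1.05,
                       fit_window_s = 15,
                       k_grid = c(0.05, 0.1, 0.2, 0.4, 0.8, 1.5, 3),
                       w_grid = c(0, 1, 2, 5, 10, 20, 30),
                       delay_grid = c(0, 0.5, 1, 2, 3, 5)) {
  for (nm in c("amp", "k_per_s", "w_s", "delay_s")) {
    b <- bounds[[nm]]
    if (is.null(b) || length(b) != 2L || !all(is.finite(b)) || b[1] >= b[2])
      stop("bounds$", nm, " must be finite and ordered (lower < upper)")
  }
  if (multistart < 1L) stop("multistart must be >= 1")
  structure(list(bounds = bounds, max_iterations = as.integer(max_iterations),
                 multistart = as.integer(multistart), tol = tol,
                 flow_unit_constant = flow_unit_constant,
                 fit_window_s = fit_window_s,
                 k_grid = k_grid, w_grid = w_grid, delay_grid = delay_grid),
            class = "fit_config")
}

#' Mean signal time curve over a mask
#'
#' @param series A [dynamic_series()].
#' @param mask A non-empty [roi_mask()].
#' @return Numeric vector, one value per frame.
#' @export
extract_curve <- function(series, mask) {
  check_mask_shape(mask, frame_shape(series), "mask")
  if (!any(mask$mask)) stop("empty mask")
  apply(series$frames, 3, function(fr) mean(fr[mask$mask]))
}

#' Per-pixel signal time curves over a mask
#'
#' @inheritParams extract_curve
#' @return `n_pixels x n_frames` matrix; rows follow `which(mask$mask)`
#'   (column-major) order.
#' @export
extract_pixel_curves <- function(series, mask) {
  check_mask_shape(mask, frame_shape(series), "mask")
  px <- which(mask$mask)
  if (length(px) == 0L) stop("empty mask")
  nt <- n_frames(series)
  m <- matrix(series$frames, ncol = nt)[px, , drop = FALSE]
  m
}

#' Detect the first-pass contrast arrival (foot) of a curve
#'
#' Baseline statistics are taken over the first `n_baseline_min` frames; the
#' foot is the first index whose value exceeds `baseline_mean + max(3 *
#' baseline_SD, 0.05 * (max - baseline_mean))`.
#'
#' @param curve Numeric signal time curve.
#' @param n_baseline_min Number of leading baseline frames (curve must be at
#'   least 3 frames longer).
#' @return 1-based foot index.
#' @export
detect_foot <- function(curve, n_baseline_min = 4L) {
  if (length(curve) < n_baseline_min + 3L)
    stop("curve too short for foot detection")
  base <- curve[seq_len(n_baseline_min)]
  thr <- mean(base) + max(3 * sd(base), 0.05 * (max(curve) - mean(base)))
  idx <- which(curve > thr)
  idx <- idx[idx > n_baseline_min]
  if (length(idx) == 0L) stop("no contrast detected")
  idx[1]
}

#' Convert a signal curve to contrast concentration (linear model)
#'
#' `C(t) = max(S(t) - baseline, 0) / scale`, with the baseline the mean
#' signal over pre-foot frames. The result is in arbitrary linear
#' concentration units unless a calibration `scale` (signal per unit
#' concentration) is supplied; the arbitrary scale cancels in deconvolution
#' provided AIF and tissue share it.
#'
#' @param values Signal samples.
#' @param times_s Sample times, seconds.
#' @param foot 1-based foot index (> 1; pre-foot baseline must be nonempty).
#' @param mode Conversion model; only `"linear"` is implemented.
#' @param scale Signal per unit concentration (divided out).
#' @return A [concentration_curve()] carrying `foot`.
#' @export
signal_to_concentration <- function(values, times_s, foot, mode = "linear",
                                    scale = 1) {
  mode <- match.arg(mode, "linear")
  if (foot <= 1L) stop("foot at first frame: no pre-foot baseline")
  base <- mean(values[seq_len(foot - 1L)])
  concentration_curve(pmax(values - base, 0) / scale, times_s,
                      foot_index = foot)
}

#' Fermi impulse retention function
#'
#' `R(t) = amp / (1 + exp(k (t - delay - w)))` for `t >= delay`, 0 before;
#' non-increasing after the delay. Its initial height `R(delay)` is the flow
#' estimate in constrained deconvolution.
#'
#' @param params A [fermi_params()].
#' @param times_s Sample times, seconds.
#' @return Numeric vector of response values.
#' @export
fermi_response <- function(params, times_s) {
  e <- pmin(params$k_per_s * (times_s - params$delay_s - params$w_s), 700)
  ifelse(times_s >= params$delay_s, params$amp / (1 + exp(e)), 0)
}

fermi_initial_height <- function(amp, k_per_s, w_s) {
  amp / (1 + exp(-pmin(k_per_s * w_s, 700)))
}

# Resample the AIF onto the tissue time grid by linear interpolation.
resample_aif <- function(aif, times_s) {
  if (isTRUE(all.equal(aif$times_s, times_s))) return(aif$values)
  approx(aif$times_s, aif$values, xout = times_s, rule = 2)$y
}

fit_curves_matrix <- function(Y, aif, times_s, config, foot = NULL) {
  dt <- check_uniform_grid(times_s)
  # first-pass window: fit only frames up to fit_window_s past the foot
  if (!is.null(foot) && is.finite(config$fit_window_s)) {
    keep <- times_s <= times_s[foot] + config$fit_window_s
    if (sum(keep) >= 5L) {
      times_s <- times_s[keep]
      Y <- Y[, keep, drop = FALSE]
    }
  }
  av <- resample_aif(aif, times_s)
  if (sum(abs(av)) <= 0) stop("AIF has zero area")
  Cm <- conv_matrix(av, dt)
  lags <- (seq_along(times_s) - 1) * dt
  b <- config$bounds
  clampg <- function(g, bb) pmin(pmax(g, bb[1]), bb[2])
  fermi_fit_mat(Y, Cm, lags,
                clampg(config$k_grid, b$k_per_s),
                clampg(config$w_grid, b$w_s),
                clampg(config$delay_grid, b$delay_s),
                c(b$k_per_s[1], b$w_s[1], b$delay_s[1]),
                c(b$k_per_s[2], b$w_s[2], b$delay_s[2]),
                b$amp[1], b$amp[2],
                config$multistart, config$max_iterations, config$tol)
}

#' Fit one tissue curve by Fermi-constrained deconvolution
#'
#' Nonlinear least squares of `tissue(t)` against `(aif * fermi)(t)`
#' (trapezoidal discrete convolution), with the amplitude profiled out
#' analytically and the remaining parameters refined by bounded Nelder-Mead
#' from deterministic multistart initializations. MBF is the impulse
#' response's initial height `R(delay)` converted via the config's flow
#' units constant.
#'
#' @param aif Arterial input [concentration_curve()] (already converted to
#'   concentration; resampled to the tissue grid internally).
#' @param tissue Tissue [concentration_curve()].
#' @param config A [fit_config()].
#' @return `list(params, mbf, diagnostics)` with a [fermi_params()], MBF in
#'   mL/min/g, and `diagnostics = list(rss, converged, n_eval)`.
#' @export
fit_pixel <- function(aif, tissue, config = fit_config()) {
  Y <- matrix(tissue$values, nrow = 1)
  foot <- tissue$foot_index %||% aif$foot_index
  res <- fit_curves_matrix(Y, aif, tissue$times_s, config, foot = foot)
  params <- fermi_params(res$amp[1], res$k[1], res$w[1], res$delay[1])
  mbf <- fermi_initial_height(res$amp[1], res$k[1], res$w[1]) *
    config$flow_unit_constant
  list(params = params, mbf = mbf,
       diagnostics = list(rss = res$rss[1], converged = res$converged[1] == 1L,
                          n_eval = res$n_eval[1]))
}

#' Pixel-wise MBF map by constrained deconvolution
#'
#' Extracts per-pixel myocardial curves from a corrected series, detects the
#' tissue foot on the mean myocardial curve, converts each pixel curve to
#' concentration (per-pixel baseline subtraction, shared foot, linear
#' calibration `tissue_scale`), and fits every pixel with [fit_pixel()]'s
#' engine. Deterministic given the configuration.
#'
#' @param series Corrected perfusion [dynamic_series()] (output of
#'   [run_scic()]).
#' @param aif Concentration-converted arterial input [concentration_curve()].
#' @param myo_mask Myocardial [roi_mask()].
#' @param config A [fit_config()].
#' @param n_baseline_min Baseline frames for tissue foot detection.
#' @param tissue_scale Tissue signal per unit concentration (see
#'   [signal_to_concentration()]).
#' @return An `mbf_map_result` (see [new_mbf_map()]); errors if more than
#'   half the pixels fail to converge.
#' @export
mbf_map <- function(series, aif, myo_mask, config = fit_config(),
                    n_baseline_min = 4L, tissue_scale = 1) {
  check_mask_shape(myo_mask, frame_shape(series), "myocardial mask")
  S <- extract_pixel_curves(series, myo_mask)
  mean_curve <- colMeans(S)
  foot <- detect_foot(mean_curve, n_baseline_min)
  base <- rowMeans(S[, seq_len(foot - 1L), drop = FALSE])
  Y <- pmax(S - base, 0) / tissue_scale
  res <- fit_curves_matrix(Y, aif, series$times_s, config, foot = foot)
  shape <- frame_shape(series)
  mbf <- fit_rss <- matrix(NA_real_, shape[1], shape[2])
  conv <- matrix(NA, shape[1], shape[2])
  px <- which(myo_mask$mask)
  mbf[px] <- fermi_initial_height(res$amp, res$k, res$w) *
    config$flow_unit_constant
  fit_rss[px] <- res$rss
  conv[px] <- res$converged == 1L
  if (mean(res$converged == 1L) < 0.5)
    stop("more than 50% of myocardial pixels failed to converge")
  new_mbf_map(mbf, fit_rss, conv, myo_mask)
}
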