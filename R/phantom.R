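# Digital first-pass perfusion phantom. Emulates a dual-sequence stress
# perfusion acquisition: a saturation-recovery SSFP dynamic series (one frame
# per R-R interval), a proton-density-weighted reference frame (low flip
# angle, no saturation), and a separate low-resolution arterial-input series
# with a short effective saturation delay so its signal is near-linear in
# concentration. Tissue kinetics are generated with a one-compartment Kety
# model -- deliberately a different model class from the Fermi function used
# on the quantification side, so recovery tests are not circular. A smooth
# multiplicative coil gain field and Rician noise complete the forward model.

#' Saturation-recovery signal model parameters
#'
#' Stand-in readout model for the phantom: `S = s0 * (1 - exp(-ts * (r1_0 +
#' r * C)))` per tissue class. Values are generic 1.5 T literature-scale
#' choices, not a fit to any scanner; substitute your own to emulate a
#' different protocol.
#'
#' @param ts_s Saturation delay of the perfusion readout, seconds.
#' @param aif_ts_s Effective saturation delay of the low-resolution arterial
#'   input series; short so its signal stays near-linear in concentration.
#' @param r1_0_per_s Named pre-contrast longitudinal relaxation rates (1/s)
#'   for `myocardium`, `blood`, `body`, `lung`.
#' @param r1_relaxivity_per_mmol_s Contrast agent relaxivity, L/mmol/s.
#' @param s0 Named equilibrium signal per tissue class (arbitrary units).
#' @param pd_scale Proton-density frame gain relative to `s0` (low flip
#'   angle, no saturation preparation).
#' @return Object of class `signal_model_params`.
#' @export
signal_model_params <- function(
    ts_s = 0.05,
    aif_ts_s = 0.005,
    r1_0_per_s = c(myocardium = 1.0, blood = 0.625, body = 1.4, lung = 0.8),
    r1_relaxivity_per_mmol_s = 4.5,
    s0 = c(myocardium = 1.0, blood = 1.05, body = 0.95, lung = 0.15),
    pd_scale = 0.25) {
  p <- list(ts_s = ts_s, aif_ts_s = aif_ts_s, r1_0_per_s = r1_0_per_s,
            r1_relaxivity_per_mmol_s = r1_relaxivity_per_mmol_s,
            s0 = s0, pd_scale = pd_scale)
  if (any(unlist(p[c("ts_s", "aif_ts_s", "r1_relaxivity_per_mmol_s",
                     "pd_scale")]) <= 0) ||
      any(r1_0_per_s <= 0) || any(s0 <= 0))
    stop("all signal model parameters must be positive")
  structure(p, class = "signal_model_params")
}

#' Anterior-weighted surface-coil gain preset
#'
#' One exponential gain lobe just above the top edge of the grid, offset
#' toward the anteroseptal side of the heart (image left, where the
#' anteroseptum faces the chest-wall coil elements). Emulates the
#' anterior/ventral signal weighting of a phased-array chest coil: over the
#' default annulus the anterior sector receives roughly twice the mean gain
#' of the inferior sector, and the anterior + anteroseptal (LAD) sectors
#' about 1.5 times the mean gain of the remaining territory.
#'
#' @param grid_shape `(ny, nx)` image shape.
#' @return A list of gain lobes for [coil_gain_field()].
#' @export
anterior_coil_preset <- function(grid_shape) {
  ny <- grid_shape[1]; nx <- grid_shape[2]
  list(list(position_px = c(-0.05 * ny, (nx + 1) / 2 - 0.35 * nx),
            amplitude = 7, decay_px = 0.28 * ny))
}

#' Evaluate a sum-of-lobes coil gain field
#'
#' `g(y, x) = 1 + sum_l amplitude_l * exp(-dist((y, x), position_l) /
#' decay_l)`; strictly positive by construction for non-negative amplitudes.
#'
#' @param coil_gains List of lobes, each `list(position_px = c(y, x),
#'   amplitude, decay_px)`.
#' @param grid_shape `(ny, nx)`.
#' @return A strictly positive `ny x nx` matrix.
#' @export
coil_gain_field <- function(coil_gains, grid_shape) {
  if (length(coil_gains) < 1L) stop("need at least one gain lobe")
  ny <- grid_shape[1]; nx <- grid_shape[2]
  yy <- matrix(seq_len(ny), ny, nx)
  xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  g <- matrix(1, ny, nx)
  for (lobe in coil_gains) {
    d <- sqrt((yy - lobe$position_px[1])^2 + (xx - lobe$position_px[2])^2)
    g <- g + lobe$amplitude * exp(-d / lobe$decay_px)
  }
  if (any(g <= 0)) stop("gain field not strictly positive")
  g
}

#' Evaluate a polynomial gain field
#'
#' A gain field inside the model class of the third-order surface fit used
#' for surface-coil intensity correction: useful for exact-recovery
#' validation studies.
#'
#' @param coefficients 10 coefficients of `sum_{i+j<=3} c_ij x^i y^j` on
#'   coordinates normalized to `[-1, 1]^2`, ordered as in [fit_bias_surface()].
#' @param grid_shape `(ny, nx)`.
#' @return A strictly positive `ny x nx` matrix.
#' @export
polynomial_gain_field <- function(coefficients, grid_shape) {
  if (length(coefficients) != 10L) stop("need exactly 10 coefficients")
  ny <- grid_shape[1]; nx <- grid_shape[2]
  idx <- which(matrix(TRUE, ny, nx), arr.ind = TRUE)
  X <- poly_design_3(norm_coord(idx[, 2], nx), norm_coord(idx[, 1], ny))
  g <- matrix(X %*% coefficients, ny, nx)
  if (any(g <= 0)) stop("polynomial gain field not strictly positive")
  g
}

#' Phantom study specification
#'
#' Geometry, timing, kinetics, coil gain and noise of a synthetic
#' mid-ventricular stress perfusion study. Defaults follow a typical
#' single-slice acquisition: 60 frames at one frame per 1-s R-R interval, a
#' 128 x 128 grid with a myocardial annulus of radii 28/40 px, a 0.05
#' mmol/kg-scale bolus peaking at 4 mmol/L in blood, stress-level flow of
#' 2 mL/min/g in all territories, and baseline myocardial SNR 20.
#'
#' @param grid_shape `(ny, nx)`, both even.
#' @param myo_center_px `(y, x)` annulus centre; default grid centre.
#' @param myo_radii_px `(inner, outer)` annulus radii in px.
#' @param lv_radius_px LV blood-pool disc radius.
#' @param body_ellipse_px `(semi_y, semi_x)` body ellipse semi-axes.
#' @param rv_insertion_angle_deg Anterior RV insertion angle (degrees
#'   clockwise from vertical in the standard anterior-up display).
#' @param n_frames Number of frames (>= 10).
#' @param rr_interval_s R-R interval, seconds (frame spacing).
#' @param aif_params `list(t0_s, alpha, beta_s, peak_mmol_per_L)` of the
#'   gamma-variate bolus.
#' @param territory_mbf Named flows, mL/min/g, for `LAD`, `LCX`, `RCA`.
#' @param vd_ml_per_g Contrast distribution volume, mL/g.
#' @param coil_gains Gain lobes for [coil_gain_field()]; default anterior
#'   preset. May also be a precomputed gain matrix.
#' @param snr Rician SNR at baseline myocardial signal, or `NULL` for
#'   noise-free.
#' @param seed Integer RNG seed (mandatory; same seed, same study).
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(128, 128),
                         myo_center_px = (grid_shape + 1) / 2,
                         myo_radii_px = c(28, 40),
                         lv_radius_px = 24,
                         body_ellipse_px = c(0.45, 0.47) * grid_shape,
                         rv_insertion_angle_deg = -60,
                         n_frames = 60,
                         rr_interval_s = 1,
                         aif_params = list(t0_s = 8, alpha = 2.5, beta_s = 4,
                                           peak_mmol_per_L = 4),
                         territory_mbf = c(LAD = 2, LCX = 2, RCA = 2),
                         vd_ml_per_g = 0.15,
                         coil_gains = anterior_coil_preset(grid_shape),
                         snr = 20,
                         seed = 1L) {
  if (any(myo_radii_px <= 0) || myo_radii_px[1] >= myo_radii_px[2])
    stop("myocardial radii must be positive and nested (inner < outer)")
  if (lv_radius_px <= 0 || lv_radius_px >= myo_radii_px[1])
    stop("lv_radius_px must be positive and inside the annulus")
  if (n_frames < 10) stop("n_frames must be >= 10")
  if (vd_ml_per_g <= 0) stop("vd must be > 0")
  if (is.null(names(territory_mbf)) ||
      !setequal(names(territory_mbf), c("LAD", "LCX", "RCA")))
    stop("territory_mbf must be named LAD, LCX, RCA")
  if (any(territory_mbf < 0)) stop("territory flows must be >= 0")
  structure(list(grid_shape = as.integer(grid_shape),
                 myo_center_px = myo_center_px, myo_radii_px = myo_radii_px,
                 lv_radius_px = lv_radius_px, body_ellipse_px = body_ellipse_px,
                 rv_insertion_angle_deg = rv_insertion_angle_deg,
                 n_frames = as.integer(n_frames), rr_interval_s = rr_interval_s,
                 aif_params = aif_params,
                 territory_mbf = territory_mbf[c("LAD", "LCX", "RCA")],
                 vd_ml_per_g = vd_ml_per_g, coil_gains = coil_gains,
                 snr = snr, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Gamma-variate arterial bolus
#'
#' `Ca(t) = K (t - t0)^alpha exp(-(t - t0) / beta)` for `t > t0`, else 0,
#' with `K` chosen so the continuous-time maximum (at `t0 + alpha * beta`)
#' equals `peak_mmol_per_L`.
#'
#' @param aif_params `list(t0_s, alpha, beta_s, peak_mmol_per_L)`.
#' @param times_s Sample times, seconds.
#' @return A [concentration_curve()] with `foot_index` at the first sample
#'   after `t0_s` (when one exists).
#' @export
gamma_variate_aif <- function(aif_params, times_s) {
  a <- aif_params
  if (a$alpha <= 0 || a$beta_s <= 0)
    stop("gamma-variate shape parameters must be positive")
  K <- a$peak_mmol_per_L / ((a$alpha * a$beta_s)^a$alpha * exp(-a$alpha))
  dt <- times_s - a$t0_s
  v <- ifelse(dt > 0, K * dt^a$alpha * exp(-dt / a$beta_s), 0)
  foot <- which(dt > 0)[1]
  concentration_curve(v, times_s,
                      foot_index = if (is.na(foot)) NULL else foot)
}

#' Trapezoidal discrete-convolution matrix
#'
#' Lower-triangular matrix `C` such that `C %*% r` approximates the causal
#' convolution `(a * r)(t_i)` by the trapezoidal rule on a uniform grid,
#' where `r` is an impulse response sampled at lags `0, dt, 2 dt, ...`.
#' Shared by the phantom generator and the deconvolution fit.
#'
#' @param aif_values Input-function samples on the uniform grid.
#' @param dt Grid spacing, seconds.
#' @return An `n x n` matrix.
#' @export
conv_matrix <- function(aif_values, dt) {
  n <- length(aif_values)
  C <- matrix(0, n, n)
  if (n >= 2) {
    for (i in 2:n) {
      j <- seq_len(i)
      w <- rep(1, i); w[1] <- 0.5; w[i] <- 0.5
      C[i, i - j + 1] <- dt * w * aif_values[j]
    }
  }
  C
}

check_uniform_grid <- function(times_s) {
  if (length(times_s) < 2) stop("need at least 2 time samples")
  dts <- diff(times_s)
  dt <- mean(dts)
  if (max(abs(dts - dt)) > 1e-8 * dt)
    stop("time grid must be uniform for discrete deconvolution")
  dt
}

#' One-compartment Kety tissue curve
#'
#' `Ct(t) = (Ca * R)(t)` by trapezoidal discrete convolution with
#' `R(t) = f exp(-f t / vd)` (flow converted to per-second internally).
#' The returned concentration is per gram of tissue; multiply by tissue
#' density (1.05 g/mL) for a per-mL concentration.
#'
#' @param aif A [concentration_curve()] sampled on the output (uniform) grid.
#' @param f Flow, mL/min/g (>= 0).
#' @param vd Distribution volume, mL/g (> 0).
#' @return A [concentration_curve()] on the same grid.
#' @export
kety_tissue_curve <- function(aif, f, vd) {
  if (f < 0) stop("flow must be >= 0")
  if (vd <= 0) stop("vd must be > 0")
  dt <- check_uniform_grid(aif$times_s)
  f_s <- f / 60
  lags <- (seq_along(aif$times_s) - 1) * dt
  r <- f_s * exp(-f_s * lags / vd)
  ct <- as.vector(conv_matrix(aif$values, dt) %*% r)
  concentration_curve(ct, aif$times_s, foot_index = aif$foot_index)
}

#' Saturation-recovery signal
#'
#' `S = s0 * (1 - exp(-ts * (r1_0 + r * C)))`: monotone increasing and
#' saturating in concentration.
#'
#' @param conc Concentration(s), mmol/L, >= 0.
#' @param params A [signal_model_params()].
#' @param tissue_class One of `"myocardium"`, `"blood"`, `"body"`, `"lung"`.
#' @param ts_s Saturation delay; defaults to the perfusion readout's.
#' @return Signal value(s), same length as `conc`.
#' @export
sr_signal <- function(conc, params, tissue_class, ts_s = params$ts_s) {
  if (any(conc < 0)) stop("concentration must be >= 0")
  r1 <- params$r1_0_per_s[[tissue_class]] +
    params$r1_relaxivity_per_mmol_s * conc
  params$s0[[tissue_class]] * (1 - exp(-ts_s * r1))
}

# Small-concentration slope of baseline-normalized SR signal: the linear
# calibration constant used when converting signal to concentration.
# d(S/S_base)/dC at C = 0; s0 cancels.
sr_linear_calibration <- function(params, tissue_class, ts_s = params$ts_s) {
  r1_0 <- params$r1_0_per_s[[tissue_class]]
  ts_s * params$r1_relaxivity_per_mmol_s * exp(-ts_s * r1_0) /
    (1 - exp(-ts_s * r1_0))
}

# --- geometry helpers ---------------------------------------------------

grid_coords <- function(grid_shape) {
  ny <- grid_shape[1]; nx <- grid_shape[2]
  list(yy = matrix(seq_len(ny), ny, nx),
       xx = matrix(seq_len(nx), ny, nx, byrow = TRUE))
}

phantom_geometry <- function(spec) {
  g <- grid_coords(spec$grid_shape)
  cy <- spec$myo_center_px[1]; cx <- spec$myo_center_px[2]
  r <- sqrt((g$yy - cy)^2 + (g$xx - cx)^2)
  myo <- r >= spec$myo_radii_px[1] & r <= spec$myo_radii_px[2]
  blood <- r <= spec$lv_radius_px
  body <- ((g$yy - cy) / spec$body_ellipse_px[1])^2 +
    ((g$xx - cx) / spec$body_ellipse_px[2])^2 <= 1
  ny <- spec$grid_shape[1]; nx <- spec$grid_shape[2]
  lung <- matrix(FALSE, ny, nx)
  for (sgn in c(-1, 1)) {
    lcx <- cx + sgn * 0.42 * nx
    lung <- lung | (((g$yy - cy) / (0.22 * ny))^2 +
                      ((g$xx - lcx) / (0.08 * nx))^2 <= 1)
  }
  lung <- lung & body & !myo & !blood
  # tissue class map: 0 background, 1 myocardium, 2 blood, 3 body, 4 lung
  class_map <- matrix(0L, ny, nx)
  class_map[body] <- 3L
  class_map[lung] <- 4L
  class_map[blood] <- 2L
  class_map[myo] <- 1L
  list(myo = myo, blood = blood, body = body, lung = lung,
       class_map = class_map)
}

block_mean <- function(mat, f = 2L) {
  ny <- (nrow(mat) %/% f) * f; nx <- (ncol(mat) %/% f) * f
  m <- mat[seq_len(ny), seq_len(nx)]
  a <- array(m, c(f, ny %/% f, f, nx %/% f))
  apply(a, c(2, 4), mean)
}

rician <- function(signal, sigma) {
  n <- length(signal)
  sqrt((signal + rnorm(n, 0, sigma))^2 + rnorm(n, 0, sigma)^2)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

territory_of_sector <- function() {
  c(anterior = "LAD", anterolateral = "LCX", inferolateral = "LCX",
    inferior = "RCA", inferoseptum = "RCA", anteroseptum = "LAD")
}

#' Generate a synthetic dual-sequence perfusion study
#'
#' Builds the perfusion series, proton-density reference frame, and
#' low-resolution arterial-input series for the geometry, kinetics, coil
#' gain and noise level in `spec`, together with the ground truth (flow map,
#' gain field, masks, true input function, sector labels). The same spec and
#' seed always produce bit-identical output.
#'
#' @param spec A [phantom_spec()].
#' @param signal A [signal_model_params()].
#' @return A list of class `phantom_study`: `perfusion`, `pd`, `aif`
#'   ([dynamic_series()]), `truth` (fields `mbf_true`, `gain_true`, `masks`,
#'   `aif_true`, `segment_labels`, `territory_mbf`), plus the `spec` and
#'   `signal` used.
#' @export
generate_phantom <- function(spec, signal = signal_model_params()) {
  geo <- phantom_geometry(spec)
  if (sum(geo$myo) < 10) stop("geometry leaves fewer than 10 myocardial pixels")
  ny <- spec$grid_shape[1]; nx <- spec$grid_shape[2]
  nt <- spec$n_frames
  times <- (seq_len(nt) - 1) * spec$rr_interval_s

  myo_mask <- roi_mask(geo$myo, "myocardium")
  labels <- sectorize(myo_mask, spec$myo_center_px, spec$rv_insertion_angle_deg)
  terr <- territory_of_sector()[SECTOR_NAMES]

  aif_true <- gamma_variate_aif(spec$aif_params, times)

  # per-territory tissue concentration, per mL of tissue (density 1.05 g/mL)
  ct_by_territory <- lapply(c(LAD = "LAD", LCX = "LCX", RCA = "RCA"), function(tn)
    1.05 * kety_tissue_curve(aif_true, spec$territory_mbf[[tn]],
                             spec$vd_ml_per_g)$values)

  mbf_true <- matrix(NA_real_, ny, nx)
  sector_px <- lapply(1:6, function(s) which(!is.na(labels$labels) &
                                               labels$labels == s))
  for (s in 1:6)
    mbf_true[sector_px[[s]]] <- spec$territory_mbf[[terr[s]]]

  gain <- if (is.matrix(spec$coil_gains)) spec$coil_gains else
    coil_gain_field(spec$coil_gains, spec$grid_shape)

  # noise-free signal stack at perfusion readout
  base_sig <- c(sr_signal(0, signal, "myocardium"), sr_signal(0, signal, "blood"),
                sr_signal(0, signal, "body"), sr_signal(0, signal, "lung"))
  blood_sig <- sr_signal(aif_true$values, signal, "blood")
  myo_sig_by_sector <- lapply(1:6, function(s)
    sr_signal(ct_by_territory[[terr[s]]], signal, "myocardium"))
  perf <- array(0, c(ny, nx, nt))
  for (k in 1:4) {
    px <- which(geo$class_map == k)
    if (length(px)) perf[px + rep((0:(nt - 1)) * ny * nx, each = length(px))] <-
        base_sig[k]
  }
  blood_px <- which(geo$class_map == 2L)
  frame_off <- (0:(nt - 1)) * ny * nx
  perf[rep(blood_px, nt) + rep(frame_off, each = length(blood_px))] <-
    rep(blood_sig, each = length(blood_px))
  for (s in 1:6) {
    px <- sector_px[[s]]
    perf[rep(px, nt) + rep(frame_off, each = length(px))] <-
      rep(myo_sig_by_sector[[s]], each = length(px))
  }
  perf <- perf * as.vector(gain)  # recycles over frames (column-major)

  pd <- signal$pd_scale * gain *
    ifelse(geo$class_map > 0, signal$s0[c("myocardium", "blood", "body",
                                          "lung")][pmax(geo$class_map, 1L)], 0)

  # low-resolution arterial-input series: short-TS readout, 2x downsampled
  aif_base <- c(sr_signal(0, signal, "myocardium", signal$aif_ts_s),
                sr_signal(0, signal, "blood", signal$aif_ts_s),
                sr_signal(0, signal, "body", signal$aif_ts_s),
                sr_signal(0, signal, "lung", signal$aif_ts_s))
  aif_blood_sig <- sr_signal(aif_true$values, signal, "blood", signal$aif_ts_s)
  class_sig0 <- matrix(0, ny, nx)
  for (k in 1:4) class_sig0[geo$class_map == k] <- aif_base[k]
  nylo <- ny %/% 2L; nxlo <- nx %/% 2L
  aif_arr <- array(0, c(nylo, nxlo, nt))
  base_lo <- block_mean(class_sig0 * gain)
  blood_frac <- block_mean((geo$class_map == 2L) * 1)
  gain_blood_lo <- block_mean((geo$class_map == 2L) * gain)
  for (i in seq_len(nt))
    aif_arr[, , i] <- base_lo +
      gain_blood_lo * (aif_blood_sig[i] - aif_base[2])
  blood_lo <- blood_frac == 1

  if (!is.null(spec$snr)) {
    sigma_perf <- mean((base_sig[1] * gain)[geo$myo]) / spec$snr
    sigma_aif <- mean(base_lo[blood_lo]) / spec$snr
    noisy <- with_seed(spec$seed, {
      p <- array(rician(perf, sigma_perf), dim(perf))
      d <- matrix(rician(pd, sigma_perf), ny, nx)
      a <- array(rician(aif_arr, sigma_aif), dim(aif_arr))
      list(p = p, d = d, a = a)
    })
    perf <- noisy$p; pd <- noisy$d; aif_arr <- noisy$a
  }

  spacing <- c(1, 1)
  truth <- structure(list(
    mbf_true = mbf_true,
    gain_true = gain,
    masks = list(
      myocardium = myo_mask,
      body = roi_mask(geo$body, "body"),
      blood_pool = roi_mask(geo$blood, "blood_pool"),
      blood_pool_aif = roi_mask(blood_lo, "blood_pool")),
    aif_true = aif_true,
    segment_labels = labels,
    territory_mbf = spec$territory_mbf), class = "phantom_truth")

  structure(list(
    perfusion = dynamic_series(perf, times, spacing, "perfusion"),
    pd = dynamic_series(pd, 0, spacing, "pd"),
    aif = dynamic_series(aif_arr, times, spacing * 2, "aif"),
    truth = truth, spec = spec, signal = signal), class = "phantom_study")
}
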