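# Shared fixtures: all synthetic, built in code at test time.

default_aif_params <- list(t0_s = 8, alpha = 2.5, beta_s = 4,
                           peak_mmol_per_L = 4)

default_aif <- function(times = as.numeric(0:59))
  gamma_variate_aif(default_aif_params, times)

# flat (unit) gain field as a lobe list
uniform_gain <- function()
  list(list(position_px = c(1, 1), amplitude = 0, decay_px = 10))

# compact study geometry used for replicate experiments: 48x48 grid,
# annulus radii 10/16 px (~490 myocardial pixels), 60 frames at 1 s
small_spec <- function(seed = 1L, snr = 20,
                       territory_mbf = c(LAD = 2, LCX = 2, RCA = 2),
                       coil_gains = anterior_coil_preset(c(48, 48)), ...) {
  phantom_spec(grid_shape = c(48, 48), myo_radii_px = c(10, 16),
               lv_radius_px = 8, snr = snr, seed = seed,
               territory_mbf = territory_mbf, coil_gains = coil_gains, ...)
}

# annulus + body-ellipse masks on an arbitrary grid (for surface-fit tests)
test_masks <- function(gs = c(64, 64), radii = c(14, 20), body = c(0.45, 0.47)) {
  cy <- (gs[1] + 1) / 2; cx <- (gs[2] + 1) / 2
  yy <- matrix(seq_len(gs[1]), gs[1], gs[2])
  xx <- matrix(seq_len(gs[2]), gs[1], gs[2], byrow = TRUE)
  r <- sqrt((yy - cy)^2 + (xx - cx)^2)
  list(myo = roi_mask(r >= radii[1] & r <= radii[2], "myocardium"),
       body = roi_mask(((yy - cy) / (body[1] * gs[1]))^2 +
                         ((xx - cx) / (body[2] * gs[2]))^2 <= 1, "body"))
}

# positive cubic on [-1,1]^2, inside the model class of the order-3 fit
test_cubic_coefs <- c(2, 0.5, 0.4, 0.15, 0.2, -0.1, -0.08, 0.1, 0.05, -0.06)

# trapezoidal causal convolution by direct double loop (independent oracle)
conv_loop <- function(a, r, dt) {
  n <- length(a)
  out <- numeric(n)
  if (n >= 2) for (i in 2:n) {
    s <- 0
    for (j in 1:i) {
      wgt <- if (j == 1 || j == i) 0.5 else 1
      s <- s + wgt * a[j] * r[i - j + 1]
    }
    out[i] <- dt * s
  }
  out
}

# random valid dynamic series for round-trip tests
random_series <- function() {
  ny <- sample(3:8, 1); nx <- sample(3:8, 1); nt <- sample(1:4, 1)
  role <- sample(c("perfusion", "aif", "pd"), 1)
  dynamic_series(array(abs(rnorm(ny * nx * nt)), c(ny, nx, nt)),
                 times_s = cumsum(runif(nt, 0.5, 1.5)),
                 pixel_spacing_mm = runif(2, 0.5, 3), series_role = role)
}
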