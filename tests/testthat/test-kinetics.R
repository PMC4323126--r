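test_that("curve extraction averages exactly over the mask", {
  fr <- array(0, c(3, 3, 4))
  fr[1, 1, ] <- c(1, 2, 3, 4)
  fr[2, 2, ] <- c(3, 4, 5, 6)
  s <- dynamic_series(fr, 1:4)

  flat <- dynamic_series(array(7, c(3, 3, 4)), 1:4)
  all_m <- roi_mask(matrix(TRUE, 3, 3), "myocardium")
  expect_equal(extract_curve(flat, all_m), rep(7, 4))

  one <- matrix(FALSE, 3, 3); one[2, 2] <- TRUE
  expect_equal(extract_curve(s, roi_mask(one, "myocardium")), c(3, 4, 5, 6))

  two <- one; two[1, 1] <- TRUE
  expect_equal(extract_curve(s, roi_mask(two, "myocardium")),
               (c(1, 2, 3, 4) + c(3, 4, 5, 6)) / 2)
  expect_equal(extract_pixel_curves(s, roi_mask(two, "myocardium")),
               rbind(c(1, 2, 3, 4), c(3, 4, 5, 6)))
  expect_error(extract_curve(s, roi_mask(matrix(FALSE, 3, 3), "body")),
               "empty mask")
})

test_that("foot detection implements the threshold rule and is shift
           invariant", {
  # hand evaluation: threshold 10 + max(0, 0.05 * 70) = 13.5; the 30 at the
  # sixth sample (1-based) is the first to exceed it
  curve <- c(10, 10, 10, 10, 10, 30, 80)
  expect_identical(detect_foot(curve, 4), 6L)
  expect_identical(detect_foot(curve + 100, 4), 6L)

  expect_error(detect_foot(rep(5, 20), 4), "no contrast")
  expect_error(detect_foot(c(1, 2, 3), 4), "too short")

  # 3*SD branch: noisy baseline raises the threshold above the 5% rule
  set.seed(1)
  base <- 10 + rnorm(8, 0, 2)
  curve2 <- c(base, 10, 10, 11, 30, 80)
  thr <- mean(base) + max(3 * sd(base), 0.05 * (80 - mean(base)))
  expect_identical(detect_foot(curve2, 8),
                   which(curve2 > thr & seq_along(curve2) > 8)[1])
})

test_that("linear concentration conversion subtracts baseline, clips and
           rescales", {
  v <- c(5, 5, 5, 5, 5, 3, 9, 15)
  cc <- signal_to_concentration(v, 0:7, foot = 6)
  expect_equal(cc$values[1:5], rep(0, 5))  # constant pre-foot baseline
  expect_equal(cc$values[6], 0)            # negative excursion clipped
  expect_equal(cc$values[7:8], c(4, 10))
  expect_identical(cc$foot_index, 6L)

  cc2 <- signal_to_concentration(v, 0:7, foot = 6, scale = 2)
  expect_equal(cc2$values, cc$values / 2)
  expect_error(signal_to_concentration(v, 0:7, foot = 1), "baseline")
})

test_that("the Fermi impulse response has its closed-form landmarks", {
  p <- fermi_params(0.04, 0.5, 3, delay_s = 2)
  tt <- seq(0, 40, by = 0.25)
  r <- fermi_response(p, tt)
  expect_true(all(r[tt < 2] == 0))
  expect_equal(fermi_response(p, 2 + 3), 0.02)
  expect_true(all(diff(r[tt >= 2]) <= 0))
  # infinite shoulder: plateau at amp over any fixed window
  p2 <- fermi_params(0.04, 0.5, 1e6, delay_s = 0)
  expect_equal(fermi_response(p2, tt), rep(0.04, length(tt)),
               tolerance = 1e-12)
  expect_error(fermi_params(-1, 1, 1), ">= 0")
  expect_error(fermi_params(1, 0, 1), "> 0")
})

test_that("the trapezoidal convolution matrix equals a direct double loop", {
  set.seed(5)
  for (i in 1:20) {
    n <- 5
    a <- runif(n); r <- runif(n); dt <- runif(1, 0.5, 2)
    expect_equal(as.vector(conv_matrix(a, dt) %*% r), conv_loop(a, r, dt),
                 tolerance = 1e-14)
  }
})

test_that("deconvolution recovers its own model exactly and the Kety model
           within tolerance", {
  times <- as.numeric(0:59)
  aif <- default_aif(times)

  # degenerate tissue: zero flow, amplitude at its lower bound
  z <- fit_pixel(aif, concentration_curve(rep(0, 60), times))
  expect_equal(z$mbf, 0)
  expect_equal(z$params$amp, 0)

  # self-consistency at delay 0, where the discrete model is identifiable
  p <- fermi_params(0.035, 0.4, 4, delay_s = 0)
  ct <- as.vector(conv_matrix(aif$values, 1) %*% fermi_response(p, times))
  f1 <- fit_pixel(aif, concentration_curve(ct, times,
                                           foot_index = aif$foot_index))
  true_mbf <- fermi_response(p, 0) * 60 / 1.05
  expect_lt(abs(f1$mbf - true_mbf) / true_mbf, 1e-3)
  expect_true(f1$diagnostics$converged)

  # cross-model: one-compartment tissue, concentration per mL (x1.05 g/mL)
  fk <- fit_pixel(aif, concentration_curve(
    1.05 * kety_tissue_curve(aif, 2, 0.15)$values, times,
    foot_index = aif$foot_index))
  expect_lt(abs(fk$mbf - 2) / 2, 0.10)
})

test_that("recovered flow is equivariant under concentration rescaling", {
  times <- as.numeric(0:59)
  aif <- default_aif(times)
  tis <- concentration_curve(1.05 * kety_tissue_curve(aif, 2, 0.15)$values,
                             times, foot_index = aif$foot_index)
  base <- fit_pixel(aif, tis)$mbf
  for (cf in c(0.5, 2)) {
    aif_c <- concentration_curve(cf * aif$values, times,
                                 foot_index = aif$foot_index)
    tis_c <- concentration_curve(cf * tis$values, times,
                                 foot_index = tis$foot_index)
    expect_equal(fit_pixel(aif_c, tis)$mbf, base / cf, tolerance = 1e-9)
    expect_equal(fit_pixel(aif_c, tis_c)$mbf, base, tolerance = 1e-9)
  }
})

test_that("recovered flow is stable under time-grid refinement", {
  t1 <- as.numeric(0:59)
  t2 <- seq(0, 59, by = 0.5)
  f <- 2
  m1 <- fit_pixel(default_aif(t1), concentration_curve(
    1.05 * kety_tissue_curve(default_aif(t1), f, 0.15)$values, t1,
    foot_index = default_aif(t1)$foot_index))$mbf
  m2 <- fit_pixel(default_aif(t2), concentration_curve(
    1.05 * kety_tissue_curve(default_aif(t2), f, 0.15)$values, t2,
    foot_index = default_aif(t2)$foot_index))$mbf
  expect_lt(abs(m2 - m1) / m1, 0.02)
})

test_that("pixel-wise maps are uniform, ordered, deterministic and unbiased
           where they should be", {
  # uniform flow, uniform gain, no noise: every pixel sees the same curve
  st <- generate_phantom(small_spec(snr = NULL, coil_gains = uniform_gain()))
  q <- quantify_study(st, "none")
  myo <- st$truth$masks$myocardium$mask
  expect_lt(100 * sd(q$map$mbf[myo]) / mean(q$map$mbf[myo]), 1)

  # two flow levels: territory means ordered and each within 10% of truth
  st2 <- generate_phantom(small_spec(
    snr = NULL, coil_gains = uniform_gain(),
    territory_mbf = c(LAD = 1, LCX = 2, RCA = 2)))
  q2 <- quantify_study(st2, "none")
  sm <- sector_stats(q2$map, q2$labels)
  lad <- mean(sm[c("anterior", "anteroseptum")])
  rem <- mean(sm[c("anterolateral", "inferolateral", "inferior",
                   "inferoseptum")])
  expect_lt(lad, rem)
  expect_lt(abs(lad - 1) / 1, 0.10)
  expect_lt(abs(rem - 2) / 2, 0.10)

  # determinism of the full map path
  q2b <- quantify_study(st2, "none")
  expect_identical(q2$map$mbf, q2b$map$mbf)

  # noise behaviour: mean pixel MBF over a uniform region unbiased within 5%
  stn <- generate_phantom(phantom_spec(
    grid_shape = c(52, 52), myo_radii_px = c(11, 17), lv_radius_px = 9,
    coil_gains = uniform_gain(), snr = 20, seed = 33))
  qn <- quantify_study(stn, "none")
  v <- qn$map$mbf[stn$truth$masks$myocardium$mask]
  expect_gte(length(v), 500)
  expect_lt(abs(mean(v) - 2) / 2, 0.05)
})
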