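test_that("body-mask construction applies the intensity band around the
           myocardial median", {
  m <- test_masks(c(40, 40), radii = c(8, 12))
  ref <- matrix(10, 40, 40)

  b <- build_body_mask(ref, m$myo, m$body, 0.5, 2.0)
  expect_identical(b$mask, m$body$mask & !m$myo$mask)

  ref2 <- ref
  ref2[1:10, 1:10] <- 50  # bright fat-like patch at 5x the median
  b2 <- build_body_mask(ref2, m$myo, m$body, 0.5, 2.0)
  expect_false(any(b2$mask[1:10, 1:10]))

  # lung-like dark region plus random texture: pixel-by-pixel band oracle
  set.seed(7)
  ref3 <- matrix(10 * exp(rnorm(1600, 0, 0.3)), 40, 40)
  ref3[25:34, 4:10] <- 1
  b3 <- build_body_mask(ref3, m$myo, m$body, 0.5, 2.0)
  med <- median(ref3[m$myo$mask])
  oracle <- m$body$mask & !m$myo$mask &
    ref3 >= 0.5 * med & ref3 <= 2.0 * med
  expect_identical(b3$mask, oracle)
  expect_false(any(b3$mask[25:34, 4:10]))

  expect_error(build_body_mask(ref, m$myo, m$body, 1.5, 2.0), "lo_frac")
  expect_error(build_body_mask(ref * 0 + 1e9, m$myo,
                               roi_mask(matrix(FALSE, 40, 40), "body")),
               "empty")
})

test_that("the polynomial surface fit recovers in-class gain fields", {
  m <- test_masks(c(64, 64))

  # constant reference: field is 1 everywhere after normalization
  fb <- fit_bias_surface(matrix(5, 64, 64), m$myo, m$body)
  expect_lt(max(abs(fb$bias$field - 1)), 1e-9)
  expect_length(fb$fit$coefficients, 10L)

  # linear ramp (in model class): exact recovery up to scalar
  xn <- matrix(2 * (seq_len(64) - 1) / 63 - 1, 64, 64, byrow = TRUE)
  ramp <- 100 * (1 + 0.5 * xn)
  fb2 <- fit_bias_surface(ramp, m$myo, m$body)
  target <- ramp / mean(ramp[m$myo$mask])
  expect_lt(max(abs(fb2$bias$field / target - 1)), 1e-6)
  expect_lt(fb2$fit$rms_residual, 1e-9)

  # full cubic recovered over the fitted region
  g <- polynomial_gain_field(test_cubic_coefs, c(64, 64))
  fb3 <- fit_bias_surface(3 * g, m$myo, m$body)
  un <- m$myo$mask | m$body$mask
  ratio <- fb3$bias$field[un] / (g / mean(g[m$myo$mask]))[un]
  expect_lt(max(abs(ratio - 1)), 1e-6)

  # exactly 10 pixels in general position: interpolation, zero residual
  set.seed(3)
  px <- matrix(FALSE, 64, 64)
  px[cbind(sample(5:60, 10), sample(5:60, 10))] <- TRUE
  fb4 <- fit_bias_surface(3 * g, roi_mask(px, "myocardium"),
                          roi_mask(matrix(FALSE, 64, 64), "body"))
  expect_lt(fb4$fit$rms_residual, 1e-9)

  # degenerate geometry: all pixels on one column cannot fix 10 coefficients
  col_mask <- matrix(FALSE, 64, 64); col_mask[10:40, 20] <- TRUE
  expect_error(fit_bias_surface(3 * g, roi_mask(col_mask, "myocardium"),
                                roi_mask(matrix(FALSE, 64, 64), "body")),
               "rank-deficient")
  expect_error(fit_bias_surface(matrix(-1, 4, 4),
                                roi_mask(matrix(TRUE, 4, 4), "myocardium"),
                                roi_mask(matrix(FALSE, 4, 4), "body")),
               ">= 0")
})

test_that("bias application is exact multiplicative inversion", {
  truth <- dynamic_series(array(runif(5 * 5 * 4, 1, 2), c(5, 5, 4)), 1:4)
  g <- matrix(runif(25, 0.5, 2), 5, 5)
  g <- g / mean(g)
  bias <- bias_field(g, "myocardium")

  expect_equal(apply_scic(truth, bias_field(matrix(1, 5, 5)))$frames,
               truth$frames)
  corrupted <- with_frames(truth, truth$frames * as.vector(g))
  rec <- apply_scic(corrupted, bias)
  expect_equal(rec$frames, truth$frames, tolerance = 1e-12)
  expect_identical(rec$times_s, truth$times_s)

  g2 <- matrix(runif(25, 0.5, 2), 5, 5); g2 <- g2 / mean(g2)
  lhs <- apply_scic(apply_scic(truth, bias), bias_field(g2))
  rhs <- apply_scic(truth, bias_field(g * g2 / mean(g * g2)))
  expect_equal(rhs$frames, lhs$frames * mean(g * g2), tolerance = 1e-12)

  expect_error(apply_scic(truth, bias_field(matrix(1, 4, 4))),
               "does not match")
})

test_that("baseline normalization scales by the myocardial baseline and
           preserves spatial variation", {
  m <- test_masks(c(40, 40), radii = c(8, 12))
  fr <- array(50, c(40, 40, 10))
  fr[, , 7:10] <- 150
  s <- dynamic_series(fr, 0:9)
  bn <- baseline_normalize(s, m$myo, 4)
  expect_equal(bn$scale, 50)
  expect_equal(mean(get_frame(bn$series, 1)[m$myo$mask]), 1)

  bn2 <- baseline_normalize(bn$series, m$myo, 4)
  expect_equal(bn2$scale, 1)
  expect_equal(bn2$series$frames, bn$series$frames)

  # scalar division leaves the spatial CoV of a gain-corrupted frame alone
  g <- coil_gain_field(anterior_coil_preset(c(40, 40)), c(40, 40))
  sg <- dynamic_series(array(50 * as.vector(g), c(40, 40, 10)), 0:9)
  bng <- baseline_normalize(sg, m$myo, 4)
  expect_equal(cov_si(get_frame(bng$series, 1), m$myo),
               cov_si(get_frame(sg, 1), m$myo))

  expect_error(baseline_normalize(s, m$myo, 0), "n_baseline")
  expect_error(baseline_normalize(s, m$myo, 10), "n_baseline")
})

test_that("run_scic dispatches the three arms consistently", {
  # uniform gain, no noise, contrast-free PD reference (uniform proton
  # density): the PD fit finds a flat field, so PD and no-SCIC corrected
  # series agree
  flat_sig <- signal_model_params(s0 = c(myocardium = 1, blood = 1,
                                         body = 1, lung = 1))
  st <- generate_phantom(small_spec(snr = NULL, coil_gains = uniform_gain()),
                         signal = flat_sig)
  masks <- list(myocardium = st$truth$masks$myocardium,
                body = st$truth$masks$body)
  s_none <- run_scic("none", st$perfusion, st$pd, masks)
  s_pd <- run_scic("pd", st$perfusion, st$pd, masks)
  expect_equal(s_pd$frames, s_none$frames, tolerance = 1e-6)

  # uniform tissue: PD and SSFP references are scalar multiples of the same
  # gain, so the fitted bias fields agree up to scalar
  gs <- c(48, 48)
  m <- test_masks(gs, radii = c(10, 16), body = c(0.45, 0.47))
  g <- coil_gain_field(anterior_coil_preset(gs), gs)
  perf <- dynamic_series(array(0.05 * as.vector(g), c(gs, 10)), 0:9)
  pd1 <- dynamic_series(0.25 * g, 0, series_role = "pd")
  d_pd <- run_scic("pd", perf, pd1, list(myocardium = m$myo, body = m$body),
                   details = TRUE)
  d_sf <- run_scic("ssfp", perf, NULL, list(myocardium = m$myo, body = m$body),
                   details = TRUE)
  expect_lt(max(abs(d_sf$bias$field / d_pd$bias$field - 1)), 1e-3)

  # gain-corrupted noisy study: correction reduces the reference-image CoV
  stn <- generate_phantom(small_spec(seed = 21))
  d <- run_scic("pd", stn$perfusion, stn$pd,
                list(myocardium = stn$truth$masks$myocardium,
                     body = stn$truth$masks$body), details = TRUE)
  myo <- stn$truth$masks$myocardium
  expect_lt(cov_si(d$reference_corrected, myo), cov_si(d$reference, myo))

  expect_error(run_scic("pd", st$perfusion, NULL, masks), "proton-density")
  expect_error(run_scic("ssfp", st$perfusion, NULL, masks,
                        ssfp_ref_frame = 9), "baseline")
})
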