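brute_force_sectors <- function(mask, center, rv_deg) {
  # independent pixel-angle loop
  out <- matrix(NA_integer_, nrow(mask), ncol(mask))
  for (y in seq_len(nrow(mask))) for (x in seq_len(ncol(mask))) {
    if (!mask[y, x]) next
    ang <- atan2(x - center[2], -(y - center[1])) * 180 / pi
    out[y, x] <- as.integer((floor(((ang - rv_deg) %% 360) / 60) %% 6) + 1)
  }
  out
}

make_map <- function(values, mask, converged = NULL) {
  mbf <- matrix(NA_real_, nrow(mask$mask), ncol(mask$mask))
  mbf[mask$mask] <- values
  conv <- matrix(NA, nrow(mbf), ncol(mbf))
  conv[mask$mask] <- if (is.null(converged)) TRUE else converged
  mbf[mask$mask & !conv] <- 0  # value is irrelevant, must just be non-NA
  new_mbf_map(mbf, ifelse(is.na(mbf), NA_real_, 0), conv, mask)
}

test_that("sectorization follows the clockwise AHA order from the RV
           insertion point", {
  gs <- c(41, 41); ctr <- c(21, 21)
  yy <- matrix(seq_len(gs[1]), gs[1], gs[2])
  xx <- matrix(seq_len(gs[2]), gs[1], gs[2], byrow = TRUE)
  r <- sqrt((yy - ctr[1])^2 + (xx - ctr[2])^2)
  annulus <- roi_mask(r >= 8 & r <= 15, "myocardium")

  lab <- sectorize(annulus, ctr, -60)
  # a pixel 30 degrees clockwise of the insertion point sits mid-sector-1:
  # insertion at -60, so -30 in display terms = up and slightly left
  ang <- (-30) * pi / 180
  px <- c(round(21 - 12 * cos(ang)), round(21 + 12 * sin(ang)))
  expect_identical(lab$labels[px[1], px[2]], 1L)
  # mid-sector-4 direction (display angle 150 degrees) = inferior
  expect_identical(lab$labels[31, 27], 4L)

  # full-turn periodicity
  lab2 <- sectorize(annulus, ctr, -60 + 360)
  expect_identical(lab$labels, lab2$labels)

  # equal sectors cover equal areas on a symmetric annulus (large enough
  # that pixelation stays under the tolerance)
  big <- 101; bctr <- c(51, 51)
  byy <- matrix(seq_len(big), big, big)
  bxx <- matrix(seq_len(big), big, big, byrow = TRUE)
  br <- sqrt((byy - bctr[1])^2 + (bxx - bctr[2])^2)
  bann <- roi_mask(br >= 20 & br <= 37, "myocardium")
  blab <- sectorize(bann, bctr, -60)
  counts <- tabulate(blab$labels[bann$mask], 6)
  expect_true(all(abs(counts - sum(counts) / 6) <= 0.02 * sum(counts) / 6))

  # exact agreement with the brute-force pixel loop
  expect_identical(lab$labels, brute_force_sectors(annulus$mask, ctr, -60))

  expect_error(sectorize(roi_mask(matrix(FALSE, 5, 5), "myocardium"),
                         c(3, 3), 0), "empty")
})

test_that("signal CoV and MBF heterogeneity are the sample-SD ratios in
           percent", {
  mask3 <- roi_mask(matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2), "myocardium")
  img <- matrix(c(8, 10, 12, 99), 2, 2)
  expect_equal(cov_si(img, mask3), 20)
  expect_equal(cov_si(matrix(4, 2, 2),
                      roi_mask(matrix(TRUE, 2, 2), "myocardium")), 0)
  expect_equal(cov_si(3.7 * img, mask3), cov_si(img, mask3))
  expect_error(cov_si(img * 0, mask3), "non-positive")

  m <- make_map(c(1, 2, 3), mask3)
  expect_equal(heterogeneity(m), 50)
  expect_equal(heterogeneity(make_map(c(2, 2, 2), mask3)), 0)

  # a non-converged outlier is excluded from the statistic
  mask4 <- roi_mask(matrix(TRUE, 2, 2), "myocardium")
  m2 <- make_map(c(1, 2, 3, 1000), mask4,
                 converged = c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(heterogeneity(m2), 50)
})

test_that("sector means, septal-lateral and remote-ischaemic differences
           compose correctly", {
  gs <- c(41, 41); ctr <- c(21, 21)
  yy <- matrix(seq_len(gs[1]), gs[1], gs[2])
  xx <- matrix(seq_len(gs[2]), gs[1], gs[2], byrow = TRUE)
  r <- sqrt((yy - ctr[1])^2 + (xx - ctr[2])^2)
  annulus <- roi_mask(r >= 8 & r <= 15, "myocardium")
  lab <- sectorize(annulus, ctr, -60)

  v <- as.double(lab$labels[annulus$mask])  # map equal to its sector index
  m <- make_map(v, annulus)
  sm <- sector_stats(m, lab)
  expect_equal(unname(sm), as.double(1:6))

  u <- make_map(rep(2.5, sum(annulus$mask)), annulus)
  expect_equal(unname(sector_stats(u, lab)), rep(2.5, 6))
  expect_equal(septal_lateral_difference(sector_stats(u, lab)), 0)

  # brute-force masked means per sector
  oracle <- sapply(1:6, function(s)
    mean(m$mbf[annulus$mask & lab$labels == s]))
  expect_equal(unname(sm), oracle)

  sm2 <- c(anterior = 1, anterolateral = 1.5, inferolateral = 1.5,
           inferior = 9, inferoseptum = 3, anteroseptum = 3)
  expect_equal(septal_lateral_difference(sm2), 1.5)
  sm3 <- sm2
  sm3[c("anteroseptum", "inferoseptum")] <- 1.5
  sm3[c("anterolateral", "inferolateral")] <- 3
  expect_equal(septal_lateral_difference(sm3),
               -septal_lateral_difference(sm2))

  sm4 <- c(anterior = 1, anterolateral = 2, inferolateral = 2,
           inferior = 2, inferoseptum = 2, anteroseptum = 1)
  ri <- remote_ischaemic_difference(sm4, territory_assignment("LAD"))
  expect_equal(ri$remote, 2)
  expect_equal(ri$ischaemic, 1)
  expect_equal(ri$difference, 1)
  expect_equal(
    remote_ischaemic_difference(u5 <- setNames(rep(2, 6), names(sm4)),
                                territory_assignment("LCX"))$difference, 0)
  expect_error(territory_assignment(c("LAD", "LCX", "RCA")), "no remote")
  expect_error(territory_assignment(character(0)), "nonempty")
})

test_that("the paired t-test matches its closed form and reference
           implementation", {
  # pairs (1,2), (2,4), (3,3): d = (-1, -2, 0), t = -sqrt(3), df = 2
  x <- c(1, 2, 3); y <- c(2, 4, 3)
  r <- paired_t_test(x, y)
  expect_equal(r$t, -sqrt(3), tolerance = 1e-12)
  expect_identical(r$df, 2L)
  expect_equal(r$p, 2 * pt(-sqrt(3), 2), tolerance = 1e-12)
  expect_equal(r$p, 0.2254, tolerance = 1e-4)

  ref <- stats::t.test(x, y, paired = TRUE)
  expect_equal(r$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(r$p, ref$p.value, tolerance = 1e-12)

  sw <- paired_t_test(y, x)
  expect_equal(sw$t, -r$t)
  expect_equal(sw$p, r$p)

  expect_error(paired_t_test(x, x), "degenerate")
  expect_error(paired_t_test(1, 2), "at least 2")
  expect_error(paired_t_test(1:3, 1:4), "equal length")
})
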