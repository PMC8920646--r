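test_that("windowed power spectrum peaks at the tone frequency and conserves energy", {
  fs <- 40e6
  n <- 128L
  t <- (0:(n - 1)) / fs
  seg <- cos(2 * pi * 5e6 * t)
  sp <- windowed_power_spectrum(seg, fs)
  expect_equal(sp$frequency[which.max(sp$power_db)], 5)   # exact bin
  # Parseval: one-sided linear bins sum to the tapered-segment energy
  w <- as.numeric(signal::hamming(n))
  expect_equal(sum(sp$power_linear), sum((seg * w)^2), tolerance = 1e-10)
  # degenerate all-zero segment floors and flags
  spz <- windowed_power_spectrum(numeric(n), fs, db_floor = -150)
  expect_true(attr(spz, "flagged"))
  expect_true(all(spz$power_db == -150))
})

test_that("spectral line fit recovers constants and exact lines", {
  f <- seq(0, 20, by = 0.25)
  flat <- fit_spectral_line(f, rep(-20, length(f)), c(4, 8))
  expect_equal(flat$slope, 0, tolerance = 1e-12)
  expect_equal(flat$intercept, -20, tolerance = 1e-12)
  expect_equal(flat$midband, -20, tolerance = 1e-12)

  line <- fit_spectral_line(f, 10 - 2 * f, c(4, 8))
  expect_equal(line$slope, -2, tolerance = 1e-10)
  expect_equal(line$intercept, 10, tolerance = 1e-10)
  expect_equal(line$f0, 6)
  expect_equal(line$midband, -2, tolerance = 1e-10)

  expect_error(fit_spectral_line(f, 10 - 2 * f, c(18, 25)), "outside")
  expect_error(fit_spectral_line(f, 10 - 2 * f, c(4, 4.3)), "3 frequency bins")
})

test_that("spectral fit equals the closed-form least-squares oracle", {
  f <- seq(3, 9, by = 0.2)
  for (s in 1:100) {
    set.seed(s)
    p <- 5 - 1.5 * f + rnorm(length(f), sd = 2)
    fit <- fit_spectral_line(f, p, c(3, 9))
    X <- cbind(1, f)
    beta <- solve(crossprod(X), crossprod(X, p))
    expect_equal(fit$intercept, beta[1], tolerance = 1e-9)
    expect_equal(fit$slope, beta[2], tolerance = 1e-9)
  }
})

test_that("usable band brackets the -6 dB points of a Gaussian spectrum", {
  f <- seq(0, 20, by = 0.25)
  db <- -6 * ((f - 7.5) / 1.5)^2        # -6 dB exactly at 6 and 9 MHz
  band <- determine_band(f, db, 6)
  expect_equal(as.numeric(band), c(6, 9))
  expect_false(attr(band, "clipped"))

  mono <- determine_band(f, -2 * f, 6)  # monotone: clipped at the low edge
  expect_true(attr(mono, "clipped"))
  expect_equal(mono[1], 0)

  expect_error(determine_band(f, db, 0), "band")
})

test_that("attenuation correction follows the 2*alpha*d term", {
  fit <- structure(list(slope = -2, intercept = 10, midband = -2,
                        f0 = 6, depth = 2), class = "spectral_fit")
  # alpha = 0 and d = 0 are identities
  expect_equal(correct_attenuation(fit, 0)$slope, -2)
  fit0 <- fit; fit0$depth <- 0
  expect_equal(correct_attenuation(fit0, 1)$midband, -2)
  # compensate: c = 2*1*2 = 4, s' = 2, M' = 10 + 2*6 = 22
  comp <- correct_attenuation(fit, 1, "compensate")
  expect_equal(comp$slope, 2)
  expect_equal(comp$midband, 22)
  expect_equal(comp$intercept, 10)      # intercept invariant
  # literal printed form subtracts the term
  lit <- correct_attenuation(fit, 1, "paper_literal")
  expect_equal(lit$slope, -6)
  expect_equal(lit$midband, 10 - 36)
})

test_that("parametric image grid follows the window/overlap protocol", {
  # fs = 40 MHz, c = 1540 m/s: 2.4 mm / 19.25 um = 125 samples; hop 16
  set.seed(1)
  fr <- rf_frame(matrix(rnorm(1000 * 4), 1000, 4), 40e6, 10e6)
  pim <- build_parametric_images(fr, spectral_config(attenuation_coefficient = 0))
  expect_equal(length(pim$window_centers), 55L)   # floor((1000-125)/16)+1
  expect_equal(diff(pim$window_centers)[1], 16)
  expect_true(all(diff(pim$window_centers) > 0))
  expect_identical(dim(pim$mbf), dim(pim$sl))
  # midband identity M = I + s * f0 for every window
  expect_lt(max(abs(pim$mbf - (pim$int + pim$sl * pim$f0))), 1e-9)
  expect_error(build_parametric_images(
    rf_frame(matrix(rnorm(100 * 2), 100, 2), 40e6, 10e6)), "shorter")
})

test_that("intercept images are invariant under attenuation correction", {
  sim <- simulate_rf_frame(sim_config(n_lines = 16, n_samples = 1024, seed = 12))
  p0 <- build_parametric_images(sim$frame, spectral_config(attenuation_coefficient = 0))
  p1 <- build_parametric_images(sim$frame, spectral_config(attenuation_coefficient = 1))
  expect_equal(p0$int, p1$int, tolerance = 1e-12)
  expect_gt(max(abs(p0$sl - p1$sl)), 0.1)
})

test_that("stationary frames show no depth trend; attenuation induces one and is compensable", {
  # no attenuation: corrected-with-alpha=0 slope image is depth-stationary
  sim0 <- simulate_rf_frame(sim_config(n_lines = 48, n_samples = 2048, seed = 5))
  p0 <- build_parametric_images(sim0$frame, spectral_config(attenuation_coefficient = 0))
  rows <- seq(1, length(p0$depths_cm), by = 8)  # decorrelate overlapping windows
  fit0 <- stats::lm(rowMeans(p0$sl)[rows] ~ p0$depths_cm[rows])
  ci0 <- stats::confint(fit0)[2, ]
  expect_true(ci0[1] < 0 && ci0[2] > 0)
  # the average slope at band center of the Gaussian pulse spectrum is ~0
  expect_lt(abs(mean(p0$sl)), 0.5)

  # beta = 1 dB/MHz-cm: uncorrected SL falls at ~ -2*beta dB/MHz per cm,
  # compensate-mode alpha = beta removes the trend
  simb <- simulate_rf_frame(sim_config(n_lines = 48, n_samples = 2048,
                                       attenuation = 1, seed = 6))
  pu <- build_parametric_images(simb$frame, spectral_config(attenuation_coefficient = 0))
  pc <- build_parametric_images(simb$frame, spectral_config(attenuation_coefficient = 1))
  d <- pu$depths_cm[rows]
  su <- summary(stats::lm(rowMeans(pu$sl)[rows] ~ d))$coefficients
  expect_lt(su[2, 1], -1)         # strongly negative trend
  expect_lt(su[2, 4], 0.001)
  cic <- stats::confint(stats::lm(rowMeans(pc$sl)[rows] ~ d))[2, ]
  expect_true(cic[1] < 0 && cic[2] > 0)
})

test_that("roi_statistics computes mean and n-1 standard deviation", {
  img <- matrix(7, 4, 4)
  st <- roi_statistics(img, roi_mask(matrix(TRUE, 4, 4)))
  expect_equal(unname(st), c(7, 0))

  img2 <- matrix(0, 2, 2); img2[] <- c(1, 2, 3, 4)
  st2 <- roi_statistics(img2, roi_mask(matrix(TRUE, 2, 2)))
  expect_equal(st2[["mean"]], 2.5)
  expect_equal(st2[["sd"]], sqrt(sum((1:4 - 2.5)^2) / 3))

  one <- matrix(FALSE, 2, 2); one[1] <- TRUE
  expect_warning(st3 <- roi_statistics(img2, roi_mask(one)), "single-pixel")
  expect_equal(st3[["sd"]], 0)
  expect_error(roi_statistics(matrix(1, 3, 3), roi_mask(matrix(TRUE, 2, 2))),
               "does not match")
})
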