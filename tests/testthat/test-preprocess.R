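test_that("resampling interpolates linearly and respects the data range", {
  s <- raman_spectrum(c(500, 502), c(1, 3))
  r <- resample_to_grid(s, 500, 502, 1)
  expect_equal(r$wavenumber, c(500, 501, 502))
  expect_equal(r$intensity[2], 2.0)
  expect_match(tail(r$meta$preprocessing_steps, 1), "resample")

  u <- raman_spectrum(500:510, sin(500:510))
  r2 <- resample_to_grid(u, 500, 510, 1)
  expect_equal(r2$intensity, u$intensity)

  expect_error(resample_to_grid(u, 400, 510, 1),
               class = "sipraman_range_error")
})

test_that("fingerprint cropping restricts the axis and is idempotent", {
  x <- seq(500, 3200, by = 2)
  s <- raman_spectrum(x, runif(length(x)))
  c1 <- crop_fingerprint(s)
  expect_lte(max(c1$wavenumber), 1800)
  expect_gte(min(c1$wavenumber), 500)
  c2 <- crop_fingerprint(c1)
  expect_equal(c2$wavenumber, c1$wavenumber)
  expect_equal(c2$intensity, c1$intensity)
  expect_error(crop_fingerprint(s, 1000, 1000),
               class = "sipraman_range_error")
  inside <- raman_spectrum(600:700, runif(101))
  expect_equal(crop_fingerprint(inside)$intensity, inside$intensity)
})

test_that("AsLS baseline removes slow trends without touching peaks", {
  # Lorentzian (amp 1, FWHM 12) on a linear ramp 0.005 * wavenumber
  s <- single_band_cell(center = 800, fwhm = 12, amplitude = 1,
                        lo = 500, hi = 1100, slope = 0.005, eta = 1)
  corr <- correct_baseline(s)
  free <- abs(corr$wavenumber - 800) > 100
  expect_lt(max(abs(corr$intensity[free])), 0.01)  # < 1% of peak amplitude
  expect_length(corr$baseline, length(s$wavenumber))

  z <- raman_spectrum(500:600, rep(0, 101))
  expect_equal(correct_baseline(z)$intensity, rep(0, 101), tolerance = 1e-12)

  k <- raman_spectrum(500:600, rep(7, 101))
  expect_lt(max(abs(correct_baseline(k)$intensity)), 1e-6 * 7)

  expect_error(correct_baseline(raman_spectrum(500:509, rep(1, 10))),
               class = "sipraman_parameter_error")
})

test_that("baseline correction never inflates an isolated apex by > 2%", {
  for (ctr in c(747, 1002, 1584)) {
    s <- single_band_cell(center = ctr, fwhm = 12, amplitude = 1,
                          lo = ctr - 200, hi = ctr + 200,
                          slope = 0.002, intercept = 1)
    corr <- correct_baseline(s)
    apex_before <- 1  # generative amplitude above the local baseline
    apex_after <- corr$intensity[which.min(abs(corr$wavenumber - ctr))]
    expect_lt(apex_after, apex_before * 1.02)
  }
})

test_that("Savitzky-Golay smoothing reproduces polynomials, damps noise", {
  x <- seq(500, 600, by = 1)
  quad <- raman_spectrum(x, 3 + 0.1 * (x - 550) + 0.01 * (x - 550)^2)
  sm <- smooth_spectrum(quad, window_cm1 = 9, polyorder = 2)
  expect_lt(max(abs(sm$intensity - quad$intensity)), 1e-9)

  set.seed(42)
  noisy <- raman_spectrum(x, rnorm(length(x)))
  smn <- smooth_spectrum(noisy, window_cm1 = 9, polyorder = 2)
  expect_lt(var(smn$intensity), var(noisy$intensity))

  expect_error(smooth_spectrum(noisy, window_cm1 = 1, polyorder = 2),
               class = "sipraman_parameter_error")
})

test_that("normalization modes behave and l2 is idempotent/scale-free", {
  x <- seq(500, 600, by = 1)
  s <- raman_spectrum(x, 1 + sin(x / 10)^2)
  l2 <- normalize_spectrum(s, "l2")
  expect_equal(sqrt(sum(l2$intensity^2)), 1, tolerance = 1e-12)
  l2b <- normalize_spectrum(l2, "l2")
  expect_equal(l2b$intensity, l2$intensity, tolerance = 1e-12)

  s10 <- s; s10$intensity <- s$intensity * 10
  expect_equal(normalize_spectrum(s10, "l2")$intensity, l2$intensity,
               tolerance = 1e-12)

  ar <- normalize_spectrum(s, "area")
  expect_equal(sum((ar$intensity[-1] + ar$intensity[-length(x)]) / 2 *
                     diff(x)), 1, tolerance = 1e-9)
  expect_equal(max(normalize_spectrum(s, "max")$intensity), 1)

  expect_error(normalize_spectrum(raman_spectrum(x, rep(0, length(x)))),
               class = "sipraman_normalization_error")
})

test_that("cohort averaging gives pointwise mean and population SD", {
  x <- 500:520
  same <- replicate(50, raman_spectrum(x, sin(x)), simplify = FALSE)
  for (i in seq_along(same)) same[[i]]$cell_id <- sprintf("c%02d", i)
  m <- average_spectra(raman_set(same))
  expect_equal(m$n, 50)
  expect_equal(max(m$sd), 0)

  two <- raman_set(list(raman_spectrum(x, rep(0, 21), cell_id = "a"),
                        raman_spectrum(x, rep(2, 21), cell_id = "b")))
  m2 <- average_spectra(two)
  expect_equal(unique(m2$mean), 1)
  expect_equal(unique(m2$sd), 1)  # population SD with n = 2

  off <- raman_set(list(raman_spectrum(x, rep(0, 21), cell_id = "a"),
                        raman_spectrum(x + 0.5, rep(2, 21), cell_id = "b")))
  expect_error(average_spectra(off), class = "sipraman_axis_error")
  expect_error(average_spectra(raman_set(list())),
               class = "sipraman_parameter_error")

  # averaging commutes with global intensity scaling
  set.seed(7)
  cells <- lapply(1:5, function(i)
    raman_spectrum(x, runif(21), cell_id = sprintf("c%d", i)))
  m1 <- average_spectra(raman_set(cells))
  scaled <- lapply(cells, function(s) { s$intensity <- 3 * s$intensity; s })
  m3 <- average_spectra(raman_set(scaled))
  expect_equal(m3$mean, 3 * m1$mean, tolerance = 1e-12)
  expect_equal(m3$sd, 3 * m1$sd, tolerance = 1e-12)
})

test_that("the full chain preserves apex positions of isolated bands", {
  # resample -> crop -> baseline -> normalize at infinite SNR must keep the
  # apex within +/- 0.5 cm-1 of the generative center
  for (ctr in c(747, 1002, 1312, 1584)) {
    s <- single_band_cell(center = ctr, fwhm = 12, amplitude = 1,
                          lo = 500, hi = 3200, slope = 0.001, intercept = 2)
    p <- preprocess_spectrum(s)
    apex <- p$wavenumber[which.max(p$intensity)]
    expect_lt(abs(apex - ctr), 0.5 + 1e-9)
  }
})

test_that("preprocessing provenance is recorded step by step", {
  s <- single_band_cell(center = 747, lo = 500, hi = 3200)
  p <- preprocess_spectrum(s)
  steps <- p$meta$preprocessing_steps
  expect_true(any(grepl("resample", steps)))
  expect_true(any(grepl("crop", steps)))
  expect_true(any(grepl("baseline_asls", steps)))
  expect_true(any(grepl("normalize_l2", steps)))
})
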