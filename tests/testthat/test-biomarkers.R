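ref_table <- load_band_table("reference_strains")
pyrrole <- ref_table$bands[1, ]
phe <- ref_table$bands[grep("^phe", ref_table$bands$name), ]

test_that("fit_band recovers an isolated noiseless band center", {
  s <- single_band_cell(center = 747, fwhm = 12, amplitude = 1, eta = 1,
                        lo = 650, hi = 850)
  fit <- fit_band(s, pyrrole)
  expect_true(fit$success)
  expect_lt(abs(fit$center - 747), 0.5)
  expect_gt(fit$fwhm, 0)
  expect_false(fit$bimodal_flag)
})

test_that("fit_band reports failure on empty windows, errors off-axis", {
  flat <- raman_spectrum(650:850, rep(0, 201))
  fit <- fit_band(flat, pyrrole)
  expect_false(fit$success)
  expect_true(is.na(fit$center))
  far <- raman_spectrum(2000:2100, runif(101))
  expect_error(fit_band(far, pyrrole), class = "sipraman_range_error")
})

test_that("two-population windows raise the bimodal flag, taller apex wins", {
  x <- seq(900, 1100, by = 1)
  y <- pseudo_voigt(x, 1002, 12, 1, eta = 1) +
       pseudo_voigt(x, 965, 12, 1, eta = 1)
  s <- raman_spectrum(x, y)
  fit <- fit_band(s, phe)
  expect_true(fit$success)
  expect_true(fit$bimodal_flag)
  # brute-force maxima of the summed profile on a 0.1 cm-1 grid
  xd <- seq(950, 1015, by = 0.1)
  yd <- pseudo_voigt(xd, 1002, 12, 1, eta = 1) +
        pseudo_voigt(xd, 965, 12, 1, eta = 1)
  maxima <- dense_local_maxima(xd, yd)
  expect_lt(min(abs(fit$center - maxima)), 0.5)
})

test_that("shift profiles report the printed endmember shifts", {
  cfg <- noiseless_config()
  full <- preprocess_spectrum(simulate_spectrum(cfg, 1, seed = 1))
  prof <- compute_shift_profile(full)
  expected <- c(pyrrole_breathing = 22, nu_CN = 10, delta_CH = 12,
                nu_CC = 48, phe_ring = 37)
  expect_true(all(prof$fits$success))
  expect_equal(prof$delta[names(expected)], expected, tolerance = 1 / 22)

  none <- preprocess_spectrum(simulate_spectrum(cfg, 0, seed = 1))
  prof0 <- compute_shift_profile(none)
  expect_true(all(abs(prof0$delta) < 1))
})

test_that("bands outside the axis fail softly inside a profile", {
  cfg <- noiseless_config()
  s <- preprocess_spectrum(simulate_spectrum(cfg, 0, seed = 1),
                           grid = c(1050, 1800, 1))
  prof <- compute_shift_profile(s)
  f <- prof$fits
  expect_false(f$success[f$band_name == "phe_ring"])
  expect_false(f$success[f$band_name == "pyrrole_breathing"])
  kept <- c("nu_CN", "delta_CH", "nu_CC")
  expect_true(all(f$success[f$band_name %in% kept]))
  expect_true(all(abs(prof$delta[kept]) < 1))
})

test_that("position-based labeling fraction interpolates and clamps", {
  fit_at <- function(ctr, band) {
    x <- seq(band$c13 - 40, band$c12 + 40, by = 1)
    fit_band(raman_spectrum(x, pseudo_voigt(x, ctr, 8, 1)), band)
  }
  expect_equal(as.numeric(
    estimate_label_fraction_position(fit_at(1002, phe), phe)), 0,
    tolerance = 0.02)
  expect_equal(as.numeric(
    estimate_label_fraction_position(fit_at(965, phe), phe)), 1,
    tolerance = 0.02)
  # partially labeled phenylalanine at 985 with endmembers (1003, 965)
  tx1_phe <- band_definition("phe_ring", "ring breathing", 1003, 965)
  f <- estimate_label_fraction_position(fit_at(985, tx1_phe), tx1_phe)
  expect_equal(as.numeric(f), 0.474, tolerance = 0.02)
  # monotone non-increasing in fitted center, always within [0, 1]
  centers <- seq(958, 1010, by = 2)
  fs <- vapply(centers, function(ctr) as.numeric(
    estimate_label_fraction_position(fit_at(ctr, phe), phe)), numeric(1))
  expect_true(all(diff(fs) <= 1e-9))
  expect_true(all(fs >= 0 & fs <= 1))
  # failed fits have no defined labeling fraction
  flat <- raman_spectrum(940:1020, rep(0, 81))
  expect_error(
    estimate_label_fraction_position(fit_band(flat, phe), phe),
    class = "sipraman_undefined_error")
})

test_that("decomposition estimator unmixes endmember mixtures", {
  cfg <- noiseless_config(grid = c(500, 1800, 1))
  e12 <- endmember_spectrum(config = cfg)
  e13 <- endmember_spectrum(which = "13C", config = cfg)
  mix <- function(w) raman_spectrum(e12$wavenumber,
                                    (1 - w) * e12$intensity +
                                      w * e13$intensity)
  f0 <- estimate_label_fraction_decomposition(mix(0), ref_table,
                                              list(e12, e13))
  f1 <- estimate_label_fraction_decomposition(mix(1), ref_table,
                                              list(e12, e13))
  f3 <- estimate_label_fraction_decomposition(mix(0.3), ref_table,
                                              list(e12, e13))
  expect_true(all(abs(f0) <= 0.01))
  expect_true(all(abs(f1 - 1) <= 0.01))
  expect_true(all(abs(f3 - 0.3) <= 0.02))
  shifted <- mix(0.3)
  shifted$wavenumber <- shifted$wavenumber + 0.5
  expect_error(
    estimate_label_fraction_decomposition(shifted, ref_table,
                                          list(e12, e13)),
    class = "sipraman_axis_error")
})

test_that("the sorting criterion requires all four Cyt c bands plus phe", {
  cfg <- noiseless_config()
  active <- classify_cell(compute_shift_profile(
    preprocess_spectrum(simulate_spectrum(cfg, 1, seed = 1))))
  expect_true(active$is_active)
  expect_equal(active$n_cytc_shifted, 4)
  expect_true(active$phe_shifted)

  inactive <- classify_cell(compute_shift_profile(
    preprocess_spectrum(simulate_spectrum(cfg, 0, seed = 1))))
  expect_false(inactive$is_active)
  expect_equal(inactive$n_cytc_shifted, 0)

  # three of four Cyt c bands shifted + phe shifted is NOT active
  b <- ref_table$bands
  x <- seq(500, 1800, by = 1)
  centers <- ifelse(b$name == "nu_CC", b$c12, b$c13)  # nu_CC stays unlabeled
  y <- rowSums(vapply(seq_len(nrow(b)), function(i)
    pseudo_voigt(x, centers[i], 10, 1), numeric(length(x))))
  prof <- compute_shift_profile(raman_spectrum(x, y))
  cls <- classify_cell(prof)
  expect_equal(cls$n_cytc_shifted, 3)
  expect_true(cls$phe_shifted)
  expect_false(cls$is_active)
  # quartet-only rule also refuses: nu_CC is still unshifted
  expect_false(classify_cell(prof, require_phe = FALSE)$is_active)

  # a table without required bands is a configuration error
  lone <- band_table("lone", band_definition("phe_ring", "rb", 1002, 965,
                                             required = TRUE))
  lone$bands$required <- FALSE
  expect_error(validate_band_table(lone),
               class = "sipraman_validation_error")
})

test_that("cohort summaries count actives and rank sort candidates", {
  cfg <- noiseless_config(n_cells = 10, label_fraction = 1)
  co <- simulate_cohort(cfg)
  fit <- sip_raman(co$set)
  rep <- summary(fit)
  expect_equal(rep$n_active, 10)
  expect_equal(nrow(rep$sort_candidates), 10)
  expect_true(all(diff(rep$sort_candidates$mean_cytc_delta) <= 1e-12))

  cfg0 <- noiseless_config(n_cells = 4, active_fraction = 0)
  rep0 <- summary(sip_raman(simulate_cohort(cfg0)$set))
  expect_equal(rep0$n_active, 0)
  expect_equal(nrow(rep0$sort_candidates), 0)

  expect_error(summarize_cohort(list(), list()),
               class = "sipraman_parameter_error")
})

test_that("mixed cohorts recover the simulator's ground-truth counts", {
  cfg <- sim_config(n_cells = 60, active_fraction = 0.5, label_fraction = 1,
                    snr = 30, seed = 99)
  co <- simulate_cohort(cfg)
  fit <- sip_raman(co$set)
  pred <- fit$classification
  m <- match(co$truth$cell_id, pred$cell_id)
  expect_equal(sum(pred$is_active), sum(co$truth$is_active))
  expect_equal(pred$is_active[m], co$truth$is_active)
})
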