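#' Configure the synthetic single-cell SIP-Raman generator
#'
#' The generator emulates 13C stable-isotope-probing spectra of single
#' microbial cells: resonance-enhanced cytochrome c bands plus the
#' phenylalanine ring-breathing band, non-shifting protein/lipid background
#' bands (1240, 1450, 1664 cm^-1), a broad autofluorescence baseline,
#' Gaussian instrument broadening, and additive detector noise.
#'
#' Two labeling models are available. `interpolate` (default) moves each
#' biomarker center continuously to `(1 - f) * c12 + f * c13`, which
#' reproduces the observed intermediate single peaks under partial
#' labeling. `two_population` mixes the 12C and 13C endmember band sets
#' with weights `(1 - f, f)`, producing genuinely bimodal windows at
#' intermediate `f`; the two models coincide exactly at `f = 0` and
#' `f = 1`.
#'
#' @param band_table a `band_table` or packaged id.
#' @param labeling_mode `"interpolate"` or `"two_population"`.
#' @param label_fraction labeling fraction for active cells: a scalar in
#'   `[0, 1]`, or `list(dist = "uniform", min =, max =)`, or
#'   `list(dist = "beta", shape1 =, shape2 =)`.
#' @param n_cells number of cells per cohort.
#' @param active_fraction probability a cell is an active incorporator.
#' @param snr ratio of the tallest nominal band amplitude to the additive
#'   noise SD; `Inf` gives noiseless spectra.
#' @param jitter_sd per-cell, per-band random center offset SD (cm^-1);
#'   models wavenumber calibration repeatability.
#' @param intensity_cv lognormal per-band amplitude variability.
#' @param fwhm_cytc,fwhm_phe band widths (cm^-1) for cytochrome c and
#'   phenylalanine bands.
#' @param amplitudes optional named vector of per-band peak amplitudes
#'   overriding the defaults (Cyt c quartet 1.0/0.6/0.7/0.9, phe 0.5).
#' @param baseline list: `hump_amplitude`, `hump_center`, `hump_fwhm`
#'   (broad Gaussian autofluorescence hump) and `slope`, `intercept`
#'   (linear ramp).
#' @param background_bands data.frame with `center`, `amplitude`, `fwhm` of
#'   non-biomarker bands.
#' @param background_coshift logical; when `TRUE` background bands also
#'   redshift (by `10 * f` cm^-1) for robustness testing.
#' @param instrument_fwhm Gaussian instrument broadening FWHM (cm^-1).
#' @param grid numeric `c(start, stop, step)` acquisition grid (cm^-1).
#' @param seed integer seed recorded in the cohort manifest.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(band_table = "reference_strains",
                       labeling_mode = c("interpolate", "two_population"),
                       label_fraction = 1, n_cells = 50,
                       active_fraction = 1, snr = 20, jitter_sd = 0.5,
                       intensity_cv = 0.1, fwhm_cytc = 12, fwhm_phe = 8,
                       amplitudes = NULL,
                       baseline = list(hump_amplitude = 2,
                                       hump_center = 1200,
                                       hump_fwhm = 1500,
                                       slope = 5e-4, intercept = 0.1),
                       background_bands = data.frame(
                         center = c(1240, 1450, 1664),
                         amplitude = c(0.2, 0.3, 0.3), fwhm = 16),
                       background_coshift = FALSE, instrument_fwhm = 3,
                       grid = c(500, 3200, 1), seed = 1L) {
  labeling_mode <- match.arg(labeling_mode)
  if (!(is.numeric(snr) && snr > 0))
    abort("snr must be > 0 (Inf allowed)", "sipraman_parameter_error")
  if (active_fraction < 0 || active_fraction > 1)
    abort("active_fraction must be in [0, 1]", "sipraman_parameter_error")
  if (length(grid) != 3L || grid[3] <= 0 || grid[1] >= grid[2])
    abort("grid must be c(start, stop, step) with step > 0",
          "sipraman_parameter_error")
  structure(list(
    band_table = load_band_table(band_table), labeling_mode = labeling_mode,
    label_fraction = label_fraction, n_cells = as.integer(n_cells),
    active_fraction = active_fraction, snr = snr, jitter_sd = jitter_sd,
    intensity_cv = intensity_cv, fwhm_cytc = fwhm_cytc,
    fwhm_phe = fwhm_phe, amplitudes = amplitudes, baseline = baseline,
    background_bands = background_bands,
    background_coshift = background_coshift,
    instrument_fwhm = instrument_fwhm, grid = grid,
    seed = as.integer(seed)), class = "sim_config")
}

# Resolve per-band shape parameters (fwhm and nominal amplitude) from the
# configuration: required (Cyt c) bands take the default amplitude sequence
# in table order, phenylalanine-named bands take 0.5 and the narrower width.
band_params <- function(config) {
  b <- config$band_table$bands
  phe <- is_phe_band(b$name)
  amp_defaults <- c(1.0, 0.6, 0.7, 0.9)
  amp <- numeric(nrow(b))
  amp[!phe] <- rep_len(amp_defaults, sum(!phe))
  amp[phe] <- 0.5
  if (!is.null(config$amplitudes)) {
    hit <- b$name %in% names(config$amplitudes)
    amp[hit] <- config$amplitudes[b$name[hit]]
  }
  fwhm <- ifelse(phe, config$fwhm_phe, config$fwhm_cytc)
  data.frame(name = b$name, c12 = b$c12, c13 = b$c13, fwhm = fwhm,
             amplitude = amp, stringsAsFactors = FALSE)
}

draw_label_fraction <- function(spec) {
  if (is.numeric(spec)) return(spec[1])
  if (is.list(spec)) {
    if (identical(spec$dist, "uniform"))
      return(stats::runif(1, spec$min %||% 0, spec$max %||% 1))
    if (identical(spec$dist, "beta"))
      return(stats::rbeta(1, spec$shape1, spec$shape2))
  }
  abort("unrecognized label_fraction specification",
        "sipraman_parameter_error")
}

#' Simulate one single-cell spectrum
#'
#' Draws per-band center jitter and amplitude factors from the current RNG
#' state, composes the biomarker and background bands for labeling fraction
#' `f` under the configured labeling model, applies Gaussian instrument
#' broadening, adds the autofluorescence baseline, and adds white noise at
#' the configured SNR.
#'
#' @param config a `sim_config`.
#' @param f labeling fraction in `[0, 1]`.
#' @param cell_id cell identifier.
#' @param isotope_condition metadata label; defaults to `"13C"` for
#'   `f > 0` and `"12C"` otherwise.
#' @param seed optional seed applied before drawing (otherwise the current
#'   RNG state is used).
#' @return a `raman_spectrum` with attribute `truth` (list with `f` and
#'   realized per-band centers).
#' @export
simulate_spectrum <- function(config, f, cell_id = "cell",
                              isotope_condition = NULL, seed = NULL) {
  if (!inherits(config, "sim_config"))
    abort("config must be a sim_config", "sipraman_parameter_error")
  if (!is.numeric(f) || f < 0 || f > 1)
    abort("f must be in [0, 1]", "sipraman_parameter_error")
  if (!is.null(seed)) set.seed(seed)
  g <- config$grid
  x <- seq(g[1], g[2], by = g[3])
  bp <- band_params(config)
  nb <- nrow(bp)
  jit <- stats::rnorm(nb, 0, config$jitter_sd)
  ampf <- exp(stats::rnorm(nb, 0, config$intensity_cv))
  clean <- numeric(length(x))
  for (i in seq_len(nb)) {
    a <- bp$amplitude[i] * ampf[i]
    if (config$labeling_mode == "interpolate") {
      ci <- (1 - f) * bp$c12[i] + f * bp$c13[i] + jit[i]
      clean <- clean + pseudo_voigt(x, ci, bp$fwhm[i], a)
    } else {
      clean <- clean +
        (1 - f) * pseudo_voigt(x, bp$c12[i] + jit[i], bp$fwhm[i], a) +
        f * pseudo_voigt(x, bp$c13[i] + jit[i], bp$fwhm[i], a)
    }
  }
  bg <- config$background_bands
  if (!is.null(bg) && nrow(bg)) {
    shift <- if (isTRUE(config$background_coshift)) 10 * f else 0
    for (i in seq_len(nrow(bg)))
      clean <- clean +
        pseudo_voigt(x, bg$center[i] - shift, bg$fwhm[i], bg$amplitude[i])
  }
  y <- broaden(clean, config$instrument_fwhm, g[3])
  bl <- config$baseline
  if (!is.null(bl)) {
    sdh <- (bl$hump_fwhm %||% 1500) / (2 * sqrt(2 * log(2)))
    y <- y + (bl$hump_amplitude %||% 0) *
      exp(-(x - (bl$hump_center %||% 1200))^2 / (2 * sdh^2)) +
      (bl$slope %||% 0) * (x - g[1]) + (bl$intercept %||% 0)
  }
  noise_sd <- if (is.finite(config$snr)) max(bp$amplitude) / config$snr else 0
  y <- y + stats::rnorm(length(x), 0, noise_sd)
  cond <- isotope_condition %||% (if (f > 0) "13C" else "12C")
  s <- raman_spectrum(x, y, cell_id = cell_id, sample_group = "synthetic",
                      isotope_condition = cond)
  attr(s, "truth") <- list(
    f = f,
    centers = stats::setNames((1 - f) * bp$c12 + f * bp$c13 + jit, bp$name))
  s
}

#' Noiseless endmember spectrum of a pure isotopic state
#'
#' Baseline-free, jitter-free sum of the table's bands at their 12C or 13C
#' centers with the configured shapes and instrument broadening, on the
#' configured grid — the inputs to the decomposition estimator.
#'
#' @param table a `band_table` or packaged id.
#' @param which `"12C"` or `"13C"`.
#' @param config a `sim_config` supplying shapes and grid (defaults built
#'   from `table` when omitted).
#' @return a `raman_spectrum`.
#' @export
endmember_spectrum <- function(table = "reference_strains",
                               which = c("12C", "13C"), config = NULL) {
  which <- match.arg(which)
  table <- load_band_table(table)
  if (is.null(config)) config <- sim_config(band_table = table)
  config$band_table <- table
  g <- config$grid
  x <- seq(g[1], g[2], by = g[3])
  bp <- band_params(config)
  centers <- if (which == "12C") bp$c12 else bp$c13
  clean <- numeric(length(x))
  for (i in seq_len(nrow(bp)))
    clean <- clean + pseudo_voigt(x, centers[i], bp$fwhm[i], bp$amplitude[i])
  y <- broaden(clean, config$instrument_fwhm, g[3])
  raman_spectrum(x, y, cell_id = sprintf("endmember_%s", which),
                 sample_group = "endmember", isotope_condition = which)
}

#' Simulate a cohort of single cells with ground truth
#'
#' Each cell is active with probability `active_fraction`; active cells
#' draw their labeling fraction from the configured distribution, inactive
#' cells have `f = 0`. Every cell uses a substream seeded from the cohort
#' seed and the cell index, so cohorts are bit-reproducible and insensitive
#' to generation order. Seed and configuration are recorded in the set's
#' provenance (and hence the written manifest).
#'
#' @param config a `sim_config` with `n_cells >= 1`.
#' @param isotope_condition metadata label for the incubation condition of
#'   the whole cohort (default `"13C"`; use `"12C"` for control cohorts,
#'   typically with `active_fraction = 0`).
#' @return list with `set` (a `raman_set`) and `truth` (data.frame:
#'   `cell_id`, `is_active`, `f_true`, and realized per-band centers).
#' @export
simulate_cohort <- function(config, isotope_condition = "13C") {
  if (!inherits(config, "sim_config"))
    abort("config must be a sim_config", "sipraman_parameter_error")
  if (config$n_cells < 1L)
    abort("n_cells must be >= 1", "sipraman_parameter_error")
  spectra <- vector("list", config$n_cells)
  rows <- vector("list", config$n_cells)
  for (i in seq_len(config$n_cells)) {
    cell_seed <- as.integer((as.numeric(config$seed) + 104729 * i) %%
                              2147483647)
    set.seed(cell_seed)
    active <- stats::runif(1) < config$active_fraction
    f <- if (active) draw_label_fraction(config$label_fraction) else 0
    id <- sprintf("cell_%04d", i)
    s <- simulate_spectrum(config, f, cell_id = id,
                           isotope_condition = isotope_condition)
    truth <- attr(s, "truth")
    attr(s, "truth") <- NULL
    spectra[[i]] <- s
    rows[[i]] <- cbind(
      data.frame(cell_id = id, is_active = active, f_true = f,
                 stringsAsFactors = FALSE),
      as.data.frame(as.list(truth$centers)))
  }
  truth <- do.call(rbind, rows)
  prov <- list(simulated = TRUE, seed = config$seed,
               labeling_mode = config$labeling_mode, snr = config$snr,
               active_fraction = config$active_fraction,
               band_table = config$band_table$table_id,
               jitter_sd = config$jitter_sd,
               intensity_cv = config$intensity_cv)
  list(set = raman_set(spectra, set_id = sprintf("sim_seed%d", config$seed),
                       provenance = prov),
       truth = truth)
}
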