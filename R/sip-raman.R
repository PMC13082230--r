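#' Fit the SIP-Raman band-shift model to a cohort of single-cell spectra
#'
#' The central entry point: for every cell it (optionally) applies the
#' standard preprocessing chain (resampling to the working grid, cropping
#' to the 500-1800 cm^-1 fingerprint region, asymmetric-least-squares
#' baseline subtraction, normalization), fits every biomarker band of the
#' table, quantifies the isotopic redshift and labeling fraction per band,
#' and classifies the cell by the sorting criterion (all required
#' cytochrome c bands, plus phenylalanine under the default rule, shifted
#' by at least `delta_min`).
#'
#' @param x a `raman_set`, a list of `raman_spectrum` objects, or a single
#'   spectrum.
#' @param bands a `band_table` or packaged table id
#'   (`"reference_strains"`, `"sediment_enrichment"`, `"strain_TX1"`).
#' @param delta_min minimum redshift (cm^-1) for a band to count as
#'   shifted; default 5.
#' @param require_phe require the phenylalanine shift in addition to the
#'   cytochrome c quartet (default `TRUE`).
#' @param preprocess apply the standard chain before fitting; set `FALSE`
#'   when the spectra are already preprocessed.
#' @param grid working grid `c(start, stop, step)` in cm^-1.
#' @param baseline asymmetric-least-squares parameters (see
#'   [correct_baseline()]), or `NULL` to skip.
#' @param normalize normalization method, or `NULL` to skip.
#' @param smooth_window apex-detection smoothing window (cm^-1).
#' @param f_method `"position"` for the band-position labeling-fraction
#'   estimator only, `"both"` to additionally run the endmember
#'   decomposition estimator.
#' @param endmember_config optional `sim_config` controlling the endmember
#'   shapes used by the decomposition estimator.
#' @return an object of class `sip_raman` with components `classification`
#'   (per-cell data.frame), `centers`, `delta`, `f_position` (and
#'   optionally `f_decomposition`) matrices (cells x bands), `profiles`,
#'   `report` (a `cohort_report`), `bands`, `params`, and the preprocessed
#'   spectra. Methods: `print`, `summary`, `coef`, `plot`, `predict`,
#'   `as.data.frame`.
#' @export
#' @examples
#' cfg <- sim_config(n_cells = 4, label_fraction = 1, snr = 30, seed = 1)
#' cohort <- simulate_cohort(cfg)
#' fit <- sip_raman(cohort$set)
#' summary(fit)
#' coef(fit, "delta")
sip_raman <- function(x, bands = "reference_strains", delta_min = 5,
                      require_phe = TRUE, preprocess = TRUE,
                      grid = c(500, 1800, 1),
                      baseline = list(lambda = 1e5, p = 0.01, n_iter = 10L),
                      normalize = "l2", smooth_window = 7,
                      f_method = c("position", "both"),
                      endmember_config = NULL) {
  cl <- match.call()
  f_method <- match.arg(f_method)
  if (inherits(x, "raman_spectrum")) x <- raman_set(list(x))
  if (is.list(x) && !inherits(x, "raman_set")) x <- raman_set(x)
  if (length(x$spectra) == 0L)
    abort("no spectra to fit", "sipraman_parameter_error")
  table <- load_band_table(bands)
  prepped <- lapply(x$spectra, function(s) {
    if (preprocess)
      preprocess_spectrum(s, grid = grid, baseline = baseline,
                          normalize = normalize)
    else s
  })
  profiles <- lapply(prepped, compute_shift_profile, table = table,
                     smooth_window = smooth_window)
  classifications <- lapply(profiles, classify_cell, delta_min = delta_min,
                            require_phe = require_phe)

  bn <- table$bands$name
  ids <- names(prepped)
  mat <- function(extract) {
    m <- do.call(rbind, lapply(profiles, extract))
    dimnames(m) <- list(ids, bn)
    m
  }
  centers <- mat(function(p)
    ifelse(p$fits$success, p$fits$center, NA_real_))
  delta <- mat(function(p) unname(p$delta))
  f_position <- mat(function(p) unname(p$f_position))

  f_decomposition <- NULL
  if (f_method == "both") {
    em_cache <- new.env(parent = emptyenv())
    f_decomposition <- do.call(rbind, lapply(prepped, function(s) {
      key <- sprintf("%.6f_%.6f_%d", min(s$wavenumber), max(s$wavenumber),
                     length(s$wavenumber))
      if (is.null(em_cache[[key]])) {
        ecfg <- endmember_config %||% sim_config(band_table = table)
        ecfg$band_table <- table
        ecfg$grid <- c(min(s$wavenumber), max(s$wavenumber),
                       axis_step(s$wavenumber))
        em_cache[[key]] <- list(endmember_spectrum(table, "12C", ecfg),
                                endmember_spectrum(table, "13C", ecfg))
      }
      estimate_label_fraction_decomposition(s, table, em_cache[[key]])
    }))
    dimnames(f_decomposition) <- list(ids, bn)
  }

  classification <- data.frame(
    cell_id = ids,
    n_cytc_shifted = vapply(classifications, function(z) z$n_cytc_shifted,
                            numeric(1)),
    phe_shifted = vapply(classifications, function(z) z$phe_shifted,
                         logical(1)),
    is_active = vapply(classifications, function(z) z$is_active,
                       logical(1)),
    stringsAsFactors = FALSE, row.names = NULL)

  structure(list(
    call = cl, bands = table,
    params = list(delta_min = delta_min, require_phe = require_phe,
                  preprocess = preprocess, grid = grid,
                  baseline = baseline, normalize = normalize,
                  smooth_window = smooth_window, f_method = f_method),
    profiles = profiles, classifications = classifications,
    classification = classification, centers = centers, delta = delta,
    f_position = f_position, f_decomposition = f_decomposition,
    spectra = prepped, set_id = x$set_id, provenance = x$provenance,
    report = summarize_cohort(classifications, profiles)
  ), class = "sip_raman")
}

#' @export
print.sip_raman <- function(x, ...) {
  cat("SIP-Raman band-shift fit\n")
  cat(sprintf("  set '%s': %d cells, band table '%s'\n", x$set_id,
              nrow(x$classification), x$bands$table_id))
  cat(sprintf("  rule %s, delta_min = %g cm-1\n", x$report$rule,
              x$params$delta_min))
  cat(sprintf("  active carbon fixers: %d / %d\n",
              sum(x$classification$is_active), nrow(x$classification)))
  invisible(x)
}

#' @export
summary.sip_raman <- function(object, ...) object$report

#' Extract fitted quantities from a sip_raman object
#'
#' @param object a `sip_raman` fit.
#' @param what `"center"` (fitted band centers, cm^-1), `"delta"`
#'   (redshifts `c12 - center`), `"f"` (position-based labeling fractions)
#'   or `"f_decomposition"`.
#' @param ... unused.
#' @return numeric matrix, cells x bands.
#' @export
coef.sip_raman <- function(object, what = c("center", "delta", "f",
                                            "f_decomposition"), ...) {
  what <- match.arg(what)
  switch(what, center = object$centers, delta = object$delta,
         f = object$f_position,
         f_decomposition = object$f_decomposition %||%
           stop("fit was run without the decomposition estimator"))
}

#' @export
as.data.frame.sip_raman <- function(x, ...) {
  bn <- colnames(x$centers)
  out <- x$classification
  for (b in bn) {
    out[[paste0("center_", b)]] <- x$centers[, b]
    out[[paste0("delta_", b)]] <- x$delta[, b]
    out[[paste0("f_", b)]] <- x$f_position[, b]
  }
  out
}

#' Classify new spectra with a fitted object's parameters
#'
#' @param object a `sip_raman` fit.
#' @param newdata a `raman_set` (or list of spectra).
#' @param ... unused.
#' @return a new `sip_raman` object for `newdata`.
#' @export
predict.sip_raman <- function(object, newdata, ...) {
  p <- object$params
  sip_raman(newdata, bands = object$bands, delta_min = p$delta_min,
            require_phe = p$require_phe, preprocess = p$preprocess,
            grid = p$grid, baseline = p$baseline, normalize = p$normalize,
            smooth_window = p$smooth_window, f_method = p$f_method)
}

#' Plot group mean spectra with SD envelopes and band markers
#'
#' Draws the mean preprocessed spectrum (with a shaded +/- SD envelope) for
#' each isotope-condition group and marks the 12C (dashed) and 13C
#' (dotted) endmember positions of the fitted band table.
#'
#' @param x a `sip_raman` fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.sip_raman <- function(x, ...) {
  conds <- vapply(x$spectra, function(s) s$meta$isotope_condition,
                  character(1))
  groups <- split(names(x$spectra), conds)
  cols <- stats::setNames(
    grDevices::hcl.colors(max(2L, length(groups)), "Dark 2")[
      seq_along(groups)], names(groups))
  means <- lapply(groups, function(idx)
    average_spectra(raman_set(unname(x$spectra[idx]))))
  xr <- range(unlist(lapply(means, function(m) range(m$wavenumber))))
  yr <- range(unlist(lapply(means, function(m)
    c(m$mean - m$sd, m$mean + m$sd))))
  graphics::plot(NA, xlim = xr, ylim = yr, xlab = "wavenumber (cm-1)",
                 ylab = "normalized intensity",
                 main = sprintf("mean spectra, set '%s'", x$set_id), ...)
  for (g in names(means)) {
    m <- means[[g]]
    graphics::polygon(c(m$wavenumber, rev(m$wavenumber)),
                      c(m$mean - m$sd, rev(m$mean + m$sd)),
                      col = grDevices::adjustcolor(cols[g], alpha.f = 0.25),
                      border = NA)
    graphics::lines(m$wavenumber, m$mean, col = cols[g], lwd = 1.5)
  }
  graphics::abline(v = x$bands$bands$c12, lty = 2,
                   col = grDevices::adjustcolor("grey30", 0.6))
  graphics::abline(v = x$bands$bands$c13, lty = 3,
                   col = grDevices::adjustcolor("grey30", 0.6))
  graphics::legend("topright", legend = names(means), col = cols[names(means)],
                   lwd = 1.5, bty = "n")
  invisible(x)
}
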