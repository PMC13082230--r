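#' Resample a spectrum onto a uniform wavenumber grid
#'
#' Linear interpolation onto `seq(start, stop, by = step)`. Averaging and
#' endmember decomposition require all cells on one shared grid, so this is
#' the first step of the standard chain.
#'
#' @param spectrum a `raman_spectrum`.
#' @param start,stop grid limits (cm^-1); must lie within the data range.
#' @param step grid spacing (cm^-1), > 0.
#' @return resampled `raman_spectrum`.
#' @export
resample_to_grid <- function(spectrum, start, stop, step = 1) {
  validate_spectrum(spectrum)
  if (step <= 0) abort("step must be > 0", "sipraman_parameter_error")
  rng <- range(spectrum$wavenumber)
  if (start < rng[1] || stop > rng[2] || start >= stop)
    abort(sprintf("requested grid [%g, %g] outside data range [%g, %g]",
                  start, stop, rng[1], rng[2]), "sipraman_range_error")
  grid <- seq(start, stop, by = step)
  yi <- stats::approx(spectrum$wavenumber, spectrum$intensity,
                      xout = grid, method = "linear")$y
  spectrum$wavenumber <- grid
  spectrum$intensity <- yi
  append_step(spectrum, sprintf("resample(%g,%g,%g)", start, stop, step))
}

#' Crop a spectrum to the biological fingerprint region
#'
#' The 500-1800 cm^-1 fingerprint region carries the biomarker bands; all
#' downstream analysis works there.
#'
#' @param spectrum a `raman_spectrum`.
#' @param lo,hi crop bounds (cm^-1), `lo < hi`.
#' @return cropped `raman_spectrum`.
#' @export
crop_fingerprint <- function(spectrum, lo = 500, hi = 1800) {
  validate_spectrum(spectrum)
  if (lo >= hi) abort("lo must be < hi", "sipraman_range_error")
  keep <- spectrum$wavenumber >= lo & spectrum$wavenumber <= hi
  if (sum(keep) < 2L)
    abort(sprintf("crop [%g, %g] leaves no usable points", lo, hi),
          "sipraman_range_error")
  if (all(keep)) return(append_step(spectrum, sprintf("crop(%g,%g)", lo, hi)))
  spectrum$wavenumber <- spectrum$wavenumber[keep]
  spectrum$intensity <- spectrum$intensity[keep]
  append_step(spectrum, sprintf("crop(%g,%g)", lo, hi))
}

# Asymmetric least squares baseline: penalized regression where points above
# the current estimate get weight p and points below get 1 - p, iterated to
# a fixed point; the second-difference penalty lambda sets stiffness.
asls_baseline <- function(y, lambda = 1e5, p = 0.01, n_iter = 10L) {
  m <- length(y)
  D <- Matrix::bandSparse(m - 2L, m, k = 0:2,
                          diagonals = list(rep(1, m - 2L), rep(-2, m - 2L),
                                           rep(1, m - 2L)))
  P <- lambda * Matrix::crossprod(D)
  w <- rep(1, m)
  converged <- FALSE
  for (i in seq_len(n_iter)) {
    W <- Matrix::Diagonal(x = w)
    z <- as.numeric(Matrix::solve(W + P, w * y))
    w_new <- ifelse(y > z, p, 1 - p)
    if (identical(w_new, w)) { converged <- TRUE; break }
    w <- w_new
  }
  list(baseline = z, converged = converged)
}

#' Subtract a slowly varying (fluorescence) baseline
#'
#' Asymmetric least squares: a stiff smooth curve is fit under the spectrum
#' so that peaks sit on, not in, the baseline estimate. The estimate is kept
#' on the result (`$baseline`) for inspection; non-convergence within
#' `n_iter` sets `meta$baseline_converged = FALSE` rather than erroring.
#'
#' @param spectrum a `raman_spectrum` with at least 16 points.
#' @param lambda smoothness weight (larger = stiffer baseline).
#' @param p asymmetry in (0, 0.5); small values let peaks escape upward.
#' @param n_iter maximum reweighting iterations.
#' @return baseline-subtracted `raman_spectrum` with `$baseline` attached.
#' @export
correct_baseline <- function(spectrum, lambda = 1e5, p = 0.01, n_iter = 10L) {
  validate_spectrum(spectrum)
  if (length(spectrum$wavenumber) < 16L)
    abort("baseline correction needs >= 16 points", "sipraman_parameter_error")
  res <- asls_baseline(spectrum$intensity, lambda, p, n_iter)
  spectrum$intensity <- spectrum$intensity - res$baseline
  spectrum$baseline <- res$baseline
  spectrum$meta$baseline_converged <- res$converged
  append_step(spectrum, sprintf("baseline_asls(%g,%g,%d)", lambda, p,
                                as.integer(n_iter)))
}

#' Savitzky-Golay smoothing
#'
#' Least-squares polynomial moving-window smoothing on a uniform axis;
#' endpoints use the truncated-window projection rows, so low-order
#' polynomial signals pass through unchanged.
#'
#' @param spectrum a `raman_spectrum` on a uniform grid.
#' @param window_cm1 window width in cm^-1; must cover at least
#'   `polyorder + 2` samples.
#' @param polyorder polynomial order.
#' @return smoothed `raman_spectrum`.
#' @export
smooth_spectrum <- function(spectrum, window_cm1 = 7, polyorder = 2L) {
  validate_spectrum(spectrum)
  x <- spectrum$wavenumber
  if (!is_uniform_axis(x))
    abort("smoothing needs a uniform axis; resample first",
          "sipraman_parameter_error")
  step <- axis_step(x)
  n <- 2L * floor(window_cm1 / (2 * step)) + 1L
  if (n < polyorder + 2L)
    abort(sprintf("window of %d sample(s) < polyorder + 2 = %d",
                  n, polyorder + 2L), "sipraman_parameter_error")
  n <- min(n, length(x) - (1 - length(x) %% 2L))
  spectrum$intensity <- sg_smooth(spectrum$intensity, polyorder, n)
  append_step(spectrum, sprintf("smooth_sg(%g,%d)", window_cm1,
                                as.integer(polyorder)))
}

sg_smooth <- function(y, p, n) {
  if (n >= length(y)) {
    n <- length(y) - (1 - length(y) %% 2L)  # largest odd <= length
    if (n < p + 2L) return(y)
  }
  as.numeric(signal::sgolayfilt(y, p = p, n = n))
}

#' Normalize a spectrum
#'
#' `l2` scales to unit Euclidean norm over the current axis (the default:
#' it makes every downstream comparison invariant to acquisition intensity),
#' `area` to unit trapezoidal integral of the positive part, `max` to unit
#' peak height.
#'
#' @param spectrum a `raman_spectrum`, not identically zero.
#' @param method one of `"l2"`, `"area"`, `"max"`.
#' @return normalized `raman_spectrum`.
#' @export
normalize_spectrum <- function(spectrum, method = c("l2", "area", "max")) {
  validate_spectrum(spectrum)
  method <- match.arg(method)
  y <- spectrum$intensity
  denom <- switch(method,
    l2 = sqrt(sum(y^2)),
    area = trapz(spectrum$wavenumber, pmax(y, 0)),
    max = max(y))
  if (!is.finite(denom) || denom <= 0)
    abort("cannot normalize a zero (or non-positive) spectrum",
          "sipraman_normalization_error")
  spectrum$intensity <- y / denom
  append_step(spectrum, sprintf("normalize_%s", method))
}

# Optional cosmic-ray despike (off by default in the standard chain):
# replaces points deviating from a running median by more than k robust SDs.
despike_spectrum <- function(spectrum, k = 6) {
  y <- spectrum$intensity
  med <- stats::runmed(y, 5)
  resid <- y - med
  s <- stats::mad(resid)
  if (s > 0) {
    bad <- abs(resid) > k * s
    y[bad] <- med[bad]
  }
  spectrum$intensity <- y
  append_step(spectrum, "despike")
}

#' Average a cohort of spectra into a mean trace with an SD envelope
#'
#' Pointwise mean and population standard deviation across cells sharing an
#' identical axis (resample first), as used for mean-spectrum figures with
#' shaded SD envelopes.
#'
#' @param set a `raman_set` whose spectra share one axis.
#' @return an object of class `mean_spectrum`: list with `wavenumber`,
#'   `mean`, `sd`, `n`.
#' @export
average_spectra <- function(set) {
  if (!inherits(set, "raman_set") || length(set$spectra) == 0L)
    abort("need a non-empty raman_set", "sipraman_parameter_error")
  ax <- set$spectra[[1L]]$wavenumber
  for (s in set$spectra)
    if (length(s$wavenumber) != length(ax) ||
        max(abs(s$wavenumber - ax)) > 1e-9)
      abort("spectra are on differing axes; resample to a shared grid first",
            "sipraman_axis_error")
  Y <- do.call(rbind, lapply(set$spectra, function(s) s$intensity))
  mu <- colMeans(Y)
  n <- nrow(Y)
  sdv <- sqrt(colMeans(Y^2) - mu^2)
  sdv[sdv < 0 | !is.finite(sdv)] <- 0
  structure(list(wavenumber = ax, mean = mu, sd = sdv, n = n),
            class = "mean_spectrum")
}

#' @export
print.mean_spectrum <- function(x, ...) {
  cat(sprintf("<mean_spectrum> n = %d cells, %d points, %.1f-%.1f cm-1\n",
              x$n, length(x$wavenumber), min(x$wavenumber),
              max(x$wavenumber)))
  invisible(x)
}

#' Apply the standard preprocessing chain to one spectrum
#'
#' Resample to the working grid (clipped to the cell's own range), crop to
#' the fingerprint region, subtract the asymmetric-least-squares baseline,
#' and normalize. This is the chain [sip_raman()] applies before band
#' fitting.
#'
#' @param spectrum a `raman_spectrum`.
#' @param grid numeric `c(start, stop, step)` working grid (cm^-1).
#' @param baseline list of [correct_baseline()] parameters, or `NULL` to
#'   skip baseline subtraction.
#' @param normalize normalization method (see [normalize_spectrum()]), or
#'   `NULL` to skip.
#' @param despike logical; median-filter cosmic-ray removal (off by
#'   default).
#' @return preprocessed `raman_spectrum`.
#' @export
preprocess_spectrum <- function(spectrum, grid = c(500, 1800, 1),
                                baseline = list(lambda = 1e5, p = 0.01,
                                                n_iter = 10L),
                                normalize = "l2", despike = FALSE) {
  validate_spectrum(spectrum)
  rng <- range(spectrum$wavenumber)
  step <- grid[3]
  start <- grid[1] + step * ceiling(max(0, rng[1] - grid[1]) / step)
  stop <- grid[1] + step * floor((min(grid[2], rng[2]) - grid[1]) / step)
  if (stop - start < step)
    abort("working grid does not overlap the spectrum",
          "sipraman_range_error")
  s <- resample_to_grid(spectrum, start, stop, step)
  if (despike) s <- despike_spectrum(s)
  s <- crop_fingerprint(s, grid[1], grid[2])
  if (!is.null(baseline) && length(s$wavenumber) >= 16L)
    s <- correct_baseline(s, baseline$lambda %||% 1e5,
                          baseline$p %||% 0.01,
                          baseline$n_iter %||% 10L)
  if (!is.null(normalize)) s <- normalize_spectrum(s, normalize)
  s
}
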