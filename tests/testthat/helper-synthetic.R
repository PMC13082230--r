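# Shared fixture builders and independent oracles. Everything here is
# generated in code; the oracle model evaluation is written independently
# of the package's band-fitting path (direct dense evaluation + argmax).

toy_spectrum <- function(x, y, ...) raman_spectrum(x, y, ...)

# single pseudo-Voigt band (optionally on a linear ramp) on a 1 cm-1 grid
single_band_cell <- function(center = 747, fwhm = 12, amplitude = 1,
                             lo = center - 150, hi = center + 150,
                             slope = 0, intercept = 0, eta = 0.5,
                             cell_id = "toy") {
  x <- seq(lo, hi, by = 1)
  y <- pseudo_voigt(x, center, fwhm, amplitude, eta) + slope * x + intercept
  raman_spectrum(x, y, cell_id = cell_id)
}

# noiseless, jitter-free generator configuration
noiseless_config <- function(table = "reference_strains", ...) {
  sim_config(band_table = table, snr = Inf, jitter_sd = 0,
             intensity_cv = 0, ...)
}

# Independent dense-evaluation oracle for apex positions: rebuilds the
# generative model (same published shape conventions as the simulator
# defaults: Cyt c amplitudes 1.0/0.6/0.7/0.9 with FWHM 12, phenylalanine
# 0.5 with FWHM 8, background bands 1240/1450/1664 at 0.2/0.3/0.3 with
# FWHM 16, Gaussian instrument FWHM 3) from scratch with its own
# convolution, evaluates it on a fine grid, and takes the argmax in a
# band's search window.
oracle_clean_model <- function(table, f, x) {
  b <- table$bands
  phe <- grepl("^phe", b$name)
  amp <- numeric(nrow(b))
  amp[!phe] <- rep_len(c(1.0, 0.6, 0.7, 0.9), sum(!phe))
  amp[phe] <- 0.5
  fwhm <- ifelse(phe, 8, 12)
  y <- numeric(length(x))
  for (i in seq_len(nrow(b))) {
    ci <- (1 - f) * b$c12[i] + f * b$c13[i]
    y <- y + pseudo_voigt(x, ci, fwhm[i], amp[i])
  }
  for (j in seq_along(c(1240, 1450, 1664)))
    y <- y + pseudo_voigt(x, c(1240, 1450, 1664)[j], 16, c(0.2, 0.3, 0.3)[j])
  # Gaussian instrument broadening, independent implementation
  step <- x[2] - x[1]
  sdk <- 3 / (2 * sqrt(2 * log(2)))
  kx <- seq(-4 * sdk, 4 * sdk, by = step)
  k <- exp(-kx^2 / (2 * sdk^2)); k <- k / sum(k)
  h <- (length(k) - 1) / 2
  yp <- c(rep(y[1], h), y, rep(y[length(y)], h))
  ys <- numeric(length(y))
  for (i in seq_along(y)) ys[i] <- sum(yp[i:(i + 2 * h)] * rev(k))
  ys
}

oracle_apex <- function(table, f, band_row, by = 0.01) {
  wlo <- band_row$c13 - band_row$window_halfwidth
  whi <- band_row$c12 + band_row$window_halfwidth
  x <- seq(wlo - 30, whi + 30, by = by)
  y <- oracle_clean_model(table, f, x)
  inwin <- x >= wlo & x <= whi
  x[inwin][which.max(y[inwin])]
}

# local maxima (interior) of a dense curve, tallest first
dense_local_maxima <- function(x, y) {
  m <- length(y)
  i <- which(y[2:(m - 1)] >= y[1:(m - 2)] & y[2:(m - 1)] > y[3:m]) + 1L
  i <- i[order(y[i], decreasing = TRUE)]
  x[i]
}
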