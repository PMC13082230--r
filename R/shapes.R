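#' Pseudo-Voigt band profile
#'
#' Linear mixture of a Lorentzian and a Gaussian sharing one center and one
#' full width at half maximum — the standard line-shape model for Raman
#' bands. `amplitude` is the peak height (the profile equals `amplitude` at
#' `center` for any mixing parameter).
#'
#' @param x wavenumber axis (cm^-1).
#' @param center band center (cm^-1).
#' @param fwhm full width at half maximum (cm^-1), > 0.
#' @param amplitude peak height (arbitrary units).
#' @param eta Lorentzian fraction in `[0, 1]`; 1 = pure Lorentzian,
#'   0 = pure Gaussian.
#' @return numeric vector of profile values at `x`.
#' @export
#' @examples
#' x <- seq(700, 800, by = 0.5)
#' y <- pseudo_voigt(x, center = 747, fwhm = 12, amplitude = 1)
#' x[which.max(y)]
pseudo_voigt <- function(x, center, fwhm, amplitude = 1, eta = 0.5) {
  if (fwhm <= 0) abort("fwhm must be > 0", "sipraman_parameter_error")
  u <- (x - center) / (fwhm / 2)
  lor <- 1 / (1 + u^2)
  gau <- exp(-log(2) * u^2)
  amplitude * (eta * lor + (1 - eta) * gau)
}

# Normalized Gaussian convolution kernel on a uniform grid.
gaussian_kernel <- function(fwhm, step) {
  sd <- fwhm / (2 * sqrt(2 * log(2)))
  half <- max(1L, ceiling(4 * sd / step))
  x <- (-half:half) * step
  k <- exp(-x^2 / (2 * sd^2))
  k / sum(k)
}

# Gaussian instrument broadening by discrete convolution; edges handled by
# replicate padding so the output has the input's length.
broaden <- function(y, fwhm, step) {
  if (fwhm <= 0) return(y)
  k <- gaussian_kernel(fwhm, step)
  h <- (length(k) - 1L) / 2L
  ypad <- c(rep(y[1L], h), y, rep(y[length(y)], h))
  out <- stats::filter(ypad, k, sides = 2)
  as.numeric(out)[(h + 1L):(h + length(y))]
}
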