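# Independent oracles the implementation is checked against.

# O(N^2) direct-summation DFT amplitude spectrum: mean-subtract, zero-pad,
# evaluate bins 1 .. n_fft/2 by explicit sums.
dft_oracle <- function(values, n_fft) {
  x <- c(values - mean(values), rep(0, n_fft - length(values)))
  n <- seq_along(x) - 1L
  vapply(seq_len(n_fft %/% 2L), function(k) {
    re <- sum(x * cos(2 * pi * k * n / n_fft))
    im <- sum(x * sin(2 * pi * k * n / n_fft))
    sqrt(re^2 + im^2)
  }, numeric(1))
}

# a toy EIIP-like table covering the 20 standard residues, with chosen
# values on a few residues for direct-lookup tests
toy_eiip_table <- function(override = c(A = 0.1, G = 0.2)) {
  standard <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  v <- stats::setNames(seq(0, 0.19, by = 0.01), standard)
  v[names(override)] <- override
  structure(v, table_mean = mean(v), class = "eiip_table")
}

# closed-form Gaussian band, FWHM parameterization
gauss_band <- function(w, center, fwhm, amplitude = 1) {
  amplitude * exp(-4 * log(2) * (w - center)^2 / fwhm^2)
}

# analytic second derivative of a Gaussian band
gauss_band_d2 <- function(w, center, fwhm, amplitude = 1) {
  b <- 4 * log(2) / fwhm^2
  amplitude * exp(-b * (w - center)^2) * (4 * b^2 * (w - center)^2 - 2 * b)
}

# analytic integral of a Gaussian band over [lo, hi]
gauss_band_area <- function(center, fwhm, amplitude, lo, hi) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  amplitude * sigma * sqrt(2 * pi) *
    (stats::pnorm((hi - center) / sigma) - stats::pnorm((lo - center) / sigma))
}

# flat-grid ir_spectrum shorthand
flat_spectrum <- function(lo = 900, hi = 1800, step = 1, value = 0) {
  w <- seq(lo, hi, by = step)
  ir_spectrum(w, rep(value, length(w)))
}
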