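#' Default transform length for a series
#'
#' The informational spectrum of a molecule pair must live on a shared
#' frequency grid, so series are zero-padded to
#' `max(512, next power of two >= n)`.  A 512-point grid places a bin at
#' 8/512 = 0.015625, the representable frequency closest to the commonly
#' reported ligand frequency 0.016.
#'
#' @param n Series length (or the longer of a pair).
#' @return An even integer FFT length.
#' @export
default_n_fft <- function(n) {
  n <- as.integer(n)
  stopifnot(n >= 1L)
  max(512L, 2L^as.integer(ceiling(log2(n))))
}

#' Informational spectrum of a numeric series
#'
#' Step 2 of the ISM: the series is mean-subtracted (so constant
#' sequences carry no signal), zero-padded to `n_fft`, and discrete
#' Fourier transformed.  The spectrum holds the amplitude (magnitude) at
#' bins 1 ... n_fft/2, i.e. normalized frequencies k/n_fft in (0, 0.5];
#' the DC bin is excluded.
#'
#' @param series A [numeric_series()] or bare numeric vector.
#' @param n_fft Even transform length, at least the series length.
#' @return An object of class `amplitude_spectrum`: a list with
#'   `n_fft`, `frequencies`, `amplitudes`, and `molecule_id`.
#' @export
#' @examples
#' is1 <- informational_spectrum(cos(2 * pi * 8 * (0:511) / 512), 512)
#' dominant_frequency(is1)  # 8/512 = 0.015625
informational_spectrum <- function(series, n_fft = NULL) {
  if (inherits(series, "numeric_series")) {
    values <- series$values
    id <- series$molecule_id
  } else {
    values <- as.numeric(series)
    id <- "series"
  }
  n <- length(values)
  if (n < 2L) stop("series must have at least 2 values")
  if (is.null(n_fft)) n_fft <- default_n_fft(n)
  n_fft <- as.integer(n_fft)
  if (n_fft %% 2L != 0L) stop("n_fft must be even")
  if (n_fft < n) stop("n_fft must be >= series length")
  x <- c(values - mean(values), rep(0, n_fft - n))
  amp <- Mod(stats::fft(x))[2:(n_fft %/% 2L + 1L)]
  structure(list(n_fft = n_fft,
                 frequencies = seq_len(n_fft %/% 2L) / n_fft,
                 amplitudes = amp,
                 molecule_id = id),
            class = "amplitude_spectrum")
}

#' @export
print.amplitude_spectrum <- function(x, ...) {
  cat(sprintf("<%s> %s: n_fft %d, %d bins in (0, 0.5]\n",
              class(x)[1L], x$molecule_id, x$n_fft, length(x$frequencies)))
  if (!is.null(x$dominant_frequency)) {
    cat(sprintf("  dominant frequency %.6g, S/N %.4f%s\n",
                x$dominant_frequency, x$snr,
                if (isTRUE(x$degenerate)) " (degenerate)" else ""))
  }
  invisible(x)
}

#' Cross-spectrum of two informational spectra
#'
#' Step 3 of the ISM: element-wise product of two amplitude spectra on a
#' common frequency grid.  A shared pronounced peak of the two molecules
#' survives the product and becomes the dominant cross-spectrum peak; its
#' frequency and signal-to-noise are recorded on the result.
#'
#' @param a,b `amplitude_spectrum` objects with identical `n_fft`.
#' @return An object of classes `cross_spectrum` and
#'   `amplitude_spectrum` with extra fields `dominant_frequency`, `snr`
#'   and `degenerate`.  When every product amplitude is zero the
#'   cross-spectrum is flagged degenerate and both statistics are `NA`.
#' @export
cross_spectrum <- function(a, b) {
  stopifnot(inherits(a, "amplitude_spectrum"),
            inherits(b, "amplitude_spectrum"))
  if (a$n_fft != b$n_fft) {
    stop(sprintf(paste0("spectra live on different grids (n_fft %d vs %d); ",
                        "re-pad both series to a common n_fft"),
                 a$n_fft, b$n_fft))
  }
  amp <- a$amplitudes * b$amplitudes
  cs <- structure(list(n_fft = a$n_fft,
                       frequencies = a$frequencies,
                       amplitudes = amp,
                       molecule_id = paste(a$molecule_id, b$molecule_id,
                                           sep = " x ")),
                  class = c("cross_spectrum", "amplitude_spectrum"))
  if (all(amp == 0)) {
    cs$degenerate <- TRUE
    cs$dominant_frequency <- NA_real_
    cs$snr <- NA_real_
  } else {
    cs$degenerate <- FALSE
    cs$dominant_frequency <- dominant_frequency(cs)
    cs$snr <- snr_at(cs, cs$dominant_frequency)
  }
  cs
}

#' Frequency of the most pronounced spectral peak
#'
#' @param s An `amplitude_spectrum`, or a list with `frequencies` and
#'   `amplitudes`.
#' @return The grid frequency of the maximum amplitude; ties are broken
#'   toward the lowest frequency.
#' @export
dominant_frequency <- function(s) {
  if (all(s$amplitudes == 0)) {
    stop("all amplitudes are zero; dominant frequency is undefined")
  }
  s$frequencies[which.max(s$amplitudes)]
}

#' Signal-to-noise of a spectrum at a frequency
#'
#' S/N is the amplitude at the queried grid frequency divided by the mean
#' amplitude over all grid frequencies — the standard ISM peak statistic.
#' It is invariant under uniform rescaling of the underlying series.
#'
#' @param s An `amplitude_spectrum` (or list with `frequencies`,
#'   `amplitudes`).
#' @param at A frequency on the grid.
#' @return The S/N ratio (a positive real).
#' @export
snr_at <- function(s, at) {
  i <- which(abs(s$frequencies - at) <= 1e-12)
  if (length(i) != 1L) stop("frequency ", at, " is not on the spectrum grid")
  m <- mean(s$amplitudes)
  if (m == 0) stop("zero-mean spectrum; S/N is undefined")
  s$amplitudes[i] / m
}

#' Export a spectrum as tab-separated text
#'
#' Writes `frequency<TAB>amplitude` rows at 6 significant digits.
#'
#' @param s An `amplitude_spectrum`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path) {
  rows <- sprintf("%s\t%s",
                  formatC(s$frequencies, format = "g", digits = 6),
                  formatC(s$amplitudes, format = "g", digits = 6))
  writeLines(c("frequency\tamplitude", rows), path)
  invisible(path)
}
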