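test_that("protein encoding is a direct EIIP lookup with policy handling", {
  tab <- toy_eiip_table(c(A = 0.1, G = 0.2))
  expect_equal(encode_protein("AGGA", tab)$values, c(0.1, 0.2, 0.2, 0.1))
  expect_equal(encode_protein(" ag\nGA ", tab)$values,
               c(0.1, 0.2, 0.2, 0.1))
  expect_error(encode_protein("", tab), "empty sequence")
  m <- attr(tab, "table_mean")
  expect_warning(s <- encode_protein("AXA", tab), "non-standard")
  expect_equal(s$values, c(0.1, m, 0.1))
  expect_error(encode_protein("AXA", tab, unknown_policy = "error"),
               "position 2")
})

test_that("packaged EIIP table covers the 20 residues with the stated mean", {
  tab <- eiip_table()
  expect_length(unclass(tab), 20L)
  expect_true(all(is.finite(tab)))
  expect_equal(attr(tab, "table_mean"), mean(unclass(tab)))
})

test_that("ligand profile files parse, validate and round-trip exactly", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("1\t0.5", "2\t0.3"), f)
  prof <- read_ligand_profile(f)
  expect_equal(prof$values, c(0.5, 0.3))
  expect_equal(prof$source, "ligand_profile")

  writeLines(c("1, 0.5", "2, abc"), f)
  expect_error(read_ligand_profile(f), "line 2")

  writeLines(c("1\t0.5", "3\t0.3"), f)
  expect_error(read_ligand_profile(f), "consecutively")

  writeLines("1\t0.5", f)
  expect_error(read_ligand_profile(f), "at least 2")

  orig <- numeric_series("m", c(pi, exp(1), 1 / 3, -2.5e-7),
                         source = "ligand_profile")
  write_series(orig, f)
  expect_identical(read_ligand_profile(f, "m")$values, orig$values)
})

test_that("informational spectrum matches a direct-summation DFT oracle", {
  set.seed(42)
  for (len in c(2L, 5L, 13L, 31L, 64L)) {
    x <- rnorm(len)
    n_fft <- if (len <= 13L) 32L else 128L
    s <- informational_spectrum(x, n_fft)
    o <- dft_oracle(x, n_fft)
    expect_lt(max(abs(s$amplitudes - o)) / max(o), 1e-9)
    expect_equal(s$frequencies, seq_len(n_fft / 2) / n_fft)
  }
})

test_that("mean removal kills constant series; on-bin cosine is a single peak", {
  s <- informational_spectrum(rep(3.7, 40), 512)
  expect_lt(max(s$amplitudes), 1e-12)

  cosx <- cos(2 * pi * 8 * (0:511) / 512)
  s <- informational_spectrum(cosx, 512)
  expect_equal(dominant_frequency(s), 8 / 512)
  expect_lt(max(s$amplitudes[-8]), 1e-9 * s$amplitudes[8])
})

test_that("transform-length preconditions are enforced", {
  expect_error(informational_spectrum(rnorm(20), 16), ">= series length")
  expect_error(informational_spectrum(rnorm(20), 21), "even")
  expect_equal(default_n_fft(13), 512L)
  expect_equal(default_n_fft(513), 1024L)
})

test_that("cross-spectrum multiplies amplitudes, is commutative, flags zeros", {
  set.seed(7)
  a <- informational_spectrum(rnorm(30), 64)
  expect_equal(cross_spectrum(a, a)$amplitudes, a$amplitudes^2)

  b <- informational_spectrum(rnorm(50), 64)
  ab <- cross_spectrum(a, b)
  ba <- cross_spectrum(b, a)
  expect_equal(ab$amplitudes, ba$amplitudes)
  expect_equal(ab$dominant_frequency, ba$dominant_frequency)
  expect_equal(ab$snr, ba$snr)
  expect_true(all(cross_spectrum(a, a)$amplitudes >= 0))

  z <- informational_spectrum(rep(1, 10), 64)  # all-zero spectrum
  cz <- cross_spectrum(a, z)
  expect_true(cz$degenerate)
  expect_true(is.na(cz$dominant_frequency))
  expect_true(is.na(cz$snr))

  c128 <- informational_spectrum(rnorm(30), 128)
  expect_error(cross_spectrum(a, c128), "re-pad")
})

test_that("two noisy series sharing a planted bin give that CS frequency", {
  set.seed(11)
  t <- 0:511
  x <- cos(2 * pi * 8 * t / 512) + rnorm(512, 0, 0.2)
  y <- cos(2 * pi * 8 * t / 512) + rnorm(512, 0, 0.2)
  cs <- cross_spectrum(informational_spectrum(x, 512),
                       informational_spectrum(y, 512))
  expect_equal(cs$dominant_frequency, 8 / 512)
})

test_that("dominant frequency is the argmax with low-frequency tie-break", {
  f <- (1:4) / 8
  s <- list(frequencies = f, amplitudes = c(0, 5, 0, 0))
  expect_equal(dominant_frequency(s), f[2])
  s$amplitudes <- c(3, 3, 1, 0)
  expect_equal(dominant_frequency(s), f[1])
  set.seed(3)
  for (i in 1:20) {
    amp <- abs(rnorm(32))
    s <- list(frequencies = (1:32) / 64, amplitudes = amp)
    scan <- s$frequencies[order(-amp)][1]  # linear-scan argmax
    expect_equal(dominant_frequency(s), scan)
  }
  s$amplitudes <- rep(0, 32)
  expect_error(dominant_frequency(s), "zero")
})

test_that("S/N is peak over mean amplitude", {
  f <- (1:10) / 20
  flat <- list(frequencies = f, amplitudes = rep(2.5, 10))
  expect_equal(snr_at(flat, f[4]), 1.0)
  onehot <- list(frequencies = f, amplitudes = c(rep(0, 9), 7))
  expect_equal(snr_at(onehot, f[10]), 10)
  set.seed(5)
  amp <- abs(rnorm(10)) + 0.1
  s <- list(frequencies = f, amplitudes = amp)
  expect_equal(snr_at(s, f[3]), amp[3] / mean(amp), tolerance = 1e-12)
  expect_error(snr_at(s, 0.123), "not on the spectrum grid")
  expect_error(snr_at(list(frequencies = f, amplitudes = rep(0, 10)), f[1]),
               "zero-mean")
})

test_that("rescaling a series scales amplitudes but not frequency or S/N", {
  set.seed(9)
  x <- rnorm(40)
  s1 <- informational_spectrum(x, 128)
  s2 <- informational_spectrum(3.5 * x, 128)
  expect_equal(s2$amplitudes, 3.5 * s1$amplitudes)
  expect_equal(dominant_frequency(s1), dominant_frequency(s2))
  f <- dominant_frequency(s1)
  expect_equal(snr_at(s1, f), snr_at(s2, f))
})

test_that("planted-cosine S/N is monotone in amplitude for fixed noise", {
  set.seed(13)
  noise <- rnorm(256)
  t <- 0:255
  snrs <- vapply(c(0.5, 1, 2, 4, 8), function(a) {
    s <- informational_spectrum(noise + a * cos(2 * pi * 16 * t / 512), 512)
    snr_at(s, 16 / 512)
  }, numeric(1))
  expect_true(all(diff(snrs) > 0))
  # and the dominant frequency locks onto the planted bin at high amplitude
  s <- informational_spectrum(noise + 8 * cos(2 * pi * 16 * t / 512), 512)
  expect_equal(dominant_frequency(s), 16 / 512)
})

test_that("spectrum export writes the documented two-column dialect", {
  s <- informational_spectrum(rnorm(16), 32)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_spectrum(s, f)
  dat <- read.delim(f)
  expect_equal(names(dat), c("frequency", "amplitude"))
  expect_equal(dat$frequency, s$frequencies, tolerance = 1e-5)
  expect_equal(dat$amplitude, s$amplitudes, tolerance = 1e-5)
})
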