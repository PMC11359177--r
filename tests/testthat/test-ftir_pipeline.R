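test_that("cropping restricts the grid inclusively and rejects empty overlap", {
  s <- flat_spectrum(900, 1800, 1, 0.5)
  c1 <- crop_spectrum(s, 1480, 1700)
  expect_equal(range(c1$wavenumber), c(1480, 1700))
  expect_equal(grid_step <- diff(c1$wavenumber[1:2]), 1)
  expect_equal(crop_spectrum(s, 900, 1800)$wavenumber, s$wavenumber)
  expect_error(crop_spectrum(s, 2000, 2100), "does not overlap")
})

test_that("descending grids are reversed; non-uniform grids rejected", {
  s <- ir_spectrum(seq(1800, 900, by = -1), seq_len(901))
  expect_equal(s$wavenumber[1], 900)
  expect_equal(s$absorbance[1], 901)
  expect_error(ir_spectrum(c(1, 2, 4), c(0, 0, 0)), "uniform")
})

test_that("rubber-band baseline removes hulls and preserves band areas", {
  w <- seq(900, 1800, by = 1)
  # a line is its own hull
  ramp <- ir_spectrum(w, 0.2 + 3e-4 * w)
  expect_lt(max(abs(rubberband_baseline(ramp)$absorbance)), 1e-12)

  # convex quadratic baseline + one Gaussian band: corrected area within
  # 2% of the analytic band area
  x <- w - 1350
  band <- gauss_band(w, 1650, 25, 1)
  s <- ir_spectrum(w, 0.1 + 1e-5 * x + 3e-7 * x^2 + band)
  corr <- rubberband_baseline(s)
  got <- amide_area(corr, 1550, 1750)
  want <- gauss_band_area(1650, 25, 1, 1550, 1750)
  expect_lt(abs(got - want) / want, 0.02)

  # output is non-negative (to 1e-9) with exactly-zero endpoints
  expect_gte(min(corr$absorbance), -1e-9)
  expect_identical(corr$absorbance[1], 0)
  expect_identical(corr$absorbance[length(w)], 0)

  # an already-corrected single-peak spectrum is a fixed point
  clean <- ir_spectrum(w, band)
  again <- rubberband_baseline(clean)
  expect_lt(max(abs(again$absorbance - clean$absorbance)), 1e-9)
})

test_that("vector normalization yields unit norm, scale-invariant direction", {
  s <- ir_spectrum(c(1000, 1001), c(3, 4))
  expect_equal(vector_normalize(s)$absorbance, c(0.6, 0.8))
  set.seed(4)
  x <- ir_spectrum(seq(900, 1000), abs(rnorm(101)) + 0.1)
  cx <- ir_spectrum(x$wavenumber, 7.3 * x$absorbance)
  expect_equal(vector_normalize(cx)$absorbance,
               vector_normalize(x)$absorbance)
  nx <- vector_normalize(x)
  expect_equal(vector_normalize(nx)$absorbance, nx$absorbance)
  expect_equal(sqrt(sum(nx$absorbance^2)), 1)
  expect_error(vector_normalize(flat_spectrum(value = 0)), "zero spectrum")
})

test_that("the SG second derivative is exact on polynomials and symmetric", {
  w <- seq(1000, 1200, by = 2)
  a <- 3e-4
  quad <- sg_second_derivative(ir_spectrum(w, a * w^2))
  expect_equal(quad$absorbance, rep(2 * a, length(quad$wavenumber)),
               tolerance = 1e-9)
  # trimming: 7 points lost at each edge for a 15-point window
  expect_equal(length(quad$wavenumber), length(w) - 14L)
  expect_equal(quad$wavenumber[1], w[8])

  b <- 1e-7
  cub <- sg_second_derivative(ir_spectrum(w, b * w^3))
  expect_equal(cub$absorbance, 6 * b * cub$wavenumber, tolerance = 1e-9)

  # noiseless on-grid Gaussian: global minimum exactly at the centre
  wg <- seq(900, 1800, by = 1)
  d2 <- sg_second_derivative(ir_spectrum(wg, gauss_band(wg, 1650, 25)))
  expect_equal(d2$wavenumber[which.min(d2$absorbance)], 1650)

  expect_error(sg_second_derivative(ir_spectrum(w, w), window_points = 14),
               "odd")
  expect_error(sg_second_derivative(ir_spectrum(w, w), window_points = 15,
                                    poly_order = 15), "smaller")
  expect_error(sg_second_derivative(ir_spectrum(w[1:10], w[1:10])),
               "shorter")
})

test_that("the six amide sub-bands are detected within 2 cm^-1 of the table", {
  g <- generate_cell_spectra(band_mix_spec(noise_sd = 0),
                             list(treatment_effect("c", n_cells = 2)),
                             seed = 1)
  q <- detect_sub_bands(process_spectrum(g$spectra[[1]])$d2)
  expect_equal(nrow(q), 6L)
  expect_true(all(q$present))
  expect_true(all(abs(q$detected_center - q$center) <= 2))
  expect_true(all(q$d2_intensity > 0))
})

test_that("a flat spectrum has no detectable sub-bands", {
  d2 <- sg_second_derivative(flat_spectrum(1400, 1750, 1, 0.3))
  q <- detect_sub_bands(d2)
  expect_true(all(!q$present))
  expect_true(all(is.na(q$detected_center)))
})

test_that("overlapping-band minima match the analytic second derivative", {
  # two Gaussians 12 cm^-1 apart, 25 cm^-1 FWHM: heavily overlapped
  w <- seq(1550, 1750, by = 1)
  mix <- gauss_band(w, 1644, 25, 1) + gauss_band(w, 1656, 25, 0.8)
  d2 <- sg_second_derivative(ir_spectrum(w, mix))
  got_mins <- d2$wavenumber[which(diff(sign(diff(d2$absorbance))) > 0) + 1]

  wd <- seq(1560, 1740, by = 0.01)  # dense analytic oracle
  od2 <- gauss_band_d2(wd, 1644, 25, 1) + gauss_band_d2(wd, 1656, 25, 0.8)
  oracle_mins <- wd[which(diff(sign(diff(od2))) > 0) + 1]

  expect_equal(length(got_mins), length(oracle_mins))
  expect_true(all(abs(got_mins - oracle_mins) <= 1))
})

test_that("coverage violations in band detection are errors", {
  d2 <- sg_second_derivative(flat_spectrum(1500, 1700, 1, 0.1))
  expect_error(detect_sub_bands(d2), "does not cover")
})

test_that("amide area integrates trapezoidally with closed-form checks", {
  w <- seq(900, 1800, by = 1)
  rect <- ir_spectrum(w, as.numeric(w >= 1600 & w <= 1700))
  expect_equal(amide_area(rect), 100)

  g <- ir_spectrum(w, gauss_band(w, 1650, 25, 2))
  sigma <- 25 / (2 * sqrt(2 * log(2)))
  expect_equal(amide_area(g), 2 * sigma * sqrt(2 * pi), tolerance = 0.005)

  s <- ir_spectrum(seq(900, 1700), rep(1, 801))
  expect_error(amide_area(s, 1750, 1800), "outside the")
})

test_that("group comparison matches hand-computed ANOVA arithmetic", {
  # 2 groups x 3 values, sums worked by hand:
  # g1 = {1, 2, 3} mean 2; g2 = {5, 6, 10} mean 7
  # SSB = 3*(2-4.5)^2 + 3*(7-4.5)^2 = 37.5 (df 1)
  # SSW = (0+1+1) + (4+1+9) = 16 (df 4); F = 37.5 / (16/4) = 9.375
  cmp <- compare_groups(c(1, 2, 3, 5, 6, 10), rep(c("a", "b"), each = 3))
  expect_equal(cmp$f_statistic, 9.375)
  expect_equal(cmp$p_value, stats::pf(9.375, 1, 4, lower.tail = FALSE))
  expect_equal(cmp$groups$mean, c(2, 7))
  expect_equal(cmp$groups$n, c(3L, 3L))

  expect_error(compare_groups(c(0, 0, 0, 0), c("a", "a", "b", "b")),
               "degenerate groups")
  expect_error(compare_groups(1:4, rep("a", 4)), "at least 2 groups")
  expect_error(compare_groups(1:3, c("a", "a", "b")), "at least 2 values")
})

test_that("ANOVA type-I error is ~5% when both groups share a distribution", {
  set.seed(77)
  n_sim <- 1000
  rej <- 0L
  for (i in seq_len(n_sim)) {
    v <- rnorm(20)
    p <- compare_groups(v, rep(c("a", "b"), each = 10))$p_value
    if (p < 0.05) rej <- rej + 1L
  }
  se <- sqrt(0.05 * 0.95 / n_sim)
  expect_lt(abs(rej / n_sim - 0.05), 3 * se)
})

test_that("band depth responds linearly to the generator amplitude", {
  # SG filtering is linear, so with every other band fixed the second
  # derivative at the 1635 grid point is exactly affine in the 1635
  # amplitude; the detected depth grows monotonically with it.
  d2_and_depth <- function(mult) {
    b <- amide_band_table()
    b$fwhm <- c(22, 25, 25, 25, 14, 12)
    b$amplitude <- c(0.5, 1.0, mult * 0.65, 0.75, 0.3, 0.2)
    b$shape <- "gaussian"
    g <- generate_cell_spectra(band_mix_spec(bands = b, baseline_coeffs = 0,
                                             noise_sd = 0),
                               list(treatment_effect("c", n_cells = 2)),
                               seed = 1)
    d2 <- sg_second_derivative(crop_spectrum(g$spectra[[1]], 1480, 1700))
    q <- detect_sub_bands(d2)
    c(at1635 = d2$absorbance[d2$wavenumber == 1635],
      depth = q$d2_intensity[q$center == 1635])
  }
  r <- vapply(c(0.5, 1, 2), d2_and_depth, numeric(2))
  # affine: second difference over the {0.5, 1, 2} grid vanishes
  expect_equal(r["at1635", 3] - r["at1635", 2],
               2 * (r["at1635", 2] - r["at1635", 1]),
               tolerance = 1e-9)
  expect_true(all(diff(r["depth", ]) > 0))
})

test_that("a -3 cm^-1 shift of the amide I component moves the band maximum", {
  groups <- list(treatment_effect("control", n_cells = 2),
                 treatment_effect("shifted",
                                  center_shifts = c("1656" = -3),
                                  n_cells = 2))
  g <- generate_cell_spectra(band_mix_spec(noise_sd = 0), groups, seed = 1)
  peak_of <- function(s) {
    p <- process_spectrum(s)$spectrum
    k <- p$wavenumber >= 1600 & p$wavenumber <= 1700
    p$wavenumber[k][which.max(p$absorbance[k])]
  }
  shift <- peak_of(g$spectra[[3]]) - peak_of(g$spectra[[1]])
  expect_true(shift >= -4 && shift <= -2)
})

test_that("the pipeline runner applies crop, baseline, normalize, then d2", {
  g <- generate_cell_spectra(groups = list(treatment_effect("c", n_cells = 2)),
                             seed = 9)
  s <- g$spectra[[1]]
  pr <- process_spectrum(s, region = c(1480, 1700))
  manual <- vector_normalize(rubberband_baseline(crop_spectrum(s, 1480, 1700)))
  expect_equal(pr$spectrum$absorbance, manual$absorbance)
  expect_equal(pr$d2$absorbance, sg_second_derivative(manual)$absorbance)
})

test_that("the spectra CSV dialect round-trips cells, groups, and values", {
  g <- generate_cell_spectra(groups = list(treatment_effect("t1", n_cells = 3)),
                             seed = 12)
  f <- withr::local_tempfile(fileext = ".csv")
  write_spectra_csv(g$spectra, f)
  back <- read_spectra_csv(f)
  expect_equal(length(back), 3L)
  expect_equal(back[[2]]$cell_id, g$spectra[[2]]$cell_id)
  expect_equal(back[[2]]$group, "t1")
  expect_equal(back[[2]]$absorbance, g$spectra[[2]]$absorbance)
  expect_equal(back[[1]]$wavenumber, g$spectra[[1]]$wavenumber)
})
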