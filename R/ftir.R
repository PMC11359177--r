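#' Construct an infrared spectrum
#'
#' One cell's absorbance sampled on a uniform ascending wavenumber grid
#' (cm^-1).  Descending input grids are reversed on construction.
#'
#' @param wavenumber Numeric grid, cm^-1, uniformly spaced (relative
#'   tolerance 1e-9).
#' @param absorbance Numeric, same length.
#' @param cell_id Cell identifier.
#' @param group Treatment group label.
#' @return An object of class `ir_spectrum`.
#' @export
ir_spectrum <- function(wavenumber, absorbance, cell_id = "cell",
                        group = NA_character_) {
  wavenumber <- as.numeric(wavenumber)
  absorbance <- as.numeric(absorbance)
  if (length(wavenumber) != length(absorbance)) {
    stop("wavenumber and absorbance lengths differ")
  }
  if (length(wavenumber) < 2L) stop("a spectrum needs at least 2 points")
  if (wavenumber[1L] > wavenumber[length(wavenumber)]) {
    wavenumber <- rev(wavenumber)
    absorbance <- rev(absorbance)
  }
  d <- diff(wavenumber)
  if (any(d <= 0) || max(abs(d - d[1L])) > 1e-9 * abs(d[1L])) {
    stop("wavenumber grid must be uniform and strictly monotone")
  }
  structure(list(wavenumber = wavenumber, absorbance = absorbance,
                 cell_id = as.character(cell_id)[1L],
                 group = as.character(group)[1L]),
            class = "ir_spectrum")
}

#' @export
print.ir_spectrum <- function(x, ...) {
  cat(sprintf("<ir_spectrum> %s%s: %.6g-%.6g cm^-1, %d points\n",
              x$cell_id,
              if (is.na(x$group)) "" else paste0(" [", x$group, "]"),
              min(x$wavenumber), max(x$wavenumber), length(x$wavenumber)))
  invisible(x)
}

grid_step <- function(s) s$wavenumber[2L] - s$wavenumber[1L]

#' Crop a spectrum to a wavenumber window
#'
#' @param s An [ir_spectrum()].
#' @param lo,hi Window bounds, cm^-1 (`lo < hi`); the grid is restricted
#'   to `[lo, hi]` inclusive, spacing unchanged.
#' @return The cropped `ir_spectrum`.
#' @export
crop_spectrum <- function(s, lo, hi) {
  stopifnot(inherits(s, "ir_spectrum"), lo < hi)
  eps <- 1e-9 * grid_step(s)
  keep <- s$wavenumber >= lo - eps & s$wavenumber <= hi + eps
  if (!any(keep)) {
    stop(sprintf("crop window [%g, %g] does not overlap the %g-%g grid",
                 lo, hi, min(s$wavenumber), max(s$wavenumber)))
  }
  ir_spectrum(s$wavenumber[keep], s$absorbance[keep], s$cell_id, s$group)
}

# indices of the lower convex hull of (x, y), x strictly increasing
lower_hull <- function(x, y) {
  n <- length(x)
  h <- integer(n)
  k <- 0L
  for (i in seq_len(n)) {
    while (k >= 2L &&
           (x[h[k]] - x[h[k - 1L]]) * (y[i] - y[h[k - 1L]]) -
           (y[h[k]] - y[h[k - 1L]]) * (x[i] - x[h[k - 1L]]) <= 0) {
      k <- k - 1L
    }
    k <- k + 1L
    h[k] <- i
  }
  h[seq_len(k)]
}

#' Rubber-band baseline correction
#'
#' Estimates the baseline as the lower convex hull of the spectrum
#' (linear interpolation between hull vertices) and subtracts it: the
#' standard rubber-band correction.  Both endpoints of the result are
#' exactly zero and no point is below -1e-9.
#'
#' @param s An [ir_spectrum()] with at least 3 points.
#' @return The baseline-corrected `ir_spectrum`.
#' @export
rubberband_baseline <- function(s) {
  stopifnot(inherits(s, "ir_spectrum"))
  if (length(s$wavenumber) < 3L) stop("need at least 3 points")
  h <- lower_hull(s$wavenumber, s$absorbance)
  base <- stats::approx(s$wavenumber[h], s$absorbance[h],
                        xout = s$wavenumber)$y
  out <- s$absorbance - base
  out[h] <- 0  # hull vertices (incl. both endpoints) sit on the baseline
  ir_spectrum(s$wavenumber, out, s$cell_id, s$group)
}

#' Vector normalization
#'
#' Scales the absorbance to unit Euclidean norm, removing optical
#' path-length / cell-thickness differences between cells.
#'
#' @param s An [ir_spectrum()] with non-zero norm.
#' @return The normalized `ir_spectrum`.
#' @export
vector_normalize <- function(s) {
  stopifnot(inherits(s, "ir_spectrum"))
  nrm <- sqrt(sum(s$absorbance^2))
  if (nrm == 0) stop("cannot vector-normalize a zero spectrum")
  ir_spectrum(s$wavenumber, s$absorbance / nrm, s$cell_id, s$group)
}

#' Savitzky-Golay second derivative
#'
#' Second derivative of absorbance with respect to wavenumber
#' (units absorbance * cm^2) via a Savitzky-Golay polynomial filter.
#' The output is trimmed to the interior points where the full window
#' fits; no edge padding is used, so the result is `window_points - 1`
#' points shorter than the input.
#'
#' @param s An [ir_spectrum()].
#' @param window_points Odd window length in samples (default 15).
#' @param poly_order Polynomial order (default 3), less than
#'   `window_points`.
#' @return An `ir_spectrum` holding the second derivative on the interior
#'   grid.
#' @export
sg_second_derivative <- function(s, window_points = 15L, poly_order = 3L) {
  stopifnot(inherits(s, "ir_spectrum"))
  window_points <- as.integer(window_points)
  poly_order <- as.integer(poly_order)
  if (window_points %% 2L == 0L) stop("window_points must be odd")
  if (poly_order >= window_points) {
    stop("poly_order must be smaller than window_points")
  }
  n <- length(s$wavenumber)
  if (n < window_points) stop("spectrum shorter than the filter window")
  fm <- signal::sgolay(p = poly_order, n = window_points, m = 2,
                       ts = grid_step(s))
  coef <- fm[(window_points + 1L) %/% 2L, ]
  d2 <- stats::filter(s$absorbance, coef, sides = 2)
  half <- (window_points - 1L) %/% 2L
  interior <- seq.int(half + 1L, n - half)
  ir_spectrum(s$wavenumber[interior], as.numeric(d2[interior]),
              s$cell_id, s$group)
}

#' Amide I/II sub-band assignment table
#'
#' The six second-derivative sub-bands of the protein Amide I and II
#' region used for secondary-structure quantification: antiparallel
#' beta-sheet (1685), alpha-helix (1656), parallel beta-sheet (1635),
#' alpha-helix (1543), tyrosine (1515) and phenylalanine (1495) cm^-1.
#'
#' @return Data frame with columns `center` (cm^-1, strictly decreasing)
#'   and `label`.
#' @export
amide_band_table <- function() {
  data.frame(center = c(1685, 1656, 1635, 1543, 1515, 1495),
             label = c("antiparallel beta-sheet", "alpha-helix (Amide I)",
                       "parallel beta-sheet", "alpha-helix (Amide II)",
                       "tyrosine", "phenylalanine"),
             stringsAsFactors = FALSE)
}

#' Detect and quantify sub-bands in a second-derivative spectrum
#'
#' Absorption sub-bands appear as local minima of the second derivative.
#' For each table band the deepest local minimum within `center +/-
#' match_window` is taken; its depth (absolute second-derivative value)
#' is the band intensity.
#'
#' @param d2 Second-derivative `ir_spectrum` (from
#'   [sg_second_derivative()]); its grid must cover every band center
#'   +/- `match_window`.
#' @param bands A band table as from [amide_band_table()].
#' @param match_window Half-width of the search window, cm^-1 (default 8,
#'   below half the smallest inter-band gap so bands cannot be
#'   cross-assigned).
#' @return Data frame with one row per table band: `label`, `center`,
#'   `detected_center`, `d2_intensity`, `present`.  Absent bands (no
#'   local minimum in the window) have `NA` center and intensity.
#' @export
detect_sub_bands <- function(d2, bands = amide_band_table(),
                             match_window = 8) {
  stopifnot(inherits(d2, "ir_spectrum"), match_window > 0)
  w <- d2$wavenumber
  y <- d2$absorbance
  if (min(bands$center) - match_window < min(w) ||
      max(bands$center) + match_window > max(w)) {
    stop("second-derivative grid does not cover all band windows")
  }
  # strict interior local minima
  mins <- which(diff(sign(diff(y))) > 0) + 1L
  res <- lapply(seq_len(nrow(bands)), function(i) {
    ctr <- bands$center[i]
    cand <- mins[abs(w[mins] - ctr) <= match_window]
    if (length(cand) == 0L) {
      return(data.frame(label = bands$label[i], center = ctr,
                        detected_center = NA_real_,
                        d2_intensity = NA_real_, present = FALSE,
                        stringsAsFactors = FALSE))
    }
    best <- cand[which.min(y[cand])]
    data.frame(label = bands$label[i], center = ctr,
               detected_center = w[best], d2_intensity = abs(y[best]),
               present = TRUE, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Integrated Amide band area
#'
#' Trapezoidal integral of absorbance over a wavenumber window, by
#' default the Amide I integration region 1600-1700 cm^-1.
#'
#' @param s An [ir_spectrum()].
#' @param lo,hi Integration bounds, cm^-1; must lie within the grid.
#' @return The integral (absorbance * cm^-1).
#' @export
amide_area <- function(s, lo = 1600, hi = 1700) {
  stopifnot(inherits(s, "ir_spectrum"), lo < hi)
  eps <- 1e-9 * grid_step(s)
  if (lo < min(s$wavenumber) - eps || hi > max(s$wavenumber) + eps) {
    stop(sprintf("integration window [%g, %g] outside the %g-%g grid",
                 lo, hi, min(s$wavenumber), max(s$wavenumber)))
  }
  keep <- s$wavenumber >= lo - eps & s$wavenumber <= hi + eps
  pracma::trapz(s$wavenumber[keep], s$absorbance[keep])
}

#' One-way ANOVA group comparison of a per-cell measure
#'
#' Classic fixed-effects one-way ANOVA (equal-variance F test) across
#' treatment groups, with per-group descriptive statistics.
#'
#' @param values Numeric measure, one value per cell.
#' @param labels Group label per cell; at least 2 groups with at least 2
#'   cells each.
#' @param measure Name of the measure (for reporting).
#' @return A list of class `group_comparison`: `measure`, `groups` (data
#'   frame `group`, `n`, `mean`, `sd`), `f_statistic`, `df`, `p_value`.
#' @export
compare_groups <- function(values, labels, measure = "measure") {
  labels <- factor(labels)
  stopifnot(length(values) == length(labels))
  counts <- table(labels)
  if (length(counts) < 2L) stop("need at least 2 groups")
  if (any(counts < 2L)) stop("each group needs at least 2 values")
  within_var <- tapply(values, labels, stats::var)
  if (all(within_var == 0)) stop("degenerate groups: zero pooled variance")
  ft <- stats::oneway.test(values ~ labels, var.equal = TRUE)
  groups <- data.frame(group = names(counts), n = as.integer(counts),
                       mean = as.numeric(tapply(values, labels, mean)),
                       sd = as.numeric(tapply(values, labels, stats::sd)),
                       stringsAsFactors = FALSE)
  structure(list(measure = measure, groups = groups,
                 f_statistic = unname(ft$statistic),
                 df = unname(ft$parameter),
                 p_value = unname(ft$p.value)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: F(%g, %g) = %.4g, p = %.4g\n",
              x$measure, x$df[1L], x$df[2L], x$f_statistic, x$p_value))
  print.data.frame(x$groups, ...)
  invisible(x)
}

#' Run the standard per-cell processing chain
#'
#' Enforces the processing order crop -> rubber-band baseline -> vector
#' normalization -> Savitzky-Golay second derivative.
#'
#' @param s An [ir_spectrum()].
#' @param region Analysis window, cm^-1 (default the Amide I/II region
#'   1480-1700).
#' @param sg_window,sg_order Savitzky-Golay parameters (defaults 15, 3).
#' @param baseline,normalize Logical switches for the two preprocessing
#'   steps (both default `TRUE`).
#' @return A list with `spectrum` (the processed absorbance spectrum) and
#'   `d2` (its second derivative, trimmed to the interior grid).
#' @export
process_spectrum <- function(s, region = c(1480, 1700), sg_window = 15L,
                             sg_order = 3L, baseline = TRUE,
                             normalize = TRUE) {
  out <- crop_spectrum(s, region[1L], region[2L])
  if (baseline) out <- rubberband_baseline(out)
  if (normalize) out <- vector_normalize(out)
  list(spectrum = out,
       d2 = sg_second_derivative(out, sg_window, sg_order))
}

#' Quantify Amide sub-bands and areas for a set of cells
#'
#' Applies [process_spectrum()] to each cell and collects per-cell band
#' intensities and (optionally) Amide I areas into one table.
#'
#' @param spectra List of [ir_spectrum()] objects.
#' @param bands Band table (default [amide_band_table()]).
#' @param region,sg_window,sg_order,match_window Passed through to the
#'   processing chain and [detect_sub_bands()].
#' @param area_window `NULL`, or `c(lo, hi)` to also report the
#'   integrated area of the processed spectrum over that window.
#' @return Data frame with one row per cell x band: `cell_id`, `group`,
#'   `label`, `center`, `detected_center`, `d2_intensity`, `present`,
#'   and `area` when requested.
#' @export
quantify_cells <- function(spectra, bands = amide_band_table(),
                           region = c(1480, 1700), sg_window = 15L,
                           sg_order = 3L, match_window = 8,
                           area_window = NULL) {
  rows <- lapply(spectra, function(s) {
    pr <- process_spectrum(s, region, sg_window, sg_order)
    q <- detect_sub_bands(pr$d2, bands, match_window)
    q$cell_id <- s$cell_id
    q$group <- s$group
    if (!is.null(area_window)) {
      q$area <- amide_area(pr$spectrum, area_window[1L], area_window[2L])
    }
    q
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read per-cell spectra from CSV
#'
#' Dialect: column 1 `wavenumber_cm-1`, one column per cell; first header
#' row carries cell ids, second header row (`group,...`) the treatment
#' labels.
#'
#' @param path CSV path.
#' @return A list of [ir_spectrum()] objects.
#' @export
read_spectra_csv <- function(path) {
  head2 <- readLines(path, n = 2L)
  ids <- strsplit(head2[1L], ",")[[1]][-1L]
  groups <- strsplit(head2[2L], ",")[[1]][-1L]
  if (length(ids) == 0L || length(groups) != length(ids)) {
    stop("malformed spectra CSV header in ", path)
  }
  dat <- utils::read.csv(path, skip = 2L, header = FALSE)
  w <- dat[[1L]]
  lapply(seq_along(ids), function(j) {
    ir_spectrum(w, dat[[j + 1L]], cell_id = ids[j], group = groups[j])
  })
}

#' Write per-cell spectra as CSV
#'
#' Emits the same dialect [read_spectra_csv()] reads.  All spectra must
#' share one grid.
#'
#' @param spectra List of [ir_spectrum()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(spectra, path) {
  w <- spectra[[1L]]$wavenumber
  same <- vapply(spectra, function(s) {
    length(s$wavenumber) == length(w) && max(abs(s$wavenumber - w)) <= 1e-9
  }, logical(1))
  if (!all(same)) stop("all spectra must share one wavenumber grid")
  ids <- vapply(spectra, function(s) s$cell_id, character(1))
  groups <- vapply(spectra, function(s) s$group, character(1))
  mat <- vapply(spectra, function(s) s$absorbance, numeric(length(w)))
  body <- apply(cbind(w, mat), 1L, function(r) {
    paste(formatC(r, format = "g", digits = 17), collapse = ",")
  })
  writeLines(c(paste(c("wavenumber_cm-1", ids), collapse = ","),
               paste(c("group", groups), collapse = ","),
               body), path)
  invisible(path)
}
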