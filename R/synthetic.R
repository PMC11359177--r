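#' Expand one global seed into per-stream sub-seeds
#'
#' Lets an analysis regenerate its proteome, network and spectra inputs
#' independently while being driven by a single seed.
#'
#' @param seed Integer global seed.
#' @return Named integer vector with elements `proteome`, `ligand`,
#'   `network`, `spectra` (all below 2^31).
#' @export
derive_seeds <- function(seed) {
  withr::with_seed(as.integer(seed), {
    stats::setNames(sample.int(.Machine$integer.max - 1L, 4L),
                    c("proteome", "ligand", "network", "spectra"))
  })
}

#' Generate a proteome with planted EIIP periodicities
#'
#' Background proteins draw residues i.i.d. uniformly over the 20
#' standard amino acids.  Planted proteins are built so their EIIP series
#' approximates `centre + noise + planted_amplitude *
#' cos(2*pi*planted_frequency*position)`: at each position the residue
#' whose EIIP value is nearest the target value is chosen, so the FASTA
#' stays a legal protein sequence and the periodic component survives up
#' to quantization error (recorded in the ground-truth sidecar).
#'
#' @param n_background,n_planted Class sizes.
#' @param length_range Protein length range in residues, `c(min, max)`,
#'   minimum 8.
#' @param planted_frequency Normalized frequency in (0, 0.5).
#' @param planted_amplitude Cosine amplitude in EIIP units; must not
#'   exceed half the EIIP table's value range (the largest realizable
#'   swing), otherwise the signal is unrealizable and an error is thrown.
#' @param noise_sd Positional noise added before quantization, EIIP
#'   units (default 0.01, a mild perturbation relative to the ~0.126
#'   table range).
#' @param seed Integer seed; identical calls are byte-identical.
#' @param table [eiip_table()].
#' @return A list: `records` (data frame `id`, `sequence`) and `truth`
#'   (sidecar data frame: `id`, `class`, `length`, `dominant_frequency`
#'   of the realized EIIP series, `quantization_rmse`).
#' @export
generate_proteome <- function(n_background = 50L, n_planted = 10L,
                              length_range = c(100L, 400L),
                              planted_frequency = 8 / 512,
                              planted_amplitude = 0.06,
                              noise_sd = 0.01, seed = 1L,
                              table = eiip_table()) {
  stopifnot(planted_frequency > 0, planted_frequency < 0.5,
            planted_amplitude >= 0, noise_sd >= 0,
            length_range[1L] >= 8L, length_range[2L] >= length_range[1L])
  vals <- unclass(table)
  half_range <- (max(vals) - min(vals)) / 2
  if (planted_amplitude > half_range + 1e-12) {
    stop(sprintf(
      "planted_amplitude %.4g exceeds the realizable EIIP half-range %.4g",
      planted_amplitude, half_range))
  }
  centre <- (max(vals) + min(vals)) / 2
  residues <- names(vals)
  withr::with_seed(as.integer(seed), {
    lens <- sample(length_range[1L]:length_range[2L],
                   n_background + n_planted, replace = TRUE)
    bg <- vapply(seq_len(n_background), function(i) {
      paste(sample(residues, lens[i], replace = TRUE), collapse = "")
    }, character(1))
    planted <- character(n_planted)
    q_rmse <- numeric(n_planted)
    for (j in seq_len(n_planted)) {
      L <- lens[n_background + j]
      t <- seq_len(L) - 1L
      target <- centre + stats::rnorm(L, 0, noise_sd) +
        planted_amplitude * cos(2 * pi * planted_frequency * t)
      pick <- vapply(target, function(v) which.min(abs(vals - v)),
                     integer(1))
      planted[j] <- paste(residues[pick], collapse = "")
      q_rmse[j] <- sqrt(mean((vals[pick] - target)^2))
    }
  })
  ids <- c(sprintf("bg_%04d", seq_len(n_background)),
           sprintf("planted_%04d", seq_len(n_planted)))
  records <- data.frame(id = ids, sequence = c(bg, planted),
                        stringsAsFactors = FALSE)
  dom <- vapply(seq_len(nrow(records)), function(i) {
    enc <- encode_protein(records$sequence[i], table, records$id[i])
    dominant_frequency(informational_spectrum(enc))
  }, numeric(1))
  truth <- data.frame(id = ids,
                      class = rep(c("background", "planted"),
                                  c(n_background, n_planted)),
                      length = nchar(records$sequence),
                      dominant_frequency = dom,
                      quantization_rmse = c(rep(NA_real_, n_background),
                                            q_rmse),
                      stringsAsFactors = FALSE)
  list(records = records, truth = truth)
}

#' Generate a ligand numeric profile
#'
#' Gaussian noise plus a cosine at `planted_frequency`; with `amplitude`
#' well above `noise_sd`, the profile's informational spectrum peaks at
#' the grid bin nearest the planted frequency.
#'
#' @param length Profile length (>= 8).  The default 128 keeps the
#'   rectangular-window leakage lobes narrow enough that the informational
#'   spectrum's dominant bin cannot be displaced off the planted bin on a
#'   512-point grid; profiles shorter than ~96 points can peak one bin
#'   high through sidelobe interference.
#' @param planted_frequency Normalized frequency; default 8/512, the grid
#'   neighbour of the commonly screened 0.016.
#' @param amplitude Cosine amplitude (default 1).
#' @param noise_sd Noise standard deviation (default 0.3, which puts the
#'   profile's informational-spectrum S/N near 12 -- the scale of
#'   cross-spectrum S/N values reported for real ligand screens, rather
#'   than an unrealistically clean single-line spectrum).
#' @param seed Integer seed.
#' @param molecule_id Identifier (default `"ligand"`).
#' @return A [numeric_series()] with `source = "ligand_profile"`.
#' @export
generate_ligand_profile <- function(length = 128L,
                                    planted_frequency = 8 / 512,
                                    amplitude = 1, noise_sd = 0.3,
                                    seed = 1L, molecule_id = "ligand") {
  stopifnot(length >= 8L, amplitude >= 0, noise_sd >= 0)
  t <- seq_len(length) - 1L
  values <- withr::with_seed(as.integer(seed), {
    amplitude * cos(2 * pi * planted_frequency * t) +
      stats::rnorm(length, 0, noise_sd)
  })
  numeric_series(molecule_id, values, source = "ligand_profile")
}

#' Generate a toy seed/interactor network with known hit counts
#'
#' Random bipartite attachment: each seed is linked to a random subset of
#' an interactor pool, a fixed fraction of which is designated as screen
#' hits (with plausible S/N values).  The sidecar records the true
#' per-seed hit counts, so network counting can be verified exactly.
#'
#' @param n_seeds,n_interactors Pool sizes (>= 1).
#' @param hit_fraction Fraction of the interactor pool marked as hits,
#'   in `[0, 1]`.
#' @param neighbors_range Per-seed neighbour count range.
#' @param seed Integer seed.
#' @return A list: `seeds`, `edges` (data frame `a`, `b`), `hits` (data
#'   frame `protein_id`, `snr`), `truth` (data frame `seed_id`,
#'   `true_hit_count`).
#' @export
generate_network <- function(n_seeds = 10L, n_interactors = 100L,
                             hit_fraction = 0.2,
                             neighbors_range = c(3L, 15L), seed = 1L) {
  stopifnot(n_seeds >= 1L, n_interactors >= 1L,
            hit_fraction >= 0, hit_fraction <= 1)
  seeds <- sprintf("seed_%03d", seq_len(n_seeds))
  pool <- sprintf("int_%04d", seq_len(n_interactors))
  withr::with_seed(as.integer(seed), {
    n_hits <- round(hit_fraction * n_interactors)
    hit_ids <- sort(sample(pool, n_hits))
    snr <- round(stats::runif(n_hits, 6, 17), 5)
    k <- sample(neighbors_range[1L]:neighbors_range[2L], n_seeds,
                replace = TRUE)
    edges <- do.call(rbind, lapply(seq_len(n_seeds), function(i) {
      data.frame(a = seeds[i],
                 b = sample(pool, min(k[i], n_interactors)),
                 stringsAsFactors = FALSE)
    }))
  })
  truth <- data.frame(
    seed_id = seeds,
    true_hit_count = vapply(seeds, function(s) {
      sum(edges$b[edges$a == s] %in% hit_ids)
    }, integer(1)),
    stringsAsFactors = FALSE)
  rownames(truth) <- NULL
  list(seeds = seeds, edges = edges,
       hits = data.frame(protein_id = hit_ids, snr = snr,
                         stringsAsFactors = FALSE),
       truth = truth)
}

#' Base band-mixture specification for synthetic cell spectra
#'
#' Defaults encode the six Amide I/II sub-bands of the assignment table
#' (centers 1685/1656/1635/1543/1515/1495 cm^-1), Gaussian, with the
#' Amide I alpha-helix band tallest.  Backbone amide components get
#' 22-25 cm^-1 FWHM; the aromatic side-chain ring modes (Tyr 1515,
#' Phe 1495) are intrinsically much sharper and get 14 and 12 cm^-1, so
#' all six components stay resolvable in the second derivative.  A mild
#' convex quadratic baseline is added, plus Gaussian noise whose sd is a
#' fraction of the tallest band (default 0.01, i.e. 1%).
#'
#' @param bands Data frame `center`, `fwhm`, `amplitude`, `shape`
#'   (`"gaussian"` or `"lorentzian"`).
#' @param baseline_coeffs Polynomial coefficients `c(c0, c1, c2)` in the
#'   centered variable `x = wavenumber - mean(grid range)`; `c2 >= 0`
#'   keeps the baseline convex.
#' @param noise_sd Noise sd as a fraction of the tallest band amplitude.
#' @param grid `c(lo, hi, step)` wavenumber grid, cm^-1.
#' @return A list of class `band_mix_spec`.
#' @export
band_mix_spec <- function(bands = NULL,
                          baseline_coeffs = c(0.05, 1e-5, 2e-7),
                          noise_sd = 0.01,
                          grid = c(900, 1800, 1)) {
  if (is.null(bands)) {
    bands <- amide_band_table()
    bands$fwhm <- c(22, 25, 25, 25, 14, 12)
    bands$amplitude <- c(0.5, 1.0, 0.65, 0.75, 0.3, 0.2)
    bands$shape <- "gaussian"
  }
  stopifnot(all(bands$fwhm > 0), all(bands$amplitude >= 0),
            all(bands$shape %in% c("gaussian", "lorentzian")),
            noise_sd >= 0, grid[3L] > 0, grid[1L] < grid[2L],
            all(bands$center > grid[1L]), all(bands$center < grid[2L]))
  if (length(baseline_coeffs) >= 3L && baseline_coeffs[3L] < 0) {
    stop("baseline must be convex (quadratic coefficient >= 0)")
  }
  structure(list(bands = bands, baseline_coeffs = baseline_coeffs,
                 noise_sd = noise_sd, grid = grid),
            class = "band_mix_spec")
}

#' Treatment-effect specification
#'
#' Per-group modification of the base band mixture: multiplicative
#' amplitude changes and additive center shifts, keyed by the base band
#' center.
#'
#' @param group_label Group name.
#' @param amplitude_multipliers Named numeric vector, names = base band
#'   centers (e.g. `c("1635" = 1.3)`); unnamed bands keep multiplier 1.
#' @param center_shifts Named numeric vector of shifts in cm^-1.
#' @param n_cells Cells in the group (>= 2; default 28).
#' @return A list of class `treatment_effect`.
#' @export
treatment_effect <- function(group_label,
                             amplitude_multipliers = numeric(0),
                             center_shifts = numeric(0),
                             n_cells = 28L) {
  stopifnot(n_cells >= 2L, all(amplitude_multipliers >= 0))
  structure(list(group_label = group_label,
                 amplitude_multipliers = amplitude_multipliers,
                 center_shifts = center_shifts,
                 n_cells = as.integer(n_cells)),
            class = "treatment_effect")
}

#' Treatment presets for the drug / nanocarrier experiment
#'
#' Encodes the reported secondary-structure responses of ovarian cancer
#' cells as generator presets, with effect size `delta`:
#' * `control` - untreated.
#' * `RuCN` - the ruthenium-complex drug alone: alpha-helix bands (1656,
#'   1543) up by `delta`, parallel beta-sheet (1635) down.
#' * `RuCN_CD` - drug on a pristine carbon-dot carrier: no effect (the
#'   carrier blocks the drug's coordination).
#' * `RuCN_NCD` - drug on an N-doped carbon-dot carrier: parallel
#'   beta-sheet (1635) and tyrosine (1515) up, alpha-helix (1656) down,
#'   and the Amide I alpha-helix center shifted down by 3 cm^-1.
#'
#' @param delta Fractional amplitude change (default 0.3).
#' @param n_cells Cells per group (default 28).
#' @return Named list of [treatment_effect()] objects.
#' @export
treatment_presets <- function(delta = 0.3, n_cells = 28L) {
  list(
    control = treatment_effect("control", n_cells = n_cells),
    RuCN = treatment_effect(
      "RuCN",
      amplitude_multipliers = c("1656" = 1 + delta, "1543" = 1 + delta,
                                "1635" = 1 - delta),
      n_cells = n_cells),
    RuCN_CD = treatment_effect("RuCN_CD", n_cells = n_cells),
    RuCN_NCD = treatment_effect(
      "RuCN_NCD",
      amplitude_multipliers = c("1635" = 1 + delta, "1656" = 1 - delta,
                                "1515" = 1 + delta),
      center_shifts = c("1656" = -3),
      n_cells = n_cells))
}

band_profile <- function(w, center, fwhm, amplitude, shape) {
  if (shape == "gaussian") {
    amplitude * exp(-4 * log(2) * (w - center)^2 / fwhm^2)
  } else {
    amplitude / (1 + (2 * (w - center) / fwhm)^2)
  }
}

#' Generate grouped per-cell IR spectra with known composition
#'
#' Each cell is `baseline + sum of (group-modified) bands + i.i.d.
#' Gaussian noise`.  The sidecar records every cell's group and realized
#' band parameters, so downstream quantification can be checked against
#' ground truth.
#'
#' @param base A [band_mix_spec()].
#' @param groups List of [treatment_effect()] objects (default
#'   [treatment_presets()]).
#' @param seed Integer seed; identical calls are byte-identical.
#' @return A list: `spectra` (list of [ir_spectrum()]) and `truth`
#'   (data frame: `cell_id`, `group`, then `amp_<center>` and
#'   `center_<center>` columns per band, and `noise_sd` in absorbance
#'   units).
#' @export
generate_cell_spectra <- function(base = band_mix_spec(),
                                  groups = treatment_presets(),
                                  seed = 1L) {
  stopifnot(inherits(base, "band_mix_spec"))
  w <- seq(base$grid[1L], base$grid[2L], by = base$grid[3L])
  x <- w - mean(range(w))
  baseline <- drop(outer(x, seq_along(base$baseline_coeffs) - 1L, `^`) %*%
                     base$baseline_coeffs)
  sd_abs <- base$noise_sd * max(base$bands$amplitude)
  spectra <- list()
  truth <- list()
  withr::with_seed(as.integer(seed), {
    for (g in groups) {
      stopifnot(inherits(g, "treatment_effect"))
      bands <- base$bands
      key <- as.character(bands$center)
      mult <- g$amplitude_multipliers[key]
      bands$amplitude <- bands$amplitude * ifelse(is.na(mult), 1, mult)
      shift <- g$center_shifts[key]
      bands$center <- bands$center + ifelse(is.na(shift), 0, shift)
      if (any(bands$center <= min(w)) || any(bands$center >= max(w))) {
        stop("center shift moves a band outside the grid")
      }
      clean <- baseline + Reduce(`+`, lapply(seq_len(nrow(bands)),
        function(i) band_profile(w, bands$center[i], bands$fwhm[i],
                                 bands$amplitude[i], bands$shape[i])))
      for (j in seq_len(g$n_cells)) {
        cid <- sprintf("%s_cell_%02d", g$group_label, j)
        noise <- if (sd_abs > 0) stats::rnorm(length(w), 0, sd_abs) else 0
        spectra[[cid]] <- ir_spectrum(w, clean + noise, cid, g$group_label)
        row <- data.frame(cell_id = cid, group = g$group_label,
                          stringsAsFactors = FALSE)
        for (i in seq_len(nrow(bands))) {
          row[[paste0("amp_", base$bands$center[i])]] <- bands$amplitude[i]
          row[[paste0("center_", base$bands$center[i])]] <- bands$center[i]
        }
        row$noise_sd <- sd_abs
        truth[[cid]] <- row
      }
    }
  })
  list(spectra = unname(spectra), truth = {
    tr <- do.call(rbind, truth)
    rownames(tr) <- NULL
    tr
  })
}

#' Write a ground-truth sidecar table
#'
#' Tab-separated with a `# spec:` header echoing the generator
#' parameters.
#'
#' @param truth Sidecar data frame.
#' @param path Output path.
#' @param spec Named list/vector of parameters to echo.
#' @return `path`, invisibly.
#' @export
write_sidecar <- function(truth, path, spec = list()) {
  hdr <- sprintf("# spec: %s",
                 paste(sprintf("%s=%s", names(spec),
                               vapply(spec, function(v)
                                 paste(format(v), collapse = ":"),
                                 character(1))),
                       collapse = " "))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(truth, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
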