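---
title: "Informational-spectrum target screening and FTIR secondary-structure analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Informational-spectrum target screening and FTIR secondary-structure analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ismftir)
```

This vignette is the package's own account of the two methods it
implements and of the design decisions behind them.

## 1. The Informational Spectrum Method (ISM)

ISM predicts whether two molecules are candidates for long-range
interaction from shared periodicities in their electron-ion interaction
potential (EIIP) profiles.  Three steps:

1. **Encode.**  Each residue of a protein's primary structure is
   replaced by its EIIP value (Rydberg units, the Veljkovic scale
   shipped in `inst/extdata/eiip_amino_acids.tsv`), giving a numeric
   series.  A small-molecule ligand enters as a precomputed numeric
   profile (`read_ligand_profile()`), since atom-level ligand encodings
   are outside this package's scope.
2. **Transform.**  The series is mean-subtracted, zero-padded to an even
   length $N$, and discrete-Fourier-transformed.  The *informational
   spectrum* (IS) is the amplitude $|X_k|$ at bins $k = 1 \dots N/2$,
   i.e. normalized frequencies $f_k = k/N \in (0, 0.5]$.  Mean
   subtraction and DC-bin exclusion make "dominant peak" meaningful: a
   constant sequence carries no signal.
3. **Cross-spectrum.**  For a molecule pair, both series are padded to a
   common grid and their amplitude spectra multiplied pointwise.  A
   frequency at which *both* spectra carry power survives the product;
   the cross-spectrum (CS) dominant frequency and its signal-to-noise
   are the interaction statistics.

**S/N definition.**  The reported peak statistic is
$\mathrm{S/N}(f) = A(f) / \overline{A}$, the amplitude at the queried
grid frequency over the mean amplitude across the grid — the standard
ISM definition.  It is invariant under uniform rescaling of the series.

**Grid policy.**  Spectra are computed on
$N = \max(512,\ 2^{\lceil \log_2 L\rceil})$ points, per pair (the ligand
is re-padded for each protein).  512 is the smallest grid with a bin at
$8/512 = 0.015625$, the representable frequency closest to the
conventionally reported ligand frequency 0.016.  "At frequency 0.016"
is interpreted as: the CS dominant bin lies within `tolerance_bins`
(default 1) of the bin nearest $0.016 \cdot N$, since the target is a
rounded value.  Ties in the argmax break toward the lowest frequency,
deterministically.

**Screening.**  `screen_proteome()` applies this filter across a FASTA
proteome, ranks passing proteins by CS S/N (descending, id ascending on
ties), skips fragments shorter than `min_length` (default 8) with a
warning, and reports screened/skipped/passed counts.  Non-standard
residues (X, B, Z, U, O) are imputed with the EIIP table mean under the
default policy, or rejected under `unknown_policy = "error"`.

### What the screen does and does not select

With the product-argmax rule, a ligand whose own IS has a dominant peak
at the target bin pulls the CS argmax to that bin for *most* random
proteins, not only for true periodicity carriers: the frequency filter
is permissive under a frequency-matched ligand, and the practical
selectivity of the method lives in the S/N ranking, where proteins
genuinely carrying the shared periodicity stand far above background
(in the bundled analysis, planted proteins occupy the top ranks with a
\>50% S/N margin).  Consequently the null-calibration property — pass
rate $\approx (2\,\mathrm{tol}+1)/(N/2)$ — is stated and tested for
*unpeaked* random ligands, pairing each protein with an independent
ligand draw so the pass events are independent Bernoulli trials and the
binomial standard error applies.  A single fixed ligand realization
biases the conditional pass rate through its own spectral shape (we
measured 0–2.3% across draws against a nominal 1.17%).

## 2. Network annotation

Screen hits are counted inside the interaction neighbourhoods of
disease seed genes: for each seed, the intersection of its PPI
neighbours with the hit set, carrying S/N through
(`count_hits_per_seed()`), plus the multiplicity of each hit across
seed networks (`hit_multiplicity()`) and a minimum-hit-count filter.
Identifier matching is exact and case-sensitive — alias resolution is
an external-database concern.  Seeds without edges are reported with
count 0 rather than dropped, so input seed lists keep their length.
Self-matches (a seed appearing in its own neighbour list) are excluded.
Edge lists are STRING-export style TSV; per-seed neighbour caps apply
only when scores are present, keeping the highest-scoring partners.
The package ships a worked ovarian-neoplasm example
(`ovarian_target_example()`) whose counts the tests verify exactly.

## 3. The FTIR secondary-structure pipeline

Per-cell infrared spectra are processed in a fixed order, enforced by
`process_spectrum()`:

1. **Crop** to the Amide I/II analysis region, default 1480–1700
   cm$^{-1}$.
2. **Rubber-band baseline**: the baseline is the lower convex hull of
   the spectrum, interpolated linearly between hull vertices, and
   subtracted.  Endpoints are exactly zero; no point drops below
   $-10^{-9}$.
3. **Vector normalization** to unit Euclidean norm, removing
   thickness/concentration scale.
4. **Savitzky–Golay second derivative**, window 15 points, polynomial
   order 3.  "15 smoothing points" is taken as a window of 15 *samples*
   on the instrument grid, not a wavenumber width.  The output is
   trimmed to interior points where the full window fits — no mirrored
   padding — because the amide region sits far from the grid edges and
   trimming avoids edge artifacts.  The filter is exact on cubics, so a
   band that is locally quadratic reproduces its curvature exactly.

Absorption sub-bands appear as *minima* of the second derivative; band
"intensity" is the absolute value at the local minimum.
`detect_sub_bands()` assigns, for each entry of the six-band amide
table (1685 antiparallel β-sheet, 1656 α-helix, 1635 parallel β-sheet,
1543 α-helix, 1515 Tyr, 1495 Phe), the deepest local minimum within
±8 cm$^{-1}$ — below half the smallest inter-band gap (21 cm$^{-1}$),
so neighbouring bands cannot be cross-assigned.  Amide I content is
additionally summarized as the trapezoidal integral over
1600–1700 cm$^{-1}$, computed after normalization (configurable).
Group differences are tested with classic fixed-effects one-way ANOVA
(`compare_groups()`), significance at $p < 0.05$; groups with zero
pooled within-group variance are rejected as degenerate.

## 4. Synthetic data: what it emulates, and what not

The generators define the study conditions for every test.

**Proteomes** (`generate_proteome()`): background proteins are i.i.d.
uniform over the 20 residues, lengths uniform on 100–400 aa (a
realistic central range; real proteomes reach further in both
directions but the spectral behaviour is governed by the
$N \ge 512$ grid either way).  Planted proteins quantize
$\mathrm{centre} + \mathcal{N}(0, \sigma) + a\cos(2\pi f t)$ to the
nearest-EIIP residue, so the FASTA stays a legal sequence; the residual
quantization error is recorded in the sidecar.  The largest realizable
amplitude is half the EIIP table range (0.0632); requests beyond it are
errors.  Default positional noise is $\sigma = 0.01$, a mild
perturbation relative to the 0.126 table range.

**Ligand profiles** (`generate_ligand_profile()`): cosine at the
planted frequency plus white noise.  The default length is 128: a
64-point rectangular window leaks enough that the neighbouring bin can
edge out the planted bin on a 512-grid through sidelobe interference,
independent of amplitude; from 96 points up the planted bin always
dominates.  The default noise (sd 0.3 at unit amplitude) puts the
profile's IS S/N near 12, the scale reported for such screens, rather
than an unrealistically clean single line.

**Networks** (`generate_network()`): random bipartite attachment with a
designated hit fraction and exact sidecar counts.  No attempt at
STRING-like topology.

**Cell spectra** (`generate_cell_spectra()`): each cell is a convex
quadratic baseline plus the six-band mixture plus i.i.d. Gaussian noise
(sd expressed as a fraction of the tallest band, default 1%).  Band
widths are 22–25 cm$^{-1}$ FWHM for the backbone amide components and
14 / 12 cm$^{-1}$ for the Tyr / Phe ring modes: aromatic side-chain
bands are intrinsically much sharper, and at a uniform 25 cm$^{-1}$ the
tail of the 4×-taller 1543 band displaces the 1515 second-derivative
minimum by 3–4 cm$^{-1}$, which would defeat the ±2 cm$^{-1}$
assignment the six-band analysis relies on.  Treatment presets encode
the qualitative treatment responses of interest: drug alone — α-helix
up, parallel β-sheet down; drug on a pristine carbon-dot carrier — no
change; drug on an N-doped carrier — parallel β-sheet and Tyr up,
α-helix down and its centre shifted $-3$ cm$^{-1}$; effect size
$\delta = 0.3$, 28 cells per group.  The generator does **not** emulate
IR physics (Mie scattering, dispersion artifacts, water vapour), cell
heterogeneity within a group, or correlated noise — so passing tests
demonstrate correctness of the computational chain under the stated
signal model, not robustness to every real-data artifact.

All generators are pure functions of (specification, seed):
`withr::with_seed()` isolates the RNG, identical calls produce
byte-identical files, and `derive_seeds()` expands one global seed into
per-stream sub-seeds.

## 5. Numerical choices and degeneracies

* All-zero cross-spectra (e.g. against a constant molecule) are flagged
  degenerate: dominant frequency and S/N are `NA`, never invented.
* S/N queries off the grid, zero-mean spectra, zero-norm spectra, empty
  crops, and coverage violations in band detection are errors, not
  silent answers.
* The lower convex hull is computed by a monotone-chain sweep; hull
  vertices are set to exactly zero after subtraction so endpoint
  invariants hold to machine precision.
* Spectra arriving on descending wavenumber grids are reversed on
  construction; non-uniform grids (relative tolerance $10^{-9}$) are
  rejected.  Spectra on unequal grids should be interpolated to the
  coarsest common grid before group statistics.

## 6. Problem sizes used by the test suite

The suite exercises the DFT against a direct-summation oracle on 100
series of length 2–64; null calibration on 2000 protein/ligand pairs;
planted-signal recovery on 10 planted among 50 background proteins; and
the FTIR power analysis on 200 replicate experiments of 28 cells per
group for both the effect and the identity preset, which together
complete in a few minutes on one core.  These sizes give the binomial
bands stated in the tests; they are the package's chosen study
conditions, not estimates of instrument throughput.

## 7. Known limitations

* The ligand encoding itself (atom-level EIIP of a small molecule) is
  out of scope; profiles are pluggable inputs.
* Absolute S/N values depend on the (undisclosed in the source
  literature) padding and spectrum conventions; only relative ranking
  and frequency matching are meaningful across implementations.
* No curve-fitting/deconvolution of Amide I — the second-derivative
  approach only; no PCA, EMSC, or atmospheric correction.
* ANOVA assumes independent cells and equal variances; with 28 cells
  per group the F test is robust to mild departures, but clustered
  acquisition (several spectra per field) would require mixed models.
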