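# ismftir

Predicting candidate protein targets of a small-molecule drug from
sequence alone, and quantifying the protein secondary-structure changes
the drug induces in cells — two halves of one target-identification
workflow, built for computational chemists and spectroscopists who work
with drug–nanocarrier systems.

## What it computes

**Informational Spectrum Method (ISM) screening.**  A protein is encoded
as the series of electron–ion interaction potentials (EIIP, Rydberg
units) of its residues.  The series is mean-subtracted, zero-padded to
*N* ≥ 512 points and Fourier-transformed; the *informational spectrum*
is the amplitude |X<sub>k</sub>| at normalized frequencies
f<sub>k</sub> = k/N ∈ (0, 0.5].  For a protein–ligand pair the two
spectra are multiplied pointwise into a *cross-spectrum* (CS); a shared
dominant frequency flags a candidate long-range interaction, ranked by

S/N(f) = A(f) / mean(A),

the CS peak amplitude over the mean CS amplitude.  `screen_proteome()`
batch-applies this to a FASTA proteome against a ligand profile,
keeping proteins whose CS dominant peak falls within a bin tolerance of
a target frequency (default 0.016 → grid bin 8/512 = 0.015625).

**Network annotation.**  `count_hits_per_seed()` locates screen hits
inside the protein–protein interaction neighbourhoods of disease seed
genes, `hit_multiplicity()` counts how many seed networks share a hit,
and `filter_seeds_by_min_hits()` extracts the most-affected networks.
A worked ovarian-neoplasm example ships with the package.

**FTIR secondary structure.**  Per-cell infrared spectra are cropped to
the Amide I/II region (1480–1700 cm⁻¹), rubber-band baseline-corrected
(lower convex hull), vector-normalized, and second-differentiated with
a Savitzky–Golay filter (15 points, order 3).  Sub-bands appear as d²
minima at 1685 (antiparallel β-sheet), 1656 (α-helix), 1635 (parallel
β-sheet), 1543 (α-helix), 1515 (Tyr) and 1495 (Phe) cm⁻¹; band depths,
Amide I areas (1600–1700 cm⁻¹) and one-way ANOVA group comparisons
quantify treatment effects.

**Synthetic data.**  Seeded generators produce ground-truthed inputs
for every stage: proteomes with planted EIIP periodicities (realized by
nearest-EIIP residue quantization, so the FASTA stays a legal protein),
ligand profiles, toy seed/interactor networks, and grouped cell spectra
with preset treatment effects.

## Worked example

```r
library(ismftir)

# --- ISM screen of a synthetic proteome --------------------------------
proteome <- generate_proteome(n_background = 50, n_planted = 10,
                              planted_frequency = 8/512,
                              planted_amplitude = 0.06, seed = 101)
ligand <- generate_ligand_profile(planted_frequency = 8/512, seed = 102)
hits <- screen_proteome(proteome$records, ligand)
head(as.data.frame(hits), 3)
#>     protein_id length n_fft dominant_frequency      snr
#> 1 planted_0004    385   512           0.015625 116.8796
#> 2 planted_0005    313   512           0.015625 102.2171
#> 3 planted_0007    300   512           0.015625 100.1155

# --- hits in disease seed networks -------------------------------------
ex <- ovarian_target_example()
reports <- count_hits_per_seed(ex$seeds, ex$edges, ex$hits)
filter_seeds_by_min_hits(reports, 5)[, c("seed_id", "hit_count")]
#>   seed_id hit_count
#> 1    AKT1         5
#> 2    MDM2         6
#> 3    PRKN         6

# --- FTIR group comparison ---------------------------------------------
cells <- generate_cell_spectra(groups = treatment_presets(delta = 0.3),
                               seed = 7)
quant <- quantify_cells(cells$spectra)
beta <- quant[quant$center == 1635, ]
compare_groups(beta$d2_intensity, beta$group, "1635 cm-1 band depth")
#> <group_comparison> 1635 cm-1 band depth: F(3, 108) = 1766, p = 1.409e-91
#>      group  n         mean           sd
#> 1  control 28 3.060671e-04 3.193452e-05
#> 2     RuCN 28 2.304766e-05 1.618808e-05
#> 3  RuCN_CD 28 3.116435e-04 4.258329e-05
#> 4 RuCN_NCD 28 6.689026e-04 3.665660e-05
```

The first block shows that every planted-periodicity protein passes the
0.016 frequency filter and outranks background by cross-spectrum S/N.
The second reproduces the bundled network table: three ovarian seeds
(AKT1, MDM2, PRKN) carry five or more predicted targets in their PPI
neighbourhoods.  The third detects the preset treatment effects on the
parallel β-sheet band depth: roughly doubled under the
N-doped-carrier preset (6.7e-4 vs 3.1e-4 for control), collapsed under
the drug alone (the −30% band amplitude is amplified by overlap with
the strengthened neighbouring 1656 α-helix band, whose positive d²
tail fills the 1635 minimum), and unchanged for the pristine-carrier
preset.

A complete run of the workflow lives in `analysis/` as numbered
drivers (`01_screen_proteome.R`, `02_network_annotation.R`,
`03_ftir_secondary_structure.R`); each writes its tables under
`results/`.

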