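Package: ismftir
Title: Informational-Spectrum Target Screening and FTIR Protein
    Secondary-Structure Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts candidate drug-protein interactions with the
    Informational Spectrum Method (ISM): protein sequences are encoded as
    electron-ion interaction potential (EIIP) series, Fourier-transformed
    into amplitude spectra, and cross-multiplied with a ligand profile so
    that proteins sharing the ligand's dominant frequency can be screened
    out of a proteome and ranked by cross-spectrum signal-to-noise.
    Screen hits are annotated by counting them inside the protein-protein
    interaction neighbourhoods of disease seed genes.  A companion FTIR
    pipeline quantifies protein secondary structure from per-cell infrared
    spectra: rubber-band (convex-hull) baseline correction, vector
    normalization, Savitzky-Golay second derivatives, Amide I/II sub-band
    detection, Amide-area integration, and one-way ANOVA group comparison.
    Seeded synthetic-data generators provide ground-truthed proteomes,
    ligand profiles, toy interaction networks, and grouped cell spectra
    for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    pracma,
    signal,
    stats,
    tools,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
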