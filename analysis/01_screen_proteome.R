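#!/usr/bin/env Rscript
# Stage 1: informational-spectrum screen of a synthetic proteome against a
# ligand profile with a planted frequency of 8/512 = 0.015625, the grid
# neighbour of the ligand frequency 0.016 screened for in practice.
#
# Writes: results/screen_hits.tsv, results/proteome_truth.tsv,
#         results/ligand_profile.txt

suppressPackageStartupMessages(library(ismftir))

seed <- 20260921L
seeds <- derive_seeds(seed)
dir.create("results", showWarnings = FALSE)

message("Generating a 510-protein synthetic proteome (10 planted) ...")
proteome <- generate_proteome(n_background = 500, n_planted = 10,
                              planted_frequency = 8 / 512,
                              planted_amplitude = 0.06,
                              seed = seeds[["proteome"]])
write_sidecar(proteome$truth, "results/proteome_truth.tsv",
              spec = list(seed = seeds[["proteome"]], n_background = 500,
                          n_planted = 10, planted_frequency = 8 / 512,
                          planted_amplitude = 0.06))

ligand <- generate_ligand_profile(planted_frequency = 8 / 512,
                                  seed = seeds[["ligand"]])
write_series(ligand, "results/ligand_profile.txt")

cfg <- screen_config(target_frequency = 0.016, tolerance_bins = 1)
hits <- screen_proteome(proteome$records, ligand, cfg)
write_hits(hits, "results/screen_hits.tsv")

s <- attr(hits, "summary")
planted <- proteome$truth$id[proteome$truth$class == "planted"]
recovered <- sum(planted %in% hits$protein_id)
message(sprintf("Screened %d proteins; %d passed the 0.016 filter.",
                s[["screened"]], s[["passed"]]))
message(sprintf("Planted-signal sensitivity: %d/10; top-ranked hit: %s (S/N %.2f).",
                recovered, hits$protein_id[1], hits$snr[1]))
ranks <- match(planted, hits$protein_id)
message(sprintf(
  "S/N ranking separates the classes: planted occupy ranks %d-%d; best background S/N %.2f vs worst planted %.2f.",
  min(ranks), max(ranks),
  max(hits$snr[!hits$protein_id %in% planted]),
  min(hits$snr[ranks])))
message(paste("Note: a frequency-matched ligand makes the dominant-peak",
              "filter permissive on random background; candidate",
              "prioritisation comes from the S/N ranking."))
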