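#!/usr/bin/env Rscript
# Stage 1 - render the synthetic study materials.
#
# Three data sets with known ground truth stand in for the survey's raw
# materials: a PAS/hematoxylin-like testis section (with tubule centers,
# radii and abnormality labels), five-class sperm head tracks at 60 Hz,
# and an 8-strain phenotype table with known variance components
# (va = 0.7, ve = 0.3, ages uniform on 70-461 d). Everything below is
# reproducible from the single seed.

suppressPackageStartupMessages(library(spermatoscope))
dir.create("results/simulated", recursive = TRUE, showWarnings = FALSE)
seed <- 20260921L

section <- gen_histology(histology_sim_config(seed = seed))
write_section_png(section, "results/simulated/section.png",
                  "results/simulated/section_truth.json")
message(sprintf("section: %d tubule cross sections + %d rete (%.0f x %.0f px at %.1f um/px)",
                sum(section$truth$kind == "tubule"),
                sum(section$truth$kind == "rete"),
                nrow(section$image), ncol(section$image), section$um_per_px))

tracks <- gen_tracks(track_sim_config(n_per_class = 60L, seed = seed + 1L))
write_tracks_csv(tracks, "results/simulated/tracks.csv")
readr::write_csv(unique(tracks[, c("sample_id", "track_id", "class")]),
                 "results/simulated/track_labels.csv")
message(sprintf("tracks: %d tracks x %d frames at 60 Hz",
                length(unique(tracks$track_id)), max(tracks$frame) + 1L))

pheno <- gen_phenotypes(pheno_sim_config(seed = seed + 2L))
write_phenotypes_csv(pheno, "results/simulated/phenotypes.csv")
message(sprintf("phenotypes: %d animals x %d strains (trait h2_true = 0.7)",
                nrow(pheno), length(unique(pheno$strain))))
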