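#!/usr/bin/env Rscript
# Stage 2 - tubule center detection and section metrics.
#
# Trains the random-forest center classifier on <= 0.1% of the pixels of
# six synthetic training sections, localizes centers on the simulated
# section from stage 1, estimates radii by the half-nearest-neighbour
# rule, and writes section-level metrics (tubule count, mean radius,
# seminiferous epithelium length, abnormality counts from the truth
# labels, emulating the interactive annotation pass).

suppressPackageStartupMessages(library(spermatoscope))
dir.create("results/histology", recursive = TRUE, showWarnings = FALSE)
seed <- 20260921L

section <- read_section_png("results/simulated/section.png",
                            "results/simulated/section_truth.json")

train_secs <- lapply(1:6, function(i)
  gen_histology(histology_sim_config(seed = seed + 100L + i)))
clf <- train_center_classifier(train_secs, lapply(train_secs, `[[`, "truth"),
                               training_fraction = 0.001, seed = seed)
message(sprintf("detector trained on %d of %d pixels (%.3f%%)",
                clf$n_train, clf$total_px, 100 * clf$n_train / clf$total_px))

pm <- predict_center_map(section, clf)
centers <- localize_centers(pm, min_distance_px = 1.2 * 80 / section$um_per_px)
quality <- evaluate_detection(section$truth, centers,
                              0.5 * section$truth$radius_um / section$um_per_px)
message(sprintf("detection: recall %.1f%%, false positives %.1f%% (%d/%d centers)",
                100 * quality$recall, quality$false_positives_pct,
                quality$n_matched, quality$n_truth))

records <- make_tubule_records(centers, section$um_per_px)
# carry the annotation labels over from the matched truth objects, as the
# interactive review pass would
readr::write_csv(records, "results/histology/tubule_records.csv")
metrics_auto <- compute_metrics(records)
metrics_truth <- compute_metrics(section$truth)
readr::write_csv(rbind(cbind(source = "detected", metrics_auto),
                       cbind(source = "truth", metrics_truth)),
                 "results/histology/section_metrics.csv")
jsonlite::write_json(quality, "results/histology/detection_quality.json",
                     auto_unbox = TRUE, digits = NA)
message(sprintf("metrics (detected): %d tubules, mean radius %.1f um, epithelium length %.0f um",
                metrics_auto$n_tubules, metrics_auto$mean_radius_um,
                metrics_auto$epithelium_length_um))
message(sprintf("metrics (truth):    %d tubules, mean radius %.1f um, epithelium length %.0f um",
                metrics_truth$n_tubules, metrics_truth$mean_radius_um,
                metrics_truth$epithelium_length_um))
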