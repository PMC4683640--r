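# Detection-quality benchmark on held-out synthetic sections.

#' Benchmark the center detector on held-out synthetic sections
#'
#' Renders `n_sections` synthetic sections with the default histology
#' generator (seeds derived from `seed`), trains the random-forest center
#' classifier on the first `n_train` of them using at most
#' `training_fraction` of their pixels, localizes centers on the remaining
#' held-out sections, and scores detections by greedy one-to-one matching
#' within half the true radius of each object.
#'
#' @param seed integer seed driving section rendering and training.
#' @param n_sections total sections rendered.
#' @param n_train sections used for training (the rest are held out).
#' @param training_fraction fraction of training-section pixels used.
#' @param histology_cfg_fn function(seed) returning a
#'   [histology_sim_config()]; defaults to the generator defaults.
#' @param nms_factor non-maximum-suppression distance as a multiple of the
#'   expected tubule radius.
#' @return list: `recall_pct` and `false_positives_pct` (means over
#'   held-out sections, in percent), per-section vectors `recall_by_image`
#'   and `fp_by_image`, and counts `n_truth_total`, `n_held_out`.
#' @export
detection_benchmark <- function(seed = 1L, n_sections = 12L, n_train = 6L,
                                training_fraction = 0.001,
                                histology_cfg_fn = NULL,
                                nms_factor = 1.2) {
  stopifnot(n_sections > n_train, n_train >= 1L)
  cfg_fn <- histology_cfg_fn %||%
    function(s) histology_sim_config(seed = s)
  secs <- lapply(seq_len(n_sections),
                 function(i) gen_histology(cfg_fn(derive_seed(seed, 1000L + i))))
  train <- secs[seq_len(n_train)]
  test <- secs[(n_train + 1L):n_sections]
  clf <- train_center_classifier(train, lapply(train, `[[`, "truth"),
                                 feature_config(), training_fraction,
                                 seed = derive_seed(seed, 77L))
  rec <- fp <- numeric(length(test))
  n_truth <- 0L
  for (i in seq_along(test)) {
    s <- test[[i]]
    pm <- predict_center_map(s, clf)
    exp_r_px <- cfg_fn(1L)$radius_mean_um / s$um_per_px
    cen <- localize_centers(pm, min_distance_px = nms_factor * exp_r_px)
    q <- evaluate_detection(s$truth, cen,
                            0.5 * s$truth$radius_um / s$um_per_px)
    rec[i] <- q$recall; fp[i] <- q$false_positives_pct
    n_truth <- n_truth + q$n_truth
  }
  list(recall_pct = 100 * mean(rec), false_positives_pct = mean(fp),
       recall_by_image = rec, fp_by_image = fp,
       n_truth_total = n_truth, n_held_out = length(test))
}
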