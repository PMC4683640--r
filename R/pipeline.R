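# End-to-end pipeline: synthetic data -> detection / kinematics -> strain
# statistics, with a manifest of checksums for reproducibility checks.

#' Build a pipeline configuration
#'
#' Per-stage seeds are derived deterministically from the global seed, so
#' a config fully determines every artifact.
#'
#' @param out_dir output directory (created if needed).
#' @param stages subset of c("simulate", "histology", "casa", "stats") to
#'   run, in dependency order.
#' @param seed global integer seed.
#' @param histology_sim,track_sim,pheno_sim simulator configs (defaults:
#'   the package defaults with derived seeds). Set a simulator to NULL to
#'   skip its branch.
#' @param phenotype_csv optional path to an existing phenotype CSV; when
#'   given, the stats stage reads it instead of the simulated table.
#' @param detector list of detector settings (window_px, bins_per_channel,
#'   training_fraction, num_trees, threshold, smooth_sigma_px,
#'   nms_factor).
#' @param casa list of CASA settings (window, vcl_min_um_s, disp_min_um).
#' @param log_level "info" or "quiet".
#' @return config list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            stages = c("simulate", "histology", "casa",
                                       "stats"),
                            seed = 1L,
                            histology_sim = NULL,
                            track_sim = NULL,
                            pheno_sim = NULL,
                            phenotype_csv = NULL,
                            detector = list(),
                            casa = list(),
                            log_level = "info") {
  stages <- match.arg(stages, c("simulate", "histology", "casa", "stats"),
                      several.ok = TRUE)
  if (!is.null(phenotype_csv) && !file.exists(phenotype_csv)) {
    stop(sprintf("phenotype_csv '%s' does not exist", phenotype_csv),
         call. = FALSE)
  }
  det <- utils::modifyList(list(window_px = 21L, bins_per_channel = 8L,
                                training_fraction = 0.001, num_trees = 200L,
                                threshold = 0.5, smooth_sigma_px = 6,
                                nms_factor = 1.2), detector)
  cas <- utils::modifyList(list(window = 5L, vcl_min_um_s = 25,
                                disp_min_um = 4), casa)
  structure(list(
    out_dir = out_dir, stages = stages, seed = as.integer(seed),
    histology_sim = histology_sim %||%
      histology_sim_config(seed = derive_seed(seed, 11L)),
    track_sim = track_sim %||% track_sim_config(seed = derive_seed(seed, 23L)),
    pheno_sim = pheno_sim %||% pheno_sim_config(seed = derive_seed(seed, 37L)),
    phenotype_csv = phenotype_csv, detector = det, casa = cas,
    log_level = log_level
  ), class = "pipeline_config")
}

#' Build a pipeline configuration from a YAML file
#'
#' The YAML mirrors [pipeline_config()]: top-level `out_dir`, `stages`,
#' `seed`, `phenotype_csv`, `detector`, `casa`, `log_level`, plus optional
#' `histology_sim` / `track_sim` / `pheno_sim` blocks whose keys are the
#' corresponding config-constructor arguments.
#'
#' @param path YAML file path.
#' @return a validated [pipeline_config()].
#' @export
pipeline_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$out_dir)) stop("YAML config needs an `out_dir`", call. = FALSE)
  build <- function(block, fn) {
    if (is.null(block)) NULL else do.call(fn, block)
  }
  pipeline_config(
    out_dir = y$out_dir,
    stages = y$stages %||% c("simulate", "histology", "casa", "stats"),
    seed = y$seed %||% 1L,
    histology_sim = build(y$histology_sim, histology_sim_config),
    track_sim = build(y$track_sim, track_sim_config),
    pheno_sim = build(y$pheno_sim, pheno_sim_config),
    phenotype_csv = y$phenotype_csv,
    detector = y$detector %||% list(),
    casa = y$casa %||% list(),
    log_level = y$log_level %||% "info"
  )
}

.log <- function(cfg, stage, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the phenotyping pipeline
#'
#' Executes the requested stages in dependency order, writes every
#' artifact under `out_dir`, and returns a manifest with per-file MD5
#' checksums. Deterministic stages reproduce identical checksums when
#' re-run with an identical config.
#'
#' @param cfg a [pipeline_config()].
#' @return manifest list: `config_hash`, `stages_run`, `files` (named MD5
#'   vector), `timestamp`, `version`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  path <- function(...) file.path(cfg$out_dir, ...)

  cfg_json <- path("config.json")
  cfg_ser <- cfg
  cfg_ser$out_dir <- NULL          # hash the settings, not the location
  jsonlite::write_json(cfg_ser, cfg_json, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  files <- c(files, cfg_json)

  section <- NULL; tracks <- NULL; pheno <- NULL
  if ("simulate" %in% cfg$stages) {
    .log(cfg, "simulate", "rendering section, tracks and phenotype table")
    section <- gen_histology(cfg$histology_sim)
    write_section_png(section, path("section.png"), path("section_truth.json"))
    tracks <- gen_tracks(cfg$track_sim)
    write_tracks_csv(tracks, path("tracks.csv"))
    readr::write_csv(unique(tracks[, c("sample_id", "track_id", "class")]),
                     path("track_labels.csv"))
    pheno <- gen_phenotypes(cfg$pheno_sim)
    write_phenotypes_csv(pheno, path("phenotypes.csv"))
    files <- c(files, path("section.png"), path("section_truth.json"),
               path("tracks.csv"), path("track_labels.csv"),
               path("phenotypes.csv"))
  }

  if ("histology" %in% cfg$stages) {
    if (is.null(section)) stop("[histology] no section available: run the simulate stage or provide one",
                               call. = FALSE)
    det <- cfg$detector
    .log(cfg, "histology", "training detector and localizing tubule centers")
    fcfg <- feature_config(det$window_px, det$bins_per_channel)
    clf <- train_center_classifier(list(section), list(section$truth),
                                   fcfg, det$training_fraction,
                                   num_trees = det$num_trees,
                                   seed = derive_seed(cfg$seed, 53L))
    pm <- predict_center_map(section, clf)
    exp_r_px <- cfg$histology_sim$radius_mean_um / section$um_per_px
    centers <- localize_centers(pm, min_distance_px = det$nms_factor * exp_r_px,
                                threshold = det$threshold,
                                smooth_sigma_px = det$smooth_sigma_px)
    recs <- make_tubule_records(centers, section$um_per_px)
    metrics <- compute_metrics(recs,
                               cfg$histology_sim$many_vacuole_threshold)
    qual <- evaluate_detection(section$truth, centers,
                               0.5 * section$truth$radius_um / section$um_per_px)
    readr::write_csv(recs, path("tubule_records.csv"))
    readr::write_csv(metrics, path("section_metrics.csv"))
    jsonlite::write_json(qual, path("detection_quality.json"),
                         auto_unbox = TRUE, digits = NA)
    .log(cfg, "histology", sprintf("recall %.1f%%, false positives %.1f%%",
                                   100 * qual$recall,
                                   qual$false_positives_pct))
    files <- c(files, path("tubule_records.csv"), path("section_metrics.csv"),
               path("detection_quality.json"))
  }

  if ("casa" %in% cfg$stages) {
    if (is.null(tracks)) stop("[casa] no tracks available: run the simulate stage or provide tracks",
                              call. = FALSE)
    .log(cfg, "casa", "computing kinematics and classifying motility")
    kin <- kinematics_table(tracks, window = cfg$casa$window)
    kin$motile <- is_motile(kin, cfg$casa$vcl_min_um_s, cfg$casa$disp_min_um)
    model <- train_motility_svm(kin[kin$motile, , drop = FALSE],
                                seed = derive_seed(cfg$seed, 71L))
    kin$pred_class <- NA_character_
    kin$pred_class[kin$motile] <-
      classify_tracks(model, kin[kin$motile, , drop = FALSE])
    readr::write_csv(kin, path("kinematics.csv"))
    files <- c(files, path("kinematics.csv"))
  }

  if ("stats" %in% cfg$stages) {
    if (!is.null(cfg$phenotype_csv)) {
      pheno <- read_phenotypes_csv(cfg$phenotype_csv)
    }
    if (is.null(pheno)) stop("[stats] no phenotype table: run the simulate stage or set phenotype_csv",
                             call. = FALSE)
    traits <- setdiff(names(pheno), c("animal_id", "strain", "age_days"))
    .log(cfg, "stats", sprintf("summarizing %d trait(s)", length(traits)))
    summ <- do.call(rbind, lapply(traits, function(tr) {
      s <- strain_summaries(pheno, tr); s$trait <- tr; s
    }))
    her <- do.call(rbind, lapply(traits, function(tr) heritability(pheno, tr)))
    anv <- do.call(rbind, lapply(traits, function(tr) two_way_anova(pheno, tr)))
    readr::write_csv(summ, path("strain_summaries.csv"))
    readr::write_csv(her, path("heritability.csv"))
    readr::write_csv(anv, path("anova.csv"))
    files <- c(files, path("strain_summaries.csv"), path("heritability.csv"),
               path("anova.csv"))
    if (length(traits) >= 2L) {
      corr <- pairwise_pearson(pheno, traits)
      readr::write_csv(corr$long, path("correlations.csv"))
      files <- c(files, path("correlations.csv"))
    }
  }

  manifest <- list(
    version = as.character(utils::packageVersion("spermatoscope")),
    config_hash = unname(tools::md5sum(cfg_json)),
    stages_run = cfg$stages,
    files = as.list(tools::md5sum(files)),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  manifest
}

#' Reproduce survey summary statistics from a primary-data table
#'
#' Runs the full statistics layer over an animal-level trait table of the
#' survey's layout (`animal_id,strain,age_days,<trait...>`): broad-sense
#' heritability under both estimators for every trait, per-strain means
#' and modified z-scores. Intended for the published supplementary
#' primary-data tables, which must be supplied by the user (they have no
#' public programmatic accession).
#'
#' @param path phenotype CSV path.
#' @return list with `heritability` (both estimators, one row per trait x
#'   estimator) and `strain_means` (per strain x trait mean, n, z).
#' @export
reproduce_study_table <- function(path) {
  pheno <- read_phenotypes_csv(path)
  traits <- setdiff(names(pheno), c("animal_id", "strain", "age_days"))
  her <- do.call(rbind, lapply(traits, function(tr) {
    rbind(heritability(pheno, tr, "strain_mean_variance"),
          heritability(pheno, tr, "anova_mom"))
  }))
  sm <- do.call(rbind, lapply(traits, function(tr) {
    s <- strain_summaries(pheno, tr); s$trait <- tr; s
  }))
  list(heritability = her, strain_means = sm)
}
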