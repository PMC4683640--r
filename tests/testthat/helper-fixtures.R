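# Shared fixtures. Everything is generated in code; heavier objects are
# built lazily once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

# small section config: fast to render and to predict over. No rete: the
# cramped canvas leaves it no room; rete handling is exercised at full
# scale by the detection benchmark.
tiny_histology_config <- function(seed = 1L, ...) {
  histology_sim_config(canvas_height_px = 360L, canvas_width_px = 460L,
                       n_tubules = 10L, include_rete = FALSE,
                       seed = seed, ...)
}

tiny_section <- function(seed = 1L, ...) {
  key <- paste0("sec_", seed, "_", paste(c(...), collapse = "_"))
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- gen_histology(tiny_histology_config(seed, ...))
  }
  .fixture_env[[key]]
}

# detector trained once on two tiny sections
tiny_detector <- function() {
  if (is.null(.fixture_env$clf)) {
    secs <- list(tiny_section(301L), tiny_section(302L))
    .fixture_env$clf <- train_center_classifier(
      secs, lapply(secs, `[[`, "truth"),
      training_fraction = 0.004, seed = 5L)
  }
  .fixture_env$clf
}

# labelled kinematics from the default track generator, computed once
labelled_kinematics <- function(seed = 11L, n_per_class = 40L) {
  key <- paste0("kin_", seed, "_", n_per_class)
  if (is.null(.fixture_env[[key]])) {
    kin <- kinematics_table(gen_tracks(track_sim_config(
      n_per_class = n_per_class, seed = seed)))
    kin$motile <- is_motile(kin)
    .fixture_env[[key]] <- kin
  }
  .fixture_env[[key]]
}

# deterministic straight-line track: speed um/frame along +x
straight_track <- function(n = 90L, step = 2) {
  cbind(x = step * (0:(n - 1L)), y = rep(0, n))
}

random_track <- function(n = 30L) {
  cbind(cumsum(stats::rnorm(n)), cumsum(stats::rnorm(n)))
}
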