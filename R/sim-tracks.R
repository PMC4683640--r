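# Synthetic CASA sperm head tracks with known motility class.
#
# Track model: a progressive drift with a slowly wandering heading, plus a
# sinusoidal lateral (flagellar-beat) displacement perpendicular to the
# heading, plus Gaussian positional jitter. The five motility patterns
# differ only in their parameter ranges: progressive swims fast and
# straight; hyperactivated trades forward progress for large, vigorous
# lateral excursions; intermediate sits between; slow progresses weakly;
# weakly motile barely displaces at all.

MOTILITY_CLASSES <- c("progressive", "intermediate", "hyperactivated",
                      "slow", "weakly_motile")

#' Default per-class kinematic parameter ranges
#'
#' Units: forward speed um/s, lateral amplitude um, beat frequency Hz,
#' heading change rate rad/s, jitter sd um (per frame). Ranges are chosen
#' so the classes are separable by (VCL, LIN, ALH) by construction, and so
#' the fastest tracks reach the curvilinear velocities (> 300 um/s) seen in
#' the fastest wild-derived strains.
#' @return named list of per-class `c(lo, hi)` ranges.
#' @export
default_class_params <- function() {
  list(
    progressive = list(speed = c(150, 220), amp = c(2, 4), freq = c(6, 9),
                       heading_rate = c(0.05, 0.3), jitter = c(0.1, 0.25)),
    intermediate = list(speed = c(70, 120), amp = c(5, 8), freq = c(6, 9),
                        heading_rate = c(0.3, 0.8), jitter = c(0.15, 0.3)),
    hyperactivated = list(speed = c(15, 50), amp = c(10, 16), freq = c(6, 9),
                          heading_rate = c(0.8, 1.6), jitter = c(0.2, 0.4)),
    slow = list(speed = c(15, 35), amp = c(1, 3), freq = c(4, 7),
                heading_rate = c(0.2, 0.8), jitter = c(0.1, 0.25)),
    weakly_motile = list(speed = c(0, 2.5), amp = c(0.8, 2), freq = c(3, 6),
                         heading_rate = c(1, 2.5), jitter = c(0.15, 0.35))
  )
}

#' Configuration for the synthetic track generator
#'
#' @param n_per_class named integer vector (or single count recycled over
#'   the five classes) of tracks per motility class.
#' @param frame_rate_hz acquisition rate; 60 Hz as in standard CASA.
#' @param n_frames frames per track; 90 frames = 1.5 s at 60 Hz.
#' @param class_params per-class ranges, see [default_class_params()].
#' @param seed integer seed.
#' @return config list of class `track_sim_config`.
#' @export
track_sim_config <- function(n_per_class = 40L,
                             frame_rate_hz = 60,
                             n_frames = 90L,
                             class_params = default_class_params(),
                             seed = 1L) {
  if (length(n_per_class) == 1L && is.null(names(n_per_class))) {
    n_per_class <- stats::setNames(rep(as.integer(n_per_class), 5L),
                                   MOTILITY_CLASSES)
  }
  if (!all(MOTILITY_CLASSES %in% names(n_per_class))) {
    stop("`n_per_class` must cover all five motility classes", call. = FALSE)
  }
  n_per_class <- n_per_class[MOTILITY_CLASSES]
  if (all(n_per_class <= 0)) stop("empty class mix", call. = FALSE)
  check_pos(frame_rate_hz, "frame_rate_hz")
  if (n_frames < 2L) stop("`n_frames` must be >= 2", call. = FALSE)
  stopifnot(all(MOTILITY_CLASSES %in% names(class_params)))
  structure(list(n_per_class = n_per_class,
                 frame_rate_hz = frame_rate_hz,
                 n_frames = as.integer(n_frames),
                 class_params = class_params,
                 seed = as.integer(seed)),
            class = "track_sim_config")
}

#' Generate labelled synthetic sperm tracks
#'
#' @param cfg a [track_sim_config()].
#' @return tibble with columns `sample_id`, `track_id`, `class`, `frame`
#'   (0-based), `x_um`, `y_um`, `frame_rate_hz`; one row per frame.
#' @export
gen_tracks <- function(cfg) {
  stopifnot(inherits(cfg, "track_sim_config"))
  with_seed(cfg$seed, {
    out <- vector("list", sum(cfg$n_per_class))
    k <- 0L
    for (cl in MOTILITY_CLASSES) {
      for (i in seq_len(cfg$n_per_class[[cl]])) {
        k <- k + 1L
        xy <- sim_one_track(cfg$class_params[[cl]], cfg$n_frames,
                            cfg$frame_rate_hz)
        out[[k]] <- tibble::tibble(
          sample_id = "sim",
          track_id = sprintf("%s_%03d", cl, i),
          class = cl,
          frame = 0:(cfg$n_frames - 1L),
          x_um = xy[, 1], y_um = xy[, 2],
          frame_rate_hz = cfg$frame_rate_hz
        )
      }
    }
    do.call(rbind, out)
  })
}

# One track: heading random walk + sinusoidal lateral beat + jitter.
sim_one_track <- function(p, n_frames, fps) {
  dt <- 1 / fps
  speed <- stats::runif(1, p$speed[1], p$speed[2])
  amp <- stats::runif(1, p$amp[1], p$amp[2])
  freq <- stats::runif(1, p$freq[1], p$freq[2])
  hrate <- stats::runif(1, p$heading_rate[1], p$heading_rate[2])
  jit <- stats::runif(1, p$jitter[1], p$jitter[2])
  phase <- stats::runif(1, 0, 2 * pi)
  theta0 <- stats::runif(1, 0, 2 * pi)

  t <- (0:(n_frames - 1L)) * dt
  dtheta <- stats::rnorm(n_frames - 1L, 0, hrate * sqrt(dt))
  theta <- theta0 + c(0, cumsum(dtheta))
  # centerline: integrate drift along the wandering heading
  cx <- c(0, cumsum(speed * dt * cos(theta[-n_frames])))
  cy <- c(0, cumsum(speed * dt * sin(theta[-n_frames])))
  lat <- amp * sin(2 * pi * freq * t + phase)
  x <- cx - lat * sin(theta) + stats::rnorm(n_frames, 0, jit)
  y <- cy + lat * cos(theta) + stats::rnorm(n_frames, 0, jit)
  cbind(x, y)
}
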