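# CASA kinematic parameters from sperm head tracks.
#
# A track is an ordered list of head positions (um) at a fixed frame rate
# (60 Hz, 90 frames = 1.5 s in the standard protocol). Seven parameters
# summarize it: VCL (curvilinear velocity, raw path length / duration),
# VSL (straight-line velocity, net displacement / duration), VAP (average
# path velocity, length of a smoothed "average path" / duration), ALH
# (amplitude of lateral head displacement, 2 x mean perpendicular
# deviation of the raw track from the average path), BCF (beat cross
# frequency, sign changes of that deviation per second), STR = VSL/VAP and
# LIN = VSL/VCL.

#' Smooth a track into its average path
#'
#' Centered moving average whose window shrinks symmetrically near the
#' ends, so the first and last raw positions are preserved and the output
#' has the same length as the input. `window = 1` is the identity.
#'
#' @param xy n x 2 matrix of positions (um).
#' @param window odd window length in frames.
#' @return n x 2 matrix of smoothed positions.
#' @export
average_path <- function(xy, window = 5L) {
  stopifnot(is.matrix(xy), ncol(xy) == 2L, window >= 1L)
  n <- nrow(xy)
  if (window == 1L || n <= 2L) return(xy)
  hw <- window %/% 2L
  out <- xy
  for (i in seq_len(n)) {
    h <- min(hw, i - 1L, n - i)     # shrink symmetrically at the ends
    out[i, ] <- colMeans(xy[(i - h):(i + h), , drop = FALSE])
  }
  out
}

# signed perpendicular deviation of raw points from the average path,
# using the local tangent of the average path
.signed_deviation <- function(xy, avg) {
  n <- nrow(xy)
  tx <- numeric(n); ty <- numeric(n)
  tx[1] <- avg[2, 1] - avg[1, 1]; ty[1] <- avg[2, 2] - avg[1, 2]
  tx[n] <- avg[n, 1] - avg[n - 1, 1]; ty[n] <- avg[n, 2] - avg[n - 1, 2]
  if (n > 2L) {
    mid <- 2:(n - 1)
    tx[mid] <- avg[mid + 1, 1] - avg[mid - 1, 1]
    ty[mid] <- avg[mid + 1, 2] - avg[mid - 1, 2]
  }
  len <- sqrt(tx^2 + ty^2)
  len[len == 0] <- 1
  dx <- xy[, 1] - avg[, 1]; dy <- xy[, 2] - avg[, 2]
  (tx * dy - ty * dx) / len       # cross product with unit tangent
}

#' Compute the seven CASA parameters for one track
#'
#' @param xy n x 2 matrix of head positions (um), n >= 2.
#' @param frame_rate_hz acquisition rate (Hz).
#' @param window average-path smoothing window (frames).
#' @return one-row tibble: `vcl_um_s`, `vsl_um_s`, `vap_um_s`, `alh_um`,
#'   `bcf_hz`, `str_frac`, `lin_frac`, `net_disp_um`, `n_frames`. Ratio
#'   parameters are 0 when their denominator is 0.
#' @export
compute_kinematics <- function(xy, frame_rate_hz = 60, window = 5L) {
  stopifnot(is.matrix(xy), ncol(xy) == 2L)
  n <- nrow(xy)
  if (n < 2L) stop("a track needs at least 2 frames", call. = FALSE)
  if (!all(is.finite(xy))) stop("track has non-finite coordinates", call. = FALSE)
  dur <- (n - 1) / frame_rate_hz
  step <- sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2)
  vcl <- sum(step) / dur
  net <- sqrt(sum((xy[n, ] - xy[1, ])^2))
  vsl <- net / dur
  avg <- average_path(xy, window)
  astep <- sqrt(diff(avg[, 1])^2 + diff(avg[, 2])^2)
  vap <- sum(astep) / dur
  dev <- .signed_deviation(xy, avg)
  alh <- 2 * mean(abs(dev))
  s <- sign(dev)
  s <- s[s != 0]
  bcf <- if (length(s) > 1L) sum(diff(s) != 0) / dur else 0
  tibble::tibble(
    vcl_um_s = vcl, vsl_um_s = vsl, vap_um_s = vap,
    alh_um = alh, bcf_hz = bcf,
    str_frac = if (vap > 0) vsl / vap else 0,
    lin_frac = if (vcl > 0) vsl / vcl else 0,
    net_disp_um = net, n_frames = n
  )
}

#' Kinematics for every track in a long track table
#'
#' @param tracks tibble with `sample_id`, `track_id`, `frame`, `x_um`,
#'   `y_um` and optionally `frame_rate_hz` and `class`.
#' @param frame_rate_hz used when the table has no `frame_rate_hz` column.
#' @param window average-path smoothing window.
#' @return tibble, one row per track: ids, the seven parameters, and
#'   `class` if present in the input.
#' @export
kinematics_table <- function(tracks, frame_rate_hz = 60, window = 5L) {
  key <- paste(tracks$sample_id, tracks$track_id, sep = "\r")
  idx <- split(seq_len(nrow(tracks)), key)
  out <- lapply(idx, function(i) {
    i <- i[order(tracks$frame[i])]
    fps <- if ("frame_rate_hz" %in% names(tracks)) {
      tracks$frame_rate_hz[i[1]]
    } else frame_rate_hz
    k <- compute_kinematics(cbind(tracks$x_um[i], tracks$y_um[i]), fps, window)
    k$sample_id <- tracks$sample_id[i[1]]
    k$track_id <- tracks$track_id[i[1]]
    if ("class" %in% names(tracks)) k$class <- tracks$class[i[1]]
    k
  })
  out <- do.call(rbind, out)
  front <- intersect(c("sample_id", "track_id", "class"), names(out))
  out[, c(front, setdiff(names(out), front))]
}

#' Motile/static gate
#'
#' A track is motile if it clears either a curvilinear-velocity gate or a
#' net-displacement gate. Defaults are permissive so slow sperm are counted
#' motile; "static" means essentially no movement.
#'
#' @param params one-row (or multi-row) kinematics table from
#'   [compute_kinematics()]/[kinematics_table()].
#' @param vcl_min_um_s curvilinear velocity gate.
#' @param disp_min_um net displacement gate (over the track duration).
#' @return logical vector, TRUE = motile.
#' @export
is_motile <- function(params, vcl_min_um_s = 25, disp_min_um = 4) {
  params$vcl_um_s >= vcl_min_um_s | params$net_disp_um >= disp_min_um
}
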