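# Local color-histogram features for tubule-center classification.
#
# The feature at a pixel is the concatenation of per-channel intensity
# histograms over a square window centered there, each channel normalized
# to sum 1 (windows shrink at image borders). Whole-image feature stacks
# are computed with integral images so per-pixel prediction stays fast.

#' Feature configuration for the center classifier
#'
#' @param window_px odd window side length in pixels. The default spans
#'   roughly one tubule radius at the default section scale, so a window at
#'   a tubule center is dominated by lumen while a window inside the
#'   epithelium ring is dominated by stain.
#' @param bins_per_channel histogram bins per RGB channel.
#' @return config list of class `feature_config`.
#' @export
feature_config <- function(window_px = 21L, bins_per_channel = 8L) {
  if (window_px < 1L || window_px %% 2L == 0L) {
    stop("`window_px` must be an odd positive integer", call. = FALSE)
  }
  if (bins_per_channel < 2L) stop("`bins_per_channel` must be >= 2", call. = FALSE)
  structure(list(window_px = as.integer(window_px),
                 bins_per_channel = as.integer(bins_per_channel)),
            class = "feature_config")
}

# bin index in 1..bins for intensities in [0, 1]
.bin_index <- function(v, bins) pmin(bins, floor(v * bins) + 1L)

#' Extract the local color-histogram feature at one pixel
#'
#' Reference (per-position) implementation; [feature_stack()] computes the
#' same features for every pixel at once and the two agree exactly.
#'
#' @param image H x W x 3 array with intensities in 0..1.
#' @param position `c(row, col)`, 0-based.
#' @param cfg a [feature_config()].
#' @return numeric vector of length `3 * bins_per_channel`; each channel's
#'   block sums to 1.
#' @export
extract_features <- function(image, position, cfg) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L)
  H <- dim(image)[1]; W <- dim(image)[2]
  r0 <- as.integer(position[1]) + 1L; c0 <- as.integer(position[2]) + 1L
  stopifnot(r0 >= 1L, r0 <= H, c0 >= 1L, c0 <= W)
  hw <- cfg$window_px %/% 2L
  rs <- max(1L, r0 - hw):min(H, r0 + hw)
  cs <- max(1L, c0 - hw):min(W, c0 + hw)
  bins <- cfg$bins_per_channel
  out <- numeric(3L * bins)
  for (ch in 1:3) {
    b <- .bin_index(image[rs, cs, ch], bins)
    h <- tabulate(b, nbins = bins)
    out[(ch - 1L) * bins + seq_len(bins)] <- h / sum(h)
  }
  names(out) <- paste0(rep(c("r", "g", "b"), each = bins), "_b",
                       rep(seq_len(bins), 3L))
  out
}

# Clipped-window box sum of a matrix via an integral image.
.box_sum <- function(m, hw) {
  H <- nrow(m); W <- ncol(m)
  S <- matrix(0, H + 1L, W + 1L)
  S[-1L, -1L] <- apply(apply(m, 2L, cumsum), 1L, cumsum) |> t()
  r2 <- pmin(seq_len(H) + hw, H); r1 <- pmax(seq_len(H) - hw, 1L)
  c2 <- pmin(seq_len(W) + hw, W); c1 <- pmax(seq_len(W) - hw, 1L)
  S[r2 + 1L, c2 + 1L] - S[r1, c2 + 1L] - S[r2 + 1L, c1] + S[r1, c1]
}

#' Compute the per-pixel feature stack for a whole image
#'
#' @param image H x W x 3 array in 0..1.
#' @param cfg a [feature_config()].
#' @return numeric matrix, `H*W` rows (column-major pixel order) by
#'   `3 * bins_per_channel` feature columns.
#' @export
feature_stack <- function(image, cfg) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L)
  H <- dim(image)[1]; W <- dim(image)[2]
  hw <- cfg$window_px %/% 2L
  bins <- cfg$bins_per_channel
  counts <- .box_sum(matrix(1, H, W), hw)
  out <- matrix(0, H * W, 3L * bins)
  for (ch in 1:3) {
    b <- matrix(.bin_index(image[, , ch], bins), H, W)
    for (k in seq_len(bins)) {
      out[, (ch - 1L) * bins + k] <- as.vector(.box_sum((b == k) * 1, hw) / counts)
    }
  }
  colnames(out) <- paste0(rep(c("r", "g", "b"), each = bins), "_b",
                          rep(seq_len(bins), 3L))
  out
}
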