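# Random-forest tubule/rete center detection.
#
# Training samples a very small fraction (<0.1% by default) of pixels from
# annotated sections. Pixels within a core radius (0.3 x the local radius)
# of a truth center are positives for that center's class ("tubule" or
# "rete"); pixels outside every core are background. A probability forest
# over the local color-histogram features yields a per-pixel center-core
# probability map, which is Gaussian-smoothed, thresholded and reduced to
# point detections by non-maximum suppression.

#' Train the tubule-center random-forest classifier
#'
#' @param sections list of section objects as returned by [gen_histology()]
#'   (elements `image`, `um_per_px`) or bare `H x W x 3` arrays with a
#'   `um_per_px` attribute.
#' @param truths list (parallel to `sections`) of truth tables with 0-based
#'   `center_row_px`, `center_col_px`, `radius_um`, `kind`.
#' @param cfg a [feature_config()].
#' @param training_fraction fraction of all pixels used for training;
#'   default 0.001 (at most 0.1%).
#' @param core_frac positives are pixels within `core_frac` x radius of a
#'   truth center.
#' @param num_trees random-forest size.
#' @param seed integer seed; training is deterministic under it.
#' @return object of class `center_classifier` holding the fitted forest
#'   and its feature config.
#' @export
train_center_classifier <- function(sections, truths, cfg = feature_config(),
                                    training_fraction = 0.001,
                                    core_frac = 0.3, num_trees = 200L,
                                    seed = 1L) {
  if (!is.list(sections) || length(sections) == 0L ||
      length(sections) != length(truths)) {
    stop("`sections` and `truths` must be non-empty parallel lists",
         call. = FALSE)
  }
  if (!is.numeric(training_fraction) || training_fraction <= 0) {
    stop("`training_fraction` must be positive", call. = FALSE)
  }
  with_seed(seed, {
    feats <- list(); labs <- list()
    total_px <- 0
    for (i in seq_along(sections)) {
      sec <- sections[[i]]
      img <- if (is.list(sec)) sec$image else sec
      truth <- truths[[i]]
      if (nrow(truth) == 0L) next
      scale <- if (is.list(sec)) sec$um_per_px else attr(sec, "um_per_px")
      H <- dim(img)[1]; W <- dim(img)[2]
      total_px <- total_px + H * W

      # per-pixel core membership: 0 background, else truth row index
      core_id <- integer(H * W)
      rr <- rep.int(seq_len(H), W); cc <- rep(seq_len(W), each = H)
      for (j in seq_len(nrow(truth))) {
        core <- core_frac * truth$radius_um[j] / scale
        y <- truth$center_row_px[j] + 1; x <- truth$center_col_px[j] + 1
        hit <- abs(rr - y) <= core & abs(cc - x) <= core &
          (rr - y)^2 + (cc - x)^2 <= core^2
        core_id[hit] <- j
      }
      lab <- integer(H * W)
      lab[core_id > 0L] <- ifelse(truth$kind[core_id[core_id > 0L]] == "rete",
                                  2L, 1L)
      n_take <- floor(training_fraction * H * W)
      if (n_take < 2L) next
      pos_idx <- which(lab > 0L)
      if (length(pos_idx) == 0L) next
      n_pos <- min(length(pos_idx), max(1L, n_take %/% 2L))
      # stratify positives by object so small tubule cores are not swamped
      # by large ones
      per_obj <- split(pos_idx, core_id[pos_idx])
      quota <- max(1L, ceiling(n_pos / length(per_obj)))
      take_pos <- unlist(lapply(per_obj, function(px) {
        sample(px, min(length(px), quota))
      }), use.names = FALSE)
      if (length(take_pos) > n_pos) take_pos <- sample(take_pos, n_pos)
      n_neg <- n_take - length(take_pos)
      take_neg <- sample(which(lab == 0L), n_neg)
      idx <- c(take_pos, take_neg)

      pr <- ((idx - 1L) %% H)        # 0-based rows/cols of sampled pixels
      pc <- ((idx - 1L) %/% H)
      fs <- t(vapply(seq_along(idx),
                     function(k) extract_features(img, c(pr[k], pc[k]), cfg),
                     numeric(3L * cfg$bins_per_channel)))
      feats[[length(feats) + 1L]] <- fs
      labs[[length(labs) + 1L]] <- lab[idx]
    }
    if (length(feats) == 0L || !any(unlist(labs) > 0L)) {
      stop("no positive training pixels available", call. = FALSE)
    }
    x <- do.call(rbind, feats)
    y <- factor(c("bg", "tubule", "rete")[unlist(labs) + 1L],
                levels = c("bg", "tubule", "rete"))
    fit <- ranger::ranger(
      x = x, y = droplevels(y), probability = TRUE,
      num.trees = num_trees, seed = seed, num.threads = 1L
    )
    structure(list(forest = fit, feature_cfg = cfg,
                   training_fraction = training_fraction,
                   core_frac = core_frac, classes = levels(droplevels(y)),
                   n_train = nrow(x), total_px = total_px, seed = seed),
              class = "center_classifier")
  })
}

#' Predict the per-pixel center-core probability map
#'
#' @param image `H x W x 3` array (or list with an `image` element).
#' @param clf a trained [train_center_classifier()] model.
#' @return list with `prob` (H x W matrix, probability of any center core)
#'   and `prob_rete` (H x W, rete-core probability; zero if the training
#'   data had no rete).
#' @export
predict_center_map <- function(image, clf) {
  stopifnot(inherits(clf, "center_classifier"))
  img <- if (is.list(image)) image$image else image
  H <- dim(img)[1]; W <- dim(img)[2]
  fs <- feature_stack(img, clf$feature_cfg)
  pr <- stats::predict(clf$forest, data = fs, num.threads = 1L)$predictions
  cls <- colnames(pr)
  core <- 1 - pr[, "bg"]
  rete <- if ("rete" %in% cls) pr[, "rete"] else rep(0, H * W)
  list(prob = matrix(core, H, W), prob_rete = matrix(rete, H, W))
}

#' Localize center points in a probability map
#'
#' Gaussian-smooths the map, thresholds it, and applies greedy non-maximum
#' suppression so no two detections are closer than `min_distance_px`.
#'
#' @param prob_map H x W probability matrix (or the list returned by
#'   [predict_center_map()], whose `prob` element is used).
#' @param min_distance_px suppression radius; a sensible choice is on the
#'   order of the expected tubule radius in pixels (the pipeline default
#'   is 1.2 x the expected radius, large enough that a single wide lumen
#'   cannot yield two surviving peaks).
#' @param threshold minimum smoothed probability for a detection.
#' @param smooth_sigma_px Gaussian smoothing sigma.
#' @return tibble with 0-based `center_row_px`, `center_col_px` and
#'   `peak_prob`, sorted by descending peak probability; zero rows if no
#'   pixel clears the threshold.
#' @export
localize_centers <- function(prob_map, min_distance_px, threshold = 0.5,
                             smooth_sigma_px = 6) {
  pm <- if (is.list(prob_map)) prob_map$prob else prob_map
  stopifnot(is.matrix(pm))
  sm <- if (smooth_sigma_px > 0) {
    EBImage::gblur(pm, sigma = smooth_sigma_px)
  } else pm
  H <- nrow(sm); W <- ncol(sm)
  cand <- which(sm > threshold)
  if (length(cand) == 0L) {
    return(tibble::tibble(center_row_px = numeric(0),
                          center_col_px = numeric(0),
                          peak_prob = numeric(0)))
  }
  # one candidate per connected supra-threshold component, placed at the
  # component's probability-weighted centroid: a single wide lumen or duct
  # region yields a single, well-centered candidate instead of several
  # off-center local maxima
  lab <- EBImage::bwlabel(matrix(sm > threshold, H, W))
  comp <- split(cand, lab[cand])
  rs <- cs <- vals <- numeric(length(comp))
  for (i in seq_along(comp)) {
    px <- comp[[i]]
    w <- sm[px]
    rs[i] <- sum((((px - 1L) %% H) + 1L) * w) / sum(w)
    cs[i] <- sum((((px - 1L) %/% H) + 1L) * w) / sum(w)
    vals[i] <- max(w)
  }
  ord <- order(vals, decreasing = TRUE)
  rs <- rs[ord]; cs <- cs[ord]; vals <- vals[ord]
  acc_r <- numeric(0); acc_c <- numeric(0); acc_v <- numeric(0)
  for (i in seq_along(rs)) {
    if (length(acc_r) == 0L ||
        all((acc_r - rs[i])^2 + (acc_c - cs[i])^2 >= min_distance_px^2)) {
      acc_r <- c(acc_r, rs[i]); acc_c <- c(acc_c, cs[i])
      acc_v <- c(acc_v, vals[i])
    }
  }
  tibble::tibble(center_row_px = acc_r - 1, center_col_px = acc_c - 1,
                 peak_prob = acc_v)
}

#' Score detections against ground truth
#'
#' Greedy one-to-one matching by increasing distance within a tolerance.
#'
#' @param truth truth table with 0-based `center_row_px`, `center_col_px`
#'   (all kinds count).
#' @param detected detection table with the same coordinate columns.
#' @param match_tol_px scalar tolerance, or one tolerance per truth row
#'   (e.g. `0.5 * radius_px`).
#' @return list with `recall` (matched / truth, in 0..1),
#'   `false_positives_pct` (unmatched detections as % of truth count),
#'   `n_truth`, `n_detected`, `n_matched`.
#' @export
evaluate_detection <- function(truth, detected, match_tol_px) {
  if (is.null(truth) || nrow(truth) == 0L) {
    stop("empty truth: detection quality is undefined", call. = FALSE)
  }
  stopifnot(all(match_tol_px > 0))
  tol <- rep_len(match_tol_px, nrow(truth))
  nt <- nrow(truth); nd <- if (is.null(detected)) 0L else nrow(detected)
  if (nd == 0L) {
    return(list(recall = 0, false_positives_pct = 0,
                n_truth = nt, n_detected = 0L, n_matched = 0L))
  }
  d <- outer(truth$center_row_px, detected$center_row_px, "-")^2 +
    outer(truth$center_col_px, detected$center_col_px, "-")^2
  d <- sqrt(d)
  ok <- which(d <= tol, arr.ind = TRUE)   # tol recycles down columns = per truth row
  matched_t <- logical(nt); matched_d <- logical(nd)
  if (nrow(ok) > 0L) {
    ord <- order(d[ok])
    for (k in ord) {
      i <- ok[k, 1L]; j <- ok[k, 2L]
      if (!matched_t[i] && !matched_d[j]) {
        matched_t[i] <- TRUE; matched_d[j] <- TRUE
      }
    }
  }
  n_matched <- sum(matched_t)
  list(recall = n_matched / nt,
       false_positives_pct = 100 * sum(!matched_d) / nt,
       n_truth = nt, n_detected = nd, n_matched = n_matched)
}
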