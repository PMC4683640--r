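# Five-class sperm motility classification with an SVM cascade.
#
# Motile tracks (the static gate runs first, elsewhere) are classified by
# a cascade of binary RBF SVMs over the standardized 7 CASA parameters:
#   1. vigorous (progressive/intermediate/hyperactivated) vs nonvigorous
#   2a. within vigorous: hyperactivated vs not
#   2b. within the rest of vigorous: progressive vs intermediate
#   3. within nonvigorous: slow vs weakly motile

KINEMATIC_FEATURES <- c("vcl_um_s", "vsl_um_s", "vap_um_s", "alh_um",
                        "bcf_hz", "str_frac", "lin_frac")

VIGOROUS_CLASSES <- c("progressive", "intermediate", "hyperactivated")

.fit_binary_svm <- function(x, y, cost, gamma) {
  e1071::svm(x = x, y = factor(y), kernel = "radial", cost = cost,
             gamma = gamma, scale = FALSE, probability = FALSE)
}

#' Train the five-class motility SVM cascade
#'
#' @param kin labelled kinematics table: the seven parameter columns of
#'   [kinematics_table()] plus a `class` column covering all five motility
#'   classes.
#' @param cost,gamma RBF SVM hyperparameters shared by the cascade stages
#'   (`gamma` defaults to 1/7, the kernlab/e1071 default for 7 features).
#' @param seed integer seed (SVM fitting is deterministic; the seed pins
#'   any tie-breaking and is recorded in the model metadata).
#' @return object of class `motility_model`.
#' @export
train_motility_svm <- function(kin, cost = 10, gamma = 1 / 7, seed = 1L) {
  if (!all(KINEMATIC_FEATURES %in% names(kin))) {
    stop("`kin` must contain the seven CASA parameter columns", call. = FALSE)
  }
  cls <- kin$class
  missing_cls <- setdiff(MOTILITY_CLASSES, unique(cls))
  if (length(missing_cls) > 0L) {
    stop("all five motility classes must be represented; missing: ",
         paste(missing_cls, collapse = ", "), call. = FALSE)
  }
  x <- as.matrix(kin[, KINEMATIC_FEATURES])
  mu <- colMeans(x); sd <- apply(x, 2L, stats::sd)
  sd[sd == 0] <- 1
  xs <- scale(x, mu, sd)
  vig <- cls %in% VIGOROUS_CLASSES
  with_seed(seed, {
    m_vig <- .fit_binary_svm(xs, ifelse(vig, "vigorous", "nonvigorous"),
                             cost, gamma)
    m_hyp <- .fit_binary_svm(xs[vig, , drop = FALSE],
                             ifelse(cls[vig] == "hyperactivated",
                                    "hyperactivated", "not"), cost, gamma)
    pi_idx <- vig & cls != "hyperactivated"
    m_pro <- .fit_binary_svm(xs[pi_idx, , drop = FALSE], cls[pi_idx],
                             cost, gamma)
    m_slow <- .fit_binary_svm(xs[!vig, , drop = FALSE], cls[!vig],
                              cost, gamma)
    structure(list(center = mu, scale = sd,
                   vigorous = m_vig, hyperactivated = m_hyp,
                   progressive = m_pro, slow = m_slow,
                   features = KINEMATIC_FEATURES,
                   seed = seed, cost = cost, gamma = gamma,
                   n_train = nrow(kin)),
              class = "motility_model")
  })
}

#' Classify motile tracks into the five motility patterns
#'
#' Static tracks must be gated out with [is_motile()] before this call;
#' the cascade only assigns the five motile classes.
#'
#' @param model a trained [train_motility_svm()] model.
#' @param kin kinematics table (one row per motile track).
#' @return character vector of class labels, one per row of `kin`, in
#'   input order.
#' @export
classify_tracks <- function(model, kin) {
  if (!inherits(model, "motility_model")) {
    stop("`model` must be a trained motility_model", call. = FALSE)
  }
  if (nrow(kin) == 0L) return(character(0))
  x <- as.matrix(kin[, model$features])
  xs <- scale(x, model$center, model$scale)
  out <- character(nrow(xs))
  p_vig <- as.character(stats::predict(model$vigorous, xs))
  vig <- p_vig == "vigorous"
  if (any(vig)) {
    xv <- xs[vig, , drop = FALSE]
    hyp <- as.character(stats::predict(model$hyperactivated, xv)) == "hyperactivated"
    lab <- character(nrow(xv))
    lab[hyp] <- "hyperactivated"
    if (any(!hyp)) {
      lab[!hyp] <- as.character(stats::predict(model$progressive,
                                               xv[!hyp, , drop = FALSE]))
    }
    out[vig] <- lab
  }
  if (any(!vig)) {
    out[!vig] <- as.character(stats::predict(model$slow,
                                             xs[!vig, , drop = FALSE]))
  }
  out
}

#' Build a capacitation time-course motility profile
#'
#' @param classified tibble with one row per track: `time_min` (nominal
#'   incubation minute, e.g. 10/30/60/90/120), `motile` (logical) and
#'   `class` (one of the five motility classes for motile tracks, ignored
#'   for static ones).
#' @return tibble, one row per time point: `time_min`, `pct_<class>` (five
#'   columns, percentages of motile tracks summing to 100),
#'   `percent_motile` (of all tracks), `percent_vigorous` (progressive +
#'   intermediate + hyperactivated), `n_tracks`, `n_motile`.
#' @export
timecourse_profile <- function(classified) {
  stopifnot(all(c("time_min", "motile", "class") %in% names(classified)))
  tps <- sort(unique(classified$time_min))
  if (length(tps) == 0L) stop("no time points", call. = FALSE)
  rows <- lapply(tps, function(tp) {
    d <- classified[classified$time_min == tp, , drop = FALSE]
    if (nrow(d) == 0L) stop("time point with zero tracks", call. = FALSE)
    m <- d[d$motile, , drop = FALSE]
    if (nrow(m) == 0L) {
      stop(sprintf("time point %s has no motile tracks", tp), call. = FALSE)
    }
    pct <- 100 * vapply(MOTILITY_CLASSES,
                        function(cl) mean(m$class == cl), numeric(1))
    out <- tibble::tibble(time_min = tp)
    for (cl in MOTILITY_CLASSES) out[[paste0("pct_", cl)]] <- pct[[cl]]
    out$percent_motile <- 100 * nrow(m) / nrow(d)
    out$percent_vigorous <- sum(pct[VIGOROUS_CLASSES])
    out$n_tracks <- nrow(d)
    out$n_motile <- nrow(m)
    out
  })
  do.call(rbind, rows)
}
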