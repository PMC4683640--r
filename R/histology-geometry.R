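# Tubule geometry and section-level metrics.
#
# The radius of each cross section is estimated as half the distance to the
# nearest neighbouring center; seminiferous epithelium length per transverse
# section is mean radius x 2 x pi x number of tubule cross sections.

#' Estimate tubule radii from center positions
#'
#' `radius_i = 0.5 * min_j d(center_i, center_j)`, reported in pixels and
#' micrometres.
#'
#' @param centers table with `center_row_px`, `center_col_px` (any basis;
#'   only distances matter).
#' @param um_per_px physical scale.
#' @return tibble `radius_px`, `radius_um`, one row per center, in input
#'   order.
#' @export
estimate_radii <- function(centers, um_per_px) {
  check_pos(um_per_px, "um_per_px")
  n <- nrow(centers)
  if (is.null(n) || n < 2L) {
    stop("cannot estimate radii from fewer than 2 centers", call. = FALSE)
  }
  d <- as.matrix(stats::dist(cbind(centers$center_row_px,
                                   centers$center_col_px)))
  diag(d) <- Inf
  r_px <- 0.5 * unname(apply(d, 1L, min))
  tibble::tibble(radius_px = r_px, radius_um = r_px * um_per_px)
}

#' Assemble tubule records from detections
#'
#' Radii come from the nearest-neighbour rule; abnormality fields start
#' unknown (they are set by annotation/corrections, not by the detector).
#'
#' @param centers detection table with 0-based `center_row_px`,
#'   `center_col_px` and optionally `kind`.
#' @param um_per_px physical scale.
#' @param source provenance tag for all rows.
#' @return tibble of tubule records with `record_id`, coordinates, radii,
#'   `kind`, abnormality fields (`n_vacuoles` NA = unknown), `source`.
#' @export
make_tubule_records <- function(centers, um_per_px, source = "auto") {
  rad <- estimate_radii(centers, um_per_px)
  tibble::tibble(
    record_id = sprintf("t%03d", seq_len(nrow(centers))),
    center_row_px = centers$center_row_px,
    center_col_px = centers$center_col_px,
    radius_px = rad$radius_px,
    radius_um = rad$radius_um,
    kind = if ("kind" %in% names(centers)) centers$kind else "tubule",
    n_vacuoles = NA_integer_,
    germ_cell_loss = NA,
    abnormal_germ_cells = NA,
    sloughing = NA,
    source = source
  )
}

#' Apply a correction set to tubule records
#'
#' File-driven replacement for interactive review: add missed centers,
#' delete spurious ones, relabel flags. Radii are recomputed afterwards
#' because nearest neighbours change. Idempotent: deleting an id that is
#' already gone, or re-adding a previously added (corrected) center, is a
#' no-op; adding a duplicate of an existing auto center is an error, as is
#' relabelling an unknown id.
#'
#' @param records tubule record table (see [make_tubule_records()]).
#' @param corr list with optional elements `additions` (data frame
#'   `center_row_px`, `center_col_px`, `kind`), `deletions` (character
#'   record ids), `relabels` (data frame with `record_id` plus any of
#'   `n_vacuoles`, `germ_cell_loss`, `abnormal_germ_cells`, `sloughing`,
#'   `kind`).
#' @param um_per_px physical scale for the radius recomputation.
#' @return corrected record table.
#' @export
apply_corrections <- function(records, corr, um_per_px) {
  out <- records
  for (id in corr$deletions %||% character(0)) {
    out <- out[out$record_id != id, , drop = FALSE]
  }
  adds <- corr$additions
  if (!is.null(adds) && nrow(adds) > 0L) {
    for (j in seq_len(nrow(adds))) {
      dup <- out$center_row_px == adds$center_row_px[j] &
        out$center_col_px == adds$center_col_px[j]
      if (any(dup)) {
        if (all(out$source[dup] == "corrected")) next   # re-application
        stop(sprintf("addition duplicates existing center at (%s, %s)",
                     adds$center_row_px[j], adds$center_col_px[j]),
             call. = FALSE)
      }
      new_id <- sprintf("c%03d", sum(grepl("^c", out$record_id)) + 1L)
      out <- rbind(out, tibble::tibble(
        record_id = new_id,
        center_row_px = adds$center_row_px[j],
        center_col_px = adds$center_col_px[j],
        radius_px = NA_real_, radius_um = NA_real_,
        kind = if ("kind" %in% names(adds)) adds$kind[j] else "tubule",
        n_vacuoles = NA_integer_, germ_cell_loss = NA,
        abnormal_germ_cells = NA, sloughing = NA,
        source = "corrected"
      ))
    }
  }
  rel <- corr$relabels
  if (!is.null(rel) && nrow(rel) > 0L) {
    for (j in seq_len(nrow(rel))) {
      i <- which(out$record_id == rel$record_id[j])
      if (length(i) != 1L) {
        stop(sprintf("relabel reference '%s' does not resolve",
                     rel$record_id[j]), call. = FALSE)
      }
      for (f in intersect(names(rel), c("n_vacuoles", "germ_cell_loss",
                                        "abnormal_germ_cells", "sloughing",
                                        "kind"))) {
        if (!is.na(rel[[f]][j])) out[[f]][i] <- rel[[f]][j]
      }
      out$source[i] <- "corrected"
    }
  }
  if (nrow(out) >= 2L) {
    rad <- estimate_radii(out, um_per_px)
    out$radius_px <- rad$radius_px
    out$radius_um <- rad$radius_um
  }
  out
}

#' Vacuole class from a count
#'
#' @param n_vacuoles integer count (NA = unknown).
#' @param many_threshold count at or above which the class is "many".
#' @return "none", "some", "many" or NA.
#' @export
vacuole_class <- function(n_vacuoles, many_threshold = 3L) {
  ifelse(is.na(n_vacuoles), NA_character_,
         ifelse(n_vacuoles == 0L, "none",
                ifelse(n_vacuoles >= many_threshold, "many", "some")))
}

#' Section-level histology metrics
#'
#' Counts and mean radius over tubule cross sections (rete excluded);
#' seminiferous epithelium length = mean radius x 2 x pi x tubule count.
#'
#' @param records tubule record or truth table; rows with `kind != "tubule"`
#'   are dropped. Needs `radius_um`; abnormality counts use `n_vacuoles`,
#'   `germ_cell_loss`, `abnormal_germ_cells`, `sloughing` where present
#'   (NAs count as not affected).
#' @param many_threshold vacuole count defining the "many vacuoles" class.
#' @return one-row tibble: `n_tubules`, `mean_radius_um`,
#'   `epithelium_length_um`, `n_vacuole_tubules`, `n_many_vacuole_tubules`,
#'   `n_germ_cell_loss`, `n_abnormal_germ_cells`, `n_sloughing`.
#' @export
compute_metrics <- function(records, many_threshold = 3L) {
  tub <- records[records$kind == "tubule", , drop = FALSE]
  if (nrow(tub) == 0L) {
    stop("no tubule cross sections: metrics undefined", call. = FALSE)
  }
  col <- function(nm) if (nm %in% names(tub)) tub[[nm]] else NULL
  nv <- col("n_vacuoles") %||% rep(NA_integer_, nrow(tub))
  flag_count <- function(nm) {
    x <- col(nm)
    if (is.null(x)) 0L else sum(x, na.rm = TRUE)
  }
  mean_r <- mean(tub$radius_um)
  tibble::tibble(
    n_tubules = nrow(tub),
    mean_radius_um = mean_r,
    epithelium_length_um = mean_r * 2 * pi * nrow(tub),
    n_vacuole_tubules = sum(nv > 0L, na.rm = TRUE),
    n_many_vacuole_tubules = sum(nv >= many_threshold, na.rm = TRUE),
    n_germ_cell_loss = flag_count("germ_cell_loss"),
    n_abnormal_germ_cells = flag_count("abnormal_germ_cells"),
    n_sloughing = flag_count("sloughing")
  )
}
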