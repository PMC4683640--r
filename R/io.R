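# Readers and writers for the pipeline's on-disk formats.
#
# Doubles destined for CSV are pre-formatted with 17 significant digits so
# a write/read cycle reproduces them bit for bit.

.format_doubles <- function(d) {
  for (j in seq_along(d)) {
    if (is.double(d[[j]])) {
      v <- sprintf("%.17g", d[[j]])
      v[is.na(d[[j]])] <- NA_character_
      d[[j]] <- v
    }
  }
  d
}
#
# CSV: comma-separated, UTF-8, mandatory header, empty string = missing,
# doubles written with full round-trip precision. Geometric/annotation
# data (truth, detections, corrections) travel as JSON; sections as PNG
# with a JSON truth sidecar; configs as YAML.

#' Write a section image as PNG with a JSON truth sidecar
#'
#' @param section list with `image` (H x W x 3, 0..1), `um_per_px` and
#'   optionally `truth` (as from [gen_histology()]).
#' @param image_path output PNG path.
#' @param truth_path optional sidecar JSON path; written when `section`
#'   carries a truth table.
#' @return `image_path`, invisibly.
#' @export
write_section_png <- function(section, image_path, truth_path = NULL) {
  png::writePNG(section$image, image_path)
  if (!is.null(truth_path) && !is.null(section$truth)) {
    tr <- section$truth
    jsonlite::write_json(list(
      um_per_px = section$um_per_px,
      tubules = lapply(seq_len(nrow(tr)), function(i) {
        list(row = tr$center_row_px[i], col = tr$center_col_px[i],
             radius_um = tr$radius_um[i], kind = tr$kind[i],
             flags = list(n_vacuoles = tr$n_vacuoles[i],
                          germ_cell_loss = tr$germ_cell_loss[i],
                          abnormal_germ_cells = tr$abnormal_germ_cells[i],
                          sloughing = tr$sloughing[i]))
      })
    ), truth_path, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  }
  invisible(image_path)
}

#' Read a section image (PNG) and optional truth sidecar
#'
#' @param image_path PNG path.
#' @param truth_path optional truth JSON path.
#' @param um_per_px scale to use when no sidecar provides one.
#' @return list with `image`, `um_per_px` and (if available) `truth`.
#' @export
read_section_png <- function(image_path, truth_path = NULL, um_per_px = NULL) {
  img <- png::readPNG(image_path)
  if (length(dim(img)) == 3L && dim(img)[3] == 4L) img <- img[, , 1:3]
  out <- list(image = img, um_per_px = um_per_px)
  if (!is.null(truth_path)) {
    j <- jsonlite::read_json(truth_path)
    out$um_per_px <- j$um_per_px
    out$truth <- do.call(rbind, lapply(j$tubules, function(t) {
      tibble::tibble(
        center_row_px = t$row, center_col_px = t$col,
        radius_um = t$radius_um, kind = t$kind,
        n_vacuoles = t$flags$n_vacuoles %||% NA_integer_,
        germ_cell_loss = t$flags$germ_cell_loss %||% NA,
        abnormal_germ_cells = t$flags$abnormal_germ_cells %||% NA,
        sloughing = t$flags$sloughing %||% NA
      )
    }))
  }
  out
}

#' Write sperm tracks in the canonical CSV layout
#'
#' Header `sample_id,track_id,frame,x_um,y_um`; frames 0-based.
#' @param tracks track tibble.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracks_csv <- function(tracks, path) {
  readr::write_csv(.format_doubles(tracks[, c("sample_id", "track_id",
                                              "frame", "x_um", "y_um")]),
                   path, na = "", quote = "none")
  invisible(path)
}

#' Read sperm tracks from CSV
#'
#' @param path track CSV (header `sample_id,track_id,frame,x_um,y_um`).
#' @param frame_rate_hz acquisition rate to attach.
#' @return track tibble with a `frame_rate_hz` column.
#' @export
read_tracks_csv <- function(path, frame_rate_hz = 60) {
  d <- utils::read.csv(path, colClasses = c(sample_id = "character",
                                            track_id = "character",
                                            frame = "integer",
                                            x_um = "numeric",
                                            y_um = "numeric"))
  d <- tibble::as_tibble(d)
  d$frame_rate_hz <- frame_rate_hz
  d
}

#' Write a phenotype table (empty cell = missing)
#' @param table phenotype tibble.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_phenotypes_csv <- function(table, path) {
  readr::write_csv(.format_doubles(table), path, na = "", quote = "none")
  invisible(path)
}

#' Read a phenotype table
#'
#' @param path CSV with header `animal_id,strain,age_days,<trait...>`;
#'   empty cells are missing.
#' @return phenotype tibble; trait columns parsed as doubles.
#' @export
read_phenotypes_csv <- function(path) {
  d <- tibble::as_tibble(utils::read.csv(path, na.strings = c("", "NA")))
  d$animal_id <- as.character(d$animal_id)
  d$strain <- as.character(d$strain)
  d
}

#' Read a correction set from JSON
#'
#' Layout: `{"additions": [{"row":..,"col":..,"kind":..}, ...],
#' "deletions": ["t001", ...], "relabels": [{"record_id":..,
#' "n_vacuoles":.., ...}, ...]}` (all three keys optional).
#'
#' @param path JSON path.
#' @return correction list usable by [apply_corrections()].
#' @export
read_corrections_json <- function(path) {
  j <- jsonlite::read_json(path)
  out <- list()
  if (length(j$additions)) {
    out$additions <- do.call(rbind, lapply(j$additions, function(a) {
      tibble::tibble(center_row_px = a$row, center_col_px = a$col,
                     kind = a$kind %||% "tubule")
    }))
  }
  out$deletions <- as.character(unlist(j$deletions))
  if (length(j$relabels)) {
    out$relabels <- do.call(rbind, lapply(j$relabels, function(r) {
      tibble::tibble(record_id = r$record_id,
                     n_vacuoles = r$n_vacuoles %||% NA_integer_,
                     germ_cell_loss = r$germ_cell_loss %||% NA,
                     abnormal_germ_cells = r$abnormal_germ_cells %||% NA,
                     sloughing = r$sloughing %||% NA,
                     kind = r$kind %||% NA_character_)
    }))
  }
  out
}

#' Validate an input file against its expected schema
#'
#' @param path file path.
#' @param format_tag one of "tracks", "phenotypes", "truth_json".
#' @return list with `ok` (logical) and `errors` (character vector of
#'   line-referenced messages; empty when valid).
#' @export
validate_inputs <- function(path, format_tag = c("tracks", "phenotypes",
                                                 "truth_json")) {
  format_tag <- match.arg(format_tag)
  if (!file.exists(path)) stop(sprintf("cannot read '%s'", path), call. = FALSE)
  errs <- character(0)
  if (format_tag == "tracks") {
    d <- tryCatch(readr::read_csv(path, show_col_types = FALSE,
                                  progress = FALSE),
                  error = function(e) NULL)
    if (is.null(d)) return(list(ok = FALSE, errors = "unparseable CSV"))
    need <- c("sample_id", "track_id", "frame", "x_um", "y_um")
    miss <- setdiff(need, names(d))
    if (length(miss)) {
      errs <- c(errs, paste("header missing columns:",
                            paste(miss, collapse = ", ")))
    } else {
      if (any(!is.finite(d$x_um)) || any(!is.finite(d$y_um))) {
        bad <- which(!is.finite(d$x_um) | !is.finite(d$y_um))[1]
        errs <- c(errs, sprintf("row %d: non-finite coordinate", bad + 1L))
      }
      if (any(d$frame < 0)) {
        errs <- c(errs, sprintf("row %d: frames must be 0-based and non-negative",
                                which(d$frame < 0)[1] + 1L))
      }
      key <- paste(d$sample_id, d$track_id)
      for (g in split(seq_len(nrow(d)), key)) {
        f <- d$frame[g]
        if (any(diff(f) <= 0)) {
          errs <- c(errs, sprintf("row %d: non-monotone frame column in track '%s'",
                                  g[which(diff(f) <= 0)[1] + 1L] + 1L,
                                  d$track_id[g[1]]))
        }
      }
    }
  } else if (format_tag == "phenotypes") {
    d <- tryCatch(readr::read_csv(path, show_col_types = FALSE,
                                  progress = FALSE, na = c("", "NA")),
                  error = function(e) NULL)
    if (is.null(d)) return(list(ok = FALSE, errors = "unparseable CSV"))
    need <- c("animal_id", "strain", "age_days")
    miss <- setdiff(need, names(d))
    if (length(miss)) {
      errs <- c(errs, paste("header missing columns:",
                            paste(miss, collapse = ", ")))
    } else {
      if (length(setdiff(names(d), need)) == 0L) {
        errs <- c(errs, "no trait columns present")
      }
      if (any(!is.na(d$age_days) & d$age_days <= 0)) {
        errs <- c(errs, sprintf("row %d: non-positive age",
                                which(d$age_days <= 0)[1] + 1L))
      }
    }
  } else {
    j <- tryCatch(jsonlite::read_json(path), error = function(e) NULL)
    if (is.null(j)) return(list(ok = FALSE, errors = "unparseable JSON"))
    if (is.null(j$um_per_px) || j$um_per_px <= 0) {
      errs <- c(errs, "missing or non-positive um_per_px")
    }
    if (is.null(j$tubules)) errs <- c(errs, "missing 'tubules' list")
  }
  list(ok = length(errs) == 0L, errors = errs)
}
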