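# Synthetic PAS/hematoxylin-like testis sections with known ground truth.
#
# A transverse testis section is emulated as an elliptical tissue region
# packed with non-overlapping circular tubule cross sections. Each tubule is
# an annulus: a stained (purple) seminiferous-epithelium ring around a pale
# lumen, set in pale-pink interstitium. Abnormalities with ground-truth
# labels: vacuoles (small white ellipses inside the epithelium ring), germ
# cell loss (thinned epithelium), plus abnormal-germ-cell and sloughing
# flags (label-only; they do not change rendering). Optionally one rete
# testis region, rendered as a pale duct network and labelled kind "rete".

#' Configuration for the synthetic histology generator
#'
#' Defaults emulate a mid-line transverse section holding ~40 tubule cross
#' sections of mean radius 80 um at 2.5 um/px, with vacuolization rates in
#' the range seen across an eight-strain survey.
#'
#' @param canvas_height_px,canvas_width_px canvas size in pixels.
#' @param um_per_px physical scale (micrometres per pixel).
#' @param n_tubules number of tubule cross sections to place.
#' @param radius_mean_um,radius_sd_um mean and sd of the lognormal tubule
#'   radius law, in micrometres.
#' @param min_gap_um minimum interstitial gap between tubule circles.
#' @param p_vacuole_tubule probability a tubule carries at least one vacuole.
#' @param vacuole_count_law probability weights over 1..10 vacuoles for a
#'   vacuolated tubule.
#' @param many_vacuole_threshold count at or above which a tubule is in the
#'   "many vacuoles" class.
#' @param p_germ_cell_loss probability of significant germ cell loss
#'   (rendered as a thinned epithelium).
#' @param p_abnormal_germ_cells,p_sloughing probabilities of the two
#'   label-only defect flags.
#' @param include_rete place one rete testis region (labelled, excluded
#'   from tubule metrics downstream).
#' @param palette named list of RGB triplets (0..1) for epithelium, lumen,
#'   interstitium, vacuole and slide background.
#' @param noise_sd sd of independent Gaussian pixel noise.
#' @param seed integer seed; identical configs give bit-identical output.
#' @return a validated config list of class `histology_sim_config`.
#' @export
histology_sim_config <- function(canvas_height_px = 640L,
                                 canvas_width_px = 840L,
                                 um_per_px = 2.5,
                                 n_tubules = 40L,
                                 radius_mean_um = 80,
                                 radius_sd_um = 12,
                                 min_gap_um = 12,
                                 p_vacuole_tubule = 0.2,
                                 vacuole_count_law = c(0.30, 0.22, 0.15, 0.10,
                                                       0.08, 0.06, 0.04, 0.03,
                                                       0.01, 0.01),
                                 many_vacuole_threshold = 3L,
                                 p_germ_cell_loss = 0.08,
                                 p_abnormal_germ_cells = 0.05,
                                 p_sloughing = 0.03,
                                 include_rete = TRUE,
                                 palette = default_palette(),
                                 noise_sd = 0.02,
                                 seed = 1L) {
  check_pos(canvas_height_px, "canvas_height_px")
  check_pos(canvas_width_px, "canvas_width_px")
  check_pos(um_per_px, "um_per_px")
  check_pos(n_tubules, "n_tubules")
  check_pos(radius_mean_um, "radius_mean_um")
  check_pos(radius_sd_um, "radius_sd_um")
  check_pos(min_gap_um, "min_gap_um", strict = FALSE)
  check_prob(p_vacuole_tubule, "p_vacuole_tubule")
  check_prob(p_germ_cell_loss, "p_germ_cell_loss")
  check_prob(p_abnormal_germ_cells, "p_abnormal_germ_cells")
  check_prob(p_sloughing, "p_sloughing")
  check_pos(many_vacuole_threshold, "many_vacuole_threshold")
  check_pos(noise_sd, "noise_sd", strict = FALSE)
  if (length(vacuole_count_law) != 10L || any(vacuole_count_law < 0) ||
      sum(vacuole_count_law) <= 0) {
    stop("`vacuole_count_law` must be 10 non-negative weights over 1..10",
         call. = FALSE)
  }
  diameter_px <- (2 * radius_mean_um + min_gap_um) / um_per_px
  if (diameter_px > min(canvas_height_px, canvas_width_px)) {
    stop("a mean-radius tubule plus gap does not fit in the canvas",
         call. = FALSE)
  }
  structure(list(
    canvas_height_px = as.integer(canvas_height_px),
    canvas_width_px = as.integer(canvas_width_px),
    um_per_px = um_per_px, n_tubules = as.integer(n_tubules),
    radius_mean_um = radius_mean_um, radius_sd_um = radius_sd_um,
    min_gap_um = min_gap_um, p_vacuole_tubule = p_vacuole_tubule,
    vacuole_count_law = vacuole_count_law / sum(vacuole_count_law),
    many_vacuole_threshold = as.integer(many_vacuole_threshold),
    p_germ_cell_loss = p_germ_cell_loss,
    p_abnormal_germ_cells = p_abnormal_germ_cells,
    p_sloughing = p_sloughing,
    include_rete = isTRUE(include_rete),
    palette = palette, noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "histology_sim_config")
}

#' Default 5-color stain palette
#'
#' PAS/hematoxylin-like: purple epithelium, near-white lumen, pale-pink
#' interstitium, white vacuoles, off-white slide background.
#' @return named list of RGB triplets in 0..1.
#' @export
default_palette <- function() {
  list(
    epithelium   = c(0.45, 0.25, 0.55),
    lumen        = c(0.95, 0.92, 0.95),
    interstitium = c(0.92, 0.80, 0.85),
    vacuole      = c(0.99, 0.99, 0.99),
    slide        = c(0.97, 0.97, 0.96)
  )
}

#' Generate a synthetic testis section with ground truth
#'
#' Tubule centers are placed by rejection-sampled dart throwing (largest
#' radius first) inside an elliptical section mask so that circles plus the
#' configured interstitial gap never overlap. Each tubule is rendered as a
#' stained annulus around a pale lumen; vacuolated tubules carry white
#' elliptical vacuoles inside the epithelium ring; germ-cell-loss tubules
#' have a thinned epithelium. Gaussian pixel noise is added last.
#'
#' @param cfg a [histology_sim_config()].
#' @return list with `image` (H x W x 3 array in 0..1), `um_per_px`, and
#'   `truth`: a tibble with one row per placed object — 0-based
#'   `center_row_px`/`center_col_px`, `radius_um`, `kind` ("tubule"/"rete"),
#'   `n_vacuoles`, `germ_cell_loss`, `abnormal_germ_cells`, `sloughing`
#'   (all NA for rete).
#' @export
gen_histology <- function(cfg) {
  stopifnot(inherits(cfg, "histology_sim_config"))
  with_seed(cfg$seed, gen_histology_impl(cfg))
}

gen_histology_impl <- function(cfg) {
  H <- cfg$canvas_height_px; W <- cfg$canvas_width_px
  scale <- cfg$um_per_px

  # lognormal radius law, moment-matched to (mean, sd)
  cv2 <- (cfg$radius_sd_um / cfg$radius_mean_um)^2
  sdlog <- sqrt(log1p(cv2))
  meanlog <- log(cfg$radius_mean_um) - sdlog^2 / 2
  radii_um <- stats::rlnorm(cfg$n_tubules, meanlog, sdlog)

  kinds <- rep("tubule", cfg$n_tubules)
  if (cfg$include_rete) {
    radii_um <- c(1.6 * cfg$radius_mean_um, radii_um)
    kinds <- c("rete", kinds)
  }
  ord <- order(radii_um, decreasing = TRUE)
  radii_um <- radii_um[ord]; kinds <- kinds[ord]
  radii_px <- radii_um / scale

  # elliptical section mask (semi-axes slightly inside the canvas)
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  b <- 0.46 * H; a <- 0.46 * W
  gap_px <- cfg$min_gap_um / scale

  n <- length(radii_px)
  rows <- numeric(n); cols <- numeric(n)
  max_attempts <- 4000L
  for (i in seq_len(n)) {
    r <- radii_px[i]
    placed <- FALSE
    for (att in seq_len(max_attempts)) {
      y <- stats::runif(1, cy - b + r, cy + b - r)
      x <- stats::runif(1, cx - a + r, cx + a - r)
      # whole circle inside the ellipse: center within the shrunken ellipse
      if (((x - cx) / (a - r))^2 + ((y - cy) / (b - r))^2 > 1) next
      if (i > 1L) {
        j <- seq_len(i - 1L)
        d2 <- (rows[j] - y)^2 + (cols[j] - x)^2
        if (any(d2 < (radii_px[j] + r + gap_px)^2)) next
      }
      rows[i] <- y; cols[i] <- x; placed <- TRUE
      break
    }
    if (!placed) {
      stop("tubule placement failed: canvas too crowded for this config",
           call. = FALSE)
    }
  }

  is_tub <- kinds == "tubule"
  n_tub <- sum(is_tub)
  has_vac <- stats::runif(n) < cfg$p_vacuole_tubule & is_tub
  n_vac <- integer(n)
  n_vac[has_vac] <- sample.int(10L, sum(has_vac), replace = TRUE,
                               prob = cfg$vacuole_count_law)
  gcl <- stats::runif(n) < cfg$p_germ_cell_loss & is_tub
  agc <- stats::runif(n) < cfg$p_abnormal_germ_cells & is_tub
  slough <- stats::runif(n) < cfg$p_sloughing & is_tub

  pal <- cfg$palette
  img <- array(0, dim = c(H, W, 3))
  for (ch in 1:3) img[, , ch] <- pal$slide[ch]

  # tissue ellipse -> interstitium
  rr <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  in_ellipse <- ((cc - cx) / a)^2 + ((rr - cy) / b)^2 <= 1
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[in_ellipse] <- pal$interstitium[ch]
    img[, , ch] <- plane
  }

  paint <- function(img, idx, col) {
    np <- H * W
    for (ch in 1:3) img[idx + (ch - 1L) * np] <- col[ch]
    img
  }

  for (i in seq_len(n)) {
    r <- radii_px[i]
    y0 <- rows[i]; x0 <- cols[i]
    rs <- max(1L, floor(y0 - r)):min(H, ceiling(y0 + r))
    cs <- max(1L, floor(x0 - r)):min(W, ceiling(x0 + r))
    sub_r <- matrix(rs, length(rs), length(cs))
    sub_c <- matrix(cs, length(rs), length(cs), byrow = TRUE)
    d2 <- (sub_r - y0)^2 + (sub_c - x0)^2
    lin <- (sub_c - 1L) * H + sub_r          # linear indices into a plane

    if (kinds[i] == "rete") {
      # pale duct region with scattered stained strands
      inside <- d2 <= r^2
      img <- paint(img, lin[inside], c(0.90, 0.85, 0.90))
      n_str <- 24L
      for (s in seq_len(n_str)) {
        ang <- stats::runif(1, 0, 2 * pi)
        rad <- stats::runif(1, 0.15, 0.92) * r
        ey <- y0 + rad * sin(ang); ex <- x0 + rad * cos(ang)
        sa <- stats::runif(1, 2, 5); sb <- stats::runif(1, 1, 2.5)
        th <- stats::runif(1, 0, pi)
        dy <- sub_r - ey; dx <- sub_c - ex
        u <- dx * cos(th) + dy * sin(th); v <- -dx * sin(th) + dy * cos(th)
        blob <- (u / sa)^2 + (v / sb)^2 <= 1 & inside
        img <- paint(img, lin[blob], pal$epithelium)
      }
      next
    }

    lumen_frac <- if (gcl[i]) 0.80 else 0.45
    ring <- d2 <= r^2 & d2 > (lumen_frac * r)^2
    lum <- d2 <= (lumen_frac * r)^2
    img <- paint(img, lin[ring], pal$epithelium)
    img <- paint(img, lin[lum], pal$lumen)

    if (n_vac[i] > 0L) {
      for (v in seq_len(n_vac[i])) {
        ang <- stats::runif(1, 0, 2 * pi)
        rad <- stats::runif(1, (lumen_frac + 0.1) * r, 0.9 * r)
        ey <- y0 + rad * sin(ang); ex <- x0 + rad * cos(ang)
        sa <- stats::runif(1, 2, 5); sb <- stats::runif(1, 1.5, 3.5)
        th <- stats::runif(1, 0, pi)
        dy <- sub_r - ey; dx <- sub_c - ex
        u <- dx * cos(th) + dy * sin(th); v2 <- -dx * sin(th) + dy * cos(th)
        vac <- (u / sa)^2 + (v2 / sb)^2 <= 1 & ring
        img <- paint(img, lin[vac], pal$vacuole)
      }
    }
  }

  if (cfg$noise_sd > 0) {
    img <- img + stats::rnorm(length(img), 0, cfg$noise_sd)
    img[img < 0] <- 0; img[img > 1] <- 1
  }

  truth <- tibble::tibble(
    center_row_px = rows - 1,           # 0-based
    center_col_px = cols - 1,
    radius_um = radii_um,
    kind = kinds,
    n_vacuoles = ifelse(is_tub, n_vac, NA_integer_),
    germ_cell_loss = ifelse(is_tub, gcl, NA),
    abnormal_germ_cells = ifelse(is_tub, agc, NA),
    sloughing = ifelse(is_tub, slough, NA)
  )

  list(image = img, um_per_px = scale, truth = truth)
}
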