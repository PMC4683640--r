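# Nearest-neighbour radii, corrections, and section metrics.

test_that("radii are half the nearest-neighbour distance", {
  pair <- tibble::tibble(center_row_px = c(0, 0), center_col_px = c(0, 100))
  expect_equal(estimate_radii(pair, 1)$radius_px, c(50, 50))
  # collinear triple, hand-checked
  tri <- tibble::tibble(center_row_px = c(0, 0, 0),
                        center_col_px = c(0, 100, 250))
  r <- estimate_radii(tri, 2)
  expect_equal(r$radius_px, c(50, 50, 75))
  expect_equal(r$radius_um, c(100, 100, 150))
  expect_error(estimate_radii(pair[1, ], 1), "fewer than 2")
})

test_that("nearest-neighbour radii agree with brute force on random point sets", {
  set.seed(7)
  for (rep in 1:5) {
    n <- sample(3:200, 1)
    pts <- tibble::tibble(center_row_px = stats::runif(n, 0, 500),
                          center_col_px = stats::runif(n, 0, 500))
    fast <- estimate_radii(pts, 1)$radius_px
    brute <- vapply(seq_len(n), function(i) {
      0.5 * sqrt(min(((pts$center_row_px[i] - pts$center_row_px)^2 +
                      (pts$center_col_px[i] - pts$center_col_px)^2)[-i]))
    }, numeric(1))
    expect_equal(fast, brute, tolerance = 1e-12)
  }
})

test_that("corrections add, delete, relabel, and recompute radii", {
  centers <- tibble::tibble(center_row_px = c(0, 0, 0),
                            center_col_px = c(0, 100, 250))
  recs <- make_tubule_records(centers, 2)
  expect_identical(apply_corrections(recs, list(), 2), recs)

  # deleting the middle record changes nearest neighbours of the rest
  del <- apply_corrections(recs, list(deletions = "t002"), 2)
  expect_equal(nrow(del), 2L)
  expect_equal(del$radius_px, c(125, 125))
  # idempotent re-application
  expect_identical(apply_corrections(del, list(deletions = "t002"), 2), del)

  add <- apply_corrections(recs, list(
    additions = tibble::tibble(center_row_px = 0, center_col_px = 400,
                               kind = "tubule")), 2)
  expect_equal(nrow(add), 4L)
  expect_equal(add$source[4], "corrected")
  expect_equal(add$radius_px[4], 75)   # nearest neighbour at col 250
  # re-adding the same corrected center is a no-op; duplicating an auto
  # center errors
  expect_identical(apply_corrections(add, list(
    additions = tibble::tibble(center_row_px = 0, center_col_px = 400,
                               kind = "tubule")), 2), add)
  expect_error(apply_corrections(recs, list(
    additions = tibble::tibble(center_row_px = 0, center_col_px = 100,
                               kind = "tubule")), 2), "duplicates")

  rel <- apply_corrections(recs, list(
    relabels = tibble::tibble(record_id = "t001", n_vacuoles = 4L)), 2)
  expect_equal(rel$n_vacuoles[1], 4L)
  expect_equal(rel$source[1], "corrected")
  expect_error(apply_corrections(recs, list(
    relabels = tibble::tibble(record_id = "zz", n_vacuoles = 1L)), 2),
    "resolve")
})

test_that("section metrics follow the epithelium-length formula and counts", {
  recs <- tibble::tibble(kind = "tubule", radius_um = rep(50, 100),
                         n_vacuoles = 0L, germ_cell_loss = FALSE,
                         abnormal_germ_cells = FALSE, sloughing = FALSE)
  m <- compute_metrics(recs)
  expect_equal(m$n_tubules, 100L)
  expect_equal(m$epithelium_length_um, 50 * 2 * pi * 100)
  expect_equal(round(m$epithelium_length_um, 2), 31415.93)
  expect_equal(m$n_vacuole_tubules + m$n_germ_cell_loss +
                 m$n_abnormal_germ_cells + m$n_sloughing, 0L)

  recs2 <- tibble::tibble(kind = c("tubule", "tubule", "tubule", "rete"),
                          radius_um = c(40, 50, 60, 120),
                          n_vacuoles = c(0L, 2L, 5L, NA),
                          germ_cell_loss = c(TRUE, FALSE, FALSE, NA),
                          abnormal_germ_cells = c(FALSE, FALSE, FALSE, NA),
                          sloughing = c(FALSE, TRUE, FALSE, NA))
  m2 <- compute_metrics(recs2, many_threshold = 3L)
  expect_equal(m2$n_tubules, 3L)             # rete excluded
  expect_equal(m2$mean_radius_um, 50)
  expect_equal(m2$n_vacuole_tubules, 2L)
  expect_equal(m2$n_many_vacuole_tubules, 1L)
  expect_equal(m2$n_germ_cell_loss, 1L)
  expect_equal(m2$n_sloughing, 1L)
  expect_error(compute_metrics(recs2[recs2$kind == "rete", ]), "no tubule")
})

test_that("vacuole counts and classes stay ordered on generated truth", {
  for (seed in c(2L, 12L)) {
    sec <- tiny_section(seed)
    m <- compute_metrics(sec$truth, many_threshold = 3L)
    expect_lte(m$n_many_vacuole_tubules, m$n_vacuole_tubules)
    expect_lte(m$n_vacuole_tubules, m$n_tubules)
  }
  expect_equal(vacuole_class(c(0L, 2L, 5L, NA), 3L),
               c("none", "some", "many", NA))
})
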