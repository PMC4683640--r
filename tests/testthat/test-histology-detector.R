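# Center classifier and localization on small synthetic sections.

test_that("training rejects zero training fractions and missing positives", {
  sec <- tiny_section(301L)
  expect_error(train_center_classifier(list(sec), list(sec$truth),
                                       training_fraction = 0),
               "positive")
  no_truth <- sec$truth[0, ]
  expect_error(train_center_classifier(list(sec), list(no_truth)),
               "positive training pixels")
})

test_that("training is deterministic under the seed", {
  sec <- tiny_section(301L)
  probe <- tiny_section(303L)
  clf1 <- train_center_classifier(list(sec), list(sec$truth),
                                  training_fraction = 0.002, seed = 9L)
  clf2 <- train_center_classifier(list(sec), list(sec$truth),
                                  training_fraction = 0.002, seed = 9L)
  sub <- probe$image[1:60, 1:80, , drop = FALSE]
  expect_identical(predict_center_map(sub, clf1)$prob,
                   predict_center_map(sub, clf2)$prob)
})

test_that("the probability map separates center cores from the rest", {
  clf <- tiny_detector()
  sec <- tiny_section(303L)
  pm <- predict_center_map(sec, clf)
  expect_true(all(pm$prob >= 0 & pm$prob <= 1))
  # self-consistency: core pixels score high, others low
  H <- nrow(pm$prob)
  core <- matrix(FALSE, H, ncol(pm$prob))
  tr <- sec$truth
  for (j in seq_len(nrow(tr))) {
    r_px <- 0.3 * tr$radius_um[j] / sec$um_per_px
    y <- tr$center_row_px[j] + 1; x <- tr$center_col_px[j] + 1
    rs <- max(1, round(y - r_px)):min(H, round(y + r_px))
    cs <- max(1, round(x - r_px)):min(ncol(core), round(x + r_px))
    core[rs, cs] <- TRUE
  }
  expect_gt(mean(pm$prob[core]), mean(pm$prob[!core]))
  expect_gt(mean(pm$prob[core] > 0.5), 0.9)   # training-distribution accuracy
  # pure interstitium scores low everywhere
  flat <- array(rep(default_palette()$interstitium, each = 40 * 40),
                dim = c(40, 40, 3))
  pm_flat <- predict_center_map(flat, clf)
  expect_true(all(pm_flat$prob < 0.5))
})

test_that("localization thresholds, suppresses and sorts peaks", {
  empty <- localize_centers(matrix(0, 50, 50), min_distance_px = 5)
  expect_equal(nrow(empty), 0L)
  # two well-separated unit peaks, no smoothing
  m <- matrix(0, 60, 60)
  m[15, 15] <- 1; m[45, 45] <- 0.9
  found <- localize_centers(m, min_distance_px = 10, threshold = 0.5,
                            smooth_sigma_px = 0)
  expect_equal(nrow(found), 2L)
  expect_equal(found$center_row_px, c(14, 44))   # sorted by peak prob
  # peaks closer than min_distance collapse to one
  m2 <- matrix(0, 60, 60)
  m2[30, 28] <- 1; m2[30, 34] <- 0.8
  found2 <- localize_centers(m2, min_distance_px = 10, threshold = 0.5,
                             smooth_sigma_px = 0)
  expect_equal(nrow(found2), 1L)
  expect_equal(found2$center_row_px, 29)
  expect_equal(found2$center_col_px, 27)
})

test_that("the trained detector recovers tubule centers on a held-out section", {
  clf <- tiny_detector()
  sec <- tiny_section(303L)
  pm <- predict_center_map(sec, clf)
  cen <- localize_centers(pm, min_distance_px = 1.2 * 80 / sec$um_per_px)
  q <- evaluate_detection(sec$truth, cen,
                          0.5 * sec$truth$radius_um / sec$um_per_px)
  expect_gte(q$recall, 0.9)
  expect_lte(q$false_positives_pct, 10)
})

test_that("detection scoring matches greedily one-to-one", {
  truth <- tibble::tibble(center_row_px = c(10, 50, 90),
                          center_col_px = c(10, 50, 90),
                          radius_um = c(20, 20, 20))
  perfect <- truth[, 1:2]
  q <- evaluate_detection(truth, perfect, 5)
  expect_equal(q$recall, 1)
  expect_equal(q$false_positives_pct, 0)
  # one spurious among 50 truths -> 2% type-1 error
  truth50 <- tibble::tibble(center_row_px = 10 * (1:50),
                            center_col_px = rep(5, 50))
  det <- rbind(truth50, tibble::tibble(center_row_px = 3, center_col_px = 400))
  q50 <- evaluate_detection(truth50, det, 2)
  expect_equal(q50$recall, 1)
  expect_equal(q50$false_positives_pct, 2)
  # empty detections, duplicate detections, empty truth
  q0 <- evaluate_detection(truth, truth[0, 1:2], 5)
  expect_equal(q0$recall, 0)
  dup <- rbind(perfect, perfect[1, ])
  qd <- evaluate_detection(truth, dup, 5)
  expect_equal(qd$recall, 1)
  expect_equal(qd$n_detected - qd$n_matched, 1L)
  expect_error(evaluate_detection(truth[0, ], perfect, 5), "empty truth")
})
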