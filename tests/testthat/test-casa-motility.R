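# SVM motility cascade and capacitation time-course profiles.

test_that("training requires all five classes and is deterministic", {
  kin <- labelled_kinematics()
  mot <- kin[kin$motile, ]
  expect_error(train_motility_svm(mot[mot$class != "slow", ]), "slow")
  m1 <- train_motility_svm(mot, seed = 4L)
  m2 <- train_motility_svm(mot, seed = 4L)
  expect_identical(classify_tracks(m1, mot), classify_tracks(m2, mot))
})

test_that("the cascade recovers training labels and held-out labels", {
  kin <- labelled_kinematics()
  mot <- kin[kin$motile, ]
  model <- train_motility_svm(mot)
  self <- classify_tracks(model, mot)
  expect_gt(mean(self == mot$class), 0.95)
  held <- labelled_kinematics(seed = 303L)
  heldm <- held[held$motile, ]
  pred <- classify_tracks(model, heldm)
  expect_gte(mean(pred == heldm$class), 0.9)
  # hyperactivated tracks show higher ALH and lower LIN than progressive
  expect_gt(mean(heldm$alh_um[heldm$class == "hyperactivated"]),
            mean(heldm$alh_um[heldm$class == "progressive"]))
  expect_lt(mean(heldm$lin_frac[heldm$class == "hyperactivated"]),
            mean(heldm$lin_frac[heldm$class == "progressive"]))
})

test_that("classification is empty on empty input and order-equivariant", {
  kin <- labelled_kinematics()
  mot <- kin[kin$motile, ]
  model <- train_motility_svm(mot)
  expect_identical(classify_tracks(model, mot[0, ]), character(0))
  perm <- sample(nrow(mot))
  expect_identical(classify_tracks(model, mot[perm, ]),
                   classify_tracks(model, mot)[perm])
  expect_error(classify_tracks(list(), mot), "trained")
})

test_that("time-course profiles compute class percentages over motile tracks", {
  all_prog <- tibble::tibble(time_min = 10, motile = TRUE,
                             class = rep("progressive", 8))
  p <- timecourse_profile(all_prog)
  expect_equal(p$pct_progressive, 100)
  expect_equal(p$percent_vigorous, 100)

  # counts (2,1,1,3,3) motile of 20 tracks total
  cls <- c(rep("progressive", 2), "intermediate", "hyperactivated",
           rep("slow", 3), rep("weakly_motile", 3))
  d <- tibble::tibble(time_min = 90,
                      motile = c(rep(TRUE, 10), rep(FALSE, 10)),
                      class = c(cls, rep(NA_character_, 10)))
  p2 <- timecourse_profile(d)
  expect_equal(unname(unlist(p2[, paste0("pct_", c("progressive",
    "intermediate", "hyperactivated", "slow", "weakly_motile"))])),
    c(20, 10, 10, 30, 30))
  expect_equal(p2$percent_vigorous, 40)
  expect_equal(p2$percent_motile, 50)

  # multiple time points keep time order and percentages sum to 100
  d2 <- rbind(d, tibble::tibble(time_min = 10, motile = TRUE,
                                class = sample(c("progressive", "slow"), 12,
                                               replace = TRUE)))
  p3 <- timecourse_profile(d2)
  expect_equal(p3$time_min, c(10, 90))
  sums <- rowSums(p3[, paste0("pct_", c("progressive", "intermediate",
    "hyperactivated", "slow", "weakly_motile"))])
  expect_equal(unname(sums), c(100, 100), tolerance = 1e-4)

  expect_error(timecourse_profile(tibble::tibble(time_min = 10,
                                                 motile = FALSE,
                                                 class = NA_character_)),
               "no motile")
})
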