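# Modified z-scores, heritability, correlations and ANOVA.

test_that("modified z-scores reproduce the hand-evaluated formula cases", {
  # strain A: median 4, MAD 1; population median 2 -> z = 0.6745*2/1
  tab <- tibble::tibble(
    animal_id = as.character(1:8),
    strain = c(rep("A", 3), rep("B", 5)),
    age_days = 100,
    y = c(3, 4, 5, 0, 1, 2, 2, 2))
  s <- strain_summaries(tab, "y")
  a <- s[s$strain == "A", ]
  expect_equal(a$z, 1.349, tolerance = 5e-4)
  expect_equal(a$z_class, "high")

  # MAD = 0 fallback: strain {5,5,7}, population median 4
  tab2 <- tibble::tibble(
    animal_id = as.character(1:8),
    strain = c(rep("A", 3), rep("B", 5)),
    age_days = 100,
    y = c(5, 5, 7, 1, 3, 4, 4, 4))
  s2 <- strain_summaries(tab2, "y")
  a2 <- s2[s2$strain == "A", ]
  expect_equal(a2$mad, 0)
  expect_equal(a2$mean_ad, 2 / 3)
  expect_equal(a2$z, 1.47, tolerance = 5e-3)

  # strain median equal to the population median -> z = 0 whatever the spread
  tab3 <- tibble::tibble(
    animal_id = as.character(1:8),
    strain = c(rep("A", 4), rep("B", 4)),
    age_days = 100,
    y = c(1, 2, 8, 9, 3, 4.5, 5.5, 40))
  s3 <- strain_summaries(tab3, "y")
  expect_equal(s3$z[s3$strain == "A"], 0)
})

test_that("z classification thresholds are exclusive at +/-1 and +/-3", {
  # boundary values are NOT outliers ("larger than" is strict); z = -3 is
  # low, not very low
  expect_equal(classify_z(c(1, -1, 3, -3, 0)),
               c("normal", "normal", "high", "low", "normal"))
  expect_equal(classify_z(1.0001), "high")
  expect_equal(classify_z(3.0001), "very_high")
  expect_equal(classify_z(-3.2), "very_low")
  expect_equal(classify_z(-1.5), "low")
})

test_that("modified z is shift-invariant and scale-free", {
  set.seed(10)
  tab <- gen_phenotypes(pheno_sim_config(seed = 31L))
  z0 <- strain_summaries(tab, "trait")$z
  tab$trait <- tab$trait + 17.3
  expect_equal(strain_summaries(tab, "trait")$z, z0, tolerance = 1e-9)
  tab$trait <- tab$trait * 4.2
  expect_equal(strain_summaries(tab, "trait")$z, z0, tolerance = 1e-9)
})

test_that("heritability limits and estimator agreement hold", {
  # VE = 0 limit: strain means differ, no within-strain spread
  tab <- tibble::tibble(animal_id = as.character(1:6),
                        strain = rep(c("A", "B", "C"), each = 2),
                        age_days = 100, y = rep(c(1, 5, 9), each = 2))
  expect_equal(heritability(tab, "y")$h2, 1)
  expect_error(heritability(tab[1:2, ], "y"), "2 strains")
  tab$y <- 1
  expect_error(heritability(tab, "y"), "degenerate")

  # va = 0: estimates near zero at large n
  p0 <- gen_phenotypes(pheno_sim_config(n_strains = 8L, n_per_strain = 100L,
                                        va = 0, ve = 1, seed = 77L))
  expect_lt(heritability(p0, "trait")$h2, 0.15)

  # the two estimators agree on balanced data with n >= 25
  p <- gen_phenotypes(pheno_sim_config(va = 0.7, ve = 0.3, seed = 13L))
  h1 <- heritability(p, "trait", "strain_mean_variance")$h2
  h2 <- heritability(p, "trait", "anova_mom")$h2
  expect_lt(abs(h1 - h2), 0.02)

  # va=0.7/ve=0.3 at 8 strains x 25: replicate-mean estimate in [0.55, 0.85]
  hmean <- mean(vapply(1:50, function(r) {
    pr <- gen_phenotypes(pheno_sim_config(va = 0.7, ve = 0.3,
                                          seed = 400L + r))
    heritability(pr, "trait")$h2
  }, numeric(1)))
  expect_gt(hmean, 0.55); expect_lt(hmean, 0.85)
})

test_that("pairwise correlations use complete pairs and stay symmetric", {
  tt <- tibble::tibble(animal_id = as.character(1:4), strain = "A",
                       age_days = 1,
                       x = c(1, 2, 3, 4), y = c(1, 2, NA, 8),
                       z = c(2, 3, 4, 5))
  pc <- pairwise_pearson(tt, c("x", "y", "z"))
  expect_equal(diag(pc$r), c(x = 1, y = 1, z = 1))
  expect_identical(pc$r, t(pc$r))
  # hand Pearson on the 3 complete pairs (1,2,4) vs (1,2,8)
  expect_equal(pc$r["x", "y"], 0.9799, tolerance = 1e-4)
  expect_equal(pc$n["x", "y"], 3L)
  expect_equal(pc$r["x", "z"], 1)       # exact linear relation
  # too few complete pairs -> NA
  tt$w <- c(1, 2, NA, NA)
  pc2 <- pairwise_pearson(tt, c("y", "w"))
  expect_true(is.na(pc2$r["y", "w"]))
})

test_that("one-way ANOVA reproduces hand-computed sums of squares", {
  tab <- tibble::tibble(animal_id = as.character(1:6),
                        strain = rep(c("A", "B"), each = 3),
                        age_days = 100, y = c(1, 2, 3, 4, 5, 6))
  a <- one_way_anova(tab, "y")
  expect_equal(a$statistic[1], 13.5)
  expect_equal(a$df, c(1, 4))
  expect_equal(a$sumsq[1], 13.5)
  # identical groups -> F = 0
  tab$y <- rep(c(1, 2, 3), 2)
  expect_equal(one_way_anova(tab, "y")$statistic[1], 0)
  expect_error(one_way_anova(tab[1:3, ], "y"), "2 factor levels")
})

test_that("two-way ANOVA fits strain, age and their interaction sequentially", {
  p <- gen_phenotypes(pheno_sim_config(va = 5, ve = 0.5, age_slope = 0.02,
                                       seed = 21L))
  a <- two_way_anova(p, "trait")
  expect_equal(a$term, c("strain", "age_days", "strain:age_days", "Residuals"))
  expect_equal(a$df[1:3], c(7, 1, 7))
  expect_lt(a$p[1], 1e-6)          # strong simulated strain effect
  expect_lt(a$p[2], 1e-6)          # strong simulated age effect
  p$trait <- 1
  expect_error(two_way_anova(p, "trait"), "zero-variance")
})

test_that("null two-way ANOVA p-values are uniform across replicates", {
  ps <- vapply(1:120, function(r) {
    p <- gen_phenotypes(pheno_sim_config(n_strains = 5L, n_per_strain = 10L,
                                         va = 0, ve = 1, age_slope = 0,
                                         seed = 9000L + r))
    two_way_anova(p, "trait")$p[1]
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})
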