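# CASA kinematics: analytic cases, a dense-sampling oracle, and geometric
# invariances.

test_that("the average path is the identity at window 1 and preserves lines", {
  xy <- random_track(20)
  expect_identical(average_path(xy, 1L), xy)
  line <- straight_track(30, 1.5)
  sm <- average_path(line, 7L)
  expect_equal(sm[, 2], rep(0, 30))
  expect_equal(sm[1, ], line[1, ])          # endpoints preserved
  expect_equal(sm[30, ], line[30, ])
  # 3-point hand case: middle of (0,0),(1,1),(2,0) with window 3
  tri <- cbind(c(0, 1, 2), c(0, 1, 0))
  expect_equal(average_path(tri, 3L)[2, ], c(1, 1 / 3))
})

test_that("a straight constant-speed track has the analytic parameter values", {
  k <- compute_kinematics(straight_track(90, 2), frame_rate_hz = 60)
  expect_equal(k$vcl_um_s, 120)
  expect_equal(k$vsl_um_s, 120)
  expect_equal(k$vap_um_s, 120)
  expect_equal(k$lin_frac, 1)
  expect_equal(k$str_frac, 1)
  expect_equal(k$alh_um, 0)
  expect_equal(k$bcf_hz, 0)
})

test_that("a closed loop has zero straight-line velocity and linearity", {
  t <- seq(0, 2 * pi, length.out = 61)
  loop <- cbind(10 * cos(t), 10 * sin(t))
  k <- compute_kinematics(loop, 60)
  expect_equal(k$vsl_um_s, 0, tolerance = 1e-9)
  expect_equal(k$lin_frac, 0, tolerance = 1e-9)
  expect_error(compute_kinematics(loop[1, , drop = FALSE], 60), "2 frames")
})

test_that("sinusoidal tracks match a dense-sampling oracle within 5%", {
  # oracle: the same parameter definitions evaluated independently on the
  # continuous curve over a dense (10 kHz) time grid
  v <- 120; A <- 3; f <- 4
  curve <- function(t) cbind(v * t, A * sin(2 * pi * f * t))
  t60 <- seq(0, 89 / 60, by = 1 / 60)
  k <- compute_kinematics(curve(t60), 60, window = 5L)
  dur <- 89 / 60

  tdense <- seq(0, dur, by = 1e-4)
  steps <- function(xy) sum(sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2))
  vcl_oracle <- steps(curve(tdense)) / dur
  vsl_oracle <- sqrt(sum((curve(dur) - curve(0))^2)) / dur
  expect_equal(k$vcl_um_s / vcl_oracle, 1, tolerance = 0.05)
  expect_equal(k$vsl_um_s / vsl_oracle, 1, tolerance = 0.001)

  # ALH oracle: average path = 5-point, 60 Hz-spaced boxcar of the
  # continuous curve; deviation taken perpendicular to its tangent
  ti <- seq(5 / 60, dur - 5 / 60, by = 1e-4)
  ysm <- rowMeans(sapply(-2:2, function(kk) A * sin(2 * pi * f * (ti + kk / 60))))
  dysm <- c(diff(ysm) / 1e-4, NA)
  dysm[length(dysm)] <- dysm[length(dysm) - 1]
  dev <- v * (A * sin(2 * pi * f * ti) - ysm) / sqrt(v^2 + dysm^2)
  alh_oracle <- 2 * mean(abs(dev))
  expect_equal(k$alh_um / alh_oracle, 1, tolerance = 0.05)

  # BCF: the deviation changes sign twice per beat cycle
  expect_equal(k$bcf_hz, 2 * f, tolerance = 0.15)
})

test_that("VSL <= VCL and VAP <= VCL over randomized tracks", {
  set.seed(99)
  for (i in 1:200) {
    xy <- random_track(sample(5:60, 1))
    k <- compute_kinematics(xy, 60, window = sample(c(1L, 3L, 5L, 7L), 1))
    expect_lte(k$vsl_um_s, k$vcl_um_s + 1e-9)
    expect_lte(k$vap_um_s, k$vcl_um_s + 1e-9)
    expect_gte(k$str_frac, 0); expect_lte(k$str_frac, 1 + 1e-9)
    expect_gte(k$lin_frac, 0); expect_lte(k$lin_frac, 1 + 1e-9)
  }
})

test_that("kinematics are invariant to rigid rotation and translation", {
  set.seed(3)
  xy <- random_track(40)
  k0 <- compute_kinematics(xy, 60)
  th <- 0.83
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  k1 <- compute_kinematics(sweep(xy %*% R, 2, c(-12.5, 40), "+"), 60)
  for (p in c("vcl_um_s", "vsl_um_s", "vap_um_s", "alh_um", "bcf_hz",
              "str_frac", "lin_frac")) {
    expect_equal(k1[[p]], k0[[p]], tolerance = 1e-9)
  }
})

test_that("the motile gate passes slow sperm and rejects the static", {
  zero <- compute_kinematics(cbind(rep(0, 90), rep(0, 90)), 60)
  expect_false(is_motile(zero))
  # slow but moving: VCL 30 um/s clears the gate despite tiny VSL
  slow <- tibble::tibble(vcl_um_s = 30, net_disp_um = 2)
  expect_true(is_motile(slow))
  # just below both gates -> static
  below <- tibble::tibble(vcl_um_s = 24.9, net_disp_um = 3.9)
  expect_false(is_motile(below))
  expect_true(is_motile(tibble::tibble(vcl_um_s = 10, net_disp_um = 4)))
})
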