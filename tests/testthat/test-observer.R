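test_that("hill-of-vision field follows the linear decline formula", {
  grid <- build_grid_30_2("OD")
  f <- make_normal_field(grid, s0 = 33, slope = 0.3, noise_sd = 0)
  expect_equal(f$sens[f$x == 3 & f$y == 3], 33 - 0.3 * sqrt(18),
               tolerance = 1e-12)
  expect_equal(f$sens, 33 - 0.3 * grid$ecc, tolerance = 1e-12)
  flat <- make_normal_field(grid, s0 = 33, slope = 0, noise_sd = 0)
  expect_true(all(flat$sens == 33))
  f1 <- make_normal_field(grid, seed = 99)
  f2 <- make_normal_field(grid, seed = 99)
  expect_identical(f1$sens, f2$sens)
  expect_true(all(f1$sens >= 0 & f1$sens <= 50))
  expect_error(make_normal_field(grid, s0 = 10), "\\[20, 45\\]")
})

test_that("lesion injection is local, depth-capped, and shape-correct", {
  f <- flat_field(33)
  expect_identical(inject_lesion(f, "arcuate", depth = 0)$sens, f$sens)
  # blind-spot lesion hits exactly the two points at (temporal 15, +/-3)
  bs <- inject_lesion(f, "blind_spot", depth = 10)
  changed <- which(bs$sens != f$sens)
  expect_length(changed, 2)
  expect_setequal(paste(f$x[changed], f$y[changed]), c("15 3", "15 -3"))
  # quadrantanopia zeroes nothing outside its quadrant
  q <- inject_lesion(f, "quadrantanopia", quadrant = "ST", depth = 30)
  expect_true(all(q$sens[f$quadrant != "ST"] == 33))
  expect_true(all(q$sens[f$quadrant == "ST"] == 3))
  # depth floors at 0
  deep <- inject_lesion(f, "quadrantanopia", quadrant = "ST", depth = 99)
  expect_true(all(deep$sens >= 0))
  # rim artifact clips only the chosen peripheral side
  rim <- inject_lesion(f, "rim_artifact", rim_side = "inferior", depth = 20)
  hit <- rim$sens != f$sens
  expect_true(all(f$ecc[hit] >= 21))
  expect_true(all(f$y[hit] < 0))
  # nasal step confined to one hemifield's nasal points near the meridian
  ns <- inject_lesion(f, "nasal_step", hemifield = "inferior", depth = 10)
  hit <- ns$sens != f$sens
  expect_true(all(f$side[hit] == "nasal" & f$y[hit] < 0 & abs(f$y[hit]) <= 9))
  expect_error(inject_lesion(f, "unknown_kind"), "arg")
})

test_that("frequency-of-seeing probabilities follow the psychometric model", {
  # step-function limit: presented brighter than threshold is always seen
  expect_equal(seen_probability(30, 25, fos_slope = 1e-9, 0, 0), 1)
  expect_equal(seen_probability(30, 35, fos_slope = 1e-9, 0, 0), 0)
  # at threshold the probability is exactly 1/2 without fp/fn
  expect_equal(seen_probability(30, 30, 1, 0, 0), 0.5)
  # the false-positive floor dominates far above threshold
  expect_equal(seen_probability(0, 40, 1, 0.05, 0), 0.05, tolerance = 1e-12)
  # the false-negative rate caps the curve far below threshold
  expect_equal(seen_probability(40, 14, 1, 0, 0.1), 0.9, tolerance = 1e-6)
})

test_that("responses are reproducible under a fixed seed and order", {
  f <- flat_field(30)
  obs <- observer_model(f, rng_seed = 5)
  draw <- function() {
    set.seed(obs$rng_seed)
    vapply(seq(20, 40, by = 2), function(db) respond(obs, 3, 3, db),
           logical(1))
  }
  expect_identical(draw(), draw())
  expect_error(observer_model(f, fp_rate = 0.6), "0.5")
  expect_error(observer_model(f, fos_slope = 0), "positive")
})

test_that("off-lattice sensitivity interpolation is exact on nodes and local", {
  f <- flat_field(30)
  f$sens[f$x == 3 & f$y == 3] <- 20
  expect_equal(field_sensitivity_at(f, 3, 3), 20)
  expect_equal(field_sensitivity_at(f, 9, 9), 30)
  # between nodes the value lies between the neighbours
  v <- field_sensitivity_at(f, 4.5, 3)
  expect_true(v > 20 && v < 30)
})

test_that("gaze traces are AR(1) wander with the stated stationary spread", {
  z <- gaze_trace(1, gaze_sd = 0, seed = 1)
  expect_true(all(z$gx == 0) && all(z$gy == 0))
  expect_equal(nrow(z), 120)
  expect_equal(nrow(gaze_trace(0.5, rate = 120)), 60)
  tr <- gaze_trace(600, gaze_sd = 1.0, seed = 2)
  expect_true(all(diff(tr$t) > 0))
  expect_lt(abs(sd(tr$gx) - 1.0) / 1.0, 0.15)
  expect_lt(abs(sd(tr$gy) - 1.0) / 1.0, 0.15)
  expect_identical(gaze_trace(2, seed = 4), gaze_trace(2, seed = 4))
  expect_error(gaze_trace(0), "positive")
})

test_that("paired cohorts are reproducible and correlation-calibrated", {
  c1 <- make_paired_cohort(5, seed = 10)
  c2 <- make_paired_cohort(5, seed = 10)
  expect_identical(c1$fields, c2$fields)
  expect_identical(c1$manifest, c2$manifest)
  expect_equal(nrow(c1$fields), 5 * 76)
  expect_true(all(c1$manifest$fl >= 0 & c1$manifest$fl <= 1))
  # no independent or device-bias noise: global means correlate exactly
  ident <- make_paired_cohort(6, shared_sd = 1, indep_sd_a = 0,
                              indep_sd_b = 0, seed = 3)
  gm <- dplyr::summarise(dplyr::group_by(ident$fields, eye_id),
                         a = mean(sens_a), b = mean(sens_b))
  expect_equal(cor(gm$a, gm$b), 1, tolerance = 1e-12)
  expect_error(make_paired_cohort(2), "at least 3")
})

test_that("the analytic nominal correlation matches its inverse solver", {
  for (r in c(0.3, 0.5, 0.8, 0.95)) {
    bias <- eye_bias_for_r(r)
    expect_equal(nominal_global_r(eye_bias_sd_a = bias, eye_bias_sd_b = bias),
                 r, tolerance = 1e-12)
  }
  expect_equal(nominal_global_r(indep_sd_a = 0, indep_sd_b = 0), 1)
  expect_error(eye_bias_for_r(0), "\\(0, 1\\]")
})

test_that("a nominal-0.8 cohort of 65 eyes recovers r in the sampling band", {
  bias <- eye_bias_for_r(0.8)
  coh <- make_paired_cohort(65, eye_bias_sd_a = bias, eye_bias_sd_b = bias,
                            seed = 20)
  gm <- dplyr::summarise(dplyr::group_by(coh$fields, eye_id),
                         a = mean(sens_a), b = mean(sens_b))
  r <- cor(gm$a, gm$b)
  expect_gt(r, 0.65)
  expect_lt(r, 0.90)
})
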