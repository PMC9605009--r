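test_that("30-2 grid has 76 points with the canonical row structure", {
  for (eye in c("OD", "OS")) {
    g <- build_grid_30_2(eye)
    expect_equal(nrow(g), 76)
    expect_equal(sum(g$hemifield == "superior"), 38)
    expect_equal(as.integer(table(g$quadrant)), rep(19L, 4))
    # rows of 4/6/8/10/10 per hemifield, top row first
    expect_equal(as.integer(table(factor(g$y[g$y > 0], levels = c(27, 21, 15, 9, 3)))),
                 c(4L, 6L, 8L, 10L, 10L))
  }
})

test_that("grid matches brute-force lattice enumeration and its symmetries", {
  g <- build_grid_30_2("OD")
  # independent enumeration of the inclusion rule
  lattice <- expand.grid(x = seq(-27, 27, by = 6), y = seq(-27, 27, by = 6))
  ref <- lattice[sqrt(lattice$x^2 + lattice$y^2) <= 28.5, ]
  expect_setequal(paste(g$x, g$y), paste(ref$x, ref$y))
  # invariance under x -> -x and y -> -y
  expect_setequal(paste(g$x, g$y), paste(-g$x, g$y))
  expect_setequal(paste(g$x, g$y), paste(g$x, -g$y))
  # top row
  expect_equal(sort(g$x[g$y == 27]), c(-9, -3, 3, 9))
  # the rule has slack: nearest excluded lattice point is >= 29.6 deg out
  excl <- lattice[sqrt(lattice$x^2 + lattice$y^2) > 28.5, ]
  expect_gte(min(sqrt(excl$x^2 + excl$y^2)), 29.6)
  expect_lte(max(g$ecc), 28.5)
})

test_that("grid is in deterministic row-major order with correct labels", {
  g <- build_grid_30_2("OD")
  expect_equal(g$y, sort(g$y, decreasing = TRUE))
  for (yy in unique(g$y)) {
    expect_equal(g$x[g$y == yy], sort(g$x[g$y == yy]))
  }
  # OD: temporal = +x, blind-spot pair at (15, +/-3); OS mirrored
  expect_setequal(paste(g$x[g$blind_spot], g$y[g$blind_spot]),
                  c("15 3", "15 -3"))
  gs <- build_grid_30_2("OS")
  expect_setequal(paste(gs$x[gs$blind_spot], gs$y[gs$blind_spot]),
                  c("-15 3", "-15 -3"))
  expect_equal(g$quadrant[g$x == 9 & g$y == 9], "ST")
  expect_equal(gs$quadrant[gs$x == 9 & gs$y == 9], "SN")
})

test_that("bowl projection lies on the sphere and round-trips angles", {
  b <- field_to_bowl(0, 0)
  expect_equal(c(b$px, b$py, b$pz), c(0, 0, 330))
  b27 <- field_to_bowl(27, 0)
  expect_equal(b27$px, 330 * sin(27 * pi / 180), tolerance = 1e-12)
  expect_equal(b27$pz, 330 * cos(27 * pi / 180), tolerance = 1e-12)
  # sphere membership and angle recovery over random angles
  set.seed(42)
  xs <- runif(200, -80, 80)
  ys <- runif(200, -80, 80)
  b <- field_to_bowl(xs, ys, radius = 330)
  expect_equal(sqrt(b$px^2 + b$py^2 + b$pz^2), rep(330, 200),
               tolerance = 1e-9)
  expect_equal(atan2(b$px, b$pz) * 180 / pi, xs, tolerance = 1e-9)
  expect_equal(atan2(b$py, b$pz) * 180 / pi, ys, tolerance = 1e-9)
  expect_error(field_to_bowl(90, 0), "within")
})

test_that("gaze-contingent placement preserves retinal eccentricity", {
  # identity rotation reproduces the plain projection
  expect_equal(gaze_contingent_position(9, 0, 0, 0), field_to_bowl(9, 0))
  # angle to gaze equals target eccentricity, via the dot-product oracle
  p <- gaze_contingent_position(9, 0, 5, 0)
  gdir <- perisim:::field_direction(5, 0)
  ang <- acos(sum(c(p$px, p$py, p$pz) / 330 * gdir)) * 180 / pi
  expect_equal(ang, 9, tolerance = 1e-9)
  # property: 1000 random gaze/target pairs, gaze offsets up to 20 deg
  set.seed(7)
  for (i in 1:1000) {
    tx <- runif(1, -27, 27); ty <- runif(1, -27, 27)
    gx <- runif(1, -20, 20); gy <- runif(1, -20, 20)
    p <- gaze_contingent_position(tx, ty, gx, gy)
    tdir <- perisim:::field_direction(tx, ty)
    gdir <- perisim:::field_direction(gx, gy)
    ecc_target <- acos(drop(tdir %*% c(0, 0, 1))) * 180 / pi
    ecc_retinal <- acos(sum(c(p$px, p$py, p$pz) / 330 * gdir)) * 180 / pi
    expect_equal(ecc_retinal, ecc_target, tolerance = 1e-9)
  }
  expect_error(gaze_contingent_position(60, 0, 45, 0),
               class = "perisim_out_of_display")
})

test_that("Goldmann III angle and bowl extent follow the closed forms", {
  expect_equal(round(goldmann_iii_angle(), 2), 0.43)
  expect_equal(goldmann_iii_angle(), 2 * atan(sqrt(4 / pi) / 300) * 180 / pi,
               tolerance = 1e-12)
  expect_equal(stimulus_extent_on_bowl(0.431, 330),
               2 * 330 * tan(0.431 / 2 * pi / 180), tolerance = 1e-12)
  expect_equal(stimulus_extent_on_bowl(0.431, 330), 2.48, tolerance = 1e-2)
  # doubling the area multiplies the diameter by sqrt(2) (small angles)
  d1 <- 2 * atan(sqrt(4 / pi) / 300)
  d2 <- 2 * atan(sqrt(8 / pi) / 300)
  expect_equal(d2 / d1, sqrt(2), tolerance = 1e-4)
  # monotone in both arguments
  expect_gt(stimulus_extent_on_bowl(1, 330), stimulus_extent_on_bowl(0.5, 330))
  expect_gt(stimulus_extent_on_bowl(1, 400), stimulus_extent_on_bowl(1, 330))
  expect_error(stimulus_extent_on_bowl(0, 330), "must lie")
})
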