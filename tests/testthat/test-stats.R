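test_that("sector map covers the grid with consistent labels", {
  for (eye in c("OD", "OS")) {
    sm <- sector_map_30_2(eye)
    expect_equal(nrow(sm), 76)
    expect_false(any(is.na(sm$hemifield)))
    expect_false(any(is.na(sm$quadrant)))
    # quadrant label agrees with the sign of y and the nasal side
    expect_true(all(substr(sm$quadrant, 1, 1) ==
                      toupper(substr(sm$hemifield, 1, 1))))
    expect_true(all((substr(sm$quadrant, 2, 2) == "N") ==
                      (sm$side == "nasal")))
    # GHT sectors are mirror-symmetric across the horizontal meridian
    sup <- sm[sm$hemifield == "superior", ]
    inf <- sm[sm$hemifield == "inferior", ]
    key <- function(df) {
      df <- df[!is.na(df$ght_sector), ]
      sort(paste(df$x, abs(df$y), substr(df$ght_sector, 2, 2)))
    }
    expect_equal(key(sup), key(inf))
    # blind-spot points never carry a sector
    expect_true(all(is.na(sm$ght_sector[sm$blind_spot])))
  }
})

test_that("a user sector map overrides the default assignment", {
  g <- build_grid_30_2("OD")
  ovr <- tibble::tibble(x = g$x[1:4], y = g$y[1:4], ght_sector = "Z9")
  sm <- sector_map_30_2("OD", ght = ovr)
  expect_equal(sum(sm$ght_sector == "Z9", na.rm = TRUE), 4)
  expect_equal(sum(!is.na(sm$ght_sector)), 4)
})

test_that("regional means are filtered means with blind-spot exclusion", {
  f <- flat_field(30)
  sm <- sector_map_30_2("OD")
  for (reg in c("global", "superior", "IT", "S1")) {
    expect_equal(region_mean(f, reg, sm)$mean_db, 30)
  }
  # one point lowered by 7.4 dB moves the 74-point global mean by 0.1
  f2 <- f
  f2$sens[f2$x == 3 & f2$y == 3] <- 30 - 7.4
  expect_equal(region_mean(f2, "global", sm)$mean_db, 30 - 0.1)
  expect_equal(region_mean(f2, "global", sm)$n, 74)
  # superior mean ignores y < 0: oracle = direct filtered mean
  f3 <- f
  f3$sens[f3$y < 0] <- 0
  expect_equal(region_mean(f3, "superior", sm)$mean_db, 30)
  oracle <- mean(f2$sens[f2$y > 0 & !f2$blind_spot])
  expect_equal(region_mean(f2, "superior", sm)$mean_db, oracle)
  # blind-spot inclusion is configurable
  expect_equal(region_mean(f, "global", sm, exclude_blind_spot = FALSE)$n, 76)
  expect_error(region_mean(f, "nowhere", sm), "unknown region")
})

test_that("quadrant means recombine to hemifield and global means", {
  f <- make_normal_field(build_grid_30_2("OD"), seed = 12)
  sm <- sector_map_30_2("OD")
  q <- purrr::map(c("SN", "ST", "IN", "IT"),
                  ~ region_mean(f, .x, sm)) |> purrr::list_rbind()
  sup <- region_mean(f, "superior", sm)
  glob <- region_mean(f, "global", sm)
  sq <- q[q$region %in% c("SN", "ST"), ]
  expect_equal(sum(sq$mean_db * sq$n) / sum(sq$n), sup$mean_db,
               tolerance = 1e-12)
  expect_equal(sum(q$mean_db * q$n) / sum(q$n), glob$mean_db,
               tolerance = 1e-12)
})

test_that("correlation strength classes honour the cut-offs exactly", {
  expect_equal(classify_r(0.81), "strong")
  expect_equal(classify_r(0.7), "strong")
  expect_equal(classify_r(0.4), "moderate")
  expect_equal(classify_r(0.6999), "moderate")
  expect_equal(classify_r(0.39), "weak")
  expect_equal(classify_r(c(1, -0.2)), c("strong", "weak"))
  expect_true(is.na(classify_r(NA_real_)))
  expect_error(classify_r(1.2), "exceed")
})

test_that("Pearson r agrees with the sum-formula oracle to 1e-12", {
  sum_formula_r <- function(a, b) {
    n <- length(a)
    (n * sum(a * b) - sum(a) * sum(b)) /
      sqrt((n * sum(a^2) - sum(a)^2) * (n * sum(b^2) - sum(b)^2))
  }
  set.seed(21)
  for (i in 1:20) {
    a <- rnorm(30)
    b <- rnorm(30)
    expect_equal(perisim:::pearson_or_na(a, b)$r, sum_formula_r(a, b),
                 tolerance = 1e-12)
  }
})

test_that("cohort correlations: exact cases and undefined flags", {
  coh <- make_paired_cohort(5, shared_sd = 0, indep_sd_a = 0, indep_sd_b = 0,
                            seed = 30)
  coh$fields$sens_b <- coh$fields$sens_a  # B identical to A
  rep <- cohort_correlations(coh)
  expect_equal(rep$regions$r, rep(1, nrow(rep$regions)), tolerance = 1e-12)
  expect_true(all(rep$regions$class == "strong"))
  expect_equal(nrow(rep$points), 76)
  expect_equal(rep$points$r, rep(1, 76), tolerance = 1e-12)
  # perfect anticorrelation of global means across 3 eyes
  coh3 <- make_paired_cohort(3, seed = 31)
  coh3$fields$sens_a <- rep(c(1, 2, 3), each = 76)
  coh3$fields$sens_b <- rep(c(3, 2, 1), each = 76)
  rep3 <- cohort_correlations(coh3)
  expect_equal(rep3$regions$r[rep3$regions$region == "global"], -1)
  # zero variance yields an undefined flag, not a coerced number
  coh0 <- make_paired_cohort(4, seed = 32)
  coh0$fields$sens_a <- 30
  rep0 <- cohort_correlations(coh0)
  expect_true(all(rep0$regions$undefined))
  expect_true(all(is.na(rep0$regions$r)))
  small <- make_paired_cohort(3, seed = 1)
  small$manifest <- small$manifest[1:2, ]
  expect_error(cohort_correlations(small), "at least 3")
})

test_that("reliability filter applies strict inequalities per index", {
  recs <- tibble::tibble(
    id = 1:5,
    fl = c(0.25, 0.20, 0.05, 0.00, 0.10),
    fp = c(0.05, 0.15, 0.20, 0.00, 0.10),
    fn = c(0.05, 0.30, 0.05, 0.00, 0.35)
  )
  out <- reliability_filter(recs)
  expect_equal(out$excluded$id, c(1L, 3L, 5L))
  expect_equal(out$excluded$reasons, c("FL", "FP", "FN"))
  # records exactly at the thresholds are kept
  expect_true(2L %in% out$kept$id)
  expect_true(4L %in% out$kept$id)
  # combined violations name every reason
  both <- reliability_filter(tibble::tibble(fl = 0.3, fp = 0.2, fn = 0.0))
  expect_equal(both$excluded$reasons, "FL+FP")
  expect_error(reliability_filter(tibble::tibble(fl = NA, fp = 0, fn = 0)),
               "missing reliability")
  expect_error(reliability_filter(tibble::tibble(fl = 0.1)), "lack")
})

test_that("paired t matches the hand computation and flags zero variance", {
  res <- paired_t(c(1, 2, 3, 4), c(2, 2, 4, 5))
  # differences (-1, 0, -1, -1): mean -0.75, sd 0.5, t = -3, df = 3
  expect_equal(res$t, -3)
  expect_equal(res$df, 3)
  expect_equal(res$p, 2 * pt(-3, 3), tolerance = 1e-12)
  expect_equal(res$mean_diff, -0.75)
  expect_true(paired_t(c(1, 2), c(1, 2))$undefined)       # identical vectors
  expect_true(paired_t(c(2, 3, 4, 5), c(1, 2, 3, 4))$undefined)  # constant diff
  expect_error(paired_t(1:3, 1:4), "equal length")
  expect_error(paired_t(1, 2), "at least 2")
})

test_that("comparison report assembles filtering, regions, points and t", {
  bias <- eye_bias_for_r(0.8)
  coh <- make_paired_cohort(20, eye_bias_sd_a = bias, eye_bias_sd_b = bias,
                            seed = 33,
                            reliability_ranges = list(
                              fl = c(0, 0.4), fp = c(0, 0.1), fn = c(0, 0.2)))
  rep <- comparison_report(coh)
  expect_equal(rep$filter_counts$n_input, 20)
  expect_equal(rep$filter_counts$n_analyzed + rep$filter_counts$n_excluded, 20)
  expect_gt(rep$filter_counts$n_excluded, 0)  # fl range spans past 0.20
  expect_equal(nrow(rep$points), 76)
  expect_true(all(c("global", "superior", "inferior", "SN", "ST", "IN", "IT")
                  %in% rep$regions$region))
  expect_true(all(rep$points$class %in% c("strong", "moderate", "weak") |
                    is.na(rep$points$class)))
  # JSON round trip
  p <- withr::local_tempfile(fileext = ".json")
  write_report(rep, p)
  back <- read_report(p)
  expect_equal(back$regions$r, rep$regions$r)
  expect_equal(back$points$class, rep$points$class)
  expect_equal(back$filter_counts, rep$filter_counts)
  # classification grid renders 76 cells at three levels
  img <- render_classification_grid(rep)
  expect_true(all(unique(as.vector(img)) %in% c(85L, 170L, 200L, 255L)))
  # tidiers
  expect_equal(nrow(generics::tidy(rep, "points")), 76)
  gl <- generics::glance(rep)
  expect_equal(gl$n_strong + gl$n_moderate + gl$n_weak,
               sum(!is.na(rep$points$class)))
})
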