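# a cheap, deterministic surrogate fit (exact inverse-cube law through the
# baseline threshold) for tests that only need the geometry -> threshold map
toy_fit <- function(P85 = 330) {
  x <- c(55, 70, 85, 100, 120, 150)
  fit_power_law(tibble::tibble(value_nm = x, threshold_kPa = P85 * (85 / x)^3))
}

test_that("sampling is reproducible and respects the stated defaults", {
  a <- sample_population(5000, seed = 7)
  b <- sample_population(5000, seed = 7)
  expect_identical(a$diameter_nm, b$diameter_nm)
  expect_identical(a$length_nm, b$length_nm)
  c <- sample_population(5000, seed = 8)
  expect_false(identical(a$diameter_nm, c$diameter_nm))
  expect_error(sample_population(100), "seed")
  expect_true(all(a$diameter_nm >= 50 & a$diameter_nm <= 120))
  expect_true(all(a$length_nm >= 200 & a$length_nm <= 900))
})

test_that("large samples recover the stated median diameter within 1%", {
  pop <- sample_population(1e5, seed = 11)
  expect_lt(abs(median(pop$diameter_nm) - 85) / 85, 0.01)
})

test_that("zero-variance distributions give identical vesicles", {
  pop <- sample_population(
    50, seed = 3,
    diameter_dist = list(family = "lognormal", meanlog = log(85), sdlog = 0,
                         lower = 0, upper = Inf),
    length_dist = list(family = "normal", mean = 500, sd = 0,
                       lower = 0, upper = Inf))
  expect_equal(var(pop$diameter_nm), 0)
  expect_equal(var(pop$length_nm), 0)
})

test_that("the surrogate is strictly decreasing in diameter", {
  fit <- toy_fit()
  d <- seq(55, 120, by = 5)
  thr <- suppressWarnings(threshold_surrogate(d, fit))
  expect_true(all(diff(thr) < 0))
  expect_warning(threshold_surrogate(300, fit), "outside the fitted range")
})

test_that("calibration yields ~30% intact at 200 kPa and max survivor <= 90 nm", {
  pop <- sample_population(50000, seed = 5)
  pop <- assign_thresholds(pop, toy_fit(), 1)
  ratio <- calibrate_collapse_ratio(pop, target_intact = 0.30,
                                    at_pressure = 200)
  pop <- assign_thresholds(pop, toy_fit(), ratio)
  sel <- hydrostatic_select(pop, 200)
  expect_equal(sel$report$intact_fraction, 0.30, tolerance = 0.01)
  expect_lte(sel$report$max_survivor_d, 90)
  # length distribution essentially unchanged
  expect_lt(abs(sel$report$post_mean_l - sel$report$pre_mean_l) /
              sel$report$pre_mean_l, 0.02)
  # and formally: KS distance between pre/post lengths is small
  ks <- suppressWarnings(stats::ks.test(
    pop$length_nm, sel$population$length_nm[sel$population$intact]))
  expect_gt(ks$p.value, 0.01)
})

test_that("selection is monotone and nested in the applied pressure", {
  pop <- assign_thresholds(sample_population(20000, seed = 9), toy_fit(), 0.6)
  s1 <- hydrostatic_select(pop, 150)
  s2 <- hydrostatic_select(pop, 220)
  surv1 <- which(s1$population$intact)
  surv2 <- which(s2$population$intact)
  expect_true(all(surv2 %in% surv1))
  expect_lte(s2$report$intact_fraction, s1$report$intact_fraction)
  expect_lte(s2$report$post_mean_d, s1$report$post_mean_d)
})

test_that("selection limits: zero pressure keeps all, huge pressure none", {
  pop <- assign_thresholds(sample_population(2000, seed = 2), toy_fit(), 0.6)
  s0 <- hydrostatic_select(pop, 0)
  expect_equal(s0$report$intact_fraction, 1)
  expect_warning(sH <- hydrostatic_select(pop, 1e6), "no vesicles")
  expect_equal(sH$report$intact_fraction, 0)
})

test_that("collapse curve is monotone, consistent, and right-shifted after selection", {
  pop <- assign_thresholds(sample_population(20000, seed = 13), toy_fit(), 0.6)
  grid <- seq(0, 400, by = 10)
  cc <- collapse_curve(pop, grid)
  expect_true(all(diff(cc$intact_fraction) <= 1e-12))
  expect_equal(cc$intact_fraction[cc$pressure_kPa == 0], 1)
  sel <- hydrostatic_select(pop, 200)
  cc2 <- collapse_curve(sel$population, grid)
  expect_true(all(cc2$intact_fraction >= cc$intact_fraction - 1e-12))
  # curve at the selection pressure equals the reported intact fraction
  expect_equal(cc$intact_fraction[cc$pressure_kPa == 200],
               sel$report$intact_fraction)
})

test_that("precollapsed populations require higher pressure for signal onset", {
  fit <- toy_fit()
  onsets <- vapply(1:20, function(s) {
    pop <- assign_thresholds(sample_population(5000, seed = s), fit, 1)
    ratio <- calibrate_collapse_ratio(pop)
    pop <- assign_thresholds(pop, fit, ratio)
    sel <- hydrostatic_select(pop, 200)
    grid <- seq(100, 800, by = 5)
    o1 <- attr(xam_signal(pop, grid), "onset_kPa")
    o2 <- attr(xam_signal(sel$population, grid), "onset_kPa")
    o2 - o1
  }, numeric(1))
  expect_true(all(onsets > 0))
})

test_that("signal curve is monotone with onset above the minimum threshold", {
  pop <- assign_thresholds(sample_population(5000, seed = 21), toy_fit(), 0.6)
  grid <- seq(50, 900, by = 10)
  sig <- xam_signal(pop, grid)
  expect_true(all(diff(sig$signal) >= -1e-12))
  expect_equal(sig$signal[1], 0) # grid start below every threshold
  expect_gte(attr(sig, "onset_kPa"), min(pop$threshold_kPa))
  expect_error(xam_signal(pop[pop$diameter_nm > 1e5, ], grid), "empty")
})

test_that("optical density converts linearly to concentration", {
  expect_equal(od_to_concentration(1)$concentration_pM, 184)
  expect_equal(od_to_concentration(0)$concentration_pM, 0)
  expect_equal(od_to_concentration(2)$concentration_pM, 368)
  expect_equal(od_to_concentration(1)$volume_fraction_percent, 0.04)
  expect_error(od_to_concentration(-1), "non-negative")
})

test_that("diameter consistency follows the stated SD/mean formula", {
  expect_equal(diameter_consistency(c(80, 80, 80)), 0)
  expect_equal(diameter_consistency(c(80, 90)), 100 * sd(c(80, 90)) / 85)
  expect_equal(diameter_consistency(c(80, 90)),
               diameter_consistency(c(160, 180)))
  expect_error(diameter_consistency(85), "two measurements")
})
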