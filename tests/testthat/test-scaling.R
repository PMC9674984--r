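test_that("exact inverse-cube data recovers alpha = -3", {
  x <- c(60, 80, 100, 130, 170, 220)
  d <- tibble::tibble(value_nm = x, threshold_kPa = 2e8 * x^-3)
  fit <- fit_power_law(d)
  expect_equal(fit$alpha, -3, tolerance = 1e-6)
  expect_equal(fit$A, 2e8, tolerance = 1e-4)
  expect_lt(abs(fit$B), 1e-3 * max(d$threshold_kPa))
})

test_that("constant data yields a flat fitted model", {
  x <- c(60, 80, 100, 130, 170, 220)
  d <- tibble::tibble(value_nm = x, threshold_kPa = rep(250, 6))
  fit <- fit_power_law(d)
  # either branch (A -> 0 or alpha -> 0) is acceptable: the fitted derivative
  # must vanish relative to the level
  dPdx <- fit$A * fit$alpha * x^(fit$alpha - 1)
  expect_lt(max(abs(dPdx)) * diff(range(x)), 1e-3 * 250)
})

test_that("ring-buckling closed form matches independent arithmetic and cubes", {
  # independent hand evaluation: P = 2 E t^3 / ((1 - nu^2) D^3)
  E <- 1; nu <- 0.499; t <- 2.4; D <- 85
  by_hand <- 2 * (E * 1e9) * (t * 1e-9)^3 / ((1 - nu^2) * (D * 1e-9)^3) / 1e3
  expect_equal(ring_buckling_pressure(E, nu, t, D), by_hand, tolerance = 1e-12)
  expect_equal(ring_buckling_pressure(E, nu, t, 2 * D),
               ring_buckling_pressure(E, nu, t, D) / 8)
  expect_error(ring_buckling_pressure(-1, 0.3, 2.4, 85), "non-physical")
})

test_that("sweep input validation rejects bad grids", {
  expect_error(sweep_thresholds("diameter", 500, grid = 85), "two points")
  expect_error(sweep_thresholds("diameter", 500, grid = c(100, 60)),
               "increasing")
  expect_error(sweep_thresholds("diameter", 500, grid = c(30, 60)),
               "outside")
  expect_error(sweep_thresholds("length", 83, grid = c(100, 300)),
               "outside")
  expect_error(fit_power_law(tibble::tibble(value_nm = c(60, 80),
                                            threshold_kPa = c(1, 2))),
               "at least 5")
})

test_that("thresholds decrease strictly with diameter at fixed length", {
  sw <- cached("mini_dsweep",
               sweep_thresholds("diameter", 300, grid = c(70, 100, 170),
                                target_edge = 10))
  expect_true(all(diff(sw$threshold_kPa) < 0))
})

test_that("length dependence of the threshold weakens toward long vesicles", {
  # with the conical caps pinned, short vesicles are end-stiffened; the
  # dependence must decay monotonically as the ends move apart
  sw <- cached("mini_lsweep",
               sweep_thresholds("length", 83, grid = c(350, 450, 600),
                                target_edge = 8))
  p <- sw$threshold_kPa
  expect_true(all(diff(p) < 0))
  drop1 <- (p[1] - p[2]) / p[1] / 100 # per nm over 350->450
  drop2 <- (p[2] - p[3]) / p[2] / 150 # per nm over 450->600
  expect_lt(drop2, drop1)
})

test_that("surrogate thresholds agree with direct analysis off the grid", {
  fit <- diameter_fit()
  held_out <- c(75, 95, 110, 130, 155)
  direct <- vapply(held_out, function(D) {
    linear_buckling(gv_model(gv_mesh(gv_capsule(D, 500), target_edge = 8)),
                    n_modes = 1)$pressure_kPa[1]
  }, numeric(1))
  pred <- threshold_surrogate(held_out, fit)
  # the direct thresholds are not a smooth function of diameter: the
  # critical mode family switches as D/L changes (a plateau near D ~
  # 95-110 nm), which no smooth power law can follow. The surrogate tracks
  # the trend (typical error a few percent) with ~20% error at the plateau.
  relerr <- abs(pred - direct) / direct
  expect_lt(max(relerr), 0.25)
  expect_lt(median(relerr), 0.05)
  expect_gt(stats::cor(pred, direct), 0.95)
})

test_that("fit tidiers report terms and the one-row summary", {
  x <- c(60, 80, 100, 130, 170, 220)
  fit <- fit_power_law(tibble::tibble(value_nm = x, threshold_kPa = 2e8 * x^-3))
  td <- tidy(fit)
  expect_setequal(td$term, c("A", "alpha", "B"))
  expect_equal(glance(fit)$alpha, fit$alpha)
})
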