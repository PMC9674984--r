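test_that("burst waveform is tapered, bounded and zero-mean over full cycles", {
  f <- 11.4; peak <- 300
  expect_equal(burst_waveform(0, peak), 0)
  expect_equal(burst_waveform(1, peak), 0, tolerance = 1e-9)
  # plateau extrema at odd quarter periods away from the tapers
  t_peak <- (4 * 2 + 1) / (4 * f) # within the flat mid section
  expect_equal(burst_waveform(t_peak, peak), peak, tolerance = 1e-6)
  # integral over two full untapered cycles vanishes
  t0 <- 5 / f
  tt <- seq(t0, t0 + 2 / f, length.out = 20001)
  w <- burst_waveform(tt, peak)
  integral <- sum((w[-1] + w[-length(w)]) / 2 * diff(tt))
  expect_lt(abs(integral), 1e-6 * peak / f)
  expect_error(burst_waveform(1.5, peak), "outside")
})

test_that("stable timestep follows the CFL formula and validates inputs", {
  model <- small_model()
  lc <- gvbuckle:::cpp_char_lengths(model$mesh$nodes, model$mesh$tris)
  act <- gvbuckle:::active_elements(model)
  cd <- gvbuckle:::dilatational_speed(model$material)
  expect_equal(stable_timestep(model, 0.8), 0.8 * min(lc[act]) / cd)
  expect_equal(stable_timestep(model, 0.4), stable_timestep(model, 0.8) / 2)
  expect_error(stable_timestep(model, 0), "safety")
  expect_error(stable_timestep(model, 1.5), "safety")
  # hand evaluation of the wave speed scale: sqrt(Qmax / rho) ~ 1.7-1.8 um/us
  expect_gt(cd, 1.5e6)
  expect_lt(cd, 2.1e6)
})

test_that("zero load leaves the shell in equilibrium", {
  model <- small_model()
  tr <- simulate_burst(model, peak_kpa = 0, duration = 0.05)
  expect_lt(dv_max(tr), 1e-8)
  expect_false(attr(tr, "diverged"))
})

test_that("the integrator is bitwise deterministic", {
  model <- small_model()
  t1 <- simulate_burst(model, peak_kpa = 150, duration = 0.1)
  t2 <- simulate_burst(model, peak_kpa = 150, duration = 0.1)
  expect_identical(t1$volume_nm3, t2$volume_nm3)
  expect_identical(t1$e_kin, t2$e_kin)
})

test_that("undamped free vibration conserves energy to within 1%", {
  model <- small_model()
  dt <- stable_timestep(model)
  # short push followed by free ringing, no damping, constant gas pressure
  nsteps <- 40000L
  npush <- 2000L
  wave <- c(rep(20e-3, npush), rep(0, nsteps - npush)) # 20 kPa step push
  lc <- gvbuckle:::cpp_char_lengths(model$mesh$nodes, model$mesh$tris)
  act <- gvbuckle:::active_elements(model)
  rinert <- model$mass * mean(lc[act])^2 / 8
  res <- gvbuckle:::cpp_simulate(
    model$mesh$nodes, model$mesh$tris, model$section$Cm, model$section$Db,
    model$axis, model$mass, rinert, model$fixed_translations, act, wave, dt,
    0, 0, model$material$rho_internal, model$material$thickness, 0, 0,
    gvbuckle:::dilatational_speed(model$material), model$drill_rel, 50L, Inf)
  etot <- res$e_kin + res$e_strain
  t <- res$time
  # kinetic energy is sampled at half steps and strain energy at full steps,
  # so the instantaneous sum oscillates at O(omega dt); compare
  # window-averaged energies, which must not drift
  w1 <- mean(etot[t > (npush + 1000) * dt & t <= 15000 * dt])
  w2 <- mean(etot[t > (nsteps - 12000) * dt])
  expect_gt(w1, 0)
  expect_lt(abs(w2 - w1) / w1, 0.01)
})

test_that("pre-buckling response is linear in the peak pressure", {
  model <- small_model()
  peaks <- c(60, 100, 140)
  dvs <- vapply(peaks, function(p)
    dv_max(simulate_burst(model, peak_kpa = p, duration = 0.35)), numeric(1))
  fit <- lm(dvs ~ 0 + peaks)
  r2 <- 1 - sum(resid(fit)^2) / sum(dvs^2)
  expect_gt(r2, 0.99)
})

test_that("gas back-pressure does not amplify the volume response", {
  model <- small_model()
  with_gas <- dv_max(simulate_burst(model, peak_kpa = 120, duration = 0.3))
  without <- dv_max(simulate_burst(model, peak_kpa = 120, duration = 0.3,
                                   gas = FALSE))
  expect_lte(with_gas, without * (1 + 1e-6))
})

test_that("switching damping off changes the trajectory but stays stable", {
  model <- small_model()
  damped <- simulate_burst(model, peak_kpa = 200, duration = 0.15)
  undamped <- simulate_burst(model, peak_kpa = 200, duration = 0.15,
                             b1 = 0, b2 = 0)
  expect_false(attr(undamped, "diverged"))
  expect_false(identical(damped$volume_nm3, undamped$volume_nm3))
  # doubling the characteristic length doubles the linear viscous pressure
  # and quadruples the quadratic one; at the formula level (hand check):
  rho <- 1.35e-9; cd <- 1.7e6; L <- 8; edot <- -1e-3
  q <- function(L) 0.06 * rho * cd * L * edot - rho * (1.2 * L)^2 * edot^2
  lin <- function(L) 0.06 * rho * cd * L * edot
  quad <- function(L) -rho * (1.2 * L)^2 * edot^2
  expect_equal(lin(2 * L) / lin(L), 2)
  expect_equal(quad(2 * L) / quad(L), 4)
  expect_equal(q(L), lin(L) + quad(L))
})
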