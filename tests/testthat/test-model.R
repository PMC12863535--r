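test_that("rate constant reduces to k0 when both exponents vanish and matches direct evaluation", {
  cond <- reaction_conditions(16.56, 18000, 120, 40.97)
  expect_equal(rate_constant(1.0, 0, 0, cond), 1.0)
  # frozen hand-calculator evaluation of
  # 60.59 * exp(-0.288 / (8.314 * 393.15)) * exp(0.463 * 16.56)
  expect_equal(rate_constant(60.59, 0.288, 0.463, cond), 129485.1851,
               tolerance = 1e-9)
})

test_that("rate constant is strictly increasing in catalyst concentration and temperature", {
  for (i in 1:20) {
    set.seed(i)
    cond <- draw_conditions()
    cond2 <- cond; cond2$catalyst_conc <- 2 * cond$catalyst_conc
    cond3 <- cond; cond3$temperature_C <- cond$temperature_C + 10
    k0 <- runif(1, 0.1, 10); E <- runif(1, 1e3, 5e4); f <- runif(1, 0.01, 0.5)
    expect_gt(rate_constant(k0, E, f, cond2), rate_constant(k0, E, f, cond))
    expect_gt(rate_constant(k0, E, f, cond3), rate_constant(k0, E, f, cond))
  }
})

test_that("rate constant rejects invalid inputs", {
  cond <- reaction_conditions(5, 100, 120, 50)
  expect_error(rate_constant(NA, 0, 0, cond), "finite")
  expect_error(rate_constant(-1, 0, 0, cond), ">= 0")
  expect_error(reaction_conditions(5, 100, -300, 50), "absolute zero")
})

test_that("sludge decay obeys the t = 0, zero-rate and half-life identities", {
  c0 <- reaction_conditions(16.56, 0, 140, 40.97)
  expect_equal(sludge_decay(c0, 0.01), 40.97)
  ct <- reaction_conditions(16.56, 5000, 140, 40.97)
  expect_equal(sludge_decay(ct, 0), 40.97)
  kf <- log(2) / 5000
  expect_equal(sludge_decay(ct, kf), 40.97 / 2)
})

test_that("protein time course starts at zero, vanishes with zero yield, and is non-negative", {
  p <- plausible_params("acid")
  cond0 <- reaction_conditions(16, 0, 120, 60)
  expect_equal(protein_timecourse(cond0, p), 0)
  p0 <- kinetic_params(7e-4, 2e-4, 0, 2e4, 1e3, 0.14, 0.09)
  cond <- reaction_conditions(16, c(0, 1e3, 1e4, 1.8e4), 120, 60)
  expect_equal(protein_timecourse(cond, p0), rep(0, 4))
  for (i in 1:25) {
    set.seed(100 + i)
    pp <- draw_params(); cc <- draw_conditions()
    expect_gte(protein_timecourse(cc, pp), 0)
  }
})

test_that("protein decays to zero at long times when both rates are positive", {
  p <- plausible_params("acid")
  cond <- reaction_conditions(16, c(1e4, 1e7, 1e9), 120, 60)
  v <- protein_timecourse(cond, p)
  expect_lt(v[3], v[2])
  expect_lt(v[3], 1e-6 * max(v))
})

test_that("confluent limit is continuous across the degeneracy threshold", {
  # parameters tuned so Ks is within a hair of Kf
  tol <- 1e-10
  for (mult in c(1 + 2 * tol, 1 - 2 * tol)) {
    p_near <- kinetic_params(7e-4, 7e-4 * mult, 2.5e4, 0, 0, 0.1, 0.1)
    p_conf <- kinetic_params(7e-4, 7e-4, 2.5e4, 0, 0, 0.1, 0.1)
    cond <- reaction_conditions(10, 3600, 120, 60)
    v_near <- protein_timecourse(cond, p_near)
    v_conf <- protein_timecourse(cond, p_conf)
    expect_equal(v_near, v_conf, tolerance = 1e-6)
  }
})

test_that("as-printed solution form is a single exponential and errors when degenerate", {
  p <- plausible_params("acid")
  cfg <- model_config(solution_form = "as_printed")
  cond0 <- reaction_conditions(16, 0, 120, 60)
  # no P(0) = 0 constraint: nonzero at t = 0
  expect_gt(abs(protein_timecourse(cond0, p, cfg)), 0)
  p_deg <- kinetic_params(7e-4, 7e-4, 2.5e4, 0, 0, 0.1, 0.1)
  expect_error(protein_timecourse(cond0, p_deg, cfg), "degenerate")
})

test_that("ODE right-hand side matches the model structure", {
  p <- plausible_params("acid")
  cond <- reaction_conditions(16, 3600, 120, 60)
  expect_equal(ode_rhs(c(0, 0), cond, p), c(0, 0))
  # no degradation when ks0 = 0: protein derivative is the production term
  p_nodeg <- kinetic_params(7e-4, 0, 2.5e4, 2e4, 0, 0.14, 0)
  d <- ode_rhs(c(50, 1000), cond, p_nodeg)
  expect_gte(d[2], 0)
  # sludge never grows
  for (i in 1:10) {
    set.seed(200 + i)
    d <- ode_rhs(c(runif(1, 0, 95), runif(1, 0, 3e4)), cond, draw_params())
    expect_lte(d[1], 0)
  }
})

test_that("numerical integration reproduces the closed form and its linear regime", {
  p <- plausible_params("acid")
  cond <- reaction_conditions(16, 0, 120, 60)
  expect_equal(integrate_ode(cond, p), 0)
  # first-order Taylor limit: P ~ Kf*K1*Cs0*t when both Kf*t and Ks*t << 1
  p_lin <- kinetic_params(7e-4, 1e-6, 2.5e4, 2e4, 1e3, 0.14, 0)
  k <- rate_constant(7e-4, 2e4, 0.14, cond, model_config())
  t_small <- 1e-3 / k
  cond_small <- reaction_conditions(16, t_small, 120, 60)
  lin <- k * 2.5e4 * 60 * t_small
  expect_equal(integrate_ode(cond_small, p_lin), lin, tolerance = 0.01)
  # closed form vs integrator across random draws
  for (i in 1:10) {
    set.seed(300 + i)
    pp <- draw_params(); cc <- draw_conditions()
    expect_equal(integrate_ode(cc, pp, n_steps = 2000),
                 protein_timecourse(cc, pp), tolerance = 1e-6)
  }
})

test_that("lysed-yield bound caps the protein time course", {
  # protein present never exceeds the cumulative lysed yield K1*Cs0*(1 - exp(-Kf t))
  for (i in 1:30) {
    set.seed(400 + i)
    pp <- draw_params(); cc <- draw_conditions()
    k <- sludgekin:::rate_constants(pp, cc, model_config())
    bound <- unclass(pp)[["K1"]] * cc$sludge_conc * (1 - exp(-k$Kf * cc$time_s))
    expect_lte(protein_timecourse(cc, pp), bound * (1 + 1e-12))
  }
})

test_that("precipitation rate covers the boundary and interior cases", {
  expect_equal(precipitation_rate(100, 0), 100)
  expect_equal(precipitation_rate(100, 100), 0)
  expect_equal(precipitation_rate(200, 50), 75)
  expect_error(precipitation_rate(0, 10), "> 0")
  expect_error(precipitation_rate(100, -1), ">= 0")
})

test_that("exponent clipping keeps extreme draws finite and is counted", {
  clipping_events(reset = TRUE)
  p_extreme <- kinetic_params(1e4, 1e4, 1e6, 0, 0, 10, 10)
  cond <- reaction_conditions(100, 18000, 140, 95)
  v <- protein_timecourse(cond, p_extreme)
  expect_true(is.finite(v))
  expect_gt(clipping_events(), 0)
})
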