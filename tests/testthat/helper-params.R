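# shared fixtures built in code

# parameter draws that keep Kf*t and Ks*t of order 1 over the applicable
# ranges, so both the closed form and the fixed-step integrator are
# well-conditioned
draw_params <- function() {
  kinetic_params(
    kf0 = 10^runif(1, -5, -3),
    ks0 = 10^runif(1, -6, -4),
    K1  = 10^runif(1, 2, 4.5),
    E1  = runif(1, 0, 3e4),
    E2  = runif(1, 0, 3e4),
    f1  = runif(1, 0, 0.2),
    f2  = runif(1, 0, 0.1)
  )
}

draw_conditions <- function(catalyst = "acid") {
  rng <- applicable_ranges(catalyst)
  reaction_conditions(
    runif(1, rng$catalyst_conc[1], rng$catalyst_conc[2]),
    runif(1, 1, rng$time_s[2]),
    runif(1, rng$temperature_C[1], rng$temperature_C[2]),
    runif(1, rng$sludge_conc[1], rng$sludge_conc[2])
  )
}

# small multistart budget for unit tests; acceptance tests use the default
quick_fit_config <- function(n_starts = 40L, seed = 42L, ...) {
  fit_config(n_starts = n_starts, seed = seed, ...)
}

# a 40-point factorial design used by the recovery checks
forty_point_design <- function(noise_scale = 0, seed = 7L,
                               noise_model = "gaussian_additive") {
  synthetic_design(
    temperature_C = c(100, 140),
    time_s = c(1800, 5400, 9000, 12600, 18000),
    catalyst_conc = c(10, 20),
    sludge_conc = c(40, 90),
    noise_model = noise_model,
    noise_scale = noise_scale,
    seed = seed
  )
}
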