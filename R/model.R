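#' Reaction conditions for a sludge hydrolysis run
#'
#' Bundles the four controlled factors of a hydrolysis experiment into a
#' validated data frame, one row per run. Vectors are recycled to a common
#' length the way `data.frame()` recycles them.
#'
#' @param catalyst_conc catalyst mass concentration, g/kg (sulfuric acid or
#'   sodium hydroxide depending on the dataset).
#' @param time_s reaction time, s.
#' @param temperature_C reaction temperature, degrees Celsius. Converted to
#'   Kelvin internally wherever a rate law is evaluated.
#' @param sludge_conc initial sludge (solids) concentration, g/kg; the proxy
#'   for microbial cell concentration.
#' @return A data frame of class `"reaction_conditions"` with the four
#'   columns above.
#' @examples
#' reaction_conditions(16.56, 18000, 140, 40.97)
#' @export
reaction_conditions <- function(catalyst_conc, time_s, temperature_C, sludge_conc) {
  d <- data.frame(
    catalyst_conc = as.numeric(catalyst_conc),
    time_s        = as.numeric(time_s),
    temperature_C = as.numeric(temperature_C),
    sludge_conc   = as.numeric(sludge_conc)
  )
  if (!all(vapply(d, function(x) all(is.finite(x)), logical(1))))
    stop("reaction_conditions: all fields must be finite", call. = FALSE)
  if (any(d$time_s < 0))
    stop("reaction_conditions: time_s must be >= 0", call. = FALSE)
  if (any(d$sludge_conc < 0))
    stop("reaction_conditions: sludge_conc must be >= 0", call. = FALSE)
  if (any(d$catalyst_conc < 0))
    stop("reaction_conditions: catalyst_conc must be >= 0", call. = FALSE)
  if (any(d$temperature_C <= -273.15))
    stop("reaction_conditions: temperature_C must exceed absolute zero", call. = FALSE)
  class(d) <- c("reaction_conditions", "data.frame")
  d
}

#' Kinetic parameter vector of the two-step dissolution model
#'
#' The seven parameters of the lysis/proteolysis model:
#' pre-exponential factors `kf0` (lysis) and `ks0` (proteolysis) in 1/s,
#' yield coefficient `K1` in mg.kg/(g.L) converting lysed sludge mass to
#' released protein concentration, activation energies `E1`, `E2` in J/mol,
#' and catalyst influence coefficients `f1`, `f2` in kg/g that enter the
#' rate constants as `exp(f * C)`.
#'
#' @param kf0,ks0 pre-exponential factors, 1/s.
#' @param K1 yield coefficient, mg.kg/(g.L).
#' @param E1,E2 activation energies, J/mol.
#' @param f1,f2 catalyst influence coefficients, kg/g.
#' @return Named numeric vector of class `"kinetic_params"`.
#' @examples
#' kinetic_params(60.59, 14.37, 220.61, 0.288, 1.533, 0.463, 0.452)
#' @export
kinetic_params <- function(kf0, ks0, K1, E1, E2, f1, f2) {
  p <- c(kf0 = kf0, ks0 = ks0, K1 = K1, E1 = E1, E2 = E2, f1 = f1, f2 = f2)
  p <- as.numeric(p)
  names(p) <- c("kf0", "ks0", "K1", "E1", "E2", "f1", "f2")
  if (length(p) != 7L || !all(is.finite(p)))
    stop("kinetic_params: all seven parameters must be finite scalars", call. = FALSE)
  if (any(p < 0))
    stop("kinetic_params: parameters must be >= 0", call. = FALSE)
  class(p) <- "kinetic_params"
  p
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Kinetic parameters (lysis -> proteolysis):\n")
  print(signif(unclass(x), 4))
  invisible(x)
}

as_kinetic_params <- function(p) {
  do.call(kinetic_params, as.list(unname(unclass(p))[1:7]))
}

#' Model evaluation settings
#'
#' @param solution_form `"full"` (default) uses the series-reaction solution
#'   of the protein balance with P(0) = 0, i.e. the difference of the two
#'   exponentials; `"as_printed"` keeps the single-exponential variant that
#'   drops the second exponential and therefore violates P(0) = 0 — retained
#'   only for comparison.
#' @param gas_constant gas constant, J/(mol.K).
#' @param energy_scale multiplicative factor applied to `E1`, `E2` before the
#'   Arrhenius exponent. `1` reads the activation energies in J/mol as
#'   reported; `1000` probes the kJ/mol reading, since energies of order
#'   1 J/mol make the Arrhenius factor indistinguishable from 1 over
#'   90-140 degrees C.
#' @param degeneracy_tol relative tolerance on `|Ks - Kf|` below which the
#'   confluent (equal-rates) limit formula is used.
#' @param exponent_clip cap on the magnitude of any exponent argument, to
#'   keep extreme optimizer draws finite. Clips are counted; see
#'   [clipping_events()].
#' @return List of class `"model_config"`.
#' @export
model_config <- function(solution_form = c("full", "as_printed"),
                         gas_constant = 8.314,
                         energy_scale = 1,
                         degeneracy_tol = 1e-10,
                         exponent_clip = 700) {
  solution_form <- match.arg(solution_form)
  stopifnot(gas_constant > 0, degeneracy_tol > 0, energy_scale > 0,
            exponent_clip > 0)
  structure(list(solution_form = solution_form,
                 gas_constant = gas_constant,
                 energy_scale = energy_scale,
                 degeneracy_tol = degeneracy_tol,
                 exponent_clip = exponent_clip),
            class = "model_config")
}

# clip exponent arguments and count how often the cap binds
clip_exponent <- function(x, cap) {
  hit <- sum(abs(x) > cap)
  if (hit > 0L) .sk_env$clip_events <- .sk_env$clip_events + as.integer(hit)
  pmin(pmax(x, -cap), cap)
}

#' Arrhenius rate constant with catalyst-concentration modifier
#'
#' `k = k0 * exp(-E * energy_scale / (R * T_K)) * exp(f * C)`, with the
#' temperature taken from `conditions` and converted to Kelvin, and the
#' catalyst concentration `C` in g/kg. The total exponent (including
#' `log(k0)`) is clipped at `+/- exponent_clip`, so the result is always
#' finite.
#'
#' @param k0 pre-exponential factor, 1/s.
#' @param E activation energy, J/mol (scaled by `config$energy_scale`).
#' @param f catalyst influence coefficient, kg/g.
#' @param conditions a [reaction_conditions()] data frame.
#' @param config a [model_config()].
#' @return Numeric vector of rate constants, 1/s, one per condition row.
#' @examples
#' cond <- reaction_conditions(16.56, 18000, 120, 40.97)
#' rate_constant(60.59, 0.288, 0.463, cond)
#' @export
rate_constant <- function(k0, E, f, conditions, config = model_config()) {
  if (!all(is.finite(c(k0, E, f))))
    stop("rate_constant: k0, E, f must be finite", call. = FALSE)
  if (k0 < 0 || E < 0)
    stop("rate_constant: k0 and E must be >= 0", call. = FALSE)
  T_K <- conditions$temperature_C + 273.15
  if (any(T_K <= 0))
    stop("rate_constant: absolute temperature must be positive", call. = FALSE)
  safe_rate(k0, E, f, conditions, config)
}

# k0 * exp(-E*scale/(R*T)) * exp(f*C) with the total exponent (including
# log k0) clipped at +/- exponent_clip, so the result is always finite;
# k0 = 0 stays exactly 0
safe_rate <- function(k0, E, f, conditions, config) {
  if (k0 == 0) return(rep(0, nrow(conditions)))
  T_K <- conditions$temperature_C + 273.15
  total <- log(k0) -
    E * config$energy_scale / (config$gas_constant * T_K) +
    f * conditions$catalyst_conc
  exp(clip_exponent(total, config$exponent_clip))
}

# both rate constants for a parameter vector, vectorized over condition rows
rate_constants <- function(params, conditions, config = model_config()) {
  p <- unclass(params)
  list(
    Kf = rate_constant(p[["kf0"]], p[["E1"]], p[["f1"]], conditions, config),
    Ks = rate_constant(p[["ks0"]], p[["E2"]], p[["f2"]], conditions, config)
  )
}

#' Exponential sludge decay
#'
#' First-order disappearance of sludge solids under lysis:
#' `Cs(t) = Cs0 * exp(-Kf * t)`.
#'
#' @param conditions a [reaction_conditions()] data frame; `time_s` and
#'   `sludge_conc` are used.
#' @param kf lysis rate constant, 1/s (scalar or one per row).
#' @return Sludge concentration at `time_s`, g/kg.
#' @export
sludge_decay <- function(conditions, kf) {
  if (any(kf < 0)) stop("sludge_decay: kf must be >= 0", call. = FALSE)
  if (any(conditions$time_s < 0))
    stop("sludge_decay: time must be >= 0", call. = FALSE)
  conditions$sludge_conc * exp(-kf * conditions$time_s)
}

#' Closed-form protein time course
#'
#' Supernatant protein concentration predicted by the two-step model. With
#' `solution_form = "full"` this is the series-reaction solution of
#' `dP/dt = Kf*K1*Cs0*exp(-Kf*t) - Ks*P` with `P(0) = 0`:
#' \deqn{P(t) = \frac{K_f K_1 C_{S,0}}{K_s - K_f}\left(e^{-K_f t} - e^{-K_s t}\right),}
#' switching to the confluent limit `Kf*K1*Cs0*t*exp(-Kf*t)` when `Ks` and
#' `Kf` agree to within `degeneracy_tol` (relative). With
#' `solution_form = "as_printed"` the second exponential is dropped, which
#' breaks the `P(0) = 0` initial condition; that variant errors when
#' `Ks == Kf` exactly.
#'
#' @inheritParams rate_constant
#' @param params a [kinetic_params()] vector.
#' @return Predicted protein concentration, mg/L, one value per condition row.
#' @examples
#' p <- kinetic_params(7e-4, 2e-4, 2.5e4, 2e4, 1e3, 0.14, 0.09)
#' cond <- reaction_conditions(16.56, c(0, 3600, 18000), 120, 40.97)
#' protein_timecourse(cond, p)
#' @export
protein_timecourse <- function(conditions, params, config = model_config()) {
  k <- rate_constants(params, conditions, config)
  Kf <- k$Kf; Ks <- k$Ks
  K1 <- unclass(params)[["K1"]]
  Cs0 <- conditions$sludge_conc
  t <- conditions$time_s
  if (config$solution_form == "as_printed") {
    if (any(Ks == Kf))
      stop("protein_timecourse: degenerate parameters (Ks == Kf) in the ",
           "single-exponential form", call. = FALSE)
    return(Kf * K1 * Cs0 / (Ks - Kf) * exp(-Kf * t))
  }
  series_solution(Kf, Ks, K1, Cs0, t, config$degeneracy_tol)
}

# series-reaction solution with P(0) = 0, guarded against the 0 * Inf
# indeterminates that extreme (clipped) rate constants can produce
series_solution <- function(Kf, Ks, K1, Cs0, t, degeneracy_tol) {
  n <- length(t)
  Kf <- rep_len(Kf, n); Ks <- rep_len(Ks, n)
  Cs0 <- rep_len(Cs0, n)
  scale <- pmax(Ks, Kf)
  degen <- scale == 0 | abs(Ks - Kf) < degeneracy_tol * scale
  out <- numeric(n)
  if (any(!degen)) {
    i <- which(!degen)
    diff_exp <- exp(-Kf[i] * t[i]) - exp(-Ks[i] * t[i])
    v <- Kf[i] * K1 * Cs0[i] / (Ks[i] - Kf[i]) * diff_exp
    v[diff_exp == 0] <- 0  # t = 0, or both exponentials underflowed
    out[i] <- v
  }
  if (any(degen)) {
    i <- which(degen)
    x <- Kf[i] * t[i]
    xe <- x * exp(-x)
    xe[!is.finite(xe) | x > 700] <- 0  # x e^{-x} underflows past ~700
    out[i] <- K1 * Cs0[i] * xe
  }
  # exact-arithmetic result is >= 0; snap away roundoff-level negatives
  pmax(out, 0)
}

#' Right-hand side of the lysis/proteolysis ODE system
#'
#' `d(Cs)/dt = -Kf * Cs`; `dP/dt = Kf * K1 * Cs - Ks * P`. Intended for a
#' single condition row (the rate constants are evaluated at that row's
#' temperature and catalyst concentration).
#'
#' @param state numeric vector `c(sludge_conc, protein_conc)` in (g/kg, mg/L).
#' @inheritParams protein_timecourse
#' @return Numeric vector `c(d_sludge_dt, d_protein_dt)`.
#' @export
ode_rhs <- function(state, conditions, params, config = model_config()) {
  if (nrow(conditions) != 1L)
    stop("ode_rhs: conditions must be a single row", call. = FALSE)
  if (length(state) != 2L || !all(is.finite(state)))
    stop("ode_rhs: state must be two finite values", call. = FALSE)
  if (any(state < 0))
    stop("ode_rhs: state components must be >= 0", call. = FALSE)
  k <- rate_constants(params, conditions, config)
  K1 <- unclass(params)[["K1"]]
  c(-k$Kf * state[1], k$Kf * K1 * state[1] - k$Ks * state[2])
}

#' Numerical integration of the protein balance
#'
#' Integrates [ode_rhs()] from 0 to each row's `time_s` with a fixed-step
#' fourth-order Runge-Kutta scheme (via \pkg{deSolve}), starting from
#' `(Cs0, 0)`. Serves as the independent numerical oracle for
#' [protein_timecourse()]: the two agree to the scheme's truncation error,
#' which shrinks as `n_steps` grows.
#'
#' @inheritParams protein_timecourse
#' @param n_steps number of integration steps (>= 1).
#' @return Protein concentration at `time_s`, mg/L, one value per row.
#' @export
integrate_ode <- function(conditions, params, config = model_config(),
                          n_steps = 4000L) {
  n_steps <- as.integer(n_steps)
  if (n_steps < 1L) stop("integrate_ode: n_steps must be >= 1", call. = FALSE)
  k <- rate_constants(params, conditions, config)
  K1 <- unclass(params)[["K1"]]
  vapply(seq_len(nrow(conditions)), function(i) {
    t_end <- conditions$time_s[i]
    if (t_end == 0) return(0)
    h <- t_end / n_steps
    if (h <= 0 || !is.finite(h) || t_end / h > 1e9)
      stop("integrate_ode: step size underflow", call. = FALSE)
    Kf <- k$Kf[i]; Ks <- k$Ks[i]
    times <- seq(0, t_end, length.out = n_steps + 1L)
    sol <- deSolve::rk4(
      y = c(Cs = conditions$sludge_conc[i], P = 0),
      times = times,
      func = function(t, y, parms) list(c(-Kf * y[1], Kf * K1 * y[1] - Ks * y[2])),
      parms = NULL
    )
    unname(sol[nrow(sol), "P"])
  }, numeric(1))
}

#' Protein precipitation rate
#'
#' Percentage of dissolved protein removed by a precipitation step:
#' `(c_before - c_after) / c_before * 100`.
#'
#' @param c_before protein concentration before precipitation, mg/L (> 0).
#' @param c_after protein concentration after precipitation, mg/L (>= 0).
#' @return Precipitation rate in percent.
#' @examples
#' precipitation_rate(200, 50)  # 75
#' @export
precipitation_rate <- function(c_before, c_after) {
  if (any(!is.finite(c_before)) || any(!is.finite(c_after)))
    stop("precipitation_rate: inputs must be finite", call. = FALSE)
  if (any(c_before <= 0))
    stop("precipitation_rate: c_before must be > 0", call. = FALSE)
  if (any(c_after < 0))
    stop("precipitation_rate: c_after must be >= 0", call. = FALSE)
  (c_before - c_after) / c_before * 100
}
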