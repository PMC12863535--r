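#' Default parameter bounds for estimation
#'
#' Closed box constraints for the seven parameters: all lower bounds 0;
#' upper bounds 1e4 1/s for the pre-exponential factors, 1e6 mg.kg/(g.L) for
#' the yield, 1e5 J/mol for the activation energies and 10 kg/g for the
#' catalyst coefficients.
#'
#' @return A 2 x 7 matrix with rows `lower`, `upper`.
#' @export
default_bounds <- function() {
  b <- rbind(lower = rep(0, 7),
             upper = c(1e4, 1e4, 1e6, 1e5, 1e5, 10, 10))
  colnames(b) <- c("kf0", "ks0", "K1", "E1", "E2", "f1", "f2")
  b
}

#' Multistart optimizer settings
#'
#' Controls the seeded multistart Levenberg-Marquardt fit. Starts are drawn
#' log-uniformly over the bounds (lower bounds clamped to 1e-8 for the log
#' draw), and each local solve runs on the log-parameter scale, which
#' conditions this many-decade, all-non-negative parameter space well.
#' After all starts have been run, the best `n_polish` local optima
#' are refined by restarting the local solver from the converged point up to
#' `max_polish_restarts` times (a restart resets the trust region, which
#' often buys further digits on this ill-conditioned surface).
#'
#' @param bounds 2 x 7 matrix as from [default_bounds()].
#' @param n_starts number of multistart draws.
#' @param seed integer seed controlling the start draws.
#' @param convergence_tol relative SSE / parameter tolerance passed to the
#'   local solver (`ftol`, `ptol`).
#' @param max_iter maximum iterations per local solve (the LM backend caps
#'   this at 1024).
#' @param n_polish number of best starts to polish.
#' @param max_polish_restarts maximum solver restarts during polish.
#' @return List of class `"fit_config"`.
#' @export
fit_config <- function(bounds = default_bounds(),
                       n_starts = 200L,
                       seed = 42L,
                       convergence_tol = 1e-12,
                       max_iter = 1024L,
                       n_polish = 10L,
                       max_polish_restarts = 4L) {
  stopifnot(is.matrix(bounds), nrow(bounds) == 2, ncol(bounds) == 7,
            all(bounds["lower", ] <= bounds["upper", ]),
            n_starts >= 1, convergence_tol > 0, max_iter >= 1,
            n_polish >= 0, max_polish_restarts >= 0)
  structure(list(bounds = bounds, n_starts = as.integer(n_starts),
                 seed = as.integer(seed), convergence_tol = convergence_tol,
                 max_iter = as.integer(min(max_iter, 1024L)),
                 n_polish = as.integer(n_polish),
                 max_polish_restarts = as.integer(max_polish_restarts)),
            class = "fit_config")
}

# model predictions for a raw parameter vector (no constructor validation:
# the optimizer explores the whole box, including zeros)
predict_raw <- function(p, conditions, config) {
  Kf <- safe_rate(p[1], p[4], p[6], conditions, config)
  Ks <- safe_rate(p[2], p[5], p[7], conditions, config)
  Cs0 <- conditions$sludge_conc; t <- conditions$time_s
  if (config$solution_form == "as_printed") {
    return(Kf * p[3] * Cs0 / (Ks - Kf) * exp(-Kf * t))
  }
  series_solution(Kf, Ks, p[3], Cs0, t, config$degeneracy_tol)
}

#' Model predictions for a dataset
#'
#' @param params a [kinetic_params()] vector (or bare numeric length-7
#'   vector in the order kf0, ks0, K1, E1, E2, f1, f2).
#' @param dataset a `protein_dataset`.
#' @param config a [model_config()].
#' @return Predicted protein concentrations, mg/L.
#' @export
predict_dataset <- function(params, dataset, config = model_config()) {
  predict_raw(as.numeric(unclass(params)), dataset_conditions(dataset), config)
}

#' Residual sum of squares of the model on a dataset
#'
#' Unweighted SSE in (mg/L)^2: `sum((predicted - measured)^2)`. Parameter
#' draws whose predictions are non-finite even after exponent clipping
#' receive `+Inf` (the multistart layer logs and discards them) rather than
#' raising an error.
#'
#' @inheritParams predict_dataset
#' @return Scalar SSE, (mg/L)^2.
#' @export
objective_sse <- function(params, dataset, config = model_config()) {
  pred <- predict_dataset(params, dataset, config)
  if (any(!is.finite(pred))) return(Inf)
  sum((pred - dataset$data$protein_mg_L)^2)
}

#' Coefficient of determination of the model on a dataset
#'
#' `R^2 = 1 - SSE / SST`, with SST the total sum of squares of the measured
#' protein about its mean. Can be negative for a model worse than the mean;
#' never exceeds 1.
#'
#' @inheritParams predict_dataset
#' @return Scalar R-squared.
#' @export
r_squared <- function(params, dataset, config = model_config()) {
  y <- dataset$data$protein_mg_L
  if (length(y) < 2 || all(y == y[1]))
    stop("r_squared: undefined for constant measurements", call. = FALSE)
  1 - objective_sse(params, dataset, config) / sum((y - mean(y))^2)
}

draw_starts <- function(cfg) {
  lo <- pmax(cfg$bounds["lower", ], 1e-8)
  hi <- cfg$bounds["upper", ]
  m <- matrix(NA_real_, cfg$n_starts, 7,
              dimnames = list(NULL, colnames(cfg$bounds)))
  for (i in seq_len(cfg$n_starts))
    m[i, ] <- exp(runif(7, log(lo), log(hi)))
  m
}

# One bounded Levenberg-Marquardt solve. The free parameters are optimized
# on the log scale (all seven are non-negative and span many decades, so the
# log parameterization conditions the problem far better); lower bounds are
# clamped to 1e-8 for the transform, the same clamp used for the log-uniform
# start draws. nls.lm rejects lower == upper, so pinned parameters are held
# out of the optimization and spliced back on every evaluation.
local_solve <- function(p0, conditions, y, cfg, model_cfg, counter) {
  lower <- cfg$bounds["lower", ]; upper <- cfg$bounds["upper", ]
  free <- which(lower < upper)
  if (length(free) == 0L)
    return(list(par = p0, info = 1L))
  llb <- log(pmax(lower[free], 1e-8))
  lub <- log(upper[free])
  full <- p0
  fn <- function(theta) {
    counter$n <- counter$n + 1L
    full[free] <- exp(theta)
    r <- predict_raw(full, conditions, model_cfg) - y
    r[!is.finite(r)] <- 1e8
    r
  }
  f <- tryCatch(
    minpack.lm::nls.lm(
      par = pmin(pmax(log(pmax(p0[free], 1e-8)), llb), lub),
      lower = llb, upper = lub,
      fn = fn,
      control = minpack.lm::nls.lm.control(
        maxiter = cfg$max_iter,
        ftol = cfg$convergence_tol, ptol = cfg$convergence_tol)),
    error = function(e) NULL)
  if (is.null(f)) return(NULL)
  full[free] <- exp(f$par)
  list(par = full, info = f$info)
}

#' Fit the seven-parameter dissolution model to a dataset
#'
#' Seeded multistart bounded Levenberg-Marquardt least squares: `n_starts`
#' log-uniform draws over the bounds, a local LM solve from each, then
#' deterministic polish (solver restarts) of the best `n_polish` local
#' optima. The returned fit is the minimum-SSE result; the whole procedure
#' is deterministic for a fixed `(seed, config, dataset)`.
#'
#' @param dataset a `protein_dataset`.
#' @param config a [fit_config()].
#' @param model_config a [model_config()].
#' @return Object of class `"kinetic_fit"`: `params` ([kinetic_params()]),
#'   `sse`, `r_squared`, `fitted`, `residuals` (predicted - measured),
#'   `n_starts`, `seed`, `best_start_index`, `converged`,
#'   `n_function_evals`, `starts` (the start matrix), `start_sse`
#'   (per-start local-optimum SSE), `n_failed_starts`, plus the two configs.
#' @examples
#' \donttest{
#' fit <- fit_kinetics(load_acid_dataset(), fit_config(n_starts = 50))
#' fit$sse; fit$r_squared
#' }
#' @export
fit_kinetics <- function(dataset, config = fit_config(),
                         model_config = sludgekin::model_config()) {
  stopifnot(inherits(dataset, "protein_dataset"),
            inherits(config, "fit_config"))
  conditions <- dataset_conditions(dataset)
  y <- dataset$data$protein_mg_L
  counter <- new.env(parent = emptyenv()); counter$n <- 0L

  set.seed(config$seed)
  starts <- draw_starts(config)

  sols <- vector("list", config$n_starts)
  sse <- rep(Inf, config$n_starts)
  conv <- logical(config$n_starts)
  for (i in seq_len(config$n_starts)) {
    f <- local_solve(starts[i, ], conditions, y, config, model_config, counter)
    if (is.null(f)) next
    s <- objective_sse(f$par, dataset, model_config)
    if (!is.finite(s)) next
    sols[[i]] <- f$par
    sse[i] <- s
    conv[i] <- f$info %in% 1:4
  }
  if (all(!is.finite(sse)))
    stop("fit_kinetics: every start failed to produce a finite fit; ",
         sum(vapply(sols, is.null, logical(1))), " solver failures out of ",
         config$n_starts, " starts", call. = FALSE)

  # polish: restart the solver from the best local optima until it stalls
  for (i in order(sse)[seq_len(min(config$n_polish, config$n_starts))]) {
    if (!is.finite(sse[i])) next
    p <- sols[[i]]
    for (r in seq_len(config$max_polish_restarts)) {
      f <- local_solve(p, conditions, y, config, model_config, counter)
      if (is.null(f)) break
      s <- objective_sse(f$par, dataset, model_config)
      if (is.finite(s) && s < sse[i] * (1 - 1e-10)) {
        sse[i] <- s; p <- f$par; conv[i] <- f$info %in% 1:4
      } else {
        # a restart that cannot improve the SSE is stationarity evidence
        conv[i] <- TRUE
        break
      }
    }
    sols[[i]] <- p
  }

  best <- which.min(sse)
  p_best <- sols[[best]]
  fitted <- predict_raw(p_best, conditions, model_config)
  res <- fitted - y
  structure(list(
    params = as_kinetic_params(setNames(p_best, colnames(starts))),
    sse = sum(res^2),
    r_squared = 1 - sum(res^2) / sum((y - mean(y))^2),
    fitted = fitted,
    residuals = res,
    n_starts = config$n_starts,
    seed = config$seed,
    best_start_index = best,
    converged = conv[best],
    n_function_evals = counter$n,
    n_failed_starts = sum(!is.finite(sse)),
    starts = starts,
    start_sse = sse,
    catalyst = dataset$catalyst,
    fit_config = config,
    model_config = model_config
  ), class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("Kinetic model fit (%s catalysis, %s form)\n",
              x$catalyst, x$model_config$solution_form))
  cat(sprintf("  SSE = %.4g (mg/L)^2, R^2 = %.4f\n", x$sse, x$r_squared))
  cat(sprintf("  %d starts (seed %d), best start %d, %s, %d model evals\n",
              x$n_starts, x$seed, x$best_start_index,
              if (x$converged) "converged" else "not converged",
              x$n_function_evals))
  print(x$params)
  invisible(x)
}

#' Refit under alternative model readings
#'
#' Runs [fit_kinetics()] for every combination of solution form and energy
#' scale requested. The published account leaves both ambiguous (the printed
#' closed form drops one exponential, and activation energies of order
#' 1 J/mol are indistinguishable from zero over 90-140 degrees C if read
#' literally), so the sweep records which reading the data prefer.
#'
#' @param dataset a `protein_dataset`.
#' @param solution_forms character vector of solution forms to try.
#' @param energy_scales numeric vector of energy scales to try.
#' @param config a [fit_config()].
#' @return Object of class `"fit_sweep"`: `summary` (data frame of variant,
#'   SSE, R^2), `fits` (list of `kinetic_fit`), `best` (index of the
#'   minimum-SSE variant).
#' @export
fit_variant_sweep <- function(dataset,
                              solution_forms = c("full", "as_printed"),
                              energy_scales = c(1, 1000),
                              config = fit_config()) {
  grid <- expand.grid(solution_form = solution_forms,
                      energy_scale = energy_scales,
                      stringsAsFactors = FALSE)
  fits <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    mc <- model_config(solution_form = grid$solution_form[i],
                       energy_scale = grid$energy_scale[i])
    fits[[i]] <- fit_kinetics(dataset, config, mc)
  }
  summary <- data.frame(
    solution_form = grid$solution_form,
    energy_scale = grid$energy_scale,
    sse = vapply(fits, `[[`, numeric(1), "sse"),
    r_squared = vapply(fits, `[[`, numeric(1), "r_squared")
  )
  structure(list(summary = summary, fits = fits,
                 best = which.min(summary$sse)),
            class = "fit_sweep")
}

#' @export
print.fit_sweep <- function(x, ...) {
  cat("Model-reading sweep:\n")
  s <- x$summary
  s$best <- ifelse(seq_len(nrow(s)) == x$best, "*", "")
  print(s, row.names = FALSE)
  invisible(x)
}

#' Compare acid and alkali catalysis through the fitted rate laws
#'
#' Evaluates both fits' lysis (`Kf`) and proteolysis (`Ks`) rate constants
#' at a shared reference condition and reports acid/alkali ratios together
#' with the catalyst-coefficient differences. Note the two catalysts operate
#' at very different concentrations, so ratios at a shared `C` and the `f`
#' coefficients carry the substantive comparison.
#'
#' @param acid_fit,alkali_fit `kinetic_fit` objects.
#' @param conditions single-row [reaction_conditions()] at which to evaluate
#'   the rate constants.
#' @return Object of class `"catalyst_comparison"`.
#' @export
compare_catalysts <- function(acid_fit, alkali_fit, conditions) {
  stopifnot(inherits(acid_fit, "kinetic_fit"),
            inherits(alkali_fit, "kinetic_fit"),
            nrow(conditions) == 1L)
  ka <- rate_constants(acid_fit$params, conditions, acid_fit$model_config)
  kb <- rate_constants(alkali_fit$params, conditions, alkali_fit$model_config)
  pa <- unclass(acid_fit$params); pb <- unclass(alkali_fit$params)
  structure(list(
    conditions = conditions,
    Kf_acid = ka$Kf, Kf_alkali = kb$Kf,
    Ks_acid = ka$Ks, Ks_alkali = kb$Ks,
    Kf_ratio = ka$Kf / kb$Kf,
    Ks_ratio = ka$Ks / kb$Ks,
    f1_delta = pa[["f1"]] - pb[["f1"]],
    f2_delta = pa[["f2"]] - pb[["f2"]],
    lysis_dominant = ifelse(pa[["f1"]] > pb[["f1"]], "acid", "alkali"),
    proteolysis_dominant = ifelse(pa[["f2"]] > pb[["f2"]], "acid", "alkali")
  ), class = "catalyst_comparison")
}

#' @export
print.catalyst_comparison <- function(x, ...) {
  cat("Catalyst comparison at shared conditions:\n")
  cat(sprintf("  Kf: acid %.4g vs alkali %.4g 1/s (ratio %.3g)\n",
              x$Kf_acid, x$Kf_alkali, x$Kf_ratio))
  cat(sprintf("  Ks: acid %.4g vs alkali %.4g 1/s (ratio %.3g)\n",
              x$Ks_acid, x$Ks_alkali, x$Ks_ratio))
  cat(sprintf("  f1 delta (acid - alkali): %.4g kg/g -> %s-dominant lysis\n",
              x$f1_delta, x$lysis_dominant))
  cat(sprintf("  f2 delta (acid - alkali): %.4g kg/g -> %s-dominant proteolysis\n",
              x$f2_delta, x$proteolysis_dominant))
  invisible(x)
}
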