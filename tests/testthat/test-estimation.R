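test_that("objective SSE matches hand-summed values and scales quadratically", {
  acid <- load_acid_dataset()
  # K1 = 0 predicts 0 everywhere, so the SSE is the sum of squared
  # measurements, summed independently from the printed column
  p0 <- kinetic_params(1, 1, 0, 0, 0, 0, 0)
  expect_equal(objective_sse(p0, acid), 6601325013.4407, tolerance = 1e-12)
  expect_equal(objective_sse(p0, load_alkali_dataset()), 4687557922.22744,
               tolerance = 1e-12)

  # a one-row dataset whose prediction is forced onto the measurement
  p <- plausible_params("acid")
  cond <- reaction_conditions(16, 3600, 120, 60)
  mu <- protein_timecourse(cond, p)
  one <- sludgekin:::new_dataset(
    data.frame(catalyst_conc = 16, time_s = 3600, temperature_C = 120,
               sludge_conc = 60, protein_mg_L = mu), "acid")
  expect_equal(objective_sse(p, one), 0)

  # doubling every residual quadruples the SSE: compare y and 2*mu - y
  acid2 <- acid
  mu_a <- predict_dataset(p, acid)
  acid2$data$protein_mg_L <- pmax(2 * acid2$data$protein_mg_L - mu_a, 0)
  # restrict to rows where the clamp did not bind
  keep <- 2 * acid$data$protein_mg_L - mu_a >= 0
  a1 <- sludgekin:::new_dataset(acid$data[keep, ], "acid")
  a2 <- sludgekin:::new_dataset(acid2$data[keep, ], "acid")
  expect_equal(objective_sse(p, a2), 4 * objective_sse(p, a1))
})

test_that("R-squared is 1 for perfect predictions, 0 for the mean, and uses 1 - SSE/SST", {
  acid <- load_acid_dataset()
  y <- acid$data$protein_mg_L
  p <- plausible_params("acid")
  mu <- predict_dataset(p, acid)
  perfect <- sludgekin:::new_dataset(
    transform(acid$data, protein_mg_L = mu), "acid")
  expect_equal(r_squared(p, perfect), 1)
  SST <- sum((y - mean(y))^2)
  expect_equal(r_squared(p, acid), 1 - objective_sse(p, acid) / SST)
  const <- sludgekin:::new_dataset(
    transform(acid$data, protein_mg_L = 100), "acid")
  expect_error(r_squared(p, const), "constant")
})

test_that("multistart fit is deterministic and never worse than any start", {
  acid <- load_acid_dataset()
  cfg <- quick_fit_config(n_starts = 30)
  f1 <- fit_kinetics(acid, cfg)
  f2 <- fit_kinetics(acid, cfg)
  expect_identical(unclass(f1$params), unclass(f2$params))
  expect_identical(f1$sse, f2$sse)
  expect_identical(f1$start_sse, f2$start_sse)
  # reported SSE equals the objective at the returned parameters
  expect_equal(f1$sse, objective_sse(f1$params, acid), tolerance = 1e-15)
  # monotone improvement over every multistart initial point
  start_obj <- apply(f1$starts, 1, function(p)
    objective_sse(sludgekin:::as_kinetic_params(p), acid))
  expect_true(all(f1$sse <= start_obj + 1e-9))
  # provenance fields populated
  expect_identical(f1$seed, 42L)
  expect_identical(f1$n_starts, 30L)
  expect_gt(f1$n_function_evals, 0)
})

test_that("restricted two-parameter fit agrees with a dense grid search", {
  # pin all but kf0 and K1; fit a small noise-free synthetic dataset and
  # compare the LM minimum against brute-force enumeration over the box
  true <- plausible_params("acid")
  des <- synthetic_design(temperature_C = 120, time_s = c(1800, 5400, 9000, 12600, 18000),
                          catalyst_conc = 14.5, sludge_conc = 65,
                          noise_scale = 500, seed = 11)
  ds <- generate_dataset(des, true)
  pt <- unclass(true)
  bounds <- default_bounds()
  bounds["lower", ] <- c(1e-6, pt[["ks0"]], 1e2, pt[["E1"]], pt[["E2"]],
                         pt[["f1"]], pt[["f2"]])
  bounds["upper", ] <- c(1e-2, pt[["ks0"]], 1e6, pt[["E1"]], pt[["E2"]],
                         pt[["f1"]], pt[["f2"]])
  fit <- fit_kinetics(ds, fit_config(bounds = bounds, n_starts = 60))

  kf0_grid <- exp(seq(log(1e-6), log(1e-2), length.out = 200))
  K1_grid <- exp(seq(log(1e2), log(1e6), length.out = 200))
  sse_grid <- outer(kf0_grid, K1_grid, Vectorize(function(kf0, K1) {
    objective_sse(kinetic_params(kf0, pt[["ks0"]], K1, pt[["E1"]],
                                 pt[["E2"]], pt[["f1"]], pt[["f2"]]), ds)
  }))
  best <- arrayInd(which.min(sse_grid), dim(sse_grid))
  # enumeration cannot beat the multistart LM optimum
  expect_lte(fit$sse, min(sse_grid) * (1 + 1e-9))
  # the kf0 x K1 objective has a shallow curved valley along which the
  # lattice argmin can slide a few cells, but the identifiable combination
  # kf0 * K1 must agree to grid resolution
  step_kf0 <- diff(log(kf0_grid))[1]
  step_K1 <- diff(log(K1_grid))[1]
  p <- unclass(fit$params)
  expect_lt(abs(log(p[["kf0"]] * p[["K1"]]) -
                  log(kf0_grid[best[1]] * K1_grid[best[2]])),
            step_kf0 + step_K1)
})

test_that("noise-free synthetic data is fit essentially exactly", {
  true <- plausible_params("acid")
  des <- synthetic_design(noise_scale = 0, seed = 3)
  ds <- generate_dataset(des, true)
  fit <- fit_kinetics(ds, fit_config(n_starts = 200))
  y2 <- sum(ds$data$protein_mg_L^2)
  expect_lt(fit$sse / y2, 1e-8)
})

test_that("catalyst comparison reports ratios and dominance flags", {
  acid <- load_acid_dataset(); alk <- load_alkali_dataset()
  cfg <- quick_fit_config(n_starts = 40)
  fa <- fit_kinetics(acid, cfg)
  fb <- fit_kinetics(alk, cfg)
  cond <- reaction_conditions(3, 10800, 120, 65)
  cmp <- compare_catalysts(fa, fb, cond)
  expect_equal(cmp$Kf_ratio, cmp$Kf_acid / cmp$Kf_alkali)
  expect_equal(cmp$Ks_ratio, cmp$Ks_acid / cmp$Ks_alkali)
  expect_true(cmp$lysis_dominant %in% c("acid", "alkali"))
  # identical fits give unit ratios and zero deltas; use a fit recovered
  # from noise-free synthetic data so both rate constants are nonzero
  fs <- fit_kinetics(
    generate_dataset(synthetic_design(noise_scale = 0, seed = 6),
                     plausible_params("acid")),
    quick_fit_config(n_starts = 60))
  same <- compare_catalysts(fs, fs, cond)
  expect_equal(same$Kf_ratio, 1)
  expect_equal(same$Ks_ratio, 1)
  expect_equal(same$f1_delta, 0)
  # with the published parameter vectors the acid coefficients dominate
  pa <- unclass(published_params("acid"))
  pb <- unclass(published_params("alkali"))
  expect_gt(pa[["f1"]], pb[["f1"]])
  expect_gt(pa[["f2"]], pb[["f2"]])
})

test_that("fit workflow writes reproducible report files", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  cfg <- quick_fit_config(n_starts = 25)
  f1 <- run_fit_workflow("acid", dir1, cfg)
  f2 <- run_fit_workflow("acid", dir2, cfg)
  for (f in c("fit_report.json", "fit_report.txt", "residuals.csv")) {
    expect_true(file.exists(file.path(dir1, f)))
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
  }
  rep <- jsonlite::read_json(file.path(dir1, "fit_report.json"),
                             simplifyVector = TRUE)
  expect_equal(rep$sse, f1$sse)
  expect_equal(rep$seed, 42)
  expect_named(rep$params, c("kf0", "ks0", "K1", "E1", "E2", "f1", "f2"))
  # range-filtered variant drops the out-of-range acid rows
  f3 <- run_fit_workflow("acid", withr::local_tempdir(), cfg,
                         range_filter = TRUE)
  expect_equal(length(f3$residuals), 18)
})

test_that("prediction workflow honours the solution form and the t = 0 identity", {
  p <- plausible_params("acid")
  cond <- reaction_conditions(16, c(0, 9000, 18000), 120, 60)
  out <- run_predict_workflow(p, cond)
  expect_equal(out$predicted[1], 0)
  expect_equal(out$predicted, protein_timecourse(cond, p))
  out2 <- run_predict_workflow(p, cond,
                               config = model_config("as_printed"))
  expect_false(isTRUE(all.equal(out$predicted, out2$predicted)))
})
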