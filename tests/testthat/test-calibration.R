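test_that("the objective is mean absolute error plus ensemble spread", {
  # a delta-distribution limit: uniform-gene circuits always score 0, so the
  # objective reduces to |0 - d1| + 0 + |0 - d2| + 0
  data0 <- calibration_data(d1 = 0.4, d2 = 0.7,
                            genes1 = rep("GFP", 4), genes2 = rep("mCherry", 4))
  E <- blade_objective(blade_params(), data0, ensemble_size = 3, seed = 9,
                       config = quick_ssa(500))
  expect_equal(E, 0.4 + 0.7)

  # invariance to the ensemble seed stream only through mean/sd; exact
  # reproducibility under the same seed
  E2 <- blade_objective(blade_params(), data0, ensemble_size = 3, seed = 9,
                        config = quick_ssa(500))
  expect_identical(E, E2)

  # invalid parameter draws yield the sentinel, not an exception
  bad <- blade_params()
  bad$alpha <- -1
  expect_equal(blade_objective(bad, calibration_data(), ensemble_size = 2), 1e6)
})

test_that("the objective at the calibrated optimum beats random parameter draws", {
  E_opt <- blade_objective(blade_params(), ensemble_size = 5, seed = 31,
                           config = quick_ssa())
  set.seed(88)
  E_rand <- vapply(1:8, function(i) {
    blade_objective(random_params(), ensemble_size = 3, seed = 31,
                    config = quick_ssa(2000))
  }, numeric(1))
  expect_lt(E_opt, median(E_rand))
})

test_that("a smoke-scale GA improves, stays in bounds, and traces non-increasingly", {
  cfg <- ga_config(pop_size = 6, generations = 3, ensemble_size = 3, seed = 12,
                   stall_generations = 50)
  fit <- blade_ga(cfg, ssa = quick_ssa(1500))
  expect_s3_class(fit, "blade_calibration")

  # elitism: best-so-far never worsens
  expect_true(all(diff(fit$trace$best) <= 0))
  # final best at least as good as the random initial population
  expect_lte(fit$best_score, fit$trace$best[1])
  # every surviving individual respects the search interval
  expect_true(all(fit$population >= 1e-5 & fit$population <= 1e5))
  expect_true(all(unlist(fit$best_params) >= 1e-5 &
                  unlist(fit$best_params) <= 1e5))
  # tied search: the 7 degrees of freedom expand to the full parameter list
  expect_named(fit$best_params, c("k1c", "k2c", "k1f", "k2f", "k_1c", "k_2c",
                                  "k_1f", "k_2f", "alpha", "beta_p",
                                  "delta_D", "delta_X"))
  expect_equal(fit$best_params$k1c, fit$best_params$k2c)

  # reproducible under the master seed
  fit2 <- blade_ga(cfg, ssa = quick_ssa(1500))
  expect_equal(fit$best_score, fit2$best_score)
  expect_equal(fit$trace, fit2$trace)
})

test_that("self-consistency: targets generated by a known parameter set are recoverable", {
  # simulate the known set to create synthetic targets, then check its own
  # objective is near the irreducible floor (the ensemble sd terms) and that
  # a short GA approaches it within a factor of two
  p_true <- blade_params()
  e1 <- simulate_circuit(genes_train1, p_true, quick_ssa(), ensemble_size = 5, seed = 301)
  e2 <- simulate_circuit(genes_train2, p_true, quick_ssa(), ensemble_size = 5, seed = 302)
  data_syn <- calibration_data(d1 = e1$mean_theta_bar, d2 = e2$mean_theta_bar)

  E_true <- blade_objective(p_true, data_syn, ensemble_size = 3, seed = 77,
                            config = quick_ssa())
  fit <- blade_ga(ga_config(pop_size = 10, generations = 6, ensemble_size = 3,
                            seed = 99), data_syn, ssa = quick_ssa())
  expect_lt(fit$best_score, 2 * max(E_true, 0.5))
})

test_that("calibration reports serialise to CSV", {
  dir <- withr::local_tempdir()
  fit <- blade_ga(ga_config(pop_size = 4, generations = 2, ensemble_size = 2,
                            seed = 3), ssa = quick_ssa(500))
  write_calibration_report(fit, dir)
  best <- readr::read_csv(file.path(dir, "best_parameters.csv"), show_col_types = FALSE)
  expect_equal(unlist(best), unlist(fit$best_params), ignore_attr = TRUE)
  trace <- readr::read_csv(file.path(dir, "convergence_trace.csv"), show_col_types = FALSE)
  expect_equal(nrow(trace), nrow(fit$trace))
  pop <- readr::read_csv(file.path(dir, "final_population.csv"), show_col_types = FALSE)
  expect_equal(nrow(pop), 4)
})
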