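test_that("occupancies map to the canonical % cells ON vector", {
  to_vec <- getFromNamespace("occupancy_to_vector", "bladesim")
  occ <- list(c(1, 0, 0, 0), c(0, 1, 0, 0), c(0, 0, 1, 0), c(0, 0, 0, 1))
  # perfect switching reproduces the truth table of any design
  for (genes in list(genes_train1, genes_train2, c("GFP", "mCherry", "STOP", "GFPmCherry"))) {
    expect_equal(to_vec(occ, genes), as.numeric(ideal_vector(genes)))
  }
  # mixed occupancy splits across reporters by gene content
  mixed <- list(c(0.5, 0.5, 0, 0), c(0.25, 0.75, 0, 0),
                c(0, 0, 1, 0), c(0.1, 0, 0, 0.9))
  v <- to_vec(mixed, c("GFP", "mCherry", "STOP", "GFPmCherry"))
  expect_equal(v, c(50, 50, 25, 75, 0, 0, 100 * 0.9 + 10, 90))
})

test_that("a uniform-gene circuit scores perfectly whatever the dynamics", {
  ens <- simulate_circuit(rep("GFP", 4), ensemble_size = 3, seed = 21,
                          config = quick_ssa(800))
  expect_equal(ens$theta_bar, rep(0, 3))
  gfp_entries <- ens$mean_vector[c(1, 3, 5, 7)]
  expect_equal(gfp_entries, rep(100, 4), ignore_attr = TRUE)
  expect_equal(ens$mean_vector[c(2, 4, 6, 8)], rep(0, 4), ignore_attr = TRUE)
})

test_that("fast irreversible kinetics drive every input to its target address", {
  p <- blade_params(k1c = 10, k2c = 10, k1f = 10, k2f = 10,
                    k_1c = 1e-300, k_2c = 1e-300, k_1f = 1e-300, k_2f = 1e-300,
                    delta_D = 1e-300, delta_X = 1e-300)
  ens <- simulate_circuit(genes_train1, params = p, ensemble_size = 5, seed = 33)
  expect_lt(ens$mean_theta_bar, 0.3)
  expect_gt(ens$mean_occupancy["input11", "f11"], 0.95)
  expect_gt(ens$mean_occupancy["input10", "f10"], 0.95)
})

test_that("ensembles are reproducible and their summaries coherent", {
  a <- simulate_circuit(genes_train2, ensemble_size = 4, seed = 17, config = quick_ssa())
  b <- simulate_circuit(genes_train2, ensemble_size = 4, seed = 17, config = quick_ssa())
  expect_equal(a$theta_bar, b$theta_bar)
  expect_equal(a$mean_theta_bar, mean(a$theta_bar))
  expect_equal(a$sd_theta_bar, sd(a$theta_bar))
  expect_equal(glance(a)$mean_theta_bar, a$mean_theta_bar)
  expect_equal(nrow(tidy(a)), 4)
  # with the full event budget the no-input run always outlives its DNA pool,
  # so every replicate is flagged once
  full <- simulate_circuit(genes_train2, ensemble_size = 2, seed = 18)
  expect_equal(full$n_extinct_runs, 2L)
  expect_true(all(is.finite(full$theta_bar)))
})

test_that("cohort scoring partitions circuits and tallies gene composition", {
  circuits <- blade_circuits()[seq(1, 255, by = 16), ]
  co <- cohort_scores(circuits, ensemble_size = 3, seed = 5, config = quick_ssa())
  expect_equal(nrow(co$scores), nrow(circuits))
  expect_equal(co$mu, mean(co$scores$mean_theta_bar))
  expect_equal(co$sigma, sd(co$scores$mean_theta_bar))
  expect_equal(co$scores$is_poor, co$scores$mean_theta_bar > co$mu + co$sigma)
  expect_equal(sum(co$scores$is_poor) + sum(!co$scores$is_poor), nrow(circuits))
  # composition percentages sum to 100 within each partition
  comp <- co$composition
  sums <- tapply(comp$percent, comp$partition, sum)
  expect_equal(as.numeric(sums), rep(100, length(sums)), tolerance = 1e-9)
  expect_error(cohort_scores(blade_circuits(include_trivial = TRUE),
                             ensemble_size = 2), "all-STOP")
})

test_that("two cohort runs with different master seeds agree within sampling error", {
  circuits <- blade_circuits()[seq(3, 255, by = 8), ]
  a <- cohort_scores(circuits, ensemble_size = 4, seed = 100, config = quick_ssa())
  b <- cohort_scores(circuits, ensemble_size = 4, seed = 200, config = quick_ssa())
  pooled <- sqrt((a$sigma^2 + b$sigma^2) / 2)
  expect_lt(abs(a$mu - b$mu), 2 * pooled / sqrt(nrow(circuits)) +
              4 * mean(a$scores$sd_theta_bar) / sqrt(4 * nrow(circuits)))
})

test_that("the ratio scan reproduces the unscaled run at scale 1 under shared seeds", {
  circ <- blade_circuits()[blade_circuits()$circuit_id == 100, ]
  scan <- ratio_scan(circ, scales = c(1, 0.5), ensemble_size = 4, seed = 7,
                     config = quick_ssa())
  derive <- getFromNamespace("derive_seed", "bladesim")
  base <- simulate_circuit(circuit_genes(circ[1, ]), ensemble_size = 4,
                           seed = derive(7, 2000L, 1), config = quick_ssa())
  expect_equal(scan$mean_theta_bar[scan$scale == 1], base$mean_theta_bar)
  expect_error(ratio_scan(circ, scales = c(1, 2)), "scales")
})
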