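test_that("angular and adapted metrics reproduce the printed worked examples", {
  g <- golden_vectors

  th1 <- angular_metric(g$c1$obs, g$c1$ideal)
  expect_equal(th1, 11.58, tolerance = 0.02 / 11.58)  # rounded vectors are exact here
  expect_equal(adapted_metric(th1, g$c1$n), 1.45, tolerance = 0.005 / 1.45)

  # remaining printed values derive from unrounded source data: 1.5% relative
  th2 <- angular_metric(g$c2$obs, g$c2$ideal)
  expect_equal(th2, 1.29, tolerance = 0.015)
  th3 <- angular_metric(g$c3$obs, g$c3$ideal)
  expect_equal(th3, 8.2, tolerance = 0.015)
  expect_equal(adapted_metric(th3, g$c3$n), 2.04, tolerance = 0.015)
  th4 <- angular_metric(g$c4$obs, g$c4$ideal)
  expect_equal(th4, 8.9, tolerance = 0.015)
  expect_equal(adapted_metric(th4, g$c4$n), 2.22, tolerance = 0.015)
})

test_that("L1 errors match the printed totals from the rounded vectors", {
  g <- golden_vectors
  e1 <- l1_errors(g$c1$obs, g$c1$ideal)
  expect_equal(e1$total, 398)
  expect_equal(e1$average, 398 / 8)
  e2 <- l1_errors(g$c2$obs, g$c2$ideal)
  expect_equal(e2$total, 13)
  expect_equal(e2$average, 1.625)
  expect_equal(l1_errors(g$c3$obs, g$c3$obs), list(total = 0, average = 0))
})

test_that("angular metric has the geometry of an angle", {
  set.seed(41)
  for (i in 1:25) {
    a <- runif(8, 0, 100)
    b <- as.numeric(ideal_vector(circuit_genes(blade_circuits()[sample.int(255, 1), ])))
    th <- angular_metric(a, b)
    expect_gte(th, 0)
    expect_lte(th, 90)
    # scale invariance and symmetry
    expect_equal(angular_metric(a * runif(1, 0.01, 50), b), th)
    expect_equal(angular_metric(b, a), th)
  }
  # theta = 0 iff proportional; orthogonal vectors score 90
  v <- runif(8, 1, 100)
  expect_equal(angular_metric(v, 3 * v), 0)
  expect_equal(angular_metric(c(100, rep(0, 7)), c(0, 100, rep(0, 6))), 90)
})

test_that("degenerate inputs raise the documented errors", {
  expect_error(angular_metric(rep(0, 8), rep(100, 8)), "all-zero")
  expect_error(angular_metric(rep(1, 8), rep(0, 8)), "all-zero")
  expect_error(adapted_metric(5, 0), "division by zero")
  expect_error(angular_metric(1:4, rep(100, 8)), "length 8")
  expect_error(score_circuit(rep(10, 8), rep("STOP", 4)), "trivial")
})

test_that("score_circuit composes the metric pipeline", {
  rec <- score_circuit(golden_vectors$c1$obs, rep("GFPmCherry", 4))
  expect_s3_class(rec, "tbl_df")
  expect_equal(rec$theta_deg, 11.58, tolerance = 0.002)
  expect_equal(rec$theta_bar_deg, rec$theta_deg / 8)
  expect_equal(rec$n, 8L)
  expect_equal(rec$total_error, 398)

  perfect <- score_circuit(as.numeric(ideal_vector(genes_train1)), genes_train1)
  expect_equal(perfect$theta_deg, 0)
  expect_equal(perfect$total_error, 0)
})

test_that("score_circuits validates and scores tables row-wise", {
  circuits <- blade_circuits()
  obs <- generate_observed(circuits[1:6, ], seed = 3)
  scored <- score_circuits(obs, circuits)
  expect_equal(nrow(scored), 6)
  expect_true(all(is.finite(scored$theta_bar_deg)))
  expect_equal(scored$theta_bar_deg, scored$theta_deg / scored$n)
  expect_equal(scored$average_error, scored$total_error / 8)

  bad <- obs
  bad$circuit_id[2] <- 9999L
  expect_error(score_circuits(bad, circuits), "9999")
  expect_error(score_circuits(obs[, -2], circuits), "obs_v1")
})
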