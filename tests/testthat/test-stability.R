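test_that("bootstrap is deterministic and CIs behave on echo panels", {
  p <- echo_panel(300, seed = 53)
  b1 <- bootstrap_edges(p, n_boot = 30, seed = 9, refit = "fixed_lambda")
  b2 <- bootstrap_edges(p, n_boot = 30, seed = 9, refit = "fixed_lambda")
  expect_identical(b1$ci, b2$ci)
  expect_identical(b1$replicates, b2$replicates)
  # every CI contains its bootstrap mean; lower <= upper
  expect_true(all(b1$ci$lower <= b1$ci$upper))
  expect_true(all(b1$ci$lower <= b1$ci$boot_mean &
                  b1$ci$boot_mean <= b1$ci$upper))
  # near-deterministic refits: tight autoregressive intervals
  diag_rows <- b1$ci$source == b1$ci$target
  expect_true(all(b1$ci$upper[diag_rows] - b1$ci$lower[diag_rows] < 0.05))
})

test_that("edge difference tests are symmetric and null on self-comparison", {
  sim <- generate_panel(generator_spec(n = 400, seed = 59))
  boot <- bootstrap_edges(sim$panel, n_boot = 40, seed = 3,
                          refit = "fixed_lambda")
  self <- edge_difference_test(boot, c(9, 1), c(9, 1))
  expect_false(self$significant)
  expect_equal(self$ci, c(0, 0))
  ab <- edge_difference_test(boot, c(9, 1), c(2, 3))
  ba <- edge_difference_test(boot, c(2, 3), c(9, 1))
  expect_identical(ab$significant, ba$significant)
  expect_equal(ab$ci, -rev(ba$ci), tolerance = 1e-15)
  # label-based addressing matches index addressing
  lab <- edge_difference_test(boot, "suicidal_ideation->anhedonia",
                              c(2, 3))
  expect_identical(lab$significant, ab$significant)
  expect_error(edge_difference_test(boot, c(0, 1), c(1, 1)), "unknown edge")
})

test_that("centrality difference tests mirror the edge-test contracts", {
  sim <- generate_panel(generator_spec(n = 400, seed = 61))
  boot <- bootstrap_edges(sim$panel, n_boot = 40, seed = 5,
                          refit = "fixed_lambda")
  self <- centrality_difference_test(boot, 4, 4, index = "out_ei")
  expect_false(self$significant)
  ab <- centrality_difference_test(boot, "suicidal_ideation", "appetite",
                                   index = "out_ei")
  ba <- centrality_difference_test(boot, "appetite", "suicidal_ideation",
                                   index = "out_ei")
  expect_identical(ab$significant, ba$significant)
})

test_that("difference matrices are symmetric with non-significant diagonal", {
  sim <- generate_panel(generator_spec(n = 300, seed = 67))
  boot <- bootstrap_edges(sim$panel, n_boot = 30, seed = 7,
                          refit = "fixed_lambda")
  for (what in c("in_ei", "out_ei")) {
    M <- difference_matrix(boot, what)
    expect_true(isSymmetric(M))
    expect_false(any(diag(M)))
  }
  E <- difference_matrix(boot, "edge")
  expect_equal(dim(E), c(81, 81))
  expect_true(isSymmetric(E))
  expect_false(any(diag(E)))
})

test_that("CS saturates on strongly structured panels and is reproducible", {
  # stability of the centrality RANK ORDER needs centralities that are
  # heterogeneous across nodes yet tightly estimated: strong graded
  # autoregression, no cross-lags, low noise
  spec <- generator_spec(n = 2000, true_B = diag(seq(0.9, 0.1, length.out = 9)),
                         latent_cov_t1 = diag(9), noise_sd = 0.3, seed = 71)
  p <- generate_panel(spec)$panel
  cs1 <- case_drop_cs(p, "out_ei", reps_per_level = 20, seed = 13,
                      refit = "fixed_lambda")
  cs2 <- case_drop_cs(p, "out_ei", reps_per_level = 20, seed = 13,
                      refit = "fixed_lambda")
  expect_identical(cs1$correlations, cs2$correlations)
  expect_identical(cs1$cs_value, cs2$cs_value)
  expect_equal(cs1$cs_value, 0.7)  # grid maximum
})

test_that("CS decreases (weakly) as the correlation threshold rises", {
  sim <- generate_panel(generator_spec(n = 600, seed = 73))
  cs_lo <- case_drop_cs(sim$panel, "in_ei", reps_per_level = 15, seed = 17,
                        correlation_threshold = 0.5, refit = "fixed_lambda")
  cs_hi <- case_drop_cs(sim$panel, "in_ei", reps_per_level = 15, seed = 17,
                        correlation_threshold = 0.9, refit = "fixed_lambda")
  expect_lte(cs_hi$cs_value, cs_lo$cs_value)
})

test_that("CS guards its preconditions", {
  p <- echo_panel(30, seed = 79)
  expect_error(case_drop_cs(p, "in_ei", drop_grid = numeric(0)), "non-empty")
  expect_error(case_drop_cs(p, "in_ei", drop_grid = seq(0.1, 0.7, 0.05)),
               "too small")
})

test_that("degenerate bootstrap resamples are flagged but retained", {
  # one symptom almost constant: resamples often hit zero variance
  sim <- generate_panel(generator_spec(n = 60, seed = 83))
  t2 <- sim$panel$t2
  t2[, 5] <- 0L
  t2[1, 5] <- 1L
  p <- symptom_panel(sim$panel$t1, t2)
  boot <- suppressWarnings(
    bootstrap_edges(p, n_boot = 25, seed = 19, refit = "fixed_lambda"))
  expect_equal(dim(boot$replicates), c(25, 9, 9))
  expect_true(any(boot$degenerate))
  expect_false(anyNA(boot$replicates))
})
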