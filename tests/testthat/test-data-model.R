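test_that("panel CSV round trip preserves scores and covariates exactly", {
  set.seed(11)
  t1 <- matrix(sample(0:3, 27, replace = TRUE), 3, 9)
  t2 <- matrix(sample(0:3, 27, replace = TRUE), 3, 9)
  covs <- data.frame(sex = c(0, 1, 1), age = c(19.5, 20, 22.25))
  p0 <- symptom_panel(t1, t2, covariates = covs)
  path <- withr::local_tempfile(fileext = ".csv")
  write_panel(p0, path)
  p1 <- read_panel(path, covariate_columns = c("sex", "age"))
  expect_equal(n_subjects(p1), 3)
  expect_identical(p1$t1, p0$t1)
  expect_identical(p1$t2, p0$t2)
  expect_equal(p1$covariates, p0$covariates)
})

test_that("out-of-range and missing scores are rejected with row/column detail", {
  t1 <- matrix(1L, 2, 9)
  t2 <- matrix(1L, 2, 9)
  bad <- t1
  bad[2, 5] <- 4L
  expect_error(symptom_panel(bad, t2), "row 2, item 5")

  path <- withr::local_tempfile(fileext = ".csv")
  write_panel(symptom_panel(matrix(1L, 3, 9), matrix(2L, 3, 9)), path)
  dat <- read.csv(path)
  dat$phq3_t2[1] <- NA
  dat$phq1_t1[2] <- 4
  write.csv(dat, path, row.names = FALSE)
  # strict mode: validation error naming the offending cell
  expect_error(read_panel(path, drop_incomplete = FALSE), "phq3_t2")
  # default: listwise drop with a per-row report
  p <- read_panel(path)
  expect_equal(n_subjects(p), 1)
  rep <- attr(p, "validation")
  expect_setequal(rep$row, c(1, 2))
  expect_setequal(rep$column, c("phq3_t2", "phq1_t1"))
})

test_that("read_panel flags missing required columns as configuration error", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(a = 1), path, row.names = FALSE)
  expect_error(read_panel(path), "missing required column")
})

test_that("cronbach_alpha matches direct formula, handles degenerate cases", {
  # 9 parallel copies of one varying item -> exactly 1
  set.seed(2)
  base <- sample(0:3, 40, replace = TRUE)
  par9 <- matrix(rep(base, 9), ncol = 9)
  p <- symptom_panel(par9, par9)
  expect_equal(cronbach_alpha(p, "t1"), 1.0)

  # 4-subject x 3-item toy table vs independent transcription of the formula
  toy <- rbind(c(0, 1, 2), c(1, 1, 3), c(2, 0, 1), c(3, 2, 2))
  pt <- symptom_panel(cbind(toy, matrix(0L, 4, 6)), matrix(0L, 4, 9))
  expect_equal(cronbach_alpha(pt, "t1"),
               alpha_direct(cbind(toy, matrix(0L, 4, 6))), tolerance = 1e-12)

  # all subjects identical -> undefined reliability
  const <- matrix(2L, 5, 9)
  expect_error(cronbach_alpha(symptom_panel(const, const), "t1"),
               "variance")
})

test_that("cronbach_alpha is invariant to constant shifts and matches Spearman-Brown", {
  # shift invariance (within the 0..3 range)
  set.seed(3)
  t1 <- matrix(sample(0:2, 20 * 9, replace = TRUE), 20, 9)
  p0 <- symptom_panel(t1, t1)
  p1 <- symptom_panel(t1 + 1L, t1 + 1L)
  expect_equal(cronbach_alpha(p0, "t1"), cronbach_alpha(p1, "t1"),
               tolerance = 1e-12)

  # noiseless parallel items with equal pairwise correlation r:
  # alpha equals Spearman-Brown k*r/(1+(k-1)*r). Construct continuous
  # scores with an exact exchangeable correlation, then verify on the
  # formula scale (bypassing the 0-3 integer container via direct formula).
  k <- 9
  n <- 60
  r <- 0.5
  set.seed(4)
  common <- rnorm(n)
  uniq <- matrix(rnorm(n * k), n, k)
  x <- sqrt(r) * common + sqrt(1 - r) * uniq
  # force the exact exchangeable structure: project to equicorrelation
  S <- matrix(r, k, k) + diag(1 - r, k)
  x <- scale(x) %*% solve(chol(cov(scale(x)))) %*% chol(S)
  expect_equal(alpha_direct(x), k * r / (1 + (k - 1) * r), tolerance = 1e-10)
})

test_that("edge lists are written losslessly, zeros retained", {
  sim <- generate_panel(generator_spec(n = 120, seed = 5))
  fit <- clpn(sim$panel, seed = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_edgelist(fit, path)
  back <- read_edgelist(path)
  expect_equal(nrow(back), 81)
  expect_identical(edgelist_to_matrix(back, fit$item_labels),
                   fit$edge_matrix)  # bit-exact round trip
  expect_identical(back$is_autoregressive,
                   back$source_label == back$target_label)

  # all-zero off-diagonals survive: no silent dropping
  fit0 <- fit
  fit0$edge_matrix[row(fit0$edge_matrix) != col(fit0$edge_matrix)] <- 0
  write_edgelist(fit0, path)
  back0 <- read_edgelist(path)
  expect_equal(nrow(back0), 81)
  expect_equal(sum(back0$weight == 0), sum(fit0$edge_matrix == 0))
})
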