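test_that("standardize_columns centers, scales, and flags zero variance", {
  s <- standardize_columns(cbind(a = c(1, 2, 3), b = c(5, 5, 5)))
  expect_equal(s$x[, "a"], c(-1, 0, 1))
  expect_equal(s$x[, "b"], c(0, 0, 0))
  expect_equal(unname(s$zero_variance), c(FALSE, TRUE))
  # idempotence
  s2 <- standardize_columns(s$x)
  expect_equal(s2$x, s$x, tolerance = 1e-12)
  expect_error(standardize_columns(cbind(1)), "n >= 2")
})

test_that("lambda >= lambda_max forces the all-zero solution", {
  inst <- random_instance(50, 5, seed = 21)
  lmax <- max(abs(crossprod(inst$X, inst$y))) / nrow(inst$X)
  expect_identical(solve_lasso(inst$X, inst$y, lmax), rep(0, 5))
  expect_identical(solve_lasso(inst$X, inst$y, lmax * 1.5), rep(0, 5))
  expect_gt(sum(solve_lasso(inst$X, inst$y, lmax * 0.9) != 0), 0)
})

test_that("single standardized predictor matches the soft-threshold closed form", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 200
    x <- standardize_columns(cbind(rnorm(n)))$x
    y <- standardize_columns(cbind(0.6 * x[, 1] + rnorm(n)))$x[, 1]
    # with unit-sample-sd scaling, x'x/n = (n-1)/n, x'y/n = c*(n-1)/n
    c_ <- cor(x[, 1], y)
    for (lam in c(0.05, 0.1, 0.3)) {
      expected <- sign(c_) * max(abs(c_) - lam * n / (n - 1), 0)
      expect_equal(solve_lasso(x, y, lam)[1], expected, tolerance = 1e-9)
    }
  }
})

test_that("solver objective matches a proximal-gradient oracle on random instances", {
  for (seed in 1:20) {
    inst <- random_instance(40, 3, seed = 100 + seed)
    lam <- runif(1, 0.02, 0.3)
    b_cd <- solve_lasso(inst$X, inst$y, lam)
    b_pg <- prox_grad_lasso(inst$X, inst$y, lam)
    expect_equal(lasso_objective(inst$X, inst$y, b_cd, lam),
                 lasso_objective(inst$X, inst$y, b_pg, lam),
                 tolerance = 1e-6)
  }
})

test_that("penalty-free solution matches ordinary least squares", {
  inst <- random_instance(100, 4, seed = 31)
  b0 <- solve_lasso(inst$X, inst$y, 0)
  ols <- qr.coef(qr(inst$X), inst$y)
  expect_equal(b0, unname(ols), tolerance = 1e-6)
})

test_that("support size is non-increasing in lambda along the path", {
  inst <- random_instance(120, 8, seed = 41, rho = 0.5)
  lams <- lambda_grid(inst$X, inst$y, nlambda = 60)
  n <- nrow(inst$X)
  path <- apply(cbind(lams), 1, function(l) solve_lasso(inst$X, inst$y, l))
  supp <- colSums(path != 0)  # along decreasing lambda
  expect_true(all(diff(supp) >= 0))
  expect_equal(supp[1], 0)  # grid starts at the all-zero solution
})

test_that("coordinate descent agrees with glmnet at matched normalization", {
  skip_if_not_installed("glmnet")
  inst <- random_instance(150, 6, seed = 51, rho = 0.4)
  lam <- 0.08
  b_cd <- solve_lasso(inst$X, inst$y, lam)
  gf <- glmnet::glmnet(inst$X, inst$y, family = "gaussian", alpha = 1,
                       standardize = FALSE, intercept = FALSE,
                       lambda = c(0.3, lam, 0.02), thresh = 1e-14)
  b_gn <- as.numeric(coef(gf, s = lam, exact = TRUE, x = inst$X, y = inst$y))[-1]
  expect_equal(b_cd, b_gn, tolerance = 1e-5)
})

test_that("cross-validated lambda selection is deterministic and sane", {
  inst <- random_instance(200, 9, seed = 61)
  cv1 <- select_lambda_cv(inst$X, inst$y, seed = 7)
  cv2 <- select_lambda_cv(inst$X, inst$y, seed = 7)
  expect_identical(cv1$lambda, cv2$lambda)
  expect_identical(cv1$cvm, cv2$cvm)
  expect_equal(length(cv1$lambdas), 100)
  expect_true(all(diff(cv1$lambdas) < 0))
  expect_error(select_lambda_cv(inst$X[1:5, ], inst$y[1:5], n_folds = 10),
               "n_folds")
})

test_that("CV keeps a pure-noise model sparse and finds a real signal", {
  # y independent of X: at least 7 of 9 coefficients exactly zero
  set.seed(71)
  X <- standardize_columns(matrix(rnorm(500 * 9), 500, 9))$x
  y <- standardize_columns(cbind(rnorm(500)))$x[, 1]
  cv <- select_lambda_cv(X, y, seed = 3)
  b <- solve_lasso(X, y, cv$lambda)
  expect_gte(sum(b == 0), 7)

  # y = 0.8 x1 + noise: x1 selected, coefficient near 0.8
  set.seed(72)
  X2 <- standardize_columns(matrix(rnorm(1000 * 9), 1000, 9))$x
  y2 <- 0.8 * X2[, 1] + rnorm(1000, sd = 0.3)
  cv2 <- select_lambda_cv(X2, y2, seed = 3)
  b2 <- solve_lasso(X2, y2, cv2$lambda)
  expect_true(b2[1] != 0)
  expect_lt(abs(b2[1] - 0.8), 0.1)
})

test_that("1-SE rule never selects a smaller lambda than the minimizer", {
  inst <- random_instance(300, 9, seed = 81)
  cv_min <- select_lambda_cv(inst$X, inst$y, seed = 5, rule = "min")
  cv_1se <- select_lambda_cv(inst$X, inst$y, seed = 5, rule = "1se")
  expect_gte(cv_1se$lambda, cv_min$lambda)
})
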