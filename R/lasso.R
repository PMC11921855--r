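#' Column-wise z-standardization
#'
#' Centers each column to mean zero and scales positive-variance columns to
#' unit sample standard deviation (denominator n-1). Zero-variance columns
#' become all-zero and are flagged rather than producing NaN.
#'
#' @param x Numeric matrix, n x k with n >= 2.
#' @return List with `x` (standardized matrix), `center`, `scale` (the
#'   original sds; 1 recorded for zero-variance columns), and
#'   `zero_variance` (logical per column).
#' @export
standardize_columns <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("standardization requires n >= 2", call. = FALSE)
  ctr <- colMeans(x)
  sds <- apply(x, 2, stats::sd)
  zv <- sds <= 0 | !is.finite(sds)
  scl <- ifelse(zv, 1, sds)
  z <- sweep(x, 2, ctr, "-")
  z <- sweep(z, 2, scl, "/")
  z[, zv] <- 0
  list(x = z, center = ctr, scale = scl, zero_variance = zv)
}

soft_threshold <- function(z, lambda) sign(z) * pmax(abs(z) - lambda, 0)

# Coordinate descent on precomputed Gram quantities.
# Minimizes (1/2n)||y - Xb||^2 + lambda*||b||_1 given XtX = X'X/n and
# Xty = X'y/n. Covariance updates make the per-sweep cost O(k^2),
# independent of n, which at k <= ~15 predictors makes pathwise fits
# cheap; the sweep itself runs in compiled code (src/lasso_cd.cpp).
lasso_cd <- function(XtX, Xty, lambda, beta = NULL,
                     tol = 1e-10, max_iter = 100000L) {
  k <- length(Xty)
  if (is.null(beta)) beta <- numeric(k)
  drop(lasso_path_cpp(as.matrix(XtX), as.numeric(Xty), lambda,
                      as.numeric(beta), tol, as.integer(max_iter)))
}

#' Solve a single LASSO problem
#'
#' Minimizes `(1/2n) * sum((y - X b)^2) + lambda * sum(|b|)` by cyclic
#' coordinate descent with covariance updates. No intercept is fitted:
#' inputs are expected centered (typically z-standardized via
#' [standardize_columns()]). Coefficients inside the soft-threshold dead
#' band are exact zeros.
#'
#' @param X Numeric matrix n x k of predictors.
#' @param y Numeric response vector of length n.
#' @param lambda Penalty, `>= 0`.
#' @param tol Convergence tolerance on the max coefficient change per sweep.
#' @param max_iter Sweep limit.
#' @param beta_init Optional warm start.
#' @return Coefficient vector of length k.
#' @export
solve_lasso <- function(X, y, lambda, tol = 1e-10, max_iter = 100000L,
                        beta_init = NULL) {
  X <- as.matrix(X)
  if (!all(is.finite(X)) || !all(is.finite(y)) || !is.finite(lambda))
    stop("non-finite inputs to solve_lasso", call. = FALSE)
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  n <- nrow(X)
  lasso_cd(crossprod(X) / n, drop(crossprod(X, y)) / n, lambda,
           beta = beta_init, tol = tol, max_iter = max_iter)
}

#' LASSO objective value
#'
#' `(1/2n) * RSS + lambda * L1`, the normalization under which all penalties
#' in this package are expressed.
#'
#' @param X,y,lambda As in [solve_lasso()].
#' @param beta Coefficient vector.
#' @return Scalar objective value.
#' @export
lasso_objective <- function(X, y, beta, lambda) {
  r <- y - as.matrix(X) %*% beta
  sum(r^2) / (2 * length(y)) + lambda * sum(abs(beta))
}

#' The lambda grid used for pathwise fits
#'
#' 100 log-spaced values descending from `lambda_max` (the smallest penalty
#' at which all coefficients are zero, `max_j |x_j' y| / n`) to
#' `1e-4 * lambda_max`.
#'
#' @param X,y As in [solve_lasso()].
#' @param nlambda Grid length (default 100).
#' @param lambda_min_ratio Ratio of smallest to largest lambda.
#' @return Decreasing numeric vector.
#' @export
lambda_grid <- function(X, y, nlambda = 100L, lambda_min_ratio = 1e-4) {
  n <- nrow(as.matrix(X))
  lmax <- max(abs(crossprod(as.matrix(X), y))) / n
  if (!is.finite(lmax) || lmax <= 0) return(rep(0, nlambda))
  exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = nlambda))
}

# Pathwise coordinate descent with warm starts down a decreasing grid.
# Returns k x nlambda coefficient matrix.
lasso_path <- function(XtX, Xty, lambdas, tol = 1e-9) {
  lasso_path_cpp(as.matrix(XtX), as.numeric(Xty), as.numeric(lambdas),
                 numeric(length(Xty)), tol, 100000L)
}

#' Select the LASSO penalty by k-fold cross-validation
#'
#' Folds are assigned by a single seeded shuffle; the lambda path is the
#' log-spaced grid of [lambda_grid()] computed on the full data. The
#' selected lambda minimizes mean cross-validated squared error; ties are
#' broken toward the larger lambda (sparser model). A one-standard-error
#' rule is available as an option.
#'
#' @param X,y As in [solve_lasso()]; typically standardized.
#' @param n_folds Number of CV folds (default 10).
#' @param seed Integer seed for the fold shuffle.
#' @param nlambda,lambda_min_ratio Grid parameters, see [lambda_grid()].
#' @param rule `"min"` (default) or `"1se"`.
#' @return List with `lambda` (selected), `lambdas` (grid), `cvm` (mean CV
#'   MSE per lambda), `cvsd` (its standard error), `fold_id`, `rule`.
#' @export
select_lambda_cv <- function(X, y, n_folds = 10L, seed = 1L,
                             nlambda = 100L, lambda_min_ratio = 1e-4,
                             rule = c("min", "1se")) {
  rule <- match.arg(rule)
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < n_folds)
    stop(sprintf("need n >= n_folds (n = %d, folds = %d)", n, n_folds),
         call. = FALSE)
  lambdas <- lambda_grid(X, y, nlambda, lambda_min_ratio)
  fold_id <- local({
    set.seed(seed)
    sample(rep_len(seq_len(n_folds), n))
  })
  sqerr <- matrix(NA_real_, n, length(lambdas))
  for (f in seq_len(n_folds)) {
    tr <- fold_id != f
    Xt <- X[tr, , drop = FALSE]
    yt <- y[tr]
    path <- lasso_path(crossprod(Xt) / sum(tr), drop(crossprod(Xt, yt)) / sum(tr),
                       lambdas)
    pred <- X[!tr, , drop = FALSE] %*% path
    sqerr[!tr, ] <- (y[!tr] - pred)^2
  }
  cvm <- colMeans(sqerr)
  fold_means <- rowsum(sqerr, fold_id) / as.vector(table(fold_id))
  cvsd <- apply(fold_means, 2, stats::sd) / sqrt(n_folds)
  i_min <- which.min(cvm)                       # first index = largest lambda
  i_sel <- if (rule == "1se") {
    which(cvm <= cvm[i_min] + cvsd[i_min])[1]
  } else i_min
  list(lambda = lambdas[i_sel], lambdas = lambdas, cvm = cvm, cvsd = cvsd,
       fold_id = fold_id, rule = rule)
}
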