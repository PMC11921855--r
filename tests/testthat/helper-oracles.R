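# Independent oracles and small panel builders used across the suite.

# Proximal-gradient (ISTA) LASSO oracle for (1/2n)||y-Xb||^2 + lambda||b||_1,
# deliberately independent of the package's coordinate-descent path.
prox_grad_lasso <- function(X, y, lambda, max_iter = 200000, tol = 1e-12) {
  X <- as.matrix(X)
  n <- nrow(X)
  G <- crossprod(X) / n
  g <- drop(crossprod(X, y)) / n
  L <- max(eigen(G, symmetric = TRUE, only.values = TRUE)$values)
  step <- 1 / L
  b <- numeric(ncol(X))
  for (i in seq_len(max_iter)) {
    grad <- G %*% b - g
    z <- b - step * grad
    b_new <- sign(z) * pmax(abs(z) - step * lambda, 0)
    if (max(abs(b_new - b)) < tol) { b <- b_new; break }
    b <- b_new
  }
  as.numeric(b)
}

# Direct transcription of the alpha formula, independent of cronbach_alpha().
alpha_direct <- function(scores) {
  k <- ncol(scores)
  item_vars <- sum(apply(scores, 2, var))
  total_var <- var(rowSums(scores))
  (k / (k - 1)) * (1 - item_vars / total_var)
}

# Build a 9-item panel from two n x 9 score matrices.
panel_of <- function(t1, t2, ...) symptom_panel(t1, t2, ...)

# A panel whose subjects have prescribed total scores at each wave: each
# total is spread over items greedily (3s first), so any total in 0..27 is
# representable.
panel_with_totals <- function(t1_totals, t2_totals) {
  spread <- function(total) {
    total <- as.integer(total)
    sc <- integer(9)
    for (i in 1:9) {
      take <- min(3L, total)
      sc[i] <- take
      total <- total - take
    }
    sc
  }
  panel_of(t(vapply(t1_totals, spread, integer(9))),
           t(vapply(t2_totals, spread, integer(9))))
}

# Pure-noise panel: independent waves, no cross-lag structure.
noise_panel <- function(n, seed) {
  spec <- generator_spec(n = n, true_B = matrix(0, 9, 9),
                         latent_cov_t1 = diag(9), seed = seed)
  generate_panel(spec)$panel
}

# Strongly structured panel: T2 scores equal T1 scores up to tiny latent
# jitter, giving near-deterministic refits.
echo_panel <- function(n, seed, jitter = 0.01) {
  set.seed(seed)
  z <- matrix(rnorm(n * 9), n, 9)
  t1 <- matrix(findInterval(z, c(-0.6, 0.4, 1.2)), n, 9)
  z2 <- z + matrix(rnorm(n * 9, sd = jitter), n, 9)
  t2 <- matrix(findInterval(z2, c(-0.6, 0.4, 1.2)), n, 9)
  panel_of(t1, t2)
}

# Random standardized regression instance for solver tests.
random_instance <- function(n, k, seed, rho = 0.3, beta = NULL, noise = 1) {
  set.seed(seed)
  S <- matrix(rho, k, k) + diag(1 - rho, k)
  X <- matrix(rnorm(n * k), n, k) %*% chol(S)
  if (is.null(beta)) beta <- rnorm(k)
  y <- drop(X %*% beta) + rnorm(n, sd = noise)
  X <- standardize_columns(X)$x
  y <- standardize_columns(cbind(y))$x[, 1]
  list(X = X, y = y, beta = beta)
}
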