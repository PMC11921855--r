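#' Fit a cross-lagged panel network
#'
#' Estimates the temporal network of a two-wave symptom panel by node-wise
#' regularized regression: for each symptom j, the z-standardized T2 score
#' of j is regressed on all z-standardized T1 symptom scores (plus any
#' standardized covariates) with an L1 penalty, the penalty chosen per
#' equation by k-fold cross-validation. Entry (i, j) of the edge matrix is
#' the coefficient of T1 symptom i predicting T2 symptom j: the diagonal
#' holds autoregressive paths, off-diagonal entries cross-lagged paths.
#' Covariate coefficients are stored separately and never enter the edge
#' matrix.
#'
#' All variables (predictors and outcomes) are standardized within the
#' analyzed group so the penalty treats every coefficient symmetrically and
#' edge weights are comparable across equations and groups. LASSO produces
#' exact zeros, so absent edges are structural zeros, not small numbers.
#'
#' @param panel A [symptom_panel()].
#' @param covariates `TRUE` to use all panel covariates, `FALSE`/`NULL` for
#'   none, or a character vector of covariate names.
#' @param seed Integer master seed; equation j shuffles its CV folds with
#'   `seed + j`, recorded in the fit for bit-reproducibility.
#' @param n_folds CV folds (default 10).
#' @param nlambda,lambda_min_ratio Penalty-grid parameters ([lambda_grid()]).
#' @param rule CV selection rule, `"min"` (default) or `"1se"`.
#' @param lambda Optional fixed penalty vector (one per target symptom, or a
#'   scalar recycled): skips cross-validation. Used by the fast resampling
#'   mode.
#'
#' @return An object of class `clpn`: list with `edge_matrix` (p x p, rows =
#'   T1 source, columns = T2 target), `covariate_effects` (covariates x p
#'   matrix or NULL), `lambdas` (selected penalty per target), `cv` (per-
#'   target CV curves, when run), `n_subjects`, `fold_seed`, `item_labels`,
#'   `zero_variance` flags, standardized data (`z1`, `z2`, `zcov`) for
#'   prediction/residuals, and the `call`.
#' @examples
#' sim <- generate_panel(generator_spec(n = 300, seed = 1))
#' fit <- clpn(sim$panel, seed = 1)
#' summary(fit)
#' @export
clpn <- function(panel, covariates = TRUE, seed = 1L, n_folds = 10L,
                 nlambda = 100L, lambda_min_ratio = 1e-4,
                 rule = c("min", "1se"), lambda = NULL) {
  stopifnot(inherits(panel, "symptom_panel"))
  rule <- match.arg(rule)
  n <- n_subjects(panel)
  if (n < 20) warning("fewer than 20 subjects; estimates will be unstable")
  p <- length(panel$item_labels)

  cov_mat <- NULL
  cov_names <- character(0)
  if (!is.null(panel$covariates) && !isFALSE(covariates) && !is.null(covariates)) {
    cov_names <- if (isTRUE(covariates)) names(panel$covariates) else {
      miss <- setdiff(covariates, names(panel$covariates))
      if (length(miss)) stop("unknown covariate(s): ",
                             paste(miss, collapse = ", "), call. = FALSE)
      covariates
    }
    if (length(cov_names))
      cov_mat <- as.matrix(panel$covariates[cov_names])
  }

  s1 <- standardize_columns(panel$t1)
  s2 <- standardize_columns(panel$t2)
  scov <- if (!is.null(cov_mat)) standardize_columns(cov_mat) else NULL
  X <- if (is.null(scov)) s1$x else cbind(s1$x, scov$x)
  q <- length(cov_names)

  edge_matrix <- matrix(0, p, p,
                        dimnames = list(panel$item_labels, panel$item_labels))
  cov_effects <- if (q) matrix(0, q, p, dimnames = list(cov_names, panel$item_labels))
  lambdas <- stats::setNames(numeric(p), panel$item_labels)
  cv_curves <- vector("list", p)
  names(cv_curves) <- panel$item_labels
  if (!is.null(lambda)) lambda <- rep_len(lambda, p)

  XtX <- crossprod(X) / n
  for (j in seq_len(p)) {
    if (s2$zero_variance[j]) {
      warning(sprintf("target '%s' has zero variance at T2; its incoming edges are zero",
                      panel$item_labels[j]))
      next
    }
    y <- s2$x[, j]
    if (is.null(lambda)) {
      cv <- select_lambda_cv(X, y, n_folds = n_folds, seed = seed + j,
                             nlambda = nlambda,
                             lambda_min_ratio = lambda_min_ratio, rule = rule)
      lambdas[j] <- cv$lambda
      cv_curves[[j]] <- cv[c("lambda", "lambdas", "cvm", "cvsd")]
    } else {
      lambdas[j] <- lambda[j]
    }
    beta <- lasso_cd(XtX, drop(crossprod(X, y)) / n, lambdas[j])
    edge_matrix[, j] <- beta[seq_len(p)]
    if (q) cov_effects[, j] <- beta[p + seq_len(q)]
  }

  structure(
    list(edge_matrix = edge_matrix,
         covariate_effects = cov_effects,
         lambdas = lambdas,
         cv = cv_curves,
         n_subjects = n,
         fold_seed = seed,
         item_labels = panel$item_labels,
         zero_variance = list(t1 = s1$zero_variance, t2 = s2$zero_variance,
                              covariates = if (!is.null(scov)) scov$zero_variance),
         z1 = s1$x, z2 = s2$x, zcov = if (!is.null(scov)) scov$x,
         call = match.call()),
    class = "clpn")
}

#' @export
print.clpn <- function(x, ...) {
  p <- length(x$item_labels)
  nz <- sum(x$edge_matrix[row(x$edge_matrix) != col(x$edge_matrix)] != 0)
  cat(sprintf("Cross-lagged panel network: %d nodes, n = %d\n", p, x$n_subjects))
  cat(sprintf("  nonzero cross-lagged edges: %d of %d\n", nz, p * (p - 1)))
  cat(sprintf("  selected lambdas: %s\n",
              paste(sprintf("%.4f", x$lambdas), collapse = " ")))
  invisible(x)
}

#' Extract CLPN coefficients
#'
#' @param object A `clpn` fit.
#' @param which `"edges"` (default) for the p x p symptom edge matrix,
#'   `"covariates"` for covariate coefficients.
#' @param ... Unused.
#' @return Numeric matrix.
#' @export
coef.clpn <- function(object, which = c("edges", "covariates"), ...) {
  which <- match.arg(which)
  if (which == "edges") object$edge_matrix else object$covariate_effects
}

#' Summarize a CLPN fit
#'
#' Reports the count of nonzero cross-lagged (off-diagonal) edges out of the
#' p*(p-1) possible slots, the strongest autoregressive path, and the
#' strongest (largest-magnitude) cross-lagged edge with its signed weight.
#'
#' @param object A `clpn` fit.
#' @param ... Unused.
#' @return Object of class `summary.clpn`.
#' @export
summary.clpn <- function(object, ...) {
  B <- object$edge_matrix
  p <- nrow(B)
  off <- row(B) != col(B)
  n_nonzero <- sum(B[off] != 0)
  d <- diag(B)
  i_auto <- which.max(d)
  Boff <- B
  diag(Boff) <- 0
  i_cross <- which(abs(Boff) == max(abs(Boff)), arr.ind = TRUE)[1, ]
  structure(
    list(n_nodes = p,
         n_subjects = object$n_subjects,
         n_nonzero_cross = n_nonzero,
         n_possible_cross = p * (p - 1),
         max_autoregressive = list(item = object$item_labels[i_auto],
                                   weight = d[[i_auto]]),
         max_cross_lagged = list(source = object$item_labels[i_cross[1]],
                                 target = object$item_labels[i_cross[2]],
                                 weight = Boff[i_cross[1], i_cross[2]]),
         lambdas = object$lambdas),
    class = "summary.clpn")
}

#' @export
print.summary.clpn <- function(x, ...) {
  cat(sprintf("CLPN over %d symptoms (n = %d)\n", x$n_nodes, x$n_subjects))
  cat(sprintf("  %d of %d cross-lagged edges nonzero\n",
              x$n_nonzero_cross, x$n_possible_cross))
  cat(sprintf("  strongest autoregressive path: %s (weight = %.3f)\n",
              x$max_autoregressive$item, x$max_autoregressive$weight))
  cat(sprintf("  strongest cross-lagged edge: %s -> %s (weight = %.3f)\n",
              x$max_cross_lagged$source, x$max_cross_lagged$target,
              x$max_cross_lagged$weight))
  invisible(x)
}

#' Predict standardized T2 symptom scores
#'
#' @param object A `clpn` fit.
#' @param newdata Optional [symptom_panel()]; its T1 scores (and covariates,
#'   if the fit used them) are standardized with their own moments, matching
#'   the within-group standardization convention. Defaults to the training
#'   panel.
#' @param ... Unused.
#' @return n x p matrix of predicted standardized T2 scores.
#' @export
predict.clpn <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    z1 <- object$z1
    zcov <- object$zcov
  } else {
    stopifnot(inherits(newdata, "symptom_panel"))
    z1 <- standardize_columns(newdata$t1)$x
    zcov <- if (!is.null(object$covariate_effects)) {
      cn <- rownames(object$covariate_effects)
      standardize_columns(as.matrix(newdata$covariates[cn]))$x
    }
  }
  pred <- z1 %*% object$edge_matrix
  if (!is.null(object$covariate_effects) && !is.null(zcov))
    pred <- pred + zcov %*% object$covariate_effects
  pred
}

#' Residuals of a CLPN fit
#'
#' Standardized T2 scores minus fitted values, per symptom equation.
#'
#' @param object A `clpn` fit.
#' @param ... Unused.
#' @return n x p matrix.
#' @export
residuals.clpn <- function(object, ...) {
  object$z2 - predict(object)
}

#' Plot a CLPN as a directed graph
#'
#' Edges with `|weight|` below `threshold` (default 0.025, a display
#' convention only — estimation never thresholds) are hidden. Positive
#' edges are drawn blue, negative orange; width scales with magnitude.
#' Autoregressive paths appear as self-loops.
#'
#' @param x A `clpn` fit.
#' @param threshold Display threshold on `|weight|`.
#' @param ... Passed to [igraph::plot.igraph()].
#' @return The igraph object, invisibly.
#' @export
plot.clpn <- function(x, threshold = 0.025, ...) {
  B <- x$edge_matrix
  B[abs(B) < threshold] <- 0
  g <- igraph::graph_from_adjacency_matrix(B, mode = "directed",
                                           weighted = TRUE, diag = TRUE)
  w <- igraph::E(g)$weight
  igraph::plot.igraph(
    g,
    edge.width = 1 + 8 * abs(w) / max(abs(w), 1e-12),
    edge.color = ifelse(w > 0, "steelblue", "darkorange"),
    edge.arrow.size = 0.4,
    vertex.color = "white", vertex.label.color = "black",
    layout = igraph::layout_in_circle, ...)
  invisible(g)
}

#' Serialize a CLPN fit to JSON
#'
#' Writes the edge matrix (row-major), item labels, covariate effects,
#' selected penalties, seed and sample size.
#'
#' @param fit A `clpn` fit.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clpn_json <- function(fit, path) {
  stopifnot(inherits(fit, "clpn"))
  obj <- list(
    item_labels = fit$item_labels,
    edge_matrix = as.vector(t(fit$edge_matrix)),  # row-major
    covariate_effects = if (!is.null(fit$covariate_effects))
      list(names = rownames(fit$covariate_effects),
           values = as.vector(t(fit$covariate_effects))),
    lambdas = as.vector(fit$lambdas),
    n_subjects = fit$n_subjects,
    fold_seed = fit$fold_seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
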