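#' z-standardize a vector of centrality values
#'
#' `(x - mean) / sd` with sample sd (denominator n-1). A constant vector
#' returns all zeros with attribute `"degenerate" = TRUE` instead of NaN.
#'
#' @param values Numeric vector, length >= 2.
#' @return Standardized vector (mean 0, sample sd 1 when non-degenerate).
#' @export
z_standardize <- function(values) {
  stopifnot(length(values) >= 2)
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0)
    return(structure(rep(0, length(values)), degenerate = TRUE))
  (values - mean(values)) / s
}

# Raw in/out expected influence for one variant.
ei_raw <- function(B, variant, communities = NULL) {
  p <- nrow(B)
  M <- B
  if (variant == "cross_lagged") {
    diag(M) <- 0
  } else if (variant == "cross_construct") {
    same <- outer(communities, communities, "==")
    M[same] <- 0
  }
  list(out_ei = rowSums(M), in_ei = colSums(M))
}

#' Expected influence centrality of a CLPN
#'
#' For each symptom: out-EI is the sum of its signed outgoing edge weights
#' (how strongly its T1 state predicts the T2 network) and in-EI the sum of
#' its signed incoming weights (how strongly it is predicted). Three
#' variants: `"overall"` sums all edges including the node's autoregressive
#' path; `"cross_lagged"` excludes the autoregressive path of the node of
#' interest; `"cross_construct"` additionally excludes edges between nodes
#' in the same community (requires `communities`). Raw values are reported
#' alongside z-standardized ones ([z_standardize()]); ranks are identical.
#'
#' @param fit A [clpn()] fit or a p x p edge matrix.
#' @param variant One of `"overall"`, `"cross_lagged"`, `"cross_construct"`.
#' @param communities For `"cross_construct"`: vector of community labels,
#'   one per symptom.
#' @return A data frame of class `centrality_table` with columns `symptom`,
#'   `in_ei_raw`, `out_ei_raw`, `in_ei_z`, `out_ei_z`, `variant`.
#' @export
expected_influence <- function(fit,
                               variant = c("overall", "cross_lagged",
                                           "cross_construct"),
                               communities = NULL) {
  variant <- match.arg(variant)
  B <- if (inherits(fit, "clpn")) fit$edge_matrix else as.matrix(fit)
  labels <- rownames(B)
  if (is.null(labels)) labels <- paste0("item", seq_len(nrow(B)))
  if (variant == "cross_construct") {
    if (is.null(communities))
      stop("cross_construct requires a community label per symptom",
           call. = FALSE)
    stopifnot(length(communities) == nrow(B))
  }
  ei <- ei_raw(B, variant, communities)
  out <- data.frame(
    symptom = labels,
    in_ei_raw = unname(ei$in_ei),
    out_ei_raw = unname(ei$out_ei),
    in_ei_z = as.numeric(z_standardize(unname(ei$in_ei))),
    out_ei_z = as.numeric(z_standardize(unname(ei$out_ei))),
    variant = variant)
  class(out) <- c("centrality_table", "data.frame")
  out
}

#' Correlation between two network structures
#'
#' Pearson correlation of the vectorized edge matrices of two fits over the
#' same symptom set (81 entries with the autoregressive diagonal, 72
#' without). The two-sided p-value uses the t transform with
#' `n_elements - 2` degrees of freedom; because edges within a network are
#' not independent this p is approximate and labeled as such.
#'
#' @param fit_a,fit_b [clpn()] fits (or edge matrices) with identical
#'   symptom labels and ordering.
#' @param include_diagonal Include autoregressive entries (default `TRUE`).
#' @return Object of class `network_comparison`: list with `r`, `p_value`,
#'   `n_elements`, `include_diagonal`, `p_value_method`.
#' @export
network_correlation <- function(fit_a, fit_b, include_diagonal = TRUE) {
  A <- if (inherits(fit_a, "clpn")) fit_a$edge_matrix else as.matrix(fit_a)
  B <- if (inherits(fit_b, "clpn")) fit_b$edge_matrix else as.matrix(fit_b)
  if (!all(dim(A) == dim(B)))
    stop("edge matrices must have identical dimensions", call. = FALSE)
  if (!is.null(rownames(A)) && !is.null(rownames(B)) &&
      !identical(rownames(A), rownames(B)))
    stop("symptom labels do not align between the two fits", call. = FALSE)
  keep <- if (include_diagonal) rep(TRUE, length(A)) else
    as.vector(row(A) != col(A))
  a <- as.vector(A)[keep]
  b <- as.vector(B)[keep]
  m <- length(a)
  r <- stats::cor(a, b)
  p <- if (is.na(r) || abs(r) >= 1) {
    if (is.na(r)) NA_real_ else 0
  } else {
    tval <- r * sqrt((m - 2) / (1 - r^2))
    2 * stats::pt(-abs(tval), df = m - 2)
  }
  structure(
    list(r = r, p_value = p, n_elements = m,
         include_diagonal = include_diagonal,
         p_value_method = "approximate (elementwise-independence t transform)"),
    class = "network_comparison")
}

#' @export
print.network_comparison <- function(x, ...) {
  cat(sprintf("Network-structure correlation: r = %.3f, p = %.4g (%s, %d elements%s)\n",
              x$r, x$p_value, x$p_value_method, x$n_elements,
              if (x$include_diagonal) ", diagonal included" else ""))
  invisible(x)
}
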