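# Subset (or resample with replacement) a panel by row indices.
resample_panel <- function(panel, idx) {
  symptom_panel(
    panel$t1[idx, , drop = FALSE], panel$t2[idx, , drop = FALSE],
    covariates = if (!is.null(panel$covariates))
      panel$covariates[idx, , drop = FALSE] else NULL,
    subject_id = seq_along(idx),
    item_labels = panel$item_labels)
}

# Independent per-replicate seeds spawned from a master seed, so results are
# reproducible regardless of execution order.
spawn_seeds <- function(master, k) {
  set.seed(master)
  sample.int(.Machine$integer.max - 1L, k)
}

edge_labels <- function(labels) {
  as.vector(outer(labels, labels, function(a, b) paste0(a, "->", b)))
}

# Resolve an edge reference (c(i, j) indices or "source->target" label)
# to integer indices.
resolve_edge <- function(edge, labels) {
  if (is.character(edge) && length(edge) == 1) {
    parts <- strsplit(edge, "->", fixed = TRUE)[[1]]
    edge <- match(trimws(parts), labels)
  }
  if (length(edge) != 2 || anyNA(edge) ||
      any(edge < 1) || any(edge > length(labels)))
    stop("unknown edge: must be c(source, target) indices or 'source->target'",
         call. = FALSE)
  as.integer(edge)
}

#' Nonparametric bootstrap of CLPN edge weights
#'
#' Resamples subjects with replacement `n_boot` times and refits the full
#' network on each resample; 95% confidence intervals per edge are the
#' empirical 2.5/97.5 percentiles across replicates. By default each
#' replicate re-runs the complete procedure including cross-validated
#' penalty selection (`refit = "full"`); `refit = "fixed_lambda"` freezes
#' the point fit's per-target penalties, a fast mode intended for testing
#' and exploration. Replicates with degenerate (zero-variance) columns are
#' retained, their affected coefficients at zero, and flagged.
#'
#' @param panel A [symptom_panel()].
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param seed Master seed; spawns one substream per replicate.
#' @param covariates Passed to [clpn()].
#' @param refit `"full"` or `"fixed_lambda"`.
#' @param conf Confidence level for the percentile intervals (default 0.95).
#' @param ... Further arguments to [clpn()] (e.g. `n_folds`).
#' @return Object of class `clpn_boot`: list with `point` (the full-sample
#'   fit), `replicates` (n_boot x p x p array of edge matrices), `ci`
#'   (data frame: source, target, estimate, boot_mean, lower, upper),
#'   `degenerate` (logical per replicate), `n_boot`, `seed`, `conf`,
#'   `refit`.
#' @export
bootstrap_edges <- function(panel, n_boot = 1000L, seed = 1L,
                            covariates = TRUE,
                            refit = c("full", "fixed_lambda"),
                            conf = 0.95, ...) {
  stopifnot(inherits(panel, "symptom_panel"), n_boot >= 1)
  refit <- match.arg(refit)
  point <- clpn(panel, covariates = covariates, seed = seed, ...)
  p <- length(point$item_labels)
  n <- n_subjects(panel)
  seeds <- spawn_seeds(seed, n_boot)
  reps <- array(NA_real_, dim = c(n_boot, p, p),
                dimnames = list(NULL, point$item_labels, point$item_labels))
  degenerate <- logical(n_boot)
  for (b in seq_len(n_boot)) {
    set.seed(seeds[b])
    idx <- sample.int(n, n, replace = TRUE)
    sub <- resample_panel(panel, idx)
    fit_b <- withCallingHandlers(
      if (refit == "full")
        clpn(sub, covariates = covariates, seed = seeds[b], ...)
      else
        clpn(sub, covariates = covariates, seed = seeds[b],
             lambda = point$lambdas, ...),
      warning = function(w) {
        degenerate[b] <<- TRUE
        invokeRestart("muffleWarning")
      })
    reps[b, , ] <- fit_b$edge_matrix
  }
  alpha <- (1 - conf) / 2
  flat <- matrix(reps, nrow = n_boot)  # columns in (source, target) column-major order
  lo <- apply(flat, 2, stats::quantile, probs = alpha, names = FALSE)
  hi <- apply(flat, 2, stats::quantile, probs = 1 - alpha, names = FALSE)
  ci <- data.frame(
    source = rep(point$item_labels, times = p),
    target = rep(point$item_labels, each = p),
    estimate = as.vector(point$edge_matrix),
    boot_mean = colMeans(flat),
    lower = lo, upper = hi)
  structure(
    list(point = point, replicates = reps, ci = ci,
         degenerate = degenerate, n_boot = n_boot, seed = seed,
         conf = conf, refit = refit),
    class = "clpn_boot")
}

#' @export
print.clpn_boot <- function(x, ...) {
  cat(sprintf("CLPN bootstrap: %d replicates (%s refit), %.0f%% percentile CIs\n",
              x$n_boot, x$refit, 100 * x$conf))
  cat(sprintf("  degenerate replicates flagged: %d\n", sum(x$degenerate)))
  invisible(x)
}

# Per-replicate centrality draws (n_boot x p) for one index.
boot_centrality_draws <- function(boot, index = c("in_ei", "out_ei"),
                                  variant = "overall") {
  index <- match.arg(index)
  p <- dim(boot$replicates)[2]
  t(apply(boot$replicates, 1, function(B) {
    ei <- ei_raw(matrix(B, p, p), variant)
    if (index == "in_ei") ei$in_ei else ei$out_ei
  }))
}

#' Bootstrap difference test between two edge weights
#'
#' Two edges differ significantly when the percentile confidence interval
#' of their per-replicate difference excludes zero. The decision is
#' symmetric in the two edges.
#'
#' @param boot A [bootstrap_edges()] result (replicates retained).
#' @param edge_a,edge_b Edge references: `c(source, target)` index pairs or
#'   `"source_label->target_label"` strings.
#' @return List with `significant` (logical), `ci` (difference interval),
#'   `estimate` (point difference).
#' @export
edge_difference_test <- function(boot, edge_a, edge_b) {
  stopifnot(inherits(boot, "clpn_boot"))
  labs <- boot$point$item_labels
  a <- resolve_edge(edge_a, labs)
  b <- resolve_edge(edge_b, labs)
  d <- boot$replicates[, a[1], a[2]] - boot$replicates[, b[1], b[2]]
  alpha <- (1 - boot$conf) / 2
  ci <- stats::quantile(d, c(alpha, 1 - alpha), names = FALSE)
  list(significant = ci[1] > 0 || ci[2] < 0,
       ci = ci,
       estimate = boot$point$edge_matrix[a[1], a[2]] -
         boot$point$edge_matrix[b[1], b[2]])
}

#' Bootstrap difference test between two nodes' centralities
#'
#' As [edge_difference_test()], applied to per-replicate expected-influence
#' values of two symptoms.
#'
#' @param boot A [bootstrap_edges()] result.
#' @param node_a,node_b Symptom indices or labels.
#' @param index `"in_ei"` or `"out_ei"`.
#' @param variant Centrality variant (see [expected_influence()]).
#' @return List with `significant`, `ci`, `estimate`.
#' @export
centrality_difference_test <- function(boot, node_a, node_b,
                                       index = c("in_ei", "out_ei"),
                                       variant = "overall") {
  stopifnot(inherits(boot, "clpn_boot"))
  index <- match.arg(index)
  labs <- boot$point$item_labels
  to_idx <- function(v) {
    if (is.character(v)) v <- match(v, labs)
    if (is.na(v) || v < 1 || v > length(labs))
      stop("unknown symptom node", call. = FALSE)
    as.integer(v)
  }
  a <- to_idx(node_a)
  b <- to_idx(node_b)
  draws <- boot_centrality_draws(boot, index, variant)
  d <- draws[, a] - draws[, b]
  alpha <- (1 - boot$conf) / 2
  ci <- stats::quantile(d, c(alpha, 1 - alpha), names = FALSE)
  full <- ei_raw(boot$point$edge_matrix, variant)
  v <- if (index == "in_ei") full$in_ei else full$out_ei
  list(significant = ci[1] > 0 || ci[2] < 0, ci = ci,
       estimate = unname(v[a] - v[b]))
}

#' Pairwise bootstrap difference-test matrix
#'
#' Boolean significance of every pairwise difference among all p*p edges
#' (`what = "edge"`) or among the p nodes' centralities. Symmetric with an
#' all-FALSE diagonal.
#'
#' @param boot A [bootstrap_edges()] result.
#' @param what `"edge"`, `"in_ei"` or `"out_ei"`.
#' @param variant Centrality variant for the centrality matrices.
#' @return Logical matrix.
#' @export
difference_matrix <- function(boot, what = c("edge", "in_ei", "out_ei"),
                              variant = "overall") {
  stopifnot(inherits(boot, "clpn_boot"))
  what <- match.arg(what)
  alpha <- (1 - boot$conf) / 2
  draws <- if (what == "edge") {
    m <- matrix(boot$replicates, nrow = boot$n_boot)
    colnames(m) <- edge_labels(boot$point$item_labels)
    m
  } else {
    d <- boot_centrality_draws(boot, what, variant)
    colnames(d) <- boot$point$item_labels
    d
  }
  k <- ncol(draws)
  sig <- matrix(FALSE, k, k, dimnames = list(colnames(draws), colnames(draws)))
  for (i in seq_len(k - 1)) {
    di <- draws[, i]
    for (j in seq((i + 1), k)) {
      ci <- stats::quantile(di - draws[, j], c(alpha, 1 - alpha), names = FALSE)
      sig[i, j] <- sig[j, i] <- (ci[1] > 0 || ci[2] < 0)
    }
  }
  sig
}

#' Case-drop correlation stability (CS) coefficient
#'
#' For each drop proportion q in the grid, repeatedly subsamples
#' `round(n * (1 - q))` subjects without replacement, refits the network,
#' computes the chosen centrality, and correlates it (Pearson) with the
#' full-sample centrality. The CS coefficient is the largest q whose
#' empirical `(1 - confidence)` quantile of correlations still reaches the
#' threshold (default 0.7), or 0 if none does. Conventional reading: CS
#' below 0.25 is unstable, above 0.5 preferred. Subsamples whose refit is
#' degenerate (zero-variance centrality, correlation undefined) count as
#' correlation 0.
#'
#' @param panel A [symptom_panel()].
#' @param index `"in_ei"` or `"out_ei"`.
#' @param variant Centrality variant (default `"overall"`).
#' @param drop_grid Drop proportions (default 0.10 to 0.70 by 0.05).
#' @param reps_per_level Subsamples per proportion (default 100).
#' @param seed Master seed (one substream per subsample).
#' @param correlation_threshold,confidence CS definition parameters.
#' @param covariates,refit,... Passed to the refits as in
#'   [bootstrap_edges()]; `refit = "fixed_lambda"` freezes the full-sample
#'   penalties (fast mode).
#' @return Object of class `cs_result`: list with `cs_value`, `index`,
#'   `variant`, `drop_grid`, `quantiles` (per-level correlation quantile),
#'   `correlations` (levels x reps matrix), `correlation_threshold`,
#'   `confidence`, `seed`.
#' @export
case_drop_cs <- function(panel, index = c("in_ei", "out_ei"),
                         variant = "overall",
                         drop_grid = seq(0.10, 0.70, by = 0.05),
                         reps_per_level = 100L, seed = 1L,
                         correlation_threshold = 0.7, confidence = 0.95,
                         covariates = TRUE,
                         refit = c("full", "fixed_lambda"), ...) {
  stopifnot(inherits(panel, "symptom_panel"))
  index <- match.arg(index)
  refit <- match.arg(refit)
  if (!length(drop_grid)) stop("drop_grid must be non-empty", call. = FALSE)
  drop_grid <- sort(drop_grid)
  n <- n_subjects(panel)
  if (n * (1 - max(drop_grid)) < 20)
    stop("panel too small for the requested drop grid (need n*(1-max drop) >= 20)",
         call. = FALSE)
  full <- clpn(panel, covariates = covariates, seed = seed, ...)
  full_ei <- ei_raw(full$edge_matrix, variant)
  full_c <- if (index == "in_ei") full_ei$in_ei else full_ei$out_ei
  seeds <- spawn_seeds(seed, length(drop_grid) * reps_per_level)
  cors <- matrix(NA_real_, length(drop_grid), reps_per_level)
  s <- 0L
  for (l in seq_along(drop_grid)) {
    m <- round(n * (1 - drop_grid[l]))
    for (r in seq_len(reps_per_level)) {
      s <- s + 1L
      set.seed(seeds[s])
      idx <- sample.int(n, m, replace = FALSE)
      sub <- resample_panel(panel, idx)
      fit_s <- suppressWarnings(
        if (refit == "full")
          clpn(sub, covariates = covariates, seed = seeds[s], ...)
        else
          clpn(sub, covariates = covariates, seed = seeds[s],
               lambda = full$lambdas, ...))
      sub_ei <- ei_raw(fit_s$edge_matrix, variant)
      sub_c <- if (index == "in_ei") sub_ei$in_ei else sub_ei$out_ei
      r_ <- suppressWarnings(stats::cor(full_c, sub_c))
      cors[l, r] <- if (is.na(r_)) 0 else r_
    }
  }
  qtl <- apply(cors, 1, stats::quantile, probs = 1 - confidence, names = FALSE)
  ok <- drop_grid[qtl >= correlation_threshold]
  structure(
    list(cs_value = if (length(ok)) max(ok) else 0,
         index = index, variant = variant,
         drop_grid = drop_grid, quantiles = qtl, correlations = cors,
         correlation_threshold = correlation_threshold,
         confidence = confidence, seed = seed, refit = refit),
    class = "cs_result")
}

#' @export
print.cs_result <- function(x, ...) {
  cat(sprintf("CS coefficient (%s, %s variant): %.2f\n",
              x$index, x$variant, x$cs_value))
  cat(sprintf("  (largest drop proportion keeping the %.0f%% correlation quantile >= %.2f)\n",
              100 * (1 - x$confidence), x$correlation_threshold))
  invisible(x)
}
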