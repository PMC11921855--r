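#' Default sparse cross-lag coefficient matrix
#'
#' A 9 x 9 latent-scale coefficient matrix with dominant autoregressive
#' paths (diagonal 0.35), a hub of five strong outgoing paths from
#' suicidal ideation (node 9, weight 0.3), and seven further cross-lags of
#' magnitude 0.15-0.25 (12 nonzero cross-lags in total). Spectral radius
#' well below 1.
#'
#' @return 9 x 9 numeric matrix, entry (i, j) = effect of T1 latent i on
#'   T2 latent j.
#' @export
default_true_B <- function() {
  B <- diag(0.35, 9)
  B[9, c(1, 2, 4, 6, 8)] <- 0.30
  B[4, 1] <- 0.25
  B[3, 4] <- 0.20
  B[1, 2] <- 0.20
  B[2, 6] <- 0.20
  B[5, 3] <- 0.15
  B[7, 8] <- 0.15
  B[3, 2] <- 0.15
  dimnames(B) <- list(phq9_items(), phq9_items())
  B
}

#' Specify a two-wave ordinal panel generator
#'
#' Defines a latent linear cross-lag process whose waves are discretized
#' into PHQ-style 0-3 ordinal scores. T1 latents are multivariate normal
#' (correlation `latent_cov_t1`, mean `t1_mean_shift`); T2 latents are
#' `t(true_B) %*% z1` plus covariate effects and Gaussian noise, rescaled
#' to unit variance and shifted by `t2_mean_shift`, so each wave's symptom
#' severity is governed by its mean-shift alone. Latents above the three
#' increasing `thresholds` map to scores 1, 2, 3.
#'
#' @param n Number of subjects.
#' @param p Number of items (default 9).
#' @param true_B p x p latent cross-lag matrix; spectral radius must be < 1.
#' @param t1_mean_shift,t2_mean_shift Latent mean shifts (scenario
#'   severity; 0 = community-level right-skewed scores).
#' @param latent_cov_t1 T1 latent covariance (symmetric positive-definite);
#'   default exchangeable correlation 0.4, a typical inter-symptom
#'   correlation for depressive items.
#' @param noise_sd Innovation sd of the T2 latents (> 0; default 1).
#' @param thresholds Three increasing cut points (default 0.5, 1.2, 2.0,
#'   giving right-skewed community-like score distributions at shift 0).
#' @param covariate_spec Optional list with `effects` (q x p matrix of
#'   latent-scale covariate effects on T2); q standard-normal covariates
#'   `cov1..covq` are generated and attached to the panel.
#' @param seed Integer seed.
#' @return Object of class `generator_spec` (validated list of the above).
#' @export
generator_spec <- function(n, p = 9, true_B = default_true_B(),
                           t1_mean_shift = 0, t2_mean_shift = 0,
                           latent_cov_t1 = NULL, noise_sd = 1,
                           thresholds = c(0.5, 1.2, 2.0),
                           covariate_spec = NULL, seed = 1L) {
  if (is.null(latent_cov_t1))
    latent_cov_t1 <- matrix(0.4, p, p) + diag(0.6, p)
  true_B <- as.matrix(true_B)
  stopifnot(n >= 1, p >= 2, all(dim(true_B) == p),
            all(dim(latent_cov_t1) == p), noise_sd > 0,
            length(thresholds) == 3)
  if (any(diff(thresholds) <= 0))
    stop("thresholds must be strictly increasing", call. = FALSE)
  if (max(abs(latent_cov_t1 - t(latent_cov_t1))) > 1e-10)
    stop("latent_cov_t1 must be symmetric", call. = FALSE)
  ev <- eigen(latent_cov_t1, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("latent_cov_t1 must be positive-definite", call. = FALSE)
  if (max(Mod(eigen(true_B, only.values = TRUE)$values)) >= 1)
    stop("spectral radius of true_B must be < 1 (stable process)",
         call. = FALSE)
  if (!is.null(covariate_spec)) {
    stopifnot(is.list(covariate_spec), !is.null(covariate_spec$effects))
    covariate_spec$effects <- as.matrix(covariate_spec$effects)
    stopifnot(ncol(covariate_spec$effects) == p)
  }
  structure(
    list(n = as.integer(n), p = as.integer(p), true_B = true_B,
         t1_mean_shift = t1_mean_shift, t2_mean_shift = t2_mean_shift,
         latent_cov_t1 = latent_cov_t1, noise_sd = noise_sd,
         thresholds = thresholds, covariate_spec = covariate_spec,
         seed = as.integer(seed)),
    class = "generator_spec")
}

# Discretize latent values into 0-3 by the three thresholds (monotone).
discretize_latent <- function(z, thresholds) {
  matrix(findInterval(z, thresholds), nrow(z), ncol(z))
}

#' Generate a synthetic two-wave symptom panel
#'
#' Draws the latent process defined by a [generator_spec()] and discretizes
#' both waves into 0-3 ordinal scores. The exact spec travels with the
#' output so recovery checks never reconstruct the truth implicitly.
#' Because ordinal thresholding attenuates associations, estimated
#' standardized edges are biased toward zero relative to `true_B`;
#' recovery should be judged by sign and correlation, not absolute
#' equality.
#'
#' @param spec A [generator_spec()].
#' @return Object of class `clpn_sim`: list with `panel` (a
#'   [symptom_panel()]), `truth` (the spec), and `latent_scale` (per-item
#'   analytic sd of the raw T2 latent, used for the unit-variance
#'   rescaling).
#' @export
generate_panel <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  set.seed(spec$seed)
  n <- spec$n
  p <- spec$p
  R <- chol(spec$latent_cov_t1)
  z1 <- matrix(stats::rnorm(n * p), n, p) %*% R
  eta2 <- z1 %*% spec$true_B +
    matrix(stats::rnorm(n * p, sd = spec$noise_sd), n, p)
  q <- 0L
  covs <- NULL
  if (!is.null(spec$covariate_spec)) {
    q <- nrow(spec$covariate_spec$effects)
    cv <- matrix(stats::rnorm(n * q), n, q)
    eta2 <- eta2 + cv %*% spec$covariate_spec$effects
    covs <- as.data.frame(cv)
    names(covs) <- paste0("cov", seq_len(q))
  }
  # Analytic scale of the raw T2 latent: Var = diag(B' Sigma B) + noise^2
  # (+ covariate contribution); rescaled to unit sd so t2_mean_shift alone
  # sets wave-2 severity.
  v2 <- diag(t(spec$true_B) %*% spec$latent_cov_t1 %*% spec$true_B) +
    spec$noise_sd^2
  if (q) v2 <- v2 + colSums(spec$covariate_spec$effects^2)
  s2 <- sqrt(v2)
  lat1 <- z1 + spec$t1_mean_shift
  lat2 <- sweep(eta2, 2, s2, "/") + spec$t2_mean_shift
  panel <- symptom_panel(
    discretize_latent(lat1, spec$thresholds),
    discretize_latent(lat2, spec$thresholds),
    covariates = covs,
    item_labels = if (p == 9) phq9_items() else paste0("item", seq_len(p)))
  structure(list(panel = panel, truth = spec, latent_scale = s2),
            class = "clpn_sim")
}

#' Trajectory-scenario generator presets
#'
#' Four presets sharing one cross-lag support ([default_true_B()]) whose
#' wave-specific latent mean shifts reproduce the four depressive
#' trajectories under the default cutoff: chronic = elevated severity at
#' both waves (shift +1.3), delayed = low T1 / high T2, recovery = high T1
#' / low T2, resistance = low at both waves (shift -0.3). Shift values come
#' from the threshold arithmetic: +1.3 puts the expected total score well
#' above the cutoff of 7, -0.3 well below, so each preset's cohort is
#' majority-labeled with its intended trajectory.
#'
#' @param n Subjects per scenario (default 2000).
#' @param seed Base seed; scenario k uses `seed + k`.
#' @param ... Further arguments passed to [generator_spec()].
#' @return Named list of four `generator_spec`s, in trajectory order.
#' @export
trajectory_scenarios <- function(n = 2000L, seed = 1L, ...) {
  hi <- 1.3
  lo <- -0.3
  shifts <- list(chronic = c(hi, hi), delayed = c(lo, hi),
                 recovery = c(hi, lo), resistance = c(lo, lo))
  out <- lapply(seq_along(shifts), function(k) {
    generator_spec(n = n, t1_mean_shift = shifts[[k]][1],
                   t2_mean_shift = shifts[[k]][2], seed = seed + k, ...)
  })
  names(out) <- names(shifts)
  out
}
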