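# Write a data frame as CSV with numeric columns at full (%.17g) precision
# so identical runs produce byte-identical files.
write_csv_full <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer, logical(1))
  for (j in which(num)) df[[j]] <- sprintf("%.17g", df[[j]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Read a pipeline run configuration
#'
#' Accepts a YAML file path or a plain list and fills in defaults. Fields:
#' `input` (panel CSV path) or `panel` (a [symptom_panel()] given
#' programmatically), `cutoff` (7), `covariates` (TRUE / FALSE / names),
#' `seed` (1), `n_boot` (1000), `refit` ("full"), `cs` (list:
#' `drop_grid`, `reps_per_level`, `correlation_threshold`, `confidence`),
#' `min_group_n` (50), `out_dir`, `plot_threshold` (0.025, display only),
#' `plots` (FALSE), `stability` (TRUE), `item_columns`,
#' `covariate_columns` (for [read_panel()]).
#'
#' @param config List or YAML path.
#' @return Completed config list.
#' @export
read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(cutoff = 7, covariates = TRUE, seed = 1L, n_boot = 1000L,
                   refit = "full", min_group_n = 50L,
                   plot_threshold = 0.025, plots = FALSE, stability = TRUE,
                   cs = list(), item_columns = NULL, covariate_columns = NULL)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  cs_defaults <- list(drop_grid = seq(0.10, 0.70, by = 0.05),
                      reps_per_level = 100L,
                      correlation_threshold = 0.7, confidence = 0.95)
  for (nm in names(cs_defaults))
    if (is.null(config$cs[[nm]])) config$cs[[nm]] <- cs_defaults[[nm]]
  if (is.null(config$panel) && is.null(config$input))
    stop("config needs either 'input' (CSV path) or 'panel'", call. = FALSE)
  if (is.null(config$out_dir))
    stop("config needs 'out_dir'", call. = FALSE)
  config
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full trajectory-stratified CLPN pipeline
#'
#' Orchestrates the complete analysis from a single configuration:
#' stratifies the cohort into the four depressive trajectories, fits one
#' cross-lagged panel network per group of at least `min_group_n` subjects,
#' computes expected-influence centralities (overall and cross-lagged
#' variants), bootstrap edge CIs, CS coefficients and difference-test
#' matrices per group, the between-group network-correlation matrix (both
#' diagonal conventions), and writes everything plus a reproducibility
#' manifest to `out_dir`. A failing stage aborts with the stage name;
#' outputs written before the failure are preserved.
#'
#' Files written: `groups.csv`, `cohort_summary.json`,
#' `fit_<group>.json`, `edges_<group>.csv`, `centrality_<group>.csv`,
#' `stability_<group>.json`, `network_correlation.csv`,
#' `network_correlation_offdiag.csv`, `manifest.json`, and optionally
#' `network_<group>.pdf`.
#'
#' @param config See [read_run_config()].
#' @return The run directory path, invisibly; the collected results as
#'   attribute `"results"`.
#' @export
run_clpn_pipeline <- function(config) {
  config <- read_run_config(config)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  panel <- run_stage("load", {
    if (!is.null(config$panel)) config$panel
    else read_panel(config$input, item_columns = config$item_columns,
                    covariate_columns = config$covariate_columns)
  })

  strat <- run_stage("stratify", stratify_cohort(panel, config$cutoff))
  write_csv_full(strat$assignments, file.path(out, "groups.csv"))
  jsonlite::write_json(
    list(counts = as.list(strat$counts),
         percentages = as.list(strat$percentages),
         total_n = strat$total_n, cutoff = config$cutoff, seed = config$seed),
    file.path(out, "cohort_summary.json"), auto_unbox = TRUE, digits = NA)

  groups <- run_stage("split", split_by_trajectory(panel, strat))
  small <- names(groups)[vapply(groups, n_subjects, 0L) < config$min_group_n]
  for (g in small)
    warning(sprintf("group '%s' has fewer than %d subjects; skipped", g,
                    config$min_group_n))
  groups <- groups[setdiff(names(groups), small)]

  fits <- list()
  for (g in names(groups)) {
    fits[[g]] <- run_stage(paste0("fit:", g),
                           clpn(groups[[g]], covariates = config$covariates,
                                seed = config$seed))
    write_clpn_json(fits[[g]], file.path(out, paste0("fit_", g, ".json")))
    write_edgelist(fits[[g]], file.path(out, paste0("edges_", g, ".csv")))
    cent <- run_stage(paste0("centrality:", g), rbind(
      expected_influence(fits[[g]], "overall"),
      expected_influence(fits[[g]], "cross_lagged")))
    write_csv_full(cent, file.path(out, paste0("centrality_", g, ".csv")))
    if (isTRUE(config$plots)) {
      grDevices::pdf(file.path(out, paste0("network_", g, ".pdf")))
      plot(fits[[g]], threshold = config$plot_threshold)
      grDevices::dev.off()
    }
  }

  stability <- list()
  if (isTRUE(config$stability)) {
    for (g in names(groups)) {
      stability[[g]] <- run_stage(paste0("stability:", g), {
        boot <- bootstrap_edges(groups[[g]], n_boot = config$n_boot,
                                seed = config$seed,
                                covariates = config$covariates,
                                refit = config$refit)
        cs_in <- case_drop_cs(
          groups[[g]], "in_ei", seed = config$seed,
          drop_grid = config$cs$drop_grid,
          reps_per_level = config$cs$reps_per_level,
          correlation_threshold = config$cs$correlation_threshold,
          confidence = config$cs$confidence,
          covariates = config$covariates, refit = config$refit)
        cs_out <- case_drop_cs(
          groups[[g]], "out_ei", seed = config$seed,
          drop_grid = config$cs$drop_grid,
          reps_per_level = config$cs$reps_per_level,
          correlation_threshold = config$cs$correlation_threshold,
          confidence = config$cs$confidence,
          covariates = config$covariates, refit = config$refit)
        list(boot = boot, cs_in = cs_in, cs_out = cs_out)
      })
      s <- stability[[g]]
      jsonlite::write_json(
        list(edge_ci = s$boot$ci,
             cs = list(in_ei = s$cs_in$cs_value, out_ei = s$cs_out$cs_value),
             n_boot = s$boot$n_boot, refit = s$boot$refit,
             degenerate_replicates = sum(s$boot$degenerate),
             edge_difference = difference_matrix(s$boot, "edge"),
             in_ei_difference = difference_matrix(s$boot, "in_ei"),
             out_ei_difference = difference_matrix(s$boot, "out_ei"),
             seed = config$seed),
        file.path(out, paste0("stability_", g, ".json")),
        auto_unbox = TRUE, digits = NA)
    }
  }

  comp <- run_stage("compare", {
    gs <- names(fits)
    lapply(c(TRUE, FALSE), function(diag) {
      M <- matrix(NA_real_, length(gs), length(gs), dimnames = list(gs, gs))
      P <- M
      for (i in seq_along(gs)) for (j in seq_along(gs)) {
        nc <- network_correlation(fits[[gs[i]]], fits[[gs[j]]],
                                  include_diagonal = diag)
        M[i, j] <- nc$r
        P[i, j] <- nc$p_value
      }
      list(r = M, p = P)
    })
  })
  for (k in 1:2) {
    fn <- if (k == 1) "network_correlation.csv" else
      "network_correlation_offdiag.csv"
    df <- as.data.frame(comp[[k]]$r)
    df <- cbind(group = rownames(comp[[k]]$r), df)
    write_csv_full(df, file.path(out, fn))
  }

  jsonlite::write_json(
    list(package = "clpnet",
         package_version = as.character(utils::packageVersion("clpnet")),
         r_version = paste(R.version$major, R.version$minor, sep = "."),
         seed = config$seed,
         config = config[setdiff(names(config), "panel")]),
    file.path(out, "manifest.json"), auto_unbox = TRUE, digits = NA)

  res <- list(stratification = strat, fits = fits, stability = stability,
              comparison = comp[[1]]$r, comparison_offdiag = comp[[2]]$r)
  invisible(structure(out, results = res))
}
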