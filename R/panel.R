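#' Default PHQ-9 item labels
#'
#' Short field-standard labels for the nine PHQ-9 symptom items, in
#' questionnaire order.
#'
#' @return Character vector of length 9.
#' @export
phq9_items <- function() {
  c("anhedonia", "depressed_mood", "sleep", "lack_of_energy", "appetite",
    "guilt", "concentration", "motor", "suicidal_ideation")
}

#' Construct a two-wave symptom panel
#'
#' A `symptom_panel` holds complete ordinal item scores (0-3) for every
#' subject at two waves (T1, T2), plus optional per-subject covariates.
#' Subjects with any missing or out-of-range score are rejected: only
#' completers enter the analysis.
#'
#' @param t1,t2 Numeric matrices or data frames, subjects x items, with
#'   integer scores in `{0,1,2,3}`. Must have identical dimensions.
#' @param covariates Optional data frame of per-subject numeric/binary
#'   covariates (e.g. sex, age, exposure indicators); must be complete.
#' @param subject_id Optional vector of unique subject identifiers; defaults
#'   to `1:n`.
#' @param item_labels Item names; defaults to [phq9_items()] when there are
#'   nine items.
#'
#' @return An object of class `symptom_panel`: a list with elements
#'   `t1`, `t2` (integer matrices), `covariates` (data frame or `NULL`),
#'   `subject_id`, `item_labels`.
#' @export
symptom_panel <- function(t1, t2, covariates = NULL, subject_id = NULL,
                          item_labels = NULL) {
  t1 <- as.matrix(t1)
  t2 <- as.matrix(t2)
  if (!all(dim(t1) == dim(t2)))
    stop("t1 and t2 must have identical dimensions", call. = FALSE)
  n <- nrow(t1)
  p <- ncol(t1)
  if (is.null(item_labels))
    item_labels <- if (p == 9) phq9_items() else paste0("item", seq_len(p))
  if (length(item_labels) != p)
    stop("item_labels must have one entry per item", call. = FALSE)
  if (is.null(subject_id)) subject_id <- seq_len(n)
  if (anyDuplicated(subject_id))
    stop("subject_id must be unique", call. = FALSE)
  for (w in list(T1 = t1, T2 = t2)) {
    bad <- !is.finite(w) | w != round(w) | w < 0 | w > 3
    if (any(bad)) {
      idx <- which(bad, arr.ind = TRUE)
      stop(sprintf(
        "invalid item score (must be integer in 0..3): subject row %d, item %d",
        idx[1, 1], idx[1, 2]), call. = FALSE)
    }
  }
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != n)
      stop("covariates must have one row per subject", call. = FALSE)
    num <- vapply(covariates, is.numeric, logical(1))
    if (!all(num))
      stop("covariate columns must be numeric", call. = FALSE)
    if (!all(vapply(covariates, function(x) all(is.finite(x)), logical(1))))
      stop("covariate columns must be complete and finite", call. = FALSE)
  }
  storage.mode(t1) <- "integer"
  storage.mode(t2) <- "integer"
  dimnames(t1) <- list(NULL, item_labels)
  dimnames(t2) <- list(NULL, item_labels)
  structure(
    list(t1 = t1, t2 = t2, covariates = covariates,
         subject_id = subject_id, item_labels = item_labels),
    class = "symptom_panel")
}

#' @export
print.symptom_panel <- function(x, ...) {
  cat(sprintf("Two-wave symptom panel: %d subjects, %d items, 2 waves\n",
              nrow(x$t1), ncol(x$t1)))
  if (!is.null(x$covariates))
    cat("Covariates:", paste(names(x$covariates), collapse = ", "), "\n")
  invisible(x)
}

#' Number of subjects in a panel
#' @param panel A [symptom_panel()].
#' @return Integer subject count.
#' @export
n_subjects <- function(panel) {
  stopifnot(inherits(panel, "symptom_panel"))
  nrow(panel$t1)
}

#' Read a wide-format panel CSV
#'
#' Expects one row per subject with one column per item x wave
#' (default names `phq1_t1 ... phq9_t1, phq1_t2 ... phq9_t2`) and optional
#' covariate columns. Rows with missing or out-of-range scores are dropped
#' listwise by default (completers-only), with a per-row validation report
#' attached; in strict mode they raise an error instead.
#'
#' @param path CSV file path (header row required, UTF-8).
#' @param item_columns Optional list with elements `t1` and `t2`, each a
#'   character vector of 9 column names; defaults to `phq{1..9}_t1/_t2`.
#' @param covariate_columns Optional character vector of covariate column
#'   names.
#' @param drop_incomplete If `TRUE` (default) rows violating completeness or
#'   the 0-3 score range are excluded; if `FALSE` any violation is an error.
#' @param item_labels Passed to [symptom_panel()].
#'
#' @return A `symptom_panel` with an attribute `"validation"`: a data frame
#'   listing dropped rows and the offending column.
#' @export
read_panel <- function(path, item_columns = NULL, covariate_columns = NULL,
                       drop_incomplete = TRUE, item_labels = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(item_columns))
    item_columns <- list(t1 = paste0("phq", 1:9, "_t1"),
                         t2 = paste0("phq", 1:9, "_t2"))
  dat <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  need <- c(item_columns$t1, item_columns$t2, covariate_columns)
  missing_cols <- setdiff(need, names(dat))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  score_cols <- c(item_columns$t1, item_columns$t2)
  scores <- as.matrix(dat[score_cols])
  ok_cell <- is.finite(scores) & scores == round(scores) & scores >= 0 & scores <= 3
  bad_rows <- which(!apply(ok_cell, 1, all))
  report <- if (length(bad_rows)) {
    first_bad <- vapply(bad_rows, function(r) score_cols[which(!ok_cell[r, ])[1]],
                        character(1))
    data.frame(row = bad_rows, column = first_bad,
               reason = "missing or out-of-range score")
  } else {
    data.frame(row = integer(0), column = character(0), reason = character(0))
  }
  if (length(bad_rows) && !drop_incomplete) {
    stop(sprintf("validation error: row %d, column '%s' has a missing or out-of-range score",
                 report$row[1], report$column[1]), call. = FALSE)
  }
  keep <- setdiff(seq_len(nrow(dat)), bad_rows)
  if (!length(keep)) stop("no complete subjects remain after validation", call. = FALSE)
  dat <- dat[keep, , drop = FALSE]
  covs <- if (!is.null(covariate_columns)) dat[covariate_columns] else NULL
  sid <- if ("subject_id" %in% names(dat)) dat$subject_id else keep
  panel <- symptom_panel(dat[item_columns$t1], dat[item_columns$t2],
                         covariates = covs, subject_id = sid,
                         item_labels = item_labels)
  attr(panel, "validation") <- report
  panel
}

#' Write a panel to a wide-format CSV
#'
#' Inverse of [read_panel()]: writes `phq{1..9}_t1/_t2` score columns,
#' `subject_id`, and any covariate columns.
#'
#' @param panel A [symptom_panel()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "symptom_panel"))
  out <- data.frame(subject_id = panel$subject_id)
  t1 <- as.data.frame(panel$t1)
  t2 <- as.data.frame(panel$t2)
  names(t1) <- paste0("phq", seq_along(panel$item_labels), "_t1")
  names(t2) <- paste0("phq", seq_along(panel$item_labels), "_t2")
  out <- cbind(out, t1, t2)
  if (!is.null(panel$covariates)) out <- cbind(out, panel$covariates)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Cronbach's alpha for one wave of a panel
#'
#' Internal-consistency reliability of the item set at a wave:
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(item sum))`,
#' with sample variances (denominator n-1).
#'
#' @param panel A [symptom_panel()].
#' @param wave `"t1"` or `"t2"`.
#' @return Alpha in `(-Inf, 1]`.
#' @export
cronbach_alpha <- function(panel, wave = c("t1", "t2")) {
  stopifnot(inherits(panel, "symptom_panel"))
  wave <- match.arg(wave)
  x <- panel[[wave]]
  if (nrow(x) < 2 || ncol(x) < 2)
    stop("cronbach_alpha requires at least 2 subjects and 2 items", call. = FALSE)
  total_var <- stats::var(rowSums(x))
  if (total_var <= 0)
    stop("total-score variance is zero; reliability is undefined", call. = FALSE)
  k <- ncol(x)
  item_var <- sum(apply(x, 2, stats::var))
  k / (k - 1) * (1 - item_var / total_var)
}

#' Write a CLPN edge list to CSV
#'
#' Writes all `p*p` directed edges (including exact zeros: no silent
#' thresholding) as `source_label,target_label,weight,is_autoregressive`.
#' Weights are written with 17 significant digits so a read-back reproduces
#' them bit-exactly.
#'
#' @param fit A fitted [clpn()] object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @seealso [read_edgelist()]
#' @export
write_edgelist <- function(fit, path) {
  stopifnot(inherits(fit, "clpn"))
  B <- fit$edge_matrix
  labs <- fit$item_labels
  p <- length(labs)
  idx <- expand.grid(source = seq_len(p), target = seq_len(p))
  lines <- c(
    "source_label,target_label,weight,is_autoregressive",
    sprintf("%s,%s,%s,%s",
            labs[idx$source], labs[idx$target],
            sprintf("%.17g", B[cbind(idx$source, idx$target)]),
            ifelse(idx$source == idx$target, "TRUE", "FALSE")))
  con <- tryCatch(file(path, "w", encoding = "UTF-8"),
                  error = function(e) stop("cannot write to ", path, call. = FALSE))
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a CLPN edge list written by [write_edgelist()]
#'
#' @param path CSV path.
#' @return Data frame with columns `source_label`, `target_label`,
#'   `weight`, `is_autoregressive`.
#' @export
read_edgelist <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Rebuild an edge matrix from an edge-list data frame
#'
#' @param edges Data frame as returned by [read_edgelist()].
#' @param item_labels Node ordering for rows/columns; defaults to order of
#'   first appearance.
#' @return A p x p numeric matrix, entry (i, j) = weight of edge i -> j.
#' @export
edgelist_to_matrix <- function(edges, item_labels = NULL) {
  if (is.null(item_labels)) item_labels <- unique(edges$source_label)
  p <- length(item_labels)
  B <- matrix(0, p, p, dimnames = list(item_labels, item_labels))
  B[cbind(match(edges$source_label, item_labels),
          match(edges$target_label, item_labels))] <- edges$weight
  B
}
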