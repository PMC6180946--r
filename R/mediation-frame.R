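#' Assemble a role-tagged mediation data set
#'
#' Bundles a continuous outcome with exposure, mediator, and (optionally)
#' confounder columns, tagging each column with its causal role. Rows with
#' a missing value in any used column are dropped (listwise deletion) and
#' the number of dropped rows is recorded and reported via a message.
#'
#' @param data A data frame (or path handled by the caller) holding all
#'   columns; only the named columns are retained.
#' @param outcome Name of the continuous outcome column.
#' @param exposures Character vector of exposure column names.
#' @param mediators Character vector of mediator column names.
#' @param confounders Optional character vector of confounder column names.
#' @param quiet If `TRUE`, suppress the dropped-row message.
#'
#' @return An object of class `"mediation_frame"`: a list with elements
#'   `y` (outcome vector), `X` (exposure matrix), `M` (mediator matrix),
#'   `C` (confounder matrix, possibly zero columns), the role name vectors,
#'   `n`, and `n_dropped`.
#'
#' @examples
#' d <- data.frame(x = rnorm(50), m = rnorm(50), y = rnorm(50))
#' mf <- mediation_frame(d, outcome = "y", exposures = "x", mediators = "m")
#' mf$n
#' @export
mediation_frame <- function(data, outcome, exposures, mediators,
                            confounders = NULL, quiet = FALSE) {
  data <- as.data.frame(data)
  roles <- list(outcome = outcome, exposures = exposures,
                mediators = mediators, confounders = confounders)
  cols <- unlist(roles, use.names = FALSE)
  if (anyDuplicated(cols))
    emc_abort("role_overlap", sprintf(
      "column(s) %s assigned to more than one role",
      paste(unique(cols[duplicated(cols)]), collapse = ", ")))
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols))
    emc_abort("unknown_column", sprintf(
      "column(s) not found in data: %s", paste(missing_cols, collapse = ", ")))
  dat <- data[cols]
  not_num <- cols[!vapply(dat, is.numeric, logical(1))]
  if (length(not_num))
    emc_abort("non_numeric_column", sprintf(
      "non-numeric column(s): %s", paste(not_num, collapse = ", ")))

  keep <- stats::complete.cases(dat)
  n_dropped <- sum(!keep)
  dat <- dat[keep, , drop = FALSE]
  if (n_dropped > 0L && !quiet)
    message(sprintf("mediation_frame: dropped %d row(s) with missing values",
                    n_dropped))
  n <- nrow(dat)
  # a generous lower bound; the real n > k check happens at fit time
  if (n < length(cols) + 1L)
    emc_abort("too_few_rows", sprintf(
      "only %d complete rows for %d model columns", n, length(cols)))

  structure(list(
    y = dat[[outcome]],
    X = as.matrix(dat[exposures]),
    M = as.matrix(dat[mediators]),
    C = if (length(confounders)) as.matrix(dat[confounders])
        else matrix(numeric(0), nrow = n, ncol = 0),
    outcome = outcome,
    exposures = exposures,
    mediators = mediators,
    confounders = confounders %||% character(0),
    n = n,
    n_dropped = n_dropped
  ), class = "mediation_frame")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.mediation_frame <- function(x, ...) {
  cat("<mediation_frame> n =", x$n,
      if (x$n_dropped) sprintf("(%d rows dropped)", x$n_dropped), "\n")
  cat("  outcome:    ", x$outcome, "\n")
  cat("  exposures:  ", paste(x$exposures, collapse = ", "), "\n")
  cat("  mediators:  ", paste(x$mediators, collapse = ", "), "\n")
  if (length(x$confounders))
    cat("  confounders:", paste(x$confounders, collapse = ", "), "\n")
  invisible(x)
}

# raw column lookup across roles
frame_column <- function(frame, name) {
  if (name %in% frame$exposures) return(frame$X[, name])
  if (name %in% frame$mediators) return(frame$M[, name])
  if (name %in% frame$confounders) return(frame$C[, name])
  emc_abort("unknown_column", sprintf("column '%s' has no role in the frame",
                                      name))
}

frame_role <- function(frame, name) {
  if (name %in% frame$exposures) return("exposure")
  if (name %in% frame$mediators) return("mediator")
  if (name %in% frame$confounders) return("confounder")
  emc_abort("unknown_column", sprintf("column '%s' has no role in the frame",
                                      name))
}
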