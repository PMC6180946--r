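#' Declare the exposure basis and interaction terms of the full model
#'
#' The outcome model allows each exposure to enter through a flexible basis
#' h(X) — identity, powers, log, or a linear spline — and allows pairwise
#' interaction terms between declared columns. Mediators and confounders
#' always enter linearly as main effects; interactions are declared
#' explicitly.
#'
#' Term codes, per exposure:
#' \describe{
#'   \item{`"identity"`}{the column itself (the default).}
#'   \item{`"power:d"`}{the d-th power, e.g. `"power:2"` for a quadratic.}
#'   \item{`"log"`}{natural log (requires positive values).}
#'   \item{`"spline:k1,k2,..."`}{linear spline: the linear term plus one
#'     hinge `pmax(x - k, 0)` per knot.}
#' }
#'
#' @param exposure_terms Named list mapping exposure column names to a
#'   character vector of term codes. Exposures not named get `"identity"`.
#'   `NULL` means identity for every exposure.
#' @param interactions Character vector of `"A:B"` pairs of raw column
#'   names (exposure, mediator, or confounder). The product column's role
#'   is inferred: any product involving a mediator joins the mediator
#'   block; a mediator-free product involving an exposure joins the
#'   exposure pathway.
#' @param intercept Include an intercept column (default `TRUE`; the
#'   intercept is excluded from the exposure and mediator blocks).
#'
#' @return An object of class `"basis_spec"`.
#' @examples
#' basis_spec(exposure_terms = list(x = c("identity", "power:2")),
#'            interactions = "x:m")
#' @export
basis_spec <- function(exposure_terms = NULL, interactions = NULL,
                       intercept = TRUE) {
  if (!is.null(exposure_terms)) {
    if (!is.list(exposure_terms) || is.null(names(exposure_terms)) ||
        any(!nzchar(names(exposure_terms))))
      emc_abort("bad_spec", "exposure_terms must be a named list")
    for (e in names(exposure_terms)) {
      codes <- exposure_terms[[e]]
      if (anyDuplicated(codes))
        emc_abort("bad_spec", sprintf("duplicate term codes for '%s'", e))
      lapply(codes, parse_term_code)  # validates
    }
  }
  if (!is.null(interactions)) {
    if (anyDuplicated(interactions))
      emc_abort("bad_spec", "duplicate interaction terms")
    bad <- !grepl("^[^:]+:[^:]+$", interactions)
    if (any(bad))
      emc_abort("bad_spec", sprintf("malformed interaction(s): %s",
                                    paste(interactions[bad], collapse = ", ")))
  }
  structure(list(exposure_terms = exposure_terms,
                 interactions = interactions %||% character(0),
                 intercept = isTRUE(intercept)),
            class = "basis_spec")
}

#' @export
print.basis_spec <- function(x, ...) {
  cat("<basis_spec>\n")
  if (is.null(x$exposure_terms)) {
    cat("  exposure terms: identity (default)\n")
  } else {
    for (e in names(x$exposure_terms))
      cat("  ", e, ": ", paste(x$exposure_terms[[e]], collapse = " + "),
          "\n", sep = "")
  }
  if (length(x$interactions))
    cat("  interactions:", paste(x$interactions, collapse = ", "), "\n")
  if (!x$intercept) cat("  (no intercept)\n")
  invisible(x)
}

# Parse a term code into kind + parameters; errors on unknown codes.
parse_term_code <- function(code) {
  if (identical(code, "identity")) return(list(kind = "identity"))
  if (identical(code, "log")) return(list(kind = "log"))
  if (grepl("^power:[0-9]+$", code)) {
    d <- as.integer(sub("^power:", "", code))
    if (d < 1L) emc_abort("bad_spec", "power degree must be >= 1")
    return(list(kind = "power", degree = d))
  }
  if (grepl("^spline:", code)) {
    knots <- suppressWarnings(
      as.numeric(strsplit(sub("^spline:", "", code), ",")[[1]]))
    if (!length(knots) || anyNA(knots))
      emc_abort("bad_spec", sprintf("bad spline knots in '%s'", code))
    return(list(kind = "spline", knots = sort(knots)))
  }
  emc_abort("bad_spec", sprintf("unknown term code '%s'", code))
}

# Expand one term code for exposure `e` into a list of column definitions,
# each with a label and an evaluator f(x) applied to the raw exposure value.
expand_exposure_term <- function(e, code) {
  t <- parse_term_code(code)
  switch(t$kind,
    identity = list(list(label = e, f = function(v) v)),
    power = {
      d <- t$degree
      list(list(label = sprintf("%s^%d", e, d), f = function(v) v^d))
    },
    log = list(list(label = sprintf("log(%s)", e), f = function(v) log(v))),
    spline = c(
      list(list(label = e, f = function(v) v)),
      lapply(t$knots, function(k) {
        force(k)
        list(label = sprintf("(%s-%g)+", e, k),
             f = function(v) pmax(v - k, 0))
      })
    )
  )
}
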