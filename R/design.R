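#' Build the role-tagged design matrix of the full outcome model
#'
#' Expands a [basis_spec()] against a [mediation_frame()] into the design
#' matrix of the full model E[Y | X, M, C]. Columns are ordered intercept,
#' exposure basis terms, confounder main effects, mediator main effects,
#' then declared interactions, and each column carries a role tag:
#' \describe{
#'   \item{intercept}{excluded from all coefficient blocks.}
#'   \item{exposure-pathway}{mediator-free columns involving an exposure,
#'     including exposure-by-confounder and exposure-by-exposure products;
#'     these are the columns whose coefficients change between the full
#'     and marginal models.}
#'   \item{confounder}{confounder main effects (and confounder-only
#'     products).}
#'   \item{mediator-block}{any column whose product involves a mediator,
#'     including exposure-by-mediator products.}
#' }
#'
#' @param frame A [mediation_frame()].
#' @param spec A [basis_spec()]; `NULL` means identity basis, no
#'   interactions.
#' @return An object of class `"emc_design"` with elements `values`
#'   (n-by-k matrix), `labels`, `roles`, per-column term metadata, the
#'   originating frame, and sample means of the confounders and mediators
#'   (used as default reference values).
#' @seealso [fit_ols()], [emc_contrast()]
#' @examples
#' d <- data.frame(x = c(0, 0, 1, 1), m = c(0, 1, 1, 2), y = c(0, 1, 1, 2))
#' mf <- mediation_frame(d, "y", "x", "m")
#' des <- build_design(mf, basis_spec())
#' des$roles
#' @export
build_design <- function(frame, spec = NULL) {
  stopifnot(inherits(frame, "mediation_frame"))
  if (is.null(spec)) spec <- basis_spec()
  stopifnot(inherits(spec, "basis_spec"))

  if (!is.null(spec$exposure_terms)) {
    unknown <- setdiff(names(spec$exposure_terms), frame$exposures)
    if (length(unknown))
      emc_abort("unknown_column", sprintf(
        "exposure_terms references non-exposure column(s): %s",
        paste(unknown, collapse = ", ")))
  }

  n <- frame$n
  terms <- list()
  add <- function(label, role, values, kind, ...) {
    terms[[length(terms) + 1L]] <<- c(
      list(label = label, role = role, values = values, kind = kind),
      list(...))
  }

  if (spec$intercept)
    add("(Intercept)", "intercept", rep(1, n), "intercept")

  # exposure basis terms, frame order; declared order within an exposure
  for (e in frame$exposures) {
    codes <- spec$exposure_terms[[e]] %||% "identity"
    for (code in codes) {
      for (col in expand_exposure_term(e, code)) {
        add(col$label, "exposure-pathway", col$f(frame$X[, e]),
            "basis", exposure = e, f = col$f)
      }
    }
  }

  for (cc in frame$confounders)
    add(cc, "confounder", frame$C[, cc], "main", confounder = cc)

  for (m in frame$mediators)
    add(m, "mediator-block", frame$M[, m], "main", mediator = m)

  for (ia in spec$interactions) {
    pair <- strsplit(ia, ":", fixed = TRUE)[[1]]
    ra <- frame_role(frame, pair[1]); rb <- frame_role(frame, pair[2])
    va <- frame_column(frame, pair[1]); vb <- frame_column(frame, pair[2])
    role <- if ("mediator" %in% c(ra, rb)) "mediator-block"
            else if ("exposure" %in% c(ra, rb)) "exposure-pathway"
            else "confounder"
    add(paste(pair, collapse = ":"), role, va * vb, "interaction",
        pair = pair, pair_roles = c(ra, rb))
  }

  labels <- vapply(terms, `[[`, character(1), "label")
  if (anyDuplicated(labels))
    emc_abort("bad_spec", sprintf("duplicate design columns: %s",
      paste(unique(labels[duplicated(labels)]), collapse = ", ")))
  values <- do.call(cbind, lapply(terms, function(t) unname(t$values)))
  dimnames(values) <- list(NULL, labels)
  roles <- vapply(terms, `[[`, character(1), "role")
  k <- ncol(values)
  if (n <= k)
    emc_abort("too_few_rows", sprintf("n = %d rows for k = %d columns", n, k))

  sv <- svd(values, nu = 0, nv = 0)$d
  if (any(sv < 1e-10 * sv[1]))
    emc_abort("rank_deficient", sprintf(
      "design matrix is rank deficient (rank %d < k = %d)",
      sum(sv >= 1e-10 * sv[1]), k))

  structure(list(
    values = values, labels = labels, roles = roles,
    terms = lapply(terms, function(t) t[setdiff(names(t), "values")]),
    frame = frame, n = n, k = k,
    confounder_means = if (length(frame$confounders))
      colMeans(frame$C) else numeric(0),
    mediator_means = colMeans(frame$M),
    spec = spec
  ), class = "emc_design")
}

#' @export
print.emc_design <- function(x, ...) {
  cat(sprintf("<emc_design> %d x %d\n", x$n, x$k))
  print(data.frame(column = x$labels, role = x$roles), row.names = FALSE)
  invisible(x)
}

# Evaluate one exposure-pathway column at a raw exposure setting.
# x: named numeric over exposures; cref: named numeric over confounders.
eval_pathway_term <- function(term, x, cref) {
  switch(term$kind,
    basis = term$f(x[[term$exposure]]),
    interaction = {
      pr <- term$pair_roles
      val <- function(name, role) switch(role,
        exposure = x[[name]],
        confounder = cref[[name]],
        emc_abort("bad_spec", "mediator term in pathway evaluation"))
      val(term$pair[1], pr[1]) * val(term$pair[2], pr[2])
    },
    emc_abort("bad_spec", sprintf("cannot evaluate term kind '%s'",
                                  term$kind))
  )
}
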