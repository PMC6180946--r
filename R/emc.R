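#' Compute the essential mediation components (EMCs)
#'
#' The EMCs are the changes in the exposure-pathway coefficients between
#' the marginal model E[Y | X, C] and the full model E[Y | X, M, C]:
#' Delta = beta_X_star - beta_X. They are obtained from the single full
#' fit as Delta = -V_XM V_M^{-1} beta_M, with fully conditional covariance
#' Cov(Delta | X, M) = V_XM V_M^{-1} V_MX, where V_XM and V_M are blocks
#' of the coefficient covariance matrix. No submodel is ever fit.
#'
#' @param fit An [fit_ols()] result with at least one mediator-block
#'   column.
#' @return An object of class `"emc"`: `delta` (named vector over the
#'   exposure-pathway columns), `cov_delta`, degrees of freedom `df`, and
#'   `labels`.
#' @examples
#' d <- data.frame(x = c(0, 0, 1, 1), m = c(0, 1, 1, 2), y = c(0, 1, 1, 2))
#' fit <- fit_ols(build_design(mediation_frame(d, "y", "x", "m")))
#' compute_emc(fit)$delta   # equals 1: the full-model slope of x is 0
#' @export
compute_emc <- function(fit) {
  blk <- partition_blocks(fit)
  # the residual variance cancels in V_XM V_M^{-1}, so the ratio is taken
  # on the unscaled (D'D)^{-1} blocks; this keeps Delta well defined even
  # for a saturated fit with zero residual variance
  xi <- which(fit$roles == "exposure-pathway")
  mi <- which(fit$roles == "mediator-block")
  A_XM <- fit$xtx_inv[xi, mi, drop = FALSE]
  A_M <- fit$xtx_inv[mi, mi, drop = FALSE]
  W <- tryCatch(solve(A_M, cbind(blk$beta_M, t(A_XM))),
                error = function(e) emc_abort("singular_mediator_block",
                  paste("mediator covariance block is numerically singular:",
                        conditionMessage(e))))
  delta <- drop(-A_XM %*% W[, 1L])
  cov_delta <- fit$sigma2 * (A_XM %*% W[, -1L, drop = FALSE])
  cov_delta <- (cov_delta + t(cov_delta)) / 2   # enforce symmetry
  names(delta) <- blk$labels_X
  dimnames(cov_delta) <- list(blk$labels_X, blk$labels_X)
  structure(list(delta = delta, cov_delta = cov_delta,
                 df = fit$df, labels = blk$labels_X),
            class = "emc")
}

#' @export
print.emc <- function(x, ...) {
  cat("<emc> exposure-pathway coefficient changes (df =", x$df, ")\n")
  print(data.frame(column = x$labels, delta = x$delta,
                   se = sqrt(pmax(diag(x$cov_delta), 0))),
        row.names = FALSE)
  invisible(x)
}

#' Evaluate an exposure contrast h(x) - h(x*)
#'
#' Mediation effects are defined for a pair of exposure levels (x, x*).
#' This evaluates the difference of the exposure basis between the two
#' levels over the exposure-pathway columns, with confounders (entering
#' via exposure-confounder interactions) held at reference values.
#'
#' @param design An [build_design()] result or an [fit_ols()] result that
#'   retains its design.
#' @param x,x_star Exposure levels. Scalars for a single exposure, or
#'   named vectors over the exposure columns.
#' @param confounders Named reference values for confounders appearing in
#'   exposure-confounder interactions; defaults to the sample means.
#' @return An object of class `"emc_contrast"` with the evaluated
#'   difference vector `h_diff` (named over exposure-pathway columns),
#'   the raw per-exposure differences `x_diff`, and the settings used.
#' @examples
#' d <- data.frame(x = rnorm(40), m = rnorm(40), y = rnorm(40))
#' des <- build_design(mediation_frame(d, "y", "x", "m"))
#' emc_contrast(des, x = 1, x_star = 0)$h_diff
#' @export
emc_contrast <- function(design, x = 1, x_star = 0, confounders = NULL) {
  if (inherits(design, "emc_fit")) design <- design$design
  stopifnot(inherits(design, "emc_design"))
  exps <- design$frame$exposures
  x <- resolve_levels(x, exps); x_star <- resolve_levels(x_star, exps)
  cref <- as.list(design$confounder_means)
  if (!is.null(confounders)) cref[names(confounders)] <- confounders

  pw <- design$terms[design$roles == "exposure-pathway"]
  h_diff <- vapply(pw, function(t)
    eval_pathway_term(t, x, cref) - eval_pathway_term(t, x_star, cref),
    numeric(1))
  names(h_diff) <- vapply(pw, `[[`, character(1), "label")
  if (any(!is.finite(h_diff)))
    emc_abort("bad_spec", "contrast evaluates to non-finite values")
  structure(list(h_diff = h_diff, x = x, x_star = x_star,
                 x_diff = unlist(x) - unlist(x_star),
                 confounders = unlist(cref)),
            class = "emc_contrast")
}

resolve_levels <- function(v, exposures) {
  if (is.null(names(v))) {
    if (length(v) != length(exposures))
      emc_abort("bad_spec",
                "unnamed exposure levels must match the number of exposures")
    names(v) <- exposures
  }
  missing <- setdiff(exposures, names(v))
  if (length(missing))
    emc_abort("bad_spec", sprintf("no level given for exposure(s): %s",
                                  paste(missing, collapse = ", ")))
  as.list(v[exposures])
}

#' Contrast marginalized over confounders in exposure-confounder models
#'
#' When the full model contains exposure-by-confounder interactions, the
#' indirect effect marginalized over the confounder places (x - x*) in
#' the exposure slot and (x - x*) E[C] in each interaction slot. This is
#' [emc_contrast()] with confounders fixed at their sample means (or
#' user-supplied expectations).
#'
#' @inheritParams emc_contrast
#' @param confounder_means Optional named expectations E[C]; defaults to
#'   sample means.
#' @return An `"emc_contrast"`.
#' @export
confounder_marginal_contrast <- function(design, x = 1, x_star = 0,
                                         confounder_means = NULL) {
  emc_contrast(design, x = x, x_star = x_star,
               confounders = confounder_means)
}

# internal: one-row classed data frame holding a labeled effect
new_effect <- function(label, estimate, se, df, ci_level, method = "model") {
  se <- max(se, 0)
  half <- if (se > 0) stats::qt(1 - (1 - ci_level) / 2, df) * se else 0
  structure(data.frame(label = label, estimate = estimate, se = se,
                       df = df, ci_level = ci_level,
                       ci_low = estimate - half, ci_high = estimate + half,
                       method = method, stringsAsFactors = FALSE),
            class = c("emc_effect", "data.frame"))
}

#' Mediation effect for a contrast, from the EMCs
#'
#' Applies a contrast to the EMC vector: estimate = [h(x) - h(x*)] Delta,
#' with squared standard error [h(x) - h(x*)] Cov(Delta) [h(x) - h(x*)]'
#' and a symmetric two-sided t interval on n - k degrees of freedom. For
#' models without exposure-mediator interaction this is both the natural
#' indirect effect and the portion eliminated.
#'
#' @param emc A [compute_emc()] result.
#' @param contrast An [emc_contrast()].
#' @param label Effect label for the output row (default `"NIE"`).
#' @param ci_level Two-sided confidence level (default 0.95).
#' @return A one-row data frame of class `"emc_effect"` with columns
#'   `label`, `estimate`, `se`, `df`, `ci_low`, `ci_high`.
#' @export
mediation_effect <- function(emc, contrast, label = "NIE", ci_level = 0.95) {
  stopifnot(inherits(emc, "emc"), inherits(contrast, "emc_contrast"))
  h <- contrast$h_diff
  if (length(h) != length(emc$delta) ||
      !identical(names(h), names(emc$delta)))
    emc_abort("bad_spec",
              "contrast is not conformable with the EMC vector")
  est <- sum(h * emc$delta)
  v <- drop(h %*% emc$cov_delta %*% h)
  new_effect(label, est, sqrt(max(v, 0)), emc$df, ci_level)
}
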