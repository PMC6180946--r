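#' Check that the implied marginal model is nested in the full model
#'
#' Marginalizing the mediators out of the full model induces a marginal
#' (total-effect) model for the outcome. With a continuous exposure X and
#' an X-by-mediator interaction, a linear mediator model makes the implied
#' marginal model contain an X^2 term; the single-model framework applies
#' only if that term is already an exposure-pathway column of the full
#' model (or X is binary, in which case X^2 carries no new information).
#'
#' @param spec A [basis_spec()].
#' @param frame Optional [mediation_frame()]; when supplied, exposures
#'   with at most two distinct values are treated as binary. Without a
#'   frame, exposures are assumed continuous.
#' @return A list with `nested` (logical), `implied_terms` (character
#'   labels of exposure terms the marginal model must contain), and
#'   `missing_terms` (those not present in the full model).
#' @export
implied_submodel_check <- function(spec, frame = NULL) {
  if (is.null(spec)) spec <- basis_spec()
  stopifnot(inherits(spec, "basis_spec"))
  implied <- character(0)
  missing <- character(0)
  for (ia in spec$interactions) {
    pair <- strsplit(ia, ":", fixed = TRUE)[[1]]
    if (is.null(frame)) {
      # without data we can only classify by declared exposure terms
      exps <- names(spec$exposure_terms)
      is_exp <- pair %in% exps
      med_side <- pair[!is_exp]
      # heuristic only used when no frame: treat unmatched side as mediator
      if (sum(is_exp) != 1L) next
      e <- pair[is_exp]
      binary <- FALSE
    } else {
      rs <- c(frame_role(frame, pair[1]), frame_role(frame, pair[2]))
      if (!("exposure" %in% rs && "mediator" %in% rs)) next
      e <- pair[rs == "exposure"]
      binary <- length(unique(frame$X[, e])) <= 2L
    }
    if (binary) next
    lab <- sprintf("%s^2", e)
    implied <- union(implied, lab)
    codes <- spec$exposure_terms[[e]] %||% "identity"
    if (!"power:2" %in% codes) missing <- union(missing, lab)
  }
  list(nested = length(missing) == 0L,
       implied_terms = implied, missing_terms = missing)
}

assert_nested <- function(spec, frame) {
  chk <- implied_submodel_check(spec, frame)
  if (!chk$nested)
    emc_abort("non_nested_submodel", sprintf(
      paste("the implied marginal model contains exposure term(s) %s that",
            "are not in the full model; add them (e.g. power:2) to use the",
            "single-model framework"),
      paste(chk$missing_terms, collapse = ", ")))
  invisible(chk)
}

# marginal (total-effect) model: mediator-free columns of the full design
fit_marginal <- function(design) {
  keep <- design$roles != "mediator-block"
  fit_ols(design$values[, keep, drop = FALSE], design$frame$y,
          roles = design$roles[keep])
}

#' Total effect from the fitted marginal model
#'
#' Fits the marginal model E[Y | X, C] containing the exposure-pathway and
#' confounder columns only, and reports TE = [h(x) - h(x*)] beta_star with
#' its own OLS standard error. The total effect is estimated by actually
#' fitting the marginal model, not as the sum NDE + NIE.
#'
#' @inheritParams decompose_effects
#' @return A one-row `"emc_effect"` labeled `"TE"`.
#' @export
fit_total_effect <- function(frame, spec = NULL, x = 1, x_star = 0,
                             confounders = NULL, ci_level = 0.95) {
  design <- build_design(frame, spec)
  assert_nested(spec, frame)
  contrast <- emc_contrast(design, x, x_star, confounders)
  te_from_marginal(fit_marginal(design), contrast, ci_level)
}

te_from_marginal <- function(mfit, contrast, ci_level) {
  h <- contrast$h_diff
  xi <- which(mfit$roles == "exposure-pathway")
  est <- sum(h * mfit$beta[xi])
  v <- drop(h %*% mfit$cov_beta[xi, xi, drop = FALSE] %*% h)
  new_effect("TE", est, sqrt(max(v, 0)), mfit$df, ci_level)
}

#' Fit a linear model for a mediator
#'
#' Regresses a mediator on every mediator-free column of the full design
#' (exposure basis, confounders, and exposure-by-confounder interactions),
#' which is the conditioning set of the outcome model. The coefficients of
#' this fit are exactly the projection weights that map mediator-block
#' coefficients onto the EMCs, so mediation-formula comparators built from
#' it agree with the single-model estimates to machine precision.
#'
#' @param frame A [mediation_frame()].
#' @param spec A [basis_spec()] (defaults to identity basis).
#' @param mediator Mediator column name; default the first mediator.
#' @return An object of class `"mediator_fit"` with `alpha` (coefficients),
#'   `se`, residual variance `sigma2` (SSE / residual df), `df`, and the
#'   term metadata needed to predict E[M | x, C].
#' @export
fit_mediator <- function(frame, spec = NULL, mediator = frame$mediators[1]) {
  if (!mediator %in% frame$mediators)
    emc_abort("unknown_mediator", sprintf("'%s' is not a mediator", mediator))
  design <- build_design(frame, spec)
  keep <- design$roles != "mediator-block"
  mvec <- frame$M[, mediator]
  fit <- fit_ols(design$values[, keep, drop = FALSE], mvec,
                 roles = design$roles[keep])
  structure(list(
    mediator = mediator,
    alpha = fit$beta, se = sqrt(diag(fit$cov_beta)),
    sigma2 = fit$sigma2, df = fit$df, n = fit$n,
    labels = fit$labels, roles = fit$roles,
    terms = design$terms[keep],
    confounder_means = design$confounder_means
  ), class = "mediator_fit")
}

#' @export
print.mediator_fit <- function(x, ...) {
  cat(sprintf("<mediator_fit> %s ~ conditioning set (df = %d)\n",
              x$mediator, x$df))
  print(data.frame(column = x$labels, alpha = x$alpha, se = x$se),
        row.names = FALSE)
  invisible(x)
}

#' Predicted mediator level E[M | x, C = c_ref]
#'
#' @param med_fit A [fit_mediator()] result.
#' @param x Exposure level(s), as in [emc_contrast()].
#' @param confounders Named confounder reference values; default sample
#'   means.
#' @return Scalar predicted mediator value.
#' @export
predict_mediator <- function(med_fit, x, confounders = NULL) {
  cref <- as.list(med_fit$confounder_means)
  if (!is.null(confounders)) cref[names(confounders)] <- confounders
  exps <- unique(unlist(lapply(med_fit$terms, function(t) t$exposure)))
  exps <- exps[!vapply(exps, is.null, logical(1))]
  if (is.null(names(x)) && length(x) == 1L && length(exps) == 1L)
    names(x) <- exps
  xl <- as.list(x)
  vals <- vapply(med_fit$terms, function(t) {
    switch(t$role %||% "",
           `intercept` = 1,
           `confounder` = cref[[t$label]] %||% cref[[t$confounder]],
           eval_pathway_term(t, xl, cref))
  }, numeric(1))
  sum(vals * med_fit$alpha)
}

# exposure-by-mediator interaction columns of a design
xm_terms <- function(design) {
  idx <- which(design$roles == "mediator-block" &
               vapply(design$terms, function(t)
                 identical(t$kind, "interaction") &&
                 "exposure" %in% t$pair_roles, logical(1)))
  lapply(idx, function(i) {
    t <- design$terms[[i]]
    list(index = i, label = t$label,
         exposure = t$pair[t$pair_roles == "exposure"],
         mediator = t$pair[t$pair_roles == "mediator"])
  })
}

#' Full causal effect decomposition from the single model
#'
#' Estimates the total effect (TE, from the fitted marginal model), the
#' controlled direct effect CDE(m), the natural direct effect NDE, the
#' natural indirect effect NIE = TE - NDE, and the portion eliminated
#' PE = TE - CDE(m), for a contrast (x, x*). Without exposure-mediator
#' interaction, CDE = NDE, PE = NIE, and both equal the EMC functional
#' [h(x) - h(x*)] Delta. With interaction, CDE(m) depends on the chosen
#' mediator level m (default: sample mean) and the NDE plugs in the
#' predicted mediator level E[M | x*] from an internally fitted linear
#' mediator model.
#'
#' @param frame A [mediation_frame()].
#' @param spec A [basis_spec()]; `NULL` for the identity basis.
#' @param x,x_star Exposure levels of the contrast (default unit change
#'   1 vs 0).
#' @param m Mediator level(s) for the CDE, as a named vector over the
#'   mediators appearing in exposure-mediator interactions; default
#'   sample means. Ignored when no interaction is present.
#' @param confounders Named confounder reference values; default sample
#'   means.
#' @param ci_level Two-sided confidence level.
#' @return A data frame of class `"emc_effects"` with one row per effect
#'   (TE, CDE, NDE, NIE, PE) and attributes `diagnostics` (nestedness,
#'   dropped rows, and the fitted-vs-implied total effect discrepancy
#'   when an exposure-mediator interaction is present) and `fit`.
#' @examples
#' d <- data.frame(x = rnorm(60))
#' d$m <- 0.5 * d$x + rnorm(60)
#' d$y <- d$x + 2 * d$m + rnorm(60)
#' mf <- mediation_frame(d, "y", "x", "m")
#' decompose_effects(mf)
#' @export
decompose_effects <- function(frame, spec = NULL, x = 1, x_star = 0,
                              m = NULL, confounders = NULL,
                              ci_level = 0.95) {
  if (is.null(spec)) spec <- basis_spec()
  design <- build_design(frame, spec)
  chk <- assert_nested(spec, frame)
  fit <- fit_ols(design)
  contrast <- emc_contrast(design, x, x_star, confounders)
  emc <- compute_emc(fit)
  h <- contrast$h_diff
  xi <- which(fit$roles == "exposure-pathway")
  mfit <- fit_marginal(design)
  te <- te_from_marginal(mfit, contrast, ci_level)

  xm <- xm_terms(design)
  has_inter <- length(xm) > 0L

  # m defaults: sample mean of each interacting mediator
  m_cde <- vapply(xm, function(t) design$mediator_means[[t$mediator]],
                  numeric(1))
  if (has_inter) names(m_cde) <- vapply(xm, `[[`, character(1), "mediator")
  if (!is.null(m) && has_inter) {
    if (is.null(names(m)) && length(m) == length(m_cde)) names(m) <- names(m_cde)
    m_cde[names(m)] <- m
  }
  # NDE mediator levels: E[M_j | x*, C = cref]
  m_nde <- vapply(xm, function(t) {
    mf <- fit_mediator(frame, spec, t$mediator)
    predict_mediator(mf, unlist(contrast$x_star), confounders)
  }, numeric(1))

  direct_effect <- function(label, mlev) {
    cc <- numeric(fit$k)
    cc[xi] <- h
    for (j in seq_along(xm))
      cc[xm[[j]]$index] <- mlev[j] * contrast$x_diff[[xm[[j]]$exposure]]
    est <- sum(cc * fit$beta)
    v <- drop(cc %*% fit$cov_beta %*% cc)
    new_effect(label, est, sqrt(max(v, 0)), fit$df, ci_level)
  }
  cde <- direct_effect("CDE", m_cde)
  nde <- direct_effect("NDE", m_nde)

  indirect_effect <- function(label, mlev) {
    if (!has_inter) {
      eff <- mediation_effect(emc, contrast, label, ci_level)
      return(eff)
    }
    blk <- partition_blocks(fit)
    # coefficient vector over the mediator block for h'Delta - sum m beta_XM dx
    L <- -t(solve(blk$V_M, blk$V_MX))       # p x q
    a <- drop(t(L) %*% h)                   # q-vector
    mi <- which(fit$roles == "mediator-block")
    for (j in seq_along(xm)) {
      pos <- match(xm[[j]]$index, mi)
      a[pos] <- a[pos] - mlev[j] * contrast$x_diff[[xm[[j]]$exposure]]
    }
    est <- sum(a * blk$beta_M)
    v <- drop(a %*% blk$V_M %*% a)
    new_effect(label, est, sqrt(max(v, 0)), fit$df, ci_level)
  }
  # PE = TE - CDE and NIE = TE - NDE; estimated from the full model as
  # [h'Delta - sum_j m_j beta_XMj (x - x*)], identical by the FWL identity
  pe <- indirect_effect("PE", m_cde)
  nie <- indirect_effect("NIE", m_nde)

  diagnostics <- list(nested = chk$nested, implied_terms = chk$implied_terms,
                      n = frame$n, k = fit$k, df = fit$df,
                      n_dropped = frame$n_dropped,
                      m_cde = if (has_inter) m_cde else NULL,
                      m_nde = if (has_inter) m_nde else NULL)
  # fitted vs implied total effect (Remark-E style diagnostic): with a
  # single mediator and one X:M interaction, the mediation-formula NIE is
  # (beta_M + beta_XM x)(E[M|x] - E[M|x*]); the implied TE = NDE + NIE_mf
  # need not equal the fitted TE.
  if (has_inter && length(xm) == 1L && length(frame$mediators) == 1L) {
    t1 <- xm[[1]]
    mf1 <- fit_mediator(frame, spec, t1$mediator)
    em_x <- predict_mediator(mf1, unlist(contrast$x), confounders)
    em_xs <- predict_mediator(mf1, unlist(contrast$x_star), confounders)
    bm <- fit$beta[[t1$mediator]]
    bxm <- fit$beta[[t1$label]]
    nie_mf <- (bm + bxm * contrast$x[[t1$exposure]]) * (em_x - em_xs)
    diagnostics$te_implied <- nde$estimate + nie_mf
    diagnostics$te_discrepancy <- abs(te$estimate - diagnostics$te_implied)
  }

  out <- rbind(te, cde, nde, nie, pe)
  class(out) <- c("emc_effects", "data.frame")
  attr(out, "diagnostics") <- diagnostics
  attr(out, "fit") <- fit
  attr(out, "contrast") <- contrast
  out
}

#' @export
print.emc_effects <- function(x, digits = 4, ...) {
  cat("Causal mediation effect decomposition\n")
  df <- as.data.frame(x)
  df[] <- lapply(df, function(col)
    if (is.numeric(col)) signif(col, digits) else col)
  print(df, row.names = FALSE)
  d <- attr(x, "diagnostics")
  if (!is.null(d$te_discrepancy))
    cat(sprintf("fitted vs implied TE discrepancy: %.4g\n",
                d$te_discrepancy))
  invisible(x)
}
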