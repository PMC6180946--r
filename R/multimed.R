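# Multiple-mediator effects under the single-model framework, plus the
# parallel and serial comparator decompositions.

#' Total indirect effect through a set of mediators
#'
#' From a single full-model fit with j mediators, the total indirect
#' effect for a contrast is [h(x) - h(x*)] Delta with
#' Delta = -V_XM V_M^{-1} beta_M over the whole mediator block, and
#' variance (x - x*)^2 V_XM V_M^{-1} V_MX. No mediator models and no
#' submodels are fit, and no assumption is made about how the mediators
#' affect each other.
#'
#' @param fit Full-model [fit_ols()] (design retained).
#' @param x,x_star Contrast levels.
#' @param confounders Named confounder reference values.
#' @param ci_level Two-sided confidence level.
#' @return A one-row `"emc_effect"` labeled `"total-indirect"`.
#' @export
total_indirect <- function(fit, x = 1, x_star = 0, confounders = NULL,
                           ci_level = 0.95) {
  stopifnot(inherits(fit, "emc_fit"))
  if (is.null(fit$design))
    emc_abort("bad_spec", "fit must retain its design")
  emc <- compute_emc(fit)
  contrast <- emc_contrast(fit$design, x, x_star, confounders)
  mediation_effect(emc, contrast, label = "total-indirect", ci_level)
}

#' Mediator-specific indirect effect
#'
#' The amount of mediation attributable to one mediator above and beyond
#' the other mediators in the model, read off the same single fit using
#' the scalar diagonal block for that mediator:
#' -V_XMi V_Mi^{-1} beta_Mi (x - x*), with variance
#' (x - x*)^2 V_XMi V_Mi^{-1} V_MiX. With correlated mediators the
#' specific effects need not sum to the total indirect effect
#' (inconsistent mediation), analogous to partial sums of squares.
#'
#' @param fit Full-model [fit_ols()] (design retained).
#' @param mediator Mediator column name.
#' @inheritParams total_indirect
#' @return A one-row `"emc_effect"` labeled `"specific-indirect:<name>"`.
#' @export
specific_indirect <- function(fit, mediator, x = 1, x_star = 0,
                              confounders = NULL, ci_level = 0.95) {
  stopifnot(inherits(fit, "emc_fit"))
  if (is.null(fit$design))
    emc_abort("bad_spec", "fit must retain its design")
  frame <- fit$design$frame
  if (!mediator %in% frame$mediators)
    emc_abort("unknown_mediator",
              sprintf("'%s' is not a mediator in the model", mediator))
  mi <- which(fit$labels == mediator)      # the main-effect column
  xi <- which(fit$roles == "exposure-pathway")
  V <- fit$cov_beta
  contrast <- emc_contrast(fit$design, x, x_star, confounders)
  h <- contrast$h_diff
  v_xmi <- drop(h %*% V[xi, mi, drop = FALSE])  # h-weighted cross block
  v_mi <- V[mi, mi]
  est <- -v_xmi / v_mi * fit$beta[[mi]]
  vv <- v_xmi^2 / v_mi
  new_effect(paste0("specific-indirect:", mediator), est, sqrt(max(vv, 0)),
             fit$df, ci_level)
}

new_multimed <- function(method, total, specific, paths = NULL,
                         order = NULL) {
  structure(list(method = method, total_indirect = total,
                 specific = specific, paths = paths, order = order),
            class = "emc_multimed")
}

#' @export
print.emc_multimed <- function(x, digits = 4, ...) {
  cat(sprintf("<%s multiple-mediator decomposition>\n", x$method))
  if (!is.null(x$order))
    cat("  serial order:", paste(x$order, collapse = " -> "), "\n")
  rows <- do.call(rbind, c(list(as.data.frame(x$total_indirect)),
                           lapply(x$specific, as.data.frame)))
  rows[] <- lapply(rows, function(col)
    if (is.numeric(col)) signif(col, digits) else col)
  print(rows, row.names = FALSE)
  invisible(x)
}

#' Parallel (single-step) multiple-mediator decomposition
#'
#' Comparator estimator that assumes the mediators act in parallel
#' without affecting each other: fits the single full outcome model plus
#' one linear regression M_i ~ X (+ C) per mediator, and estimates the
#' indirect effect through M_i as alpha_Xi * beta_Mi with a Sobel
#' standard error. By OLS algebra the per-mediator products sum exactly
#' to the single-model total indirect effect.
#'
#' @param frame A [mediation_frame()] with at least two mediators.
#' @param x,x_star Contrast levels (scalar exposure).
#' @param ci_level Two-sided confidence level.
#' @return An `"emc_multimed"` with method `"parallel"`.
#' @export
parallel_model <- function(frame, x = 1, x_star = 0, ci_level = 0.95) {
  check_comparator_scope(frame)
  design <- build_design(frame, basis_spec())
  fit <- fit_ols(design)
  e <- frame$exposures[1]
  dx <- x - x_star
  specific <- lapply(frame$mediators, function(mname) {
    mf <- fit_mediator(frame, NULL, mname)
    a <- mf$alpha[[e]]; sa <- mf$se[[e]]
    b <- fit$beta[[mname]]; sb <- sqrt(fit$cov_beta[mname, mname])
    sv <- sobel_variance(a, b, sa, sb)
    new_effect(paste0("specific-indirect:", mname), a * b * dx,
               sv$se * abs(dx), fit$df, ci_level, method = "sobel")
  })
  tot_est <- sum(vapply(specific, function(s) s$estimate, numeric(1)))
  tot_se <- sqrt(sum(vapply(specific, function(s) s$se^2, numeric(1))))
  total <- new_effect("total-indirect", tot_est, tot_se, fit$df, ci_level,
                      method = "sobel-sum")
  new_multimed("parallel", total, specific)
}

#' Serial two-mediator decomposition
#'
#' Comparator estimator that assumes a causal ordering M1 -> M2 between
#' exactly two mediators: fits the full outcome model, M2 ~ X + M1
#' (giving alpha_2 and the inter-mediator coefficient delta_21), and
#' M1 ~ X (giving alpha_1). The three path effects alpha1*beta1,
#' alpha2*beta2, and alpha1*delta21*beta2 sum exactly to the total
#' indirect effect for either ordering; the split between them depends
#' on the assumed order. Two-way product variances use Sobel's formula;
#' the three-way product variance is
#' a1^2 d21^2 s_b2^2 + a1^2 b2^2 s_d21^2 + d21^2 b2^2 s_a1^2.
#'
#' @param frame A [mediation_frame()] with exactly two mediators.
#' @param order Character vector: the assumed causal order of the two
#'   mediators (first affects second).
#' @inheritParams parallel_model
#' @return An `"emc_multimed"` with method `"serial"`, the path effects
#'   in `specific`, and the assumed `order`.
#' @export
serial_model <- function(frame, order = frame$mediators, x = 1, x_star = 0,
                         ci_level = 0.95) {
  check_comparator_scope(frame)
  if (length(frame$mediators) != 2L)
    emc_abort("scope_error",
              "the serial decomposition is implemented for exactly 2 mediators")
  if (!setequal(order, frame$mediators) || length(order) != 2L)
    emc_abort("bad_spec", "order must be a permutation of the two mediators")
  m1 <- order[1]; m2 <- order[2]
  e <- frame$exposures[1]
  dx <- x - x_star

  design <- build_design(frame, basis_spec())
  fit <- fit_ols(design)
  b1 <- fit$beta[[m1]]; s_b1 <- sqrt(fit$cov_beta[m1, m1])
  b2 <- fit$beta[[m2]]; s_b2 <- sqrt(fit$cov_beta[m2, m2])

  # M2 ~ X (+C) + M1
  f2 <- mediator_on(frame, response = m2, extra = m1)
  a2 <- f2$beta[[e]]; s_a2 <- sqrt(f2$cov_beta[e, e])
  d21 <- f2$beta[[m1]]; s_d21 <- sqrt(f2$cov_beta[m1, m1])
  # M1 ~ X (+C)
  f1 <- mediator_on(frame, response = m1)
  a1 <- f1$beta[[e]]; s_a1 <- sqrt(f1$cov_beta[e, e])

  v3 <- a1^2 * d21^2 * s_b2^2 + a1^2 * b2^2 * s_d21^2 +
    d21^2 * b2^2 * s_a1^2
  paths <- list(
    new_effect(sprintf("path:%s", m1), a1 * b1 * dx,
               sobel_variance(a1, b1, s_a1, s_b1)$se * abs(dx),
               fit$df, ci_level, method = "sobel"),
    new_effect(sprintf("path:%s", m2), a2 * b2 * dx,
               sobel_variance(a2, b2, s_a2, s_b2)$se * abs(dx),
               fit$df, ci_level, method = "sobel"),
    new_effect(sprintf("path:%s->%s", m1, m2), a1 * d21 * b2 * dx,
               sqrt(v3) * abs(dx), fit$df, ci_level,
               method = "three-way-product")
  )
  tot_est <- sum(vapply(paths, function(s) s$estimate, numeric(1)))
  tot_se <- sqrt(sum(vapply(paths, function(s) s$se^2, numeric(1))))
  total <- new_effect("total-indirect", tot_est, tot_se, fit$df, ci_level,
                      method = "serial-sum")
  new_multimed("serial", total, paths, order = order)
}

# regress one mediator on intercept + exposure(s) + confounders (+ extra
# mediator columns, for the serial submodels)
mediator_on <- function(frame, response, extra = character(0)) {
  n <- frame$n
  cols <- cbind(`(Intercept)` = rep(1, n), frame$X)
  if (ncol(frame$C)) cols <- cbind(cols, frame$C)
  for (mm in extra) cols <- cbind(cols, frame$M[, mm, drop = FALSE])
  roles <- c("intercept", rep("exposure-pathway", ncol(frame$X)),
             rep("confounder", ncol(frame$C)),
             rep("mediator-block", length(extra)))
  fit_ols(cols, frame$M[, response], roles = roles)
}

check_comparator_scope <- function(frame) {
  if (length(frame$exposures) != 1L)
    emc_abort("scope_error",
              "comparator decompositions support a single exposure")
  invisible(TRUE)
}
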