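# Alternative variance estimators for the indirect effect: Sobel delta
# method, the marginal (law-of-total-variance) formula, case and residual
# bootstrap, Monte Carlo, and the moderated-mediation PE variance.

new_variance <- function(method, variance, replicates = NA_integer_,
                         seed = NA_integer_, ci = NULL, skipped = 0L) {
  structure(list(method = method, variance = max(variance, 0),
                 se = sqrt(max(variance, 0)),
                 ci = ci, replicates = replicates, seed = seed,
                 skipped = skipped),
            class = "emc_variance")
}

#' @export
print.emc_variance <- function(x, ...) {
  cat(sprintf("<emc_variance> method = %s, variance = %.6g, se = %.6g\n",
              x$method, x$variance, x$se))
  if (!is.null(x$ci))
    cat(sprintf("  percentile CI: [%.6g, %.6g] (B = %d%s)\n",
                x$ci[1], x$ci[2], x$replicates,
                if (x$skipped) sprintf(", %d skipped", x$skipped) else ""))
  invisible(x)
}

#' Sobel delta-method variance of the product of coefficients
#'
#' First-order delta-method approximation for the variance of the
#' Baron-Kenny product alpha_X * beta_M:
#' alpha_X^2 s_betaM^2 + beta_M^2 s_alphaX^2.
#'
#' @param alpha_X Exposure coefficient from the mediator model.
#' @param beta_M Mediator coefficient from the full outcome model.
#' @param s_alphaX,s_betaM Their standard errors.
#' @return An `"emc_variance"` with method `"sobel"`.
#' @examples
#' sobel_variance(2, 3, 0.5, 0.4)$variance  # 2.89
#' @export
sobel_variance <- function(alpha_X, beta_M, s_alphaX, s_betaM) {
  if (s_alphaX < 0 || s_betaM < 0)
    emc_abort("bad_spec", "standard errors must be nonnegative")
  new_variance("sobel", alpha_X^2 * s_betaM^2 + beta_M^2 * s_alphaX^2)
}

#' Marginal variance of the indirect effect (random mediator)
#'
#' Treats the mediator as random and marginalizes the conditional
#' variance over M given X via the law of total variance:
#' E[ n^2 r_XM^2 sM^2 sY|XM^2 / |D'D| ] + beta_M^2 sM|X^2 / (n sX^2),
#' evaluated by plugging in the sample correlation, the
#' maximum-likelihood (divide-by-n) variances of X and M, the full-model
#' mean squared error, and the mediator-model residual variance. Only
#' defined for the simple mediation model (one identity exposure, one
#' mediator, no confounders or interactions).
#'
#' @param fit Full-model [fit_ols()] (design must be retained).
#' @param med_fit [fit_mediator()] result for the mediator.
#' @param frame The [mediation_frame()].
#' @return An `"emc_variance"` with method `"marginal"`.
#' @export
marginal_variance <- function(fit, med_fit, frame) {
  assert_simple_scope(fit, frame)
  x <- frame$X[, 1]; m <- frame$M[, 1]; n <- frame$n
  r <- stats::cor(x, m)
  s2_m <- mean((m - mean(m))^2)          # MLE variance
  s2_x <- mean((x - mean(x))^2)
  beta_M <- fit$beta[[frame$mediators[1]]]
  term1 <- n^2 * r^2 * s2_m * fit$sigma2 / fit$gram_det
  term2 <- beta_M^2 * med_fit$sigma2 / (n * s2_x)
  new_variance("marginal", term1 + term2)
}

assert_simple_scope <- function(fit, frame) {
  simple <- length(frame$exposures) == 1L && length(frame$mediators) == 1L &&
    length(frame$confounders) == 0L &&
    sum(fit$roles == "exposure-pathway") == 1L &&
    sum(fit$roles == "mediator-block") == 1L
  if (!simple)
    emc_abort("scope_error",
              "only defined for the simple mediation model (one identity exposure, one mediator, no confounders/interactions)")
  invisible(TRUE)
}

#' Bootstrap variance of the indirect effect
#'
#' Case mode resamples rows of (y, X, M, C) jointly and so approximates
#' the fully unconditional variance; residual mode keeps the design fixed
#' and resamples full-model residuals (y* = fitted + r*), approximating
#' the conditional variance. The indirect effect recomputed on each
#' replicate is [h(x) - h(x*)] Delta*.
#'
#' @param frame A [mediation_frame()].
#' @param spec A [basis_spec()] or `NULL`.
#' @param x,x_star Contrast levels.
#' @param mode `"case"` or `"residual"`.
#' @param B Number of bootstrap replicates (default 10000).
#' @param seed Optional integer seed (local to this call).
#' @param confounders Confounder reference values for the contrast.
#' @return An `"emc_variance"` with a 2.5/97.5 percentile CI; replicates
#'   whose resampled design is rank deficient are skipped and counted
#'   (with a warning).
#' @export
bootstrap_variance <- function(frame, spec = NULL, x = 1, x_star = 0,
                               mode = c("case", "residual"), B = 10000,
                               seed = NULL, confounders = NULL) {
  mode <- match.arg(mode)
  if (B < 2) emc_abort("bad_spec", "B must be >= 2")
  design <- build_design(frame, spec)
  fit <- fit_ols(design)
  contrast <- emc_contrast(design, x, x_star, confounders)
  h <- contrast$h_diff
  D <- design$values
  xi <- which(design$roles == "exposure-pathway")
  mi <- which(design$roles == "mediator-block")
  n <- fit$n
  skipped <- 0L

  local_seed(seed)
  if (mode == "residual") {
    # fixed design: (D'D)^{-1} blocks are constant, sigma2 cancels in
    # Delta* = -A_XM A_M^{-1} beta*_M, so only beta*_M varies
    A <- fit$xtx_inv
    Lh <- drop(t(-t(solve(A[mi, mi, drop = FALSE],
                          A[mi, xi, drop = FALSE]))) %*% h)  # over block
    idx <- matrix(sample.int(n, n * B, replace = TRUE), n, B)
    Ystar <- fit$fitted + matrix(fit$residuals[idx], n, B)
    qrD <- qr(D)
    Bstar <- qr.coef(qrD, Ystar)            # k x B
    reps <- drop(Lh %*% Bstar[mi, , drop = FALSE])
  } else {
    reps <- numeric(B)
    keep <- logical(B)
    yy <- frame$y
    for (b in seq_len(B)) {
      idx <- sample.int(n, n, replace = TRUE)
      Db <- D[idx, , drop = FALSE]
      qrb <- qr(Db)
      if (qrb$rank < ncol(Db)) { skipped <- skipped + 1L; next }
      fb <- fit_ols(Db, yy[idx], roles = design$roles)
      blk <- partition_blocks(fb)
      delta <- drop(-blk$V_XM %*% solve(blk$V_M, blk$beta_M))
      reps[b] <- sum(h * delta)
      keep[b] <- TRUE
    }
    reps <- reps[keep]
    if (skipped > 0L)
      emc_warn("degenerate_resample",
               sprintf("%d rank-deficient bootstrap replicate(s) skipped",
                       skipped))
  }
  new_variance(paste0(mode, "-bootstrap"), stats::var(reps),
               replicates = length(reps),
               seed = seed %||% NA_integer_,
               ci = stats::quantile(reps, c(0.025, 0.975), names = FALSE),
               skipped = skipped)
}

#' Monte Carlo variance of the product of coefficients
#'
#' Draws (alpha_X, beta_M) independently from normal distributions
#' centered at their estimates with their squared standard errors, and
#' returns the variance of the drawn products times (x - x*). As the
#' number of draws grows this converges to the exact second moment of a
#' product of independent normals:
#' a^2 s_b^2 + b^2 s_a^2 + s_a^2 s_b^2.
#'
#' @param fit Full-model [fit_ols()] for the simple mediation model.
#' @param med_fit [fit_mediator()] result.
#' @param frame The [mediation_frame()].
#' @param x,x_star Contrast levels (scalar exposure).
#' @param draws Number of Monte Carlo draws (default 10000).
#' @param seed Optional integer seed (local to this call).
#' @return An `"emc_variance"` with method `"monte-carlo"` and a
#'   percentile CI of the drawn products.
#' @export
monte_carlo_variance <- function(fit, med_fit, frame, x = 1, x_star = 0,
                                 draws = 10000, seed = NULL) {
  assert_simple_scope(fit, frame)
  e <- frame$exposures[1]; mname <- frame$mediators[1]
  a <- med_fit$alpha[[e]]; sa <- med_fit$se[[e]]
  b <- fit$beta[[mname]]; sb <- sqrt(fit$cov_beta[mname, mname])
  local_seed(seed)
  prods <- stats::rnorm(draws, a, sa) * stats::rnorm(draws, b, sb) *
    (x - x_star)
  new_variance("monte-carlo", stats::var(prods), replicates = draws,
               seed = seed %||% NA_integer_,
               ci = stats::quantile(prods, c(0.025, 0.975), names = FALSE))
}

#' Variance of the portion eliminated under exposure-mediator interaction
#'
#' With an exposure-mediator interaction the portion eliminated at
#' mediator level m is estimated from the full model as
#' [Delta - beta_XM m](x - x*); its variance is the quadratic form of the
#' corresponding coefficient combination over the mediator block:
#' (x - x*)^2 [V_XM V_M^{-1} V_MX + m^2 Var(beta_XM)
#' - 2 m V_XM V_M^{-1} Cov(beta_M-block, beta_XM)].
#'
#' @param fit Full-model [fit_ols()] whose design contains exactly one
#'   exposure-mediator interaction column.
#' @param m Mediator level at which the PE is evaluated.
#' @param x,x_star Contrast levels for the (single) exposure.
#' @return An `"emc_variance"` with method `"interaction-pe"`.
#' @export
interaction_pe_variance <- function(fit, m, x = 1, x_star = 0) {
  stopifnot(inherits(fit, "emc_fit"))
  if (is.null(fit$design))
    emc_abort("bad_spec", "fit must retain its design")
  xm <- xm_terms(fit$design)
  if (!length(xm))
    emc_abort("no_interaction",
              "no exposure-mediator interaction column in the model")
  if (length(xm) > 1L)
    emc_abort("scope_error", "more than one exposure-mediator interaction")
  blk <- partition_blocks(fit)
  contrast <- emc_contrast(fit$design, x, x_star)
  h <- contrast$h_diff
  L <- -t(solve(blk$V_M, blk$V_MX))   # p x q
  a <- drop(t(L) %*% h)
  mi <- which(fit$roles == "mediator-block")
  pos <- match(xm[[1]]$index, mi)
  dx <- contrast$x_diff[[xm[[1]]$exposure]]
  a[pos] <- a[pos] - m * dx
  new_variance("interaction-pe", drop(a %*% blk$V_M %*% a))
}

# seed the global RNG when an explicit seed is requested (same convention
# as boot and other resampling packages: NULL leaves the RNG stream alone)
local_seed <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}
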