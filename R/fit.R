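#' Fit the full outcome model by ordinary least squares
#'
#' Solves the normal equations by QR decomposition and returns the
#' coefficient vector together with the full coefficient covariance matrix
#' sigma2 * (D'D)^{-1}, the residual variance SSE/(n - k), and the role
#' tags copied from the design. The coefficient covariance is the object
#' from which all mediation functionals and their variances are read off.
#'
#' @param design An [build_design()] result, or a plain numeric matrix
#'   (then `roles` must be supplied).
#' @param y Outcome vector of length `nrow(design)`. Defaults to the
#'   outcome stored in the design's frame.
#' @param roles Role tags when `design` is a bare matrix.
#' @return An object of class `"emc_fit"`: coefficients `beta`, covariance
#'   `cov_beta`, `sigma2`, residual degrees of freedom `df`, `roles`,
#'   `labels`, residuals/fitted values, the Gram determinant `gram_det`,
#'   and the design (for downstream functionals).
#' @examples
#' d <- data.frame(x = rnorm(40), m = rnorm(40), y = rnorm(40))
#' mf <- mediation_frame(d, "y", "x", "m")
#' fit <- fit_ols(build_design(mf))
#' fit$beta
#' @export
fit_ols <- function(design, y = NULL, roles = NULL) {
  if (inherits(design, "emc_design")) {
    D <- design$values
    roles <- design$roles
    if (is.null(y)) y <- design$frame$y
  } else {
    D <- as.matrix(design)
    if (is.null(roles))
      emc_abort("bad_spec", "roles must be supplied for a bare matrix")
    design <- NULL
  }
  n <- nrow(D); k <- ncol(D)
  if (length(y) != n)
    emc_abort("bad_spec", sprintf("length(y) = %d but design has %d rows",
                                  length(y), n))
  if (n <= k)
    emc_abort("too_few_rows", sprintf("n = %d rows for k = %d columns", n, k))

  qrD <- qr(D)
  if (qrD$rank < k)
    emc_abort("rank_deficient",
              sprintf("design matrix is rank deficient (rank %d < k = %d)",
                      qrD$rank, k))
  beta <- qr.coef(qrD, y)
  res <- y - drop(D %*% beta)
  sse <- sum(res^2)
  df <- n - k
  sigma2 <- sse / df
  if (sse <= 1e-12 * max(sum(y^2), 1))
    emc_warn("degenerate_residuals",
             "residual sum of squares is (numerically) zero; all coefficient variances are 0")

  # unscaled (D'D)^{-1}, undoing any pivoting applied by the QR routine
  R <- qr.R(qrD)
  xtx_inv <- chol2inv(R)
  piv <- qrD$pivot
  xtx_inv[piv, piv] <- xtx_inv
  cov_beta <- sigma2 * xtx_inv
  labels <- colnames(D) %||% paste0("V", seq_len(k))
  dimnames(cov_beta) <- list(labels, labels)
  names(beta) <- labels

  structure(list(
    beta = beta, cov_beta = cov_beta, xtx_inv = xtx_inv,
    sigma2 = sigma2, df = df, n = n, k = k,
    roles = roles, labels = labels,
    residuals = res, fitted = drop(D %*% beta),
    gram_det = prod(diag(R)^2),
    design = design, y = y
  ), class = "emc_fit")
}

#' @export
print.emc_fit <- function(x, ...) {
  cat(sprintf("<emc_fit> n = %d, k = %d, df = %d, sigma2 = %.6g\n",
              x$n, x$k, x$df, x$sigma2))
  print(data.frame(column = x$labels, role = x$roles,
                   beta = x$beta, se = sqrt(diag(x$cov_beta))),
        row.names = FALSE)
  invisible(x)
}

#' Partition the coefficient vector and covariance into pathway blocks
#'
#' Splits the fitted coefficients and their covariance into the
#' exposure-pathway block and the mediator block by role tag. Intercept
#' and confounder rows/columns belong to neither block.
#'
#' @param fit An [fit_ols()] result.
#' @return A list with `beta_X`, `beta_M`, `V_X`, `V_XM`, `V_M`, `V_MX`,
#'   and the label vectors of both blocks.
#' @export
partition_blocks <- function(fit) {
  stopifnot(inherits(fit, "emc_fit"))
  xi <- which(fit$roles == "exposure-pathway")
  mi <- which(fit$roles == "mediator-block")
  if (!length(mi))
    emc_abort("no_mediator_block", "fit has no mediator-block columns")
  if (!length(xi))
    emc_abort("no_exposure_pathway", "fit has no exposure-pathway columns")
  V <- fit$cov_beta
  list(
    beta_X = fit$beta[xi], beta_M = fit$beta[mi],
    V_X = V[xi, xi, drop = FALSE],
    V_XM = V[xi, mi, drop = FALSE],
    V_MX = V[mi, xi, drop = FALSE],
    V_M = V[mi, mi, drop = FALSE],
    labels_X = fit$labels[xi], labels_M = fit$labels[mi]
  )
}
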