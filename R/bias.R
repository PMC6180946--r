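# Closed-form bias expressions for the indirect-effect estimate.

#' Omitted-covariate bias of the indirect effect
#'
#' When the full model omits a covariate W that the outcome truly depends
#' on (coefficient gamma_W), the expected bias added to the estimated
#' indirect effect is (r_XW - r_XW.M) (sigma_W / sigma_X) gamma_W, where
#' r_XW is the marginal X-W correlation and r_XW.M the partial
#' correlation given the mediator. The estimate is robust to omitting W
#' whenever W is orthogonal to X or to M (r_XW = r_XW.M) or gamma_W = 0.
#'
#' @param r_XW Correlation between exposure and omitted covariate.
#' @param r_XW_given_M Partial correlation of X and W given M.
#' @param sigma_W,sigma_X Standard deviations of W and X (positive).
#' @param gamma_W True outcome coefficient of W.
#' @return Scalar bias.
#' @examples
#' omitted_covariate_bias(0.5, 0.2, 2, 1, 3)  # 1.8
#' @export
omitted_covariate_bias <- function(r_XW, r_XW_given_M, sigma_W, sigma_X,
                                   gamma_W) {
  check_correlation(r_XW); check_correlation(r_XW_given_M)
  if (sigma_W <= 0 || sigma_X <= 0)
    emc_abort("bad_spec", "standard deviations must be positive")
  (r_XW - r_XW_given_M) * (sigma_W / sigma_X) * gamma_W
}

#' Partial correlation given a conditioning variable
#'
#' Correlation of the residuals of `a ~ given` and `b ~ given` (with
#' intercepts), the standard residual-based definition.
#'
#' @param a,b,given Numeric vectors of equal length.
#' @return Scalar partial correlation.
#' @export
partial_correlation <- function(a, b, given) {
  ra <- stats::residuals(stats::lm(a ~ given))
  rb <- stats::residuals(stats::lm(b ~ given))
  stats::cor(ra, rb)
}

#' Population indirect effect in correlation form
#'
#' For the simple mediation model the population value of the
#' coefficient difference Delta = beta_X_star - beta_X is
#' rho_XM (rho_MY - rho_YX rho_XM) / (1 - rho_XM^2) (sigma_Y / sigma_X).
#' Plugging in sample correlations and standard deviations reproduces
#' the estimate Delta-hat exactly; since the sample correlation is a
#' biased estimate of rho, Delta-hat is biased but consistent.
#'
#' @param rho_XM,rho_MY,rho_YX Pairwise correlations.
#' @param sigma_Y,sigma_X Standard deviations (positive).
#' @return Scalar population (or plug-in) value of Delta.
#' @export
expected_delta_correlation_form <- function(rho_XM, rho_MY, rho_YX,
                                            sigma_Y, sigma_X) {
  check_correlation(rho_XM); check_correlation(rho_MY)
  check_correlation(rho_YX)
  if (sigma_Y <= 0 || sigma_X <= 0)
    emc_abort("bad_spec", "standard deviations must be positive")
  if (abs(rho_XM) >= 1)
    emc_abort("degenerate_correlation",
              "|rho_XM| = 1: exposure and mediator are collinear")
  rho_XM * (rho_MY - rho_YX * rho_XM) / (1 - rho_XM^2) *
    (sigma_Y / sigma_X)
}

#' Approximate expectation of the sample correlation
#'
#' Cochran's large-sample approximation
#' E[r] = rho - rho (1 - rho^2) / (2 N) for the sample correlation of N
#' bivariate-normal observations; the bias vanishes as N grows and at
#' rho in {-1, 0, 1}.
#'
#' @param rho Population correlation in [-1, 1].
#' @param N Sample size (>= 2).
#' @return Scalar approximate expectation of r.
#' @examples
#' cochran_expected_r(0.5, 20)  # 0.490625
#' @export
cochran_expected_r <- function(rho, N) {
  check_correlation(rho)
  if (N < 2) emc_abort("bad_spec", "N must be >= 2")
  rho - rho * (1 - rho^2) / (2 * N)
}

check_correlation <- function(r) {
  if (!is.numeric(r) || length(r) != 1L || is.na(r) || abs(r) > 1)
    emc_abort("bad_spec", "correlations must be scalars in [-1, 1]")
  invisible(TRUE)
}
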