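# Synthetic-data generator for the simple-mediation generative design
# (Gaussian exposure, linear mediator and outcome models with Gaussian
# errors), plus replication harnesses for the variance-comparison and
# conditioning-set-bias studies.

#' Define a simple-mediation simulation design
#'
#' The generative model is X ~ N(0, sigma_X^2),
#' M = alpha0 + alpha_X X + eps_M with eps_M ~ N(0, sigma_M^2), and
#' Y = beta0 + beta_X X + beta_M M + eps_Y with eps_Y ~ N(0, sigma_Y^2).
#' The true indirect effect for a unit exposure change is
#' alpha_X * beta_M (1.5 under the defaults). The conditioning mode
#' controls what is held fixed across replicates: `"fixed-XM"` reuses one
#' draw of X and M with fresh outcome errors, `"fixed-X-random-M"` reuses
#' X with fresh mediator and outcome errors, and `"random-XM"` redraws
#' everything.
#'
#' @param n Sample size per replicate (>= 10).
#' @param alpha0,alpha_X,sigma_M Mediator-model intercept, slope, and
#'   error SD.
#' @param beta0,beta_X,beta_M,sigma_Y Outcome-model intercept, direct
#'   effect, mediator effect, and error SD.
#' @param sigma_X Exposure SD.
#' @param reps Number of replicates for the study harnesses.
#' @param seed Master seed; every replicate draws from its own RNG
#'   stream spawned from this seed, so results do not depend on `reps`
#'   or the order of replication.
#' @param mode Conditioning mode (see above).
#' @return An object of class `"sim_design"`, including `true_indirect`.
#' @export
sim_design <- function(n = 200, alpha0 = 0, alpha_X = 0.75, sigma_M = 1,
                       beta0 = 0, beta_X = 1, beta_M = 2, sigma_Y = 1,
                       sigma_X = 1, reps = 1000, seed = 1,
                       mode = c("random-XM", "fixed-XM",
                                "fixed-X-random-M")) {
  mode <- match.arg(mode)
  if (n < 10) emc_abort("bad_spec", "n must be >= 10")
  if (reps < 1) emc_abort("bad_spec", "reps must be >= 1")
  if (min(sigma_M, sigma_Y, sigma_X) <= 0)
    emc_abort("bad_spec", "all sigmas must be positive")
  structure(list(n = as.integer(n), alpha0 = alpha0, alpha_X = alpha_X,
                 sigma_M = sigma_M, beta0 = beta0, beta_X = beta_X,
                 beta_M = beta_M, sigma_Y = sigma_Y, sigma_X = sigma_X,
                 reps = as.integer(reps), seed = as.integer(seed),
                 mode = mode, true_indirect = alpha_X * beta_M),
            class = "sim_design")
}

#' @export
print.sim_design <- function(x, ...) {
  cat(sprintf(
    "<sim_design> n = %d, reps = %d, seed = %d, mode = %s\n", x$n, x$reps,
    x$seed, x$mode))
  cat(sprintf(
    "  M = %g + %g X + N(0, %g^2);  Y = %g + %g X + %g M + N(0, %g^2)\n",
    x$alpha0, x$alpha_X, x$sigma_M, x$beta0, x$beta_X, x$beta_M,
    x$sigma_Y))
  cat(sprintf("  X ~ N(0, %g^2); true indirect effect = %g\n",
              x$sigma_X, x$true_indirect))
  invisible(x)
}

# .Random.seed state for L'Ecuyer-CMRG stream k spawned from `seed`
# (stream 0 is the set.seed state itself; stream k advances k times)
stream_state <- function(seed, k) {
  okind <- RNGkind("L'Ecuyer-CMRG")
  on.exit(RNGkind(okind[1], okind[2], okind[3]), add = TRUE)
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)
  s <- get(".Random.seed", globalenv())
  k <- as.integer(k)
  while (k > 0L) {
    s <- parallel::nextRNGStream(s)
    k <- k - 1L
  }
  s
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, globalenv())
}

# run f() with the RNG positioned at `state`; returns list(value, state)
# where state is the advanced stream state after the draws
with_rng_state <- function(state, f) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(restore_seed(old), add = TRUE)
  assign(".Random.seed", state, globalenv())
  value <- f()
  list(value = value, state = get(".Random.seed", globalenv()))
}

# draw one replicate given the fixed-draw stream state; the fresh
# (per-replicate) draws come from the replicate stream `s_rep` when
# supplied, otherwise from the current position of the global RNG (so a
# study loop can let resampling methods continue the same stream)
generate_from_states <- function(design, s_fixed, s_rep = NULL) {
  if (!is.null(s_rep))
    return(with_rng_state(s_rep, function()
      generate_from_states(design, s_fixed))$value)
  d <- design
  fixed <- with_rng_state(s_fixed, function() {
    X <- stats::rnorm(d$n, 0, d$sigma_X)
    eM <- stats::rnorm(d$n, 0, d$sigma_M)
    list(X = X, eM = eM)
  })$value
  fresh <- list(X = stats::rnorm(d$n, 0, d$sigma_X),
                eM = stats::rnorm(d$n, 0, d$sigma_M),
                eY = stats::rnorm(d$n, 0, d$sigma_Y))
  X <- switch(d$mode, `random-XM` = fresh$X, fixed$X)
  eM <- if (d$mode == "fixed-XM") fixed$eM else fresh$eM
  M <- d$alpha0 + d$alpha_X * X + eM
  Y <- d$beta0 + d$beta_X * X + d$beta_M * M + fresh$eY
  mediation_frame(data.frame(x = X, m = M, y = Y),
                  outcome = "y", exposures = "x", mediators = "m",
                  quiet = TRUE)
}

#' Generate one replicate data set from a simulation design
#'
#' Deterministic in `(design$seed, rep_index)`: replicate `i` draws from
#' its own RNG stream, and under the fixed conditioning modes the fixed
#' exposure (and mediator) values are drawn once from the reserved
#' stream 0 and reused across replicates.
#'
#' @param design A [sim_design()].
#' @param rep_index Replicate number (>= 1).
#' @return A [mediation_frame()] with columns `x`, `m`, `y`.
#' @export
generate_dataset <- function(design, rep_index = 1L) {
  stopifnot(inherits(design, "sim_design"), rep_index >= 1L)
  generate_from_states(design,
                       stream_state(design$seed, 0L),
                       stream_state(design$seed, rep_index))
}

# closed-form per-replicate quantities for the study harnesses;
# extra (resampling) methods run inside the replicate's RNG stream
replicate_stats <- function(design, frame, methods, B, draws) {
  fit <- fit_ols(build_design(frame))
  med <- fit_mediator(frame)
  emc <- compute_emc(fit)
  delta <- unname(emc$delta[1])
  out <- c(delta = delta)
  if ("model" %in% methods)
    out["model"] <- emc$cov_delta[1, 1]
  if ("marginal" %in% methods)
    out["marginal"] <- marginal_variance(fit, med, frame)$variance
  if ("sobel" %in% methods)
    out["sobel"] <- sobel_variance(med$alpha[["x"]], fit$beta[["m"]],
                                   med$se[["x"]],
                                   sqrt(fit$cov_beta["m", "m"]))$variance
  if ("case-bootstrap" %in% methods)
    out["case-bootstrap"] <-
      bootstrap_variance(frame, mode = "case", B = B)$variance
  if ("residual-bootstrap" %in% methods)
    out["residual-bootstrap"] <-
      bootstrap_variance(frame, mode = "residual", B = B)$variance
  if ("monte-carlo" %in% methods)
    out["monte-carlo"] <-
      monte_carlo_variance(fit, med, frame, draws = draws)$variance
  attr(out, "df") <- fit$df
  out
}

#' Replicated variance-comparison study
#'
#' Replicates the simulation design, computing for each replicate the
#' single-model indirect-effect estimate (Delta-hat for a unit exposure
#' change) and the requested variance estimates, then compares each
#' method's mean estimated variance with the empirical variance of
#' Delta-hat across replicates and reports the coverage of the true
#' indirect effect by each method's 95% t interval.
#'
#' @param design A [sim_design()].
#' @param methods Variance estimators to run each replicate; the
#'   closed-form methods (`"model"`, `"marginal"`, `"sobel"`) are cheap,
#'   the resampling methods (`"case-bootstrap"`, `"residual-bootstrap"`,
#'   `"monte-carlo"`) multiply the run time by `B` or `draws`.
#' @param B Bootstrap replicates per data set (when requested).
#' @param draws Monte Carlo draws per data set (when requested).
#' @param level Confidence level for the coverage calculation.
#' @return An object of class `"sim_report"`: mean and empirical
#'   variance of Delta-hat, bias against the true effect, a per-method
#'   table (mean variance, ratio to the empirical variance, coverage),
#'   and the per-replicate matrix in `$replicates`.
#' @export
run_variance_study <- function(design,
                               methods = c("model", "marginal", "sobel"),
                               B = 10000, draws = 10000, level = 0.95) {
  stopifnot(inherits(design, "sim_design"))
  if (design$reps < 2) emc_abort("bad_spec", "reps must be >= 2")
  methods <- match.arg(methods, several.ok = TRUE,
                       choices = c("model", "marginal", "sobel",
                                   "case-bootstrap", "residual-bootstrap",
                                   "monte-carlo"))
  s_fixed <- stream_state(design$seed, 0L)
  s <- s_fixed
  rows <- vector("list", design$reps)
  df <- NA_integer_
  for (i in seq_len(design$reps)) {
    s <- parallel::nextRNGStream(s)
    # generation and any resampling method share the replicate's stream
    val <- with_rng_state(s, function() {
      frame <- generate_from_states(design, s_fixed)
      replicate_stats(design, frame, methods, B, draws)
    })$value
    rows[[i]] <- val
    df <- attr(val, "df")
  }
  reps_mat <- do.call(rbind, rows)
  delta <- reps_mat[, "delta"]
  emp_var <- stats::var(delta)
  tq <- stats::qt(1 - (1 - level) / 2, df)
  true <- design$true_indirect
  tab <- do.call(rbind, lapply(methods, function(mth) {
    v <- reps_mat[, mth]
    data.frame(method = mth, mean_variance = mean(v),
               ratio_to_empirical = mean(v) / emp_var,
               coverage = mean(abs(delta - true) <= tq * sqrt(v)),
               stringsAsFactors = FALSE)
  }))
  structure(list(design = design, reps = design$reps, seed = design$seed,
                 mode = design$mode, true_indirect = true,
                 mean_delta = mean(delta), bias = mean(delta) - true,
                 empirical_var = emp_var, methods = tab, df = df,
                 replicates = reps_mat),
            class = "sim_report")
}

#' @export
print.sim_report <- function(x, digits = 4, ...) {
  cat(sprintf(
    "<sim_report> %s, n = %d, reps = %d, seed = %d\n", x$mode,
    x$design$n, x$reps, x$seed))
  cat(sprintf(
    "  true indirect = %g; mean Delta-hat = %.4f (bias %+.4f)\n",
    x$true_indirect, x$mean_delta, x$bias))
  cat(sprintf("  empirical Var(Delta-hat) = %.6g\n", x$empirical_var))
  if (!is.null(x$methods)) {
    tab <- x$methods
    tab[] <- lapply(tab, function(col)
      if (is.numeric(col)) signif(col, digits) else col)
    print(tab, row.names = FALSE)
  }
  if (!is.null(x$bias_table)) {
    tab <- x$bias_table
    tab[] <- lapply(tab, function(col)
      if (is.numeric(col)) signif(col, digits) else col)
    print(tab, row.names = FALSE)
  }
  invisible(x)
}

#' Conditioning-set bias study
#'
#' Runs the same design under fixed-X-and-M and fixed-X-with-random-M
#' conditioning and reports the mean of Delta-hat and its bias in each,
#' together with the predicted mean: under fixed X and M the estimator's
#' expectation is the fixed-sample projection of M on X times beta_M
#' (so Delta-hat inherits the bias of the fixed sample correlation),
#' while with M random (given X) the expectation is exactly
#' alpha_X beta_M.
#'
#' @param design A [sim_design()] (its `mode` is ignored; both fixed
#'   modes are run with the same master seed).
#' @return A `"sim_report"` whose `bias_table` has one row per mode with
#'   `mean_delta`, `bias`, and `predicted_mean`.
#' @export
run_bias_study <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  if (design$reps < 2) emc_abort("bad_spec", "reps must be >= 2")
  run_mode <- function(mode) {
    d <- design; d$mode <- mode
    s_fixed <- stream_state(d$seed, 0L)
    s <- s_fixed
    delta <- numeric(d$reps)
    for (i in seq_len(d$reps)) {
      s <- parallel::nextRNGStream(s)
      frame <- generate_from_states(d, s_fixed, s)
      delta[i] <- unname(compute_emc(fit_ols(build_design(frame)))$delta[1])
    }
    # predicted E[Delta-hat]: fixed-sample projection coefficient of M
    # on X times beta_M when M is fixed; alpha_X beta_M when M is random
    fixed <- with_rng_state(s_fixed, function() {
      X <- stats::rnorm(d$n, 0, d$sigma_X)
      eM <- stats::rnorm(d$n, 0, d$sigma_M)
      list(X = X, M = d$alpha0 + d$alpha_X * X + eM)
    })$value
    predicted <- if (mode == "fixed-XM")
      stats::cov(fixed$X, fixed$M) / stats::var(fixed$X) * d$beta_M
    else d$alpha_X * d$beta_M
    data.frame(mode = mode, mean_delta = mean(delta),
               bias = mean(delta) - d$true_indirect,
               empirical_var = stats::var(delta),
               predicted_mean = predicted, stringsAsFactors = FALSE)
  }
  tab <- rbind(run_mode("fixed-XM"), run_mode("fixed-X-random-M"))
  structure(list(design = design, reps = design$reps, seed = design$seed,
                 mode = "fixed-XM vs fixed-X-random-M",
                 true_indirect = design$true_indirect,
                 mean_delta = tab$mean_delta[1], bias = tab$bias[1],
                 empirical_var = tab$empirical_var[1],
                 methods = NULL, bias_table = tab),
            class = "sim_report")
}
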