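# End-to-end analysis orchestration: configuration, CSV input, the
# effect-decomposition report, and TSV output.

#' Configure an end-to-end mediation analysis
#'
#' Collects everything [run_analysis()] needs: the data (a CSV path or a
#' data frame), the role assignment, the exposure basis and interaction
#' declarations, the contrast, and the variance methods to compare.
#'
#' @param data Path to a CSV file (header row, comma-separated, `.`
#'   decimal, empty/NA cells treated as missing) or a data frame.
#' @param outcome,exposures,mediators,confounders Column role
#'   assignment.
#' @param exposure_terms,interactions Passed to [basis_spec()].
#' @param x,x_star Contrast levels (default unit change 1 vs 0).
#' @param variance Variance methods to report for the indirect effect:
#'   any of `"model"`, `"marginal"`, `"sobel"`, `"case-bootstrap"`,
#'   `"residual-bootstrap"`, `"monte-carlo"`.
#' @param m Mediator level for the CDE under exposure-mediator
#'   interaction (default sample mean).
#' @param ci_level Two-sided confidence level.
#' @param seed Seed for resampling methods.
#' @param B,draws Bootstrap replicates and Monte Carlo draws.
#' @param multimed Multiple-mediator method: `"single"` (default),
#'   `"parallel"`, or `"serial"`.
#' @param serial_order Mediator order for the serial method.
#' @param out Optional TSV output path.
#' @return An object of class `"analysis_config"`.
#' @export
analysis_config <- function(data, outcome, exposures, mediators,
                            confounders = NULL, exposure_terms = NULL,
                            interactions = NULL, x = 1, x_star = 0,
                            variance = "model", m = NULL,
                            ci_level = 0.95, seed = NULL, B = 10000,
                            draws = 10000,
                            multimed = c("single", "parallel", "serial"),
                            serial_order = NULL, out = NULL) {
  variance <- match.arg(variance, several.ok = TRUE,
                        choices = c("model", "marginal", "sobel",
                                    "case-bootstrap", "residual-bootstrap",
                                    "monte-carlo"))
  if (!all(is.finite(c(unlist(x), unlist(x_star)))))
    emc_abort("bad_spec", "contrast values must be finite")
  structure(list(data = data, outcome = outcome, exposures = exposures,
                 mediators = mediators, confounders = confounders,
                 exposure_terms = exposure_terms,
                 interactions = interactions, x = x, x_star = x_star,
                 variance = variance, m = m, ci_level = ci_level,
                 seed = seed, B = B, draws = draws,
                 multimed = match.arg(multimed),
                 serial_order = serial_order, out = out),
            class = "analysis_config")
}

read_mediation_csv <- function(path) {
  if (!file.exists(path))
    emc_abort("bad_spec", sprintf("data file not found: %s", path))
  utils::read.csv(path, header = TRUE, na.strings = c("NA", ""),
                  fileEncoding = "UTF-8")
}

#' Run a configured mediation analysis
#'
#' Builds the design, fits the single full model, computes the effect
#' decomposition and the requested indirect-effect variance methods
#' (plus the multiple-mediator decomposition when configured), and
#' returns a report. The report prints the effect table, the
#' variance-method comparison, and diagnostics (nestedness of the
#' implied marginal model, dropped rows, and the fitted-vs-implied total
#' effect discrepancy when an exposure-mediator interaction is present).
#'
#' @param config An [analysis_config()].
#' @param quiet Suppress the printed report.
#' @return An object of class `"emc_report"` with elements `effects`
#'   (data frame), `variances` (data frame), `multimed` (optional
#'   [parallel_model()]/[serial_model()] result), and `diagnostics`.
#' @export
run_analysis <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "analysis_config"))
  dat <- if (is.character(config$data)) read_mediation_csv(config$data)
         else as.data.frame(config$data)
  frame <- mediation_frame(dat, config$outcome, config$exposures,
                           config$mediators, config$confounders,
                           quiet = quiet)
  spec <- basis_spec(exposure_terms = config$exposure_terms,
                     interactions = config$interactions)
  effects <- decompose_effects(frame, spec, x = config$x,
                               x_star = config$x_star, m = config$m,
                               ci_level = config$ci_level)
  fit <- attr(effects, "fit")
  diagnostics <- attr(effects, "diagnostics")
  design <- fit$design

  variances <- do.call(rbind, lapply(config$variance, function(mth) {
    v <- switch(mth,
      model = {
        eff <- mediation_effect(compute_emc(fit),
                                emc_contrast(design, config$x,
                                             config$x_star),
                                ci_level = config$ci_level)
        new_variance("model", eff$se^2)
      },
      marginal = marginal_variance(fit, fit_mediator(frame, spec), frame),
      sobel = {
        med <- fit_mediator(frame, spec)
        e <- frame$exposures[1]; mn <- frame$mediators[1]
        sobel_variance(med$alpha[[e]], fit$beta[[mn]], med$se[[e]],
                       sqrt(fit$cov_beta[mn, mn]))
      },
      `case-bootstrap` = bootstrap_variance(frame, spec, config$x,
                                            config$x_star, "case",
                                            config$B, config$seed),
      `residual-bootstrap` = bootstrap_variance(frame, spec, config$x,
                                                config$x_star, "residual",
                                                config$B, config$seed),
      `monte-carlo` = monte_carlo_variance(fit, fit_mediator(frame, spec),
                                           frame, config$x, config$x_star,
                                           config$draws, config$seed))
    data.frame(method = v$method, variance = v$variance, se = v$se,
               stringsAsFactors = FALSE)
  }))

  mm <- switch(config$multimed,
    single = NULL,
    parallel = parallel_model(frame, config$x, config$x_star,
                              config$ci_level),
    serial = serial_model(frame,
                          config$serial_order %||% frame$mediators,
                          config$x, config$x_star, config$ci_level))

  report <- structure(list(effects = as.data.frame(effects),
                           variances = variances, multimed = mm,
                           diagnostics = diagnostics,
                           config = config),
                      class = "emc_report")
  if (!quiet) print(report)
  if (!is.null(config$out)) write_report(report, config$out)
  report
}

#' @export
print.emc_report <- function(x, digits = 4, ...) {
  cat("== Mediation analysis report ==\n")
  d <- x$diagnostics
  cat(sprintf("n = %d, k = %d, df = %d, dropped rows = %d\n",
              d$n, d$k, d$df, d$n_dropped))
  cat(sprintf("implied marginal model nested: %s\n",
              if (d$nested) "yes" else "no"))
  cat("\nEffects:\n")
  eff <- x$effects
  eff[] <- lapply(eff, function(col)
    if (is.numeric(col)) signif(col, digits) else col)
  print(eff, row.names = FALSE)
  cat("\nIndirect-effect variance methods:\n")
  v <- x$variances
  v[] <- lapply(v, function(col)
    if (is.numeric(col)) signif(col, digits) else col)
  print(v, row.names = FALSE)
  if (!is.null(x$multimed)) { cat("\n"); print(x$multimed) }
  if (!is.null(d$te_discrepancy))
    cat(sprintf("\nfitted vs implied TE discrepancy: %.4g\n",
                d$te_discrepancy))
  invisible(x)
}

#' Write a report as TSV
#'
#' One tab-separated table with a `section` column (`effect`,
#' `variance`, `diagnostic`); numbers are written with 15 significant
#' digits so the file re-parses to the same values.
#'
#' @param report An `"emc_report"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "emc_report"))
  num <- function(v) vapply(v, function(z) sprintf("%.15g", z),
                            character(1))
  eff <- report$effects
  rows <- data.frame(section = "effect", label = eff$label,
                     value = num(eff$estimate), se = num(eff$se),
                     ci_low = num(eff$ci_low), ci_high = num(eff$ci_high),
                     stringsAsFactors = FALSE)
  v <- report$variances
  rows <- rbind(rows, data.frame(
    section = "variance", label = v$method, value = num(v$variance),
    se = num(v$se), ci_low = "", ci_high = "", stringsAsFactors = FALSE))
  d <- report$diagnostics
  diag_rows <- data.frame(
    section = "diagnostic",
    label = c("nested", "n", "k", "df", "n_dropped",
              if (!is.null(d$te_discrepancy)) "te_discrepancy"),
    value = c(as.character(as.integer(d$nested)), d$n, d$k, d$df,
              d$n_dropped,
              if (!is.null(d$te_discrepancy)) num(d$te_discrepancy)),
    se = "", ci_low = "", ci_high = "", stringsAsFactors = FALSE)
  rows <- rbind(rows, diag_rows)
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
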