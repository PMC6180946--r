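test_that("EMC reproduces the two-model coefficient difference (FWL identity)", {
  # simple model
  d <- make_simple(200, seed = 17)
  mf <- mediation_frame(d, "y", "x", "m", quiet = TRUE)
  emc <- compute_emc(fit_ols(build_design(mf)))
  ref <- two_model_delta(d, y ~ x + m, y ~ x, "x")
  expect_lt(abs(emc$delta - ref), 1e-10)

  # quadratic exposure basis
  emc2 <- compute_emc(fit_ols(build_design(mf, basis_spec(
    exposure_terms = list(x = c("identity", "power:2"))))))
  ref2 <- two_model_delta(d, y ~ x + I(x^2) + m, y ~ x + I(x^2),
                          c("x", "I(x^2)"))
  expect_lt(max(abs(unname(emc2$delta) - ref2)), 1e-8)

  # two mediators
  d3 <- make_two_mediators(180, seed = 23)
  mf3 <- mediation_frame(d3, "y", "x", c("m1", "m2"), quiet = TRUE)
  emc3 <- compute_emc(fit_ols(build_design(mf3)))
  ref3 <- two_model_delta(d3, y ~ x + m1 + m2, y ~ x, "x")
  expect_lt(abs(emc3$delta - ref3), 1e-8)
})

test_that("delta vanishes when the mediator explains nothing", {
  d <- make_simple(80, seed = 19)
  d$y <- fitted(lm(y ~ x, d))   # y in span(1, x): beta_M is exactly 0
  mf <- mediation_frame(d, "y", "x", "m", quiet = TRUE)
  fit <- suppressWarnings(fit_ols(build_design(mf)))
  expect_lt(abs(compute_emc(fit)$delta), 1e-10)
})

test_that("tiny example: delta = 1 and the product identity holds", {
  fit <- suppressWarnings(fit_ols(build_design(tiny_frame())))
  expect_equal(unname(compute_emc(fit)$delta), 1, tolerance = 1e-10)
  # product of coefficients equals the difference for the simple model
  d <- make_simple(150, seed = 29)
  mf <- mediation_frame(d, "y", "x", "m", quiet = TRUE)
  full <- fit_ols(build_design(mf))
  med <- fit_mediator(mf)
  expect_lt(abs(compute_emc(full)$delta -
                med$alpha[["x"]] * full$beta[["m"]]), 1e-10)
})

test_that("mediation_effect applies the contrast with a t interval", {
  d <- make_simple(150, seed = 31)
  mf <- mediation_frame(d, "y", "x", "m", quiet = TRUE)
  fit <- fit_ols(build_design(mf))
  emc <- compute_emc(fit)
  ct <- emc_contrast(fit, 1, 0)
  eff <- mediation_effect(emc, ct)
  expect_equal(eff$estimate, unname(emc$delta))
  expect_equal(eff$se, sqrt(emc$cov_delta[1, 1]))
  expect_equal(eff$ci_high - eff$estimate,
               qt(0.975, fit$df) * eff$se, tolerance = 1e-12)

  # null contrast: zero estimate, zero se
  eff0 <- mediation_effect(emc, emc_contrast(fit, 2, 2))
  expect_equal(eff0$estimate, 0)
  expect_equal(eff0$se, 0)

  # antisymmetry in the contrast direction
  e_fwd <- mediation_effect(emc, emc_contrast(fit, 2, -1))
  e_rev <- mediation_effect(emc, emc_contrast(fit, -1, 2))
  expect_equal(e_fwd$estimate, -e_rev$estimate, tolerance = 1e-12)

  # quadratic model: matches the explicit submodel-difference oracle
  sp <- basis_spec(exposure_terms = list(x = c("identity", "power:2")))
  fitq <- fit_ols(build_design(mf, sp))
  emcq <- compute_emc(fitq)
  effq <- mediation_effect(emcq, emc_contrast(fitq, 2, 0.5))
  refd <- two_model_delta(d, y ~ x + I(x^2) + m, y ~ x + I(x^2),
                          c("x", "I(x^2)"))
  expect_equal(effq$estimate,
               refd[1] * (2 - 0.5) + refd[2] * (4 - 0.25),
               tolerance = 1e-8)
})

test_that("effect decomposition is additive with and without interaction", {
  # no interaction: CDE = NDE, NIE = PE = EMC functional
  d <- make_simple(150, seed = 37)
  mf <- mediation_frame(d, "y", "x", "m", quiet = TRUE)
  de <- decompose_effects(mf)
  est <- setNames(de$estimate, de$label)
  expect_equal(est[["CDE"]], est[["NDE"]])
  expect_equal(est[["NIE"]], est[["PE"]])
  fit <- attr(de, "fit")
  expect_equal(est[["CDE"]], unname(fit$beta[["x"]]))
  expect_equal(est[["PE"]], unname(compute_emc(fit)$delta),
               tolerance = 1e-10)
  expect_lt(abs(est[["TE"]] - est[["CDE"]] - est[["PE"]]), 1e-8)

  # binary exposure-mediator interaction: PE(m) from the full model
  mfb <- binary_interaction_frame()
  sp <- basis_spec(interactions = "x:m")
  for (m in seq(-1, 2, length.out = 6)) {
    deb <- decompose_effects(mfb, sp, m = m)
    estb <- setNames(deb$estimate, deb$label)
    expect_lt(abs(estb[["TE"]] - estb[["CDE"]] - estb[["PE"]]), 1e-8)
    expect_lt(abs(estb[["TE"]] - estb[["NDE"]] - estb[["NIE"]]), 1e-8)
    # PE = [Delta - beta_XM m](x - x*) read off the full model
    fitb <- attr(deb, "fit")
    delta <- unname(compute_emc(fitb)$delta)
    expect_equal(estb[["PE"]], delta - fitb$beta[["x:m"]] * m,
                 tolerance = 1e-8)
  }
  # no interaction column: NDE = CDE for any m
  de_m <- decompose_effects(mf, m = 5)
  expect_equal(de_m$estimate[de_m$label == "NDE"],
               de_m$estimate[de_m$label == "CDE"])
})

test_that("total effect comes from the fitted marginal model", {
  d <- make_simple(150, seed = 43)
  mf <- mediation_frame(d, "y", "x", "m", quiet = TRUE)
  te <- fit_total_effect(mf)
  sub <- lm(y ~ x, d)
  expect_equal(te$estimate, unname(coef(sub)["x"]), tolerance = 1e-10)
  expect_equal(te$se, sqrt(vcov(sub)["x", "x"]), tolerance = 1e-10)

  # y identically zero
  d0 <- d; d0$y <- 0
  mf0 <- mediation_frame(d0, "y", "x", "m", quiet = TRUE)
  expect_lt(abs(suppressWarnings(fit_total_effect(mf0))$estimate), 1e-12)

  # quadratic basis: TE equals the direct + indirect split exactly
  sp <- basis_spec(exposure_terms = list(x = c("identity", "power:2")))
  teq <- fit_total_effect(mf, sp, x = 2, x_star = 0.5)
  fitq <- fit_ols(build_design(mf, sp))
  emcq <- compute_emc(fitq)
  ct <- emc_contrast(fitq, 2, 0.5)
  direct <- sum(ct$h_diff * fitq$beta[names(ct$h_diff)])
  indirect <- mediation_effect(emcq, ct)$estimate
  expect_lt(abs(teq$estimate - direct - indirect), 1e-8)
})

test_that("implied-submodel nestedness is detected correctly", {
  d <- make_simple(100, seed = 47)
  mf <- mediation_frame(d, "y", "x", "m", quiet = TRUE)
  expect_true(implied_submodel_check(basis_spec(), mf)$nested)
  expect_true(implied_submodel_check(
    basis_spec(interactions = "x:m"), binary_interaction_frame())$nested)

  chk <- implied_submodel_check(basis_spec(interactions = "x:m"), mf)
  expect_false(chk$nested)
  expect_equal(chk$missing_terms, "x^2")
  # adding the x^2 term restores nestedness
  expect_true(implied_submodel_check(basis_spec(
    exposure_terms = list(x = c("identity", "power:2")),
    interactions = "x:m"), mf)$nested)
  expect_error(decompose_effects(mf, basis_spec(interactions = "x:m")),
               class = "emcmed_non_nested_submodel")
})

test_that("confounder-marginalized contrast matches the printed expansion", {
  mfc <- confounded_frame(200, seed = 51)
  sp <- basis_spec(interactions = "x:c1")
  fit <- fit_ols(build_design(mfc, sp))
  emc <- compute_emc(fit)
  cbar <- mean(mfc$C[, "c1"])
  ct <- confounder_marginal_contrast(fit$design, 1, 0)
  expect_equal(unname(ct$h_diff), c(1, cbar), tolerance = 1e-12)

  eff <- mediation_effect(emc, ct)
  # estimate expands as Delta_1 (x-x*) + Delta_2 (x-x*) E[C]
  expect_equal(eff$estimate,
               unname(emc$delta[1] + emc$delta[2] * cbar),
               tolerance = 1e-12)
  # variance expands term by term as the printed three-term quadratic
  v_hand <- emc$cov_delta[1, 1] + cbar^2 * emc$cov_delta[2, 2] +
    2 * cbar * emc$cov_delta[1, 2]
  expect_equal(eff$se^2, v_hand, tolerance = 1e-12)

  # centered confounder reduces to the plain unit contrast
  ct0 <- confounder_marginal_contrast(fit$design, 1, 0,
                                      confounder_means = c(c1 = 0))
  expect_equal(unname(ct0$h_diff), c(1, 0))

  # mediation-formula comparator: beta_M (alpha_X + alpha_XC E[C]) (x-x*)
  med <- fit_mediator(mfc, sp)
  comp <- fit$beta[["m"]] * (med$alpha[["x"]] +
                             med$alpha[["x:c1"]] * cbar)
  expect_lt(abs(eff$estimate - comp), 1e-8)
})

test_that("FWL identity holds across random datasets and spec families", {
  for (seed in 1:8) {
    d <- make_confounded(120, seed = seed)
    mf <- mediation_frame(d, "y", "x", "m", "c1", quiet = TRUE)
    sp <- basis_spec(exposure_terms = list(x = c("identity", "power:2")),
                     interactions = "x:c1")
    emc <- compute_emc(fit_ols(build_design(mf, sp)))
    ref <- two_model_delta(d, y ~ x + I(x^2) + c1 + x:c1 + m,
                           y ~ x + I(x^2) + c1 + x:c1,
                           c("x", "I(x^2)", "x:c1"))
    expect_lt(max(abs(unname(emc$delta) - ref)), 1e-8)
  }
})
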