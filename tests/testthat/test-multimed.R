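test_that("total indirect effect reduces to the EMC with one mediator", {
  mf <- simple_frame(150, seed = 83)
  fit <- fit_ols(build_design(mf))
  ti <- total_indirect(fit)
  emc <- compute_emc(fit)
  expect_equal(ti$estimate, unname(emc$delta))
  expect_equal(ti$se, sqrt(emc$cov_delta[1, 1]))
})

test_that("total indirect matches the two-model oracle with 2 mediators", {
  d <- make_two_mediators(200, seed = 89)
  mf <- mediation_frame(d, "y", "x", c("m1", "m2"), quiet = TRUE)
  fit <- fit_ols(build_design(mf))
  ti <- total_indirect(fit)
  ref <- two_model_delta(d, y ~ x + m1 + m2, y ~ x, "x")
  expect_lt(abs(ti$estimate - ref), 1e-8)
  # and the variance is the stated quadratic form, scaled by (x - x*)^2
  blk <- partition_blocks(fit)
  vv <- drop(blk$V_XM %*% solve(blk$V_M, blk$V_MX))
  expect_equal(ti$se^2, vv, tolerance = 1e-12)
  ti2 <- total_indirect(fit, x = 3, x_star = 1)
  expect_equal(ti2$se^2, 4 * vv, tolerance = 1e-12)
})

test_that("specific indirect effects use the scalar diagonal block", {
  d <- make_two_mediators(200, seed = 97)
  mf <- mediation_frame(d, "y", "x", c("m1", "m2"), quiet = TRUE)
  fit <- fit_ols(build_design(mf))
  s1 <- specific_indirect(fit, "m1")
  # formula oracle from the raw covariance blocks
  V <- fit$cov_beta
  expect_equal(s1$estimate,
               unname(-V["x", "m1"] / V["m1", "m1"] * fit$beta[["m1"]]),
               tolerance = 1e-12)
  expect_equal(s1$se^2, unname(V["x", "m1"]^2 / V["m1", "m1"]),
               tolerance = 1e-12)
  # correlated mediators: specific effects do not sum to the total
  s2 <- specific_indirect(fit, "m2")
  ti <- total_indirect(fit)
  expect_gt(abs(s1$estimate + s2$estimate - ti$estimate), 1e-4)
  expect_error(specific_indirect(fit, "m9"),
               class = "emcmed_unknown_mediator")
})

test_that("orthogonalized mediators make specific effects additive", {
  d <- make_two_mediators(200, seed = 101)
  # replace m2 by its residual on (1, x, m1): conditionally orthogonal
  d$m2 <- residuals(lm(m2 ~ x + m1, d))
  d$y <- d$x + 1.5 * d$m1 + 2 * d$m2 + rnorm(nrow(d))
  mf <- mediation_frame(d, "y", "x", c("m1", "m2"), quiet = TRUE)
  fit <- fit_ols(build_design(mf))
  s1 <- specific_indirect(fit, "m1")
  s2 <- specific_indirect(fit, "m2")
  ti <- total_indirect(fit)
  expect_lt(abs(s1$estimate + s2$estimate - ti$estimate), 1e-8)
})

test_that("parallel decomposition sums exactly to the single-model total", {
  d <- make_two_mediators(200, seed = 103)
  mf <- mediation_frame(d, "y", "x", c("m1", "m2"), quiet = TRUE)
  fit <- fit_ols(build_design(mf))
  pm <- parallel_model(mf)
  ti <- total_indirect(fit)
  expect_lt(abs(pm$total_indirect$estimate - ti$estimate), 1e-8)
  # per-path products alpha_Xi beta_Mi with Sobel SEs
  for (mm in c("m1", "m2")) {
    medf <- fit_mediator(mf, mediator = mm)
    a <- medf$alpha[["x"]]; b <- fit$beta[[mm]]
    row <- pm$specific[[match(mm, c("m1", "m2"))]]
    expect_equal(row$estimate, a * b, tolerance = 1e-12)
    expect_equal(row$se,
                 sobel_variance(a, b, medf$se[["x"]],
                                sqrt(fit$cov_beta[mm, mm]))$se,
                 tolerance = 1e-12)
  }
})

test_that("one-mediator parallel model degenerates to the Baron-Kenny product", {
  mf <- simple_frame(150, seed = 107)
  pm <- parallel_model(mf)
  fit <- fit_ols(build_design(mf))
  med <- fit_mediator(mf)
  expect_equal(pm$total_indirect$estimate,
               unname(med$alpha[["x"]] * fit$beta[["m"]]),
               tolerance = 1e-12)
})

test_that("serial path effects sum to the total for both orders", {
  d <- make_two_mediators(200, seed = 109)
  mf <- mediation_frame(d, "y", "x", c("m1", "m2"), quiet = TRUE)
  ti <- total_indirect(fit_ols(build_design(mf)))
  for (ord in list(c("m1", "m2"), c("m2", "m1"))) {
    sm <- serial_model(mf, ord)
    tot <- sum(vapply(sm$specific, function(s) s$estimate, numeric(1)))
    expect_lt(abs(tot - ti$estimate), 1e-8)
    expect_equal(sm$total_indirect$estimate, tot, tolerance = 1e-12)
  }
  # the split differs between the orders
  p12 <- vapply(serial_model(mf, c("m1", "m2"))$specific,
                function(s) s$estimate, numeric(1))
  p21 <- vapply(serial_model(mf, c("m2", "m1"))$specific,
                function(s) s$estimate, numeric(1))
  expect_gt(max(abs(sort(p12) - sort(p21))), 1e-4)
})

test_that("conditionally independent mediators collapse serial to parallel", {
  d <- make_two_mediators(200, seed = 113)
  # rebuild m2 = 0.4 x + r with r exactly orthogonal to (1, x, m1), so
  # the in-sample inter-mediator coefficient delta_21 is exactly zero
  d$m2 <- 0.4 * d$x + residuals(lm(m2 ~ x + m1, d))
  d$y <- d$x + 1.5 * d$m1 + 2 * d$m2 + rnorm(200)
  mf <- mediation_frame(d, "y", "x", c("m1", "m2"), quiet = TRUE)
  sm <- serial_model(mf, c("m1", "m2"))
  pm <- parallel_model(mf)
  # three-way path vanishes; two-way paths match the parallel ones
  expect_lt(abs(sm$specific[[3]]$estimate), 1e-8)
  expect_equal(sm$specific[[1]]$estimate, pm$specific[[1]]$estimate,
               tolerance = 1e-8)
  expect_equal(sm$specific[[2]]$estimate, pm$specific[[2]]$estimate,
               tolerance = 1e-8)
})

test_that("serial model enforces its two-mediator scope", {
  d <- make_two_mediators(120, seed = 127)
  d$m3 <- rnorm(120)
  mf3 <- mediation_frame(d, "y", "x", c("m1", "m2", "m3"), quiet = TRUE)
  expect_error(serial_model(mf3, c("m1", "m2", "m3")),
               class = "emcmed_scope_error")
  mf <- mediation_frame(d, "y", "x", c("m1", "m2"), quiet = TRUE)
  expect_error(serial_model(mf, c("m1", "m1")),
               class = "emcmed_bad_spec")
})

test_that("serial three-way variance follows the printed product formula", {
  d <- make_two_mediators(200, seed = 131)
  mf <- mediation_frame(d, "y", "x", c("m1", "m2"), quiet = TRUE)
  sm <- serial_model(mf, c("m1", "m2"))
  # recompute from explicit lm fits
  fit <- lm(y ~ x + m1 + m2, d)
  f2 <- lm(m2 ~ x + m1, d)
  f1 <- lm(m1 ~ x, d)
  a1 <- coef(f1)["x"]; s_a1 <- sqrt(vcov(f1)["x", "x"])
  d21 <- coef(f2)["m1"]; s_d21 <- sqrt(vcov(f2)["m1", "m1"])
  b2 <- coef(fit)["m2"]; s_b2 <- sqrt(vcov(fit)["m2", "m2"])
  v3 <- a1^2 * d21^2 * s_b2^2 + a1^2 * b2^2 * s_d21^2 +
    d21^2 * b2^2 * s_a1^2
  expect_equal(sm$specific[[3]]$estimate, unname(a1 * d21 * b2),
               tolerance = 1e-10)
  expect_equal(sm$specific[[3]]$se, unname(sqrt(v3)), tolerance = 1e-10)
})
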