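test_that("design construction orders and tags columns by role", {
  des <- build_design(tiny_frame(), basis_spec())
  expect_equal(dim(des$values), c(4L, 3L))
  expect_equal(des$labels, c("(Intercept)", "x", "m"))
  expect_equal(des$roles, c("intercept", "exposure-pathway",
                            "mediator-block"))

  # quadratic exposure: both x and x^2 on the exposure pathway
  d <- make_simple(60, seed = 2)
  mf <- mediation_frame(d, "y", "x", "m", quiet = TRUE)
  des2 <- build_design(mf, basis_spec(
    exposure_terms = list(x = c("identity", "power:2"))))
  expect_equal(des2$roles[des2$labels %in% c("x", "x^2")],
               rep("exposure-pathway", 2))

  # exposure-mediator product joins the mediator block
  des3 <- build_design(mf, basis_spec(interactions = "x:m"))
  expect_equal(des3$roles[des3$labels == "x:m"], "mediator-block")

  # exposure-confounder product joins the exposure pathway
  mfc <- confounded_frame()
  des4 <- build_design(mfc, basis_spec(interactions = "x:c1"))
  expect_equal(des4$roles[des4$labels == "x:c1"], "exposure-pathway")

  # log and spline bases evaluate correctly
  dp <- data.frame(x = rexp(50) + 0.5)
  dp$m <- dp$x + rnorm(50); dp$y <- dp$m + rnorm(50)
  mfp <- mediation_frame(dp, "y", "x", "m", quiet = TRUE)
  des5 <- build_design(mfp, basis_spec(
    exposure_terms = list(x = c("log", "spline:1"))))
  expect_equal(des5$values[, "log(x)"], log(dp$x))
  expect_equal(des5$values[, "(x-1)+"], pmax(dp$x - 1, 0))
})

test_that("design construction rejects bad specifications", {
  mf <- simple_frame()
  expect_error(build_design(mf, basis_spec(
    exposure_terms = list(zz = "identity"))),
    class = "emcmed_unknown_column")
  expect_error(basis_spec(interactions = c("x:m", "x:m")),
               class = "emcmed_bad_spec")
  expect_error(basis_spec(exposure_terms = list(x = "cubic")),
               class = "emcmed_bad_spec")
  # duplicated column makes the design rank deficient
  d <- make_simple(50, seed = 3)
  d$x2 <- d$x
  mf2 <- mediation_frame(d, "y", c("x", "x2"), "m", quiet = TRUE)
  expect_error(build_design(mf2), class = "emcmed_rank_deficient")
})

test_that("mediation_frame drops incomplete rows and validates roles", {
  d <- make_simple(50, seed = 4)
  d$m[c(3, 9)] <- NA
  expect_message(mf <- mediation_frame(d, "y", "x", "m"),
                 "dropped 2 row")
  expect_equal(mf$n, 48L)
  expect_equal(mf$n_dropped, 2L)
  expect_error(mediation_frame(d, "y", "x", "x"),
               class = "emcmed_role_overlap")
  expect_error(mediation_frame(d, "y", "x", "nope"),
               class = "emcmed_unknown_column")
})

test_that("OLS solves the normal equations with exact small-sample values", {
  # 4-point design solved by hand: y is reproduced exactly by m alone
  des <- build_design(tiny_frame())
  fit <- suppressWarnings(fit_ols(des))
  expect_equal(unname(fit$beta), c(0, 0, 1), tolerance = 1e-12)
  expect_lt(sum(fit$residuals^2), 1e-20)
  expect_warning(fit_ols(des), class = "emcmed_degenerate_residuals")

  # constant outcome: intercept only
  d <- make_simple(40, seed = 5)
  d$y <- 3.25
  mf <- mediation_frame(d, "y", "x", "m", quiet = TRUE)
  fitc <- suppressWarnings(fit_ols(build_design(mf)))
  expect_equal(unname(fitc$beta), c(3.25, 0, 0), tolerance = 1e-10)
})

test_that("OLS matches an independent pseudoinverse solve on seeded data", {
  d <- make_simple(200, seed = 11)
  mf <- mediation_frame(d, "y", "x", "m", quiet = TRUE)
  des <- build_design(mf)
  fit <- fit_ols(des)
  # pseudoinverse oracle via SVD, independent of the QR path
  sv <- svd(des$values)
  beta_pinv <- sv$v %*% ((t(sv$u) %*% mf$y) / sv$d)
  expect_lt(max(abs(fit$beta - drop(beta_pinv))), 1e-10)
  # covariance against the textbook formula
  expect_equal(fit$cov_beta,
               fit$sigma2 * solve(crossprod(des$values)),
               ignore_attr = TRUE, tolerance = 1e-10)
  expect_equal(fit$gram_det, det(crossprod(des$values)),
               tolerance = 1e-8)
})

test_that("fit invariants: residual orthogonality, PSD covariance, permutation", {
  for (seed in 1:5) {
    d <- make_simple(80, seed = seed)
    mf <- mediation_frame(d, "y", "x", "m", quiet = TRUE)
    des <- build_design(mf, basis_spec(
      exposure_terms = list(x = c("identity", "power:2"))))
    fit <- fit_ols(des)
    expect_lt(max(abs(crossprod(des$values, fit$residuals))),
              1e-8 * sqrt(sum(mf$y^2)))
    expect_gt(min(eigen(fit$cov_beta, symmetric = TRUE,
                        only.values = TRUE)$values), -1e-10)
    # row permutation leaves the coefficients unchanged
    perm <- sample(nrow(d))
    mfp <- mediation_frame(d[perm, ], "y", "x", "m", quiet = TRUE)
    fitp <- fit_ols(build_design(mfp, basis_spec(
      exposure_terms = list(x = c("identity", "power:2")))))
    expect_lt(max(abs(fit$beta - fitp$beta)), 1e-10)
  }
})

test_that("block partition has the right shapes and excludes non-block rows", {
  fit <- fit_ols(build_design(simple_frame()))
  blk <- partition_blocks(fit)
  expect_equal(dim(blk$V_XM), c(1L, 1L))
  expect_equal(dim(blk$V_M), c(1L, 1L))
  expect_identical(blk$V_MX, t(blk$V_XM))

  # quadratic exposure + one mediator: V_XM is 2x1
  d <- make_simple(100, seed = 13)
  mf <- mediation_frame(d, "y", "x", "m", quiet = TRUE)
  fit2 <- fit_ols(build_design(mf, basis_spec(
    exposure_terms = list(x = c("identity", "power:2")))))
  expect_equal(dim(partition_blocks(fit2)$V_XM), c(2L, 1L))

  # one exposure + two mediators: V_XM 1x2, V_M symmetric 2x2
  fit3 <- fit_ols(build_design(two_mediator_frame()))
  blk3 <- partition_blocks(fit3)
  expect_equal(dim(blk3$V_XM), c(1L, 2L))
  expect_equal(blk3$V_M, t(blk3$V_M))
  # intercept and confounders excluded from the blocks
  fitc <- fit_ols(build_design(confounded_frame()))
  blkc <- partition_blocks(fitc)
  expect_false("(Intercept)" %in% c(blkc$labels_X, blkc$labels_M))
  expect_false("c1" %in% c(blkc$labels_X, blkc$labels_M))
})

test_that("partition requires a mediator block", {
  d <- data.frame(x = rnorm(30), m = rnorm(30), y = rnorm(30))
  des <- build_design(mediation_frame(d, "y", "x", "m", quiet = TRUE))
  keep <- des$roles != "mediator-block"
  fit <- fit_ols(des$values[, keep], d$y, roles = des$roles[keep])
  expect_error(partition_blocks(fit), class = "emcmed_no_mediator_block")
})
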