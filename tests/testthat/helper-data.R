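# Fixture generators shared across test files. All data are built in
# code under fixed seeds.

# simple mediation data: X -> M -> Y with direct path
make_simple <- function(n = 120, seed = 7, alpha_X = 0.75, beta_X = 1,
                        beta_M = 2) {
  set.seed(seed)
  d <- data.frame(x = rnorm(n))
  d$m <- alpha_X * d$x + rnorm(n)
  d$y <- beta_X * d$x + beta_M * d$m + rnorm(n)
  d
}

simple_frame <- function(...) {
  mediation_frame(make_simple(...), "y", "x", "m", quiet = TRUE)
}

# two correlated mediators (m2 depends on m1)
make_two_mediators <- function(n = 150, seed = 21) {
  set.seed(seed)
  d <- data.frame(x = rnorm(n))
  d$m1 <- 0.5 * d$x + rnorm(n)
  d$m2 <- 0.4 * d$x + 0.6 * d$m1 + rnorm(n)
  d$y <- d$x + 1.5 * d$m1 + 2 * d$m2 + rnorm(n)
  d
}

two_mediator_frame <- function(...) {
  mediation_frame(make_two_mediators(...), "y", "x", c("m1", "m2"),
                  quiet = TRUE)
}

# confounded data with exposure-confounder interaction in both models
make_confounded <- function(n = 150, seed = 33) {
  set.seed(seed)
  d <- data.frame(x = rnorm(n), c1 = rnorm(n, mean = 1))
  d$m <- 0.5 * d$x + 0.3 * d$c1 + 0.2 * d$x * d$c1 + rnorm(n)
  d$y <- d$x + 2 * d$m + 0.5 * d$c1 + 0.3 * d$x * d$c1 + rnorm(n)
  d
}

confounded_frame <- function(...) {
  mediation_frame(make_confounded(...), "y", "x", "m", "c1",
                  quiet = TRUE)
}

# binary exposure with exposure-mediator interaction (nested submodel)
make_binary_interaction <- function(n = 150, seed = 41) {
  set.seed(seed)
  d <- data.frame(x = rbinom(n, 1, 0.5))
  d$m <- 0.7 * d$x + rnorm(n)
  d$y <- d$x + 2 * d$m + 0.8 * d$x * d$m + rnorm(n)
  d
}

binary_interaction_frame <- function(...) {
  mediation_frame(make_binary_interaction(...), "y", "x", "m",
                  quiet = TRUE)
}

# the 4-point textbook example: y ~ x has slope 1, full model slope 0
tiny_frame <- function() {
  mediation_frame(
    data.frame(x = c(0, 0, 1, 1), m = c(0, 1, 1, 2), y = c(0, 1, 1, 2)),
    "y", "x", "m", quiet = TRUE)
}

# difference-of-coefficients oracle: fit the marginal and full models
# explicitly with lm() and subtract the shared coefficients
two_model_delta <- function(d, full_formula, sub_formula, coefs) {
  cf <- coef(lm(full_formula, d))
  cs <- coef(lm(sub_formula, d))
  unname(cs[coefs] - cf[coefs])
}
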