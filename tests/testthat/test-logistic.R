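test_that("intercept-only fit equals the closed-form log odds", {
  fit <- fitLogistic(NULL, c(1, 1, 1, 0))
  expect_equal(unname(fit@coefficients), log(3), tolerance = 1e-6)
  expect_true(fit@converged)
})

test_that("a single binary covariate recovers the closed-form log odds ratio", {
  ## exposure x outcome cross-tab [[10, 5], [4, 11]]
  x <- c(rep(1, 15), rep(0, 15))
  y <- c(rep(1, 10), rep(0, 5), rep(1, 4), rep(0, 11))
  fit <- fitLogistic(data.frame(x = x), y)
  expect_equal(unname(fit@coefficients["x"]), log(5.5), tolerance = 1e-6)
  expect_equal(unname(fit@coefficients["(Intercept)"]), log(4 / 11),
               tolerance = 1e-6)
  expect_equal(unname(fit@oddsRatios["x"]), 5.5, tolerance = 1e-5)
})

test_that("affine reparameterization rescales the coefficient only", {
  set.seed(13)
  age <- rnorm(120, 65, 12)
  y <- rbinom(120, 1, plogis(-3 + 0.05 * age))
  f1 <- fitLogistic(data.frame(age = age), y)
  f2 <- fitLogistic(data.frame(age10 = age / 10), y)
  expect_equal(unname(f2@coefficients["age10"]),
               10 * unname(f1@coefficients["age"]), tolerance = 1e-6)
  expect_equal(f1@logLik, f2@logLik, tolerance = 1e-8)
})

test_that("coefficients, SEs and Wald CIs agree with base R glm", {
  set.seed(14)
  n <- 200
  d <- data.frame(a = rnorm(n), b = rbinom(n, 1, 0.4), c = rnorm(n, 2))
  y <- rbinom(n, 1, plogis(-0.5 + 0.8 * d$a - 0.6 * d$b + 0.3 * d$c))
  fit <- fitLogistic(d, y)
  ref <- glm(y ~ a + b + c, data = cbind(d, y = y), family = binomial())
  expect_equal(unname(fit@coefficients), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(fit@se), unname(sqrt(diag(vcov(ref)))),
               tolerance = 1e-4)
  sm <- summary(ref)$coefficients
  expect_equal(unname(fit@pValues), unname(sm[, 4]), tolerance = 1e-4)
})

test_that("perfect separation is flagged, not silently reported", {
  x <- c(-2, -1.5, -1, 1, 1.5, 2, 2.5, -2.5)
  y <- as.numeric(x > 0)
  expect_warning(fit <- fitLogistic(data.frame(x = x), y), "converge")
  expect_false(fit@converged)
})

test_that("known coefficients are recovered on synthetic cohorts", {
  ## mean estimate over 20 seeds of n = 500 within 10% of the truth
  truth <- c(`(Intercept)` = -0.4, a = 0.9, b = -0.6, c = 0.5)
  est <- matrix(NA_real_, 20, 4)
  for (s in 1:20) {
    set.seed(400 + s)
    d <- data.frame(a = rnorm(500), b = rnorm(500), c = rnorm(500))
    y <- rbinom(500, 1, plogis(truth[1] + as.matrix(d) %*% truth[-1]))
    est[s, ] <- fitLogistic(d, y)@coefficients
  }
  expect_true(all(abs(colMeans(est) - truth) / abs(truth) < 0.10))
})

test_that("degenerate designs and outcomes are rejected", {
  expect_error(fitLogistic(data.frame(x = 1:4), c(1, 1, 1, 1)), "both classes")
  expect_error(fitLogistic(data.frame(x = 1:3), c(0, 1, 2)), "binary")
  expect_error(fitLogistic(data.frame(x = c(1, NA, 3, 4)), c(0, 1, 0, 1)),
               "missing")
})
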