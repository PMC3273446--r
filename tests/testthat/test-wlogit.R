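test_that("intercept-only fit matches the analytic MLE", {
  f <- wlogit(NULL, c(1, 1, 0, 0))
  expect_equal(unname(coef(f)), 0, tolerance = 1e-8)
  expect_equal(f$deviance, 8 * log(2), tolerance = 1e-8)
  expect_equal(f$deviance, -2 * f$loglik)
  expect_true(f$converged)
})

test_that("coefficients agree with glm and with direct likelihood maximization", {
  set.seed(4)
  n <- 200
  x <- cbind(a = rnorm(n), b = runif(n))
  y <- rbinom(n, 1, plogis(-0.5 + x[, 1] - 2 * x[, 2]))
  f <- wlogit(x, y)
  g <- glm(y ~ x, family = binomial)
  expect_equal(unname(coef(f)), unname(coef(g)), tolerance = 1e-6)
  expect_equal(unname(diag(f$vcov)),
               unname(diag(summary(g)$cov.unscaled)), tolerance = 1e-4)
  ## independent optimizer route
  X1 <- cbind(1, x)
  nll <- function(b) {
    eta <- drop(X1 %*% b)
    -sum(y * eta - log1p(exp(eta)))
  }
  o <- optim(numeric(3), nll, method = "BFGS", control = list(reltol = 1e-15))
  expect_equal(unname(coef(f)), o$par, tolerance = 1e-5)

  ## weighted fit against glm (quasibinomial silences non-integer warnings)
  w <- rgamma(n, 5, 5)
  fw <- wlogit(x, y, w)
  gw <- glm(y ~ x, family = quasibinomial, weights = w)
  expect_equal(unname(coef(fw)), unname(coef(gw)), tolerance = 1e-6)
  mu <- fitted(gw)
  expect_equal(fw$deviance, -2 * sum(w * (y * log(mu) + (1 - y) * log(1 - mu))),
               tolerance = 1e-6)
})

test_that("the weighted likelihood is invariant to row duplication at half weight", {
  set.seed(11)
  n <- 150
  x <- matrix(rnorm(n), ncol = 1)
  y <- rbinom(n, 1, plogis(0.7 * x[, 1]))
  f1 <- wlogit(x, y)
  f2 <- wlogit(rbind(x, x), c(y, y), weights = rep(0.5, 2 * n))
  expect_equal(coef(f1), coef(f2), tolerance = 1e-8)
  expect_equal(f1$deviance, f2$deviance, tolerance = 1e-8)
})

test_that("rank deficiency and complete separation are diagnosed", {
  x <- cbind(a = rnorm(20), b = 0)
  x[, "b"] <- 2 * x[, "a"]
  expect_error(wlogit(x, rep(c(0, 1), 10)), "collinear")
  set.seed(2)
  xs <- matrix(rnorm(40), ncol = 1)
  ys <- as.numeric(xs[, 1] > 0)
  fs <- wlogit(xs, ys)
  expect_false(fs$converged)
  expect_match(fs$message, "separation")
})

test_that("deviance_test implements the upper-tail chi-square reference", {
  expect_equal(deviance_test(100, 100, 2)$p_value, 1)
  expect_equal(deviance_test(100 + qchisq(0.95, 4), 100, 4)$p_value, 0.05,
               tolerance = 1e-10)
  expect_equal(deviance_test(109.488, 100, 4)$p_value, 0.05, tolerance = 1e-3)
  big <- deviance_test(331.79, 100, 4)
  expect_equal(big$statistic, 231.79)
  expect_lt(big$p_value, 0.001)
  expect_error(deviance_test(99, 100, 1), "nested")
  expect_error(deviance_test(100, 99, 0), "df")
})

test_that("prediction is the inverse-logit of the linear predictor", {
  set.seed(5)
  x <- matrix(rnorm(60), ncol = 2)
  y <- rbinom(30, 1, 0.4)
  f <- wlogit(x, y)
  expect_equal(predict(f, c(0, 0)),
               plogis(coef(f)[["(Intercept)"]]))
  ## monotone in the linear predictor
  etas <- seq(-3, 3, by = 0.5)
  ps <- vapply(etas, function(e) plogis(e), 0)
  expect_true(all(diff(ps) > 0))
  ## Table-style arithmetic: intercept -4.366 at the centred profile
  expect_equal(plogis(-4.366), 1 / (1 + exp(4.366)))
  expect_equal(plogis(-4.366), 0.01254, tolerance = 1e-3)
  expect_error(predict(f, c(1, 2, 3)), "columns")
})

test_that("model-based Wald intervals attain nominal coverage", {
  set.seed(99)
  R <- 500
  n <- 4000
  b1 <- 0.8
  hits <- logical(R)
  for (r in seq_len(R)) {
    x <- matrix(rnorm(n), ncol = 1)
    y <- rbinom(n, 1, plogis(-2 + b1 * x[, 1]))
    f <- wlogit(x, y)
    se <- sqrt(f$vcov[2, 2])
    hits[r] <- abs(coef(f)[2] - b1) <= qnorm(0.975) * se
  }
  expect_gt(mean(hits), 0.925)
  expect_lt(mean(hits), 0.975)
})

test_that("sandwich covariance is positive definite and near model-based under unit weights", {
  set.seed(21)
  x <- matrix(rnorm(4000), ncol = 2)
  y <- rbinom(2000, 1, plogis(0.3 * x[, 1]))
  f <- wlogit(x, y)
  sw <- vcov(f, type = "sandwich")
  expect_true(all(eigen(sw, symmetric = TRUE, only.values = TRUE)$values > 0))
  expect_equal(diag(sw), diag(vcov(f)), tolerance = 0.2)
})
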