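test_that("closed-form nadirs match a grid-plus-golden-section oracle", {
  set.seed(42)
  oracle <- function(powers, b1, b2, scale) {
    f <- function(x) {
      h <- fp_transform(x, powers, scale)
      b1 * h[, 1L] + b2 * h[, 2L]
    }
    gr <- seq(18.5, 99, by = 0.05)
    x0 <- gr[which.min(f(gr))]
    stats::optimize(f, c(max(18.5, x0 - 1), min(99, x0 + 1)),
                    tol = 1e-10)$minimum
  }
  fams <- list(c(-2, -2), c(-1, -1), c(0.5, 0.5), c(0, 0),
               c(-2, -1), c(-2, 1), c(-0.5, 3), c(0, 2), c(-1, 0), c(1, 2))
  checked <- 0L
  for (pw in fams) {
    for (r in 1:150) {
      b1 <- runif(1, -60, 60)
      b2 <- runif(1, -60, 60)
      est <- tryCatch(fp_nadir(pw, b1, b2, scale = 10), error = function(e) NULL)
      if (is.null(est) || est < 19.5 || est > 95) next
      expect_equal(est, oracle(pw, b1, b2, 10), tolerance = 1e-6)
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 50L)
})

test_that("degenerate curve shapes are rejected with informative errors", {
  expect_error(fp_nadir(c(1, 2), 2, -1, 1), "maximum")
  expect_error(fp_nadir(c(-2, -2), 24, 49, 10), "maximum")
  expect_error(fp_nadir(-2, 1, scale = 10), "monotone|stationary")
  expect_error(fp_nadir(c(-2, -1), -20, -18, 10), "stationary|positive root")
})

test_that("the linear-quadratic nadir is -b1/(2 b2)", {
  expect_equal(lq_nadir(-2, 1), 1)
  expect_equal(lq_nadir(0, 5), 0)
  expect_equal(lq_nadir(-0.4, 0.00628), 31.84713, tolerance = 1e-5)
  expect_error(lq_nadir(1, 0), "curvature")
  expect_error(lq_nadir(1, -1), "maximum")
})

test_that("the delta-method gradient matches the analytic worked case", {
  ## LQ family, beta = (-2, 1), identity covariance: nadir 1, se sqrt(1.25)
  st <- fpmort:::fp_stationary(c(1, 2), -2, 1, 1)
  expect_equal(st$x, 1)
  expect_equal(abs(st$grad), c(0.5, 1))
  se <- sqrt(drop(st$grad %*% diag(2) %*% st$grad))
  expect_equal(se, sqrt(1.25), tolerance = 1e-10)
  ci <- st$x + c(-1, 1) * qnorm(0.975) * se
  expect_equal(ci, c(-1.19, 3.19), tolerance = 1e-2)
})

test_that("nadir() on a fitted model: delta CI, degenerate covariance, constancy", {
  coh <- gen_included("male", n = 20000, seed = 19)
  fit <- fit_male_fixed(coh)
  nd <- nadir(fit, at = list(age = 50, ever_smoker = 0))
  expect_false(nd$boundary)
  expect_true(nd$ci[1L] <= nd$estimate && nd$estimate <= nd$ci[2L])
  expect_gt(nd$se, 0)
  expect_gt(nd$mortality, 0)
  ## without BMI interactions the optimum ignores age and smoking
  nd2 <- nadir(fit, at = list(age = 85, ever_smoker = 1))
  expect_equal(nd2$estimate, nd$estimate)
  expect_equal(nd2$se, nd$se)
  ## zero covariance collapses the interval onto the estimate
  fit0 <- fit
  fit0$vcov[] <- 0
  nd0 <- nadir(fit0, at = list(age = 50, ever_smoker = 0))
  expect_equal(nd0$se, 0)
  expect_equal(nd0$ci, c(nd0$estimate, nd0$estimate))
})

test_that("the female reference curve's optimum increases with age", {
  cfg <- cohort_config("female")
  tr <- cfg$truth
  b <- tr$beta
  ctr_age <- fp_center(tr$center_age_at, tr$powers_age, tr$scale)
  nads <- vapply(seq(18, 85, by = 1), function(a) {
    g <- drop(fp_transform(a, tr$powers_age, tr$scale, centers = ctr_age))
    fp_nadir(tr$powers_bmi, b[["bmi1"]] + b[["age_bmi1"]] * g,
             b[["bmi2"]] + b[["age_bmi2"]] * g, tr$scale)
  }, 0)
  expect_true(all(diff(nads) > 0))
  expect_lt(nads[1L], 25)    # young-adult optimum in the normal range
  expect_gt(nads[68L], 25)   # optimum crosses into the overweight range
})

test_that("relative mortality is centring-free and anchored correctly", {
  cfg <- cohort_config("male")
  b <- cfg$truth$beta
  rm0 <- relative_mortality(c(-2, -2), b[["bmi1"]], b[["bmi2"]], 10,
                            bmi = 26.97, ref = 26.97, p_ref = 0.02)
  expect_equal(rm0$ratio, 1)
  rm1 <- relative_mortality(c(-2, -2), b[["bmi1"]], b[["bmi2"]], 10,
                            bmi = 50, ref = 26.97, p_ref = 0.02)
  expect_gt(rm1$ratio, 1)
})
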