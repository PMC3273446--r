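## One moderately sized selection fit is shared across several tests.
sel_coh <- gen_included("male", n = 20000, seed = 7)
sel_fit <- fit_mfp_default(sel_coh)

test_that("the staged closed test decides omit / linear / FP1 / FP2", {
  expect_equal(fsp_decide(100, 99, 98, 97)$chosen, "omitted")
  expect_equal(fsp_decide(150, 120, 119.5, 119)$chosen, "linear")
  d2 <- fsp_decide(300, 250, 240, 230)
  expect_equal(d2$chosen, "fp2")
  expect_equal(d2$tests$df, c(4L, 3L, 2L))
  expect_equal(fsp_decide(300, 250, 240, 239)$chosen, "fp1")
  ## degree-1 analogue uses df 2 then 1
  d1 <- fsp_decide(120, 110, 104)
  expect_equal(d1$chosen, "fp1")
  expect_equal(d1$tests$df, c(2L, 1L))
  expect_error(fsp_decide(100, 99, 98, 99.5), "inconsistent")
  ## alpha = 0: nothing is ever significant, covariate dropped
  expect_equal(fsp_decide(1000, 200, 150, 100, alpha = 0)$chosen, "omitted")
})

test_that("selection retains a strong FP signal and records a closed trace", {
  forms <- sel_fit$trace$forms
  expect_match(forms[["bmi"]], "^fp2")
  expect_match(forms[["age"]], "^fp1")
  expect_true(sel_fit$trace$converged)
  for (cy in sel_fit$trace$cycles) {
    tests <- cy$tests
    ## closedness: FP2 can only be chosen if the df-4 test was significant
    if (cy$chosen == "fp2")
      expect_lt(tests$p_value[1L], sel_fit$alpha)
    ## deviance ordering within every trace entry
    if (!is.null(cy$best_fp2)) {
      expect_lte(cy$best_fp2$deviance, cy$best_fp1$deviance + 1e-6)
      expect_lte(cy$best_fp1$deviance, cy$dev_linear + 1e-6)
    }
    expect_lte(cy$dev_linear, cy$dev_null + 1e-6)
    ## first-stage BMI signal is overwhelming at this sample size
    if (cy$covariate == "bmi") expect_lt(tests$p_value[1L], 1e-3)
  }
})

test_that("a constant covariate is rejected as rank-deficient", {
  d <- data.frame(y = rbinom(50, 1, 0.3), x = rep(2, 50), z = rnorm(50))
  expect_error(mfp_logit(y ~ fp(x, degree = 1) + z, data = d), "constant|collinear")
})

test_that("selection is deterministic and its result is a fixed point", {
  refit <- fit_mfp_default(sel_coh)
  expect_identical(refit$trace$forms, sel_fit$trace$forms)
  expect_equal(coef(refit), coef(sel_fit))
  ## the final cycle of a converged multi-covariate run changed nothing
  cyc <- sel_fit$trace$cycles
  last <- sel_fit$trace$n_cycles
  if (last > 1L) {
    for (cy in cyc[vapply(cyc, function(c) c$cycle == last, TRUE)]) {
      prev <- Filter(function(c) c$cycle == last - 1L &&
                       c$covariate == cy$covariate, cyc)[[1L]]
      expect_identical(cy$chosen, prev$chosen)
      expect_identical(cy$powers, prev$powers)
    }
  }
})

test_that("centering changes only the intercept", {
  set.seed(31)
  n <- 2000
  x <- runif(n, 19, 45)
  z <- rnorm(n)
  y <- rbinom(n, 1, plogis(-2 + 30 * (x / 10)^-2 + 0.3 * z))
  h0 <- fp_transform(x, c(-2, -2), 10)
  h1 <- fp_transform(x, c(-2, -2), 10, centers = fp_center(x, c(-2, -2), 10))
  f0 <- wlogit(cbind(h0, z), y)
  f1 <- wlogit(cbind(h1, z), y)
  expect_equal(coef(f0)[-1L], coef(f1)[-1L], tolerance = 1e-6)
  expect_equal(f0$deviance, f1$deviance, tolerance = 1e-6)
  expect_false(isTRUE(all.equal(coef(f0)[1L], coef(f1)[1L])))
})

test_that("the repeated-power basis is the limit of nearby distinct powers", {
  set.seed(8)
  n <- 800
  x <- runif(n, 19, 45)
  y <- rbinom(n, 1, plogis(-2 + 25 * (x / 10)^-2 - 50 * (x / 10)^-2 * log(x / 10)))
  dev_rep <- wlogit(fp_transform(x, c(-2, -2), 10), y)$deviance
  gaps <- vapply(c(0.5, 0.1, 0.01, 0.001), function(eps) {
    abs(wlogit(fp_transform(x, c(-2, -2 + eps), 10), y)$deviance - dev_rep)
  }, 0)
  expect_true(all(diff(gaps) < 0))
  expect_lt(gaps[length(gaps)], 1e-3)
})

test_that("MFPI detects a strong constructed interaction and skips collinear candidates", {
  set.seed(13)
  n <- 8000
  d <- data.frame(bmi = runif(n, 19, 45), age = runif(n, 20, 80),
                  s = rbinom(n, 1, 0.5))
  g <- (d$age / 10)^2 - fp_center(d$age, 2, 10)
  h <- fp_transform(d$bmi, c(-2, -2), 10,
                    centers = fp_center(d$bmi, c(-2, -2), 10))
  eta <- -3 + 20 * h[, 1] - 40 * h[, 2] + 0.05 * g + 0.02 * g * h[, 1] * 40
  d$y <- rbinom(n, 1, plogis(eta))
  fit <- mfp_logit(y ~ fp(bmi, powers = c(-2, -2)) + fp(age, powers = 2) + s,
                   data = d)
  out <- mfpi(fit, candidates = list(c("bmi", "age")))
  expect_length(out$interactions, 1L)
  expect_lt(out$trace$interaction$p_value[1L], 0.01)
  ## self-product of a binary term is collinear with its main effect
  expect_warning(out2 <- mfpi(fit, candidates = list(c("s", "s"))),
                 "skipped")
  expect_length(out2$interactions, 0L)
})

test_that("MFPI stays quiet when the generator has no interactions", {
  ## male truth has no interaction terms; aggregate over replicates
  included <- logical(20)
  for (r in seq_len(20)) {
    coh <- gen_included("male", n = 10000, seed = 300 + r)
    fit <- fit_male_fixed(coh)
    out <- mfpi(fit)
    included[r] <- length(out$interactions) > 0L
  }
  ## ~5% familywise inclusion expected over three candidates; 14/20 clean
  ## is more than 2 MC standard deviations below the expected count
  expect_gte(sum(!included), 14L)
})

test_that("Lowess empirical-logit curves recover parallel and diverging slopes", {
  set.seed(17)
  n <- 30000
  mk <- function(slope_gap) {
    age <- runif(2 * n, 20, 80)
    s <- rep(c(0, 1), each = n)
    y <- rbinom(2 * n, 1, plogis(-5 + 0.05 * age + 0.6 * s + slope_gap * age * s))
    data.frame(age = age, s = s, y = y)
  }
  slope_of <- function(cv, stratum) {
    d <- cv[cv$stratum == stratum, ]
    unname(coef(lm(smooth ~ x, data = d))[2L])
  }
  cv_par <- logit_lowess(mk(0), "age", "y", "s", bins = 20)
  expect_lt(abs(slope_of(cv_par, 0) - slope_of(cv_par, 1)), 0.05)
  cv_div <- logit_lowess(mk(0.05), "age", "y", "s", bins = 20)
  expect_gt(slope_of(cv_div, 1) - slope_of(cv_div, 0), 0.02)
  expect_error(logit_lowess(mk(0), "age", "y", "s", bins = 3), "at least 5")
})

test_that("an all-survivor stratum yields the continuity-corrected floor", {
  d <- data.frame(x = rep(seq(20, 40, length.out = 200), 2),
                  s = rep(0:1, each = 200),
                  y = c(rep(0, 200), rbinom(200, 1, 0.3)))
  cv <- logit_lowess(d, "x", "y", "s", bins = 5)
  c0 <- cv[cv$stratum == 0, ]
  expect_true(all(c0$deaths == 0))
  expect_equal(c0$logit, qlogis(0.5 / (c0$n + 1)), tolerance = 1e-10)
  expect_lt(max(c0$smooth) - min(c0$smooth), 0.1)
})
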