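test_that("BMI categorization follows right-open intervals", {
  who <- who_scheme()
  expect_identical(categorize_bmi(25, who), "Overweight")
  expect_identical(categorize_bmi(18.5, who), "Normal")
  expect_identical(categorize_bmi(c(24.999, 40), who),
                   c("Normal", "Obese III"))
  nb <- narrow_bin_scheme()
  expect_length(nb$labels, 30L)
  expect_identical(categorize_bmi(54, nb), "[54,Inf)")
  expect_identical(nb$reference, "[22,23)")
  expect_error(categorize_bmi(17, who), "below")
})

test_that("category counts are conserved for every scheme", {
  coh <- gen_included("female", n = 5000, seed = 23)
  for (sch in list(who_scheme(), narrow_bin_scheme())) {
    tab <- table(categorize_bmi(coh$bmi, sch))
    expect_equal(sum(tab), nrow(coh))
  }
})

test_that("comparator fits recover their generating structure", {
  ## linear-quadratic truth: LQ comparator recovers coefficients within 2 SE
  set.seed(29)
  n <- 20000
  d <- data.frame(bmi = runif(n, 19, 50), age = runif(n, 20, 80),
                  ever_smoker = rbinom(n, 1, 0.5))
  b1 <- -3; b2 <- 0.55
  xs <- d$bmi / 10
  d$died <- rbinom(n, 1, plogis(0.5 + b1 * xs + b2 * xs^2 +
                                  0.03 * ((d$age / 10)^2 - 25)))
  main <- mfp_logit(died ~ fp(bmi, powers = c(-2, -2)) + fp(age, powers = 2) +
                      ever_smoker, data = d)
  lq <- fit_comparator(main, "linear-quadratic")
  est <- coef(lq)[c("bmi^(1)", "bmi^(2)")]
  se <- sqrt(diag(lq$vcov)[c("bmi^(1)", "bmi^(2)")])
  expect_lt(abs(est[1L] - b1) / se[1L], 2)
  expect_lt(abs(est[2L] - b2) / se[2L], 2)

  ## uniform risk: all categorical contrasts are near zero
  d$died <- rbinom(n, 1, 0.05)
  main0 <- mfp_logit(died ~ fp(bmi, powers = c(-2, -2)) + fp(age, powers = 2) +
                       ever_smoker, data = d)
  cat0 <- fit_comparator(main0, "categorical")
  ix <- grep("^bmi", names(coef(cat0)))
  z <- coef(cat0)[ix] / sqrt(diag(cat0$vcov)[ix])
  expect_true(all(abs(z) < 3.5))
})

test_that("categorical predictions are constant within category", {
  coh <- gen_included("male", n = 8000, seed = 31)
  main <- fit_male_fixed(coh)
  cat_fit <- fit_comparator(main, "categorical")
  nd <- data.frame(bmi = c(25.1, 29.9, 30.1), age = 50, ever_smoker = 0)
  p <- predict(cat_fit, nd)
  expect_equal(p[1L], p[2L])
  expect_false(isTRUE(all.equal(p[2L], p[3L])))
})

test_that("the selected FP2 never fits worse than the linear-quadratic comparator", {
  coh <- gen_included("male", n = 20000, seed = 37)
  fit <- fit_mfp_default(coh)
  lq <- fit_comparator(fit, "linear-quadratic")
  expect_lte(fit$deviance, lq$deviance + 1e-6)
  ## untransformed BMI is nested in the FP model: df 1, non-negative gap
  lin <- fit_comparator(fit, "untransformed")
  cmp <- compare_models(fit, lin, nested = TRUE,
                        at = list(age = 50, ever_smoker = 0))
  expect_equal(cmp$df, 1L)
  expect_gte(cmp$deviance_difference, -1e-6)
  expect_false(is.na(cmp$p_value))
  ## self-comparison is exactly null
  self <- compare_models(fit, fit, at = list(age = 50, ever_smoker = 0))
  expect_equal(self$deviance_difference, 0)
  expect_equal(unname(self$divergence["max"]), 0)
  ## differing cohorts are refused
  other <- fit_male_fixed(gen_included("male", n = 20000, seed = 38))
  expect_error(compare_models(fit, other), "differing")
})

test_that("narrow-bin estimates bracket the FP curve on data from the FP truth", {
  coh <- gen_included("male", n = 50000, seed = 41)
  main <- fit_male_fixed(coh)
  nb <- suppressWarnings(
    fit_comparator(main, "categorical", scheme = narrow_bin_scheme()))
  sp <- nb$terms$bmi
  counts <- table(categorize_bmi(coh$bmi, sp$scheme))
  prof <- data.frame(age = 50, ever_smoker = 0)
  inside <- 0L; total <- 0L
  for (lev in setdiff(sp$levels, sp$reference)) {
    if (is.na(counts[lev]) || counts[lev] < 200) next
    i <- match(paste0("bmi", lev), names(coef(nb)))
    se <- sqrt(nb$vcov[i, i])
    ## bin interval midpoint (open last bin evaluated at its lower edge + 1)
    lo <- as.numeric(sub("\\[", "", strsplit(lev, ",")[[1L]][1L]))
    hi <- suppressWarnings(as.numeric(sub("\\)", "", strsplit(lev, ",")[[1L]][2L])))
    mid <- if (is.na(hi) || !is.finite(hi)) lo + 1 else (lo + hi) / 2
    nd_mid <- cbind(prof, bmi = mid)
    eta_fp <- predict(main, nd_mid, type = "link")
    eta_nb <- predict(nb, nd_mid, type = "link")
    total <- total + 1L
    if (abs(eta_fp - eta_nb) <= 2 * se) inside <- inside + 1L
  }
  expect_gt(total, 10L)
  expect_gte(inside / total, 0.9)
})

test_that("sensitivity refits: no-op filters reproduce the fit, reverse causation moves the left arm", {
  ## extreme-BMI variant is a no-op when no BMI exceeds 50
  coh <- gen_included("male", n = 15000, seed = 43)
  coh <- coh[coh$bmi <= 50, ]
  fit <- fit_mfp_default(coh)
  sr <- sensitivity_refit(fit, coh, "extreme_bmi",
                          at = list(age = 50, ever_smoker = 0))
  expect_equal(sr$n_removed, 0L)
  expect_equal(coef(sr$fit), coef(fit))

  ## injected excess first-year deaths below BMI 20: excluding early deaths
  ## lowers the left arm of the refitted curve
  coh2 <- gen_included("female", n = 40000, seed = 47,
                       reverse_causation = list(bmi_below = 20, rate = 0.06))
  fit2 <- fit_mfp_default(coh2)
  sr2 <- sensitivity_refit(fit2, coh2, "early_deaths",
                           at = list(age = 50, ever_smoker = 0),
                           bmi = seq(18.5, 60, by = 0.5))
  cv_main <- mortality_curve(fit2, bmi = seq(18.5, 60, by = 0.5),
                             at = list(age = 50, ever_smoker = 0))
  left <- cv_main$bmi <= 19.5
  expect_true(all(sr2$curve$fit[left] < cv_main$fit[left]))
})
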