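## End-to-end study orchestration: inclusion filtering, sex-stratified MFP
## selection, interaction testing, nadir estimation, comparator fits,
## sensitivity refits and report assembly.

#' Descriptive summary by sex and survey year
#'
#' One row per sex-by-year cell plus a Total row per sex: sample size,
#' deaths, deaths per 1000, mean age, WHO BMI-category prevalence (percent)
#' and ever-smoker percentage.
#'
#' @param cohort A filtered cohort data frame (`sex`, `survey_year`, `age`,
#'   `bmi`, `ever_smoker`, `died` columns).
#' @return A data frame.
#' @export
report_descriptives <- function(cohort) {
  scheme <- who_scheme()
  one <- function(d, sex, year) {
    cat_p <- 100 * prop.table(table(factor(categorize_bmi(d$bmi, scheme),
                                           levels = scheme$labels)))
    data.frame(sex = sex, survey_year = year, n = nrow(d),
               deaths = sum(d$died), deaths_per_1000 = 1000 * mean(d$died),
               age_mean = mean(d$age),
               pct_normal = cat_p[["Normal"]],
               pct_overweight = cat_p[["Overweight"]],
               pct_obese1 = cat_p[["Obese I"]],
               pct_obese2 = cat_p[["Obese II"]],
               pct_obese3 = cat_p[["Obese III"]],
               pct_ever_smoker = 100 * mean(d$ever_smoker),
               stringsAsFactors = FALSE)
  }
  out <- list()
  for (s in unique(cohort$sex)) {
    ds <- cohort[cohort$sex == s, , drop = FALSE]
    for (yr in sort(unique(ds$survey_year)))
      out[[length(out) + 1L]] <-
        one(ds[ds$survey_year == yr, , drop = FALSE], s, as.character(yr))
    out[[length(out) + 1L]] <- one(ds, s, "Total")
  }
  do.call(rbind, out)
}

#' Run the full BMI-mortality study on a cohort
#'
#' Applies the inclusion rules, stratifies by sex, and for each stratum:
#' selects the BMI and age functional forms by MFP, tests interactions by
#' MFPI, estimates the BMI of minimum mortality (per age and smoking
#' profile) with delta-method intervals, fits the comparator models, and
#' extracts mortality curves on a common BMI grid.  With `out_dir` set, the
#' reports are also written as CSV (descriptives, coefficients, nadirs,
#' curves) plus a JSON selection trace and a run log.
#'
#' @param cohort Data frame (raw records; inclusion rules are applied
#'   here), e.g. `rbind` of [generate_cohort()] output for both sexes, or
#'   [read_cohort()] output.
#' @param horizon Outcome horizon in years (5 or 3 expected; others allowed
#'   with a warning).  Deaths with `time_to_death` beyond the horizon count
#'   as survivors.
#' @param alpha Significance level for all selection tests.
#' @param sexes Strata to analyse.
#' @param comparators Comparator model kinds (see [fit_comparator()]).
#' @param sensitivity Sensitivity variants (see [sensitivity_refit()]), run
#'   only when `time_to_death` is available.
#' @param ages,smokers Profiles at which nadirs and curves are evaluated.
#' @param bmi_grid Common BMI grid for curves.
#' @param chisq_compat Emit chi-square p-values for non-nested comparisons.
#' @param out_dir Optional output directory.
#' @param seed Seed set before analysis (covers nothing stochastic in the
#'   fits themselves; recorded in the run log).
#' @return A list of class `"fpmort_study"`.
#' @export
run_study <- function(cohort, horizon = 5, alpha = 0.05,
                      sexes = c("male", "female"),
                      comparators = c("untransformed", "linear-quadratic",
                                      "categorical"),
                      sensitivity = c("early_deaths", "extreme_bmi"),
                      ages = c(40, 50, 65), smokers = c(0, 1),
                      bmi_grid = seq(18.5, 60, by = 0.5),
                      chisq_compat = FALSE, out_dir = NULL, seed = NULL) {
  if (!is.data.frame(cohort) || !nrow(cohort))
    stop("empty or invalid cohort input", call. = FALSE)
  if (!(horizon %in% c(3, 5)))
    warning("unusual outcome horizon: ", horizon, " years")
  if (!is.null(seed)) set.seed(seed)

  coh <- apply_inclusion(cohort)
  if (!nrow(coh)) stop("no records left after inclusion filtering", call. = FALSE)
  coh$died_h <- as.integer(coh$died == 1 & !is.na(coh$time_to_death) &
                             coh$time_to_death <= horizon)

  desc <- report_descriptives(transform(coh, died = died_h))
  strata <- list()
  for (s in intersect(sexes, unique(coh$sex))) {
    d <- coh[coh$sex == s, , drop = FALSE]
    if (!sum(d$died_h)) {
      strata[[s]] <- list(error = "stratum has zero deaths; skipped")
      next
    }
    fit0 <- mfp_logit(died_h ~ fp(bmi, degree = 2) + fp(age, degree = 1) +
                        ever_smoker,
                      data = d, weights = weight, alpha = alpha)
    fit <- mfpi(fit0, alpha = alpha)

    nad <- list()
    for (a in ages) for (sm in smokers) {
      nd <- tryCatch(nadir(fit, at = list(age = a, ever_smoker = sm)),
                     error = function(e) NULL)
      if (!is.null(nd))
        nad[[length(nad) + 1L]] <- data.frame(
          age = a, ever_smoker = sm, nadir = nd$estimate, se = nd$se,
          ci_low = nd$ci[1L], ci_high = nd$ci[2L],
          mortality_at_optimum = nd$mortality, boundary = nd$boundary)
    }
    nad <- if (length(nad)) do.call(rbind, nad) else NULL

    comp <- list()
    for (kind in comparators) {
      cf <- fit_comparator(fit, kind = kind)
      comp[[kind]] <- list(
        fit = cf,
        comparison = compare_models(fit, cf,
                                    nested = kind == "untransformed",
                                    chisq_compat = chisq_compat,
                                    at = list(age = 50, ever_smoker = 0),
                                    bmi = bmi_grid))
    }

    curves <- list()
    for (a in ages) for (sm in smokers) {
      cv <- mortality_curve(fit, bmi = bmi_grid,
                            at = list(age = a, ever_smoker = sm))
      cv$sex <- s; cv$model <- "fp"; cv$age <- a; cv$ever_smoker <- sm
      curves[[length(curves) + 1L]] <- cv
    }
    curves <- do.call(rbind, curves)

    sens <- list()
    if (all(c("time_to_death") %in% names(d))) {
      for (v in sensitivity)
        sens[[v]] <- tryCatch(
          sensitivity_refit(fit, d, variant = v,
                            at = list(age = 50, ever_smoker = 0),
                            bmi = bmi_grid),
          error = function(e) list(error = conditionMessage(e)))
    }

    strata[[s]] <- list(fit = fit, nadirs = nad, comparators = comp,
                        curves = curves, sensitivity = sens,
                        coef_table = coef_report(fit), trace = fit$trace)
  }

  res <- structure(list(descriptives = desc, strata = strata,
                        exclusions = attr(coh, "exclusions"),
                        settings = list(horizon = horizon, alpha = alpha,
                                        ages = ages, smokers = smokers,
                                        seed = seed)),
                   class = "fpmort_study")
  if (!is.null(out_dir)) write_study(res, out_dir)
  res
}

#' @export
print.fpmort_study <- function(x, ...) {
  cat("BMI-mortality MFP study\n")
  cat(sprintf("horizon: %g years, alpha = %g\n",
              x$settings$horizon, x$settings$alpha))
  for (s in names(x$strata)) {
    st <- x$strata[[s]]
    if (!is.null(st$error)) {
      cat(sprintf("  %s: %s\n", s, st$error))
      next
    }
    bmi_form <- st$trace$forms[["bmi"]]
    age_form <- st$trace$forms[["age"]]
    cat(sprintf("  %s: n = %d, BMI form %s, age form %s, %d interaction(s)\n",
                s, st$fit$n, bmi_form, age_form,
                length(st$fit$interactions)))
    if (!is.null(st$nadirs)) {
      i50 <- which(st$nadirs$age == 50 & st$nadirs$ever_smoker == 0)
      if (length(i50))
        cat(sprintf("     nadir at age 50 (never smoker): %.2f [%.2f, %.2f]\n",
                    st$nadirs$nadir[i50[1L]], st$nadirs$ci_low[i50[1L]],
                    st$nadirs$ci_high[i50[1L]]))
    }
  }
  invisible(x)
}

## Serialize the report bundle: CSVs + JSON trace + run log.
write_study <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(res$descriptives, file.path(out_dir, "descriptives.csv"),
                   row.names = FALSE)
  for (s in names(res$strata)) {
    st <- res$strata[[s]]
    if (!is.null(st$error)) next
    utils::write.csv(st$coef_table,
                     file.path(out_dir, paste0("coefficients_", s, ".csv")),
                     row.names = FALSE)
    if (!is.null(st$nadirs))
      utils::write.csv(st$nadirs,
                       file.path(out_dir, paste0("nadir_", s, ".csv")),
                       row.names = FALSE)
    utils::write.csv(st$curves,
                     file.path(out_dir, paste0("curves_", s, ".csv")),
                     row.names = FALSE)
    tr <- st$trace
    tr$cycles <- lapply(tr$cycles, function(cy) {
      cy$best_fp1 <- NULL; cy$best_fp2 <- NULL; cy
    })
    jsonlite::write_json(tr, file.path(out_dir, paste0("trace_", s, ".json")),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  log <- c(sprintf("fpmort run %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
           sprintf("seed: %s", deparse(res$settings$seed)),
           sprintf("horizon: %g, alpha: %g", res$settings$horizon,
                   res$settings$alpha),
           sprintf("exclusions: %s",
                   paste(names(res$exclusions), res$exclusions,
                         sep = "=", collapse = ", ")))
  writeLines(log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}
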