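## Multivariable fractional polynomial model fitting.
##
## mfp_logit() is the package's central fitting function.  Continuous
## covariates wrapped in fp() in the model formula have their functional
## form chosen by the closed test procedure: the best-fitting FP2 is
## compared against the null model (4 df), the linear model (3 df) and the
## best FP1 (2 df), in that order, so the covariate ends up omitted, linear,
## FP1 or FP2 while the staged structure controls the familywise error of
## the selection.  With several fp() terms the closed test is cycled over
## the covariates (most significant first, by the Wald test in a preliminary
## all-linear model) until a full cycle changes nothing.

#' Mark a model term for fractional polynomial selection
#'
#' Used inside the formula of [mfp_logit()], e.g.
#' `died ~ fp(bmi, degree = 2) + fp(age, degree = 1) + smoker`.
#'
#' @param x A positive continuous covariate.
#' @param degree Maximum FP degree to consider (1 or 2).
#' @param scale Positive divisor applied before transformation; the default
#'   10 suits covariates measured in the tens, such as BMI or age in years.
#' @param powers Optional fixed power vector: the term is entered with these
#'   powers and excluded from selection.
#' @return `x` with attributes; only meaningful inside a formula.
#' @export
fp <- function(x, degree = 2, scale = 10, powers = NULL) {
  structure(x, fp_degree = degree, fp_scale = scale, fp_powers = powers)
}

#' Closed-test decision among omitted / linear / FP1 / FP2
#'
#' A pure function of the four deviances.  Test 1 compares the best FP2
#' against the null model on 4 df (is the covariate needed at all?); test 2
#' against the linear model on 3 df (is any transformation needed?); test 3
#' against the best FP1 on 2 df (is second degree needed?).  With
#' `dev_fp2 = NULL` the degree-1 analogue is applied (df 2 then 1).
#'
#' @param dev_null Deviance of the model omitting the covariate.
#' @param dev_linear Deviance with the covariate entered linearly.
#' @param dev_fp1 Deviance of the best first-degree FP.
#' @param dev_fp2 Deviance of the best second-degree FP, or `NULL`.
#' @param alpha Significance level (default 0.05).
#' @param tol Tolerance for deviance-ordering consistency checks.
#' @return List with `chosen` (one of `"omitted"`, `"linear"`, `"fp1"`,
#'   `"fp2"`) and `tests`, a data frame of the staged comparisons.
#' @export
#' @examples
#' fsp_decide(300, 250, 240, 230)$chosen # "fp2"
fsp_decide <- function(dev_null, dev_linear, dev_fp1, dev_fp2 = NULL,
                       alpha = 0.05, tol = 1e-6) {
  best <- if (is.null(dev_fp2)) dev_fp1 else dev_fp2
  subs <- c(null = dev_null, linear = dev_linear, fp1 = dev_fp1)
  if (!is.null(dev_fp2)) {
    if (any(best > subs + tol))
      stop("inconsistent deviances: best FP2 fits worse than a sub-model", call. = FALSE)
  } else {
    if (best > dev_linear + tol || best > dev_null + tol)
      stop("inconsistent deviances: best FP1 fits worse than a sub-model", call. = FALSE)
  }
  d <- if (is.null(dev_fp2)) 1L else 2L
  tests <- list()
  add <- function(comparison, tt) {
    tests[[length(tests) + 1L]] <<- data.frame(
      comparison = comparison, statistic = tt$statistic, df = tt$df,
      p_value = tt$p_value, stringsAsFactors = FALSE)
  }
  out <- function(chosen) list(chosen = chosen, tests = do.call(rbind, tests))

  t1 <- deviance_test(dev_null, best, df = 2L * d, tol = tol)
  add("best FP vs null", t1)
  if (!(t1$p_value < alpha)) return(out("omitted"))
  t2 <- deviance_test(dev_linear, best, df = 2L * d - 1L, tol = tol)
  add("best FP vs linear", t2)
  if (!(t2$p_value < alpha)) return(out("linear"))
  if (is.null(dev_fp2)) return(out("fp1"))
  t3 <- deviance_test(dev_fp1, dev_fp2, df = 2L, tol = tol)
  add("FP2 vs FP1", t3)
  out(if (t3$p_value < alpha) "fp2" else "fp1")
}

## Fit every FP candidate of a covariate given fixed adjuster columns and
## apply the closed test.  Centering is irrelevant to deviances, so the
## search uses uncentred columns.
select_fp <- function(y, w, x, adjust, degree, alpha, scale,
                      tiebreak_tol = 1e-8) {
  if (length(unique(x)) < 2L)
    stop("covariate is constant: rank-deficient design", call. = FALSE)
  fit_dev <- function(cols) {
    f <- tryCatch(wlogit(cbind(cols, adjust), y, w),
                  error = function(e) NULL)
    if (is.null(f) || !f$converged) return(NA_real_)
    f$deviance
  }
  dev_null <- wlogit(adjust, y, w)$deviance

  cand1 <- fp_candidates(1)
  dev1 <- vapply(cand1, function(p) fit_dev(fp_transform(x, p, scale)), 0)
  cand_tab <- data.frame(powers = vapply(cand1, format_powers, ""),
                         degree = 1L, deviance = dev1, stringsAsFactors = FALSE)
  dev_linear <- dev1[[which(vapply(cand1, function(p) identical(p, 1), TRUE))]]
  if (is.na(dev_linear))
    stop("linear reference fit did not converge", call. = FALSE)

  pick <- function(devs) {
    ok <- which(!is.na(devs))
    if (!length(ok)) stop("no fractional polynomial candidate converged", call. = FALSE)
    best <- min(devs[ok])
    ok[which(devs[ok] <= best + tiebreak_tol)[1L]]
  }
  if (any(is.na(dev1)))
    warning(sum(is.na(dev1)), " degree-1 candidate fit(s) skipped (non-convergence)")
  i1 <- pick(dev1)
  best1 <- list(powers = cand1[[i1]], deviance = dev1[i1])

  best2 <- NULL
  if (degree >= 2) {
    cand2 <- fp_candidates(2)
    dev2 <- vapply(cand2, function(p) fit_dev(fp_transform(x, p, scale)), 0)
    if (any(is.na(dev2)))
      warning(sum(is.na(dev2)), " degree-2 candidate fit(s) skipped (non-convergence)")
    cand_tab <- rbind(cand_tab,
                      data.frame(powers = vapply(cand2, format_powers, ""),
                                 degree = 2L, deviance = dev2,
                                 stringsAsFactors = FALSE))
    i2 <- pick(dev2)
    best2 <- list(powers = cand2[[i2]], deviance = dev2[i2])
  }

  dec <- fsp_decide(dev_null, dev_linear, best1$deviance,
                    if (is.null(best2)) NULL else best2$deviance, alpha = alpha)
  powers <- switch(dec$chosen,
                   omitted = NULL, linear = 1,
                   fp1 = best1$powers, fp2 = best2$powers)
  list(chosen = dec$chosen, powers = powers, tests = dec$tests,
       dev_null = dev_null, dev_linear = dev_linear,
       best_fp1 = best1, best_fp2 = best2, candidates = cand_tab)
}

## Columns contributed by one term spec (used for the design and for
## interaction products).  Plain terms contribute their raw column.
term_columns <- function(sp, data, centered = TRUE) {
  if (sp$type == "fp") {
    if (identical(sp$chosen, "omitted")) return(NULL)
    ctr <- if (centered) sp$centers else NULL
    h <- fp_transform(data[[sp$name]], sp$powers, sp$scale, ctr)
    colnames(h) <- sp$labels
    h
  } else if (sp$type == "plain") {
    h <- matrix(as.numeric(data[[sp$name]]), ncol = 1L)
    colnames(h) <- sp$name
    h
  } else if (sp$type == "categorical") {
    categorical_columns(data[[sp$name]], sp)
  } else stop("unknown term type: ", sp$type)
}

interaction_columns <- function(ia, specs, data) {
  a <- term_columns(specs[[ia$a]], data)
  b <- term_columns(specs[[ia$b]], data)
  out <- NULL
  labs <- character()
  for (i in seq_len(ncol(a)))
    for (j in seq_len(ncol(b))) {
      out <- cbind(out, a[, i] * b[, j])
      labs <- c(labs, paste0(colnames(a)[i], ":", colnames(b)[j]))
    }
  colnames(out) <- labs
  out
}

build_design <- function(specs, interactions, data) {
  cols <- NULL
  for (sp in specs) {
    h <- term_columns(sp, data)
    if (!is.null(h)) cols <- cbind(cols, h)
  }
  for (ia in interactions) cols <- cbind(cols, interaction_columns(ia, specs, data))
  cols
}

## Final weighted fit for a given set of term specs; wraps into "mfp_logit".
mfp_finalize <- function(specs, interactions, data, y, w, trace, alpha,
                         formula = NULL, call = NULL, outcome_name = "y") {
  X <- build_design(specs, interactions, data)
  fit <- wlogit(X, y, w)
  structure(list(coefficients = fit$coefficients, vcov = fit$vcov,
                 sandwich = fit$sandwich, deviance = fit$deviance,
                 loglik = fit$loglik, n = fit$n, converged = fit$converged,
                 fit = fit, terms = specs, interactions = interactions,
                 trace = trace, alpha = alpha, formula = formula,
                 call = call, model = data, y = y, weights = w,
                 outcome_name = outcome_name),
            class = "mfp_logit")
}

#' Fit a survey-weighted logistic model with MFP covariate selection
#'
#' Covariates wrapped in [fp()] have their functional form selected by the
#' closed test procedure, cycled over covariates until stable (multivariable
#' fractional polynomials).  Plain terms are kept in the model throughout
#' (forced in), entered untransformed.  After selection, every retained FP
#' column is centered at the transform of the covariate's unweighted sample
#' mean, so the intercept refers to a mean-covariate subject and centering
#' affects no other coefficient.
#'
#' @param formula Model formula; the response must be binary.  Continuous
#'   terms to be selected are wrapped in [fp()].
#' @param data Data frame containing the variables.
#' @param weights Optional positive survey weights, evaluated in `data`
#'   (e.g. `weights = weight`), treated as frequency-type pseudo-likelihood
#'   weights after rescaling to unit mean (so deviances stay on the
#'   sample-size scale and deviance tests remain calibrated).
#' @param alpha Significance level for every selection test.
#' @param max_cycles Cap on selection cycles over the covariates.
#' @param trace_candidates Keep the full per-candidate deviance tables in the
#'   returned trace (default `TRUE`).
#' @return An object of class `"mfp_logit"`; see [summary.mfp_logit()],
#'   [predict.mfp_logit()], [nadir()], [mortality_curve()].
#' @export
#' @examples
#' cfg <- cohort_config("male", n = 4000, seed = 7)
#' coh <- apply_inclusion(generate_cohort(cfg))
#' fit <- mfp_logit(died ~ fp(bmi, degree = 2) + fp(age, degree = 1) + ever_smoker,
#'                  data = coh, weights = weight)
#' fit
mfp_logit <- function(formula, data, weights = NULL, alpha = 0.05,
                      max_cycles = 5L, trace_candidates = TRUE) {
  cl <- match.call()
  w <- eval(substitute(weights), data, environment(formula))

  tf <- stats::terms(formula, specials = "fp", data = data)
  labs <- attr(tf, "term.labels")
  if (attr(tf, "response") != 1L) stop("formula needs a response", call. = FALSE)
  yname <- deparse(attr(tf, "variables")[[2L]])
  y <- eval(attr(tf, "variables")[[2L]], data, environment(formula))
  y <- as.numeric(y)

  specs <- list()
  raw <- list()
  for (lb in labs) {
    ex <- str2lang(lb)
    if (is.call(ex) && identical(ex[[1L]], as.name("fp"))) {
      mc <- match.call(fp, ex)
      nm <- deparse(mc$x)
      val <- eval(mc$x, data, environment(formula))
      deg <- if (is.null(mc$degree)) 2 else eval(mc$degree, data, environment(formula))
      sc <- if (is.null(mc$scale)) 10 else eval(mc$scale, data, environment(formula))
      fixed <- if (is.null(mc$powers)) NULL else eval(mc$powers, data, environment(formula))
      specs[[nm]] <- list(name = nm, type = "fp", degree = deg, scale = sc,
                          fixed = fixed, chosen = NA_character_,
                          powers = NULL, centers = NULL, labels = NULL)
    } else {
      nm <- lb
      val <- eval(ex, data, environment(formula))
      specs[[nm]] <- list(name = nm, type = "plain")
    }
    raw[[nm]] <- as.numeric(val)
  }
  if (!length(specs)) stop("no covariates in formula", call. = FALSE)

  mf <- as.data.frame(raw, optional = TRUE)
  names(mf) <- names(raw)
  keep <- stats::complete.cases(mf) & !is.na(y) & (if (is.null(w)) TRUE else !is.na(w))
  if (!all(keep)) {
    warning(sum(!keep), " incomplete row(s) dropped")
    mf <- mf[keep, , drop = FALSE]
    y <- y[keep]
    if (!is.null(w)) w <- w[keep]
  }
  if (!nrow(mf)) stop("no complete observations", call. = FALSE)
  if (is.null(w)) w <- rep(1, nrow(mf))
  ## rescale to unit mean: only relative weights matter for the point
  ## estimates, and this keeps deviances on the sample-size scale so that
  ## deviance-difference chi-square tests are calibrated
  w <- w / mean(w)

  fpn <- names(specs)[vapply(specs, function(s) s$type == "fp", TRUE)]
  selectable <- fpn[vapply(specs[fpn], function(s) is.null(s$fixed), TRUE)]
  for (nm in setdiff(fpn, selectable)) {
    specs[[nm]]$chosen <- "fixed"
    specs[[nm]]$powers <- sort(specs[[nm]]$fixed)
  }

  ## initial forms: every selectable fp term linear
  for (nm in selectable) {
    specs[[nm]]$chosen <- "linear"
    specs[[nm]]$powers <- 1
  }

  ## visit order: descending Wald significance in the all-linear model
  order_nms <- selectable
  if (length(selectable) > 1L) {
    lin_cols <- NULL
    for (nm in names(specs)) {
      colv <- if (specs[[nm]]$type == "fp") mf[[nm]] / specs[[nm]]$scale else mf[[nm]]
      lin_cols <- cbind(lin_cols, colv)
    }
    colnames(lin_cols) <- names(specs)
    pre <- wlogit(lin_cols, y, w)
    z <- abs(pre$coefficients[selectable] / sqrt(diag(pre$vcov)[selectable]))
    order_nms <- selectable[order(-z, seq_along(selectable))]
  }

  cycles <- list()
  cycle_converged <- length(selectable) == 0L
  n_cycles <- 0L
  if (length(selectable)) {
    for (cyc in seq_len(max_cycles)) {
      n_cycles <- cyc
      changed <- FALSE
      for (nm in order_nms) {
        others <- specs[names(specs) != nm]
        adjust <- NULL
        for (sp in others) {
          h <- if (sp$type == "fp") {
            if (identical(sp$chosen, "omitted")) NULL
            else fp_transform(mf[[sp$name]], sp$powers, sp$scale)
          } else matrix(as.numeric(mf[[sp$name]]), ncol = 1L)
          if (!is.null(h)) adjust <- cbind(adjust, h)
        }
        res <- select_fp(y, w, mf[[nm]], adjust,
                         degree = specs[[nm]]$degree, alpha = alpha,
                         scale = specs[[nm]]$scale)
        if (!trace_candidates) res$candidates <- NULL
        cycles[[length(cycles) + 1L]] <-
          c(list(cycle = cyc, covariate = nm), res)
        if (!identical(res$chosen, specs[[nm]]$chosen) ||
            !identical(res$powers, specs[[nm]]$powers)) changed <- TRUE
        specs[[nm]]$chosen <- res$chosen
        specs[[nm]]$powers <- res$powers
      }
      if (!changed || length(selectable) == 1L) {
        ## one selectable covariate: its adjusters never change, so the
        ## first pass is already the fixed point
        cycle_converged <- TRUE
        break
      }
    }
    if (!cycle_converged)
      warning("MFP cycling hit the cycle cap without stabilizing; returning current model")
  }

  ## centering and labels for retained fp terms
  for (nm in fpn) {
    sp <- specs[[nm]]
    if (identical(sp$chosen, "omitted")) next
    specs[[nm]]$centers <- fp_center(mf[[nm]], sp$powers, sp$scale)
    specs[[nm]]$labels <- fp_labels(nm, sp$powers)
  }

  tr <- list(order = order_nms, cycles = cycles, n_cycles = n_cycles,
             converged = cycle_converged,
             forms = vapply(specs, function(s)
               if (s$type != "fp") "plain"
               else if (identical(s$chosen, "omitted")) "omitted"
               else paste0(s$chosen, " ", format_powers(s$powers)), ""))
  mf$.weights <- w
  mfp_finalize(specs, list(), mf, y, w, tr, alpha,
               formula = formula, call = cl, outcome_name = yname)
}
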