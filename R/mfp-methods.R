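## Methods for "mfp_logit" objects.

#' @export
print.mfp_logit <- function(x, digits = max(3L, getOption("digits") - 3L), ...) {
  if (!is.null(x$call)) {
    cat("Call:\n")
    print(x$call)
    cat("\n")
  }
  cat("Survey-weighted logistic model with fractional polynomial terms\n")
  if (!is.null(x$trace$forms)) {
    cat("Selected forms:\n")
    for (nm in names(x$trace$forms))
      cat(sprintf("  %-12s %s\n", nm, x$trace$forms[[nm]]))
  }
  if (length(x$interactions))
    cat("Interactions:",
        paste(vapply(x$interactions, function(i) paste0(i$a, " x ", i$b), ""),
              collapse = ", "), "\n")
  cat("\nCoefficients:\n")
  print(round(x$coefficients, digits))
  cat(sprintf("\nn = %d, deviance = %.3f, log-likelihood = %.3f\n",
              x$n, x$deviance, x$loglik))
  invisible(x)
}

#' Summarize a fitted MFP logistic model
#'
#' @param object An `"mfp_logit"` fit.
#' @param vcov_type `"model"` or `"sandwich"` standard errors.
#' @param ... Unused.
#' @return An object of class `"summary.mfp_logit"` holding the coefficient
#'   table (estimate, SE, z, p), the selected functional forms, interaction
#'   record and fit statistics.
#' @export
summary.mfp_logit <- function(object, vcov_type = c("model", "sandwich"), ...) {
  V <- vcov(object, type = match.arg(vcov_type))
  se <- sqrt(diag(V))
  z <- object$coefficients / se
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = se,
               `z value` = z, `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  structure(list(coefficients = tab, forms = object$trace$forms,
                 interactions = object$interactions, deviance = object$deviance,
                 loglik = object$loglik, n = object$n, alpha = object$alpha,
                 converged = object$converged, call = object$call),
            class = "summary.mfp_logit")
}

#' @export
print.summary.mfp_logit <- function(x, digits = max(3L, getOption("digits") - 3L), ...) {
  if (!is.null(x$call)) {
    cat("Call:\n")
    print(x$call)
    cat("\n")
  }
  if (!is.null(x$forms)) {
    cat("Selected forms:\n")
    for (nm in names(x$forms)) cat(sprintf("  %-12s %s\n", nm, x$forms[[nm]]))
    cat("\n")
  }
  stats::printCoefmat(x$coefficients, digits = digits, P.values = TRUE,
                      has.Pvalue = TRUE)
  cat(sprintf("\nn = %d, deviance = %.3f, log-likelihood = %.3f\n",
              x$n, x$deviance, x$loglik))
  invisible(x)
}

#' @export
coef.mfp_logit <- function(object, ...) object$coefficients

#' @rdname vcov.wlogit
#' @export
vcov.mfp_logit <- function(object, type = c("model", "sandwich"), ...) {
  switch(match.arg(type), model = object$vcov, sandwich = object$sandwich)
}

#' @export
logLik.mfp_logit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients),
            nobs = object$n, class = "logLik")
}

#' @export
deviance.mfp_logit <- function(object, ...) object$deviance

#' @export
formula.mfp_logit <- function(x, ...) x$formula

#' Predict mortality probabilities from an MFP logistic fit
#'
#' Rebuilds the design from the stored functional forms (powers, scale,
#' centering constants) and any interactions, so `newdata` only needs the
#' raw covariate columns.
#'
#' @param object An `"mfp_logit"` fit.
#' @param newdata Data frame of raw covariates; default the fitting data.
#' @param type `"response"` (probability) or `"link"`.
#' @param se.fit Also return delta-method standard errors (computed on the
#'   link scale; transformed by `p(1-p)` for the response scale).
#' @param ... Unused.
#' @export
predict.mfp_logit <- function(object, newdata = NULL,
                              type = c("response", "link"), se.fit = FALSE, ...) {
  type <- match.arg(type)
  if (is.null(newdata)) newdata <- object$model
  X <- build_design(object$terms, object$interactions, newdata)
  X1 <- cbind(1, X)
  if (ncol(X1) != length(object$coefficients))
    stop("design built from newdata does not match the model", call. = FALSE)
  eta <- drop(X1 %*% object$coefficients)
  if (!se.fit) {
    return(if (type == "link") eta else stats::plogis(eta))
  }
  se_eta <- sqrt(rowSums((X1 %*% object$vcov) * X1))
  if (type == "link") {
    list(fit = eta, se.fit = se_eta)
  } else {
    p <- stats::plogis(eta)
    list(fit = p, se.fit = se_eta * p * (1 - p))
  }
}

#' @export
residuals.mfp_logit <- function(object,
                                type = c("deviance", "pearson", "response"),
                                ...) {
  type <- match.arg(type)
  mu <- object$fit$fitted
  y <- object$y
  w <- object$weights
  switch(type,
         response = y - mu,
         pearson = sqrt(w) * (y - mu) / sqrt(mu * (1 - mu)),
         deviance = {
           d <- -2 * w * (y * log(mu) + (1 - y) * log(1 - mu))
           sign(y - mu) * sqrt(pmax(d, 0))
         })
}

#' Simulate outcomes from a fitted MFP logistic model
#'
#' Draws Bernoulli outcomes at the fitted probabilities, one column per
#' simulation (parametric bootstrap of the outcome vector).
#'
#' @param object An `"mfp_logit"` fit.
#' @param nsim Number of simulated outcome vectors.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @export
simulate.mfp_logit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- object$fit$fitted
  out <- as.data.frame(replicate(nsim, stats::rbinom(length(mu), 1L, mu)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Plot the fitted mortality curve against BMI
#'
#' Draws predicted mortality (with a pointwise confidence band) over a BMI
#' grid at a fixed covariate profile.
#'
#' @param x An `"mfp_logit"` fit.
#' @param term Name of the BMI-like exposure term (default: first degree-2
#'   fp term).
#' @param at Named list giving the other covariates' values.
#' @param bmi Grid of exposure values.
#' @param level Confidence level for the band.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.mfp_logit <- function(x, term = NULL, at = list(),
                           bmi = NULL, level = 0.95, ...) {
  cv <- mortality_curve(x, bmi = bmi, at = at, term = term, level = level)
  graphics::plot(cv$bmi, cv$fit, type = "n",
                 ylim = range(cv$lwr, cv$upr),
                 xlab = "BMI (kg/m²)", ylab = "Predicted mortality", ...)
  graphics::polygon(c(cv$bmi, rev(cv$bmi)), c(cv$lwr, rev(cv$upr)),
                    col = grDevices::adjustcolor("grey60", 0.4), border = NA)
  graphics::lines(cv$bmi, cv$fit, lwd = 2)
  invisible(cv)
}

#' Table-style coefficient report
#'
#' Returns the coefficient table as a data frame.  When an interaction
#' between an fp-transformed covariate and a binary covariate is present,
#' rows giving the stratum-specific slopes (e.g. the age slope among never
#' and ever smokers) are appended, with delta-method standard errors.
#'
#' @param object An `"mfp_logit"` fit.
#' @return Data frame with columns `term`, `estimate`, `se`.
#' @export
coef_report <- function(object) {
  se <- sqrt(diag(object$vcov))
  out <- data.frame(term = names(object$coefficients),
                    estimate = unname(object$coefficients),
                    se = unname(se), stringsAsFactors = FALSE)
  for (ia in object$interactions) {
    spa <- object$terms[[ia$a]]
    spb <- object$terms[[ia$b]]
    ## fp x binary: report stratum-specific slopes of the fp column
    bin <- NULL; con <- NULL
    if (spa$type == "fp" && spb$type == "plain" && length(spa$labels) == 1L) {
      con <- spa; bin <- spb
    } else if (spb$type == "fp" && spa$type == "plain" && length(spb$labels) == 1L) {
      con <- spb; bin <- spa
    }
    if (is.null(bin)) next
    main_lab <- con$labels
    int_lab <- grep(bin$name, ia$labels, value = TRUE, fixed = TRUE)[1L]
    if (!(main_lab %in% names(object$coefficients)) ||
        !(int_lab %in% names(object$coefficients))) next
    i <- match(main_lab, names(object$coefficients))
    j <- match(int_lab, names(object$coefficients))
    V <- object$vcov
    out <- rbind(out,
      data.frame(term = paste0(main_lab, " | ", bin$name, " = 0"),
                 estimate = unname(object$coefficients[i]),
                 se = sqrt(V[i, i]), stringsAsFactors = FALSE),
      data.frame(term = paste0(main_lab, " | ", bin$name, " = 1"),
                 estimate = unname(object$coefficients[i] + object$coefficients[j]),
                 se = sqrt(V[i, i] + V[j, j] + 2 * V[i, j]),
                 stringsAsFactors = FALSE))
  }
  out
}
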