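## Survey-weighted logistic regression by iteratively reweighted least
## squares.  Weights are treated as pseudo-likelihood frequency weights: the
## fit maximizes sum_i w_i [y_i log p_i + (1 - y_i) log(1 - p_i)], the
## deviance is -2 times that weighted log-likelihood, and the default
## covariance is the inverse of the weighted information matrix.  A
## design-based (sandwich) covariance is also stored for users who want
## robust standard errors.

#' Fit a weighted logistic regression
#'
#' @param x Numeric design matrix of covariate columns (no intercept column;
#'   an intercept is always added first), or `NULL` for an intercept-only fit.
#' @param y Binary outcome vector (0/1 or logical).
#' @param weights Positive case weights (default all 1).
#' @param maxit Maximum IRLS iterations.
#' @param tol Relative deviance-change convergence tolerance.
#' @param labels Optional column labels (default `colnames(x)`).
#'
#' @details Fitted probabilities are clipped to `[1e-12, 1 - 1e-12]` so that
#'   quasi-separated fits iterate to the cap instead of overflowing.  Hitting
#'   the iteration cap, or fitted probabilities pinned at the clip boundary
#'   (the signature of complete separation), sets `converged = FALSE` with a
#'   diagnostic message rather than throwing.  A rank-deficient design is an
#'   error naming the collinear columns.
#'
#' @return An object of class `"wlogit"` with elements `coefficients`
#'   (intercept first), `vcov` (model-based), `sandwich`, `deviance`,
#'   `loglik`, `n`, `converged`, `iter`, `message`, `design_labels`,
#'   `fitted`, `linear_predictors`, `y`, `weights`.
#' @export
wlogit <- function(x, y, weights = NULL, maxit = 100L, tol = 1e-10,
                   labels = NULL) {
  y <- as.numeric(y)
  if (anyNA(y) || !all(y %in% c(0, 1)))
    stop("'y' must be binary 0/1 with no missing values", call. = FALSE)
  n <- length(y)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || anyNA(weights) || any(weights <= 0))
    stop("'weights' must be positive and free of missing values", call. = FALSE)
  if (is.null(x)) {
    X <- matrix(1, n, 1L)
    labs <- "(Intercept)"
  } else {
    x <- as.matrix(x)
    if (nrow(x) != n) stop("nrow(x) must equal length(y)", call. = FALSE)
    if (anyNA(x) || any(!is.finite(x)))
      stop("design columns must be finite with no missing values", call. = FALSE)
    if (is.null(labels)) labels <- colnames(x)
    if (is.null(labels)) labels <- paste0("x", seq_len(ncol(x)))
    X <- cbind(1, x)
    labs <- c("(Intercept)", labels)
  }
  p <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < p) {
    dropped <- labs[qrX$pivot[(qrX$rank + 1L):p]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }

  clip <- 1e-12
  beta <- numeric(p)
  eta <- drop(X %*% beta)
  mu <- pmin(pmax(stats::plogis(eta), clip), 1 - clip)
  dev <- -2 * sum(weights * (y * log(mu) + (1 - y) * log(1 - mu)))
  converged <- FALSE
  iter <- 0L
  for (it in seq_len(maxit)) {
    iter <- it
    v <- mu * (1 - mu)
    W <- weights * v
    z <- eta + (y - mu) / v
    XtWX <- crossprod(X, X * W)
    XtWz <- crossprod(X, W * z)
    beta_new <- tryCatch(drop(solve(XtWX, XtWz)), error = function(e)
      stop("weighted least squares step failed (near-singular information): ",
           conditionMessage(e), call. = FALSE))
    eta <- drop(X %*% beta_new)
    mu <- pmin(pmax(stats::plogis(eta), clip), 1 - clip)
    dev_new <- -2 * sum(weights * (y * log(mu) + (1 - y) * log(1 - mu)))
    beta <- beta_new
    if (abs(dev_new - dev) / (abs(dev_new) + 0.1) < tol) {
      dev <- dev_new
      converged <- TRUE
      break
    }
    dev <- dev_new
  }

  msg <- NULL
  if (!converged) msg <- sprintf("IRLS did not converge in %d iterations", maxit)
  at_bound <- mu <= clip * 1.01 | mu >= 1 - clip * 1.01
  if (any(at_bound)) {
    converged <- FALSE
    msg <- paste0(if (!is.null(msg)) paste0(msg, "; "),
                  sprintf("%d fitted probabilities pinned at the clip boundary (possible complete separation)",
                          sum(at_bound)))
  }

  v <- mu * (1 - mu)
  XtWX <- crossprod(X, X * (weights * v))
  vc <- solve(XtWX)
  score <- X * (weights * (y - mu))
  meat <- crossprod(score)
  sand <- vc %*% meat %*% vc
  names(beta) <- labs
  dimnames(vc) <- dimnames(sand) <- list(labs, labs)
  ll <- -dev / 2

  structure(list(coefficients = beta, vcov = vc, sandwich = sand,
                 deviance = dev, loglik = ll, n = n, converged = converged,
                 iter = iter, message = msg, design_labels = labs,
                 fitted = mu, linear_predictors = eta, y = y,
                 weights = weights),
            class = "wlogit")
}

#' @export
print.wlogit <- function(x, digits = max(3L, getOption("digits") - 3L), ...) {
  cat("Weighted logistic regression (IRLS)\n")
  cat(sprintf("n = %d, deviance = %.4f, log-likelihood = %.4f, converged: %s\n",
              x$n, x$deviance, x$loglik, x$converged))
  if (!is.null(x$message)) cat("note:", x$message, "\n")
  cat("\nCoefficients:\n")
  print(round(x$coefficients, digits))
  invisible(x)
}

#' @export
coef.wlogit <- function(object, ...) object$coefficients

#' Covariance matrix of a weighted logistic fit
#'
#' @param object A `"wlogit"` fit.
#' @param type `"model"` (inverse weighted information; default) or
#'   `"sandwich"` (design-based robust covariance).
#' @param ... Unused.
#' @export
vcov.wlogit <- function(object, type = c("model", "sandwich"), ...) {
  switch(match.arg(type), model = object$vcov, sandwich = object$sandwich)
}

#' @export
logLik.wlogit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients),
            nobs = object$n, class = "logLik")
}

#' Predicted mortality probability from a weighted logistic fit
#'
#' @param object A `"wlogit"` fit.
#' @param newx Matrix (or vector, taken as one row) of covariate values in
#'   the fit's column order, excluding the intercept.  The caller must apply
#'   the same transformation and centering used at fit time.
#' @param type `"response"` (probability) or `"link"` (linear predictor).
#' @param ... Unused.
#' @export
predict.wlogit <- function(object, newx = NULL,
                           type = c("response", "link"), ...) {
  type <- match.arg(type)
  p <- length(object$coefficients)
  if (is.null(newx)) {
    eta <- object$linear_predictors
  } else {
    if (is.vector(newx)) newx <- matrix(newx, nrow = 1L)
    newx <- as.matrix(newx)
    if (ncol(newx) != p - 1L)
      stop(sprintf("design row has %d columns; model expects %d",
                   ncol(newx), p - 1L), call. = FALSE)
    eta <- drop(cbind(1, newx) %*% object$coefficients)
  }
  if (type == "link") eta else stats::plogis(eta)
}

#' Deviance difference test between nested fits
#'
#' The statistic is `dev_reduced - dev_full` (clamped at zero) referred to an
#' upper-tail chi-square with `df` degrees of freedom.
#'
#' @param dev_reduced,dev_full Deviances of the reduced and full model.
#' @param df Positive integer degrees of freedom.
#' @param tol Tolerance for a slightly negative difference from optimizer
#'   noise; a difference below `-tol` is an error (non-nested or failed fit).
#' @return List with `statistic`, `df`, `p_value`.
#' @export
#' @examples
#' deviance_test(109.5, 100.0, df = 4)
deviance_test <- function(dev_reduced, dev_full, df, tol = 1e-6) {
  if (!(length(df) == 1L && df >= 1 && df == round(df)))
    stop("'df' must be a positive integer", call. = FALSE)
  stat <- dev_reduced - dev_full
  if (stat < -tol)
    stop(sprintf("negative deviance difference (%g): models are not nested or a fit failed", stat),
         call. = FALSE)
  stat <- max(stat, 0)
  list(statistic = stat, df = as.integer(df),
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}
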