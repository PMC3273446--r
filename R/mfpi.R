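## Interaction detection for MFP models (MFPI) and its graphical
## verification by Lowess smoothing of empirical logits.

#' Test and add interactions to a fitted MFP model (MFPI)
#'
#' With the main-effect functional forms frozen, each candidate interaction
#' is represented by the products of the two terms' frozen design columns
#' (an fp term contributes its transformed, centered columns; a plain term
#' its raw column), and tested by a deviance difference on as many degrees
#' of freedom as columns added.  Candidates are entered by forward
#' selection: the most significant is added, the rest re-tested, until none
#' reaches `alpha`.
#'
#' @param object An `"mfp_logit"` fit (main effects already selected).
#' @param candidates List of character pairs naming the two interacting
#'   terms, e.g. `list(c("bmi","age"), c("age","ever_smoker"))`.  Default:
#'   all pairs of retained terms involving at least one fp term.
#' @param alpha Significance level (default: the fit's own).
#' @return An updated `"mfp_logit"` with the selected interaction columns in
#'   the design and an `interaction` element appended to the trace recording
#'   every test (candidate, statistic, df, p, included flag).
#' @export
mfpi <- function(object, candidates = NULL, alpha = object$alpha) {
  specs <- object$terms
  active <- names(specs)[vapply(specs, function(s)
    !(s$type == "fp" && identical(s$chosen, "omitted")), TRUE)]
  if (is.null(candidates)) {
    candidates <- list()
    if (length(active) >= 2L) {
      cmb <- utils::combn(active, 2L, simplify = FALSE)
      for (pr in cmb)
        if (any(vapply(specs[pr], function(s) s$type == "fp", TRUE)))
          candidates[[length(candidates) + 1L]] <- pr
    }
  }
  if (!length(candidates)) return(object)

  data <- object$model
  y <- object$y
  w <- object$weights
  mk <- function(pr) {
    ia <- list(a = pr[1L], b = pr[2L])
    cols <- interaction_columns(ia, specs, data)
    ia$labels <- colnames(cols)
    list(ia = ia, cols = cols)
  }
  included <- object$interactions
  log_rows <- list()
  remaining <- candidates
  base_X <- build_design(specs, included, data)
  base_fit <- wlogit(base_X, y, w)

  repeat {
    best <- NULL
    dropped <- integer()
    results <- vector("list", length(remaining))
    for (k in seq_along(remaining)) {
      pr <- remaining[[k]]
      cand <- mk(pr)
      Xfull <- cbind(base_X, cand$cols)
      fit_full <- tryCatch(wlogit(Xfull, y, w), error = function(e) e)
      if (inherits(fit_full, "error")) {
        warning(sprintf("interaction %s x %s skipped: %s", pr[1L], pr[2L],
                        conditionMessage(fit_full)))
        dropped <- c(dropped, k)
        next
      }
      tt <- deviance_test(base_fit$deviance, fit_full$deviance,
                          df = ncol(cand$cols))
      results[[k]] <- list(cand = cand, test = tt)
      log_rows[[length(log_rows) + 1L]] <- data.frame(
        candidate = paste0(pr[1L], ":", pr[2L]), statistic = tt$statistic,
        df = tt$df, p_value = tt$p_value,
        round = length(included) + 1L, stringsAsFactors = FALSE)
      if (tt$p_value < alpha &&
          (is.null(best) || tt$p_value < results[[best]]$test$p_value))
        best <- k
    }
    if (is.null(best)) break
    chosen <- results[[best]]
    included[[length(included) + 1L]] <- chosen$cand$ia
    base_X <- cbind(base_X, chosen$cand$cols)
    base_fit <- wlogit(base_X, y, w)
    remaining <- remaining[-unique(c(best, dropped))]
    if (!length(remaining)) break
  }

  tr <- object$trace
  itab <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(candidate = character(), statistic = numeric(), df = integer(),
               p_value = numeric(), round = integer())
  itab$included <- itab$candidate %in%
    vapply(included, function(i) paste0(i$a, ":", i$b), "")
  tr$interaction <- itab
  out <- mfp_finalize(specs, included, data, y, w, tr, alpha,
                      formula = object$formula, call = object$call,
                      outcome_name = object$outcome_name)
  out
}

#' Lowess-smoothed empirical logit curves by stratum
#'
#' Within each stratum, the outcome rate is computed in quantile bins of
#' `x`, converted to an empirical logit with continuity correction
#' `p = (deaths + 0.5) / (n + 1)`, and smoothed with [stats::lowess()]
#' (tricube weights; default span 0.6 with one robustness iteration).  Used
#' to verify interactions found by [mfpi()] by eye: diverging smoothed
#' slopes across strata corroborate an interaction.
#'
#' @param data Data frame.
#' @param x Name of the continuous variable.
#' @param outcome Name of the binary outcome column.
#' @param by Name of the stratifying column (binary or banded).
#' @param bins Number of quantile bins (at least 5).
#' @param span Lowess span.
#' @param iter Lowess robustness iterations.
#' @return Data frame with columns `stratum`, `x` (bin mean), `n`, `deaths`,
#'   `logit` (empirical) and `smooth` (Lowess fit).
#' @export
logit_lowess <- function(data, x, outcome, by, bins = 20L, span = 0.6,
                         iter = 1L) {
  if (bins < 5L) stop("'bins' must be at least 5", call. = FALSE)
  strata <- unique(data[[by]])
  if (length(strata) < 2L) stop("need at least 2 strata", call. = FALSE)
  out <- list()
  for (s in sort(strata)) {
    d <- data[data[[by]] == s, , drop = FALSE]
    if (!nrow(d)) {
      warning("empty stratum omitted: ", s)
      next
    }
    br <- unique(stats::quantile(d[[x]], probs = seq(0, 1, length.out = bins + 1L)))
    g <- cut(d[[x]], breaks = br, include.lowest = TRUE)
    xm <- tapply(d[[x]], g, mean)
    n <- tapply(rep(1, nrow(d)), g, sum)
    dth <- tapply(d[[outcome]], g, sum)
    ok <- !is.na(xm)
    p <- (dth[ok] + 0.5) / (n[ok] + 1)
    lg <- stats::qlogis(p)
    sm <- stats::lowess(xm[ok], lg, f = span, iter = iter)
    out[[length(out) + 1L]] <- data.frame(
      stratum = s, x = as.numeric(xm[ok]), n = as.numeric(n[ok]),
      deaths = as.numeric(dth[ok]), logit = as.numeric(lg),
      smooth = sm$y[match(xm[ok], sm$x)], stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
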