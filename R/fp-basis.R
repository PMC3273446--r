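## Fractional polynomial design bases.
##
## An FP basis for a positive covariate x is built from powers drawn from the
## canonical set {-2, -1, -0.5, 0, 0.5, 1, 2, 3}, where 0 denotes the natural
## log.  Repeated powers (p, p) generate the pair {x^p, x^p * ln x} (and, for
## p = 0, {ln x, (ln x)^2}).  The covariate is first divided by a positive
## scale constant, and each transformed column may have a centering constant
## subtracted; centering shifts only the intercept of a fitted model.

#' The canonical fractional polynomial power set
#'
#' @return Numeric vector `c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)`; the value 0
#'   encodes the natural-log transform.
#' @export
fp_powers <- function() c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)

#' Enumerate candidate fractional polynomial power vectors
#'
#' Degree 1 yields the 8 singleton powers; degree 2 yields all 36 unordered
#' pairs with repetition (28 distinct pairs plus 8 repeated), each stored
#' sorted ascending.  Candidates are returned in ascending lexicographic
#' order, which is also the tie-breaking order used during selection.
#'
#' @param degree 1 or 2.
#' @return A list of numeric power vectors.
#' @export
#' @examples
#' length(fp_candidates(1)) # 8
#' length(fp_candidates(2)) # 36
fp_candidates <- function(degree) {
  if (!(length(degree) == 1L && degree %in% c(1, 2)))
    stop("'degree' must be 1 or 2", call. = FALSE)
  s <- fp_powers()
  if (degree == 1) return(lapply(s, function(p) p))
  out <- list()
  for (i in seq_along(s))
    for (j in i:length(s))
      out[[length(out) + 1L]] <- c(s[i], s[j])
  out
}

#' Transform a covariate through a fractional polynomial basis
#'
#' Computes the design columns `h_j(x / scale) - centers[j]` for the given
#' powers.  Powers are used in ascending order; for a repeated power the
#' second column is the first multiplied by `ln(x / scale)` (the standard
#' repeated-power rule, so power 0 repeated gives `ln` and `ln^2`).
#' Arbitrary real powers are accepted; the canonical set is only enforced
#' during model selection.
#'
#' @param x Positive numeric vector (after division by `scale`).
#' @param powers Numeric vector of powers (length 1 or more); 0 means log.
#' @param scale Positive scalar divisor applied to `x` before transformation.
#' @param centers Numeric vector of per-column offsets (default all zero).
#' @return Numeric matrix with `length(powers)` columns in power order.
#' @export
#' @examples
#' fp_transform(40, c(-2, -1), scale = 10)        # 0.0625 0.25
#' fp_transform(10, c(-2, -2), scale = 10)        # 1 0
fp_transform <- function(x, powers, scale = 1, centers = NULL) {
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) || scale <= 0)
    stop("'scale' must be a positive scalar", call. = FALSE)
  powers <- sort(as.numeric(powers))
  if (is.null(centers)) centers <- numeric(length(powers))
  if (length(centers) != length(powers))
    stop("'centers' must have one value per power", call. = FALSE)
  xs <- x / scale
  bad <- which(!is.na(xs) & xs <= 0)
  if (length(bad))
    stop(sprintf("fractional polynomial transform requires positive scaled values; got x = %g (x/scale = %g)",
                 x[bad[1L]], xs[bad[1L]]), call. = FALSE)
  lx <- log(xs)
  h <- matrix(NA_real_, length(xs), length(powers))
  for (j in seq_along(powers)) {
    p <- powers[j]
    if (j > 1L && isTRUE(all.equal(p, powers[j - 1L]))) {
      h[, j] <- h[, j - 1L] * lx
    } else if (p == 0) {
      h[, j] <- lx
    } else {
      h[, j] <- xs^p
    }
  }
  sweep(h, 2L, centers)
}

#' Default centering constants for a fractional polynomial basis
#'
#' Each column is centered at the transform of the (unweighted) sample mean of
#' the covariate, i.e. `center_j = h_j(mean(x) / scale)`.  With this
#' convention a fitted model's non-intercept coefficients and deviance are
#' unchanged, and the intercept is interpretable as the linear predictor of a
#' mean-covariate subject.
#'
#' @param values Numeric sample of the covariate (positive after scaling).
#' @param powers Power vector as in [fp_transform()].
#' @param scale Positive scalar divisor.
#' @return Numeric vector of centering constants, one per column.
#' @export
#' @examples
#' fp_center(47.13, 2, scale = 10) # (4.713)^2 = 22.2124
fp_center <- function(values, powers, scale = 1) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("cannot centre on an empty sample", call. = FALSE)
  drop(fp_transform(mean(values), powers, scale = scale))
}

#' Format a power vector for reports
#'
#' @param powers Numeric power vector.
#' @return A string such as `"(-2,-2)"`.
#' @export
format_powers <- function(powers) {
  paste0("(", paste(format(powers, trim = TRUE, drop0trailing = TRUE), collapse = ","), ")")
}

## Column labels for a transformed covariate, e.g. bmi^(-2), bmi^(-2)*ln
fp_labels <- function(name, powers) {
  powers <- sort(powers)
  lab <- character(length(powers))
  for (j in seq_along(powers)) {
    p <- powers[j]
    if (j > 1L && isTRUE(all.equal(p, powers[j - 1L]))) {
      lab[j] <- paste0(lab[j - 1L], "*ln")
    } else if (p == 0) {
      lab[j] <- paste0("ln(", name, ")")
    } else {
      lab[j] <- paste0(name, "^(", format(p, trim = TRUE, drop0trailing = TRUE), ")")
    }
  }
  lab
}
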