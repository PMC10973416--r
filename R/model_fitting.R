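#' Fit a degree-1 or degree-2 polynomial by (weighted) least squares
#'
#' Fits `y ~ x` (linear) or `y ~ x + x^2` (quadratic) with optional positive
#' weights and returns a fit object carrying the coefficients, residual sum
#' of squares, adjusted R-squared, small-sample AICc and — for concave
#' quadratics — the location of the response maximum (the vertex).
#'
#' @param x,y Numeric vectors of equal length, at least `degree + 2` points.
#' @param degree Polynomial degree, 1 or 2.
#' @param weights Optional vector of positive case weights.
#'
#' @return An object of class `n2o_fit`: a list with elements
#'   `model_kind` (`"linear"` or `"quadratic"`), `coefficients` (named
#'   `c0`, `c1` and, for quadratics, `c2`), `n_obs`, `rss`, `adj_r2`,
#'   `aicc`, `peak_x`, `peak_y`, `x_range` and the underlying `lm` object.
#'
#' @examples
#' fit <- fit_polynomial(1:10, (1:10)^2 * -0.1 + 1:10, degree = 2)
#' vertex(fit)
#' @export
fit_polynomial <- function(x, y, degree = 2, weights = NULL) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (!degree %in% c(1, 2)) {
    stop("`degree` must be 1 (linear) or 2 (quadratic)", call. = FALSE)
  }
  keep <- stats::complete.cases(x, y)
  x <- x[keep]
  y <- y[keep]
  if (!is.null(weights)) {
    weights <- weights[keep]
    if (any(weights <= 0)) stop("weights must be positive", call. = FALSE)
  }
  n <- length(x)
  if (length(y) != n) stop("`x` and `y` must have equal length", call. = FALSE)
  if (n < degree + 2) {
    stop("need at least degree + 2 observations", call. = FALSE)
  }
  if (length(unique(x)) < degree + 1) {
    stop("design is rank deficient: too few distinct x values", call. = FALSE)
  }

  dat <- data.frame(x = x, y = y)
  fml <- if (degree == 1) y ~ x else y ~ x + I(x^2)
  fit <- if (is.null(weights)) {
    stats::lm(fml, data = dat)
  } else {
    stats::lm(fml, data = dat, weights = weights)
  }
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    stop("design is rank deficient: collinear polynomial terms", call. = FALSE)
  }
  names(cf) <- paste0("c", seq_along(cf) - 1L)

  w <- if (is.null(weights)) rep(1, n) else weights
  rss <- sum(w * stats::residuals(fit)^2)
  # a residual sum that is zero up to floating-point noise is a perfect fit
  tss <- sum(w * (y - stats::weighted.mean(y, w))^2)
  scale <- max(tss, sum(w * y^2), .Machine$double.xmin)
  if (rss <= 1e-20 * scale) rss <- 0
  # adjusted R2 from the definition; summary.lm warns on noise-free data
  r2 <- if (tss == 0) 1 else 1 - rss / tss
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - degree - 1)

  out <- structure(
    list(
      model_kind = if (degree == 1) "linear" else "quadratic",
      coefficients = cf,
      n_obs = n,
      rss = rss,
      adj_r2 = adj_r2,
      aicc = if (rss > 0 && n > degree + 3) aicc(rss, n, degree + 1L) else NA_real_,
      peak_x = NA_real_,
      peak_y = NA_real_,
      x_range = range(x),
      lm = fit
    ),
    class = "n2o_fit"
  )
  if (degree == 2 && cf[["c2"]] < 0) {
    out$peak_x <- -cf[["c1"]] / (2 * cf[["c2"]])
    out$peak_y <- unname(cf[["c0"]] + cf[["c1"]] * out$peak_x +
                           cf[["c2"]] * out$peak_x^2)
  }
  out
}

#' Build a fit object from known polynomial coefficients
#'
#' Constructs an `n2o_fit` directly from coefficients, e.g. those reported
#' in a publication, so that [vertex()] and prediction helpers can be
#' applied without refitting. Goodness-of-fit fields are `NA`.
#'
#' @param intercept,slope Coefficients `c0` and `c1`.
#' @param curvature Coefficient `c2` of the squared term, or `NULL` for a
#'   linear model.
#' @param x_range Optional numeric length-2 range over which the fit is
#'   considered supported (used to flag out-of-range peaks).
#'
#' @return An `n2o_fit` object.
#' @examples
#' # a concave quadratic peaking at x = 5
#' fit_from_coefficients(-2.5, 1, -0.1)
#' @export
fit_from_coefficients <- function(intercept, slope, curvature = NULL,
                                  x_range = NULL) {
  stopifnot(is.numeric(intercept), is.numeric(slope))
  quad <- !is.null(curvature)
  cf <- if (quad) {
    c(c0 = intercept, c1 = slope, c2 = curvature)
  } else {
    c(c0 = intercept, c1 = slope)
  }
  out <- structure(
    list(
      model_kind = if (quad) "quadratic" else "linear",
      coefficients = cf,
      n_obs = NA_integer_,
      rss = NA_real_,
      adj_r2 = NA_real_,
      aicc = NA_real_,
      peak_x = NA_real_,
      peak_y = NA_real_,
      x_range = x_range,
      lm = NULL
    ),
    class = "n2o_fit"
  )
  if (quad && curvature < 0) {
    out$peak_x <- -slope / (2 * curvature)
    out$peak_y <- intercept + slope * out$peak_x + curvature * out$peak_x^2
  }
  out
}

#' @export
print.n2o_fit <- function(x, ...) {
  cat(sprintf("<n2o_fit> %s", x$model_kind))
  if (!is.na(x$n_obs)) cat(sprintf(", n = %d", x$n_obs))
  cat("\n  coefficients:",
      paste(sprintf("%s = %.6g", names(x$coefficients), x$coefficients),
            collapse = ", "), "\n")
  if (!is.na(x$adj_r2)) cat(sprintf("  adj R2 = %.4f, AICc = %.3f\n",
                                    x$adj_r2, x$aicc))
  if (!is.na(x$peak_x)) cat(sprintf("  peak at x = %.4f (y = %.4f)\n",
                                    x$peak_x, x$peak_y))
  invisible(x)
}

#' Predict from a polynomial fit
#'
#' @param object An `n2o_fit`.
#' @param newdata Numeric vector of x values (not a data frame).
#' @param ... Unused.
#' @return Numeric vector of fitted values.
#' @export
predict.n2o_fit <- function(object, newdata, ...) {
  cf <- object$coefficients
  y <- cf[["c0"]] + cf[["c1"]] * newdata
  if (object$model_kind == "quadratic") y <- y + cf[["c2"]] * newdata^2
  unname(y)
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = n log(rss / n) + 2k + 2k(k + 1)/(n - k - 1)` where
#' `k = n_params + 1` counts the Gaussian error variance alongside the
#' regression coefficients (the convention of common model-selection
#' packages).
#'
#' @param rss Residual sum of squares, strictly positive.
#' @param n_obs Number of observations.
#' @param n_params Number of regression coefficients (2 for a line,
#'   3 for a quadratic).
#' @return The AICc value (additive constants omitted, so only
#'   differences between models on the same data are meaningful).
#' @examples
#' aicc(10, 20, 2)  # a linear fit: k = 3
#' @export
aicc <- function(rss, n_obs, n_params) {
  stopifnot(is.numeric(rss), rss > 0)
  k <- n_params + 1
  if (n_obs <= k + 1) {
    stop("AICc undefined: need n_obs > n_params + 2", call. = FALSE)
  }
  n_obs * log(rss / n_obs) + 2 * k + 2 * k * (k + 1) / (n_obs - k - 1)
}

#' Choose between a linear and a quadratic fit by AICc
#'
#' Picks the lower-AICc model when the AICc difference exceeds `threshold`;
#' within the threshold the two are considered statistically equivalent and
#' the simpler (linear) model is kept, with `tie = TRUE`.
#'
#' @param linear,quadratic `n2o_fit` objects fitted to the same data.
#' @param threshold AICc difference regarded as substantial (default 2).
#' @return A list with `fit` (the chosen `n2o_fit`), `chosen`
#'   (`"linear"`/`"quadratic"`), `delta_aicc` (linear minus quadratic) and
#'   `tie` (logical).
#' @export
select_model <- function(linear, quadratic, threshold = 2) {
  stopifnot(inherits(linear, "n2o_fit"), inherits(quadratic, "n2o_fit"))
  if (linear$model_kind != "linear" || quadratic$model_kind != "quadratic") {
    stop("arguments must be a linear and a quadratic fit, in that order",
         call. = FALSE)
  }
  if (!identical(linear$n_obs, quadratic$n_obs)) {
    stop("fits were not computed on the same data (n_obs differ)",
         call. = FALSE)
  }
  # a perfect fit (rss exactly 0) has AICc of -Inf
  la <- if (isTRUE(linear$rss == 0)) -Inf else linear$aicc
  qa <- if (isTRUE(quadratic$rss == 0)) -Inf else quadratic$aicc
  delta <- la - qa
  if (is.na(delta) || is.nan(delta)) {
    return(list(fit = linear, chosen = "linear", delta_aicc = NA_real_,
                tie = TRUE))
  }
  if (abs(delta) > threshold) {
    chosen <- if (delta > 0) quadratic else linear
    tie <- FALSE
  } else {
    chosen <- linear
    tie <- TRUE
  }
  list(fit = chosen, chosen = chosen$model_kind, delta_aicc = delta,
       tie = tie)
}

#' Vertex (peak) of a concave quadratic fit
#'
#' For a quadratic with negative curvature returns the x at which the fitted
#' response attains its maximum, `-c1 / (2 c2)`, and the fitted value there.
#' Convex quadratics have no interior maximum and return `NULL`.
#'
#' @param fit A quadratic `n2o_fit`.
#' @return `NULL` if the curvature is non-negative, otherwise a list with
#'   `peak_x`, `peak_y` and `in_range` (`NA` when the fit carries no
#'   x-range, e.g. one built from published coefficients without one).
#' @examples
#' vertex(fit_from_coefficients(-1.826, 1.030, -0.0913))
#' @export
vertex <- function(fit) {
  stopifnot(inherits(fit, "n2o_fit"))
  if (fit$model_kind != "quadratic") {
    stop("vertex is defined only for quadratic fits", call. = FALSE)
  }
  if (fit$coefficients[["c2"]] >= 0) return(NULL)
  in_range <- if (is.null(fit$x_range) || anyNA(fit$x_range)) {
    NA
  } else {
    fit$peak_x >= fit$x_range[1] && fit$peak_x <= fit$x_range[2]
  }
  list(peak_x = unname(fit$peak_x), peak_y = unname(fit$peak_y),
       in_range = in_range)
}

#' Pointwise confidence band for the mean response
#'
#' Classical t-based band around the fitted polynomial, evaluated on a grid.
#'
#' @param fit An `n2o_fit` produced by [fit_polynomial()].
#' @param x_grid Numeric vector of evaluation points.
#' @param level Confidence level in (0, 1); default 0.95.
#' @return A tibble with columns `x`, `fit`, `lower`, `upper`.
#' @export
confidence_band <- function(fit, x_grid, level = 0.95) {
  stopifnot(inherits(fit, "n2o_fit"))
  if (is.null(fit$lm)) {
    stop("confidence bands require a fit produced by fit_polynomial()",
         call. = FALSE)
  }
  if (level <= 0 || level >= 1) {
    stop("`level` must lie strictly between 0 and 1", call. = FALSE)
  }
  p <- length(fit$coefficients)
  if (fit$n_obs <= p + 1) {
    stop("too few observations for a confidence band", call. = FALSE)
  }
  pr <- stats::predict(fit$lm, newdata = data.frame(x = x_grid),
                       interval = "confidence", level = level)
  tibble::tibble(x = x_grid, fit = pr[, "fit"], lower = pr[, "lwr"],
                 upper = pr[, "upr"])
}
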