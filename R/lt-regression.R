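#' Fit the log-log lethal-time law ln(LT50) = a + b ln(C)
#'
#' Ordinary least squares of the natural-log median lethal time on the
#' natural-log exposure concentration. The fitted coefficients let the
#' lethal time of any concentration - including ones beyond those tested -
#' be computed for use in mixture lethal-time addition. Median lethal
#' times longer than the study duration (obtained by probit extrapolation)
#' are legitimate points and are included.
#'
#' @param concentration exposure concentrations (mg/L), all > 0.
#' @param lt50 median lethal times (h), all > 0.
#' @return an object of class `ltc_regression` with elements `a`
#'   (intercept), `b` (slope), `r2`, `n` and `conc_range`.
#' @examples
#' fit <- fit_loglog(c(13, 16, 19, 21, 24),
#'                   c(148.82, 149.70, 103.85, 53.55, 16.79))
#' predict_lt50(fit, 8)
#' @export
fit_loglog <- function(concentration, lt50) {
  if (length(concentration) != length(lt50)) {
    stop("concentration and lt50 must have equal length", call. = FALSE)
  }
  if (length(concentration) < 2L) {
    stop("log-log regression needs at least 2 points", call. = FALSE)
  }
  if (any(!is.finite(concentration)) || any(concentration <= 0) ||
      any(!is.finite(lt50)) || any(lt50 <= 0)) {
    stop("domain error: concentrations and LT50s must be positive",
         call. = FALSE)
  }
  if (length(unique(concentration)) < 2L) {
    stop("singular design: all concentrations identical", call. = FALSE)
  }
  x <- log(concentration)
  y <- log(lt50)
  fit <- stats::lm(y ~ x)
  # r2 computed directly: exact collinear data are a legitimate input and
  # summary.lm() warns on perfect fits
  tss <- sum((y - mean(y))^2)
  rss <- sum(stats::residuals(fit)^2)
  r2 <- if (tss > 0) 1 - rss / tss else 1
  structure(
    list(a = unname(stats::coef(fit)[1L]), b = unname(stats::coef(fit)[2L]),
         r2 = r2, n = length(concentration),
         conc_range = range(concentration)),
    class = "ltc_regression")
}

#' Construct a lethal-time regression from known coefficients
#'
#' Used when the coefficients come from an external source (for example a
#' published coefficient table) rather than from [fit_loglog()].
#'
#' @param a intercept on the natural-log hours scale.
#' @param b slope (dimensionless).
#' @param r2 coefficient of determination (optional).
#' @param n number of concentration points behind the fit (optional).
#' @param conc_range fitted concentration range, used for extrapolation
#'   flagging (optional).
#' @return an object of class `ltc_regression`.
#' @export
ltc_regression <- function(a, b, r2 = NA_real_, n = NA_integer_,
                           conc_range = c(NA_real_, NA_real_)) {
  if (!is.finite(a) || !is.finite(b)) {
    stop("coefficients must be finite", call. = FALSE)
  }
  if (!is.na(r2) && (r2 < 0 || r2 > 1)) stop("r2 must lie in [0, 1]",
                                             call. = FALSE)
  structure(list(a = a, b = b, r2 = r2, n = n, conc_range = conc_range),
            class = "ltc_regression")
}

#' @export
print.ltc_regression <- function(x, ...) {
  cat(sprintf("ln(LT50) = %.4f %+.4f ln(C)   (r2 = %s, n = %s)\n",
              x$a, x$b,
              if (is.na(x$r2)) "NA" else sprintf("%.3f", x$r2),
              if (is.na(x$n)) "NA" else x$n))
  invisible(x)
}

#' Predict the median lethal time at a concentration
#'
#' Evaluates `exp(a + b * ln(C))`. Prediction outside the fitted
#' concentration range is allowed (computing lethal times beyond the
#' tested range is the point of the law) and flagged via the
#' `"extrapolated"` attribute.
#'
#' @param coeffs an `ltc_regression` object.
#' @param concentration concentrations (mg/L), all > 0. Vectorised.
#' @return predicted LT50s in hours, with attribute `extrapolated`.
#' @export
predict_lt50 <- function(coeffs, concentration) {
  stopifnot(inherits(coeffs, "ltc_regression"))
  if (any(!is.finite(concentration)) || any(concentration <= 0)) {
    stop("domain error: concentration must be positive", call. = FALSE)
  }
  out <- exp(coeffs$a + coeffs$b * log(concentration))
  extrap <- if (all(is.finite(coeffs$conc_range))) {
    concentration < coeffs$conc_range[1L] |
      concentration > coeffs$conc_range[2L]
  } else {
    rep(NA, length(concentration))
  }
  attr(out, "extrapolated") <- extrap
  out
}
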