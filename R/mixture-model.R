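#' Component concentrations at a total mixture concentration
#'
#' Splits a total concentration over the mixture components in proportion
#' to their exact ratio weights: `Ci = total * ri / sum(r)`. Printed
#' 1-2 d.p. component concentrations in reports are display rounding; the
#' exact values are always used in computation.
#'
#' @param spec a [mixture_spec()].
#' @param total total mixture concentration (mg/L), > 0.
#' @return named numeric vector of component concentrations summing to
#'   `total`.
#' @export
component_concentrations <- function(spec, total) {
  stopifnot(inherits(spec, "mixture_spec"))
  if (!is.finite(total) || total <= 0) {
    stop("total concentration must be positive", call. = FALSE)
  }
  total * proportions_of(spec)
}

#' Mixture median lethal time by lethal-time addition
#'
#' Combines absolute component concentrations `Ci` (mg/L) and their median
#' lethal times `LTi` (h) into the mixture LT50 by the reciprocal rule
#' `LT50mix = 1 / sum(Ci / LTi)`. Each term `Ci/LTi` acts as a killing
#' rate contribution, so the result is bounded above by `min(LTi / Ci)`
#' and strictly decreases as components are added.
#'
#' Note the degenerate single-component case returns `LT/C`, which equals
#' the single-chemical LT50 only at C = 1 mg/L; the rule is intended for
#' true mixtures.
#'
#' @param concentration component concentrations (mg/L), all > 0.
#' @param lt50 component median lethal times (h), all > 0.
#' @return mixture LT50 in hours.
#' @examples
#' lethal_time_addition(c(7.7711, 0.22890), c(1271.2, 842.3)) # ~ 156.6 h
#' @export
lethal_time_addition <- function(concentration, lt50) {
  if (length(concentration) != length(lt50)) {
    stop("concentration and lt50 must have equal length", call. = FALSE)
  }
  if (length(concentration) < 1L) {
    stop("at least one component required", call. = FALSE)
  }
  if (any(!is.finite(concentration)) || any(concentration <= 0)) {
    stop("component concentrations must be positive", call. = FALSE)
  }
  if (any(!is.finite(lt50)) || any(lt50 <= 0)) {
    stop("division error: component lethal times must be positive",
         call. = FALSE)
  }
  1 / sum(concentration / lt50)
}

#' Hyperbolic (Michaelis-Menten shaped) mortality-time model
#'
#' Percentage mortality after exposure time `t` at a level whose median
#' lethal time is `lt50`: `P = p100 * t / (lt50 + t)`. By construction
#' P(0) = 0, P is strictly increasing in t, P(lt50) = p100/2 exactly, and
#' P < p100 for all finite t.
#'
#' @param t exposure duration in hours, >= 0. Vectorised.
#' @param lt50 median lethal time in hours, > 0.
#' @param p100 total mortality ceiling in percent (default 100).
#' @return predicted mortality in percent.
#' @examples
#' hyperbolic_mortality(96, 156.62) # 38.0
#' @export
hyperbolic_mortality <- function(t, lt50, p100 = 100) {
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("domain error: t must be >= 0", call. = FALSE)
  }
  if (!is.finite(lt50) || lt50 <= 0) stop("lt50 must be positive",
                                          call. = FALSE)
  if (!(p100 > 0 && p100 <= 100)) stop("p100 must lie in (0, 100]",
                                       call. = FALSE)
  # algebraically p100 * t / (lt50 + t); this form makes P(lt50) = p100/2
  # exact in floating point (lt50/t == 1 when t == lt50) and P(0) = 0
  p100 / (lt50 / t + 1)
}

#' Predict mixture LT50s and time-resolved mortality over a concentration
#' series
#'
#' For each total concentration: split into component concentrations by the
#' mixture ratio, predict each component's LT50 from its log-log lethal-time
#' regression, combine by lethal-time addition, and evaluate the hyperbolic
#' mortality model on the exposure-time grid.
#'
#' @param spec a [mixture_spec()].
#' @param coeffs named list of [ltc_regression()] objects, one per
#'   component of `spec` (names must cover `spec$components`).
#' @param totals total mixture concentrations (mg/L).
#' @param times exposure-time grid in hours (default 24, 48, 72, 96).
#' @param p100 mortality ceiling passed to [hyperbolic_mortality()].
#' @return an object of class `mixture_prediction`: list with `spec`,
#'   `coeffs`, `times`, `lt50` (data.frame: `total`, one `conc_*` and
#'   `lt50_*` column per component, `lt50_mix`) and `mortality`
#'   (data.frame: `total`, `time_h`, `percent`).
#' @export
predict_mixture_lt50_curve <- function(spec, coeffs, totals,
                                       times = c(24, 48, 72, 96),
                                       p100 = 100) {
  stopifnot(inherits(spec, "mixture_spec"))
  missing_coef <- setdiff(spec$components, names(coeffs))
  if (length(missing_coef) > 0L) {
    stop("no lethal-time coefficients for component(s): ",
         paste(missing_coef, collapse = ", "), call. = FALSE)
  }
  if (length(totals) < 1L || any(totals <= 0)) {
    stop("totals must be positive", call. = FALSE)
  }
  k <- length(spec$components)
  rows <- lapply(totals, function(tt) {
    ci <- component_concentrations(spec, tt)
    lti <- vapply(seq_len(k), function(i) {
      as.numeric(predict_lt50(coeffs[[spec$components[i]]], ci[i]))
    }, numeric(1))
    c(total = tt, stats::setNames(ci, paste0("conc_", spec$components)),
      stats::setNames(lti, paste0("lt50_", spec$components)),
      lt50_mix = lethal_time_addition(ci, lti))
  })
  lt50_tab <- as.data.frame(do.call(rbind, rows), check.names = FALSE)
  mort <- do.call(rbind, lapply(seq_along(totals), function(i) {
    data.frame(total = totals[i], time_h = times,
               percent = hyperbolic_mortality(times, lt50_tab$lt50_mix[i],
                                              p100))
  }))
  structure(list(spec = spec, coeffs = coeffs, times = times, p100 = p100,
                 lt50 = lt50_tab, mortality = mort),
            class = "mixture_prediction")
}

#' @export
print.mixture_prediction <- function(x, digits = 2, ...) {
  cat("Mixture prediction:", paste(x$spec$components, collapse = " + "),
      if (!is.na(x$spec$species)) paste0("(", x$spec$species, ")"), "\n")
  tab <- x$lt50[, c("total", "lt50_mix")]
  wide <- stats::reshape(x$mortality, idvar = "total", timevar = "time_h",
                         direction = "wide")
  names(wide) <- sub("^percent\\.", "P", names(wide))
  tab <- merge(tab, wide, by = "total")
  tab[-1] <- lapply(tab[-1], round, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Hyperbolic-model predicted mixture LC50
#'
#' Estimates the mixture LC50 at a fixed exposure time from a
#' [predict_mixture_lt50_curve()] series. The default (`method =
#' "probit"`) fits a maximum-likelihood probit line to the predicted
#' percentage mortalities at time `t` against the total concentration,
#' treating each percentage as the quantal response of a nominal group of
#' `n_nominal` organisms, and inverts it at 50% - mirroring how a
#' fixed-time LC50 is obtained from an observed bioassay. `method =
#' "invert"` instead root-solves `LT50mix(C) = t` by bisection; the two
#' agree closely when the predicted series brackets 50% symmetrically.
#'
#' @param prediction a `mixture_prediction`.
#' @param t exposure time in hours (default 96, must be on the prediction's
#'   time grid for the probit method - otherwise it is computed afresh).
#' @param method `"probit"` (default) or `"invert"`.
#' @param n_nominal nominal group size for the probit method (default 10).
#' @return for `"probit"`, the [effective_level()] row (estimate with
#'   fiducial limits); for `"invert"`, a one-row data.frame with the root
#'   as `estimate` and `NA` limits.
#' @export
hm_predicted_lc50 <- function(prediction, t = 96,
                              method = c("probit", "invert"),
                              n_nominal = 10) {
  stopifnot(inherits(prediction, "mixture_prediction"))
  method <- match.arg(method)
  totals <- prediction$lt50$total
  if (method == "probit") {
    pct <- hyperbolic_mortality_series(prediction, t)
    usable <- pct > 0 & pct < prediction$p100
    if (sum(usable) < 2L) {
      stop("need >= 2 totals with mortality strictly between 0 and p100 at t",
           call. = FALSE)
    }
    if (all(pct[usable] < 50) || all(pct[usable] > 50)) {
      warning("predicted mortalities all on one side of 50%: ",
              "LC50 is an extrapolation", call. = FALSE)
    }
    fit <- fit_probit(totals[usable], rep(n_nominal, sum(usable)),
                      n_nominal * pct[usable] / 100,
                      metameter = "concentration")
    effective_level(fit, 0.5)
  } else {
    f <- function(C) {
      ci <- component_concentrations(prediction$spec, C)
      lti <- vapply(seq_along(ci), function(i) {
        as.numeric(predict_lt50(
          prediction$coeffs[[prediction$spec$components[i]]], ci[i]))
      }, numeric(1))
      lethal_time_addition(ci, lti) - t
    }
    lo <- min(totals) / 10
    hi <- max(totals) * 10
    if (f(lo) * f(hi) > 0) {
      stop("no sign change of LT50mix(C) - t in [", lo, ", ", hi, "]",
           call. = FALSE)
    }
    root <- stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
    out <- data.frame(p = 0.5, estimate = root, lower95 = NA_real_,
                      upper95 = NA_real_,
                      extrapolated = root < min(totals) | root > max(totals),
                      limits_defined = FALSE)
    class(out) <- c("effective_level", "data.frame")
    out
  }
}

# mortality of each total at time t (recomputed if t is off the grid)
hyperbolic_mortality_series <- function(prediction, t) {
  vapply(prediction$lt50$lt50_mix,
         function(lt) hyperbolic_mortality(t, lt, prediction$p100),
         numeric(1))
}
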