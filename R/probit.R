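#' Maximum-likelihood probit analysis of quantal data
#'
#' Fits probit(p) = intercept + slope * log10(level) to dead-out-of-exposed
#' counts by maximum likelihood (iteratively reweighted least squares, the
#' classical Finney algorithm as implemented in [stats::glm()] with a
#' binomial probit link; convergence tolerance 1e-10, at most 100
#' iterations). Groups with 0% or 100% response are retained in the
#' likelihood. The modern parameterisation without the historical +5 probit
#' offset is used; median-effect estimates are invariant to that offset.
#'
#' Goodness of fit is summarised by the Pearson chi-square statistic on
#' `k - 2` degrees of freedom and the heterogeneity factor chi2/df, which
#' inflates the parameter covariance when chi2/df > 1 (Finney's
#' convention, also used by mainstream statistical packages).
#'
#' @param level exposure level per group: a concentration (mg/L) or an
#'   observation time (h), all > 0.
#' @param n_exposed organisms exposed per group.
#' @param n_dead dead organisms per group (cumulative counts when `level`
#'   is time). Non-integer "dead" counts are accepted so that smooth
#'   predicted percentages can be fed back through the same machinery.
#' @param metameter which axis was log-transformed: `"concentration"` or
#'   `"time"`. Informational; both are fitted on log10(level).
#' @return an object of class `probit_fit` with elements `intercept`,
#'   `slope`, `vcov`, `metameter`, `log_base`, `chi2`, `df`,
#'   `heterogeneity`, `converged`, `groups`, `level_range`.
#' @examples
#' fit <- fit_probit(c(1, 10), c(100, 100), c(25, 75))
#' effective_level(fit, 0.5) # ED50 = 10^0.5
#' @export
fit_probit <- function(level, n_exposed, n_dead,
                       metameter = c("concentration", "time")) {
  metameter <- match.arg(metameter)
  if (length(level) != length(n_exposed) || length(level) != length(n_dead)) {
    stop("level, n_exposed and n_dead must have equal length", call. = FALSE)
  }
  if (any(!is.finite(level)) || any(level <= 0)) {
    stop("all levels must be positive and finite", call. = FALSE)
  }
  if (any(n_dead < 0) || any(n_dead > n_exposed)) {
    stop("n_dead must lie in [0, n_exposed] for every group", call. = FALSE)
  }
  if (length(unique(level)) < 2L) {
    stop("probit fit needs at least 2 distinct levels", call. = FALSE)
  }
  partial <- any(n_dead > 0 & n_dead < n_exposed)
  all_dead <- all(n_dead == n_exposed)
  all_alive <- all(n_dead == 0)
  if (all_dead || all_alive) {
    stop("probit fit did not converge: complete separation (all groups at ",
         if (all_dead) "100%" else "0%",
         " response); only interval statements are possible", call. = FALSE)
  }
  if (!partial) {
    # only 0% and 100% groups: a finite MLE exists only if they interleave
    ord <- order(level)
    resp <- (n_dead / n_exposed)[ord]
    if (all(diff(resp) >= 0)) {
      stop("probit fit did not converge: complete separation between 0% and ",
           "100% groups; only interval statements are possible", call. = FALSE)
    }
  }
  x <- log10(level)
  fit <- suppressWarnings(
    stats::glm(cbind(n_dead, n_exposed - n_dead) ~ x,
               family = stats::binomial(link = "probit"),
               control = stats::glm.control(epsilon = 1e-10, maxit = 100)))
  cf <- stats::coef(fit)
  p_hat <- stats::fitted(fit)
  chi2 <- sum((n_dead - n_exposed * p_hat)^2 /
                pmax(n_exposed * p_hat * (1 - p_hat), .Machine$double.eps))
  df <- max(length(level) - 2L, 0L)
  structure(
    list(intercept = unname(cf[1L]), slope = unname(cf[2L]),
         vcov = stats::vcov(fit), metameter = metameter, log_base = 10,
         chi2 = chi2, df = df,
         heterogeneity = if (df > 0L) chi2 / df else NA_real_,
         converged = fit$converged,
         groups = data.frame(level = level, n_exposed = n_exposed,
                             n_dead = n_dead),
         level_range = range(level)),
    class = "probit_fit")
}

#' @export
print.probit_fit <- function(x, ...) {
  cat("Probit fit on log10(", x$metameter, ")\n", sep = "")
  cat(sprintf("  probit(p) = %.4f + %.4f * log10(level)\n",
              x$intercept, x$slope))
  cat(sprintf("  Pearson chi2 = %.3f on %d df (heterogeneity %.3f)\n",
              x$chi2, x$df,
              if (is.na(x$heterogeneity)) NA else x$heterogeneity))
  if (!x$converged) cat("  WARNING: IRLS did not converge\n")
  invisible(x)
}

# Fieller interval for m = (y0 - intercept)/slope on the log10 scale.
# Returns c(lower, upper) or NULL when g >= 1 (limits undefined).
fieller_limits <- function(y0, b0, b1, V, tcrit) {
  a <- y0 - b0
  var_a <- V[1L, 1L]
  var_b <- V[2L, 2L]
  cov_ab <- -V[1L, 2L]
  A <- b1^2 - tcrit^2 * var_b
  if (A <= 0) return(NULL) # g >= 1: slope not distinguishable from 0
  B <- -2 * (a * b1 - tcrit^2 * cov_ab)
  C <- a^2 - tcrit^2 * var_a
  disc <- B^2 - 4 * A * C
  if (disc < 0) return(NULL)
  sort((-B + c(-1, 1) * sqrt(disc)) / (2 * A))
}

#' Effective level (ED/LC/LT) at a target mortality fraction
#'
#' Inverts a fitted probit line: `estimate = 10^((probit(p) - intercept) /
#' slope)`, with 95% fiducial limits by Fieller's theorem on the fitted
#' line's covariance. When the heterogeneity factor chi2/df exceeds 1 the
#' covariance is inflated by it and a t critical value on `df` degrees of
#' freedom replaces the normal one. Extrapolation beyond the fitted level
#' range is permitted and flagged.
#'
#' @param fit a [fit_probit()] object.
#' @param p target mortality fraction, strictly between 0 and 1.
#' @param conf confidence level for the fiducial limits (default 0.95).
#' @return a one-row data.frame of class `effective_level`: `p`,
#'   `estimate`, `lower95`, `upper95`, `extrapolated`, `limits_defined`.
#'   Limits are `NA` (with `limits_defined = FALSE`) when Fieller's g >= 1.
#' @export
effective_level <- function(fit, p, conf = 0.95) {
  stopifnot(inherits(fit, "probit_fit"))
  if (!(p > 0 && p < 1)) stop("p must lie strictly in (0, 1)", call. = FALSE)
  if (!is.finite(fit$slope) || fit$slope <= 0) {
    stop("effective level undefined: probit slope must be positive ",
         "(response must increase with level)", call. = FALSE)
  }
  y0 <- stats::qnorm(p)
  m <- (y0 - fit$intercept) / fit$slope
  V <- fit$vcov
  if (!is.na(fit$heterogeneity) && fit$heterogeneity > 1) {
    V <- V * fit$heterogeneity
    tcrit <- stats::qt(1 - (1 - conf) / 2, df = fit$df)
  } else {
    tcrit <- stats::qnorm(1 - (1 - conf) / 2)
  }
  lim <- fieller_limits(y0, fit$intercept, fit$slope, V, tcrit)
  est <- 10^m
  out <- data.frame(
    p = p, estimate = est,
    lower95 = if (is.null(lim)) NA_real_ else 10^lim[1L],
    upper95 = if (is.null(lim)) NA_real_ else 10^lim[2L],
    extrapolated = est < fit$level_range[1L] || est > fit$level_range[2L],
    limits_defined = !is.null(lim))
  class(out) <- c("effective_level", "data.frame")
  out
}

#' Effective levels for a set of mortality percentages
#'
#' Convenience wrapper over [effective_level()] for the percentage grid
#' used when building concentration-addition tables (default 5, 15, 35, 60
#' and 90%).
#'
#' @param fit a [fit_probit()] object.
#' @param percents mortality percentages (0-100 scale).
#' @param conf confidence level passed to [effective_level()].
#' @return data.frame with one row per percentage.
#' @export
lc_at_percents <- function(fit, percents = c(5, 15, 35, 60, 90), conf = 0.95) {
  rows <- lapply(percents / 100, function(pp) effective_level(fit, pp, conf))
  out <- do.call(rbind, rows)
  out$percent <- percents
  rownames(out) <- NULL
  out
}
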