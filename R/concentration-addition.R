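#' Concentration-addition mixture lethal concentration at one effect level
#'
#' The classical concentration-addition rule: the mixture concentration
#' producing effect level x is the proportion-weighted harmonic mean of the
#' component concentrations producing that same effect,
#' `LCx_mix = 1 / sum(p_i / LCx_i)`. It is bounded by the component
#' extremes, scale-equivariant and permutation-invariant.
#'
#' @param component_lcx component lethal concentrations at the common
#'   effect level (mg/L), all > 0.
#' @param proportions component proportions in the mixture, summing to 1
#'   (tolerance 1e-6).
#' @return mixture lethal concentration (mg/L).
#' @examples
#' ca_lcx(c(7.025, 5.363), c(0.58159, 0.41841)) # ~ 6.22
#' @export
ca_lcx <- function(component_lcx, proportions) {
  if (length(component_lcx) != length(proportions)) {
    stop("component_lcx and proportions must have equal length",
         call. = FALSE)
  }
  if (any(!is.finite(component_lcx)) || any(component_lcx <= 0)) {
    stop("component lethal concentrations must be positive", call. = FALSE)
  }
  if (any(!is.finite(proportions)) || any(proportions <= 0)) {
    stop("proportions must be positive", call. = FALSE)
  }
  if (abs(sum(proportions) - 1) > 1e-6) {
    stop("proportions must sum to 1 (got ", sum(proportions), ")",
         call. = FALSE)
  }
  1 / sum(proportions / component_lcx)
}

#' Concentration-addition table over an effect-level grid
#'
#' Builds one row per requested mortality percentage: the component LCx
#' values (from per-component probit fits, or supplied directly) combined
#' by [ca_lcx()].
#'
#' @param fits named list of per-component [fit_probit()] objects
#'   (concentration metameter), or a numeric matrix of component LCx
#'   values with one row per percentage and one column per component.
#' @param proportions component proportions, summing to 1.
#' @param percents mortality percentages (default 5, 15, 35, 60, 90).
#' @return data.frame of class `ca_table`: `percent`, `lcx_1..k`,
#'   `p_1..k`, `lcx_mix`.
#' @export
ca_table <- function(fits, proportions, percents = c(5, 15, 35, 60, 90)) {
  if (is.matrix(fits) || is.data.frame(fits)) {
    lcx <- as.matrix(fits)
    if (nrow(lcx) != length(percents)) {
      stop("LCx matrix needs one row per percentage", call. = FALSE)
    }
  } else {
    lcx <- vapply(fits, function(f) lc_at_percents(f, percents)$estimate,
                  numeric(length(percents)))
    lcx <- matrix(lcx, nrow = length(percents))
  }
  k <- ncol(lcx)
  if (length(proportions) != k) {
    stop("one proportion per component required", call. = FALSE)
  }
  mix <- vapply(seq_along(percents),
                function(i) ca_lcx(lcx[i, ], proportions), numeric(1))
  out <- data.frame(percent = percents)
  for (j in seq_len(k)) out[[paste0("lcx_", j)]] <- lcx[, j]
  for (j in seq_len(k)) out[[paste0("p_", j)]] <- proportions[j]
  out$lcx_mix <- mix
  class(out) <- c("ca_table", "data.frame")
  out
}

#' Concentration-addition predicted mixture LC50
#'
#' Fits a probit line of effect level against log10 mixture lethal
#' concentration through the rows of a CA table and inverts it at 50%.
#' The default is the same maximum-likelihood probit used for observed
#' bioassays (nominal group size `n_nominal`); `method = "ls"` uses
#' unweighted least squares on the probit transforms, the closed-form
#' alternative.
#'
#' @param rows a [ca_table()] (or any data.frame with `percent` and
#'   `lcx_mix` columns).
#' @param method `"probit"` (maximum likelihood, default) or `"ls"`.
#' @param n_nominal nominal group size for the probit method.
#' @return the [effective_level()] row at 50%.
#' @export
ca_predicted_lc50 <- function(rows, method = c("probit", "ls"),
                              n_nominal = 10) {
  method <- match.arg(method)
  if (nrow(rows) < 2L || length(unique(rows$percent)) < 2L) {
    stop("need >= 2 rows with distinct effect levels", call. = FALSE)
  }
  if (length(unique(rows$lcx_mix)) < 2L) {
    stop("degenerate rows: all mixture lethal concentrations identical",
         call. = FALSE)
  }
  if (method == "probit") {
    fit <- fit_probit(rows$lcx_mix, rep(n_nominal, nrow(rows)),
                      n_nominal * rows$percent / 100,
                      metameter = "concentration")
    effective_level(fit, 0.5)
  } else {
    ls <- stats::lm(stats::qnorm(rows$percent / 100) ~ log10(rows$lcx_mix))
    cf <- stats::coef(ls)
    if (cf[2L] <= 0) stop("least-squares probit slope must be positive",
                          call. = FALSE)
    est <- 10^(-cf[1L] / cf[2L])
    out <- data.frame(p = 0.5, estimate = unname(est), lower95 = NA_real_,
                      upper95 = NA_real_, extrapolated = NA,
                      limits_defined = FALSE)
    class(out) <- c("effective_level", "data.frame")
    out
  }
}
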