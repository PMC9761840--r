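#' Model deviation ratio
#'
#' The MDR scores agreement between a model-predicted and an observed
#' mixture lethal concentration as `predicted / observed`. A value near 1
#' indicates the mixture behaved as predicted; the conventional validity
#' band is 0.5 < MDR < 2, while values outside it are read as interaction
#' signals (see [classify_interaction()]). The ratio is computed at full
#' precision; `mdr_2dp` rounds half-up to two decimals for display, the
#' convention of printed comparison tables.
#'
#' @param predicted predicted mixture LC50 (mg/L), > 0. Vectorised.
#' @param observed observed mixture LC50 (mg/L), > 0.
#' @return data.frame of class `mdr_result`: `predicted`, `observed`,
#'   `mdr`, `mdr_2dp`, `valid`, `interaction`.
#' @examples
#' mdr(18.5, 11.1) # MDR 1.67, additive
#' @export
mdr <- function(predicted, observed) {
  if (any(!is.finite(predicted)) || any(predicted <= 0)) {
    stop("predicted LC50 must be positive", call. = FALSE)
  }
  if (any(!is.finite(observed)) || any(observed <= 0)) {
    stop("division error: observed LC50 must be positive", call. = FALSE)
  }
  ratio <- predicted / observed
  out <- data.frame(
    predicted = predicted, observed = observed, mdr = ratio,
    mdr_2dp = round_half_up(ratio, 2),
    valid = ratio > 0.5 & ratio < 2,
    interaction = classify_interaction(ratio))
  class(out) <- c("mdr_result", "data.frame")
  out
}

#' Classify mixture interaction from the model deviation ratio
#'
#' Step function with breakpoints at 0.5 and 2: synergistic when MDR > 2
#' (mixture more toxic than predicted), antagonistic when MDR < 0.5, and
#' additive in between; the boundary values 0.5 and 2 count as additive.
#'
#' @param mdr model deviation ratio(s), > 0.
#' @return character vector: `"synergistic"`, `"additive"` or
#'   `"antagonistic"`.
#' @export
classify_interaction <- function(mdr) {
  if (any(!is.finite(mdr)) || any(mdr <= 0)) {
    stop("MDR must be positive", call. = FALSE)
  }
  ifelse(mdr > 2, "synergistic", ifelse(mdr < 0.5, "antagonistic",
                                        "additive"))
}

#' Toxicity category of an LC50
#'
#' The conventional acute-toxicity scheme for aquatic organisms: highly
#' toxic for LC50 in [0.1, 1) mg/L, moderately toxic in [1, 10), slightly
#' toxic in [10, 100). Intervals are half-open `[lower, upper)`; values
#' below 0.1 or at/above 100 mg/L fall outside the scheme and are labelled
#' `"out-of-scheme"`.
#'
#' @param lc50 96-h LC50 in mg/L, > 0. Vectorised.
#' @return character vector of category labels.
#' @examples
#' classify_toxicity(c(0.27, 5.3, 11.1))
#' @export
classify_toxicity <- function(lc50) {
  if (any(!is.finite(lc50)) || any(lc50 <= 0)) {
    stop("LC50 must be positive", call. = FALSE)
  }
  labels <- c("out-of-scheme", "highly toxic", "moderately toxic",
              "slightly toxic", "out-of-scheme")
  idx <- findInterval(lc50, c(0.1, 1, 10, 100)) + 1L
  labels[idx]
}

#' Round half away from zero
#'
#' Display rounding used in comparison tables (base R's `round()` rounds
#' half to even).
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}
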