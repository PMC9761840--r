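#' Define a chemical mixture by its mixing ratio
#'
#' A mixture specification names the components and their ratio weights
#' (for instance atrazine:chlorpyrifos at 33.95:1, the equitoxic ratio of
#' the two 96-h LC50s). Component proportions are always derived from the
#' exact ratio weights, never from rounded printed proportions, so that
#' mixture arithmetic is reproducible.
#'
#' @param components character vector of component names (>= 1; a true
#'   mixture has >= 2).
#' @param ratio numeric ratio weights, one per component, all > 0.
#' @param species organism label (optional).
#' @param unit_scale multiplicative factor converting each component's
#'   declared unit to mg/L (default 1; e.g. 1e-3 for a component whose
#'   weights were written in ug/L). Applied to the ratio weights.
#' @param stock_g_per_L optional stock-solution concentration, carried as
#'   metadata only and never used in computation.
#' @return an object of class `mixture_spec`.
#' @examples
#' mixture_spec(c("atrazine", "chlorpyrifos"), c(33.95, 1), species = "catfish")
#' @export
mixture_spec <- function(components, ratio, species = NA_character_,
                         unit_scale = 1, stock_g_per_L = NA_real_) {
  components <- as.character(components)
  ratio <- as.numeric(ratio) * unit_scale
  if (length(components) < 1L) stop("mixture needs at least one component",
                                    call. = FALSE)
  if (length(ratio) != length(components)) {
    stop("one ratio weight per component required", call. = FALSE)
  }
  if (any(!is.finite(ratio)) || any(ratio <= 0)) {
    stop("all ratio weights must be positive and finite", call. = FALSE)
  }
  if (anyDuplicated(components)) {
    stop("component names must be unique", call. = FALSE)
  }
  structure(
    list(components = components, ratio = ratio,
         species = species, stock_g_per_L = stock_g_per_L),
    class = "mixture_spec")
}

#' Component proportions of a mixture
#'
#' Proportions are the ratio weights normalised to sum to one; they are
#' invariant to overall scaling of the weights.
#'
#' @param spec a [mixture_spec()].
#' @return named numeric vector summing to 1.
#' @export
proportions_of <- function(spec) {
  stopifnot(inherits(spec, "mixture_spec"))
  p <- spec$ratio / sum(spec$ratio)
  names(p) <- spec$components
  p
}

#' @export
print.mixture_spec <- function(x, ...) {
  cat("Mixture spec", if (!is.na(x$species)) paste0("(", x$species, ")"), "\n")
  p <- proportions_of(x)
  for (i in seq_along(x$components)) {
    cat(sprintf("  %-22s ratio %-10g proportion %.6g\n",
                x$components[i], x$ratio[i], p[i]))
  }
  if (!is.na(x$stock_g_per_L)) {
    cat("  stock:", x$stock_g_per_L, "g/L (metadata only)\n")
  }
  invisible(x)
}

#' Read a mixture specification from a YAML file
#'
#' Expected keys: `components` (names), `ratio` (weights), and optionally
#' `species`, `unit_scale`, `stock_g_per_L`.
#'
#' @param path path to a YAML file.
#' @return a [mixture_spec()].
#' @export
read_mixture_spec <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$components) || is.null(y$ratio)) {
    stop("mixture spec file must define 'components' and 'ratio'",
         call. = FALSE)
  }
  mixture_spec(
    components = unlist(y$components),
    ratio = unlist(y$ratio),
    species = if (is.null(y$species)) NA_character_ else y$species,
    unit_scale = if (is.null(y$unit_scale)) 1 else unlist(y$unit_scale),
    stock_g_per_L = if (is.null(y$stock_g_per_L)) NA_real_ else y$stock_g_per_L)
}
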