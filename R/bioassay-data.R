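#' Validate a table of quantal bioassay observations
#'
#' A quantal observation records, for one exposure group, the cumulative
#' number of dead organisms out of those exposed at an observation time.
#' Validation enforces the structural constraints of an acute-toxicity
#' bioassay: positive concentrations, non-negative times, dead counts
#' bounded by the exposed count, and (within a chemical/species/
#' concentration group) cumulative mortality that never decreases in time.
#'
#' @param x data.frame with columns `chemical`, `species`,
#'   `concentration_mg_per_L`, `time_h`, `n_exposed`, `n_dead`.
#' @return `x` invisibly, with rows ordered by group and time.
#' @export
validate_bioassay <- function(x) {
  required <- c("chemical", "species", "concentration_mg_per_L",
                "time_h", "n_exposed", "n_dead")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0L) {
    stop("bioassay table schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad <- which(!(x$concentration_mg_per_L > 0))
  if (length(bad) > 0L) {
    stop("validation error in row ", bad[1L],
         ": concentration must be positive (got ",
         x$concentration_mg_per_L[bad[1L]], ")", call. = FALSE)
  }
  bad <- which(x$time_h < 0)
  if (length(bad) > 0L) {
    stop("validation error in row ", bad[1L], ": time must be >= 0",
         call. = FALSE)
  }
  bad <- which(x$n_dead < 0 | x$n_dead > x$n_exposed)
  if (length(bad) > 0L) {
    stop("validation error in row ", bad[1L], ": n_dead = ",
         x$n_dead[bad[1L]], " outside [0, n_exposed = ",
         x$n_exposed[bad[1L]], "]", call. = FALSE)
  }
  ord <- order(x$chemical, x$species, x$concentration_mg_per_L, x$time_h)
  x <- x[ord, , drop = FALSE]
  key <- interaction(x$chemical, x$species, x$concentration_mg_per_L,
                     drop = TRUE)
  for (g in split(seq_len(nrow(x)), key)) {
    d <- x$n_dead[g]
    if (any(diff(d) < 0)) {
      stop("validation error: cumulative n_dead decreases over time in group ",
           x$chemical[g[1L]], "/", x$species[g[1L]], "/",
           x$concentration_mg_per_L[g[1L]], call. = FALSE)
    }
  }
  invisible(x)
}

#' Read a delimited bioassay table
#'
#' Reads comma-separated quantal bioassay records (UTF-8, dot decimal) and
#' validates them. Rows hold cumulative dead counts per concentration group
#' and observation time; duplicate aquaria are assumed already pooled into
#' one `n_exposed` per concentration.
#'
#' @param path path to a CSV file with header columns `chemical`, `species`,
#'   `concentration_mg_per_L`, `time_h`, `n_exposed`, `n_dead`.
#' @return validated data.frame ordered by group and time.
#' @export
read_bioassay_table <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  x <- validate_bioassay(x)
  rownames(x) <- NULL
  x
}

#' Write a bioassay table
#'
#' Inverse of [read_bioassay_table()]; the round trip reproduces records
#' field for field.
#'
#' @param x validated bioassay data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_bioassay_table <- function(x, path) {
  x <- validate_bioassay(x)
  utils::write.csv(x, path, row.names = FALSE, fileEncoding = "UTF-8",
                   quote = FALSE)
  invisible(path)
}

#' Percentage mortality of a quantal observation
#'
#' @param n_exposed organisms at the start of exposure (count, > 0).
#' @param n_dead cumulative dead at the observation time.
#' @return mortality in percent, `100 * n_dead / n_exposed`. Vectorised.
#' @examples
#' mortality_percent(20, 7) # 35
#' @export
mortality_percent <- function(n_exposed, n_dead) {
  if (any(n_exposed == 0)) {
    stop("undefined mortality ratio: n_exposed is zero", call. = FALSE)
  }
  if (any(n_dead < 0 | n_dead > n_exposed)) {
    stop("validation error: n_dead outside [0, n_exposed]", call. = FALSE)
  }
  100 * n_dead / n_exposed
}
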