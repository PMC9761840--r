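#' Define a synthetic time-to-death bioassay scenario
#'
#' The simulator draws per-organism death times from the tolerance model
#' implicit in probit LT50 analysis: log10 death time is normal with
#' median `exp(a + b * ln(C))` (the log-log lethal-time law) and standard
#' deviation `1 / slope`, where `slope` is the probit slope on log10 time.
#' Deaths after the study end are censored as survivors; cumulative dead
#' counts are emitted on the observation grid. This emulates the standard
#' acute-bioassay design (10 fingerlings per aquarium, duplicates pooled to
#' n = 20 per concentration, hourly mortality counts over 96 h).
#'
#' @param a,b true log-log lethal-time coefficients of the chemical.
#' @param slope true probit slope on log10 time, > 0.
#' @param concentrations exposure concentrations (mg/L), all > 0.
#' @param n_per_group organisms per concentration group (default 20,
#'   i.e. duplicates of 10 pooled).
#' @param observation_times mortality-count grid in hours (default hourly
#'   over the study).
#' @param study_end study duration in hours (default 96).
#' @param seed integer seed; identical seeds give identical datasets.
#' @param chemical,species labels for the emitted table.
#' @return an object of class `simulation_scenario`.
#' @export
simulation_scenario <- function(a, b, slope, concentrations,
                                n_per_group = 20,
                                observation_times = NULL,
                                study_end = 96, seed = 1,
                                chemical = "simulated", species = "fish") {
  if (!is.finite(a) || !is.finite(b)) stop("coefficients must be finite",
                                           call. = FALSE)
  if (!is.finite(slope) || slope <= 0) stop("probit slope must be positive",
                                            call. = FALSE)
  if (any(concentrations <= 0)) stop("concentrations must be positive",
                                     call. = FALSE)
  if (n_per_group < 1) stop("n_per_group must be >= 1", call. = FALSE)
  if (study_end <= 0) stop("study_end must be positive", call. = FALSE)
  if (is.null(observation_times)) observation_times <- seq_len(study_end)
  if (any(observation_times <= 0) || any(observation_times > study_end)) {
    stop("observation times must lie in (0, study_end]", call. = FALSE)
  }
  structure(list(a = a, b = b, slope = slope,
                 concentrations = concentrations,
                 n_per_group = as.integer(n_per_group),
                 observation_times = sort(unique(observation_times)),
                 study_end = study_end, seed = as.integer(seed),
                 chemical = chemical, species = species),
            class = "simulation_scenario")
}

# run fn with a private RNG stream so simulation never disturbs (or is
# disturbed by) the caller's random state
with_private_seed <- function(seed, fn) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  fn()
}

#' Simulate per-organism time-to-death as a quantal bioassay table
#'
#' @param scenario a [simulation_scenario()].
#' @return validated bioassay data.frame (one row per concentration and
#'   observation time, cumulative `n_dead`).
#' @export
simulate_time_to_death <- function(scenario) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  sdlog10 <- 1 / scenario$slope
  tab <- with_private_seed(scenario$seed, function() {
    do.call(rbind, lapply(scenario$concentrations, function(C) {
      median_t <- exp(scenario$a + scenario$b * log(C))
      death_t <- 10^stats::rnorm(scenario$n_per_group,
                                 mean = log10(median_t), sd = sdlog10)
      n_dead <- vapply(scenario$observation_times,
                       function(tt) sum(death_t <= tt), numeric(1))
      data.frame(chemical = scenario$chemical, species = scenario$species,
                 concentration_mg_per_L = C,
                 time_h = scenario$observation_times,
                 n_exposed = scenario$n_per_group, n_dead = n_dead)
    }))
  })
  rownames(tab) <- NULL
  validate_bioassay(tab)
  tab
}

#' Estimate per-concentration LT50s from a simulated (or real) bioassay
#'
#' Runs a time-axis probit fit on each concentration group's cumulative
#' mortality series. Groups where no deaths occurred by study end are
#' dropped (no time-response information); groups where the fit fails to
#' converge are returned with `NA`.
#'
#' @param bioassay validated bioassay table.
#' @return data.frame: `concentration_mg_per_L`, `lt50_h`, `converged`.
#' @export
estimate_group_lt50 <- function(bioassay) {
  validate_bioassay(bioassay)
  groups <- split(bioassay, bioassay$concentration_mg_per_L)
  rows <- lapply(groups, function(g) {
    C <- g$concentration_mg_per_L[1L]
    if (max(g$n_dead) == 0) return(NULL) # no deaths: no LT50 information
    est <- tryCatch({
      fit <- fit_probit(g$time_h, g$n_exposed, g$n_dead, metameter = "time")
      effective_level(fit, 0.5)$estimate
    }, error = function(e) NA_real_)
    data.frame(concentration_mg_per_L = C, lt50_h = est,
               converged = is.finite(est))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a bioassay and recover the lethal-time law
#'
#' Full estimator validation loop: simulate time-to-death data, fit a
#' time-axis probit per concentration to get LT50s, regress ln(LT50) on
#' ln(C), and compare the recovered coefficients with the scenario's truth.
#'
#' @param scenario a [simulation_scenario()] with >= 4 concentrations.
#' @return list of class `recovery_report`: `truth` (a, b), `fit` (the
#'   recovered [fit_loglog()]), `lt50` (per-concentration estimates),
#'   `bias_a`, `bias_b` (relative, as fractions), `r2`.
#' @export
recover_pipeline <- function(scenario) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  if (length(scenario$concentrations) < 4L) {
    stop("recovery needs >= 4 concentrations", call. = FALSE)
  }
  tab <- simulate_time_to_death(scenario)
  lt <- estimate_group_lt50(tab)
  lt <- lt[lt$converged, , drop = FALSE]
  if (nrow(lt) < 2L) stop("too few converged LT50 estimates", call. = FALSE)
  fit <- fit_loglog(lt$concentration_mg_per_L, lt$lt50_h)
  structure(list(truth = c(a = scenario$a, b = scenario$b),
                 fit = fit, lt50 = lt,
                 bias_a = (fit$a - scenario$a) / abs(scenario$a),
                 bias_b = (fit$b - scenario$b) / abs(scenario$b),
                 r2 = fit$r2),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Lethal-time law recovery\n")
  cat(sprintf("  truth:     a = %8.4f  b = %8.4f\n",
              x$truth["a"], x$truth["b"]))
  cat(sprintf("  recovered: a = %8.4f  b = %8.4f   (r2 = %.3f)\n",
              x$fit$a, x$fit$b, x$r2))
  cat(sprintf("  relative bias: a %+.2f%%  b %+.2f%%\n",
              100 * x$bias_a, 100 * x$bias_b))
  invisible(x)
}
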