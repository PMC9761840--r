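#' Run the full mixture-prediction pipeline
#'
#' Ties the modules together for a set of mixtures of one species:
#' component LT50s from the log-log law, mixture LT50 by lethal-time
#' addition, time-resolved mortality from the hyperbolic model, the
#' concentration-addition reference prediction, and - where an observed
#' mixture LC50 is supplied - the model deviation ratio with interaction
#' and toxicity classification. Optionally writes the four report tables
#' plus a JSON manifest of all settings to an output directory.
#'
#' @param config a list (or path to a YAML file) with elements:
#'   * `species` - species label present in the input tables;
#'   * `mixtures` - mixture ids to run (default: all for the species);
#'   * `coefficients` - data.frame (or CSV path) with columns `species`,
#'     `chemical`, `a`, `b`; default: the bundled case-study table;
#'   * `ratios` - data.frame/CSV with `species`, `mixture`,
#'     `component_index`, `chemical`, `ratio_weight`; default bundled;
#'   * `totals` - data.frame/CSV with `species`, `mixture`,
#'     `total_mg_per_L` (the concentration series per mixture); default:
#'     the bundled published series;
#'   * `component_lcx` - data.frame/CSV with `species`, `chemical`,
#'     `percent`, `lcx_mg_per_L`; default bundled;
#'   * `observed_lc50` - optional data.frame/CSV with `species`,
#'     `mixture`, `lc50_mg_per_L` (observed); default: bundled observed
#'     values;
#'   * `times` - exposure-time grid (default 24, 48, 72, 96 h);
#'   * `t_lc50` - exposure time for the predicted LC50 (default 96 h);
#'   * `method` - `"probit"` or `"invert"` for the hyperbolic-model LC50;
#'   * `out_dir` - optional output directory;
#'   * `verbose` - print per-stage progress (default TRUE).
#' @return invisibly, a list of class `pipeline_result`: `mixture_lt50`,
#'   `mortality`, `ca`, `comparison`, `manifest`.
#' @export
run_full_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  get_tab <- function(x, default) {
    if (is.null(x)) return(default())
    if (is.character(x)) return(utils::read.csv(x, stringsAsFactors = FALSE))
    as.data.frame(x)
  }
  species <- if (is.null(config$species)) "catfish" else config$species
  coefs <- get_tab(config$coefficients,
                   function() case_study_table("coefficients"))
  ratios <- get_tab(config$ratios, function() case_study_table("ratios"))
  totals_tab <- get_tab(config$totals,
                        function() case_study_table("mixture_lt50"))
  lcx_tab <- get_tab(config$component_lcx,
                     function() case_study_table("component_lcx"))
  observed <- get_tab(config$observed_lc50, function() {
    tab <- case_study_table("mixture_lc50")
    tab[tab$model == "observed", c("species", "mixture", "lc50_mg_per_L")]
  })
  times <- if (is.null(config$times)) c(24, 48, 72, 96) else
    as.numeric(unlist(config$times))
  t_lc50 <- if (is.null(config$t_lc50)) 96 else config$t_lc50
  method <- if (is.null(config$method)) "probit" else config$method
  verbose <- if (is.null(config$verbose)) TRUE else isTRUE(config$verbose)
  say <- function(...) if (verbose) message("[", species, "] ", ...)

  ratios <- ratios[ratios$species == species, ]
  mixtures <- if (is.null(config$mixtures)) unique(ratios$mixture) else
    unlist(config$mixtures)
  if (length(mixtures) == 0L) {
    warning("no mixtures to run; nothing done", call. = FALSE)
    return(invisible(structure(list(), class = "pipeline_result")))
  }
  coefs <- coefs[coefs$species == species, ]
  coeff_list <- stats::setNames(
    lapply(seq_len(nrow(coefs)),
           function(i) ltc_regression(coefs$a[i], coefs$b[i])),
    coefs$chemical)

  lt50_out <- list(); mort_out <- list(); ca_out <- list(); cmp_out <- list()
  for (mx in mixtures) {
    stage <- paste0("mixture '", mx, "'")
    rr <- ratios[ratios$mixture == mx, ]
    if (nrow(rr) == 0L) stop("stage ", stage, ": no ratio rows", call. = FALSE)
    rr <- rr[order(rr$component_index), ]
    spec <- mixture_spec(rr$chemical, rr$ratio_weight, species = species)
    totals <- totals_tab$total_mg_per_L[totals_tab$species == species &
                                          totals_tab$mixture == mx]
    if (length(totals) == 0L) {
      stop("stage ", stage, ": no total concentrations supplied",
           call. = FALSE)
    }
    say("lethal-time addition for ", mx, " over ", length(totals), " totals")
    pred <- predict_mixture_lt50_curve(spec, coeff_list, totals, times)
    # component-long shape so mixtures of any size stack into one table
    k <- length(spec$components)
    lt50_out[[mx]] <- do.call(rbind, lapply(seq_along(totals), function(i) {
      data.frame(species = species, mixture = mx, total_mg_per_L = totals[i],
                 component = spec$components,
                 conc_mg_per_L = as.numeric(
                   pred$lt50[i, paste0("conc_", spec$components)]),
                 lt50_component_h = as.numeric(
                   pred$lt50[i, paste0("lt50_", spec$components)]),
                 lt50_mix_h = pred$lt50$lt50_mix[i])
    }))
    mort_out[[mx]] <- cbind(species = species, mixture = mx,
                            pred$mortality,
                            percent_rounded = round_half_up(
                              pred$mortality$percent))
    hm <- hm_predicted_lc50(pred, t = t_lc50, method = method)

    lcx_sp <- lcx_tab[lcx_tab$species == species, ]
    percents <- sort(unique(lcx_sp$percent))
    lcx_mat <- vapply(spec$components, function(ch) {
      sub <- lcx_sp[lcx_sp$chemical == ch, ]
      if (nrow(sub) != length(percents)) {
        stop("stage ", stage, ": component LCx grid incomplete for ", ch,
             call. = FALSE)
      }
      sub$lcx_mg_per_L[order(sub$percent)]
    }, numeric(length(percents)))
    say("concentration addition for ", mx)
    catab <- ca_table(lcx_mat, proportions_of(spec), percents)
    ca_out[[mx]] <- do.call(rbind, lapply(seq_along(percents), function(i) {
      data.frame(species = species, mixture = mx, percent = percents[i],
                 component = spec$components,
                 lcx_mg_per_L = as.numeric(
                   catab[i, paste0("lcx_", seq_along(spec$components))]),
                 proportion = as.numeric(proportions_of(spec)),
                 lcx_mix_mg_per_L = catab$lcx_mix[i])
    }))
    ca50 <- ca_predicted_lc50(catab)

    obs <- observed$lc50_mg_per_L[observed$species == species &
                                    observed$mixture == mx]
    for (model in c("hm", "ca")) {
      el <- if (model == "hm") hm else ca50
      row <- data.frame(species = species, mixture = mx, model = model,
                        predicted = el$estimate, lower95 = el$lower95,
                        upper95 = el$upper95,
                        predicted_extrapolated = isTRUE(el$extrapolated))
      if (length(obs) == 1L && is.finite(obs)) {
        m <- mdr(el$estimate, obs)
        row$observed <- obs
        row$mdr <- m$mdr
        row$mdr_2dp <- m$mdr_2dp
        row$valid <- m$valid
        row$interaction <- m$interaction
        row$toxicity_predicted <- classify_toxicity(el$estimate)
      }
      cmp_out[[paste(mx, model)]] <- row
    }
  }
  bind <- function(x) { out <- do.call(rbind, x); rownames(out) <- NULL; out }
  result <- structure(
    list(mixture_lt50 = bind(lt50_out), mortality = bind(mort_out),
         ca = bind(ca_out), comparison = bind(cmp_out),
         manifest = list(species = species, mixtures = mixtures,
                         times = times, t_lc50 = t_lc50, method = method,
                         n_coefficients = nrow(coefs),
                         generated = "lethaltime run_full_pipeline")),
    class = "pipeline_result")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in c("mixture_lt50", "mortality", "ca", "comparison")) {
      utils::write.csv(result[[nm]],
                       file.path(config$out_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    }
    jsonlite::write_json(result$manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    say("reports written to ", config$out_dir)
  }
  invisible(result)
}

#' @export
print.pipeline_result <- function(x, ...) {
  if (length(x) == 0L) { cat("empty pipeline result\n"); return(invisible(x)) }
  cat("Pipeline result:", x$manifest$species, "-",
      length(x$manifest$mixtures), "mixture(s)\n\n")
  print(x$comparison, row.names = FALSE)
  invisible(x)
}
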