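#' Configure an analysis run
#'
#' Collects everything one classify-match-fit-summarise run needs. Inputs
#' may be in-memory objects (data.frames / an [exposure_store()]) or file
#' paths; a YAML file with the same keys can be loaded with
#' [read_pipeline_config()].
#'
#' @param records health records: data.frame or CSV path (see
#'   [read_health_records()]).
#' @param exposure exposure series: [exposure_store()], long data.frame or
#'   CSV path.
#' @param categories outcome categories to run.
#' @param lag_kinds lag structures to run for every category.
#' @param modifiers effect modifiers to run for every category.
#' @param specs optional explicit list of [model_spec()] objects; when
#'   given, \code{categories}/\code{lag_kinds}/\code{modifiers} are ignored.
#' @param unit_map optional data.frame or CSV path mapping
#'   \code{location_id} to \code{unit_id}; when present, exposure is
#'   aggregated to the coarse units (unweighted daily mean) and record
#'   locations are re-labelled accordingly before extraction.
#' @param study_window optional length-2 date vector bounding visit dates.
#' @param temperature_lag lag (0..6) of the temperature main-effect
#'   covariate.
#' @param dlm_mode \code{"per_window"} or \code{"joint"}.
#' @param reference_season reference level of the season interactions.
#' @param prefix_match passed to [respiratory_code_sets()].
#' @param cutoffs optional fixed temperature cutoffs; default: computed
#'   per category from the pooled lagged temperatures of its case and
#'   referent days.
#' @return object of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(records, exposure,
                            categories = c("asthma", "LRTI", "URTI"),
                            lag_kinds = c("cumulative", "weekly_avg"),
                            modifiers = c("none", "temperature", "season"),
                            specs = NULL, unit_map = NULL,
                            study_window = NULL, temperature_lag = 0L,
                            dlm_mode = "per_window",
                            reference_season = "winter",
                            prefix_match = FALSE, cutoffs = NULL) {
  if (is.null(specs)) {
    specs <- list()
    for (cat in categories)
      for (lk in lag_kinds)
        for (mod in modifiers)
          specs[[length(specs) + 1L]] <- model_spec(
            cat, lag_kind = lk, modifier = mod,
            temperature_lag = temperature_lag, dlm_mode = dlm_mode,
            reference_season = reference_season)
  }
  structure(list(records = records, exposure = exposure,
                 categories = categories, specs = specs,
                 unit_map = unit_map, study_window = study_window,
                 prefix_match = prefix_match, cutoffs = cutoffs),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()]; \code{records},
#' \code{exposure} and \code{unit_map} are file paths.
#'
#' @param path YAML file.
#' @return a \code{"pipeline_config"}.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("records", "exposure", "categories", "lag_kinds", "modifiers",
             "unit_map", "study_window", "temperature_lag", "dlm_mode",
             "reference_season", "prefix_match")
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(pipeline_config, y)
}

.as_records <- function(x, study_window = NULL) {
  if (is.character(x)) read_health_records(x, study_window)
  else validate_health_records(x, study_window)
}

.as_store <- function(x) {
  if (inherits(x, "exposure_store")) x
  else if (is.character(x)) read_exposure(x)
  else exposure_store(x)
}

# md5 of the scalar run settings, for the run report
.config_hash <- function(config) {
  keep <- config[setdiff(names(config), c("records", "exposure"))]
  keep$specs <- lapply(keep$specs, unclass)
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(keep, tf, auto_unbox = TRUE, force = TRUE)
  unname(tools::md5sum(tf))
}

#' Run the full case-crossover distributed-lag pipeline
#'
#' classify -> match -> build design -> fit -> marginal effects, per
#' outcome category and model spec, with per-stage counts collected into a
#' run report. Deterministic: identical config and inputs give identical
#' output.
#'
#' @param config a [pipeline_config()].
#' @param verbose print stage progress messages.
#' @return object of class \code{"crosslag_run"}: list with
#'   \code{results} (long data.frame, one row per estimate: category,
#'   model, group, lag_kind, window, or, ci_lo, ci_hi, p_value, n),
#'   \code{report} (stage counts, convergence counts, package version,
#'   config hash) and \code{fits} (the underlying \code{"dlm_fit"}
#'   objects).
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  records <- .as_records(config$records, config$study_window)
  store <- .as_store(config$exposure)
  say("read %d records, %d exposure locations", nrow(records),
      length(store$locations))
  if (!is.null(config$unit_map)) {
    um <- if (is.character(config$unit_map))
      utils::read.csv(config$unit_map, stringsAsFactors = FALSE)
      else config$unit_map
    store <- aggregate_exposure(store, um)
    records$location_id <- relabel_locations(records$location_id, um)
    say("aggregated exposure to %d units", length(store$locations))
  }
  defs <- respiratory_code_sets(prefix_match = config$prefix_match)
  events <- build_case_events(records, defs)
  ev_counts <- table(events$category)
  say("classified events: %s",
      paste(names(ev_counts), ev_counts, collapse = ", "))

  results <- list()
  fits <- list()
  strata_built <- integer(0)
  strata_dropped <- integer(0)
  n_fits <- 0L
  n_converged <- 0L
  for (cat in config$categories) {
    ev <- events[events$category == cat, , drop = FALSE]
    if (!nrow(ev)) {
      say("category %s: no events, skipping fits", cat)
      strata_built[cat] <- 0L
      results[[length(results) + 1L]] <- data.frame(
        category = cat, model = "PM", group = "none", lag_kind = NA,
        window = NA, or = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
        p_value = NA_real_, n = 0L, stringsAsFactors = FALSE)
      next
    }
    ms <- build_matched_sets(ev)
    strata_built[cat] <- length(unique(ms$stratum_id))
    for (spec in config$specs) {
      if (spec$category != cat) next
      fit <- fit_dlm(ms, store, spec, cutoffs = config$cutoffs)
      fits[[length(fits) + 1L]] <- fit
      dropped <- max(vapply(fit$models, `[[`, 0L, "n_dropped"))
      strata_dropped[cat] <- max(strata_dropped[cat], dropped, 0L,
                                 na.rm = TRUE)
      conv <- vapply(fit$models, function(m) m$fit$converged, logical(1))
      n_fits <- n_fits + length(conv)
      n_converged <- n_converged + sum(conv)
      results[[length(results) + 1L]] <- marginal_effects(fit)
      say("category %s: %s/%s fitted (%d/%d converged)", cat,
          spec$lag_kind, spec$modifier, sum(conv), length(conv))
    }
  }
  results <- do.call(rbind, results)
  rownames(results) <- NULL
  report <- list(
    n_records = nrow(records),
    events_per_category = as.list(ev_counts),
    strata_built = as.list(strata_built),
    max_strata_dropped_missing_exposure = as.list(strata_dropped),
    n_models_fit = n_fits, n_models_converged = n_converged,
    package_version = as.character(utils::packageVersion("crosslag")),
    config_hash = .config_hash(config))
  structure(list(results = results, report = report, fits = fits),
            class = "crosslag_run")
}

#' @export
print.crosslag_run <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    "crosslag run: %d records; %d model fits (%d converged); %d estimates\n",
    r$n_records, r$n_models_fit, r$n_models_converged, nrow(x$results)))
  cat("events:",
      paste(names(r$events_per_category), unlist(r$events_per_category),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Write pipeline outputs
#'
#' Emits \code{results.csv}, \code{results.json} and \code{report.json}.
#'
#' @param run a [run_pipeline()] result.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_results <- function(run, dir) {
  stopifnot(inherits(run, "crosslag_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(run$results, file.path(dir, "results.csv"),
                   row.names = FALSE)
  jsonlite::write_json(run$results, file.path(dir, "results.json"),
                       dataframe = "rows", digits = NA)
  jsonlite::write_json(run$report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Wide-format view of a results table
#'
#' Re-arranges the long results into one row per category, model and
#' modifier group with OR (95 percent CI) / p-value columns side by side
#' per lag kind, for the requested window of each kind.
#'
#' @param results the \code{results} data.frame of a [run_pipeline()] run.
#' @param windows named character: which window label to display per lag
#'   kind.
#' @return data.frame in the wide layout.
#' @export
format_results_wide <- function(results,
                                windows = c(cumulative = "0-13",
                                            weekly_avg = "7-13")) {
  fmt <- function(r)
    sprintf("%.2f (%.2f-%.2f) p=%.3f", r$or, r$ci_lo, r$ci_hi, r$p_value)
  keys <- unique(results[, c("category", "model", "group")])
  out <- keys
  for (kind in names(windows)) {
    col <- rep(NA_character_, nrow(keys))
    sub <- results[results$lag_kind %in% kind &
                     results$window == windows[[kind]], , drop = FALSE]
    for (i in seq_len(nrow(keys))) {
      m <- sub[sub$category == keys$category[i] &
                 sub$model == keys$model[i] & sub$group == keys$group[i], ,
               drop = FALSE]
      if (nrow(m)) col[i] <- fmt(m[1, ])
    }
    out[[paste0(kind, "_", windows[[kind]])]] <- col
  }
  n_by <- results[!duplicated(results[, c("category", "model", "group")]),
                  c("category", "model", "group", "n")]
  merge(out, n_by, sort = FALSE)
}
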