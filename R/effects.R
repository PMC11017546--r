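#' Temperature percentile cutoffs for marginal summaries
#'
#' Computes the colder / median / hotter cutoffs (by default the 15th, 50th
#' and 85th percentiles) of a temperature collection by linear interpolation
#' between closest order statistics (\code{stats::quantile} type 7).
#'
#' @param temps numeric vector of temperatures (degrees C); \code{NA}
#'   dropped.
#' @param probs probabilities of the three cutoffs.
#' @return named numeric vector \code{c(colder, median, hotter)}. A warning
#'   is issued when the cutoffs are not strictly increasing (degenerate
#'   input).
#' @export
temperature_percentiles <- function(temps, probs = c(0.15, 0.50, 0.85)) {
  temps <- temps[!is.na(temps)]
  if (length(temps) < 3L)
    stop("need at least 3 temperature values", call. = FALSE)
  stopifnot(length(probs) == 3L, !is.unsorted(probs))
  q <- stats::quantile(temps, probs = probs, type = 7, names = FALSE)
  names(q) <- c("colder", "median", "hotter")
  if (any(diff(q) <= 0))
    warning("temperature cutoffs are not strictly increasing", call. = FALSE)
  q
}

.KINDS <- c("cumulative", "weekly_avg", "single")
.MODIFIERS <- c("none", "temperature", "season")
.SEASONS <- c("winter", "spring", "summer", "fall")

#' Default lag windows for a lag structure
#'
#' Single-day: lags 0..14; cumulative: 0-k for k = 0..14; weekly average:
#' the nine 7-day windows 0-6, 1-7, ..., 8-14.
#'
#' @param lag_kind one of \code{"single"}, \code{"cumulative"},
#'   \code{"weekly_avg"}.
#' @param max_lag largest lag considered (default 14 days).
#' @return list of integer \code{c(lo, hi)} windows.
#' @export
default_windows <- function(lag_kind = .KINDS, max_lag = 14L) {
  lag_kind <- match.arg(lag_kind)
  switch(lag_kind,
         single     = lapply(0:max_lag, function(k) c(k, k)),
         cumulative = lapply(0:max_lag, function(k) c(0L, k)),
         weekly_avg = lapply(0:(max_lag - 6L), function(l) c(l, l + 6L)))
}

#' Specify one distributed-lag model family
#'
#' A model spec names the outcome category, the lag structure and its
#' windows, the effect modifier and how the distributed lags enter the
#' conditional logistic model: \code{dlm_mode = "per_window"} (default) fits
#' one model per window with that window's summary exposure as a single
#' covariate; \code{"joint"} fits one model carrying all 15 single-day lag
#' covariates simultaneously (plus their modifier interactions) and reads
#' window effects off linear combinations of the per-lag coefficients.
#'
#' Season never enters as a main effect: referent days share the case day's
#' calendar month, so season is constant within every stratum and its main
#' effect is not identifiable; only PM x season interaction terms are used
#' (winter reference by default). Temperature does vary within strata and is
#' included as a continuous main effect at \code{temperature_lag} days
#' before each stratum day, together with the PM x temperature product.
#'
#' @param category outcome category label (e.g. \code{"asthma"}).
#' @param lag_kind \code{"cumulative"}, \code{"weekly_avg"} or
#'   \code{"single"}.
#' @param lag_windows list of integer \code{c(lo, hi)} windows; defaults to
#'   [default_windows()] for the chosen kind.
#' @param modifier \code{"none"}, \code{"temperature"} or \code{"season"}.
#' @param temperature_lag lag (0..6 days) at which the temperature
#'   main-effect covariate is taken.
#' @param dlm_mode \code{"per_window"} or \code{"joint"}.
#' @param reference_season reference level for season interactions.
#' @return object of class \code{"model_spec"}.
#' @export
model_spec <- function(category, lag_kind = .KINDS, lag_windows = NULL,
                       modifier = .MODIFIERS, temperature_lag = 0L,
                       dlm_mode = c("per_window", "joint"),
                       reference_season = "winter") {
  lag_kind <- match.arg(lag_kind)
  modifier <- match.arg(modifier)
  dlm_mode <- match.arg(dlm_mode)
  if (is.null(lag_windows)) lag_windows <- default_windows(lag_kind)
  if (!is.list(lag_windows)) lag_windows <- list(lag_windows)
  for (w in lag_windows) {
    if (length(w) != 2L || w[1] > w[2] || w[1] < 0L || w[2] > 14L)
      stop("invalid lag window", call. = FALSE)
    ok <- switch(lag_kind,
                 single     = w[1] == w[2],
                 cumulative = w[1] == 0L,
                 weekly_avg = w[2] - w[1] == 6L)
    if (!ok) stop("window (", w[1], ",", w[2], ") inconsistent with lag_kind ",
                  lag_kind, call. = FALSE)
  }
  if (temperature_lag < 0L || temperature_lag > 6L)
    stop("temperature_lag must be in 0..6", call. = FALSE)
  reference_season <- match.arg(reference_season, .SEASONS)
  structure(list(category = category, lag_kind = lag_kind,
                 lag_windows = lag_windows, modifier = modifier,
                 temperature_lag = as.integer(temperature_lag),
                 dlm_mode = dlm_mode, reference_season = reference_season),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("model_spec: %s | %s (%d window(s)) | modifier %s | %s mode\n",
              x$category, x$lag_kind, length(x$lag_windows), x$modifier,
              x$dlm_mode))
  invisible(x)
}

# summed (or averaged) lagged pm25 with NA propagation; internal twin of the
# exported lag_* functions used where dropping (not erroring) is the policy
.lag_feature_na <- function(store, loc, anchor, lo, hi, average = FALSE) {
  v <- 0
  for (j in lo:hi) v <- v + .lagged_pm(store, loc, anchor, j)
  if (average) v / (hi - lo + 1L) else v
}

.window_label <- function(w) {
  if (w[1] == w[2]) as.character(w[1]) else paste0(w[1], "-", w[2])
}

#' Build a conditional-logit design matrix from matched sets
#'
#' Attaches the lagged-exposure covariate(s) and modifier terms required by
#' a model spec to every stratum-day row of a case-crossover dataset. Strata
#' whose required lag window (or temperature lag) reaches outside exposure
#' coverage for any of their rows are dropped whole, with the count
#' reported; exposure is never imputed.
#'
#' @param matched_sets long case-crossover data from
#'   [build_matched_sets()].
#' @param store an [exposure_store()].
#' @param spec a [model_spec()].
#' @param window integer \code{c(lo, hi)}; required in
#'   \code{"per_window"} mode, ignored in \code{"joint"} mode.
#' @return list with \code{X} (model matrix), \code{stratum}, \code{case},
#'   \code{data} (the retained rows with covariates), \code{n_strata},
#'   \code{n_dropped} (strata lost to missing exposure) and
#'   \code{season_n} (strata per case-day season).
#' @export
build_design <- function(matched_sets, store, spec, window = NULL) {
  stopifnot(inherits(spec, "model_spec"), inherits(store, "exposure_store"))
  ms <- matched_sets
  if (!nrow(ms)) stop("empty matched-set table", call. = FALSE)
  loc <- as.character(ms$location_id)
  dt <- as.Date(ms$date)

  joint <- spec$dlm_mode == "joint"
  if (!joint) {
    if (is.null(window)) stop("window required in per_window mode",
                              call. = FALSE)
    cols <- list(pm = .lag_feature_na(store, loc, dt, window[1], window[2],
                                      average = spec$lag_kind == "weekly_avg"))
  } else {
    cols <- lapply(0:14, function(k) .lagged_pm(store, loc, dt, k))
    names(cols) <- paste0("pm_lag", 0:14)
  }
  pm_names <- names(cols)

  if (spec$modifier == "temperature") {
    tix <- .store_flat_index(store, loc, dt - spec$temperature_lag)
    tmax <- store$tmax[tix]
    cols$tmax <- tmax
    for (nm in pm_names) cols[[paste0(nm, "_tmax")]] <- cols[[nm]] * tmax
  } else if (spec$modifier == "season") {
    seas <- season_of(dt)
    for (s in setdiff(.SEASONS, spec$reference_season)) {
      ind <- as.numeric(seas == s)
      for (nm in pm_names) cols[[paste0(nm, "_", s)]] <- cols[[nm]] * ind
    }
  }

  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  # drop whole strata touched by any missing value
  bad_row <- rowSums(is.na(X)) > 0
  bad_strata <- unique(ms$stratum_id[bad_row])
  keep <- !(ms$stratum_id %in% bad_strata)
  if (!any(keep))
    stop("all strata dropped for missing exposure", call. = FALSE)
  X <- X[keep, , drop = FALSE]
  ms <- ms[keep, , drop = FALSE]
  case_dates <- ms$date[ms$is_case == 1L]
  season_n <- table(season_of(case_dates))
  list(X = X, stratum = ms$stratum_id, case = ms$is_case,
       data = cbind(ms, as.data.frame(X)),
       n_strata = length(unique(ms$stratum_id)),
       n_dropped = length(bad_strata),
       season_n = season_n)
}

#' Fit the distributed-lag conditional logistic model(s) of a spec
#'
#' In \code{"per_window"} mode each lag window is fitted in its own
#' conditional logistic model; in \code{"joint"} mode a single model with
#' all 15 single-day lags (and modifier interactions) is fitted.
#'
#' @inheritParams build_design
#' @param cutoffs optional temperature cutoffs (see
#'   [temperature_percentiles()]); when \code{NULL} and the spec's modifier
#'   is temperature, they are computed from the pooled lagged temperatures
#'   of all case and referent days in \code{matched_sets}.
#' @param ... passed to [cclogit_fit()].
#' @return object of class \code{"dlm_fit"}: list with the spec, one
#'   element per fitted model (each holding the window, the
#'   \code{"cclogit"} fit, stratum counts and drop counts), and the
#'   temperature cutoffs used (if any).
#' @export
fit_dlm <- function(matched_sets, store, spec, cutoffs = NULL, ...) {
  stopifnot(inherits(spec, "model_spec"))
  if (spec$modifier == "temperature" && is.null(cutoffs)) {
    tix <- .store_flat_index(store, as.character(matched_sets$location_id),
                             as.Date(matched_sets$date) - spec$temperature_lag)
    cutoffs <- temperature_percentiles(store$tmax[tix])
  }
  fit_one <- function(window) {
    des <- build_design(matched_sets, store, spec, window)
    fit <- cclogit_fit(des$X, des$stratum, des$case, ...)
    list(window = window, fit = fit, n_strata = des$n_strata,
         n_dropped = des$n_dropped, season_n = des$season_n)
  }
  models <- if (spec$dlm_mode == "joint") list(fit_one(NULL))
            else lapply(spec$lag_windows, fit_one)
  structure(list(spec = spec, models = models, cutoffs = cutoffs),
            class = "dlm_fit")
}

#' @export
print.dlm_fit <- function(x, ...) {
  print(x$spec)
  for (m in x$models) {
    lab <- if (is.null(m$window)) "joint" else .window_label(m$window)
    cat(sprintf("  window %-6s n=%d (dropped %d) %s\n", lab, m$n_strata,
                m$n_dropped,
                if (m$fit$converged) "converged" else "NOT converged"))
  }
  invisible(x)
}

#' Linear combination of conditional-logit coefficients
#'
#' Delta-method odds ratio for a weight vector \eqn{c}: estimate
#' \eqn{c'\hat\beta}, standard error \eqn{\sqrt{c'\hat\Sigma c}}, Wald 95
#' percent confidence interval \eqn{\exp(c'\hat\beta \pm z_{0.975} SE)} and
#' two-sided normal p-value.
#'
#' @param fit a converged \code{"cclogit"} fit.
#' @param w numeric weight vector; if named, names are matched against the
#'   coefficient names (missing ones get weight 0), otherwise its length
#'   must equal the number of coefficients.
#' @param level confidence level.
#' @return one-row data.frame with \code{log_or, se, or, ci_lo, ci_hi,
#'   p_value}.
#' @export
lincom <- function(fit, w, level = 0.95) {
  stopifnot(inherits(fit, "cclogit"))
  if (!fit$converged)
    stop("linear combinations require a converged fit", call. = FALSE)
  cf <- fit$coefficients
  if (!is.null(names(w))) {
    unknown <- setdiff(names(w), names(cf))
    if (length(unknown))
      stop("unknown coefficient(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    wv <- stats::setNames(rep(0, length(cf)), names(cf))
    wv[names(w)] <- w
    w <- wv
  } else if (length(w) != length(cf)) {
    stop("length(w) != number of coefficients", call. = FALSE)
  }
  est <- sum(w * cf)
  se <- sqrt(drop(t(w) %*% fit$vcov %*% w))
  q <- stats::qnorm(1 - (1 - level) / 2)
  p <- if (se == 0) 1 else 2 * stats::pnorm(-abs(est / se))
  data.frame(log_or = est, se = se, or = exp(est),
             ci_lo = exp(est - q * se), ci_hi = exp(est + q * se),
             p_value = p)
}

# weight vector (named) for one window x modifier level on a dlm model
.effect_weights <- function(spec, window, level, cutoffs) {
  joint <- spec$dlm_mode == "joint"
  if (joint) {
    pm_names <- paste0("pm_lag", window[1]:window[2])
    base <- stats::setNames(rep(1, length(pm_names)), pm_names)
  } else {
    # cumulative covariate is the raw sum: a simultaneous 1 ug/m3 increase
    # on every day of window 0-k moves it by k+1
    mult <- if (spec$lag_kind == "cumulative") window[2] - window[1] + 1 else 1
    pm_names <- "pm"
    base <- c(pm = mult)
  }
  if (spec$modifier == "temperature" && level != "none") {
    tstar <- cutoffs[[level]]
    base <- c(base, stats::setNames(unname(base) * tstar,
                                    paste0(pm_names, "_tmax")))
  } else if (spec$modifier == "season" && level != spec$reference_season) {
    base <- c(base, stats::setNames(unname(base[pm_names]),
                                    paste0(pm_names, "_", level)))
  }
  base
}

#' Marginal odds-ratio estimates from a distributed-lag fit
#'
#' Turns a [fit_dlm()] object into the long results table: one row per lag
#' window and modifier level, each the delta-method odds ratio for a
#' simultaneous 1 ug/m3 increase in PM2.5 on every day of the window, at
#' the given temperature cutoff or in the given season.
#'
#' @param object a \code{"dlm_fit"}.
#' @param cutoffs temperature cutoffs; defaults to those stored in the fit.
#' @param level confidence level.
#' @return data.frame with columns \code{category, model, group, lag_kind,
#'   window, or, ci_lo, ci_hi, p_value, n} (n: contributing strata; for
#'   season groups, strata whose case day falls in that season).
#' @export
marginal_effects <- function(object, cutoffs = object$cutoffs, level = 0.95) {
  stopifnot(inherits(object, "dlm_fit"))
  spec <- object$spec
  groups <- switch(spec$modifier,
                   none = "none",
                   temperature = c("colder", "median", "hotter"),
                   season = .SEASONS)
  model_lab <- switch(spec$modifier, none = "PM",
                      temperature = "PM-Temp", season = "PM-Season")
  rows <- list()
  for (m in object$models) {
    windows <- if (spec$dlm_mode == "joint") spec$lag_windows else
      list(m$window)
    for (w in windows) {
      for (g in groups) {
        wt <- .effect_weights(spec, w, g, cutoffs)
        lc <- lincom(m$fit, wt, level = level)
        n <- if (spec$modifier == "season")
          as.integer(m$season_n[[g]]) else m$n_strata
        rows[[length(rows) + 1L]] <- data.frame(
          category = spec$category, model = model_lab, group = g,
          lag_kind = spec$lag_kind, window = .window_label(w),
          or = lc$or, ci_lo = lc$ci_lo, ci_hi = lc$ci_hi,
          p_value = lc$p_value, n = n, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
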