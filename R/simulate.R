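#' Ground truth for the synthetic event generator
#'
#' The generative hazard is the twin of the fitted model: for child \eqn{i}
#' at location \eqn{j} on day \eqn{t},
#' \deqn{logit P(event) = \alpha + \sum_k \beta_k PM_{j,t-k}
#'   + \gamma T_{j,t} S_{j,t} + \delta T_{j,t} + \theta_{season(t)} S_{j,t}
#'   + \mu_{season(t)}}
#' where \eqn{S_{j,t} = \sum_k w_k PM_{j,t-k}} is the weighted lag sum the
#' modifiers act on. Season main offsets \eqn{\mu} are constant within
#' matched strata and are eliminated by the design; they are included so
#' that this elimination is demonstrable.
#'
#' The hazard is generative, so it must remain in the rare-event regime
#' (event probability well below 1 on every child-day) for the
#' case-crossover odds-ratio target to coincide with the hazard
#' coefficients; a per-day log odds ratio large enough to reproduce
#' 2-3-fold odds ratios per 1 ug/m3 over a realistic PM2.5 range would
#' saturate the logistic hazard during smoke episodes and break that
#' regime. Defaults therefore use a constant per-day log odds ratio of
#' 0.004 per ug/m3 over lags 0-13 (a 14-day cumulative odds ratio of about
#' 1.06 for a simultaneous 1 ug/m3 increase, the magnitude typical of
#' large multi-site studies) with a temperature interaction of -0.00015
#' per ug/m3 per degree C.
#'
#' @param baseline_daily_rate per-child per-day event probability at the
#'   calibration point (see [simulate_events()]).
#' @param lag_coeffs numeric length 15: log-OR per ug/m3 at lags 0..14.
#' @param temp_main log-OR per degree C (main effect of temperature).
#' @param temp_interaction log-OR change per ug/m3 per degree C applied to
#'   the weighted lag sum.
#' @param season_interactions named numeric: log-OR per ug/m3 offsets of
#'   the weighted lag sum by season (winter, spring, summer, fall).
#' @param season_main named numeric: additive log-odds season offsets
#'   (eliminated by the matched design).
#' @param interaction_weights numeric length 15 or \code{NULL}; weights
#'   \eqn{w_k} of the lag sum the modifiers multiply. \code{NULL} means the
#'   indicator of non-zero \code{lag_coeffs}.
#' @param category_mix named probabilities over \code{asthma, LRTI, URTI,
#'   other} ("other" draws a respiratory code outside the three
#'   case-definition sets, so the record matches no category).
#' @return object of class \code{"sim_truth"}.
#' @export
sim_truth <- function(baseline_daily_rate = 6.2e-4,
                      lag_coeffs = c(rep(0.004, 14), 0),
                      temp_main = 0,
                      temp_interaction = -0.00015,
                      season_interactions = c(winter = 0, spring = 0,
                                              summer = 0, fall = 0),
                      season_main = c(winter = 0, spring = 0,
                                      summer = 0, fall = 0),
                      interaction_weights = NULL,
                      category_mix = c(asthma = 0.0784, LRTI = 0.0630,
                                       URTI = 0.8281, other = 0.0305)) {
  stopifnot(length(lag_coeffs) == 15L, all(is.finite(lag_coeffs)),
            is.finite(temp_interaction), is.finite(temp_main),
            baseline_daily_rate > 0, baseline_daily_rate < 0.1)
  seasons <- c("winter", "spring", "summer", "fall")
  stopifnot(all(seasons %in% names(season_interactions)),
            all(seasons %in% names(season_main)))
  if (is.null(interaction_weights))
    interaction_weights <- as.numeric(lag_coeffs != 0)
  stopifnot(length(interaction_weights) == 15L)
  category_mix <- category_mix / sum(category_mix)
  structure(list(baseline_daily_rate = baseline_daily_rate,
                 lag_coeffs = lag_coeffs, temp_main = temp_main,
                 temp_interaction = temp_interaction,
                 season_interactions = season_interactions[seasons],
                 season_main = season_main[seasons],
                 interaction_weights = interaction_weights,
                 category_mix = category_mix),
            class = "sim_truth")
}

#' Configuration of a synthetic study
#'
#' Defaults emulate a sparsely populated cold-winter study region: an
#' 821-day daily series
#' (2017-12-01 to 2020-02-29) at a 45-49 degree N latitude with bimodal
#' seasonal PM2.5 (winter residential wood smoke plus sporadic multi-day
#' summer wildfire-smoke episodes, overall range about 0.5-40 ug/m3),
#' sinusoidal-plus-AR(1) daily maximum temperature, and a pediatric
#' population producing on the order of 10-13 respiratory events per day.
#'
#' @param n_locations number of residence locations.
#' @param n_days length of the daily series (>= 60: at least one month of
#'   referents plus the 14-day lag history).
#' @param start_date first day of the series.
#' @param n_children total pediatric population, split evenly over
#'   locations.
#' @param seed integer master seed; exposure uses \code{seed} and events
#'   \code{seed + 1}, so a fixed seed reproduces the study byte for byte.
#' @param pm_params list: \code{baseline_log_mean} (log ug/m3),
#'   \code{winter_amp} (log-scale winter seasonal amplitude),
#'   \code{ar_phi}, \code{ar_sd} (regional AR(1) autocorrelation and
#'   stationary SD on the log scale), \code{spatial_sd} (between-location
#'   offset SD), \code{local_sd} (within-location daily noise SD),
#'   \code{spike_rate} (expected wildfire episodes per summer),
#'   \code{spike_mag} (log-scale peak magnitude), \code{spike_decay}
#'   (per-day decay of an episode), \code{spike_loc_sd} (between-location
#'   SD of episode intensity on the log scale).
#' @param temp_params list: \code{annual_mean}, \code{amplitude} (degrees
#'   C), \code{noise_sd}, \code{ar_phi}, \code{spatial_sd}.
#' @param truth a [sim_truth()].
#' @param dx_secondary_prob probability that a record carries a secondary
#'   diagnosis code (half within, half across categories).
#' @return object of class \code{"sim_config"}.
#' @export
sim_config <- function(n_locations = 25L, n_days = 821L,
                       start_date = "2017-12-01", n_children = 20000L,
                       seed = 1L,
                       pm_params = list(), temp_params = list(),
                       truth = sim_truth(), dx_secondary_prob = 0.10) {
  stopifnot(n_days >= 60L, n_locations >= 1L, n_children >= n_locations,
            inherits(truth, "sim_truth"))
  pm_def <- list(baseline_log_mean = 1.05, winter_amp = 0.45,
                 ar_phi = 0.75, ar_sd = 0.28, spatial_sd = 0.25,
                 local_sd = 0.20, spike_rate = 2, spike_mag = 1.5,
                 spike_decay = 0.25, spike_loc_sd = 0.25)
  tm_def <- list(annual_mean = 7.5, amplitude = 11.5, noise_sd = 4,
                 ar_phi = 0.7, spatial_sd = 0.5)
  unknown <- c(setdiff(names(pm_params), names(pm_def)),
               setdiff(names(temp_params), names(tm_def)))
  if (length(unknown))
    stop("unknown simulation parameter(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  pm_def[names(pm_params)] <- pm_params
  tm_def[names(temp_params)] <- temp_params
  bad <- names(pm_def)[!vapply(pm_def, function(v)
    is.numeric(v) && is.finite(v), logical(1))]
  if (length(bad))
    stop("invalid pm parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (pm_def$ar_phi < 0 || pm_def$ar_phi >= 1 ||
      tm_def$ar_phi < 0 || tm_def$ar_phi >= 1)
    stop("ar_phi must lie in [0, 1)", call. = FALSE)
  structure(list(n_locations = as.integer(n_locations),
                 n_days = as.integer(n_days),
                 start_date = as.Date(start_date),
                 n_children = as.integer(n_children),
                 seed = as.integer(seed),
                 pm_params = pm_def, temp_params = tm_def, truth = truth,
                 dx_secondary_prob = dx_secondary_prob),
            class = "sim_config")
}

.new_exposure_store <- function(dates, locations, pm25, tmax) {
  dimnames(pm25) <- list(NULL, locations)
  dimnames(tmax) <- list(NULL, locations)
  structure(list(dates = dates, locations = locations, pm25 = pm25,
                 tmax = tmax), class = "exposure_store")
}

# stationary AR(1) path, marginal sd `sd`
.ar1 <- function(n, phi, sd) {
  if (sd == 0 || n == 0L) return(numeric(n))
  e <- stats::rnorm(n, 0, sd * sqrt(1 - phi^2))
  e[1] <- stats::rnorm(1, 0, sd)
  stats::filter(e, phi, method = "recursive")
}

#' Simulate daily exposure series
#'
#' Log-scale PM2.5 per location: baseline + winter seasonal sinusoid +
#' shared regional AR(1) + location offset + local daily noise + summer
#' wildfire-smoke episodes (Poisson-counted per summer, exponential rise
#' and decay, location-varying intensity). Temperature: annual sinusoid +
#' shared AR(1) noise + small location offsets. Reproducible under the
#' config seed.
#'
#' @param config a [sim_config()].
#' @param seed overrides the config seed stream if given.
#' @return an [exposure_store()].
#' @export
simulate_exposure <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  p <- config$pm_params; tp <- config$temp_params
  nd <- config$n_days; nl <- config$n_locations
  dates <- config$start_date + 0:(nd - 1L)
  doy <- as.POSIXlt(dates)$yday
  locs <- sprintf("L%03d", seq_len(nl))

  winter <- p$winter_amp * cos(2 * pi * (doy - 15) / 365.25)
  regional <- as.numeric(.ar1(nd, p$ar_phi, p$ar_sd))
  offsets <- stats::rnorm(nl, 0, p$spatial_sd)
  local <- matrix(stats::rnorm(nd * nl, 0, p$local_sd), nd, nl)

  # summer wildfire episodes, shared timing with location-varying intensity
  spike <- matrix(0, nd, nl)
  mon <- as.POSIXlt(dates)$mon + 1L
  yrs <- unique(as.POSIXlt(dates)$year[mon %in% 7:9])
  for (y in yrs) {
    cand <- which(as.POSIXlt(dates)$year == y & mon %in% 7:9)
    if (!length(cand)) next
    n_ep <- stats::rpois(1, p$spike_rate)
    if (n_ep == 0) next
    starts <- sample(cand, n_ep, replace = TRUE)
    for (t0 in starts) {
      mag <- p$spike_mag * stats::runif(1, 0.6, 1)
      prof <- mag * exp(-p$spike_decay * abs(seq_len(nd) - t0))
      prof[prof < 0.01] <- 0
      mult <- exp(stats::rnorm(nl, 0, p$spike_loc_sd))
      # overlapping plumes merge rather than stack
      spike <- pmax(spike, outer(prof, mult))
    }
  }

  log_pm <- p$baseline_log_mean + winter + regional +
    matrix(offsets, nd, nl, byrow = TRUE) + local + spike
  pm <- exp(log_pm)

  t_seas <- tp$annual_mean + tp$amplitude * cos(2 * pi * (doy - 201) / 365.25)
  t_noise <- as.numeric(.ar1(nd, tp$ar_phi, tp$noise_sd))
  t_off <- stats::rnorm(nl, 0, tp$spatial_sd)
  tmax <- matrix(t_seas + t_noise, nd, nl) +
    matrix(t_off, nd, nl, byrow = TRUE)

  .new_exposure_store(dates, locs, pm, tmax)
}

.ADMISSION_TYPES <- c("clinic", "inpatient", "emergency", "observation",
                      "outreach clinic", "preadmission outpatient clinic",
                      "professional services", "provider clinic",
                      "telemedicine clinic")
.OTHER_DX <- c("J39.8", "J98.8", "J98.9", "R06.02")

# per-(day, location) linear predictor of the event hazard, excluding alpha;
# rows 1..14 are NA (lag burn-in)
.sim_linear_predictor <- function(truth, store) {
  pm <- store$pm25; tm <- store$tmax
  nd <- nrow(pm)
  bsum <- matrix(0, nd, ncol(pm))
  wsum <- bsum
  for (k in 0:14) {
    shifted <- rbind(matrix(NA_real_, k, ncol(pm)),
                     pm[seq_len(nd - k), , drop = FALSE])
    bsum <- bsum + truth$lag_coeffs[k + 1] * shifted
    wsum <- wsum + truth$interaction_weights[k + 1] * shifted
  }
  seas <- as.character(season_of(store$dates))
  bsum + truth$temp_main * tm + truth$temp_interaction * tm * wsum +
    truth$season_interactions[seas] * wsum + truth$season_main[seas]
}

#' Simulate health records from an exposure store
#'
#' Draws Bernoulli events per child-day under the [sim_truth()] hazard
#' (children at one location share the hazard, so draws are pooled into one
#' binomial count per location-day), then emits each event as a health
#' record with ICD-10-CM codes drawn from the matching case-definition set.
#' The intercept is calibrated so the mean event probability over the
#' usable days equals \code{truth$baseline_daily_rate}, making the expected
#' total event count \code{rate * n_children * (n_days - 14)}. Events start
#' on day 15, after the 14-day lag burn-in.
#'
#' @param config a [sim_config()].
#' @param store exposure from [simulate_exposure()].
#' @param seed overrides the config event seed stream (\code{seed + 1}).
#' @param calibrate if \code{TRUE} (default) the intercept is solved so the
#'   mean event probability equals \code{truth$baseline_daily_rate}; if
#'   \code{FALSE} the intercept is \code{qlogis(baseline_daily_rate)}
#'   directly, so a larger positive effect raises the realized event count.
#' @return data.frame of health records (see [read_health_records()]),
#'   with the realized intercept in attribute \code{"alpha"}.
#' @export
simulate_events <- function(config, store, seed = config$seed + 1L,
                            calibrate = TRUE) {
  stopifnot(inherits(config, "sim_config"),
            inherits(store, "exposure_store"))
  set.seed(seed)
  truth <- config$truth
  lp <- .sim_linear_predictor(truth, store)
  usable <- which(!is.na(lp[, 1]))
  lp <- lp[usable, , drop = FALSE]
  rate <- truth$baseline_daily_rate
  alpha <- if (calibrate) {
    f <- function(a) mean(stats::plogis(a + lp)) - rate
    stats::uniroot(f, stats::qlogis(rate) + c(-30, 30), tol = 1e-10)$root
  } else stats::qlogis(rate)
  prob <- stats::plogis(alpha + lp)

  nl <- config$n_locations
  nchild <- rep(config$n_children %/% nl, nl)
  extra <- config$n_children %% nl
  if (extra > 0) nchild[seq_len(extra)] <- nchild[seq_len(extra)] + 1L
  counts <- matrix(stats::rbinom(length(prob),
                                 size = rep(nchild, each = nrow(prob)),
                                 prob = prob),
                   nrow(prob), nl)
  ix <- which(counts > 0, arr.ind = TRUE)
  n_ev <- counts[ix]
  day_i <- rep(usable[ix[, 1]], n_ev)
  loc_i <- rep(ix[, 2], n_ev)
  n <- length(day_i)
  if (n == 0L)
    return(structure(data.frame(record_id = character(0)), alpha = alpha))

  defs <- respiratory_code_sets()
  cats <- sample(names(truth$category_mix), n, replace = TRUE,
                 prob = truth$category_mix)
  draw_code <- function(cat_vec) {
    out <- character(length(cat_vec))
    for (cc in unique(cat_vec)) {
      pool <- if (cc == "other") .OTHER_DX else defs[[cc]]
      sel <- cat_vec == cc
      out[sel] <- sample(pool, sum(sel), replace = TRUE)
    }
    out
  }
  dx1 <- draw_code(cats)
  dx2 <- rep("", n)
  has2 <- stats::runif(n) < config$dx_secondary_prob
  if (any(has2)) {
    cross <- has2 & stats::runif(n) < 0.5
    same <- has2 & !cross
    if (any(same)) dx2[same] <- draw_code(cats[same])
    if (any(cross)) {
      alt <- vapply(cats[cross], function(cc)
        sample(setdiff(c("asthma", "LRTI", "URTI"), cc), 1), character(1))
      dx2[cross] <- draw_code(alt)
    }
  }
  rec <- data.frame(
    record_id = sprintf("R%06d", seq_len(n)),
    person_id = sprintf("%s-C%05d", store$locations[loc_i],
                        ceiling(stats::runif(n) * nchild[loc_i])),
    location_id = store$locations[loc_i],
    visit_date = store$dates[day_i],
    admission_type = sample(.ADMISSION_TYPES, n, replace = TRUE),
    age_years = sample(0:17, n, replace = TRUE),
    dx1 = dx1, dx2 = dx2,
    stringsAsFactors = FALSE
  )
  structure(rec, alpha = alpha)
}

#' Simulate a complete synthetic study
#'
#' @param config a [sim_config()].
#' @return object of class \code{"sim_study"}: list with \code{records},
#'   \code{exposure} (an [exposure_store()]), \code{truth} and
#'   \code{config}.
#' @examples
#' study <- simulate_study(sim_config(n_locations = 3, n_days = 90,
#'                                    n_children = 3000, seed = 7))
#' nrow(study$records)
#' @export
simulate_study <- function(config) {
  exposure <- simulate_exposure(config)
  records <- simulate_events(config, exposure)
  structure(list(records = records, exposure = exposure,
                 truth = config$truth, config = config),
            class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf("sim_study: %d records over %d days at %d locations (seed %d)\n",
              nrow(x$records), x$config$n_days, x$config$n_locations,
              x$config$seed))
  invisible(x)
}

#' Convert an exposure store to the long table format
#'
#' @param store an [exposure_store()].
#' @return data.frame \code{location_id, date, pm25, tmax} (coverage rows
#'   only).
#' @export
exposure_long <- function(store) {
  nd <- length(store$dates); nl <- length(store$locations)
  out <- data.frame(
    location_id = rep(store$locations, each = nd),
    date = rep(store$dates, nl),
    pm25 = as.vector(store$pm25),
    tmax = as.vector(store$tmax))
  out[!is.na(out$pm25), , drop = FALSE]
}

#' Write a synthetic study to disk
#'
#' Emits \code{records.csv}, \code{exposure.csv} and \code{truth.json}
#' (the CSV dialects match what [read_health_records()] and
#' [read_exposure()] consume).
#'
#' @param study a [simulate_study()] result.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_sim_study <- function(study, dir) {
  stopifnot(inherits(study, "sim_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(study$records, file.path(dir, "records.csv"),
                   row.names = FALSE)
  utils::write.csv(exposure_long(study$exposure),
                   file.path(dir, "exposure.csv"), row.names = FALSE)
  jsonlite::write_json(unclass(study$truth), file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
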