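#' Paired address-level vs unit-aggregated exposure simulation
#'
#' Simulates one synthetic study on a landscape built to probe spatial
#' exposure-aggregation error in a sparsely populated region: coarse units
#' (Zip-code style) each contain one populated cell, where all children
#' live, plus several unpopulated remote cells. All cells share the
#' regional signal (seasonal wood-smoke winter cycle, AR(1) weather,
#' summer smoke episodes), but the populated cells track it tightly --
#' exposure surfaces are anchored by monitors in population centres --
#' while remote cells carry substantially larger cell-level fluctuation.
#' The unit mean therefore contains day-to-day variation the resident
#' never experiences: classical-type proxy error, the mechanism expected
#' to attenuate health-effect estimates when exposure is assessed at
#' coarse spatial units instead of the residential address.
#'
#' Events are generated from the populated-cell exposure under a same-day
#' effect \code{beta0}; the same matched sets are then fitted twice, once
#' with address-level exposure and once with the unit-aggregated store
#' (unweighted daily mean over all member cells, via
#' [aggregate_exposure()]).
#'
#' @param seed integer seed for this pair.
#' @param n_units number of coarse units.
#' @param cells_per_unit cells per unit (1 populated + the rest remote).
#' @param n_days,n_children passed to [sim_config()].
#' @param beta0 true same-day log odds ratio per ug/m3.
#' @param populated_sd,remote_sd log-scale daily cell-level noise SD for
#'   populated and remote cells.
#' @return named numeric \code{c(addr, agg)}: fitted same-day log odds
#'   ratios under address-level and aggregated exposure.
#' @seealso [simulate_study()] for the main generator.
#' @export
simulate_attenuation_pair <- function(seed, n_units = 10L,
                                      cells_per_unit = 5L, n_days = 400L,
                                      n_children = 5000L, beta0 = 0.08,
                                      populated_sd = 0.05,
                                      remote_sd = 0.55) {
  truth <- sim_truth(lag_coeffs = c(beta0, rep(0, 14)),
                     temp_interaction = 0,
                     category_mix = c(asthma = 0, LRTI = 0, URTI = 1,
                                      other = 0))
  cfg <- sim_config(n_locations = n_units, n_days = n_days,
                    n_children = n_children, seed = seed, truth = truth)
  set.seed(seed)
  p <- cfg$pm_params
  nd <- cfg$n_days
  n_cells <- n_units * cells_per_unit
  dates <- cfg$start_date + 0:(nd - 1L)
  doy <- as.POSIXlt(dates)$yday
  winter <- p$winter_amp * cos(2 * pi * (doy - 15) / 365.25)
  regional <- as.numeric(.ar1(nd, p$ar_phi, p$ar_sd))
  offsets <- stats::rnorm(n_cells, 0, p$spatial_sd)
  populated <- rep(c(TRUE, rep(FALSE, cells_per_unit - 1L)), n_units)
  cell_sd <- ifelse(populated, populated_sd, remote_sd)
  local <- matrix(stats::rnorm(nd * n_cells), nd, n_cells) *
    matrix(cell_sd, nd, n_cells, byrow = TRUE)
  log_pm <- p$baseline_log_mean + winter + regional +
    matrix(offsets, nd, n_cells, byrow = TRUE) + local
  tp <- cfg$temp_params
  t_seas <- tp$annual_mean + tp$amplitude * cos(2 * pi * (doy - 201) / 365.25)
  tmax <- matrix(t_seas + as.numeric(.ar1(nd, tp$ar_phi, tp$noise_sd)),
                 nd, n_cells)
  cells <- sprintf("U%02d-G%d", rep(seq_len(n_units), each = cells_per_unit),
                   rep(seq_len(cells_per_unit), n_units))
  store_all <- .new_exposure_store(dates, cells, exp(log_pm), tmax)
  unit_map <- data.frame(location_id = cells,
                         unit_id = sprintf("U%02d",
                                           rep(seq_len(n_units),
                                               each = cells_per_unit)))

  # children live only in the populated cells
  keep <- which(populated)
  store_pop <- .new_exposure_store(dates, cells[keep],
                                   store_all$pm25[, keep, drop = FALSE],
                                   store_all$tmax[, keep, drop = FALSE])
  records <- simulate_events(cfg, store_pop)
  events <- build_case_events(records)
  events <- events[events$category == "URTI", , drop = FALSE]
  ms <- build_matched_sets(events)
  spec <- model_spec("URTI", "single", lag_windows = list(c(0L, 0L)))
  f_addr <- fit_dlm(ms, store_pop, spec)$models[[1]]$fit
  store_agg <- aggregate_exposure(store_all, unit_map)
  ms_agg <- ms
  ms_agg$location_id <- relabel_locations(ms$location_id, unit_map)
  f_agg <- fit_dlm(ms_agg, store_agg, spec)$models[[1]]$fit
  c(addr = coef(f_addr)[["pm"]], agg = coef(f_agg)[["pm"]])
}
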