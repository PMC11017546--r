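#' Daily location-level exposure store
#'
#' Holds daily PM2.5 (ug/m3) and daily maximum temperature (degrees C) series
#' for a set of locations on a common calendar grid. Within each location's
#' declared coverage the series must be complete (contiguous daily dates, no
#' missing values) and PM2.5 non-negative; coverage may differ between
#' locations, in which case days outside a location's coverage are held as
#' \code{NA} and any attempt to extract them is an explicit error.
#'
#' @param data data.frame in long format with columns \code{location_id},
#'   \code{date} (Date or ISO-8601 string), \code{pm25}, \code{tmax}.
#' @return an object of class \code{"exposure_store"}: list with
#'   \code{dates} (Date vector, the common grid), \code{locations}
#'   (character), and numeric matrices \code{pm25}, \code{tmax} of dimension
#'   days x locations.
#' @examples
#' df <- data.frame(location_id = "a",
#'                  date = as.Date("2018-01-01") + 0:9,
#'                  pm25 = 1:10, tmax = 0)
#' st <- exposure_store(df)
#' extract_exposure(st, "a", as.Date("2018-01-05"))
#' @export
exposure_store <- function(data) {
  need <- c("location_id", "date", "pm25", "tmax")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("exposure table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  data$date <- as.Date(data$date)
  if (anyNA(data$date)) stop("unparseable exposure dates", call. = FALSE)
  if (anyNA(data$pm25) || anyNA(data$tmax))
    stop("missing pm25/tmax inside declared coverage", call. = FALSE)
  if (any(data$pm25 < 0)) stop("negative pm25 values", call. = FALSE)
  locs <- sort(unique(as.character(data$location_id)))
  dates <- seq(min(data$date), max(data$date), by = "day")
  nd <- length(dates)
  pm <- matrix(NA_real_, nd, length(locs), dimnames = list(NULL, locs))
  tm <- pm
  li <- match(as.character(data$location_id), locs)
  di <- as.integer(data$date - dates[1]) + 1L
  if (anyDuplicated(cbind(li, di)))
    stop("duplicated (location, date) rows in exposure table", call. = FALSE)
  pm[cbind(di, li)] <- data$pm25
  tm[cbind(di, li)] <- data$tmax
  # contiguity: within each column, non-NA entries must form one run
  for (j in seq_along(locs)) {
    ok <- unname(which(!is.na(pm[, j])))
    if (!length(ok))
      stop("location ", locs[j], " has no exposure data", call. = FALSE)
    if (length(ok) > 1L && any(diff(ok) != 1L))
      stop("gap in daily coverage for location ", locs[j], call. = FALSE)
  }
  structure(list(dates = dates, locations = locs, pm25 = pm, tmax = tm),
            class = "exposure_store")
}

#' @export
print.exposure_store <- function(x, ...) {
  cat(sprintf(
    "exposure_store: %d location(s), %d days (%s .. %s)\n",
    length(x$locations), length(x$dates),
    format(x$dates[1]), format(x$dates[length(x$dates)])))
  pm <- x$pm25[!is.na(x$pm25)]
  cat(sprintf("  pm25 range %.2f .. %.2f ug/m3; tmax range %.1f .. %.1f C\n",
              min(pm), max(pm), min(x$tmax, na.rm = TRUE),
              max(x$tmax, na.rm = TRUE)))
  invisible(x)
}

#' Read an exposure series table
#'
#' Long-format CSV with header \code{location_id, date, pm25, tmax}.
#'
#' @param path file path.
#' @return an [exposure_store()].
#' @export
read_exposure <- function(path) {
  exposure_store(utils::read.csv(path, stringsAsFactors = FALSE))
}

# vectorized (location, date) -> flat matrix index; NA when off-grid
.store_flat_index <- function(store, location, date) {
  li <- match(as.character(location), store$locations)
  di <- as.integer(as.Date(date) - store$dates[1]) + 1L
  di[di < 1L | di > length(store$dates)] <- NA_integer_
  ifelse(is.na(li) | is.na(di), NA_integer_,
         (li - 1L) * length(store$dates) + di)
}

.missing_exposure_stop <- function(location, date, what = "exposure") {
  stop(sprintf("missing %s for location %s on %s", what,
               as.character(location)[1], format(as.Date(date)[1])),
       call. = FALSE)
}

#' Extract exposure at a location and date
#'
#' Pure lookup of the stored (pm25, tmax) pair; requesting a (location, date)
#' outside coverage is an error naming the offending pair.
#'
#' @param store an [exposure_store()].
#' @param location location id(s).
#' @param date date(s), recycled against \code{location}.
#' @return data.frame with columns \code{pm25}, \code{tmax}.
#' @export
extract_exposure <- function(store, location, date) {
  n <- max(length(location), length(date))
  location <- rep_len(as.character(location), n)
  date <- rep_len(as.Date(date), n)
  ix <- .store_flat_index(store, location, date)
  pm <- store$pm25[ix]
  if (anyNA(ix) || anyNA(pm)) {
    bad <- which(is.na(ix) | is.na(pm))[1]
    .missing_exposure_stop(location[bad], date[bad])
  }
  data.frame(pm25 = pm, tmax = store$tmax[ix])
}

# shared lag lookup: pm25 at (anchor - k) for vectors of anchors; returns
# numeric with NA where out of coverage
.lagged_pm <- function(store, location, anchor, k) {
  store$pm25[.store_flat_index(store, location, as.Date(anchor) - k)]
}

.check_lag_range <- function(k, lo = 0L, hi = 14L, what = "lag") {
  if (any(k != floor(k)) || any(k < lo) || any(k > hi))
    stop(sprintf("%s must be an integer in [%d, %d]", what, lo, hi),
         call. = FALSE)
}

#' Single-day lagged PM2.5
#'
#' The PM2.5 value \code{k} days before the anchor day (\code{k = 0} is the
#' anchor day itself). Lags run from 0 to 14 days.
#'
#' @param store an [exposure_store()].
#' @param location location id(s).
#' @param anchor anchor date(s) (the case or referent day).
#' @param k lag in days, integer in 0..14.
#' @return numeric vector of PM2.5 values (ug/m3).
#' @export
lag_single <- function(store, location, anchor, k) {
  .check_lag_range(k)
  n <- max(length(location), length(anchor))
  location <- rep_len(as.character(location), n)
  anchor <- rep_len(as.Date(anchor), n)
  v <- .lagged_pm(store, location, anchor, k)
  if (anyNA(v)) {
    bad <- which(is.na(v))[1]
    .missing_exposure_stop(location[bad], anchor[bad] - k)
  }
  v
}

#' Cumulative lagged PM2.5 over days 0..k
#'
#' Sum of daily PM2.5 over the window from the anchor day back \code{k} days,
#' both endpoints included (\code{k + 1} terms). The value is the raw sum
#' (ug/m3 x days), so a coefficient per unit of this covariate times
#' \code{k + 1} is the log-odds change for a simultaneous 1 ug/m3 increase on
#' every day of the window.
#'
#' @inheritParams lag_single
#' @param k upper lag of the window 0..k, integer in 0..14.
#' @return numeric vector of summed PM2.5.
#' @export
lag_cumulative <- function(store, location, anchor, k) {
  .check_lag_range(k)
  n <- max(length(location), length(anchor))
  location <- rep_len(as.character(location), n)
  anchor <- rep_len(as.Date(anchor), n)
  v <- rep(0, n)
  for (j in 0:k) v <- v + .lagged_pm(store, location, anchor, j)
  if (anyNA(v)) {
    bad <- which(is.na(v))[1]
    .missing_exposure_stop(location[bad], anchor[bad], "exposure in lag window")
  }
  v
}

#' Weekly-average lagged PM2.5
#'
#' Mean PM2.5 over the 7-day window \code{lag_lo .. lag_lo + 6} days before
#' the anchor. The nine windows 0-6, 1-7, ..., 8-14 correspond to
#' \code{lag_lo = 0..8}.
#'
#' @inheritParams lag_single
#' @param lag_lo lower lag of the 7-day window, integer in 0..8.
#' @return numeric vector of mean PM2.5 (ug/m3).
#' @export
lag_weekly_avg <- function(store, location, anchor, lag_lo) {
  .check_lag_range(lag_lo, 0L, 8L, "lag_lo")
  n <- max(length(location), length(anchor))
  location <- rep_len(as.character(location), n)
  anchor <- rep_len(as.Date(anchor), n)
  v <- rep(0, n)
  for (j in lag_lo:(lag_lo + 6L)) v <- v + .lagged_pm(store, location, anchor, j)
  if (anyNA(v)) {
    bad <- which(is.na(v))[1]
    .missing_exposure_stop(location[bad], anchor[bad], "exposure in lag window")
  }
  v / 7
}

#' Meteorological season of a date
#'
#' Month-block seasons: December-February winter, March-May spring,
#' June-August summer, September-November fall.
#'
#' @param date Date vector (or coercible).
#' @return factor with levels \code{winter, spring, summer, fall}.
#' @examples
#' season_of(as.Date(c("2018-12-15", "2019-03-01", "2018-08-31")))
#' @export
season_of <- function(date) {
  m <- as.POSIXlt(as.Date(date))$mon + 1L
  s <- c("winter", "winter", "spring", "spring", "spring", "summer",
         "summer", "summer", "fall", "fall", "fall", "winter")[m]
  factor(s, levels = c("winter", "spring", "summer", "fall"))
}

#' Aggregate an exposure store to coarse spatial units
#'
#' Replaces each coarse unit's series by the unweighted daily mean of its
#' member locations' PM2.5 and tmax (the "Zip-code style" exposure variant).
#' Days on which any member location lacks coverage are outside the unit's
#' coverage.
#'
#' @param store an [exposure_store()].
#' @param unit_map data.frame with columns \code{location_id},
#'   \code{unit_id}; every location in \code{store} must be mapped.
#' @return an [exposure_store()] keyed by unit id. Re-label record or event
#'   location ids with the same map before extracting from it.
#' @export
aggregate_exposure <- function(store, unit_map) {
  stopifnot(inherits(store, "exposure_store"))
  need <- c("location_id", "unit_id")
  if (length(setdiff(need, names(unit_map))))
    stop("unit_map needs columns location_id, unit_id", call. = FALSE)
  um <- unit_map
  um$location_id <- as.character(um$location_id)
  um$unit_id <- as.character(um$unit_id)
  unmapped <- setdiff(store$locations, um$location_id)
  if (length(unmapped))
    stop("unmapped location(s): ", paste(unmapped, collapse = ", "),
         call. = FALSE)
  units <- sort(unique(um$unit_id[um$location_id %in% store$locations]))
  grp <- um$unit_id[match(store$locations, um$location_id)]
  agg <- function(M) {
    out <- sapply(units, function(u) rowMeans(M[, grp == u, drop = FALSE]))
    if (is.null(dim(out))) out <- matrix(out, ncol = length(units))
    colnames(out) <- units
    out
  }
  structure(list(dates = store$dates, locations = units,
                 pm25 = agg(store$pm25), tmax = agg(store$tmax)),
            class = "exposure_store")
}

#' Map fine location ids to coarse unit ids
#'
#' @param location character vector of location ids.
#' @param unit_map data.frame with \code{location_id}, \code{unit_id}.
#' @return character vector of unit ids.
#' @export
relabel_locations <- function(location, unit_map) {
  ix <- match(as.character(location), as.character(unit_map$location_id))
  if (anyNA(ix))
    stop("unmapped location(s): ",
         paste(unique(location[is.na(ix)]), collapse = ", "), call. = FALSE)
  as.character(unit_map$unit_id)[ix]
}
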