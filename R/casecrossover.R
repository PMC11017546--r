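#' Time-stratified referent days for a case day
#'
#' All calendar dates sharing the case day's weekday within the same calendar
#' month and year, excluding the case day itself. Referents fall both before
#' and after the case day; the calendar forces either 3 or 4 of them (4 when
#' the month contains five occurrences of that weekday).
#'
#' @param case_date a single Date (or coercible).
#' @return sorted Date vector of 3 or 4 referent days.
#' @examples
#' select_referents(as.Date("2018-01-17"))  # five Wednesdays that month
#' select_referents(as.Date("2019-02-14"))  # three referents
#' @export
select_referents <- function(case_date) {
  case_date <- as.Date(case_date)
  stopifnot(length(case_date) == 1L, !is.na(case_date))
  cand <- case_date + 7L * (-4:4)
  same_month <- format(cand, "%Y-%m") == format(case_date, "%Y-%m")
  sort(cand[same_month & cand != case_date])
}

#' Build time-stratified case-crossover matched sets
#'
#' One stratum per case event (person-event level: a person with several
#' qualifying events contributes several independent strata). Each stratum
#' pairs the case day with its same-weekday/month/year referents at the same
#' residence location. Because referents never leave the calendar month,
#' season is constant within every stratum.
#'
#' @param events data.frame of case events with columns \code{record_id,
#'   person_id, location_id, event_date, category} (see
#'   [build_case_events()]).
#' @return long-format data.frame (the case-crossover dataset) with columns
#'   \code{stratum_id, person_id, location_id, category, date, is_case};
#'   4 or 5 rows per stratum, exactly one with \code{is_case == 1}.
#'   \code{stratum_id} is deterministic: \code{"<record_id>:<category>"}.
#' @export
build_matched_sets <- function(events) {
  if (nrow(events) == 0L)
    return(data.frame(stratum_id = character(0), person_id = character(0),
                      location_id = character(0),
                      category = factor(character(0),
                                        levels = c("asthma", "LRTI", "URTI")),
                      date = as.Date(character(0)), is_case = integer(0)))
  ed <- as.Date(events$event_date)
  # candidate days: event day plus same-weekday offsets, filtered to month
  off <- 7L * (-4:4)
  n <- length(ed)
  cand <- rep(ed, each = length(off)) + rep(off, times = n)
  ev_ix <- rep(seq_len(n), each = length(off))
  keep <- format(cand, "%Y-%m") == format(ed[ev_ix], "%Y-%m")
  cand <- cand[keep]
  ev_ix <- ev_ix[keep]
  o <- order(ev_ix, cand)
  cand <- cand[o]
  ev_ix <- ev_ix[o]
  out <- data.frame(
    stratum_id  = paste(events$record_id[ev_ix], events$category[ev_ix],
                        sep = ":"),
    person_id   = events$person_id[ev_ix],
    location_id = as.character(events$location_id[ev_ix]),
    category    = events$category[ev_ix],
    date        = cand,
    is_case     = as.integer(cand == ed[ev_ix]),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Write a case-crossover dataset to CSV
#'
#' @param matched_sets output of [build_matched_sets()].
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
write_matched_sets <- function(matched_sets, path) {
  utils::write.csv(matched_sets, path, row.names = FALSE)
  invisible(path)
}
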