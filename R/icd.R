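#' Normalize ICD-10-CM code strings
#'
#' Trims surrounding whitespace, removes internal whitespace and upper-cases
#' the code. The dotted form is preserved as given (codes are matched exactly
#' as printed in the shipped case-definition lists; no dot insertion or
#' removal is attempted).
#'
#' @param x character vector of raw ICD-10-CM codes.
#' @return character vector of normalized codes.
#' @examples
#' normalize_icd(c("j45.901 ", "J00"))
#' @export
normalize_icd <- function(x) {
  if (!is.character(x)) x <- as.character(x)
  out <- toupper(gsub("[[:space:]]+", "", x))
  if (any(!is.na(out) & out == ""))
    stop("empty or blank ICD code string", call. = FALSE)
  out
}

#' Respiratory outcome case definitions (ICD-10-CM)
#'
#' Loads the three shipped diagnosis-code sets defining the asthma, lower
#' respiratory tract infection (LRTI) and upper respiratory tract infection
#' (URTI) outcome categories. A handful of codes are deliberately members of
#' more than one category (e.g. the acute-bronchiolitis codes J21.0, J21.8,
#' J21.9 and influenza code J09.X2 appear in both the URTI and LRTI lists);
#' records carrying them are counted once in each category.
#'
#' @param prefix_match logical; if \code{TRUE}, three-character stems in the
#'   lists (e.g. \code{"H65"}, \code{"J04"}) also match any longer code that
#'   begins with the stem. The default is exact matching of each printed
#'   string.
#' @return an object of class \code{"dx_code_sets"}: a named list with
#'   character-vector elements \code{asthma}, \code{LRTI} and \code{URTI}
#'   (deduplicated, sorted) and attribute \code{prefix_match}.
#' @seealso [classify_record()], [build_case_events()]
#' @export
respiratory_code_sets <- function(prefix_match = FALSE) {
  path <- system.file("extdata", "icd10_respiratory_codes.csv",
                      package = "crosslag", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  defs <- lapply(split(tab$code, tab$category),
                 function(v) sort(unique(normalize_icd(v))))
  defs <- defs[c("asthma", "LRTI", "URTI")]
  structure(defs, class = "dx_code_sets", prefix_match = isTRUE(prefix_match))
}

#' @export
print.dx_code_sets <- function(x, ...) {
  cat("ICD-10-CM case-definition sets",
      if (isTRUE(attr(x, "prefix_match"))) "(prefix matching)" else "(exact matching)",
      "\n")
  for (nm in names(x)) cat(sprintf("  %-6s %3d codes\n", nm, length(x[[nm]])))
  invisible(x)
}

# membership of normalized codes in one category set, honoring prefix flag
.codes_in_set <- function(codes, set, prefix_match = FALSE) {
  hit <- codes %in% set
  if (prefix_match && !all(hit)) {
    stems <- set[!grepl("\\.", set)]
    if (length(stems)) {
      rest <- codes[!hit]
      pm <- vapply(rest, function(cd)
        any(startsWith(cd, stems)), logical(1), USE.NAMES = FALSE)
      hit[!hit] <- pm
    }
  }
  any(hit)
}

#' Classify one health record into outcome categories
#'
#' A record belongs to a category when at least one of its diagnosis codes
#' (primary or any secondary field) is a member of that category's
#' case-definition set. Multiple hits within one category still count the
#' record once; a record whose codes span several categories is returned in
#' each of them.
#'
#' @param codes character vector of the record's diagnosis codes (primary
#'   first, then secondary; \code{NA} and empty entries are ignored).
#' @param defs a \code{"dx_code_sets"} object from [respiratory_code_sets()].
#' @return character vector of matched categories, a subset of
#'   \code{c("asthma", "LRTI", "URTI")} in that fixed order (possibly empty).
#' @examples
#' defs <- respiratory_code_sets()
#' classify_record(c("J45.901", "J20.9", "J06.9"), defs)
#' @export
classify_record <- function(codes, defs) {
  stopifnot(inherits(defs, "dx_code_sets"))
  codes <- codes[!is.na(codes) & gsub("[[:space:]]", "", codes) != ""]
  if (!length(codes)) return(character(0))
  codes <- unique(normalize_icd(codes))
  pm <- isTRUE(attr(defs, "prefix_match"))
  hits <- vapply(defs, function(set) .codes_in_set(codes, set, pm), logical(1))
  names(defs)[hits]
}

#' Read health records from delimited text
#'
#' Expects a CSV with header columns \code{record_id, person_id, location_id,
#' visit_date, admission_type, age_years, dx1, ..., dx9} (\code{dx1} is the
#' primary diagnosis; up to eight secondary fields may be present or empty).
#' Dates are ISO-8601. Admission type is carried through but never filtered
#' on.
#'
#' @param path file path.
#' @param study_window optional length-2 Date (or coercible) vector; visit
#'   dates outside it raise an error.
#' @return data.frame of validated records with \code{visit_date} as Date.
#' @export
read_health_records <- function(path, study_window = NULL) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  validate_health_records(rec, study_window)
}

#' Validate a health-record table
#'
#' @param rec data.frame in the layout of [read_health_records()].
#' @inheritParams read_health_records
#' @return the validated data.frame (dates as Date, ages as integer).
#' @export
validate_health_records <- function(rec, study_window = NULL) {
  need <- c("record_id", "person_id", "location_id", "visit_date",
            "admission_type", "age_years", "dx1")
  miss <- setdiff(need, names(rec))
  if (length(miss))
    stop("health-record table is missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  rec$visit_date <- as.Date(rec$visit_date)
  if (anyNA(rec$visit_date))
    stop("unparseable visit_date values", call. = FALSE)
  rec$age_years <- as.integer(rec$age_years)
  bad <- is.na(rec$age_years) | rec$age_years < 0L | rec$age_years > 17L
  if (any(bad))
    stop(sum(bad), " record(s) with age_years outside 0-17", call. = FALSE)
  if (anyDuplicated(rec$record_id))
    stop("duplicated record_id values", call. = FALSE)
  if (!is.null(study_window)) {
    study_window <- as.Date(study_window)
    out <- rec$visit_date < study_window[1] | rec$visit_date > study_window[2]
    if (any(out))
      stop(sum(out), " record(s) with visit_date outside the study window",
           call. = FALSE)
  }
  rec
}

#' Build case events from classified health records
#'
#' Emits one case event per (record, matched category). Output order is
#' deterministic: record order, then category order asthma < LRTI < URTI.
#'
#' @param records data.frame of health records (see [read_health_records()]).
#' @param defs code sets from [respiratory_code_sets()].
#' @return data.frame with columns \code{record_id, person_id, location_id,
#'   event_date, category} (category a factor with the three levels). Zero
#'   rows when nothing matches.
#' @export
build_case_events <- function(records, defs = respiratory_code_sets()) {
  cats <- c("asthma", "LRTI", "URTI")
  dxcols <- grep("^dx[1-9]$", names(records), value = TRUE)
  if (!length(dxcols)) stop("no dx1..dx9 columns present", call. = FALSE)
  matched <- lapply(seq_len(nrow(records)), function(i) {
    classify_record(unlist(records[i, dxcols], use.names = FALSE), defs)
  })
  n_per <- lengths(matched)
  idx <- rep.int(seq_len(nrow(records)), n_per)
  ev <- data.frame(
    record_id   = records$record_id[idx],
    person_id   = records$person_id[idx],
    location_id = records$location_id[idx],
    event_date  = records$visit_date[idx],
    category    = factor(unlist(matched), levels = cats),
    stringsAsFactors = FALSE
  )
  rownames(ev) <- NULL
  ev
}
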