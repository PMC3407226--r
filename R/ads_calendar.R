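#' Asian dust storm event calendars
#'
#' An `ads_calendar` holds the dust storm events of a study window as an
#' ordered set of inclusive date ranges.  Consecutive storm days form a
#' single event; events are separated by at least one non-storm day.
#'
#' @name ads_calendar
#' @keywords internal
NULL

new_ads_calendar <- function(events, study_start, study_end) {
  stopifnot(inherits(study_start, "Date"), inherits(study_end, "Date"))
  if (study_end < study_start) stop("study window is empty (study_end < study_start)")
  events <- events[order(events$start), , drop = FALSE]
  rownames(events) <- NULL
  structure(list(events = events, study_start = study_start, study_end = study_end),
            class = "ads_calendar")
}

#' @export
print.ads_calendar <- function(x, ...) {
  cat("ADS event calendar:", nrow(x$events), "events,",
      count_storm_days(x), "storm days\n")
  cat("Study window:", format(x$study_start), "to", format(x$study_end),
      sprintf("(%d days)\n", study_window_length(x)))
  invisible(x)
}

#' Number of days in the study window (inclusive)
#'
#' @param cal an `ads_calendar`
#' @return integer day count
#' @export
study_window_length <- function(cal) {
  as.integer(cal$study_end - cal$study_start) + 1L
}

# Expand one "M/D" or "M/D-M/D" entry of a given year into a Date vector.
# The en dash used in print is accepted as an alias of the ASCII hyphen.
parse_entry <- function(entry, year, row_label) {
  entry <- gsub("–", "-", trimws(entry))
  parts <- strsplit(entry, "-", fixed = TRUE)[[1]]
  if (!length(parts) %in% c(1L, 2L))
    stop(sprintf("malformed date entry '%s' in row '%s'", entry, row_label))
  md <- function(x) {
    x <- trimws(x)
    if (!grepl("^[0-9]{1,2}/[0-9]{1,2}$", x))
      stop(sprintf("malformed date entry '%s' in row '%s'", entry, row_label))
    d <- tryCatch(as.Date(sprintf("%d-%s-%s", year,
                                  sub("/.*", "", x), sub(".*/", "", x))),
                  error = function(e) as.Date(NA))
    if (is.na(d))
      stop(sprintf("invalid calendar date '%s' in row '%s'", x, row_label))
    d
  }
  from <- md(parts[1])
  to <- if (length(parts) == 2L) md(parts[2]) else from
  if (to < from)
    stop(sprintf("descending date range '%s' in row '%s'", entry, row_label))
  seq(from, to, by = "day")
}

# Collapse a sorted, duplicate-free Date vector into maximal consecutive runs.
runs_to_events <- function(days) {
  if (length(days) == 0L)
    return(data.frame(start = as.Date(character()), end = as.Date(character())))
  brk <- c(TRUE, diff(as.integer(days)) > 1L)
  grp <- cumsum(brk)
  data.frame(start = days[!duplicated(grp)],
             end = days[!duplicated(grp, fromLast = TRUE)])
}

#' Parse a dust storm date list into an event calendar
#'
#' Reads a date-list file with one row per year, `year,entries`, where
#' `entries` is a comma-separated list of day entries `M/D` or `M/D-M/D`
#' (inclusive ranges; an en dash is accepted for the hyphen).  All listed
#' days are expanded and maximal runs of consecutive calendar days are
#' merged into single events, including runs crossing month boundaries or
#' spanning adjacent list entries.
#'
#' @param path path to the date-list file (CSV, header `year,entries`)
#' @param study_start,study_end `Date` (or coercible) bounds of the study
#'   window; every listed day must fall inside it.
#' @return an `ads_calendar`
#' @examples
#' f <- system.file("extdata", "ads_days_taipei_1997_2007.csv", package = "adstar")
#' cal <- parse_calendar(f, "1997-01-01", "2007-12-31")
#' cal
#' @export
parse_calendar <- function(path, study_start, study_end) {
  study_start <- as.Date(study_start)
  study_end <- as.Date(study_end)
  tab <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  if (!all(c("year", "entries") %in% names(tab)))
    stop("date-list file must have columns 'year' and 'entries'")
  days <- as.Date(character())
  for (i in seq_len(nrow(tab))) {
    yr <- suppressWarnings(as.integer(tab$year[i]))
    if (is.na(yr)) stop(sprintf("malformed year '%s' in row %d", tab$year[i], i))
    entries <- strsplit(tab$entries[i], ",", fixed = TRUE)[[1]]
    entries <- trimws(entries)
    entries <- entries[nzchar(entries)]
    for (e in entries) {
      d <- parse_entry(e, yr, sprintf("%d (row %d)", yr, i))
      if (any(d %in% days))
        stop(sprintf("overlapping entries: '%s' in year %d repeats a listed day", e, yr))
      days <- c(days, d)
    }
  }
  if (length(days) && (min(days) < study_start || max(days) > study_end))
    stop("listed storm days fall outside the study window")
  new_ads_calendar(runs_to_events(sort(days)), study_start, study_end)
}

#' Build a calendar directly from event date ranges
#'
#' @param start,end vectors of event start/end dates (inclusive)
#' @param study_start,study_end study window bounds
#' @return an `ads_calendar`
#' @export
ads_calendar_from_events <- function(start, end, study_start, study_end) {
  start <- as.Date(start); end <- as.Date(end)
  stopifnot(length(start) == length(end))
  if (any(end < start)) stop("event end before start")
  days <- unlist(lapply(seq_along(start),
                        function(i) as.integer(seq(start[i], end[i], by = "day"))))
  if (anyDuplicated(days)) stop("overlapping events")
  study_start <- as.Date(study_start); study_end <- as.Date(study_end)
  days <- sort(as.Date(days, origin = "1970-01-01"))
  if (length(days) && (min(days) < study_start || max(days) > study_end))
    stop("event days fall outside the study window")
  new_ads_calendar(runs_to_events(days), study_start, study_end)
}

#' Expand a calendar's events into the set of storm days
#'
#' @param cal an `ads_calendar`
#' @return sorted `Date` vector of all storm days
#' @export
storm_days <- function(cal) {
  ev <- cal$events
  if (nrow(ev) == 0L) return(as.Date(character()))
  sort(as.Date(unlist(lapply(seq_len(nrow(ev)),
    function(i) as.integer(seq(ev$start[i], ev$end[i], by = "day")))),
    origin = "1970-01-01"))
}

#' Count dust storm days
#'
#' Size of the union of all event day sets of the calendar.
#'
#' @param cal an `ads_calendar`
#' @return nonnegative integer
#' @export
count_storm_days <- function(cal) {
  length(storm_days(cal))
}

#' Storm days as a percentage of the study window
#'
#' @param cal an `ads_calendar`
#' @return `100 * storm-day count / window length` (percent)
#' @export
storm_day_fraction <- function(cal) {
  100 * count_storm_days(cal) / study_window_length(cal)
}

#' Assign every study day a dust-storm-lag-index class
#'
#' Days inside any event are `lag0`.  A day exactly K days (K in 1..7)
#' after the end of an event, and not itself a storm day, is `lagK`; when
#' several events qualify the most recent one (minimum K) wins.  All other
#' days are the reference class.
#'
#' @param cal an `ads_calendar`
#' @return a data frame (class `lag_assignment`) with columns `date` and
#'   `lag_class` (factor with levels `lag0`..`lag7`, `reference`), one row
#'   per study day.
#' @export
assign_lags <- function(cal) {
  dates <- seq(cal$study_start, cal$study_end, by = "day")
  cls <- rep("reference", length(dates))
  ends <- as.integer(cal$events$end)
  di <- as.integer(dates)
  if (length(ends)) {
    # minimum positive distance to any event end, per day
    minlag <- rep(NA_integer_, length(di))
    for (e in ends) {
      k <- di - e
      ok <- k >= 1L & k <= 7L
      minlag[ok] <- pmin(minlag[ok], k[ok], na.rm = TRUE)
    }
    cls[!is.na(minlag)] <- paste0("lag", minlag[!is.na(minlag)])
    cls[dates %in% storm_days(cal)] <- "lag0"
  }
  out <- data.frame(date = dates,
                    lag_class = factor(cls, levels = c(paste0("lag", 0:7), "reference")))
  class(out) <- c("lag_assignment", "data.frame")
  out
}

#' Write a lag assignment as CSV
#'
#' @param lag a `lag_assignment`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_lag_assignment <- function(lag, path) {
  utils::write.csv(data.frame(date = format(lag$date),
                              lag_class = as.character(lag$lag_class)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
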