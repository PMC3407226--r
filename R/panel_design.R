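#' District-day analysis panels
#'
#' A `panel_dataset` joins daily visit counts per district and age group
#' with the citywide temperature series, district populations (offset
#' source), the district adjacency graph and the dust-storm lag
#' assignment of the study window.
#'
#' @name panel_dataset
#' @keywords internal
NULL

AGE_GROUPS <- c("preschool", "school", "all")
LAG_LEVELS <- c(paste0("lag", 0:7), "reference")

#' Assemble a validated district-day panel
#'
#' Joins the count table, temperature series, populations and adjacency
#' into one validated structure.  Every (date, district, age group)
#' combination over the lag assignment's study window must be present in
#' `counts`.  Missing temperature days are filled by linear interpolation
#' (and reported via a message).
#'
#' @param counts data frame `date, district, age_group, visits`
#' @param temps data frame `date, temp_c` (single citywide series)
#' @param populations data frame `district, age_group, population`
#' @param adjacency data frame edge list `district_a, district_b`
#'   (undirected, one edge per line)
#' @param lag a `lag_assignment` from [assign_lags()]
#' @return a `panel_dataset`: list with `records` (counts joined with
#'   temperature and lag class), `populations`, `graph` (igraph), `lag`
#' @export
build_panel <- function(counts, temps, populations, adjacency, lag) {
  counts$date <- as.Date(counts$date)
  temps$date <- as.Date(temps$date)
  districts <- sort(unique(counts$district))
  groups <- unique(counts$age_group)
  if (!all(groups %in% AGE_GROUPS))
    stop("age_group must be one of: ", paste(AGE_GROUPS, collapse = ", "))
  dates <- lag$date

  # completeness of the count table over the window
  for (g in groups) {
    sub <- counts[counts$age_group == g, ]
    key <- paste(sub$date, sub$district)
    need <- as.vector(outer(as.character(dates), districts, paste))
    miss <- setdiff(need, key)
    if (length(miss))
      stop(sprintf("missing %d date x district combinations for age group '%s' (first: %s)",
                   length(miss), g, miss[1]))
    if (anyDuplicated(key))
      stop(sprintf("duplicated date x district rows for age group '%s'", g))
  }
  if (any(counts$visits < 0)) stop("negative visit counts")

  # populations must cover every district/group
  for (g in groups) {
    pd <- populations$district[populations$age_group == g]
    miss <- setdiff(districts, pd)
    if (length(miss))
      stop("populations missing district(s) for group '", g, "': ",
           paste(miss, collapse = ", "))
  }
  if (any(populations$population <= 0)) stop("populations must be positive")

  # adjacency graph: simple, undirected, covering all districts, connected
  # (a single district needs no edges and carries no spatial term)
  g_ <- if (length(districts) == 1L && nrow(adjacency) == 0L)
    igraph::set_vertex_attr(igraph::make_empty_graph(1, directed = FALSE),
                            "name", value = districts)
  else igraph::graph_from_data_frame(adjacency, directed = FALSE)
  miss <- setdiff(districts, igraph::V(g_)$name)
  if (length(miss))
    stop("adjacency omits district(s): ", paste(miss, collapse = ", "))
  g_ <- igraph::induced_subgraph(g_, districts)
  if (igraph::any_multiple(g_) || any(igraph::which_loop(g_)))
    stop("adjacency must be a simple graph (no duplicate edges or self-loops)")
  if (!igraph::is_connected(g_))
    stop("district adjacency graph is not connected")

  # temperature: one value per study day, linear interpolation for gaps
  tmp <- temps[match(dates, temps$date), "temp_c"]
  if (anyNA(tmp)) {
    n_gap <- sum(is.na(tmp))
    tmp <- stats::approx(as.numeric(temps$date), temps$temp_c,
                         xout = as.numeric(dates), rule = 2)$y
    message(sprintf("filled %d missing temperature day(s) by linear interpolation", n_gap))
  }
  temp_map <- data.frame(date = dates, temp_c = tmp)

  rec <- counts[order(counts$age_group, counts$district, counts$date), ]
  rec$temp_c <- temp_map$temp_c[match(rec$date, temp_map$date)]
  rec$lag_class <- lag$lag_class[match(rec$date, lag$date)]
  rownames(rec) <- NULL

  structure(list(records = rec,
                 populations = populations,
                 graph = g_,
                 districts = districts,
                 lag = lag),
            class = "panel_dataset")
}

#' @export
print.panel_dataset <- function(x, ...) {
  cat("District-day panel:", length(x$districts), "districts x",
      length(x$lag$date), "days;",
      "age groups:", paste(unique(x$records$age_group), collapse = ", "), "\n")
  invisible(x)
}

# Records of one age group, ordered district-major then date.
panel_group_records <- function(panel, age_group) {
  age_group <- match.arg(age_group, AGE_GROUPS)
  rec <- panel$records[panel$records$age_group == age_group, ]
  if (nrow(rec) == 0L) stop("no records for age group '", age_group, "'")
  rec[order(rec$district, rec$date), ]
}

#' Build the fixed-effect design blocks of the model
#'
#' Produces the day-of-week indicator block (Monday..Saturday, Sunday the
#' reference), the dust-storm-lag-index indicator block (`lag0`..`lag7`,
#' other days the reference), the log-population offset, the day index
#' since the start of the study window, and the temperature vector, for
#' one age group of the panel.
#'
#' @param panel a `panel_dataset`
#' @param age_group `"preschool"`, `"school"` or `"all"`
#' @return list with matrices `dow` (n x 6) and `dsli` (n x 8; zero
#'   columns dropped only when the calendar holds no events), vectors
#'   `offset`, `time_index`, `temperature`, `y` (counts), and the record
#'   table used (`records`).
#' @export
build_design <- function(panel, age_group = "all") {
  rec <- panel_group_records(panel, age_group)
  n <- nrow(rec)

  wd <- as.POSIXlt(rec$date)$wday          # 0 = Sunday .. 6 = Saturday
  dow_names <- c("Monday", "Tuesday", "Wednesday", "Thursday", "Friday", "Saturday")
  dow <- matrix(0, n, 6, dimnames = list(NULL, dow_names))
  for (k in 1:6) dow[wd == k, k] <- 1

  has_storms <- any(rec$lag_class != "reference")
  if (has_storms) {
    dsli <- matrix(0, n, 8, dimnames = list(NULL, paste0("lag", 0:7)))
    for (k in 0:7) dsli[rec$lag_class == paste0("lag", k), k + 1] <- 1
  } else {
    dsli <- matrix(0, n, 0)
  }

  pops <- panel$populations[panel$populations$age_group == age_group, ]
  offset <- log(pops$population[match(rec$district, pops$district)])

  list(dow = dow,
       dsli = dsli,
       offset = offset,
       time_index = as.numeric(rec$date - panel$lag$date[1]),
       temperature = rec$temp_c,
       y = rec$visits,
       records = rec)
}

#' Lag-stratified descriptive summaries
#'
#' Mean and sample (n-1) standard deviation of daily visit counts per
#' district within each dust-storm lag class, the layout of the published
#' district-by-lag descriptive table.
#'
#' @param panel a `panel_dataset`
#' @param age_group age group to summarise
#' @return data frame `district, lag_class, n_days, mean, sd`; empty
#'   strata have `NA` mean/sd.
#' @export
lag_stratified_means <- function(panel, age_group = "all") {
  rec <- panel_group_records(panel, age_group)
  lag_classes <- paste0("lag", 0:7)
  out <- expand.grid(district = panel$districts, lag_class = lag_classes,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$n_days <- 0L
  out$mean <- NA_real_
  out$sd <- NA_real_
  for (i in seq_len(nrow(out))) {
    v <- rec$visits[rec$district == out$district[i] &
                    rec$lag_class == out$lag_class[i]]
    out$n_days[i] <- length(v)
    if (length(v) >= 1L) out$mean[i] <- mean(v)
    if (length(v) >= 2L) out$sd[i] <- stats::sd(v)
  }
  out
}

#' Write lag-stratified descriptives in the district-by-lag layout
#'
#' @param panel a `panel_dataset`
#' @param path output CSV path
#' @param age_group age group to summarise
#' @return `path`, invisibly
#' @export
write_descriptives <- function(panel, path, age_group = "all") {
  tab <- lag_stratified_means(panel, age_group)
  wide <- data.frame(district = panel$districts, stringsAsFactors = FALSE)
  for (k in 0:7) {
    sub <- tab[tab$lag_class == paste0("lag", k), ]
    cell <- ifelse(is.na(sub$mean), "",
                   sprintf("%.2f (%.2f)", sub$mean, sub$sd))
    wide[[paste0("lag", k)]] <- cell[match(wide$district, sub$district)]
  }
  utils::write.csv(wide, path, row.names = FALSE)
  invisible(path)
}
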