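# Small scenario and panel builders shared across test files.

small_scenario <- function(seed = 1, n_districts = 3, years = 2,
                           age_groups = "all", ...) {
  generate_scenario(scenario_config(
    n_districts = n_districts,
    study_start = "2001-01-01",
    study_end = sprintf("%d-12-31", 2000 + years),
    calendar = "random", events_per_year = 8,
    age_groups = age_groups, seed = seed, ...))
}

# A fully hand-specified 2-district panel over a given number of days.
# visits defaults to a deterministic ramp so expectations are easy.
manual_panel <- function(n_days = 14, districts = c("A", "B"),
                         start = "2004-03-01", visits = NULL,
                         event_start = NULL, event_end = NULL) {
  start <- as.Date(start)
  dates <- seq(start, by = "day", length.out = n_days)
  cal <- if (is.null(event_start))
    ads_calendar_from_events(character(), character(), start, dates[n_days])
  else
    ads_calendar_from_events(event_start, event_end, start, dates[n_days])
  lag <- assign_lags(cal)
  grid <- expand.grid(date = dates, district = districts,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$age_group <- "all"
  grid$visits <- if (is.null(visits)) seq_len(nrow(grid)) else visits
  temps <- data.frame(date = dates,
                      temp_c = 20 + 5 * sin(seq_len(n_days) / 3))
  pops <- data.frame(district = districts, age_group = "all",
                     population = 1000 * seq_along(districts))
  adjacency <- data.frame(district_a = districts[-length(districts)],
                          district_b = districts[-1])
  list(panel = build_panel(grid, temps, pops, adjacency, lag),
       counts = grid, temps = temps, pops = pops,
       adjacency = adjacency, lag = lag, cal = cal)
}

table1_fixture <- function() {
  system.file("extdata", "ads_days_taipei_1997_2007.csv",
              package = "adstar", mustWork = TRUE)
}
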