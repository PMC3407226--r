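test_that("the shipped storm-day list reproduces the published calendar facts", {
  cal <- parse_calendar(table1_fixture(), "1997-01-01", "2007-12-31")
  expect_equal(nrow(cal$events), 76)
  expect_equal(count_storm_days(cal), 172)
  expect_equal(study_window_length(cal), 4017)
  expect_equal(round(storm_day_fraction(cal), 2), 4.28)
  in_2004 <- format(storm_days(cal), "%Y") == "2004"
  expect_equal(sum(in_2004), 30)
  in_2005 <- cal$events[format(cal$events$start, "%Y") == "2005", ]
  expect_equal(sum(as.integer(in_2005$end - in_2005$start) + 1L), 6)
})

test_that("range entries expand and consecutive days merge into single events", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("year,entries", '2004,"1/1-1/4, 1/13-1/14"'), f)
  cal <- parse_calendar(f, "2004-01-01", "2004-12-31")
  expect_equal(nrow(cal$events), 2)
  expect_equal(as.integer(cal$events$end - cal$events$start) + 1L, c(4L, 2L))

  # a range across a month boundary is one event; adjacent single-day
  # entries that touch are merged, separated ones are not
  writeLines(c("year,entries", '2002,"3/31-4/1, 4/15, 4/17-4/19, 4/20"'), f)
  cal <- parse_calendar(f, "2002-01-01", "2002-12-31")
  expect_equal(nrow(cal$events), 3)
  expect_equal(format(cal$events$start), c("2002-03-31", "2002-04-15", "2002-04-17"))
  expect_equal(format(cal$events$end), c("2002-04-01", "2002-04-15", "2002-04-20"))

  # en dash accepted as dash alias
  writeLines(c("year,entries", '2003,"2/18–2/19"'), f)
  cal <- parse_calendar(f, "2003-01-01", "2003-12-31")
  expect_equal(count_storm_days(cal), 2)
})

test_that("an empty date list yields a calendar with no events", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines("year,entries", f)
  cal <- parse_calendar(f, "2000-01-01", "2000-12-31")
  expect_equal(nrow(cal$events), 0)
  expect_equal(count_storm_days(cal), 0)
  expect_equal(storm_day_fraction(cal), 0)
  expect_true(all(assign_lags(cal)$lag_class == "reference"))
})

test_that("malformed or inconsistent date lists are rejected with context", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("year,entries", '2000,"3/6, not-a-date"'), f)
  expect_error(parse_calendar(f, "2000-01-01", "2000-12-31"), "malformed.*2000")
  writeLines(c("year,entries", '2000,"2/30"'), f)
  expect_error(parse_calendar(f, "2000-01-01", "2000-12-31"), "invalid calendar date")
  writeLines(c("year,entries", '2000,"3/8-3/6"'), f)
  expect_error(parse_calendar(f, "2000-01-01", "2000-12-31"), "descending")
  writeLines(c("year,entries", '2000,"3/6-3/8, 3/7"'), f)
  expect_error(parse_calendar(f, "2000-01-01", "2000-12-31"), "overlapping")
  writeLines(c("year,entries", '2000,"3/6"'), f)
  expect_error(parse_calendar(f, "2000-04-01", "2000-12-31"), "outside the study window")
})

test_that("storm day fraction is the direct ratio on a toy window", {
  cal <- ads_calendar_from_events("2000-02-10", "2000-02-10",
                                  "2000-01-01", "2000-04-09")  # 100 days
  expect_equal(study_window_length(cal), 100)
  expect_equal(storm_day_fraction(cal), 1.0)
})

test_that("lag assignment follows the event-membership-then-minimum-lag rule", {
  cal <- parse_calendar(table1_fixture(), "1997-01-01", "2007-12-31")
  la <- assign_lags(cal)
  expect_equal(as.character(la$lag_class[la$date %in% as.Date(c("1997-03-07", "1997-03-08"))]),
               c("lag0", "lag0"))
  # 1997-01-01 is a single-day event; 1997-01-09 is 8 days past its end
  # and over 7 days from anything else
  expect_equal(as.character(la$lag_class[la$date == as.Date("1997-01-09")]), "reference")

  # two events ending day 10 and day 14 of a toy month; day 16 takes the
  # minimum lag (2, from the most recent event), not 6
  cal2 <- ads_calendar_from_events(c("2000-06-08", "2000-06-13"),
                                   c("2000-06-10", "2000-06-14"),
                                   "2000-06-01", "2000-06-30")
  la2 <- assign_lags(cal2)
  expect_equal(as.character(la2$lag_class[la2$date == as.Date("2000-06-16")]), "lag2")
  # an event day within 7 days of the previous event's end stays lag0
  expect_equal(as.character(la2$lag_class[la2$date == as.Date("2000-06-13")]), "lag0")
})

test_that("lag classes partition the window and lag0 matches the storm-day count", {
  cal <- parse_calendar(table1_fixture(), "1997-01-01", "2007-12-31")
  la <- assign_lags(cal)
  expect_equal(sum(table(la$lag_class)), study_window_length(cal))
  expect_equal(sum(la$lag_class == "lag0"), count_storm_days(cal))
})

test_that("shifting every event by one day shifts interior lag assignments", {
  cal <- ads_calendar_from_events(c("2000-06-05", "2000-06-18"),
                                  c("2000-06-06", "2000-06-19"),
                                  "2000-06-01", "2000-07-15")
  cal_shift <- ads_calendar_from_events(c("2000-06-06", "2000-06-19"),
                                        c("2000-06-07", "2000-06-20"),
                                        "2000-06-01", "2000-07-15")
  la <- assign_lags(cal)
  las <- assign_lags(cal_shift)
  # every day except the boundary-affected first/last must shift by +1
  idx <- which(la$date >= as.Date("2000-06-05") & la$date <= as.Date("2000-07-14"))
  expect_equal(as.character(las$lag_class[idx + 1]), as.character(la$lag_class[idx]))
})

test_that("lag assignment matches the brute-force classifier on random toy calendars", {
  set.seed(42)
  for (case in 1:10) {
    n_ev <- sample(1:5, 1)
    starts <- sort(sample(0:80, n_ev)) + as.Date("2000-03-01")
    ends <- starts + sample(0:2, n_ev, replace = TRUE)
    # greedily drop events that collide with or touch the previous kept one
    keep <- logical(n_ev); last_end <- as.Date("1900-01-01")
    for (i in seq_len(n_ev)) {
      if (starts[i] > last_end + 1) { keep[i] <- TRUE; last_end <- ends[i] }
    }
    cal <- ads_calendar_from_events(starts[keep], ends[keep],
                                    "2000-03-01", "2000-06-30")
    la <- assign_lags(cal)
    expect_equal(as.character(la$lag_class), brute_force_lags(cal))
  }
})

test_that("lag assignments round-trip through the CSV writer", {
  cal <- ads_calendar_from_events("2000-06-05", "2000-06-06",
                                  "2000-06-01", "2000-06-30")
  f <- withr::local_tempfile(fileext = ".csv")
  write_lag_assignment(assign_lags(cal), f)
  back <- read.csv(f)
  expect_equal(nrow(back), 30)
  expect_equal(back$lag_class[back$date == "2000-06-08"], "lag2")
})
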