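test_that("independence window keeps the first of a close pair and both of a far pair", {
  expect_equal(nrow(filter_independent_events(records_at(c(0, 30)))), 1)
  expect_equal(nrow(filter_independent_events(records_at(c(0, 61)))), 2)
  # the window is measured from the last *retained* record: 0 kept, 50
  # dropped, 100 kept (100 min after the retained one)
  ev <- filter_independent_events(records_at(c(0, 50, 100)))
  expect_equal(as.numeric(difftime(ev$datetime[2], ev$datetime[1],
                                   units = "mins")), 100)
})

test_that("multi-individual photos collapse to one event, two species split", {
  rec <- records_at(0, count = 3)
  expect_equal(nrow(filter_independent_events(rec)), 1)
  two <- rbind(records_at(0, species = "sp1"), records_at(0, species = "sp2"))
  expect_equal(nrow(filter_independent_events(two)), 2)
  # conspecific pairs at different stations are both independent
  st <- rbind(records_at(0, station = "A1"), records_at(10, station = "A2"))
  expect_equal(nrow(filter_independent_events(st)), 2)
})

test_that("filtering is idempotent and bounded by the raw count", {
  set.seed(41)
  for (rep in 1:5) {
    rec <- random_records(200)
    once <- filter_independent_events(rec)
    twice <- filter_independent_events(once)
    expect_equal(twice$datetime, once$datetime)
    expect_lte(nrow(once), nrow(rec))
  }
  rec <- random_records(100)
  expect_equal(nrow(filter_independent_events(rec, window_min = 0)), 100)
})

test_that("unparseable timestamps are rejected loudly, not silently", {
  rec <- records_at(c(0, 120))
  rec$datetime <- c(format(rec$datetime[1]), "not-a-date")
  expect_warning(ev <- filter_independent_events(rec), "unparseable")
  expect_equal(nrow(ev), 1)
})

test_that("station retention reports the kept fraction to one decimal", {
  rec <- records_at(0, station = "A1")
  r <- retain_informative_stations(rec, deployed = c("A1", "A2"))
  expect_equal(r$retention_pct, 50.0)
  expect_equal(r$n_kept, 1)
  expect_error(retain_informative_stations(rec[0, ], deployed = "A1"),
               "no station")
  many <- data.frame(station = sprintf("s%03d", 1:315))
  r2 <- retain_informative_stations(many, deployed = sprintf("s%03d", 1:428))
  expect_equal(r2$retention_pct, 73.6)
})

test_that("diel classification follows the nocturnal-fraction bands", {
  # half-open boundaries: exactly 10% nocturnal is still strongly diurnal,
  # exactly 90% is strongly nocturnal
  expect_equal(diel_summary_from_counts(100, 10)$category, "strongly_diurnal")
  expect_equal(diel_summary_from_counts(100, 11)$category, "mostly_diurnal")
  expect_equal(diel_summary_from_counts(100, 30)$category, "cathemeral")
  expect_equal(diel_summary_from_counts(100, 50)$category, "cathemeral")
  expect_equal(diel_summary_from_counts(100, 70)$category, "mostly_nocturnal")
  expect_equal(diel_summary_from_counts(100, 90)$category,
               "strongly_nocturnal")
})

test_that("diel counts partition events; sunrise is diurnal, sunset nocturnal", {
  s <- classify_diel(hours_to_radians(c(6, 17.99, 18, 5.99, 12, 23)))
  expect_equal(s$n_diurnal + s$n_nocturnal, s$n_total)
  expect_equal(s$n_diurnal, 3)  # 6:00, 17:59, 12:00
  expect_equal(s$n_nocturnal, 3)  # 18:00, 5:59, 23:00
  # twilight straddles the boundary on both sides
  expect_equal(s$n_twilight, 4)  # 6:00, 17:59, 18:00, 5:59
  expect_error(classify_diel(numeric(0)), "undefined")
  set.seed(5)
  tt <- runif(500, 0, 2 * pi)
  s2 <- classify_diel(tt)
  expect_equal(s2$pct_diurnal + s2$pct_nocturnal, 100, tolerance = 0.02)
})

test_that("detection CSV round-trips through read_detections", {
  rec <- records_at(c(0, 90))
  p <- withr::local_tempfile(fileext = ".csv")
  write_detections(rec, p)
  back <- read_detections(p)
  expect_equal(back$datetime, rec$datetime)
  # a table without the required columns is refused
  bad <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(x = 1), bad, row.names = FALSE)
  expect_error(read_detections(bad), "lacks column")
})

test_that("per-site solar tables shift the day/night boundary per record", {
  ev <- filter_independent_events(rbind(
    records_at(0, station = "N1", site = "north",
               start = "2018-06-01 05:30:00"),
    records_at(0, station = "S1", site = "south",
               start = "2018-06-01 05:30:00")))
  p <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(site = "north", date = "2018-06-01",
                       sunrise = "05:00", sunset = "19:00"),
            p, row.names = FALSE)
  solar <- read_solar_schedule(p)
  out <- diel_summary_events(ev, solar)
  # 05:30 is daytime under the northern schedule, night under the default
  expect_equal(out$n_nocturnal, 1)  # only the unmatched southern record
  flat <- diel_summary_events(ev)
  expect_equal(flat$n_nocturnal, 2)
  expect_error(read_solar_schedule(p, twilight_halfwidth = 1) -> s2, NA)
  bad <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(site = "x", date = "2018-01-01",
                       sunrise = "19:00", sunset = "05:00"),
            bad, row.names = FALSE)
  expect_error(read_solar_schedule(bad), "precede")
})
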