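test_that("survey CSV parsing maps fields and normalizes habitats", {
  f <- toy_visits_csv()
  rec <- read_survey_csv(f)
  expect_equal(nrow(rec), 4)
  expect_equal(rec$location[1], "KP")
  expect_equal(as.character(rec$habitat[1]), "woods")
  expect_equal(rec$larvae[1], 14L)
  expect_equal(rec$nymphs[1], 3L)
  expect_equal(rec$adults[1], 2L)

  # case-insensitive synonyms
  f2 <- toy_visits_csv(c("location,habitat,year,month,larvae,nymphs,adults",
                         "KP,Wooded,2012,6,1,0,0",
                         "KP,GRASSY,2012,7,0,1,0"))
  rec2 <- read_survey_csv(f2)
  expect_equal(as.character(rec2$habitat), c("woods", "grass"))
})

test_that("survey CSV parse errors name the offending row", {
  f <- toy_visits_csv(c("location,habitat,year,month,larvae,nymphs,adults",
                        "KP,forest,2012,6,1,0,0"))
  expect_error(read_survey_csv(f), "forest.*row 2")
  f <- toy_visits_csv(c("location,habitat,year,month,larvae,nymphs,adults",
                        "KP,woods,2012,6,1,0,0",
                        "KP,woods,2012,6,-3,0,0"))
  expect_error(read_survey_csv(f), "larvae.*row 3")
  f <- toy_visits_csv(c("location,habitat,year,month,larvae,nymphs,adults",
                        "KP,woods,2012,13,1,0,0"))
  expect_error(read_survey_csv(f), "month.*row 2")
})

test_that("header-only file yields an empty record set", {
  f <- toy_visits_csv("location,habitat,year,month,larvae,nymphs,adults")
  expect_equal(nrow(read_survey_csv(f)), 0)
})

test_that("monthly aggregation sums visits within cells and conserves totals", {
  rec <- read_survey_csv(toy_visits_csv())
  panel <- aggregate_monthly(rec)
  kpw <- panel[panel$location == "KP" & panel$habitat == "woods", ]
  expect_equal(kpw$larvae, 17L)   # 14 + 3
  expect_equal(kpw$n_visits, 2L)
  # habitats never merge
  expect_equal(nrow(panel[panel$location == "KP", ]), 2)
  # single visit is the identity
  one <- aggregate_monthly(rec[4, ])
  expect_equal(one$larvae, rec$larvae[4])
  expect_equal(one$n_visits, 1L)
  # count conservation per stage
  for (st in tick_stages())
    expect_equal(sum(panel[[st]]), sum(rec[[st]]))
})

test_that("well-sampled filter keeps locations by total visits", {
  panel <- data.frame(
    location = rep(c("A", "B"), c(3, 2)),
    habitat = factor("edge", levels = tick_habitats()),
    year = 2010, month = c(1:3, 1:2),
    n_visits = c(40L, 40L, 40L, 25L, 25L),
    larvae = 0L, nymphs = 0L, adults = 0L,
    lag_log_larvae = NA_real_, lag_log_nymphs = NA_real_)
  expect_message(out <- filter_well_sampled(panel, 104), "B")
  expect_setequal(unique(out$location), "A")
  expect_equal(nrow(filter_well_sampled(panel, 1)), nrow(panel))
  expect_warning(empty <- suppressMessages(filter_well_sampled(panel, 1000)),
                 "empty")
  expect_equal(nrow(empty), 0)
})

test_that("lag attachment follows calendar adjacency including Dec->Jan", {
  p <- attach_lags(toy_panel())
  expect_equal(p$lag_log_larvae, c(NA, log(3), log(1)))
  expect_equal(p$lag_log_nymphs, c(NA, log(2), log(1)))
  # gap: months 5 and 7 only
  g <- toy_panel()[1:2, ]
  g$month <- c(5L, 7L); g$year <- 2010
  g <- attach_lags(g)
  expect_true(all(is.na(g$lag_log_larvae)))
  # idempotence
  expect_identical(attach_lags(p), p)
})

test_that("panel CSV round-trip preserves integers exactly and lags closely", {
  p <- attach_lags(toy_panel())
  f <- tempfile(fileext = ".csv")
  write_panel_csv(p, f)
  q <- read_panel_csv(f)
  for (col in c("year", "month", "n_visits", tick_stages()))
    expect_identical(as.integer(q[[col]]), as.integer(p[[col]]))
  expect_equal(q$lag_log_larvae, p$lag_log_larvae, tolerance = 1e-12)
  expect_equal(q$lag_log_nymphs, p$lag_log_nymphs, tolerance = 1e-12)
  expect_identical(is.na(q$lag_log_larvae), is.na(p$lag_log_larvae))
})

test_that("panel validation rejects duplicate cells", {
  p <- toy_panel()
  expect_error(validate_panel(rbind(p, p[1, ])), "duplicate")
  expect_silent(validate_panel(p))
})
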