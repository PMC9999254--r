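# Loading MIMIC-schema tables into an indexed cohort store.

write_fixture_tables <- function(dir) {
  dir.create(dir, showWarnings = FALSE)
  writeLines(c(
    "HADM_ID,SUBJECT_ID,ADMITTIME,DISCHTIME,DEATHTIME",
    "h1,p1,2130-01-01 08:00:00,2130-01-11 08:00:00,",
    "h2,p2,2130-02-01 10:00:00,2130-02-05 10:00:00,2130-02-05 10:00:00"),
    file.path(dir, "ADMISSIONS.csv"))
  writeLines(c(
    "SUBJECT_ID,DOB,DOD",
    "p1,2060-01-01,",
    "p2,1830-02-01,2130-02-05 10:00:00"),
    file.path(dir, "PATIENTS.csv"))
  writeLines(c(
    "HADM_ID,CHARTTIME,ITEMID,VALUE",
    "h1,2130-01-02 12:00:00,551,Part. Thickness",
    "h1,2130-01-01 09:00:00,220045,80",
    "h2,2130-02-02 09:00:00,551,Full Thickness",
    "orphan,2130-02-02 09:00:00,551,Full Thickness"),
    file.path(dir, "CHARTEVENTS.csv"))
  writeLines(c(
    "ROW_ID,HADM_ID,CHARTDATE,CHARTTIME,CATEGORY,TEXT",
    "1,h1,2130-01-01,2130-01-01 09:30:00,Nursing,patient stable overnight",
    "2,h1,2130-01-03,,Nursing,date-only daily note",
    "3,h2,2130-02-01,2130-02-01 11:00:00,Nursing,admitted from home",
    "4,h2,2130-02-03,2130-02-03 11:00:00,Nursing,wound care sacral pressure ulcer"),
    file.path(dir, "NOTEEVENTS.csv"))
  writeLines(c(
    "HADM_ID,ICD9_CODE,SEQ_NUM",
    "h1,4019,1", "h2,70703,1", "h2,25000,2"),
    file.path(dir, "DIAGNOSES_ICD.csv"))
  writeLines(c("HADM_ID,ICD9_CODE", "h2,8622"), file.path(dir, "PROCEDURES_ICD.csv"))
  list(admissions = file.path(dir, "ADMISSIONS.csv"),
       patients = file.path(dir, "PATIENTS.csv"),
       chartevents = file.path(dir, "CHARTEVENTS.csv"),
       noteevents = file.path(dir, "NOTEEVENTS.csv"),
       diagnoses_icd = file.path(dir, "DIAGNOSES_ICD.csv"),
       procedures_icd = file.path(dir, "PROCEDURES_ICD.csv"))
}

test_that("a small multi-table fixture loads with the expected counts and indexing", {
  paths <- write_fixture_tables(tempfile("fix"))
  store <- load_cohort(paths)
  expect_s3_class(store, "cohort_store")
  expect_equal(nrow(store$stays), 2)
  expect_equal(nrow(store$chart_events), 3)  # orphan dropped
  expect_equal(store$dropped[["chartevents"]], 1)
  expect_equal(nrow(store$notes), 4)
  expect_equal(nrow(store$diagnoses), 3)
  expect_equal(nrow(store$procedures), 1)
  # referential integrity: no orphans survive
  expect_true(all(store$chart_events$stay_id %in% store$stays$stay_id))
  expect_true(all(store$notes$stay_id %in% store$stays$stay_id))
  # per-stay event lists are time-sorted
  for (sid in store$stays$stay_id) {
    ts <- store$chart_events$ts[store$chart_events$stay_id == sid]
    expect_true(!is.unsorted(ts))
  }
  # death flag from DEATHTIME inside the stay
  expect_equal(store$stays$died_in_hospital, c(FALSE, TRUE))
  # date-only note flagged and placed at midnight
  expect_equal(store$notes$date_only[store$notes$note_id == "2"], TRUE)
  expect_equal(store$notes$ts[store$notes$note_id == "2"], ts_utc("2130-01-03 00:00:00"))
})

test_that("an empty chart-events file with a valid header yields zero chart events", {
  paths <- write_fixture_tables(tempfile("fix"))
  writeLines("HADM_ID,CHARTTIME,ITEMID,VALUE", paths$chartevents)
  store <- load_cohort(paths)
  expect_equal(nrow(store$chart_events), 0)
  expect_equal(nrow(store$stays), 2)
})

test_that("a missing required column raises a schema error naming table and column", {
  paths <- write_fixture_tables(tempfile("fix"))
  writeLines(c("HADM_ID,SUBJECT_ID,DISCHTIME", "h1,p1,2130-01-11 08:00:00"),
             paths$admissions)
  expect_error(load_cohort(paths), "admissions.*ADMITTIME")
})

test_that("discharge before admission loads but is excluded downstream", {
  paths <- write_fixture_tables(tempfile("fix"))
  writeLines(c("HADM_ID,SUBJECT_ID,ADMITTIME,DISCHTIME,DEATHTIME",
               "h1,p1,2130-01-11 08:00:00,2130-01-01 08:00:00,"),
             paths$admissions)
  store <- load_cohort(paths)
  expect_equal(nrow(store$stays), 1)
  lab <- label_cohort(store, builtin_definitions()$ehapi)
  expect_equal(lab$status, "excluded")
  expect_equal(lab$exclusion_reason, "bad_times")
})

test_that("round-trip write/load preserves per-table record counts", {
  paths <- write_fixture_tables(tempfile("fix"))
  store <- load_cohort(paths)
  out <- write_cohort(store, tempfile("rt"))
  store2 <- load_cohort(as.list(out))
  for (tb in c("stays", "chart_events", "notes", "diagnoses", "procedures")) {
    expect_equal(nrow(store2[[tb]]), nrow(store[[tb]]), info = tb)
  }
})

test_that("ages are computed in years and obfuscated ages clamp to the cap", {
  expect_equal(compute_age(ts_utc("2000-01-01"), ts_utc("2016-01-01")), 16.0)
  expect_equal(compute_age(ts_utc("1830-02-01"), ts_utc("2130-02-01")), 90)
  expect_equal(compute_age(ts_utc("1830-02-01"), ts_utc("2130-02-01"), cap = 91.4), 91.4)
  expect_true(is.na(compute_age(parse_ts(NA), ts_utc("2130-02-01"))))
  # fixture patient p2 born 300 years before admission gets the default cap
  paths <- write_fixture_tables(tempfile("fix"))
  store <- load_cohort(paths)
  expect_equal(store$stays$age_at_admission[store$stays$stay_id == "h2"], 90)
})

test_that("a stay with missing birth timestamp is excluded with reason missing_age", {
  stays <- basic_stay("s1")
  stays$age_at_admission <- NA_real_
  store <- mini_store(stays, notes = note_at("s1", 2, "patient stable"))
  lab <- label_cohort(store, builtin_definitions()$ehapi)
  expect_equal(lab$status, "excluded")
  expect_equal(lab$exclusion_reason, "missing_age")
})

test_that("timestamp parsing accepts datetimes and date-only strings", {
  x <- parse_ts(c("2130-01-02 03:04:05", "2130-01-02", NA, ""))
  expect_equal(as.numeric(x[1] - x[2], units = "hours"), 3 + 4 / 60 + 5 / 3600)
  expect_equal(attr(x, "date_only"), c(FALSE, TRUE, FALSE, FALSE))
  expect_true(all(is.na(x[3:4])))
})
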