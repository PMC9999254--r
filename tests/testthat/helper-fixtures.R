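# In-code fixture builders shared across test files.

ts_utc <- function(x) as.POSIXct(x, tz = "UTC")

# Build a cohort_store directly, bypassing CSV I/O. All children default to
# empty; stays need admit/discharge/age.
mini_store <- function(stays, chart = NULL, notes = NULL, dx = NULL, px = NULL,
                       patients = NULL) {
  empty_chart <- data.frame(stay_id = character(), ts = ts_utc(character()),
                            item_id = character(), value_text = character(),
                            stringsAsFactors = FALSE)
  empty_notes <- data.frame(note_id = character(), stay_id = character(),
                            ts = ts_utc(character()), date_only = logical(),
                            category = character(), text = character(),
                            stringsAsFactors = FALSE)
  empty_dx <- data.frame(stay_id = character(), code = character(),
                         seq = integer(), stringsAsFactors = FALSE)
  empty_px <- data.frame(stay_id = character(), code = character(),
                         stringsAsFactors = FALSE)
  empty_pat <- data.frame(patient_id = character(), birth_ts = ts_utc(character()),
                          death_ts = ts_utc(character()), stringsAsFactors = FALSE)
  structure(list(stays = stays, patients = patients %||% empty_pat,
                 chart_events = chart %||% empty_chart,
                 notes = notes %||% empty_notes,
                 diagnoses = dx %||% empty_dx, procedures = px %||% empty_px,
                 dropped = c(admissions = 0L)),
            class = "cohort_store")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One eligible stay admitted at a round timestamp, with helpers to place
# events at hours from admission.
ADMIT0 <- ts_utc("2130-01-01 08:00:00")

basic_stay <- function(stay_id = "s1", admit = ADMIT0, duration_h = 240,
                       age = 70, died = FALSE) {
  data.frame(stay_id = stay_id, patient_id = paste0("p_", stay_id),
             admit_ts = admit, discharge_ts = admit + duration_h * 3600,
             died_in_hospital = died, age_at_admission = age,
             stringsAsFactors = FALSE)
}

note_at <- function(stay_id, hours, text, note_id = NULL, admit = ADMIT0,
                    date_only = FALSE) {
  ts <- admit + hours * 3600
  if (date_only) ts <- trunc(ts, "days")
  data.frame(note_id = note_id %||% paste0("n", stay_id, "_", round(hours, 3)),
             stay_id = stay_id, ts = ts, date_only = date_only,
             category = "Nursing/other", text = text, stringsAsFactors = FALSE)
}

chart_at <- function(stay_id, hours, value, item_id = "551", admit = ADMIT0) {
  data.frame(stay_id = stay_id, ts = admit + hours * 3600, item_id = item_id,
             value_text = value, stringsAsFactors = FALSE)
}

# CareVue value strings per token, for chart_at fixtures.
cv_value <- function(token) {
  switch(token, S1 = "Red, Unbroken", S2 = "Part. Thickness",
         S3 = "Full Thickness", S4 = "Through Fascia",
         DTI = "Deep Tiss Injury", UNSTAGEABLE = "Unable to Stage")
}
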