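# EHR domain model: readers for MIMIC-III-schema CSV tables and an indexed
# per-stay cohort store. The store keeps one data frame per source table with
# canonical column names; all child tables are keyed by stay_id and sorted by
# timestamp within stay.

# Canonical column names per logical table, mapped from the MIMIC-III v1.4
# dialect. A schema_config can override any source column name so non-MIMIC
# exports can be ingested.
default_schema <- function() {
  list(
    admissions = c(stay_id = "HADM_ID", patient_id = "SUBJECT_ID",
                   admit_ts = "ADMITTIME", discharge_ts = "DISCHTIME",
                   death_ts = "DEATHTIME"),
    patients   = c(patient_id = "SUBJECT_ID", birth_ts = "DOB", death_ts = "DOD"),
    icustays   = c(stay_id = "HADM_ID", patient_id = "SUBJECT_ID"),
    chartevents = c(stay_id = "HADM_ID", ts = "CHARTTIME",
                    item_id = "ITEMID", value_text = "VALUE"),
    noteevents = c(note_id = "ROW_ID", stay_id = "HADM_ID", ts = "CHARTTIME",
                   date = "CHARTDATE", category = "CATEGORY", text = "TEXT"),
    diagnoses_icd = c(stay_id = "HADM_ID", code = "ICD9_CODE", seq = "SEQ_NUM"),
    procedures_icd = c(stay_id = "HADM_ID", code = "ICD9_CODE")
  )
}

read_source_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                  colClasses = "character")
}

# Rename source columns to canonical names; error on missing required columns.
apply_schema <- function(df, mapping, table, required) {
  out <- data.frame(row.names = seq_len(nrow(df)))
  for (canon in names(mapping)) {
    src <- mapping[[canon]]
    if (!src %in% names(df)) {
      if (canon %in% required) {
        stop(sprintf("table '%s': required column '%s' (mapped to '%s') is missing",
                     table, src, canon), call. = FALSE)
      }
      out[[canon]] <- rep(NA_character_, nrow(df))
    } else {
      out[[canon]] <- df[[src]]
    }
  }
  out
}

#' Load a cohort from MIMIC-III-schema CSV tables
#'
#' Reads the admission, patient, ICU-stay, chart-event, note, diagnosis-code
#' and procedure-code tables, normalizes column names, parses timestamps,
#' computes per-stay ages and death flags, drops records whose `stay_id` does
#' not resolve to an admission, and returns an indexed store with per-stay
#' event lists sorted by time.
#'
#' @param table_paths named list/character vector of file paths; recognized
#'   names: `admissions`, `patients`, `icustays`, `chartevents`, `noteevents`,
#'   `diagnoses_icd`, `procedures_icd`. `admissions` is required; missing
#'   optional tables yield empty components.
#' @param schema_config optional named list overriding entries of the default
#'   MIMIC-III column mapping (see [default_schema()]).
#' @param age_cap years to assign when a computed age exceeds `age_clamp`
#'   (MIMIC obfuscates ages of very old patients by shifting dates of birth).
#' @param age_clamp computed ages above this threshold are clamped to
#'   `age_cap`.
#' @return A `cohort_store`: list with data frames `stays`, `patients`,
#'   `chart_events`, `notes`, `diagnoses`, `procedures` plus a `dropped`
#'   count vector of records discarded per table (orphans and unparseable
#'   timestamps).
#' @export
load_cohort <- function(table_paths, schema_config = NULL,
                        age_cap = 90, age_clamp = 120) {
  schema <- default_schema()
  if (!is.null(schema_config)) {
    for (tb in names(schema_config)) {
      ov <- unlist(schema_config[[tb]])
      schema[[tb]][names(ov)] <- ov
    }
  }
  paths <- as.list(table_paths)
  if (is.null(paths$admissions)) stop("table_paths must include 'admissions'", call. = FALSE)

  read_one <- function(name, required) {
    if (is.null(paths[[name]])) return(NULL)
    if (!file.exists(paths[[name]]))
      stop(sprintf("file for table '%s' not found: %s", name, paths[[name]]), call. = FALSE)
    apply_schema(read_source_csv(paths[[name]]), schema[[name]], name, required)
  }

  adm <- read_one("admissions", c("stay_id", "patient_id", "admit_ts", "discharge_ts"))
  pat <- read_one("patients", c("patient_id", "birth_ts"))
  ce  <- read_one("chartevents", c("stay_id", "ts", "item_id", "value_text"))
  nte <- read_one("noteevents", c("stay_id", "text"))
  dx  <- read_one("diagnoses_icd", c("stay_id", "code"))
  px  <- read_one("procedures_icd", c("stay_id", "code"))

  dropped <- c(admissions = 0L, chartevents = 0L, noteevents = 0L,
               diagnoses_icd = 0L, procedures_icd = 0L)

  # --- stays ---
  admit <- parse_ts(adm$admit_ts)
  disch <- parse_ts(adm$discharge_ts)
  death <- parse_ts(adm$death_ts)
  bad <- is.na(admit) | is.na(disch)
  if (any(bad)) {
    warning(sprintf("admissions: dropped %d row(s) with unparseable admit/discharge time", sum(bad)))
    dropped["admissions"] <- sum(bad)
  }
  stays <- data.frame(
    stay_id = as.character(adm$stay_id),
    patient_id = as.character(adm$patient_id),
    admit_ts = admit, discharge_ts = disch,
    died_in_hospital = !is.na(death) & death >= admit & death <= disch,
    stringsAsFactors = FALSE
  )[!bad, , drop = FALSE]

  # --- patients + ages ---
  patients <- if (is.null(pat)) {
    data.frame(patient_id = character(), birth_ts = as.POSIXct(character(), tz = "UTC"),
               death_ts = as.POSIXct(character(), tz = "UTC"), stringsAsFactors = FALSE)
  } else {
    data.frame(patient_id = as.character(pat$patient_id),
               birth_ts = parse_ts(pat$birth_ts), death_ts = parse_ts(pat$death_ts),
               stringsAsFactors = FALSE)
  }
  birth <- patients$birth_ts[match(stays$patient_id, patients$patient_id)]
  stays$age_at_admission <- compute_age(birth, stays$admit_ts,
                                        cap = age_cap, clamp_above = age_clamp)

  keep_children <- function(df, name) {
    if (is.null(df)) return(NULL)
    ok <- df$stay_id %in% stays$stay_id
    if (any(!ok)) dropped[name] <<- dropped[name] + sum(!ok)
    df[ok, , drop = FALSE]
  }

  # --- chart events (timed events only) ---
  chart_events <- if (is.null(ce)) {
    data.frame(stay_id = character(), ts = as.POSIXct(character(), tz = "UTC"),
               item_id = character(), value_text = character(), stringsAsFactors = FALSE)
  } else {
    ts <- parse_ts(ce$ts)
    bad <- is.na(ts)
    if (any(bad)) {
      warning(sprintf("chartevents: dropped %d row(s) with unparseable timestamp", sum(bad)))
      dropped["chartevents"] <- sum(bad)
    }
    out <- data.frame(stay_id = as.character(ce$stay_id), ts = ts,
                      item_id = as.character(ce$item_id),
                      value_text = as.character(ce$value_text),
                      stringsAsFactors = FALSE)[!bad, , drop = FALSE]
    keep_children(out, "chartevents")
  }
  chart_events <- chart_events[order(chart_events$stay_id, chart_events$ts), , drop = FALSE]

  # --- notes: full timestamp preferred; date-only rows fall back to the
  # charted date at 00:00 and are flagged (usable for keyword scanning, but
  # hour-resolution comparisons treat them conservatively). ---
  notes <- if (is.null(nte)) {
    data.frame(note_id = character(), stay_id = character(),
               ts = as.POSIXct(character(), tz = "UTC"), date_only = logical(),
               category = character(), text = character(), stringsAsFactors = FALSE)
  } else {
    ts <- parse_ts(nte$ts)
    date_only <- rep(FALSE, length(ts))
    if ("date" %in% names(nte)) {
      dts <- parse_ts(nte$date)
      use <- is.na(ts) & !is.na(dts)
      ts[use] <- dts[use]
      date_only <- use
    }
    out <- data.frame(note_id = as.character(nte$note_id), stay_id = as.character(nte$stay_id),
                      ts = ts, date_only = date_only,
                      category = as.character(nte$category),
                      text = as.character(nte$text), stringsAsFactors = FALSE)
    empty <- is.na(out$text) | !nzchar(trimws(out$text))
    if (any(empty)) dropped["noteevents"] <- dropped["noteevents"] + sum(empty)
    keep_children(out[!empty, , drop = FALSE], "noteevents")
  }
  notes <- notes[order(notes$stay_id, notes$ts), , drop = FALSE]

  diagnoses <- if (is.null(dx)) {
    data.frame(stay_id = character(), code = character(), seq = integer(),
               stringsAsFactors = FALSE)
  } else {
    out <- data.frame(stay_id = as.character(dx$stay_id), code = as.character(dx$code),
                      seq = suppressWarnings(as.integer(dx$seq)), stringsAsFactors = FALSE)
    keep_children(out[!is.na(out$code) & nzchar(out$code), , drop = FALSE], "diagnoses_icd")
  }

  procedures <- if (is.null(px)) {
    data.frame(stay_id = character(), code = character(), stringsAsFactors = FALSE)
  } else {
    out <- data.frame(stay_id = as.character(px$stay_id), code = as.character(px$code),
                      stringsAsFactors = FALSE)
    keep_children(out[!is.na(out$code) & nzchar(out$code), , drop = FALSE], "procedures_icd")
  }

  structure(list(stays = stays, patients = patients, chart_events = chart_events,
                 notes = notes, diagnoses = diagnoses, procedures = procedures,
                 dropped = dropped),
            class = "cohort_store")
}

#' @export
print.cohort_store <- function(x, ...) {
  cat("<cohort_store>", nrow(x$stays), "stays |",
      nrow(x$chart_events), "chart events |", nrow(x$notes), "notes |",
      nrow(x$diagnoses), "diagnosis codes |", nrow(x$procedures), "procedure codes\n")
  invisible(x)
}

#' Age at admission in years
#'
#' Computed as `(admit_ts - birth_ts)` in years (365.25-day years). MIMIC
#' shifts dates of birth of patients aged over 89, producing apparent ages
#' around 300; computed ages above `clamp_above` are therefore clamped to
#' `cap`. Missing birth timestamps yield `NA` (the stay is later excluded with
#' reason `"missing_age"`).
#'
#' @param birth_ts,admit_ts `POSIXct` vectors.
#' @param cap age assigned to clamped values (default 90).
#' @param clamp_above clamp threshold in years (default 120).
#' @return numeric years, `NA` where birth is unknown.
#' @export
compute_age <- function(birth_ts, admit_ts, cap = 90, clamp_above = 120) {
  age <- as.numeric(difftime(admit_ts, birth_ts, units = "days")) / 365.25
  age[!is.na(age) & age > clamp_above] <- cap
  age
}

#' Write a cohort store back to MIMIC-III-schema CSV tables
#'
#' Inverse of [load_cohort()] up to column subsetting: emits one CSV per
#' source table using MIMIC-III v1.4 column names.
#'
#' @param store a `cohort_store`.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths written.
#' @export
write_cohort <- function(store, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(ts) ifelse(is.na(ts), "", format(ts, "%Y-%m-%d %H:%M:%S", tz = "UTC"))
  paths <- c(
    admissions = file.path(dir, "ADMISSIONS.csv"),
    patients = file.path(dir, "PATIENTS.csv"),
    chartevents = file.path(dir, "CHARTEVENTS.csv"),
    noteevents = file.path(dir, "NOTEEVENTS.csv"),
    diagnoses_icd = file.path(dir, "DIAGNOSES_ICD.csv"),
    procedures_icd = file.path(dir, "PROCEDURES_ICD.csv")
  )
  st <- store$stays
  utils::write.csv(data.frame(
    HADM_ID = st$stay_id, SUBJECT_ID = st$patient_id,
    ADMITTIME = fmt(st$admit_ts), DISCHTIME = fmt(st$discharge_ts),
    DEATHTIME = ifelse(st$died_in_hospital, fmt(st$discharge_ts), "")
  ), paths["admissions"], row.names = FALSE)
  pt <- store$patients
  utils::write.csv(data.frame(
    SUBJECT_ID = pt$patient_id, DOB = fmt(pt$birth_ts), DOD = fmt(pt$death_ts)
  ), paths["patients"], row.names = FALSE)
  ce <- store$chart_events
  utils::write.csv(data.frame(
    HADM_ID = ce$stay_id, CHARTTIME = fmt(ce$ts), ITEMID = ce$item_id, VALUE = ce$value_text
  ), paths["chartevents"], row.names = FALSE)
  nt <- store$notes
  utils::write.csv(data.frame(
    ROW_ID = nt$note_id, HADM_ID = nt$stay_id,
    CHARTDATE = ifelse(is.na(nt$ts), "", format(nt$ts, "%Y-%m-%d", tz = "UTC")),
    CHARTTIME = ifelse(nt$date_only, "", fmt(nt$ts)),
    CATEGORY = nt$category, TEXT = nt$text
  ), paths["noteevents"], row.names = FALSE)
  utils::write.csv(data.frame(
    HADM_ID = store$diagnoses$stay_id, ICD9_CODE = store$diagnoses$code,
    SEQ_NUM = store$diagnoses$seq
  ), paths["diagnoses_icd"], row.names = FALSE)
  utils::write.csv(data.frame(
    HADM_ID = store$procedures$stay_id, ICD9_CODE = store$procedures$code
  ), paths["procedures_icd"], row.names = FALSE)
  invisible(paths)
}
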