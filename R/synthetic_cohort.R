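# Synthetic MIMIC-III-schema cohort generator with planted pressure-injury
# trajectories, notes, codes and deaths, and exact per-definition
# ground-truth bookkeeping. Notes are template text: sufficient for the
# lexicon/negation logic and for bag-of-words separability, with no ambition
# of realistic clinical language.

# Trajectory patterns. Each published decision dimension has at least one
# discriminating pattern:
#   new_s2plus            new stage 2-4 after 24 h          (case everywhere)
#   unstageable_staged    unstageable on admission, staged later (D5, encodings)
#   admission_dti_worsens DTI on admission, unstageable later    (D5, D7)
#   stage1_only           stage 1 after 24 h                 (D4 = 1 vs 2)
#   improving_dti         DTI on admission and at discharge  (D7: 4 -> 3 improves)
#   admission_pi          numeric stage within 24 h          (admission screen)
QUALIFYING_PATTERNS <- c("new_s2plus", "unstageable_staged", "admission_dti_worsens")
DISTRACTOR_PATTERNS <- c("stage1_only", "improving_dti", "admission_pi")

FILLER_VOCAB <- c(
  "patient", "stable", "overnight", "vitals", "reviewed", "plan", "continue",
  "monitoring", "lungs", "clear", "abdomen", "soft", "ambulating", "with",
  "assistance", "diet", "tolerated", "medications", "administered", "family",
  "updated", "afebrile", "alert", "oriented", "respirations", "unlabored",
  "pain", "controlled", "iv", "fluids", "infusing", "foley", "draining",
  "telemetry", "sinus", "rhythm", "labs", "pending", "physical", "therapy",
  "consulted", "turning", "schedule", "maintained", "skin", "warm", "dry")

#' Generator parameters for a synthetic cohort
#'
#' Defaults describe an ICU-flavored cohort: 7% of stays receive a planted
#' hospital-acquired pressure-injury trajectory, stay durations are
#' lognormal with a median of eight days, onsets occur beyond the 24-h
#' admission window, and chart events are the most commonly emitted
#' evidence source, followed by notes, diagnosis codes and (rarely)
#' procedure codes.
#'
#' @param n_stays number of hospital stays.
#' @param seed RNG seed; identical params + seed reproduce byte-identical
#'   tables.
#' @param target_prevalence probability a stay gets a qualifying
#'   (new-or-worsened) PI trajectory.
#' @param distractor_rate probability a non-case stay gets a non-qualifying
#'   PI trajectory (stage-1-only, improving DTI, PI on admission).
#' @param death_rate probability of death in hospital.
#' @param age_mean,age_sd,age_min,age_max truncated-normal age model (years).
#' @param stay_duration_meanlog,stay_duration_sdlog lognormal stay duration
#'   (hours).
#' @param onset_lag_mean_hours mean exponential lag of PI onset beyond the
#'   24-h admission window.
#' @param stage_trajectory_probs named weights over the six trajectory
#'   patterns (split and renormalized within the qualifying and
#'   non-qualifying groups).
#' @param source_emission_probs named probabilities that a planted PI emits
#'   evidence per source (`chart`, `note`, `icd9`, `procedure`).
#' @param negated_mention_rate probability a stay gets a negated or
#'   structured-dismissal PI mention note.
#' @param date_only_note_rate probability a filler note carries a date but
#'   no time.
#' @param no_notes_rate probability a stay has no notes at all.
#' @param obfuscated_age_rate probability a patient's date of birth is
#'   shifted ~300 years (MIMIC-style age obfuscation; loader clamps to 90).
#' @param notes_per_stay_lambda Poisson mean of filler progress notes.
#' @param signal_token optional token inserted into the pre-onset notes of
#'   planted case stays (for separability experiments); `NULL` disables it.
#' @param signal_token_rate per-note insertion probability of the signal
#'   token in case stays.
#' @return a `generator_params` list.
#' @export
generator_params <- function(n_stays = 500L, seed = 1L,
                             target_prevalence = 0.07,
                             distractor_rate = 0.06,
                             death_rate = 0.08,
                             age_mean = 64, age_sd = 16, age_min = 10, age_max = 95,
                             stay_duration_meanlog = log(8 * 24),
                             stay_duration_sdlog = 0.6,
                             onset_lag_mean_hours = 60,
                             stage_trajectory_probs = c(new_s2plus = 0.50,
                                                        unstageable_staged = 0.12,
                                                        admission_dti_worsens = 0.08,
                                                        stage1_only = 0.12,
                                                        improving_dti = 0.10,
                                                        admission_pi = 0.08),
                             source_emission_probs = c(chart = 0.95, note = 0.55,
                                                       icd9 = 0.40, procedure = 0.08),
                             negated_mention_rate = 0.08,
                             date_only_note_rate = 0.05,
                             no_notes_rate = 0.01,
                             obfuscated_age_rate = 0.02,
                             notes_per_stay_lambda = 2,
                             signal_token = NULL,
                             signal_token_rate = 0.9) {
  p <- list(n_stays = as.integer(n_stays), seed = as.integer(seed),
            target_prevalence = target_prevalence, distractor_rate = distractor_rate,
            death_rate = death_rate, age_mean = age_mean, age_sd = age_sd,
            age_min = age_min, age_max = age_max,
            stay_duration_meanlog = stay_duration_meanlog,
            stay_duration_sdlog = stay_duration_sdlog,
            onset_lag_mean_hours = onset_lag_mean_hours,
            stage_trajectory_probs = stage_trajectory_probs,
            source_emission_probs = source_emission_probs,
            negated_mention_rate = negated_mention_rate,
            date_only_note_rate = date_only_note_rate,
            no_notes_rate = no_notes_rate,
            obfuscated_age_rate = obfuscated_age_rate,
            notes_per_stay_lambda = notes_per_stay_lambda,
            signal_token = signal_token, signal_token_rate = signal_token_rate)
  probs <- c(p$target_prevalence, p$distractor_rate, p$death_rate,
             p$source_emission_probs, p$negated_mention_rate,
             p$date_only_note_rate, p$no_notes_rate, p$obfuscated_age_rate,
             p$signal_token_rate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (p$n_stays < 1) stop("n_stays must be >= 1", call. = FALSE)
  if (any(p$stage_trajectory_probs < 0)) stop("trajectory weights must be >= 0", call. = FALSE)
  if (p$target_prevalence >= 1 && p$death_rate >= 1)
    stop(paste("infeasible parameters: every stay would be both a planted case",
               "and deceased, so no definition excluding the deceased can ever",
               "realize the requested prevalence"), call. = FALSE)
  structure(p, class = "generator_params")
}

#' Templated note text embedding (or dismissing) a PI mention
#'
#' @param trajectory trajectory pattern label (flavors the sentence only).
#' @param negated when `TRUE`, the mention is wrapped in a negation trigger
#'   or a structured dismissal ("bedsore: none"), chosen at random.
#' @param lex keyword lexicon supplying the phrase inventory.
#' @return a single string; scanned with [scan_note()] it yields exactly one
#'   mention with the requested negation status.
#' @export
note_text_for <- function(trajectory = "new_s2plus", negated = FALSE,
                          lex = default_lexicon()) {
  phrase <- sample(lex$phrases, 1)
  filler <- paste(sample(FILLER_VOCAB, 8, replace = TRUE), collapse = " ")
  if (negated) {
    style <- sample(c("trigger", "dismissal"), 1)
    core <- if (style == "trigger") {
      sprintf("skin assessment done. %s %s observed.",
              sample(c("no", "without", "no evidence of", "negative for"), 1), phrase)
    } else {
      sprintf("skin assessment done. %s: none.", phrase)
    }
  } else {
    site <- sample(c("sacral", "coccyx", "left heel", "right heel"), 1)
    core <- sprintf("wound care note. %s %s noted on exam.", site, phrase)
  }
  paste(filler, core)
}

filler_note <- function(extra = NULL) {
  txt <- paste(sample(FILLER_VOCAB, sample(12:24, 1), replace = TRUE), collapse = " ")
  if (!is.null(extra)) txt <- paste(txt, extra)
  paste0(txt, ".")
}

# CareVue- and Metavision-style chart value strings per token.
chart_value_for <- function(token, system) {
  if (system == "carevue") {
    switch(token, S1 = "Red, Unbroken", S2 = "Part. Thickness",
           S3 = "Full Thickness", S4 = "Through Fascia",
           DTI = "Deep Tiss Injury", UNSTAGEABLE = "Unable to Stage")
  } else {
    switch(token, S1 = "Pressure ulcer stage 1", S2 = "Pressure ulcer stage 2",
           S3 = "Pressure ulcer stage 3", S4 = "Pressure ulcer stage 4",
           DTI = "Deep tissue injury", UNSTAGEABLE = "Unable to stage; wound covered")
  }
}

# Planted chart-event schedule (hours from admission + tokens) per pattern.
trajectory_events <- function(pattern, onset_h) {
  switch(pattern,
    new_s2plus = {
      tok <- sample(c("S2", "S3", "S4"), 1, prob = c(0.7, 0.2, 0.1))
      data.frame(hours = c(onset_h, onset_h + 24), token = tok,
                 stringsAsFactors = FALSE)
    },
    unstageable_staged = data.frame(
      hours = c(stats::runif(1, 2, 20), onset_h),
      token = c("UNSTAGEABLE", sample(c("S2", "S3"), 1)), stringsAsFactors = FALSE),
    admission_dti_worsens = data.frame(
      hours = c(stats::runif(1, 2, 20), onset_h),
      token = c("DTI", "UNSTAGEABLE"), stringsAsFactors = FALSE),
    stage1_only = data.frame(hours = onset_h, token = "S1", stringsAsFactors = FALSE),
    improving_dti = data.frame(
      hours = c(stats::runif(1, 2, 20), onset_h),
      token = c("DTI", "DTI"), stringsAsFactors = FALSE),
    admission_pi = data.frame(
      hours = c(stats::runif(1, 2, 20), onset_h),
      token = c("S2", "S2"), stringsAsFactors = FALSE)
  )
}

# Direct transcription of the definition semantics over a stay's planted,
# emitted evidence: used for generation-time ground-truth bookkeeping.
gt_label_stay <- function(info, cfg, enc = default_stage_encoding()) {
  if (info$n_notes == 0) return(c("excluded", "no_notes"))
  if (info$age < cfg$min_age_years) return(c("excluded", "under_age"))
  if (cfg$use_staging_events && nrow(info$chart) > 0 &&
      any(info$chart$token %in% c("S1", "S2", "S3", "S4") &
          info$chart$hours <= cfg$admission_cutoff_hours))
    return(c("excluded", "pi_on_admission"))
  if (cfg$use_note_keywords && nrow(info$mentions) > 0 &&
      any(!info$mentions$negated & info$mentions$hours <= 24))
    return(c("excluded", "pi_on_admission"))
  if (cfg$exclude_deceased && info$died) return(c("excluded", "deceased"))

  fired <- character(0)
  if (cfg$use_staging_events && nrow(info$chart) > 0) {
    ev <- info$chart
    if (!cfg$include_dti_unstageable)
      ev <- ev[!ev$token %in% c("DTI", "UNSTAGEABLE"), , drop = FALSE]
    if (nrow(ev) > 0) {
      within <- ev$hours <= cfg$admission_cutoff_hours
      adm <- if (any(within)) max(enc$admission[ev$token[within]]) else 0L
      late <- ev$hours > cfg$admission_cutoff_hours &
        enc$discharge[ev$token] >= cfg$min_stage
      if (any(late)) {
        hl <- ev$hours[late]; vl <- enc$discharge[ev$token[late]]
        dis <- max(vl[hl == max(hl)])
        ok <- dis >= cfg$min_stage && (!cfg$require_deterioration || dis > adm)
        if (ok) fired <- c(fired, "staging")
      }
    }
  }
  if (cfg$use_note_keywords && nrow(info$mentions) > 0 &&
      any(!info$mentions$negated & !info$mentions$date_only &
          info$mentions$hours > cfg$keyword_cutoff_hours))
    fired <- c(fired, "keyword")
  if (cfg$use_icd9 && info$has_pi_icd9) fired <- c(fired, "icd9")
  if (length(fired)) c("case", fired[1]) else c("control", "none")
}

#' Generate a synthetic MIMIC-schema cohort with ground truth
#'
#' Emits the MIMIC-III-schema tables (admissions, patients, ICU stays,
#' chart events, notes, diagnosis and procedure codes) with planted PI
#' trajectories, plus per-stay, per-definition expected labels computed at
#' generation time by a direct transcription of the definition rules over
#' the planted evidence, and the planted source-indication sets.
#'
#' @param params a [generator_params()] object.
#' @param definitions definitions for which ground-truth labels are
#'   bookkept.
#' @return list with `tables` (named list of data frames in MIMIC column
#'   names), `ground_truth` (stay-level data frame with planted trajectory,
#'   emissions and one `<definition>_status` / `<definition>_route` column
#'   pair per definition), and `sources` (planted source-indication logical
#'   columns).
#' @export
generate_cohort <- function(params = generator_params(),
                            definitions = builtin_definitions()) {
  stopifnot(inherits(params, "generator_params"))
  with_seed(params$seed, generate_cohort_impl(params, definitions))
}

generate_cohort_impl <- function(p, definitions) {
  n <- p$n_stays
  origin <- as.POSIXct("2130-01-01 00:00:00", tz = "UTC")
  stay_id <- as.character(100000L + seq_len(n))
  patient_id <- as.character(50000L + seq_len(n))

  admit <- origin + round(stats::runif(n, 0, 3650 * 86400))
  duration_h <- stats::rlnorm(n, p$stay_duration_meanlog, p$stay_duration_sdlog)
  duration_h <- pmax(duration_h, 30)
  died <- stats::runif(n) < p$death_rate
  age <- pmin(pmax(stats::rnorm(n, p$age_mean, p$age_sd), p$age_min), p$age_max)
  obfuscated <- stats::runif(n) < p$obfuscated_age_rate & age >= 85
  age[obfuscated] <- 90  # what the loader's clamp will report

  w <- p$stage_trajectory_probs
  wq <- w[QUALIFYING_PATTERNS]; wd <- w[DISTRACTOR_PATTERNS]
  is_case <- if (sum(wq) > 0) stats::runif(n) < p$target_prevalence else rep(FALSE, n)
  is_distr <- !is_case & (if (sum(wd) > 0) stats::runif(n) < p$distractor_rate else FALSE)
  pattern <- rep("none", n)
  if (any(is_case))
    pattern[is_case] <- sample(QUALIFYING_PATTERNS, sum(is_case), replace = TRUE,
                               prob = wq / sum(wq))
  if (any(is_distr))
    pattern[is_distr] <- sample(DISTRACTOR_PATTERNS, sum(is_distr), replace = TRUE,
                                prob = wd / sum(wd))

  ep <- p$source_emission_probs
  has_pi <- pattern != "none"
  emit_chart <- has_pi & stats::runif(n) < ep[["chart"]]
  emit_note <- has_pi & stats::runif(n) < ep[["note"]]
  emit_icd9 <- has_pi & stats::runif(n) < ep[["icd9"]]
  emit_proc <- has_pi & stats::runif(n) < ep[["procedure"]]
  no_notes <- stats::runif(n) < p$no_notes_rate
  negated_note <- stats::runif(n) < p$negated_mention_rate & !no_notes

  ce_rows <- list(); note_rows <- list(); dx_rows <- list(); px_rows <- list()
  gt_rows <- vector("list", n)
  lex <- default_lexicon()
  note_counter <- 0L

  for (i in seq_len(n)) {
    sid <- stay_id[i]
    onset_h <- 24 + stats::rexp(1, 1 / p$onset_lag_mean_hours)
    chart <- data.frame(hours = numeric(), token = character(), stringsAsFactors = FALSE)
    if (has_pi[i]) {
      chart <- trajectory_events(pattern[i], onset_h)
      duration_h[i] <- max(duration_h[i], max(chart$hours) + 12)
    }
    disch_ts <- admit[i] + duration_h[i] * 3600

    if (emit_chart[i] && nrow(chart) > 0) {
      system <- sample(c("carevue", "metavision"), 1)
      item <- if (system == "carevue") "551" else "224631"
      ce_rows[[length(ce_rows) + 1L]] <- data.frame(
        HADM_ID = sid,
        CHARTTIME = format(admit[i] + chart$hours * 3600, "%Y-%m-%d %H:%M:%S"),
        ITEMID = item,
        VALUE = vapply(chart$token, chart_value_for, character(1), system = system),
        stringsAsFactors = FALSE)
    }

    # notes ------------------------------------------------------------------
    mention_list <- data.frame(hours = numeric(), negated = logical(),
                               date_only = logical())
    n_notes_i <- 0L
    if (!no_notes[i]) {
      sig <- !is.null(p$signal_token) && is_case[i]
      mk_note <- function(hours, text, date_only = FALSE) {
        note_counter <<- note_counter + 1L
        ts <- admit[i] + hours * 3600
        data.frame(ROW_ID = as.character(note_counter), HADM_ID = sid,
                   CHARTDATE = format(ts, "%Y-%m-%d"),
                   CHARTTIME = if (date_only) "" else format(ts, "%Y-%m-%d %H:%M:%S"),
                   CATEGORY = "Nursing/other", TEXT = text, stringsAsFactors = FALSE)
      }
      add_sig <- function(h) {
        if (sig && h < onset_h && stats::runif(1) < p$signal_token_rate)
          p$signal_token else NULL
      }
      h0 <- stats::runif(1, 1, 6)
      note_rows[[length(note_rows) + 1L]] <- mk_note(h0, filler_note(add_sig(h0)))
      n_notes_i <- n_notes_i + 1L
      k <- stats::rpois(1, p$notes_per_stay_lambda)
      if (k > 0) {
        hs <- stats::runif(k, 6, max(7, duration_h[i] - 1))
        for (h in hs) {
          date_only <- stats::runif(1) < p$date_only_note_rate
          note_rows[[length(note_rows) + 1L]] <- mk_note(h, filler_note(add_sig(h)), date_only)
          n_notes_i <- n_notes_i + 1L
        }
      }
      if (has_pi[i] && emit_note[i]) {
        h <- onset_h + stats::runif(1, 0, 2)
        duration_h[i] <- max(duration_h[i], h + 6)
        disch_ts <- admit[i] + duration_h[i] * 3600
        note_rows[[length(note_rows) + 1L]] <-
          mk_note(h, note_text_for(pattern[i], FALSE, lex))
        n_notes_i <- n_notes_i + 1L
        mention_list <- rbind(mention_list,
                              data.frame(hours = h, negated = FALSE, date_only = FALSE))
      }
      if (negated_note[i]) {
        h <- stats::runif(1, 6, max(7, duration_h[i] - 1))
        note_rows[[length(note_rows) + 1L]] <-
          mk_note(h, note_text_for(pattern[i], TRUE, lex))
        n_notes_i <- n_notes_i + 1L
        mention_list <- rbind(mention_list,
                              data.frame(hours = h, negated = TRUE, date_only = FALSE))
      }
    }

    # codes ------------------------------------------------------------------
    dx <- c(if (emit_icd9[i]) sample(c("70703", "70705", "70725"), 1),
            sample(c("4019", "25000", "42731", "5849"), sample(1:3, 1)))
    dx_rows[[length(dx_rows) + 1L]] <- data.frame(
      HADM_ID = sid, ICD9_CODE = dx, SEQ_NUM = as.character(seq_along(dx)),
      stringsAsFactors = FALSE)
    if (emit_proc[i] || stats::runif(1) < 0.05) {
      px <- if (emit_proc[i]) sample(c("8622", "8628"), 1) else "9904"
      px_rows[[length(px_rows) + 1L]] <- data.frame(
        HADM_ID = sid, ICD9_CODE = px, stringsAsFactors = FALSE)
    }

    gt_rows[[i]] <- list(
      stay_id = sid, pattern = pattern[i], died = died[i], age = age[i],
      n_notes = n_notes_i,
      chart = if (emit_chart[i]) chart else chart[0, , drop = FALSE],
      mentions = mention_list,
      has_pi_icd9 = emit_icd9[i],
      emit_chart = emit_chart[i] && nrow(chart) > 0,
      emit_note = has_pi[i] && emit_note[i] && !no_notes[i],
      emit_proc = emit_proc[i])
  }

  disch <- admit + duration_h * 3600
  fmt <- function(ts) format(ts, "%Y-%m-%d %H:%M:%S")
  tables <- list(
    admissions = data.frame(
      HADM_ID = stay_id, SUBJECT_ID = patient_id,
      ADMITTIME = fmt(admit), DISCHTIME = fmt(disch),
      DEATHTIME = ifelse(died, fmt(disch), ""), stringsAsFactors = FALSE),
    patients = data.frame(
      SUBJECT_ID = patient_id,
      DOB = format(admit - ifelse(obfuscated, 300, age) * 365.25 * 86400, "%Y-%m-%d"),
      DOD = ifelse(died, fmt(disch), ""), stringsAsFactors = FALSE),
    icustays = data.frame(HADM_ID = stay_id, SUBJECT_ID = patient_id,
                          stringsAsFactors = FALSE),
    chartevents = if (length(ce_rows)) do.call(rbind, ce_rows) else
      data.frame(HADM_ID = character(), CHARTTIME = character(),
                 ITEMID = character(), VALUE = character(), stringsAsFactors = FALSE),
    noteevents = if (length(note_rows)) do.call(rbind, note_rows) else
      data.frame(ROW_ID = character(), HADM_ID = character(), CHARTDATE = character(),
                 CHARTTIME = character(), CATEGORY = character(), TEXT = character(),
                 stringsAsFactors = FALSE),
    diagnoses_icd = do.call(rbind, dx_rows),
    procedures_icd = if (length(px_rows)) do.call(rbind, px_rows) else
      data.frame(HADM_ID = character(), ICD9_CODE = character(), stringsAsFactors = FALSE)
  )

  gt <- data.frame(stay_id = stay_id, pattern = pattern, died = died,
                   age = round(age, 2), stringsAsFactors = FALSE)
  for (nm in names(definitions)) {
    lab <- t(vapply(gt_rows, gt_label_stay, character(2), cfg = definitions[[nm]]))
    gt[[paste0(nm, "_status")]] <- lab[, 1]
    gt[[paste0(nm, "_route")]] <- lab[, 2]
  }

  sources <- data.frame(
    stay_id = stay_id,
    chart_events = vapply(gt_rows, function(g) g$emit_chart, logical(1)),
    notes = vapply(gt_rows, function(g) g$emit_note, logical(1)),
    diagnosis_codes = vapply(gt_rows, function(g) g$has_pi_icd9, logical(1)),
    procedure_codes = vapply(gt_rows, function(g) g$emit_proc, logical(1)),
    stringsAsFactors = FALSE)

  list(tables = tables, ground_truth = gt, sources = sources)
}

#' Materialize generated tables as CSV files
#'
#' @param sim output of [generate_cohort()].
#' @param dir output directory.
#' @return named vector of file paths (suitable for [load_cohort()]).
#' @export
write_sim_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  names_map <- c(admissions = "ADMISSIONS.csv", patients = "PATIENTS.csv",
                 icustays = "ICUSTAYS.csv", chartevents = "CHARTEVENTS.csv",
                 noteevents = "NOTEEVENTS.csv", diagnoses_icd = "DIAGNOSES_ICD.csv",
                 procedures_icd = "PROCEDURES_ICD.csv")
  paths <- character(0)
  for (nm in names(sim$tables)) {
    path <- file.path(dir, names_map[[nm]])
    utils::write.csv(sim$tables[[nm]], path, row.names = FALSE)
    paths[nm] <- path
  }
  utils::write.csv(sim$ground_truth, file.path(dir, "ground_truth.csv"), row.names = FALSE)
  paths
}

#' Convert generated tables to a cohort store
#'
#' Round-trips the in-memory tables through CSV and [load_cohort()] so the
#' store is exactly what a file-based pipeline would see.
#'
#' @param sim output of [generate_cohort()].
#' @return a `cohort_store`.
#' @export
as_cohort_store <- function(sim) {
  dir <- tempfile("simcohort")
  on.exit(unlink(dir, recursive = TRUE))
  paths <- write_sim_cohort(sim, dir)
  suppressWarnings(load_cohort(as.list(paths[names(paths) != "ground_truth"])))
}
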