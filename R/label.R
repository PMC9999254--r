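# The labeling engine: common inclusion criteria plus per-definition routes
# (staging / keyword / ICD-9) producing a case / control / excluded status
# per hospital stay, with the event timestamp backing each timed case.

icd9_matches <- function(codes, prefixes) {
  if (!length(codes)) return(FALSE)
  norm <- gsub("[^A-Za-z0-9]", "", codes)
  any(vapply(prefixes, function(p) any(startsWith(norm, p)), logical(1)))
}

#' Evaluate the common inclusion criteria for one stay
#'
#' Criteria shared by all definitions, checked in order: presence of at
#' least one clinical note (`"no_notes"`), discharge after admission
#' (`"bad_times"`), known age (`"missing_age"`) at or above the definition's
#' minimum (`"under_age"`), no PI documented on admission
#' (`"pi_on_admission"`), and - when the definition excludes the deceased -
#' survival to discharge (`"deceased"`).
#'
#' A PI is "documented on admission" when a numeric stage 1-4 is charted
#' within the definition's admission window, or, for keyword-using
#' definitions, when a non-negated keyword mention occurs within 24 hours of
#' admission. Admission DTI and unstageable events do not trigger this
#' screen: they feed the stage-encoding deterioration logic instead, so that
#' an unstageable wound on admission that is later staged can still qualify.
#'
#' @param stay one-row data frame from a `cohort_store`'s `stays`.
#' @param n_notes number of clinical notes for the stay.
#' @param staging data frame of the stay's staging events with
#'   `hours_from_admission` and `token` (unfiltered by D5).
#' @param mentions data frame of the stay's keyword mentions ([scan_notes()]).
#' @param cfg a `hapi_definition`.
#' @return `NULL` when the stay is eligible, else the exclusion reason.
#' @export
check_common_inclusion <- function(stay, n_notes, staging, mentions, cfg) {
  if (n_notes == 0) return("no_notes")
  if (is.na(stay$discharge_ts) || stay$discharge_ts <= stay$admit_ts) return("bad_times")
  if (is.na(stay$age_at_admission)) return("missing_age")
  if (stay$age_at_admission < cfg$min_age_years) return("under_age")

  cutoff <- if (cfg$use_staging_events) cfg$admission_cutoff_hours else NA_real_
  if (!is.na(cutoff) && nrow(staging) > 0) {
    numeric_early <- staging$token %in% c("S1", "S2", "S3", "S4") &
      staging$hours_from_admission <= cutoff
    if (any(numeric_early)) return("pi_on_admission")
  }
  if (cfg$use_note_keywords && !is.null(mentions) && nrow(mentions) > 0) {
    early <- !mentions$negated &
      hours_since(mentions$ts, stay$admit_ts) <= 24
    if (any(early, na.rm = TRUE)) return("pi_on_admission")
  }
  if (cfg$exclude_deceased && isTRUE(stay$died_in_hospital)) return("deceased")
  NULL
}

#' Label a single stay under one definition
#'
#' Applies the common inclusion criteria, then evaluates each enabled route:
#' the staging route via [admission_stage()] / [discharge_stage()] /
#' [staging_case_decision()], the keyword route via
#' [earliest_positive_mention()] beyond the definition's event-time cutoff,
#' and the untimed ICD-9 route. The event timestamp of a case is the
#' earliest timestamp among the firing timed routes.
#'
#' @inheritParams check_common_inclusion
#' @param dx_codes character vector of the stay's ICD-9 diagnosis codes.
#' @param enc stage encoding.
#' @return one-row data frame: `stay_id`, `status`, `route`, `event_ts`,
#'   `exclusion_reason`.
#' @export
label_stay <- function(stay, n_notes, staging, mentions, dx_codes, cfg,
                       enc = default_stage_encoding()) {
  res <- data.frame(stay_id = stay$stay_id, status = "control", route = "none",
                    event_ts = as.POSIXct(NA, tz = "UTC"),
                    exclusion_reason = NA_character_, stringsAsFactors = FALSE)
  reason <- check_common_inclusion(stay, n_notes, staging, mentions, cfg)
  if (!is.null(reason)) {
    res$status <- "excluded"; res$exclusion_reason <- reason
    return(res)
  }

  route_ts <- c()
  # staging route
  if (cfg$use_staging_events && nrow(staging) > 0) {
    ev <- staging
    if (!cfg$include_dti_unstageable)
      ev <- ev[!ev$token %in% c("DTI", "UNSTAGEABLE"), , drop = FALSE]
    if (nrow(ev) > 0) {
      adm <- admission_stage(ev$hours_from_admission, ev$token,
                             cfg$admission_cutoff_hours, enc)
      dis <- discharge_stage(ev$hours_from_admission, ev$token,
                             cfg$admission_cutoff_hours, enc,
                             min_numeric = cfg$min_stage)
      if (staging_case_decision(adm, dis, cfg$require_deterioration, cfg$min_stage)) {
        late <- ev$hours_from_admission > cfg$admission_cutoff_hours
        route_ts["staging"] <- min(ev$ts[late])
      }
    }
  }
  # keyword route
  if (cfg$use_note_keywords) {
    epm <- earliest_positive_mention(mentions, stay$admit_ts, cfg$keyword_cutoff_hours)
    if (!is.null(epm)) route_ts["keyword"] <- epm$ts
  }
  # ICD-9 route (untimed)
  icd_fire <- cfg$use_icd9 && icd9_matches(dx_codes, cfg$icd9_codes)

  if (length(route_ts) > 0) {
    res$status <- "case"
    best <- which.min(route_ts)
    res$route <- names(route_ts)[best]
    res$event_ts <- as.POSIXct(route_ts[[best]], origin = "1970-01-01", tz = "UTC")
  } else if (icd_fire) {
    res$status <- "case"
    res$route <- "icd9"
  }
  res
}

#' Label every stay of a cohort under one definition
#'
#' @param store a `cohort_store` from [load_cohort()] or [as_cohort_store()].
#' @param cfg a `hapi_definition` (see [builtin_definitions()]).
#' @param lex keyword lexicon.
#' @param stage_item_map staging chart-item map.
#' @param mentions optional precomputed [scan_notes()] output (saves rescanning
#'   when labeling the same cohort under several definitions).
#' @param staging_events optional precomputed [extract_staging_events()] output.
#' @return data frame with one row per stay (`stay_id`, `status`, `route`,
#'   `event_ts`, `exclusion_reason`) and a `"summary"` attribute; see
#'   [label_summary()].
#' @export
label_cohort <- function(store, cfg, lex = default_lexicon(),
                         stage_item_map = default_stage_item_map(),
                         mentions = NULL, staging_events = NULL) {
  stays <- store$stays
  admit <- stays$admit_ts
  names(admit) <- stays$stay_id
  if (is.null(staging_events))
    staging_events <- extract_staging_events(store$chart_events, stage_item_map, admit)
  if (is.null(mentions)) mentions <- scan_notes(store$notes, lex)

  lv <- stays$stay_id
  idx_of <- function(ids) split(seq_along(ids), factor(ids, levels = lv))
  se_idx <- idx_of(staging_events$stay_id)
  mn_idx <- idx_of(mentions$stay_id)
  dx_idx <- idx_of(store$diagnoses$stay_id)
  note_counts <- table(factor(store$notes$stay_id, levels = lv))

  rows <- vector("list", nrow(stays))
  for (i in seq_len(nrow(stays))) {
    sid <- lv[i]
    rows[[i]] <- label_stay(
      stays[i, , drop = FALSE],
      n_notes = as.integer(note_counts[[sid]]),
      staging = staging_events[se_idx[[sid]], , drop = FALSE],
      mentions = mentions[mn_idx[[sid]], , drop = FALSE],
      dx_codes = store$diagnoses$code[dx_idx[[sid]]],
      cfg = cfg)
  }
  labels <- if (length(rows)) do.call(rbind, rows) else
    data.frame(stay_id = character(), status = character(), route = character(),
               event_ts = as.POSIXct(character(), tz = "UTC"),
               exclusion_reason = character(), stringsAsFactors = FALSE)
  rownames(labels) <- NULL
  n_eligible <- sum(labels$status != "excluded")
  n_case <- sum(labels$status == "case")
  attr(labels, "summary") <- list(
    definition = cfg$name, n_stays = nrow(labels), n_eligible = n_eligible,
    n_case = n_case,
    prevalence_pct = if (n_eligible > 0) 100 * n_case / n_eligible else NA_real_)
  labels
}

#' Summary of a label table
#'
#' @param labels output of [label_cohort()].
#' @return list with `definition`, `n_stays`, `n_eligible`, `n_case`,
#'   `prevalence_pct` (cases over eligible stays; excluded stays are out of
#'   the denominator).
#' @export
label_summary <- function(labels) attr(labels, "summary")
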