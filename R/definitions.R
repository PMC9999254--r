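# Definition policies: the eight decision dimensions along which published
# MIMIC-III HAPI case definitions diverge, captured as a config object.
#
#   D1 exclude_deceased         exclude stays that end in death in hospital
#   D2 min_age_years            minimum age in years
#   D3 admission_cutoff_hours   window for ascertaining PI present on admission
#   D4 min_stage                minimum numerical PI stage at discharge
#   D5 include_dti_unstageable  count DTI / unstageable staging events
#   D6 use_note_keywords        PI keywords in notes label a case
#   D7 require_deterioration    only worsening or newly developed PI
#   D8 use_icd9                 ICD-9 codes label a case

#' Build a HAPI definition config
#'
#' @param name label for the policy.
#' @param exclude_deceased D1.
#' @param min_age_years D2.
#' @param admission_cutoff_hours D3; `NA` when the policy has no staging
#'   timeline (the admission screen then falls back to the 24-h note check).
#' @param min_stage D4 (`NA` when staging is unused).
#' @param include_dti_unstageable D5; when `FALSE`, DTI and unstageable
#'   events are removed before any staging logic.
#' @param use_note_keywords D6.
#' @param require_deterioration D7.
#' @param use_icd9 D8.
#' @param use_staging_events whether PI staging chart events are considered
#'   at all.
#' @param keyword_cutoff_hours keyword mentions strictly later than this many
#'   hours after admission fire the keyword route (the event-time threshold;
#'   48 for CANTRIP, else 24).
#' @param icd9_codes diagnosis-code prefixes counted as pressure injury.
#' @return a `hapi_definition` list.
#' @export
definition_config <- function(name,
                              exclude_deceased = FALSE,
                              min_age_years = 15,
                              admission_cutoff_hours = 24,
                              min_stage = 2L,
                              include_dti_unstageable = TRUE,
                              use_note_keywords = TRUE,
                              require_deterioration = FALSE,
                              use_icd9 = FALSE,
                              use_staging_events = TRUE,
                              keyword_cutoff_hours = 24,
                              icd9_codes = default_icd9_pi_codes()) {
  if (use_staging_events &&
      (is.na(admission_cutoff_hours) || is.na(min_stage)))
    stop("a staging-based definition needs admission_cutoff_hours and min_stage",
         call. = FALSE)
  structure(list(name = name, exclude_deceased = exclude_deceased,
                 min_age_years = min_age_years,
                 admission_cutoff_hours = admission_cutoff_hours,
                 min_stage = min_stage,
                 include_dti_unstageable = include_dti_unstageable,
                 use_note_keywords = use_note_keywords,
                 require_deterioration = require_deterioration,
                 use_icd9 = use_icd9,
                 use_staging_events = use_staging_events,
                 keyword_cutoff_hours = keyword_cutoff_hours,
                 icd9_codes = icd9_codes),
            class = "hapi_definition")
}

#' Default ICD-9 pressure-injury diagnosis-code prefixes
#'
#' Covers 707.0x (pressure ulcer by site) and 707.25 (stage-coded pressure
#' ulcer). Site-specific inventories should override this.
#' @return character vector of code prefixes.
#' @export
default_icd9_pi_codes <- function() c("7070", "70725")

#' The four built-in HAPI definitions
#'
#' | name | D1 | D2 | D3 | D4 | D5 | D6 | D7 | D8 |
#' |------|----|----|----|----|----|----|----|----|
#' | ehapi    | yes | 15 | 24 h | 2 | yes | yes | yes | no  |
#' | cantrip  | no  | 15 | 48 h | 1 | yes | yes | no  | no  |
#' | cramer   | no  | 18 | 24 h | 2 | no  | no  | no  | no  |
#' | sotoodeh | no  | 18 | n/a  | - | -   | yes | no  | yes |
#'
#' CANTRIP defines its date of event strictly later than 48 hours after
#' admission for both staging events and note mentions. Sotoodeh uses no
#' staging timeline at all: cases come from ICD-9 codes or note keywords.
#'
#' @return named list of four `hapi_definition` objects.
#' @export
builtin_definitions <- function() {
  list(
    ehapi = definition_config("ehapi", exclude_deceased = TRUE, min_age_years = 15,
                              admission_cutoff_hours = 24, min_stage = 2L,
                              include_dti_unstageable = TRUE, use_note_keywords = TRUE,
                              require_deterioration = TRUE, use_icd9 = FALSE,
                              use_staging_events = TRUE, keyword_cutoff_hours = 24),
    cantrip = definition_config("cantrip", exclude_deceased = FALSE, min_age_years = 15,
                                admission_cutoff_hours = 48, min_stage = 1L,
                                include_dti_unstageable = TRUE, use_note_keywords = TRUE,
                                require_deterioration = FALSE, use_icd9 = FALSE,
                                use_staging_events = TRUE, keyword_cutoff_hours = 48),
    cramer = definition_config("cramer", exclude_deceased = FALSE, min_age_years = 18,
                               admission_cutoff_hours = 24, min_stage = 2L,
                               include_dti_unstageable = FALSE, use_note_keywords = FALSE,
                               require_deterioration = FALSE, use_icd9 = FALSE,
                               use_staging_events = TRUE, keyword_cutoff_hours = 24),
    sotoodeh = definition_config("sotoodeh", exclude_deceased = FALSE, min_age_years = 18,
                                 admission_cutoff_hours = NA_real_, min_stage = NA_integer_,
                                 include_dti_unstageable = TRUE, use_note_keywords = TRUE,
                                 require_deterioration = FALSE, use_icd9 = TRUE,
                                 use_staging_events = FALSE, keyword_cutoff_hours = 24)
  )
}

#' @export
print.hapi_definition <- function(x, ...) {
  cat(sprintf("<hapi_definition '%s'> D1=%s D2=%s D3=%s D4=%s D5=%s D6=%s D7=%s D8=%s staging=%s\n",
              x$name, x$exclude_deceased, x$min_age_years, x$admission_cutoff_hours,
              x$min_stage, x$include_dti_unstageable, x$use_note_keywords,
              x$require_deterioration, x$use_icd9, x$use_staging_events))
  invisible(x)
}
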