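# Pressure-injury staging: canonical stage tokens extracted from chart
# events, the admission/discharge stage encodings, and the staging-route
# case decision.
#
# Stage semantics: numeric stages 1-4 plus deep tissue injury (DTI) and
# unstageable wounds. At admission DTI counts as stage 4 and unstageable as 0
# (NPIAP treats DTI as a stage-3-or-4 injury; an unstageable wound carries no
# admission depth information). At discharge DTI counts as stage 3 and
# unstageable as 5 so that an unstageable wound qualifies as hospital-acquired
# regardless of the admission stage, while a DTI that remains a DTI reads as
# 4 -> 3, i.e. an improvement, and is excluded by the deterioration rule.

STAGE_TOKENS <- c("S1", "S2", "S3", "S4", "DTI", "UNSTAGEABLE")

#' Stage encoding used at admission and discharge
#'
#' @return list with integer maps `admission` (`S1..S4 -> 1..4`, `DTI -> 4`,
#'   `UNSTAGEABLE -> 0`) and `discharge` (`S1..S4 -> 1..4`, `DTI -> 3`,
#'   `UNSTAGEABLE -> 5`), and `absent_admission_value = 0`.
#' @export
default_stage_encoding <- function() {
  list(
    admission = c(S1 = 1L, S2 = 2L, S3 = 3L, S4 = 4L, DTI = 4L, UNSTAGEABLE = 0L),
    discharge = c(S1 = 1L, S2 = 2L, S3 = 3L, S4 = 4L, DTI = 3L, UNSTAGEABLE = 5L),
    absent_admission_value = 0L
  )
}

#' Default chart-item map for pressure-injury staging events
#'
#' Maps `(item_id, value pattern)` pairs to canonical stage tokens, covering
#' CareVue-style categorical values ("Red, Unbroken", "Deep Tiss Injury", ...)
#' and Metavision-style "stage N" strings. Site deployments should override
#' this with their own item inventory; patterns are matched
#' case-insensitively and the first matching row wins.
#'
#' @return data frame with columns `item_id`, `value_regex`, `token`.
#' @export
default_stage_item_map <- function() {
  cv <- function(item) data.frame(
    item_id = item,
    value_regex = c("red[,;]? ?unbroken|intact", "part(\\.|ial)[a-z]* thickness",
                    "full thickness", "through (fascia|to bone)",
                    "deep tiss", "unable to stage|unstageable"),
    token = c("S1", "S2", "S3", "S4", "DTI", "UNSTAGEABLE"),
    stringsAsFactors = FALSE)
  mv <- function(item) data.frame(
    item_id = item,
    value_regex = c("deep tissue", "unable to stage|unstageable",
                    "stage ?(i|1)\\b", "stage ?(ii|2)\\b",
                    "stage ?(iii|3)\\b", "stage ?(iv|4)\\b"),
    token = c("DTI", "UNSTAGEABLE", "S1", "S2", "S3", "S4"),
    stringsAsFactors = FALSE)
  rbind(cv("551"), cv("552"), cv("553"), mv("224631"), mv("224965"))
}

#' Extract canonical staging events from chart events
#'
#' Only events whose `item_id` appears in the map are considered; value
#' strings of mapped items that match no pattern are dropped with an
#' aggregated warning.
#'
#' @param chart_events data frame with `stay_id`, `ts`, `item_id`,
#'   `value_text` (as in a `cohort_store`).
#' @param stage_item_map data frame as [default_stage_item_map()].
#' @param admit_ts named `POSIXct` vector (names = stay_id) used to express
#'   event times as hours from admission; pass `NULL` to keep timestamps only.
#' @return data frame with `stay_id`, `ts`, `hours_from_admission` (if
#'   `admit_ts` given), `token`, `raw_value`, `item_id`.
#' @export
extract_staging_events <- function(chart_events, stage_item_map = default_stage_item_map(),
                                   admit_ts = NULL) {
  if (is.null(stage_item_map) || nrow(stage_item_map) == 0)
    stop("stage_item_map is empty: refusing to silently produce zero PI evidence",
         call. = FALSE)
  ce <- chart_events[chart_events$item_id %in% unique(stage_item_map$item_id), , drop = FALSE]
  token <- rep(NA_character_, nrow(ce))
  if (nrow(ce)) {
    val <- tolower(ce$value_text)
    for (i in seq_len(nrow(stage_item_map))) {
      row <- stage_item_map[i, ]
      hit <- is.na(token) & ce$item_id == row$item_id &
        grepl(row$value_regex, val, perl = TRUE)
      token[hit] <- row$token
    }
  }
  unmapped <- is.na(token)
  if (any(unmapped))
    warning(sprintf("dropped %d staging event(s) with unmappable value strings",
                    sum(unmapped)))
  out <- data.frame(stay_id = ce$stay_id[!unmapped], ts = ce$ts[!unmapped],
                    token = token[!unmapped], raw_value = ce$value_text[!unmapped],
                    item_id = ce$item_id[!unmapped], stringsAsFactors = FALSE)
  if (!is.null(admit_ts)) {
    out$hours_from_admission <- hours_since(out$ts, admit_ts[out$stay_id])
  }
  out[order(out$stay_id, out$ts), , drop = FALSE]
}

#' Admission pressure-injury stage
#'
#' The admission stage is the maximum encoded stage among staging events
#' charted within `cutoff_hours` of admission (closed window, `<=`). In the
#' absence of any staging information at admission the stage is 0.
#'
#' @param hours numeric hours from admission of one stay's staging events.
#' @param tokens stage tokens parallel to `hours`.
#' @param cutoff_hours admission window in hours (24 or 48 by definition).
#' @param enc a stage encoding, see [default_stage_encoding()].
#' @return integer stage (0 when undocumented).
#' @export
admission_stage <- function(hours, tokens, cutoff_hours, enc = default_stage_encoding()) {
  stopifnot(length(hours) == length(tokens))
  if (cutoff_hours < 0) stop("cutoff_hours must be non-negative", call. = FALSE)
  vals <- enc$admission[tokens[hours <= cutoff_hours]]
  if (length(vals) == 0) return(enc$absent_admission_value)
  max(vals)
}

#' Discharge pressure-injury stage
#'
#' The discharge stage is the encoded value of the last staging event later
#' than `cutoff_hours` after admission (strict `>`) whose encoded value is at
#' least `min_numeric`. Events tied on the latest timestamp resolve to the
#' maximum encoded value. Returns `NA` when no event qualifies.
#'
#' @inheritParams admission_stage
#' @param min_numeric minimum encoded discharge value to qualify (D4).
#' @return integer stage or `NA`.
#' @export
discharge_stage <- function(hours, tokens, cutoff_hours, enc = default_stage_encoding(),
                            min_numeric = 2L) {
  stopifnot(length(hours) == length(tokens))
  vals <- enc$discharge[tokens]
  keep <- hours > cutoff_hours & vals >= min_numeric
  if (!any(keep)) return(NA_integer_)
  h <- hours[keep]; v <- vals[keep]
  as.integer(max(v[h == max(h)]))
}

#' Staging-route HAPI decision
#'
#' A stay is a staging-route case when a qualifying discharge stage exists
#' (`disch >= min_stage`) and, if the definition captures only worsening or
#' newly developed injuries (D7), the discharge stage strictly exceeds the
#' admission stage.
#'
#' @param adm integer admission stage (>= 0).
#' @param disch integer discharge stage or `NA`.
#' @param require_deterioration logical, D7.
#' @param min_stage minimum discharge stage, D4.
#' @return logical.
#' @export
staging_case_decision <- function(adm, disch, require_deterioration, min_stage) {
  stopifnot(adm >= 0)
  if (is.na(disch)) return(FALSE)
  if (disch < min_stage) return(FALSE)
  if (require_deterioration) disch > adm else TRUE
}
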