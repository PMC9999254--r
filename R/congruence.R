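# Source-congruence analytics: which of the four EHR data sources (chart
# events, notes, diagnosis codes, procedure codes) indicate a pressure injury
# for each stay, and exact set-intersection (UpSet-style) tabulations, both
# across sources and across definitions.

PI_SOURCES <- c("chart_events", "notes", "diagnosis_codes", "procedure_codes")

#' Default ICD-9 procedure-code prefixes suggesting pressure-injury care
#'
#' Debridement-style procedure codes (86.22 excisional debridement of wound,
#' 86.28 nonexcisional debridement, 83.45 other myectomy). Procedure codes
#' are not PI-specific; treat this source as weak evidence.
#' @return character vector of prefixes.
#' @export
default_procedure_pi_codes <- function() c("8622", "8628", "8345")

#' Per-stay pressure-injury indications across the four data sources
#'
#' Timing and eligibility are deliberately ignored: a stay appears in the
#' output when at least one source shows any PI evidence (any staging chart
#' event, any non-negated keyword mention at any time, any PI ICD-9
#' diagnosis code, any configured procedure code).
#'
#' @param store a `cohort_store`.
#' @param lex keyword lexicon.
#' @param stage_item_map staging chart-item map.
#' @param icd9_codes diagnosis-code prefixes.
#' @param procedure_codes procedure-code prefixes.
#' @param mentions optional precomputed [scan_notes()] output.
#' @return data frame with `stay_id` and logical columns `chart_events`,
#'   `notes`, `diagnosis_codes`, `procedure_codes`; only stays with at least
#'   one indication are listed.
#' @export
source_indications <- function(store, lex = default_lexicon(),
                               stage_item_map = default_stage_item_map(),
                               icd9_codes = default_icd9_pi_codes(),
                               procedure_codes = default_procedure_pi_codes(),
                               mentions = NULL) {
  se <- extract_staging_events(store$chart_events, stage_item_map)
  if (is.null(mentions)) mentions <- scan_notes(store$notes, lex)
  pos_mentions <- mentions[!mentions$negated, , drop = FALSE]

  dxn <- gsub("[^A-Za-z0-9]", "", store$diagnoses$code)
  dx_hit <- store$diagnoses$stay_id[Reduce(`|`, lapply(icd9_codes, startsWith, x = dxn),
                                           accumulate = FALSE) %||% logical(0)]
  pxn <- gsub("[^A-Za-z0-9]", "", store$procedures$code)
  px_hit <- store$procedures$stay_id[Reduce(`|`, lapply(procedure_codes, startsWith, x = pxn),
                                            accumulate = FALSE) %||% logical(0)]

  ids <- store$stays$stay_id
  out <- data.frame(stay_id = ids,
                    chart_events = ids %in% se$stay_id,
                    notes = ids %in% pos_mentions$stay_id,
                    diagnosis_codes = ids %in% dx_hit,
                    procedure_codes = ids %in% px_hit,
                    stringsAsFactors = FALSE)
  out[rowSums(out[PI_SOURCES]) > 0, , drop = FALSE]
}

#' Exact UpSet combination counts over indicator sets
#'
#' @param sets data frame with an id column followed by logical membership
#'   columns (e.g. [source_indications()] output).
#' @param id_col name of the id column.
#' @return list with `combinations` (data frame: `combination` as
#'   `"+"`-joined sorted member names, `degree`, `count`) and `totals`
#'   (named per-set cardinalities) and `n_union`.
#' @export
upset_counts <- function(sets, id_col = "stay_id") {
  members <- setdiff(names(sets), id_col)
  m <- as.matrix(sets[members])
  keep <- rowSums(m) > 0
  m <- m[keep, , drop = FALSE]
  if (nrow(m) == 0) {
    return(list(combinations = data.frame(combination = character(),
                                          degree = integer(), count = integer(),
                                          stringsAsFactors = FALSE),
                totals = stats::setNames(rep(0L, length(members)), members),
                n_union = 0L))
  }
  combo <- apply(m, 1, function(r) paste(sort(members[as.logical(r)]), collapse = "+"))
  tab <- table(combo)
  combos <- data.frame(combination = names(tab),
                       degree = lengths(strsplit(names(tab), "+", fixed = TRUE)),
                       count = as.integer(tab), stringsAsFactors = FALSE)
  combos <- combos[order(-combos$count, combos$combination), , drop = FALSE]
  rownames(combos) <- NULL
  list(combinations = combos,
       totals = colSums(m),
       n_union = nrow(m))
}

#' Overlap of case stays across definitions
#'
#' UpSet-style tabulation of which definitions call each stay a case, over
#' stays that are a case under at least one definition.
#'
#' @param label_tables named list of [label_cohort()] outputs sharing one
#'   stay universe.
#' @return list with `combinations` (as in [upset_counts()]),
#'   `per_definition` case counts, `n_union`, and `consensus` (the count of
#'   stays labeled case by every definition).
#' @export
definition_overlap <- function(label_tables) {
  stopifnot(length(label_tables) >= 2)
  ids <- lapply(label_tables, function(x) sort(x$stay_id))
  for (k in seq_along(ids)[-1]) {
    if (!identical(ids[[1]], ids[[k]])) {
      d <- length(union(setdiff(ids[[1]], ids[[k]]), setdiff(ids[[k]], ids[[1]])))
      stop(sprintf("label tables differ in stay universe (symmetric difference: %d stays)", d),
           call. = FALSE)
    }
  }
  universe <- ids[[1]]
  memb <- data.frame(stay_id = universe, stringsAsFactors = FALSE)
  for (nm in names(label_tables)) {
    lt <- label_tables[[nm]]
    memb[[nm]] <- universe %in% lt$stay_id[lt$status == "case"]
  }
  uc <- upset_counts(memb)
  consensus_name <- paste(names(label_tables), collapse = "+")
  cons <- uc$combinations$count[uc$combinations$degree == length(label_tables)]
  list(combinations = uc$combinations,
       per_definition = uc$totals,
       n_union = uc$n_union,
       consensus = if (length(cons)) sum(cons) else 0L)
}
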