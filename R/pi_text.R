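# Keyword scanning of clinical notes for pressure-injury mentions, with a
# simple window-based negation detector and structured-dismissal filtering
# ("bedsore: none"). Intentionally rule-based: the goal is to flag spurious
# mentions such as "no bedsore observed", not full contextual understanding.

#' Default pressure-injury keyword lexicon
#'
#' Phrases are matched case-insensitively at word boundaries. A mention is
#' negated when a negation trigger occurs within `window_tokens` tokens
#' before it in the same sentence, or when a dismissal pattern (a regex
#' anchored immediately after the phrase) matches, as in `"bedsore: none"`.
#' Keyword inventories are site-specific; override any component for local
#' note conventions.
#'
#' @param phrases,negation_triggers,dismissal_patterns,window_tokens overrides.
#' @return a `pi_lexicon` list.
#' @export
default_lexicon <- function(phrases = c("pressure ulcer", "pressure injury",
                                        "pressure sore", "decubitus ulcer",
                                        "decubitus", "bedsore", "bed sore"),
                            negation_triggers = c("no", "not", "without", "denies",
                                                  "negative for", "free of",
                                                  "ruled out", "no evidence of"),
                            dismissal_patterns = c("^\\s*:\\s*(none|neg(\\.|ative)?|0|absent)\\b",
                                                   "^\\s*-\\s*none\\b"),
                            window_tokens = 5L) {
  stopifnot(length(phrases) >= 1, window_tokens >= 1)
  structure(list(phrases = tolower(phrases),
                 negation_triggers = tolower(negation_triggers),
                 dismissal_patterns = dismissal_patterns,
                 window_tokens = as.integer(window_tokens)),
            class = "pi_lexicon")
}

tokenize_words <- function(text) {
  toks <- strsplit(tolower(text), "[^a-z0-9]+")[[1]]
  toks[nzchar(toks)]
}

#' Is a keyword mention negated?
#'
#' A mention is negated when a negation trigger's token sequence lies within
#' the `window_tokens` tokens immediately preceding the mention inside the
#' same sentence (sentence boundaries: `.`, `!`, `?`, newline), or when a
#' dismissal pattern matches the text directly following the mention.
#'
#' @param text full note text.
#' @param start,end 0-based character span `[start, end)` of the mention.
#' @param lex a `pi_lexicon`.
#' @return logical.
#' @export
is_negated <- function(text, start, end, lex = default_lexicon()) {
  stopifnot(start >= 0, end <= nchar(text), start < end)
  # dismissal: structured "<kw>: none" style right after the span
  tail_txt <- substr(text, end + 1, nchar(text))
  for (pat in lex$dismissal_patterns) {
    if (grepl(pat, tail_txt, ignore.case = TRUE, perl = TRUE)) return(TRUE)
  }
  # same-sentence prefix before the span
  prefix <- substr(text, 1, start)
  sent_break <- regmatches(prefix, gregexpr("[.!?\n]", prefix))[[1]]
  if (length(sent_break)) {
    last_brk <- max(gregexpr("[.!?\n]", prefix)[[1]])
    prefix <- substr(prefix, last_brk + 1, nchar(prefix))
  }
  toks <- tokenize_words(prefix)
  if (!length(toks)) return(FALSE)
  window <- toks[max(1, length(toks) - lex$window_tokens + 1):length(toks)]
  for (trig in lex$negation_triggers) {
    tt <- tokenize_words(trig)
    nt <- length(tt)
    if (nt == 0 || nt > length(window)) next
    for (k in seq_len(length(window) - nt + 1)) {
      if (all(window[k:(k + nt - 1)] == tt)) return(TRUE)
    }
  }
  FALSE
}

phrase_regex <- function(phrase) {
  esc <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", phrase)
  paste0("\\b", gsub(" +", "[^a-z0-9]+", esc), "\\b")
}

#' Scan one clinical note for pressure-injury mentions
#'
#' Finds all non-overlapping matches of the lexicon phrases
#' (longest-phrase-first, so "decubitus ulcer" wins over "decubitus") and
#' flags each with its negation status.
#'
#' @param text note text.
#' @param lex a `pi_lexicon`.
#' @return data frame with 0-based `start`, `end` (span `[start, end)`),
#'   `phrase`, `negated`.
#' @export
scan_note <- function(text, lex = default_lexicon()) {
  empty <- data.frame(start = integer(), end = integer(),
                      phrase = character(), negated = logical(),
                      stringsAsFactors = FALSE)
  if (is.na(text) || !nzchar(text)) return(empty)
  low <- tolower(text)
  hits <- list()
  occupied <- rep(FALSE, nchar(low))
  for (ph in lex$phrases[order(-nchar(lex$phrases))]) {
    m <- gregexpr(phrase_regex(ph), low, perl = TRUE)[[1]]
    if (m[1] == -1) next
    len <- attr(m, "match.length")
    for (j in seq_along(m)) {
      s <- m[j]; e <- m[j] + len[j] - 1   # 1-based inclusive
      if (any(occupied[s:e])) next
      occupied[s:e] <- TRUE
      hits[[length(hits) + 1]] <- data.frame(
        start = s - 1L, end = e, phrase = substr(text, s, e),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) return(empty)
  out <- do.call(rbind, hits)
  out <- out[order(out$start), , drop = FALSE]
  out$negated <- vapply(seq_len(nrow(out)), function(i)
    is_negated(text, out$start[i], out$end[i], lex), logical(1))
  rownames(out) <- NULL
  out
}

#' Scan a batch of notes for pressure-injury mentions
#'
#' Vectorized driver over a notes data frame (as in a `cohort_store`).
#' Notes containing no lexicon substring are skipped cheaply before the
#' full span/negation analysis.
#'
#' @param notes data frame with `note_id`, `stay_id`, `ts`, `date_only`, `text`.
#' @param lex a `pi_lexicon`.
#' @return data frame of mentions: `note_id`, `stay_id`, `ts`, `date_only`,
#'   `start`, `end`, `phrase`, `negated`.
#' @export
scan_notes <- function(notes, lex = default_lexicon()) {
  empty <- data.frame(note_id = character(), stay_id = character(),
                      ts = as.POSIXct(character(), tz = "UTC"), date_only = logical(),
                      start = integer(), end = integer(), phrase = character(),
                      negated = logical(), stringsAsFactors = FALSE)
  if (nrow(notes) == 0) return(empty)
  low <- tolower(notes$text)
  any_hit <- rep(FALSE, nrow(notes))
  for (ph in lex$phrases) {
    # fixed substring prefilter: word-boundary check happens in scan_note
    any_hit <- any_hit | grepl(ph, low, fixed = TRUE)
  }
  idx <- which(any_hit)
  if (!length(idx)) return(empty)
  res <- lapply(idx, function(i) {
    m <- scan_note(notes$text[i], lex)
    if (nrow(m) == 0) return(NULL)
    cbind(data.frame(note_id = notes$note_id[i], stay_id = notes$stay_id[i],
                     ts = rep(notes$ts[i], nrow(m)),
                     date_only = notes$date_only[i] %||% FALSE,
                     stringsAsFactors = FALSE), m)
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) return(empty)
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Earliest positive keyword mention after a time threshold
#'
#' Returns the earliest non-negated, fully timestamped mention occurring
#' strictly later than `min_hours` after admission. Date-only notes carry no
#' hour resolution and never establish an event time.
#'
#' @param mentions data frame from [scan_notes()] for one stay.
#' @param admit_ts admission timestamp.
#' @param min_hours threshold in hours (strict `>`).
#' @return one-row data frame (the mention) or `NULL`.
#' @export
earliest_positive_mention <- function(mentions, admit_ts, min_hours = 24) {
  if (is.null(mentions) || nrow(mentions) == 0) return(NULL)
  keep <- !mentions$negated & !mentions$date_only & !is.na(mentions$ts) &
    hours_since(mentions$ts, admit_ts) > min_hours
  if (!any(keep)) return(NULL)
  cand <- mentions[keep, , drop = FALSE]
  cand[which.min(cand$ts), , drop = FALSE]
}
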