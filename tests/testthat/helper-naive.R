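# Deliberately naive, independent re-implementation of the four definition
# policies, written directly from the decision-dimension table and the
# labeling flowchart semantics. Kept structurally different from the package
# engine (token-based text scanning, hard-coded definition constants,
# per-stay nested loops) so a shared bug is unlikely.

NAIVE_DEFS <- list(
  ehapi = list(d1 = TRUE, d2 = 15, d3 = 24, d4 = 2, d5 = TRUE, d6 = TRUE,
               d7 = TRUE, d8 = FALSE, staging = TRUE, kw_cut = 24),
  cantrip = list(d1 = FALSE, d2 = 15, d3 = 48, d4 = 1, d5 = TRUE, d6 = TRUE,
                 d7 = FALSE, d8 = FALSE, staging = TRUE, kw_cut = 48),
  cramer = list(d1 = FALSE, d2 = 18, d3 = 24, d4 = 2, d5 = FALSE, d6 = FALSE,
                d7 = FALSE, d8 = FALSE, staging = TRUE, kw_cut = 24),
  sotoodeh = list(d1 = FALSE, d2 = 18, d3 = NA, d4 = NA, d5 = NA, d6 = TRUE,
                  d7 = FALSE, d8 = TRUE, staging = FALSE, kw_cut = 24)
)

NAIVE_ADM_ENC <- c(S1 = 1, S2 = 2, S3 = 3, S4 = 4, DTI = 4, UNSTAGEABLE = 0)
NAIVE_DIS_ENC <- c(S1 = 1, S2 = 2, S3 = 3, S4 = 4, DTI = 3, UNSTAGEABLE = 5)

# value string -> token, by substring inspection (independent of the
# package's regex map)
naive_token <- function(item_id, value) {
  if (!item_id %in% c("551", "552", "553", "224631", "224965")) return(NA_character_)
  v <- tolower(value)
  if (grepl("deep tiss", v)) return("DTI")
  if (grepl("unable to stage", v) || grepl("unstageable", v)) return("UNSTAGEABLE")
  if (grepl("red", v) && grepl("unbroken", v)) return("S1")
  if (grepl("part", v) && grepl("thickness", v)) return("S2")
  if (grepl("full thickness", v)) return("S3")
  if (grepl("through fascia", v) || grepl("through to bone", v)) return("S4")
  if (grepl("stage 1", v)) return("S1")
  if (grepl("stage 2", v)) return("S2")
  if (grepl("stage 3", v)) return("S3")
  if (grepl("stage 4", v)) return("S4")
  NA_character_
}

NAIVE_PHRASES <- c("pressure ulcer", "pressure injury", "pressure sore",
                   "decubitus ulcer", "decubitus", "bedsore", "bed sore")
NAIVE_TRIGGERS <- list("no", "not", "without", "denies", c("negative", "for"),
                       c("free", "of"), c("ruled", "out"), c("no", "evidence", "of"))

# token-sequence scan of one note: returns data.frame(negated) per mention
naive_scan <- function(text) {
  sentences <- strsplit(text, "[.!?\n]")[[1]]
  out <- logical(0)
  for (sent in sentences) {
    # structured dismissal: "<kw>: none" style inside the raw sentence
    toks <- strsplit(tolower(sent), "[^a-z0-9]+")[[1]]
    toks <- toks[nzchar(toks)]
    if (!length(toks)) next
    used <- rep(FALSE, length(toks))
    for (ph in NAIVE_PHRASES) {  # list is ordered longest-first already
      pt <- strsplit(ph, " ")[[1]]
      np <- length(pt)
      if (np > length(toks)) next
      for (s in seq_len(length(toks) - np + 1)) {
        if (any(used[s:(s + np - 1)])) next
        if (!all(toks[s:(s + np - 1)] == pt)) next
        used[s:(s + np - 1)] <- TRUE
        neg <- FALSE
        lo <- max(1, s - 5)
        if (s > 1) {
          win <- toks[lo:(s - 1)]
          for (tr in NAIVE_TRIGGERS) {
            nt <- length(tr)
            if (nt <= length(win)) {
              for (k in seq_len(length(win) - nt + 1)) {
                if (all(win[k:(k + nt - 1)] == tr)) { neg <- TRUE; break }
              }
            }
            if (neg) break
          }
        }
        # dismissal: phrase immediately followed by ": none" / "- none" etc.
        esc <- gsub(" ", "[^a-z0-9]+", ph)
        if (grepl(paste0(esc, "\\s*(:\\s*(none|neg(\\.|ative)?|0|absent)|-\\s*none)"),
                  tolower(sent))) neg <- TRUE
        out <- c(out, neg)
      }
    }
  }
  out
}

naive_label_cohort <- function(store, def_name) {
  d <- NAIVE_DEFS[[def_name]]
  res <- data.frame(stay_id = store$stays$stay_id, status = NA_character_,
                    route = NA_character_, exclusion_reason = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(store$stays))) {
    st <- store$stays[i, ]
    sid <- st$stay_id
    notes <- store$notes[store$notes$stay_id == sid, , drop = FALSE]
    status <- NULL; route <- "none"; reason <- NA_character_

    # mentions: hours + negation per note
    mention_h <- numeric(0); mention_neg <- logical(0); mention_dateonly <- logical(0)
    for (j in seq_len(nrow(notes))) {
      negs <- naive_scan(notes$text[j])
      if (length(negs)) {
        h <- as.numeric(difftime(notes$ts[j], st$admit_ts, units = "hours"))
        mention_h <- c(mention_h, rep(h, length(negs)))
        mention_neg <- c(mention_neg, negs)
        mention_dateonly <- c(mention_dateonly, rep(notes$date_only[j], length(negs)))
      }
    }
    # staging events: hours + tokens
    ce <- store$chart_events[store$chart_events$stay_id == sid, , drop = FALSE]
    ev_h <- numeric(0); ev_tok <- character(0)
    for (j in seq_len(nrow(ce))) {
      tok <- naive_token(ce$item_id[j], ce$value_text[j])
      if (!is.na(tok)) {
        ev_h <- c(ev_h, as.numeric(difftime(ce$ts[j], st$admit_ts, units = "hours")))
        ev_tok <- c(ev_tok, tok)
      }
    }

    if (nrow(notes) == 0) { status <- "excluded"; reason <- "no_notes" }
    else if (st$discharge_ts <= st$admit_ts) { status <- "excluded"; reason <- "bad_times" }
    else if (is.na(st$age_at_admission)) { status <- "excluded"; reason <- "missing_age" }
    else if (st$age_at_admission < d$d2) { status <- "excluded"; reason <- "under_age" }
    else if (d$staging &&
             any(ev_tok %in% c("S1", "S2", "S3", "S4") & ev_h <= d$d3)) {
      status <- "excluded"; reason <- "pi_on_admission"
    } else if (d$d6 && any(!mention_neg & mention_h <= 24)) {
      status <- "excluded"; reason <- "pi_on_admission"
    } else if (d$d1 && st$died_in_hospital) { status <- "excluded"; reason <- "deceased" }

    if (is.null(status)) {
      stage_fire_h <- Inf; kw_fire_h <- Inf; icd_fire <- FALSE
      if (d$staging && length(ev_h)) {
        h <- ev_h; tok <- ev_tok
        if (!d$d5) { keep <- !(tok %in% c("DTI", "UNSTAGEABLE")); h <- h[keep]; tok <- tok[keep] }
        if (length(h)) {
          adm <- 0
          for (j in seq_along(h)) if (h[j] <= d$d3) adm <- max(adm, NAIVE_ADM_ENC[[tok[j]]])
          dis <- NA; dis_t <- -Inf
          for (j in seq_along(h)) {
            v <- NAIVE_DIS_ENC[[tok[j]]]
            if (h[j] > d$d3 && v >= d$d4) {
              if (h[j] > dis_t || (h[j] == dis_t && v > dis)) { dis <- v; dis_t <- h[j] }
            }
          }
          if (!is.na(dis) && dis >= d$d4 && (!d$d7 || dis > adm))
            stage_fire_h <- min(h[h > d$d3])
        }
      }
      if (d$d6) {
        ok <- !mention_neg & !mention_dateonly & mention_h > d$kw_cut
        if (any(ok)) kw_fire_h <- min(mention_h[ok])
      }
      if (d$d8) {
        codes <- store$diagnoses$code[store$diagnoses$stay_id == sid]
        icd_fire <- any(grepl("^7070", codes) | grepl("^70725", codes))
      }
      if (is.finite(stage_fire_h) || is.finite(kw_fire_h)) {
        status <- "case"
        route <- if (stage_fire_h <= kw_fire_h) "staging" else "keyword"
      } else if (icd_fire) { status <- "case"; route <- "icd9" }
      else status <- "control"
    }
    res$status[i] <- status; res$route[i] <- route; res$exclusion_reason[i] <- reason
  }
  res
}
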