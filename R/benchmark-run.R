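# End-to-end benchmark driver: label the cohort under every definition,
# assign event timestamps (observed for stays with timed PI evidence,
# duration-matched for the rest), build leakage-safe documents, assemble
# shared test sets, train one classifier per definition, and compare the
# best definition against the rest with paired one-sided t tests.

# Earliest timed PI evidence (staging event or positive mention) strictly
# later than min_hours after admission, for every stay that has any.
evidence_timestamps <- function(staging_events, mentions, admit_ts, min_hours = 24) {
  se <- staging_events[hours_since(staging_events$ts, admit_ts[staging_events$stay_id]) > min_hours, , drop = FALSE]
  mn <- mentions[!mentions$negated & !mentions$date_only & !is.na(mentions$ts), , drop = FALSE]
  mn <- mn[hours_since(mn$ts, admit_ts[mn$stay_id]) > min_hours, , drop = FALSE]
  ev <- rbind(data.frame(stay_id = se$stay_id, ts = as.numeric(se$ts)),
              data.frame(stay_id = mn$stay_id, ts = as.numeric(mn$ts)))
  if (nrow(ev) == 0) return(stats::setNames(as.POSIXct(character(), tz = "UTC"), character()))
  agg <- tapply(ev$ts, ev$stay_id, min)
  out <- as.POSIXct(as.numeric(agg), origin = "1970-01-01", tz = "UTC")
  names(out) <- names(agg)
  out
}

#' Run the full HAPI definition benchmark on a cohort
#'
#' Implements the leakage-safe evaluation pipeline: (1) label the cohort
#' under each definition; (2) give every stay an event timestamp - stays
#' with timed PI evidence later than 24 h after admission take their first
#' evidence time, remaining stays take a rank-paired timestamp sampled from
#' the parametric fit of the evidence stays' note-duration distribution;
#' (3) concatenate each stay's notes strictly before its event timestamp
#' into a document (stays with none are excluded); (4) build shared test
#' sets (all consensus cases, all annotated disagreement stays, a fresh
#' random draw of consensus controls per set); (5) per definition, train on
#' its eligible stays outside the test pool with its own labels and score
#' every test set; (6) compare the best-mean-AUPRC definition against each
#' other one with paired one-sided t tests.
#'
#' @param store a `cohort_store`.
#' @param definitions named list of `hapi_definition`s.
#' @param classifier `"gradient_boosting"` or `"sequential_nn"`.
#' @param annotations optional named vector of manual labels for
#'   disagreement stays (see [construct_test_sets()]).
#' @param n_sets number of test sets (default 10).
#' @param test_prevalence target case fraction of each test set; sets the
#'   consensus-control subsample size (default 0.07).
#' @param n_controls explicit control subsample size (overrides
#'   `test_prevalence`).
#' @param lex,stage_item_map lexicon and staging-item map.
#' @param cv_folds,hyper_grid passed to [train_evaluate()].
#' @param vocab_size,seq_len passed to [vectorize()].
#' @param seed RNG seed for control matching, test-set sampling and training.
#' @return a `hapi_benchmark` list: `labels` (per definition), `evals`
#'   (per-definition `hapi_eval`), `comparisons` (paired tests of the best
#'   definition vs each other), `duration_model`, `documents` bookkeeping
#'   (`n_documents`, `n_dropped_no_notes`, `n_scrubbed_case_phrases`).
#' @export
benchmark_definitions <- function(store, definitions = builtin_definitions(),
                                  classifier = "gradient_boosting",
                                  annotations = character(),
                                  n_sets = 10L, test_prevalence = 0.07,
                                  n_controls = NULL,
                                  lex = default_lexicon(),
                                  stage_item_map = default_stage_item_map(),
                                  cv_folds = 5L, hyper_grid = NULL,
                                  vocab_size = 5000L, seq_len = 800L,
                                  seed = 1L) {
  stays <- store$stays
  admit <- stays$admit_ts; names(admit) <- stays$stay_id
  disch <- stays$discharge_ts; names(disch) <- stays$stay_id
  staging_events <- extract_staging_events(store$chart_events, stage_item_map, admit)
  mentions <- scan_notes(store$notes, lex)

  labels <- lapply(definitions, function(cfg)
    label_cohort(store, cfg, lex, stage_item_map,
                 mentions = mentions, staging_events = staging_events))

  # --- event timestamps ---
  evid_ts <- evidence_timestamps(staging_events, mentions, admit)
  timed_notes <- store$notes[!is.na(store$notes$ts), , drop = FALSE]
  first_note <- tapply(as.numeric(timed_notes$ts), timed_notes$stay_id, min)
  last_note <- tapply(as.numeric(timed_notes$ts), timed_notes$stay_id, max)

  evid_ids <- intersect(names(evid_ts), names(first_note))
  durations <- hours_since(evid_ts[evid_ids],
                           as.POSIXct(first_note[evid_ids], origin = "1970-01-01", tz = "UTC"))
  durations <- durations[durations > 0]
  model <- fit_duration_distribution(durations)

  ctrl_ids <- setdiff(names(first_note), names(evid_ts))
  controls <- data.frame(
    stay_id = ctrl_ids,
    first_note_ts = as.POSIXct(first_note[ctrl_ids], origin = "1970-01-01", tz = "UTC"),
    true_duration_hours = (last_note[ctrl_ids] - first_note[ctrl_ids]) / 3600,
    discharge_ts = disch[ctrl_ids], stringsAsFactors = FALSE)
  matched <- assign_control_timestamps(controls, model, seed = seed)

  event_ts <- c(evid_ts, stats::setNames(matched$event_ts, matched$stay_id))

  # --- documents ---
  docs <- build_documents(names(event_ts), event_ts, store$notes, lex)
  has_doc <- docs$stay_id
  stopifnot(all(documents_leakage_free(docs, lex)))

  # --- test sets ---
  part <- consensus_partition(labels)
  n_fixed_cases <- length(part$consensus_cases) +
    sum(annotations %in% c("case", "1", 1))
  n_ann_ctrl <- length(annotations) - sum(annotations %in% c("case", "1", 1))
  if (is.null(n_controls)) {
    n_controls <- max(1L, round(n_fixed_cases / test_prevalence) -
                        n_fixed_cases - n_ann_ctrl)
  }
  # only stays with documents can enter the experiments
  labels_doc <- lapply(labels, function(lt) lt[lt$stay_id %in% has_doc, , drop = FALSE])
  sets <- construct_test_sets(labels_doc, annotations, n_sets = n_sets,
                              n_controls = n_controls, seed = seed)

  get_docs <- function(ids) docs[match(ids, docs$stay_id), , drop = FALSE]

  # Per-partition training: model k trains on the definition's eligible
  # stays outside test set k, so every partition keeps a full-size training
  # split. Hyperparameters are selected by cross-validation on the first
  # partition and reused for the rest.
  evals <- list(); comparisons <- list()
  for (nm in names(definitions)) {
    lt <- labels_doc[[nm]]
    grid <- hyper_grid %||% default_hyper_grid(classifier)
    pr <- numeric(n_sets); roc <- numeric(n_sets); params <- NULL
    for (k in seq_len(n_sets)) {
      ts <- sets$test_sets[[k]]
      train_ids <- lt$stay_id[lt$status != "excluded" & !(lt$stay_id %in% ts$stay_id)]
      train <- list(documents = get_docs(train_ids),
                    labels = as.integer(lt$status[match(train_ids, lt$stay_id)] == "case"))
      e <- train_evaluate(train, list(list(documents = get_docs(ts$stay_id),
                                           labels = ts$label)),
                          classifier, cv_folds = cv_folds,
                          hyper_grid = if (k == 1) grid else params,
                          seed = seed + k,
                          vocab_size = vocab_size, seq_len = seq_len)
      if (k == 1) params <- as.data.frame(e$params)
      pr[k] <- e$auprc; roc[k] <- e$auroc
    }
    evals[[nm]] <- structure(list(classifier = classifier, params = as.list(params),
                                  auprc = pr, auroc = roc,
                                  auprc_mean = mean(pr), auprc_sd = stats::sd(pr),
                                  auroc_mean = mean(roc), auroc_sd = stats::sd(roc)),
                             class = "hapi_eval")
  }

  best <- names(evals)[which.max(vapply(evals, `[[`, numeric(1), "auprc_mean"))]
  for (nm in setdiff(names(evals), best)) {
    comparisons[[paste(best, "vs", nm)]] <- list(
      auprc = paired_onesided_ttest(evals[[best]]$auprc, evals[[nm]]$auprc),
      auroc = paired_onesided_ttest(evals[[best]]$auroc, evals[[nm]]$auroc))
  }

  structure(list(labels = labels, evals = evals, best = best,
                 comparisons = comparisons, duration_model = model,
                 test_sets = sets$test_sets,
                 n_documents = nrow(docs),
                 n_dropped_no_notes = length(event_ts) - nrow(docs),
                 n_scrubbed_case_phrases = sum(docs$n_scrubbed[docs$stay_id %in%
                   unlist(lapply(labels, function(lt) lt$stay_id[lt$status == "case" & lt$route != "icd9"]))])),
            class = "hapi_benchmark")
}

#' @export
print.hapi_benchmark <- function(x, ...) {
  cat("<hapi_benchmark>", length(x$evals), "definitions |", length(x$test_sets),
      "test sets | best:", x$best, "\n")
  for (nm in names(x$evals)) {
    e <- x$evals[[nm]]
    cat(sprintf("  %-10s AUPRC %.3f (%.3f)  AUROC %.3f (%.3f)\n",
                nm, e$auprc_mean, e$auprc_sd, e$auroc_mean, e$auroc_sd))
  }
  invisible(x)
}
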