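# Event timestamps, duration fitting, control matching, document
# construction, feature extraction, test-set assembly and metrics.

lex <- default_lexicon()

mk_model <- function(draws) {
  structure(list(family = "fixed", params = NULL, chi_square = 0,
                 bin_edges = NULL, fallback = FALSE,
                 sample = function(n) draws[seq_len(n)]),
            class = "duration_model")
}

test_that("case event timestamps take the earliest qualifying evidence", {
  stays <- basic_stay("s1")
  admit <- stats::setNames(stays$admit_ts, stays$stay_id)
  labels <- data.frame(stay_id = "s1", status = "case", route = "staging",
                       event_ts = NA, exclusion_reason = NA_character_)
  se <- data.frame(stay_id = "s1", ts = ADMIT0 + 30 * 3600, token = "S2",
                   raw_value = "", item_id = "551", stringsAsFactors = FALSE)
  mn <- scan_notes(note_at("s1", 40, "pressure ulcer noted"), lex)
  expect_equal(unname(case_event_timestamps(labels, se, mn, admit)),
               ADMIT0 + 30 * 3600)
  # mention only, at 26 h
  expect_equal(unname(case_event_timestamps(labels, se[0, ],
                                            scan_notes(note_at("s1", 26, "pressure ulcer"), lex),
                                            admit)),
               ADMIT0 + 26 * 3600)
  # staging at 20 h is inside the admission window; the 50-h mention wins
  se20 <- transform(se, ts = ADMIT0 + 20 * 3600)
  mn50 <- scan_notes(note_at("s1", 50, "pressure ulcer noted"), lex)
  expect_equal(unname(case_event_timestamps(labels, se20, mn50, admit)),
               ADMIT0 + 50 * 3600)
  # a case with no timed evidence is an inconsistency
  expect_error(case_event_timestamps(labels, se20, mn50[0, ], admit), "no timed")
})

test_that("duration fitting recovers a known family and falls back when degenerate", {
  set.seed(1)
  x <- rexp(1000, rate = 1 / 48)
  m <- fit_duration_distribution(x)
  expect_equal(m$family, "exponential")
  expect_lt(abs(1 / m$params[["rate"]] - 48) / 48, 0.1)
  expect_false(m$fallback)

  # single candidate: that family is returned
  m2 <- fit_duration_distribution(x, candidates = "weibull")
  expect_equal(m2$family, "weibull")

  # identical durations: empirical fallback, flagged
  m3 <- fit_duration_distribution(rep(24, 50))
  expect_true(m3$fallback)
  expect_equal(m3$family, "empirical")
  expect_true(all(m3$sample(10) == 24))

  # too few observations: fallback
  m4 <- fit_duration_distribution(rexp(10, 1 / 48))
  expect_true(m4$fallback)
})

test_that("control offsets follow the hand-worked rank pairing", {
  # true durations 3, 4, 10 days; sampled draws sort to 2, 5, 9 days
  controls <- data.frame(
    stay_id = c("A", "B", "C"),
    first_note_ts = rep(ADMIT0, 3),
    true_duration_hours = c(3, 4, 10) * 24,
    discharge_ts = ADMIT0 + 30 * 86400)
  out <- assign_control_timestamps(controls, mk_model(c(9, 2, 5) * 24), seed = 1)
  m <- match(c("A", "B", "C"), out$stay_id)
  expect_equal(out$offset_hours[m], c(min(2, 3), min(5, 4), min(9, 10)) * 24)
  expect_equal(out$event_ts[m], ADMIT0 + c(2, 4, 9) * 86400)

  # adversarial draws beyond discharge are capped at discharge
  controls$discharge_ts <- ADMIT0 + 3.5 * 86400
  out2 <- assign_control_timestamps(controls, mk_model(c(500, 500, 500) * 24), seed = 1)
  expect_true(all(out2$event_ts <= controls$discharge_ts[1]))
  expect_equal(out2$event_ts[out2$stay_id == "C"], ADMIT0 + 3.5 * 86400)

  # empty control list
  expect_equal(nrow(assign_control_timestamps(controls[0, ], mk_model(1), 1)), 0)
})

test_that("control offsets never exceed the true duration (rank-pairing bound)", {
  set.seed(8)
  controls <- data.frame(
    stay_id = as.character(1:100),
    first_note_ts = rep(ADMIT0, 100),
    true_duration_hours = runif(100, 1, 400),
    discharge_ts = ADMIT0 + 600 * 3600)
  model <- fit_duration_distribution(rexp(100, 1 / 48))
  out <- assign_control_timestamps(controls, model, seed = 4)
  m <- match(controls$stay_id, out$stay_id)
  expect_true(all(out$offset_hours[m] <= controls$true_duration_hours + 1e-9))
})

test_that("documents contain exactly the notes before the event timestamp", {
  notes <- rbind(note_at("s1", 1, "first note"),
                 note_at("s1", 10, "second note"),
                 note_at("s1", 30, "third note"))
  ev <- stats::setNames(ADMIT0 + 20 * 3600, "s1")
  docs <- build_documents("s1", ev, notes, lex)
  expect_equal(docs$n_notes, 2)
  expect_equal(docs$text, "first note\nsecond note")

  # all notes at/after the event: the stay is excluded
  ev0 <- stats::setNames(ADMIT0 + 1 * 3600, "s1")
  expect_equal(nrow(build_documents("s1", ev0, notes, lex)), 0)

  # residual non-negated phrases are scrubbed and counted
  notes2 <- rbind(note_at("s2", 1, "early pressure ulcer mention"),
                  note_at("s2", 2, "no bedsore observed"))
  ev2 <- stats::setNames(ADMIT0 + 20 * 3600, "s2")
  docs2 <- build_documents("s2", ev2, notes2, lex)
  expect_equal(docs2$n_scrubbed, 1)
  expect_true(all(documents_leakage_free(docs2, lex)))
  expect_true(grepl("no bedsore observed", docs2$text))  # negated text is kept
})

test_that("tf-idf follows the smoothed-idf formula with L2 rows", {
  docs <- data.frame(stay_id = c("a", "b"), text = c("apple apple pear", "apple"),
                     stringsAsFactors = FALSE)
  v <- vectorize(docs, "tfidf", vocab_size = 10)
  X <- as.matrix(v$features)
  idf_apple <- log(3 / 3) + 1          # df = 2, n = 2
  idf_pear <- log(3 / 2) + 1           # df = 1
  raw_a <- c(apple = 2 * idf_apple, pear = 1 * idf_pear)
  expect_equal(X["a", c("apple", "pear")], raw_a / sqrt(sum(raw_a^2)))
  expect_equal(unname(X["b", "apple"]), 1)  # single-term row normalizes to 1
  # test-split reuse: unseen words are ignored
  v2 <- vectorize(data.frame(stay_id = "c", text = "apple kiwi"), "tfidf",
                  model = v$model)
  expect_equal(colnames(v2$features), v$model$vocabulary)
  expect_equal(unname(as.matrix(v2$features)["c", "pear"]), 0)
})

test_that("sequences truncate to length, pad, and map unseen words to OOV", {
  long <- paste(rep("tok", 801), collapse = " ")
  v <- vectorize(data.frame(stay_id = "a", text = long), "sequence",
                 vocab_size = 10, seq_len = 800)
  expect_equal(ncol(v$features), 800)
  expect_true(all(v$features == 3))  # the single vocab word
  v2 <- vectorize(data.frame(stay_id = "b", text = "tok novel tok"), "sequence",
                  seq_len = 5, model = v$model)
  expect_equal(unname(v2$features[1, ]), c(3L, 2L, 3L, 1L, 1L))  # word, OOV, word, pad, pad
})

test_that("test sets share fixed members and differ only in control draws", {
  ids <- sprintf("t%02d", 1:30)
  mk <- function(cases, excluded = character()) {
    data.frame(stay_id = ids,
               status = ifelse(ids %in% excluded, "excluded",
                               ifelse(ids %in% cases, "case", "control")),
               stringsAsFactors = FALSE)
  }
  # consensus cases t01 t02; disagreement t03-t05 (case under A only)
  labs <- list(A = mk(c("t01", "t02", "t03", "t04", "t05")),
               B = mk(c("t01", "t02")))
  ann <- c(t03 = "case", t04 = "control", t05 = "control")
  sets <- construct_test_sets(labs, ann, n_sets = 2, n_controls = 5, seed = 9)
  fixed <- c("t01", "t02", "t03", "t04", "t05")
  for (ts in sets$test_sets) {
    expect_true(all(fixed %in% ts$stay_id))
    expect_equal(nrow(ts), 10)
    expect_equal(sum(ts$label), 3)  # 2 consensus + 1 annotated case
  }
  expect_false(setequal(sets$test_sets[[1]]$stay_id, sets$test_sets[[2]]$stay_id))
  # per-definition training sets are disjoint from their test sets
  for (d in names(labs)) {
    for (k in 1:2) {
      expect_length(intersect(sets$train_sets[[d]][[k]]$stay_id,
                              sets$test_sets[[k]]$stay_id), 0)
    }
  }
  # excluded stays never enter training
  labs2 <- list(A = mk(c("t01", "t02"), excluded = "t10"), B = mk(c("t01", "t02")))
  sets2 <- construct_test_sets(labs2, character(), n_sets = 1, n_controls = 5, seed = 1)
  expect_false("t10" %in% sets2$train_sets$A[[1]]$stay_id)

  # oversized control request errors
  expect_error(construct_test_sets(labs, ann, n_sets = 1, n_controls = 26, seed = 1),
               "exceeds")
  # annotations must reference disagreement stays
  expect_error(construct_test_sets(labs, c(t01 = "case"), n_sets = 1,
                                   n_controls = 5, seed = 1),
               "not definition-disagreement")
})

test_that("metrics agree with an independent implementation and hand values", {
  set.seed(3)
  y <- rbinom(200, 1, 0.3)
  s <- runif(200) + 0.4 * y
  expect_equal(auroc(s, y),
               as.numeric(suppressMessages(pROC::auc(y, s, direction = "<"))))
  # hand-computed average precision
  expect_equal(auprc(c(0.9, 0.8, 0.7, 0.1), c(1, 0, 1, 0)),
               0.5 * 1 + 0.5 * (2 / 3))
  expect_equal(auroc(c(0.9, 0.8, 0.7, 0.1), c(1, 0, 1, 0)), 0.75)
  # bounds
  expect_true(auprc(s, y) >= 0 && auprc(s, y) <= 1)
})

test_that("the paired one-sided t test matches the closed form and flags degeneracy", {
  a <- c(0.5, 0.6, 0.7, 0.8, 0.9)
  expect_equal(paired_onesided_ttest(a, a)$p_value, 0.5)
  expect_true(paired_onesided_ttest(a, a)$degenerate)
  r0 <- paired_onesided_ttest(a + 0.1, a)
  expect_equal(r0$p_value, 0)
  expect_true(r0$degenerate)

  d <- c(0.02, 0.01, 0.03, 0.02, 0.02)
  b <- c(0.40, 0.42, 0.41, 0.44, 0.43)
  r <- paired_onesided_ttest(b + d, b)
  t_hand <- mean(d) / (sd(d) / sqrt(5))
  expect_equal(r$t, t_hand)
  expect_equal(r$p_value, pt(t_hand, df = 4, lower.tail = FALSE))
  expect_false(r$degenerate)
  expect_error(paired_onesided_ttest(1:3, 1:4), "equal-length")
})
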