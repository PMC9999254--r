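# Definition configs, common inclusion criteria, routing, and cohort-level
# labeling properties.

defs <- builtin_definitions()

label_one <- function(store, cfg) label_cohort(store, cfg)

test_that("built-in definitions carry the published decision dimensions", {
  e <- defs$ehapi
  expect_true(e$exclude_deceased)
  expect_equal(e$min_age_years, 15)
  expect_equal(e$admission_cutoff_hours, 24)
  expect_equal(e$min_stage, 2L)
  expect_true(e$include_dti_unstageable)
  expect_true(e$use_note_keywords)
  expect_true(e$require_deterioration)
  expect_false(e$use_icd9)

  ca <- defs$cantrip
  expect_false(ca$exclude_deceased)
  expect_equal(ca$min_age_years, 15)
  expect_equal(ca$admission_cutoff_hours, 48)
  expect_equal(ca$min_stage, 1L)
  expect_false(ca$require_deterioration)
  expect_equal(ca$keyword_cutoff_hours, 48)

  cr <- defs$cramer
  expect_equal(cr$min_age_years, 18)
  expect_false(cr$include_dti_unstageable)
  expect_false(cr$use_note_keywords)

  so <- defs$sotoodeh
  expect_false(so$use_staging_events)
  expect_true(so$use_icd9)
  expect_true(so$use_note_keywords)
  expect_equal(so$min_age_years, 18)
})

test_that("a staging definition without a cutoff or minimum stage is rejected", {
  expect_error(definition_config("bad", use_staging_events = TRUE,
                                 admission_cutoff_hours = NA), "min_stage|cutoff")
})

test_that("common inclusion criteria fire in order with the documented reasons", {
  # no notes
  st <- basic_stay("s1")
  lab <- label_one(mini_store(st), defs$ehapi)
  expect_equal(lab$exclusion_reason, "no_notes")
  # under age under EHAPI (minimum 15)
  st14 <- basic_stay("s1", age = 14)
  lab <- label_one(mini_store(st14, notes = note_at("s1", 2, "stable")), defs$ehapi)
  expect_equal(lab$exclusion_reason, "under_age")
  # age 16: eligible under EHAPI/CANTRIP but under-age for Cramer (minimum 18)
  st16 <- basic_stay("s1", age = 16)
  store16 <- mini_store(st16, notes = note_at("s1", 2, "stable"))
  expect_equal(label_one(store16, defs$ehapi)$status, "control")
  expect_equal(label_one(store16, defs$cramer)$exclusion_reason, "under_age")
  # deceased: excluded under EHAPI only
  std <- basic_stay("s1", died = TRUE)
  stored <- mini_store(std, notes = note_at("s1", 2, "stable"))
  expect_equal(label_one(stored, defs$ehapi)$exclusion_reason, "deceased")
  expect_equal(label_one(stored, defs$cantrip)$status, "control")
})

test_that("a numeric stage charted inside the admission window excludes the stay", {
  # S2 at 30 h: inside CANTRIP's 48-h window, outside EHAPI's 24-h window
  store <- mini_store(basic_stay("s1"),
                      chart = chart_at("s1", 30, cv_value("S2")),
                      notes = note_at("s1", 2, "stable"))
  expect_equal(label_one(store, defs$cantrip)$exclusion_reason, "pi_on_admission")
  lab <- label_one(store, defs$ehapi)
  expect_equal(lab$status, "case")  # new S2 beyond 24 h
  # an early non-negated keyword mention also counts as admission documentation
  store2 <- mini_store(basic_stay("s1"),
                       notes = rbind(note_at("s1", 3, "pressure ulcer on admission"),
                                     note_at("s1", 40, "stable")))
  expect_equal(label_one(store2, defs$ehapi)$exclusion_reason, "pi_on_admission")
  # admission DTI / unstageable do not trigger the screen
  store3 <- mini_store(basic_stay("s1"),
                       chart = chart_at("s1", 10, cv_value("UNSTAGEABLE")),
                       notes = note_at("s1", 2, "stable"))
  expect_equal(label_one(store3, defs$ehapi)$status, "control")
})

test_that("each route labels cases with the right route and event timestamp", {
  # staging route: no admission PI, new S2 at 30 h
  store <- mini_store(basic_stay("s1"),
                      chart = chart_at("s1", 30, cv_value("S2")),
                      notes = note_at("s1", 2, "stable"))
  lab <- label_one(store, defs$ehapi)
  expect_equal(lab$status, "case")
  expect_equal(lab$route, "staging")
  expect_equal(lab$event_ts, ADMIT0 + 30 * 3600)

  # keyword route: no staging events, positive mention at 40 h
  store <- mini_store(basic_stay("s1"),
                      notes = rbind(note_at("s1", 2, "stable"),
                                    note_at("s1", 40, "sacral pressure ulcer noted")))
  lab <- label_one(store, defs$ehapi)
  expect_equal(lab$status, "case")
  expect_equal(lab$route, "keyword")
  expect_equal(lab$event_ts, ADMIT0 + 40 * 3600)

  # ICD-9 route under Sotoodeh: untimed
  store <- mini_store(basic_stay("s1"),
                      notes = note_at("s1", 2, "stable"),
                      dx = data.frame(stay_id = "s1", code = "70703", seq = 1L))
  lab <- label_one(store, defs$sotoodeh)
  expect_equal(lab$status, "case")
  expect_equal(lab$route, "icd9")
  expect_true(is.na(lab$event_ts))
  # same stay is a control under EHAPI (no ICD-9 route there)
  expect_equal(label_one(store, defs$ehapi)$status, "control")

  # Cramer ignores DTI-only trajectories entirely (60 h: past CANTRIP's 48-h
  # window, so CANTRIP's staging route can fire)
  store <- mini_store(basic_stay("s1"),
                      chart = chart_at("s1", 60, cv_value("DTI")),
                      notes = note_at("s1", 2, "stable"))
  expect_equal(label_one(store, defs$cramer)$status, "control")
  expect_equal(label_one(store, defs$cantrip)$status, "case")
})

test_that("CANTRIP's date of event is strictly later than 48 hours", {
  store <- mini_store(basic_stay("s1"),
                      notes = rbind(note_at("s1", 30, "stable"),
                                    note_at("s1", 47, "pressure ulcer found")))
  # a mention at 47 h is past the 24-h admission screen but not > 48 h:
  # not a CANTRIP case
  expect_equal(label_one(store, defs$cantrip)$status, "control")
  # with a second mention at 49 h, CANTRIP's event is the 49-h mention while
  # EHAPI's is the 47-h one
  store2 <- mini_store(basic_stay("s1"),
                       notes = rbind(note_at("s1", 30, "stable"),
                                     note_at("s1", 47, "pressure ulcer found"),
                                     note_at("s1", 49, "pressure ulcer dressed")))
  expect_equal(label_one(store2, defs$ehapi)$event_ts, ADMIT0 + 47 * 3600)
  expect_equal(label_one(store2, defs$cantrip)$event_ts, ADMIT0 + 49 * 3600)
})

test_that("every stay gets exactly one status and labeling is deterministic", {
  sim <- generate_cohort(generator_params(n_stays = 200, seed = 31))
  store <- as_cohort_store(sim)
  lab1 <- label_cohort(store, defs$ehapi)
  lab2 <- label_cohort(store, defs$ehapi)
  expect_identical(lab1, lab2)
  expect_equal(nrow(lab1), 200)
  expect_true(all(lab1$status %in% c("case", "control", "excluded")))
  # cases have a route; excluded stays have a reason
  expect_true(all(lab1$route[lab1$status == "case"] != "none"))
  expect_true(all(!is.na(lab1$exclusion_reason[lab1$status == "excluded"])))
  expect_true(all(is.na(lab1$exclusion_reason[lab1$status != "excluded"])))
  # timed-route cases carry an event timestamp
  timed <- lab1$status == "case" & lab1$route %in% c("staging", "keyword")
  expect_true(all(!is.na(lab1$event_ts[timed])))
})

test_that("an empty store labels to an empty table with zero eligible stays", {
  store <- mini_store(basic_stay("s1")[0, ])
  lab <- label_cohort(store, defs$ehapi)
  expect_equal(nrow(lab), 0)
  s <- label_summary(lab)
  expect_equal(s$n_eligible, 0)
  expect_true(is.na(s$prevalence_pct))
})

test_that("removing the notes of a keyword-route case never creates a staging case", {
  store <- mini_store(basic_stay("s1"),
                      notes = rbind(note_at("s1", 2, "stable"),
                                    note_at("s1", 40, "pressure injury on sacrum")))
  lab <- label_one(store, defs$ehapi)
  expect_equal(lab$route, "keyword")
  store$notes <- store$notes[0, ]
  lab2 <- label_one(store, defs$ehapi)
  expect_equal(lab2$status, "excluded")
  expect_equal(lab2$exclusion_reason, "no_notes")
})

test_that("relaxing minimum stage or deterioration never loses cases", {
  sim <- generate_cohort(generator_params(n_stays = 400, seed = 13))
  store <- as_cohort_store(sim)
  base <- defs$ehapi
  n_base <- label_summary(label_cohort(store, base))$n_case

  relax_stage <- definition_config("ehapi_s1", exclude_deceased = TRUE,
    min_age_years = 15, admission_cutoff_hours = 24, min_stage = 1L,
    include_dti_unstageable = TRUE, use_note_keywords = TRUE,
    require_deterioration = TRUE, keyword_cutoff_hours = 24)
  relax_det <- definition_config("ehapi_nodet", exclude_deceased = TRUE,
    min_age_years = 15, admission_cutoff_hours = 24, min_stage = 2L,
    include_dti_unstageable = TRUE, use_note_keywords = TRUE,
    require_deterioration = FALSE, keyword_cutoff_hours = 24)

  expect_gte(label_summary(label_cohort(store, relax_stage))$n_case, n_base)
  expect_gte(label_summary(label_cohort(store, relax_det))$n_case, n_base)
})

test_that("labeling matches the naive transcription on small random cohorts", {
  for (s in c(101, 102)) {
    sim <- generate_cohort(generator_params(n_stays = 150, seed = s,
                                            target_prevalence = 0.15,
                                            distractor_rate = 0.15))
    store <- as_cohort_store(sim)
    for (nm in names(defs)) {
      lab <- label_cohort(store, defs[[nm]])
      nv <- naive_label_cohort(store, nm)
      m <- match(nv$stay_id, lab$stay_id)
      expect_equal(lab$status[m], nv$status, info = paste(s, nm))
      expect_equal(lab$route[m], nv$route, info = paste(s, nm))
    }
  }
})
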