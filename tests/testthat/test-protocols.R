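test_that("pack management keeps names unique among active packs, retirement is soft", {
  store <- eav_store("T1")
  p <- add_pack(store, "1H")
  expect_identical(list_packs(store)$name, "1H")
  expect_error(add_pack(store, "1H"), class = "fieldsync_invalid")
  retire_pack(store, p)
  expect_identical(nrow(list_packs(store)), 0L)
  expect_identical(nrow(list_packs(store, include_inactive = TRUE)), 1L)
  # the name is free again once its bearer is retired
  expect_no_error(add_pack(store, "1H"))
})

test_that("individuals join active packs, removal is soft and blocks new sessions", {
  pop <- tiny_population()
  roster <- pack_roster(pop$store, pop$pack)
  expect_identical(nrow(roster), 6L)
  expect_error(
    add_individual(pop$store, pop$pack, "x", "F",
                   pop$ref_date + 5, today = pop$ref_date),
    class = "fieldsync_invalid"
  )
  remove_individual(pop$store, pop$m2)
  expect_false(pop$m2 %in% pack_roster(pop$store, pop$pack)$entity_id)
  session <- open_session(pop)
  expect_error(record_presence(session, pop$m2, TRUE), class = "fieldsync_gating")
})

test_that("age arithmetic uses day counts over a 30.4375-day month", {
  expect_identical(age_months("2015-01-01", "2015-01-01"), 0)
  expect_equal(age_months("2015-01-01", "2015-11-12"), 315 / 30.4375)
  expect_equal(age_months("2015-01-01", "2015-10-01"), 273 / 30.4375)
  expect_error(age_months("2015-01-01", "2014-12-31"), class = "fieldsync_invalid")
})

test_that("pregnancy eligibility is female-only and strictly over 10 months", {
  store <- eav_store("T1")
  p <- add_pack(store, "1H")
  ref <- as.Date("2015-11-12")
  m <- add_individual(store, p, "m", "M", ref - 2000, today = ref)
  f_under <- add_individual(store, p, "fu", "F", ref - 304, today = ref)
  f_over <- add_individual(store, p, "fo", "F", ref - 315, today = ref)
  expect_false(eligible_for_pregnancy(store, m, ref))
  expect_false(eligible_for_pregnancy(store, f_under, ref))  # 9.988 months
  expect_true(eligible_for_pregnancy(store, f_over, ref))    # 10.349 months
  # exact boundary is rejected: with 1-day months a 10-day-old female is
  # exactly 10.0 "months" old, and the threshold is strict
  f10 <- add_individual(store, p, "f10", "F", ref - 10, today = ref)
  cfg1 <- protocol_config(month_days = 1)
  expect_identical(age_months("2015-11-02", ref, 1), 10)
  expect_false(eligible_for_pregnancy(store, f10, ref, cfg1))
})

test_that("a visit logs GPS on the 3-minute cadence with a fix at the start", {
  pop <- tiny_population()
  t0 <- utc(paste(pop$ref_date, "08:00:00"))
  cases <- list(list(min = 20, fixes = 7L), list(min = 25, fixes = 9L),
                list(min = 0, fixes = 1L), list(min = 18, fixes = 6L))
  for (cs in cases) {
    session <- start_visit(pop$store, pop$pack, t0)
    end_visit(session, t0 + cs$min * 60)
    track <- gps_track(session)
    expect_identical(nrow(track), cs$fixes)
    if (nrow(track) > 1) {
      expect_true(all(diff(track$t_seconds) == 180L))
    }
    expect_true(all(track$lat >= -90 & track$lat <= 90))
    t0 <- t0 + 86400  # next day, avoid the open-session guard
  }
})

test_that("visits enforce the session lifecycle", {
  pop <- tiny_population()
  t0 <- utc(paste(pop$ref_date, "08:00:00"))
  session <- start_visit(pop$store, pop$pack, t0)
  expect_error(start_visit(pop$store, pop$pack, t0 + 60), class = "fieldsync_invalid")
  expect_error(end_visit(session, t0 - 60), class = "fieldsync_invalid")
  record_presence(session, pop$adult_f, TRUE)
  end_visit(session, t0 + 25 * 60)
  expect_error(record_weight(session, pop$adult_f, 1200L), class = "fieldsync_invalid")
  # a new session the same day is allowed once the first is closed
  expect_no_error(start_visit(pop$store, pop$pack, t0 + 3600))
})

test_that("presence gates weights and status records", {
  pop <- tiny_population()
  session <- open_session(pop, present = c(pop$adult_f, pop$adult_m, pop$pup))
  # absent individual: no weight
  expect_error(record_weight(session, pop$f2, 1200L), class = "fieldsync_gating")
  # presence map covers the roster
  pm <- presence_map(session)
  expect_identical(nrow(pm), 6L)
  expect_identical(sum(pm$present), 3L)

  wid <- record_weight(session, pop$adult_f, 1234L, "morning")
  expect_identical(get_entity(pop$store, wid)$attributes$grams, 1234L)
  expect_error(record_weight(session, pop$adult_f, 0L), class = "fieldsync_invalid")

  # pregnancy: male and under-age female rejected, adult female accepted
  expect_error(record_status(session, "pregnancy", individual = pop$adult_m),
               class = "fieldsync_gating")
  expect_error(record_status(session, "pregnancy", individual = pop$young_f),
               class = "fieldsync_gating")
  expect_no_error(record_status(session, "pregnancy", individual = pop$adult_f))

  # mate-guard requires correct sexes, both present
  expect_error(record_status(session, "mate-guard", male = pop$adult_f,
                             female = pop$adult_m, strength = 2, accuracy = 3),
               class = "fieldsync_gating")
  expect_error(record_status(session, "mate-guard", male = pop$adult_m,
                             female = pop$f2, strength = 2, accuracy = 3),
               class = "fieldsync_gating")  # f2 absent
  mg <- record_status(session, "mate-guard", male = pop$adult_m,
                      female = pop$adult_f, strength = 2, accuracy = 3,
                      primary = TRUE)
  expect_true(get_entity(pop$store, mg)$attributes$primary)

  # escort: pup must be a dependent pup, both present
  expect_error(record_status(session, "escort", pup = pop$adult_m,
                             escort = pop$adult_f, strength = 1, accuracy = 1),
               class = "fieldsync_gating")
  expect_no_error(record_status(session, "escort", pup = pop$pup,
                                escort = pop$adult_f, strength = 1, accuracy = 1))

  # babysit: inferred evidence implies absence; observed requires presence
  expect_no_error(record_status(session, "babysit", individual = pop$f2,
                                evidence = "inferred"))
  expect_error(record_status(session, "babysit", individual = pop$adult_f,
                             evidence = "inferred"), class = "fieldsync_gating")
  expect_error(record_status(session, "babysit", individual = pop$f2,
                             evidence = "observed"), class = "fieldsync_gating")
  # an inapplicable screen can be skipped explicitly
  skip_screen(session, "escort")
  expect_true(get_entity(pop$store, session$id)$attributes$`skip-escort`)
})

test_that("focal follows gate the protocol, count scans, and respect pauses", {
  pop <- tiny_population()
  t0 <- utc(paste(pop$ref_date, "09:00:00"))
  expect_error(start_focal(pop$store, "oestrus-female", pop$adult_m, t0),
               class = "fieldsync_gating")
  expect_error(start_focal(pop$store, "pup", pop$adult_f, t0),
               class = "fieldsync_gating")

  f <- start_focal(pop$store, "oestrus-female", pop$adult_f, t0)
  expect_identical(nrow(focal_scans(f)), 0L)
  expect_identical(fieldsync:::focal_state(f), "running")
  expect_identical(remaining_seconds(f, t0), 1200)

  sid <- record_scan(f, 3, nearest = pop$adult_m, within_2m = c(pop$adult_m, pop$f2))
  expect_error(record_scan(f, 3, nearest = pop$f2), class = "fieldsync_invalid")
  expect_error(record_scan(f, 4, nearest = pop$adult_f), class = "fieldsync_invalid")
  # nearest auto-included in within-2m
  s5 <- record_scan(f, 5, nearest = pop$adult_m, within_2m = pop$f2)
  scans <- focal_scans(f)
  expect_setequal(scans$within_2m[scans$minute_index == 5][[1]],
                  c(pop$adult_m, pop$f2))

  # pause for 5 minutes at t=10: completion at wall-clock 25 minutes
  pause_focal(f, t0 + 600)
  expect_error(pause_focal(f, t0 + 610), class = "fieldsync_invalid")
  expect_error(record_scan(f, 11, nearest = pop$adult_m), class = "fieldsync_invalid")
  resume_focal(f, t0 + 900)
  expect_error(complete_focal(f, t0 + 1200), class = "fieldsync_invalid")
  complete_focal(f, t0 + 1500)
  scans <- focal_scans(f)
  expect_identical(nrow(scans), 20L)
  expect_identical(sort(scans$minute_index), 1:20)
  expect_identical(sum(!scans$missed), 2L)
  expect_identical(fieldsync:::focal_paused_seconds(f), 300L)

  # interactions: focal excluded as partner; affiliative never has a winner
  f2 <- start_focal(pop$store, "pregnant-female", pop$f2, t0 + 7200)
  expect_error(record_interaction(f2, "agonistic", partner = pop$f2),
               class = "fieldsync_invalid")
  i1 <- record_interaction(f2, "agonistic", partner = pop$adult_m,
                           initiator = "focal", intensity = "attack",
                           context = "food", winner = "focal")
  expect_identical(get_entity(pop$store, i1)$attributes$winner, "focal")
  i2 <- record_interaction(f2, "affiliative", partner = pop$adult_m,
                           winner = "partner")
  expect_identical(get_entity(pop$store, i2)$attributes$winner, "none")
  abort_focal(f2, t0 + 7800)
  expect_identical(fieldsync:::focal_state(f2), "aborted")
  expect_error(record_interaction(f2, "affiliative", partner = pop$adult_m),
               class = "fieldsync_invalid")
  # partial data retained after an abort
  expect_identical(nrow(query_entities(pop$store, "focal-interaction",
                                       follow = f2$id)), 2L)
})

test_that("group events require their type-specific details", {
  pop <- tiny_population()
  t0 <- utc(paste(pop$ref_date, "10:00:00"))
  other <- add_pack(pop$store, "2B")
  expect_error(
    record_group_event(pop$store, pop$pack, "intergroup-interaction", t0),
    class = "fieldsync_invalid"
  )
  e1 <- record_group_event(pop$store, pop$pack, "intergroup-interaction", t0,
                           other_pack = other, outcome = "other-group-retreated",
                           participants = c(pop$adult_m, pop$m2))
  expect_identical(get_entity(pop$store, e1)$attributes$outcome, "other-group-retreated")
  e2 <- record_group_event(pop$store, pop$pack, "alarm", t0,
                           cause = "predator-sighting")
  expect_identical(get_entity(pop$store, e2)$attributes$cause, "predator-sighting")
  e3 <- record_group_event(pop$store, pop$pack, "movement", t0,
                           target = "water-source", direction = "towards")
  expect_identical(get_entity(pop$store, e3)$attributes$target, "water-source")
  expect_error(record_group_event(pop$store, pop$pack, "note", t0),
               class = "fieldsync_invalid")
  note <- record_group_event(pop$store, pop$pack, "note", t0,
                             free_text = "weights for 703, 705 swapped; fix tomorrow")
  expect_identical(get_entity(pop$store, note)$attributes$`free-text`,
                   "weights for 703, 705 swapped; fix tomorrow")
  expect_identical(get_entity(pop$store, note)$entity_type, "note")
})

test_that("review lists a session's records and edits re-run gating", {
  pop <- tiny_population()
  session <- open_session(pop, present = c(pop$adult_f, pop$adult_m))
  wid <- record_weight(session, pop$adult_f, 1334L, "morning")
  listing <- review_records(pop$store, session$id)
  expect_true(wid %in% listing$record_id)
  expect_true(session$id %in% listing$record_id)
  expect_true("weight" %in% listing$record_type)

  # correct the typo'd weight: entry is dirty again afterwards
  for (i in seq_len(nrow(dirty_entries(pop$store)))) {
    d <- dirty_entries(pop$store)[1, ]
    mark_synced(pop$store, d$entity_id, d$attribute, 1L)
  }
  expect_identical(nrow(dirty_entries(pop$store)), 0L)
  edit_record(pop$store, wid, "grams", 1234L)
  d <- dirty_entries(pop$store)
  expect_identical(nrow(d), 1L)
  expect_identical(d$entity_id, wid)

  # an edit cannot re-point a weight at an absent individual...
  expect_error(edit_record(pop$store, wid, "individual", pop$f2),
               class = "fieldsync_gating")
  # ...until presence is flipped from absent to present
  edit_record(pop$store, session$id, fieldsync:::presence_attr(pop$f2), TRUE)
  expect_no_error(edit_record(pop$store, wid, "individual", pop$f2))
  expect_error(edit_record(pop$store, wid, "grams", -5), class = "fieldsync_invalid")
})

test_that("everything a session writes survives a sync round-trip intact", {
  pop <- tiny_population()
  session <- open_session(pop)
  record_weight(session, pop$adult_f, 1234L, "morning")
  record_status(session, "pregnancy", individual = pop$adult_f)
  end_visit(session, utc(paste(pop$ref_date, "08:20:00")))

  hub <- eav_store("HUB")
  endpoint <- serve_hub(hub)
  full_sync(pop$store, local_transport(endpoint))
  other <- eav_store("T2")
  full_sync(other, local_transport(endpoint))
  # the other replica sees the identical records, values intact
  w_here <- export_table(pop$store, "weight")
  w_there <- export_table(other, "weight")
  expect_identical(w_there, w_here)
  expect_identical(nrow(query_entities(other, "gps-fix", session = session$id)),
                   nrow(gps_track(session)))
})
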