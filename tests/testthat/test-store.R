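test_that("entity ids are unique per device and never collide across tags", {
  store <- eav_store("T1")
  id1 <- create_entity(store, "pack")
  expect_identical(id1, "T1-1")
  expect_length(fieldsync:::ordered_entity_ids(store), 1L)
  id2 <- create_entity(store, "pack")
  expect_false(identical(id1, id2))

  # 100 creates across two device tags: all distinct, 50 per prefix,
  # matching a brute-force enumeration of the expected id set
  store2 <- eav_store("T1")
  ids <- c(
    vapply(1:50, function(i) create_entity(store2, "note", device_tag = "T1"), character(1)),
    vapply(1:50, function(i) create_entity(store2, "note", device_tag = "T2"), character(1))
  )
  expect_length(unique(ids), 100L)
  expect_identical(sort(ids), sort(c(paste0("T1-", 1:50), paste0("T2-", 1:50))))

  expect_error(create_entity(store, "mongoose"), class = "fieldsync_invalid")
})

test_that("set_value upserts one dirty entry and leaves versions alone", {
  store <- eav_store("T1")
  ind <- create_entity(store, "individual")
  e <- set_value(store, ind, "date-of-birth", "2014-03-02")
  expect_true(e$dirty)
  expect_identical(e$version, 0L)
  d <- dirty_entries(store)
  expect_identical(sum(d$attribute == "date-of-birth"), 1L)

  # idempotent upsert: same value again is still one (dirty) entry
  set_value(store, ind, "date-of-birth", "2014-03-02")
  d2 <- dirty_entries(store)
  expect_identical(nrow(d2), nrow(d))

  expect_error(set_value(store, "T9-99", "x", 1), class = "fieldsync_not_found")
  expect_error(set_value(store, ind, "", 1), class = "fieldsync_invalid")
})

test_that("dirty set equals an independent replay of a random edit script", {
  store <- eav_store("T1")
  ents <- vapply(1:10, function(i) create_entity(store, "note"), character(1))
  attrs <- paste0("a", 1:6)
  set.seed(42)
  touched <- character(0)  # oracle: pairs touched since last ack, from the log
  for (k in 1:100) {
    e <- sample(ents, 1); a <- sample(attrs, 1)
    set_value(store, e, a, sample.int(1000, 1))
    touched <- union(touched, paste(e, a))
  }
  d <- dirty_entries(store)
  d <- d[d$attribute != "_type", ]
  expect_setequal(paste(d$entity_id, d$attribute), touched)

  # acking everything empties the dirty set
  all_dirty <- dirty_entries(store)
  for (i in seq_len(nrow(all_dirty))) {
    mark_synced(store, all_dirty$entity_id[i], all_dirty$attribute[i], i)
  }
  expect_identical(nrow(dirty_entries(store)), 0L)
})

test_that("values of every tag round-trip through the store, SQLite and JSON", {
  store <- eav_store("T1")
  ind <- create_entity(store, "individual")
  set_value(store, ind, "name", "789")
  set_value(store, ind, "grams", 1234L)
  set_value(store, ind, "mass", 12.345678901234)
  set_value(store, ind, "flag", TRUE)
  set_value(store, ind, "seen-at", fs_timestamp(utc("2015-01-05 08:00:00")))
  set_value(store, ind, "blank", NULL)

  check <- function(s) {
    got <- get_entity(s, ind)$attributes
    expect_identical(got$name, "789")
    expect_identical(got$grams, 1234L)
    expect_identical(got$mass, 12.345678901234)
    expect_identical(got$flag, TRUE)
    expect_identical(got$`seen-at`, "2015-01-05T08:00:00+0000")
    expect_true(is.null(got$blank))
  }
  check(store)
  path <- withr::local_tempfile(fileext = ".db")
  store_save(store, path)
  check(open_store(path))
  check(store_from_json(store_to_json(store)))
})

test_that("queries filter by type and predicates and match a linear-scan oracle", {
  pop <- tiny_population()
  store <- pop$store
  other <- add_pack(store, "2B")
  add_individual(store, other, "901", "F", pop$ref_date - 1000, today = pop$ref_date)

  got <- query_entities(store, "individual", pack = pop$pack)
  # oracle: scan every entity by hand
  ids <- fieldsync:::ordered_entity_ids(store)
  expected <- ids[vapply(ids, function(i) {
    store$entities[[i]]$entity_type == "individual" &&
      identical(fieldsync:::entity_attr(store, i, "pack"), pop$pack)
  }, logical(1))]
  expect_identical(got$entity_id, expected)
  expect_identical(nrow(got), 6L)

  expect_identical(nrow(query_entities(eav_store("X"), "individual")), 0L)
  expect_error(query_entities(store, "nonsense"), class = "fieldsync_invalid")

  # function predicates
  fem <- query_entities(store, "individual", sex = function(v) identical(v, "F"))
  expect_true(all(fem$sex == "F"))
})

test_that("soft deletion keeps data readable, excludes from default queries, syncs", {
  pop <- tiny_population()
  store <- pop$store
  n_before <- nrow(query_entities(store, "individual", include_deleted = TRUE))
  soft_delete_entity(store, pop$pup)
  ent <- get_entity(store, pop$pup)
  expect_true(ent$deleted)
  expect_identical(ent$attributes$name, "704")          # attributes intact
  expect_identical(nrow(query_entities(store, "individual")), n_before - 1L)
  expect_identical(nrow(query_entities(store, "individual", include_deleted = TRUE)),
                   n_before)
  # the deletion flag is an ordinary dirty entry
  d <- dirty_entries(store)
  expect_true("_deleted" %in% d$attribute)
  expect_error(soft_delete_entity(store, "nope-1"), class = "fieldsync_not_found")
})

test_that("mark_synced enforces version monotonicity", {
  store <- eav_store("T1")
  ent <- create_entity(store, "note")
  set_value(store, ent, "text", "hello")
  e <- mark_synced(store, ent, "text", 1L)
  expect_false(e$dirty)
  expect_identical(e$version, 1L)
  set_value(store, ent, "text", "edited")        # dirty again, version kept
  expect_identical(fieldsync:::get_entry(store, ent, "text")$version, 1L)
  expect_error(mark_synced(store, ent, "text", 0L),
               class = "fieldsync_version_conflict")
})

test_that("apply_remote materialises unknown entities and ignores stale versions", {
  store <- eav_store("T1")
  e <- apply_remote(store, "T2-7", "weight-note", "x", 3L, entity_type = "note")
  expect_identical(get_entity(store, "T2-7")$entity_type, "note")
  expect_false(e$dirty)
  expect_identical(e$version, 3L)
  # equal version: logged no-op, not an error
  expect_null(apply_remote(store, "T2-7", "weight-note", "y", 3L, entity_type = "note"))
  expect_identical(get_entity(store, "T2-7")$attributes$`weight-note`, "x")
})

test_that("interleaved local edits and remote applies equal a replayed state machine", {
  set.seed(7)
  store <- eav_store("T1")
  ids <- c(vapply(1:5, function(i) create_entity(store, "note"), character(1)),
           paste0("T2-", 1:5))
  attrs <- paste0("f", 1:3)
  # oracle: a plain environment replaying the same script
  oracle <- new.env(parent = emptyenv())
  oracle_ver <- new.env(parent = emptyenv())
  remote_ver <- 0L
  for (k in 1:200) {
    e <- sample(ids, 1); a <- sample(attrs, 1); key <- paste(e, a)
    if (runif(1) < 0.5 && startsWith(e, "T1-")) {
      v <- sample.int(10000, 1)
      set_value(store, e, a, v)
      oracle[[key]] <- v
    } else {
      remote_ver <- remote_ver + 1L
      v <- sample.int(10000, 1)
      applied <- apply_remote(store, e, a, v, remote_ver, entity_type = "note")
      prev <- oracle_ver[[key]] %||% 0L
      if (is.null(applied)) {
        # no-op expected only when the stored version was >= remote_ver
        expect_true(prev >= remote_ver)
      } else {
        oracle[[key]] <- v
        oracle_ver[[key]] <- remote_ver
      }
    }
  }
  for (key in ls(oracle)) {
    parts <- strsplit(key, " ", fixed = TRUE)[[1]]
    expect_identical(get_entity(store, parts[1])$attributes[[parts[2]]], oracle[[key]])
  }
})

test_that("version_list covers every entry including deletion flags", {
  store <- eav_store("T1")
  expect_identical(nrow(version_list(store)), 0L)
  ent <- create_entity(store, "note")
  set_value(store, ent, "text", "x")
  soft_delete_entity(store, ent)
  vl <- version_list(store)
  expect_identical(nrow(vl), 3L)  # _type, text, _deleted
  expect_true(all(vl$version >= 0L))
  expect_true("_deleted" %in% vl$attribute)
})

test_that("persistence round-trips arbitrary edit scripts exactly", {
  set.seed(11)
  for (trial in 1:5) {
    store <- eav_store(paste0("T", trial))
    ids <- vapply(1:8, function(i) {
      create_entity(store, sample(fieldsync:::entity_types, 1))
    }, character(1))
    for (k in 1:60) {
      e <- sample(ids, 1)
      val <- switch(sample.int(4, 1), sample.int(5000, 1), runif(1),
                    sample(c(TRUE, FALSE), 1), paste0("s", k))
      set_value(store, e, paste0("attr-", sample.int(6, 1)), val)
    }
    if (trial %% 2 == 0) soft_delete_entity(store, sample(ids, 1))
    path <- withr::local_tempfile(fileext = ".db")
    store_save(store, path)
    reopened <- open_store(path)
    expect_identical(fieldsync:::store_state(reopened), fieldsync:::store_state(store))
    expect_identical(version_list(reopened), version_list(store))
    expect_identical(dirty_entries(reopened)$seq, dirty_entries(store)$seq)
  }
})
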