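#' Persist and reload stores
#'
#' Each replica and the hub keep their whole database in one SQLite file
#' (tables `meta`, `entities`, `entries`; WAL off so the file can be copied
#' or emailed as-is, which is also how snapshots and backups work). The file
#' is rewritten atomically on save. [store_to_json()] / [store_from_json()]
#' provide an equivalent plain-JSON dump, convenient for diffing two stores
#' in tests or version control.
#'
#' @param store an [eav_store()]
#' @param path file path; `store_save()` defaults to the store's own path
#' @return `store_save()` the path, invisibly; `open_store()` an [eav_store()]
#' @name store-io
NULL

store_schema <- c(
  "CREATE TABLE meta (key TEXT PRIMARY KEY, value TEXT)",
  "CREATE TABLE entities (id TEXT PRIMARY KEY, entity_type TEXT NOT NULL, created_seq INTEGER NOT NULL)",
  paste0(
    "CREATE TABLE entries (entity_id TEXT NOT NULL, attribute TEXT NOT NULL, ",
    "tag TEXT NOT NULL, payload TEXT, version INTEGER NOT NULL, ",
    "dirty INTEGER NOT NULL, origin TEXT NOT NULL, seq INTEGER NOT NULL, ",
    "PRIMARY KEY (entity_id, attribute))"
  )
)

#' @rdname store-io
#' @export
store_save <- function(store, path = store$path) {
  check_store(store)
  if (is.null(path)) fs_invalid("no path: give one or create the store with a path")
  tmp <- paste0(path, ".tmp")
  if (file.exists(tmp)) unlink(tmp)
  con <- DBI::dbConnect(RSQLite::SQLite(), tmp)
  on.exit(DBI::dbDisconnect(con), add = TRUE)
  DBI::dbExecute(con, "PRAGMA journal_mode = DELETE")
  for (stmt in store_schema) DBI::dbExecute(con, stmt)
  DBI::dbWithTransaction(con, {
    counters <- ls(store$counters)
    counter_keys <- if (length(counters)) paste0("counter:", counters) else character(0)
    meta <- data.frame(
      key = c("device_tag", "seq", counter_keys),
      value = c(store$device_tag, format(store$seq),
                vapply(counters, function(k) format(store$counters[[k]]), character(1))),
      stringsAsFactors = FALSE
    )
    DBI::dbAppendTable(con, "meta", meta)
    ids <- ordered_entity_ids(store)
    if (length(ids)) {
      DBI::dbAppendTable(con, "entities", data.frame(
        id = ids,
        entity_type = vapply(ids, function(i) store$entities[[i]]$entity_type, character(1)),
        created_seq = vapply(ids, function(i) as.integer(store$entities[[i]]$created_seq), integer(1)),
        stringsAsFactors = FALSE
      ))
    }
    keys <- ls(store$entries)
    if (length(keys)) {
      es <- lapply(keys, function(k) store$entries[[k]])
      DBI::dbAppendTable(con, "entries", data.frame(
        entity_id = vapply(es, `[[`, character(1), "entity_id"),
        attribute = vapply(es, `[[`, character(1), "attribute"),
        tag = vapply(es, function(e) e$value$tag, character(1)),
        payload = vapply(es, function(e) encode_payload(e$value) %||% NA_character_, character(1)),
        version = vapply(es, `[[`, integer(1), "version"),
        dirty = vapply(es, function(e) as.integer(isTRUE(e$dirty)), integer(1)),
        origin = vapply(es, `[[`, character(1), "origin"),
        seq = vapply(es, function(e) as.integer(e$seq), integer(1)),
        stringsAsFactors = FALSE
      ))
    }
  })
  DBI::dbDisconnect(con)
  on.exit(NULL)
  file.rename(tmp, path)
  store$path <- path
  invisible(path)
}

#' @rdname store-io
#' @export
open_store <- function(path) {
  if (!file.exists(path)) fs_not_found("store file", path)
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  on.exit(DBI::dbDisconnect(con), add = TRUE)
  meta <- DBI::dbReadTable(con, "meta")
  device_tag <- meta$value[meta$key == "device_tag"]
  store <- eav_store(device_tag, path = path)
  store$seq <- as.integer(meta$value[meta$key == "seq"])
  for (i in which(startsWith(meta$key, "counter:"))) {
    store$counters[[sub("counter:", "", meta$key[i], fixed = TRUE)]] <- as.integer(meta$value[i])
  }
  ents <- DBI::dbReadTable(con, "entities")
  for (i in order(ents$created_seq)) {
    store$entities[[ents$id[i]]] <- list(
      id = ents$id[i], entity_type = ents$entity_type[i], created_seq = ents$created_seq[i]
    )
    store$by_type[[ents$entity_type[i]]] <- c(store$by_type[[ents$entity_type[i]]], ents$id[i])
  }
  es <- DBI::dbReadTable(con, "entries")
  for (i in order(es$seq)) {
    store$entries[[entry_key(es$entity_id[i], es$attribute[i])]] <- list(
      entity_id = es$entity_id[i], attribute = es$attribute[i],
      value = decode_value(es$tag[i], if (is.na(es$payload[i])) NULL else es$payload[i]),
      version = es$version[i], dirty = es$dirty[i] == 1L,
      origin = es$origin[i], seq = es$seq[i]
    )
    store$attr_names[[es$entity_id[i]]] <-
      c(store$attr_names[[es$entity_id[i]]], es$attribute[i])
  }
  store
}

# schema fingerprint of a saved store file: table set plus CREATE statements.
# Used to demonstrate that novel attribute names never change the database
# structure (the point of the EAV design).
store_schema_hash <- function(path) {
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  on.exit(DBI::dbDisconnect(con), add = TRUE)
  ddl <- DBI::dbGetQuery(con,
    "SELECT name, sql FROM sqlite_master WHERE type = 'table' ORDER BY name")
  list(tables = ddl$name, hash = sum(utf8ToInt(paste(ddl$sql, collapse = ";"))))
}

#' @rdname store-io
#' @export
store_to_json <- function(store, path = NULL) {
  check_store(store)
  tbl <- entries_tbl(store)
  dump <- list(
    device_tag = store$device_tag,
    seq = store$seq,
    counters = as.list(store$counters),
    entities = lapply(ordered_entity_ids(store), function(i) {
      e <- store$entities[[i]]
      list(id = e$id, entity_type = e$entity_type, created_seq = as.integer(e$created_seq))
    }),
    entries = lapply(seq_len(nrow(tbl)), function(i) {
      e <- store$entries[[entry_key(tbl$entity_id[i], tbl$attribute[i])]]
      list(entity_id = e$entity_id, attribute = e$attribute, tag = e$value$tag,
           payload = encode_payload(e$value), version = e$version,
           dirty = isTRUE(e$dirty), origin = e$origin, seq = as.integer(e$seq))
    })
  )
  json <- jsonlite::toJSON(dump, auto_unbox = TRUE, null = "null", pretty = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(path))
  }
  json
}

#' @rdname store-io
#' @export
store_from_json <- function(json) {
  looks_like_path <- length(json) == 1L && !grepl("[{\n]", json[1]) && file.exists(json[1])
  dump <- if (looks_like_path) {
    jsonlite::fromJSON(json, simplifyVector = FALSE)
  } else {
    jsonlite::fromJSON(paste(json, collapse = "\n"), simplifyVector = FALSE)
  }
  store <- eav_store(dump$device_tag)
  store$seq <- as.integer(dump$seq)
  for (k in names(dump$counters)) store$counters[[k]] <- as.integer(dump$counters[[k]])
  for (e in dump$entities) {
    store$entities[[e$id]] <- list(id = e$id, entity_type = e$entity_type,
                                   created_seq = as.integer(e$created_seq))
    store$by_type[[e$entity_type]] <- c(store$by_type[[e$entity_type]], e$id)
  }
  entries <- dump$entries[order(vapply(dump$entries, function(e) as.integer(e$seq), integer(1)))]
  for (e in entries) {
    store$entries[[entry_key(e$entity_id, e$attribute)]] <- list(
      entity_id = e$entity_id, attribute = e$attribute,
      value = decode_value(e$tag, e$payload),
      version = as.integer(e$version), dirty = isTRUE(e$dirty),
      origin = e$origin, seq = as.integer(e$seq)
    )
    store$attr_names[[e$entity_id]] <- c(store$attr_names[[e$entity_id]], e$attribute)
  }
  store
}

# deep in-memory copy (used by crash-retry comparisons)
store_clone <- function(store) {
  clone <- eav_store(store$device_tag, path = NULL)
  clone$seq <- store$seq
  for (k in ls(store$counters)) clone$counters[[k]] <- store$counters[[k]]
  for (k in ls(store$entities)) clone$entities[[k]] <- store$entities[[k]]
  for (k in ls(store$entries)) clone$entries[[k]] <- store$entries[[k]]
  for (k in ls(store$by_type)) clone$by_type[[k]] <- store$by_type[[k]]
  for (k in ls(store$attr_names)) clone$attr_names[[k]] <- store$attr_names[[k]]
  clone
}
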