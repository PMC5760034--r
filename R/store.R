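#' Create an entity-attribute-value replica store
#'
#' A store is the per-device database: every datum is one versioned
#' (entity, attribute, value) entry, the unit of synchronisation. Entries are
#' marked dirty as they are created or edited and stay dirty until the hub
#' acknowledges them; versions are assigned by the hub, never locally (a local
#' edit leaves the version untouched). Replicas and the hub use the identical
#' store type, which is what lets any fully synced replica serve as a backup
#' of the hub.
#'
#' The live store is an environment (mutable, like a connection object);
#' [store_save()] / [open_store()] persist it as a single SQLite file, and
#' [store_to_json()] / [store_from_json()] give a plain-text dump for diffing.
#'
#' @param device_tag short unique tag for the device (e.g. `"T1"`); minted
#'   entity ids are `<device_tag>-<counter>`, so two devices with distinct
#'   tags can never collide.
#' @param path optional file path the store saves to by default
#' @return an object of class `eav_store`
#' @export
eav_store <- function(device_tag = "T1", path = NULL) {
  if (!is_scalar_chr(device_tag) || !nzchar(device_tag) || grepl("-", device_tag)) {
    fs_invalid("device_tag must be a non-empty string without '-'")
  }
  store <- new.env(parent = emptyenv())
  store$device_tag <- device_tag
  store$counters <- new.env(parent = emptyenv())  # per-tag id counters
  store$seq <- 0L                                 # modification sequence
  store$entities <- new.env(parent = emptyenv())  # id -> list(id, entity_type, created_seq)
  store$entries <- new.env(parent = emptyenv())   # key -> entry list
  store$by_type <- new.env(parent = emptyenv())   # type -> ids in creation order
  store$attr_names <- new.env(parent = emptyenv())# id -> attribute names in first-set order
  store$path <- path
  class(store) <- "eav_store"
  store
}

entity_types <- c(
  "pack", "individual", "group-composition-session", "weight", "pregnancy",
  "mate-guard", "escort", "babysit", "gps-fix", "focal-follow", "focal-scan",
  "focal-interaction", "group-event", "note"
)

TYPE_ATTR <- "_type"
DELETED_ATTR <- "_deleted"

entry_key <- function(entity_id, attribute) paste(entity_id, attribute, sep = "\x1f")

next_seq <- function(store) {
  store$seq <- store$seq + 1L
  store$seq
}

#' @export
print.eav_store <- function(x, ...) {
  cat(sprintf(
    "<eav_store device=%s entities=%d entries=%d dirty=%d>\n",
    x$device_tag, length(ls(x$entities)), length(ls(x$entries)),
    sum(vapply(ls(x$entries), function(k) x$entries[[k]]$dirty, logical(1)))
  ))
  invisible(x)
}

#' Create a new entity
#'
#' Mints a globally unique id `<device_tag>-<n>` and records the entity with
#' only its type attribute set (a dirty, version-0 entry that syncs like any
#' other). The entity type is immutable afterwards.
#'
#' @param store an [eav_store()]
#' @param entity_type one of the recorded data types (see `fieldsync:::entity_types`)
#' @param device_tag tag to mint the id under; defaults to the store's own
#' @return the new entity id (character)
#' @export
create_entity <- function(store, entity_type, device_tag = store$device_tag) {
  check_store(store)
  if (!is_scalar_chr(entity_type) || !entity_type %in% entity_types) {
    fs_invalid(sprintf("unknown entity_type '%s'", entity_type))
  }
  n <- (store$counters[[device_tag]] %||% 0L) + 1L
  store$counters[[device_tag]] <- n
  id <- paste0(device_tag, "-", n)
  stopifnot(is.null(store$entities[[id]]))  # never reused by construction
  register_entity(store, id, entity_type)
  put_entry(store, id, TYPE_ATTR, fs_value(entity_type), version = 0L,
            dirty = TRUE, origin = "local")
  id
}

# ensure an entity shell exists for remotely received data
materialise_entity <- function(store, entity_id, entity_type) {
  existing <- store$entities[[entity_id]]
  if (!is.null(existing)) {
    if (!is.null(entity_type) && !identical(existing$entity_type, entity_type)) {
      fs_invalid(sprintf("entity '%s' already has type '%s'", entity_id, existing$entity_type))
    }
    return(invisible(existing))
  }
  if (is.null(entity_type)) fs_invalid("unknown entity requires an entity_type")
  if (!entity_type %in% entity_types) fs_invalid(sprintf("unknown entity_type '%s'", entity_type))
  register_entity(store, entity_id, entity_type)
  invisible(store$entities[[entity_id]])
}

register_entity <- function(store, id, entity_type) {
  store$entities[[id]] <- list(id = id, entity_type = entity_type,
                               created_seq = next_seq(store))
  store$by_type[[entity_type]] <- c(store$by_type[[entity_type]], id)
  invisible(store$entities[[id]])
}

put_entry <- function(store, entity_id, attribute, value, version, dirty, origin) {
  key <- entry_key(entity_id, attribute)
  if (is.null(store$entries[[key]])) {
    store$attr_names[[entity_id]] <- c(store$attr_names[[entity_id]], attribute)
  }
  store$entries[[key]] <- list(
    entity_id = entity_id, attribute = attribute, value = value,
    version = as.integer(version), dirty = dirty, origin = origin,
    seq = next_seq(store)
  )
  invisible(store$entries[[entry_key(entity_id, attribute)]])
}

get_entry <- function(store, entity_id, attribute) {
  store$entries[[entry_key(entity_id, attribute)]]
}

check_store <- function(store) {
  if (!inherits(store, "eav_store")) fs_invalid("not an eav_store")
  invisible(store)
}

check_entity <- function(store, entity_id) {
  ent <- store$entities[[entity_id]]
  if (is.null(ent)) fs_not_found("entity", entity_id)
  ent
}

#' Set an attribute value on an entity
#'
#' Upserts one entry and marks it dirty (needing sync). The entry's version is
#' left unchanged: versions are assigned by the hub on receipt, so a local
#' edit of an already-synced entry keeps the old version until the next sync
#' acknowledges it. Setting the same value again is an idempotent upsert (the
#' entry is still one entry, still dirty).
#'
#' @param store an [eav_store()]
#' @param entity_id an existing entity id
#' @param attribute non-empty attribute name; names never need declaring, the
#'   store is schema-free
#' @param value a scalar or [fs_value()]
#' @return the stored entry, invisibly
#' @export
set_value <- function(store, entity_id, attribute, value) {
  check_store(store)
  check_entity(store, entity_id)
  if (!is_scalar_chr(attribute) || !nzchar(attribute)) fs_invalid("empty attribute name")
  if (identical(attribute, TYPE_ATTR)) fs_invalid("entity_type is immutable")
  value <- fs_value(value)
  prev <- get_entry(store, entity_id, attribute)
  put_entry(store, entity_id, attribute, value,
            version = if (is.null(prev)) 0L else prev$version,
            dirty = TRUE, origin = "local")
}

#' Read one entity with all its entries
#'
#' Deleted entities are returned too — deletion is soft, a reserved attribute,
#' and all data stay readable forever.
#'
#' @inheritParams set_value
#' @return a list of class `fs_entity`: id, entity_type, deleted flag, and a
#'   named list of attribute payloads (reserved attributes excluded)
#' @export
get_entity <- function(store, entity_id) {
  check_store(store)
  ent <- check_entity(store, entity_id)
  attrs <- entity_attrs(store, entity_id)
  deleted_entry <- get_entry(store, entity_id, DELETED_ATTR)
  structure(
    list(
      id = ent$id, entity_type = ent$entity_type,
      deleted = !is.null(deleted_entry) && isTRUE(value_payload(deleted_entry$value)),
      attributes = attrs
    ),
    class = "fs_entity"
  )
}

#' @export
print.fs_entity <- function(x, ...) {
  cat(sprintf("<%s %s%s>\n", x$entity_type, x$id, if (x$deleted) " [deleted]" else ""))
  for (a in names(x$attributes)) {
    v <- x$attributes[[a]]
    cat(sprintf("  %s: %s\n", a, if (is.null(v)) "NULL" else format(v)))
  }
  invisible(x)
}

# named list of payloads for non-reserved attributes, sorted by name
entity_attrs <- function(store, entity_id) {
  attrs <- setdiff(store$attr_names[[entity_id]], c(TYPE_ATTR, DELETED_ATTR))
  attrs <- sort(attrs)
  out <- lapply(attrs, function(a) value_payload(get_entry(store, entity_id, a)$value))
  names(out) <- attrs
  out
}

entity_attr <- function(store, entity_id, attribute, default = NULL) {
  e <- get_entry(store, entity_id, attribute)
  if (is.null(e)) default else value_payload(e$value)
}

is_deleted <- function(store, entity_id) {
  e <- get_entry(store, entity_id, DELETED_ATTR)
  !is.null(e) && isTRUE(value_payload(e$value))
}

ordered_entity_ids <- function(store) {
  ids <- ls(store$entities)
  if (length(ids) == 0L) return(character(0))
  ids[order(vapply(ids, function(i) store$entities[[i]]$created_seq, numeric(1)))]
}

#' Query entities by type and attribute predicates
#'
#' Returns one row per matching entity in a stable, documented order: entity
#' creation sequence (so exports are reproducible). Soft-deleted entities are
#' excluded unless `include_deleted = TRUE`. Predicates in `...` are named
#' attribute filters: a plain value is matched by equality, a function is
#' applied to the payload.
#'
#' @inheritParams set_value
#' @param entity_type one of the recorded data types
#' @param ... named attribute predicates
#' @param include_deleted include soft-deleted entities?
#' @return a tibble: `entity_id`, `entity_type`, `deleted`, then one column
#'   per attribute seen on any matching entity (sorted by name); columns are
#'   atomic when every payload shares a tag, list-columns otherwise
#' @export
query_entities <- function(store, entity_type, ..., include_deleted = FALSE) {
  check_store(store)
  if (!entity_type %in% entity_types) fs_invalid(sprintf("unknown entity_type '%s'", entity_type))
  preds <- rlang::list2(...)
  if (length(preds) && (is.null(names(preds)) || any(!nzchar(names(preds))))) {
    fs_invalid("predicates must be named")
  }
  ids <- store$by_type[[entity_type]] %||% character(0)
  if (!include_deleted && length(ids)) {
    ids <- ids[!vapply(ids, function(i) is_deleted(store, i), logical(1))]
  }
  rows <- lapply(ids, function(i) {
    attrs <- entity_attrs(store, i)
    for (nm in names(preds)) {
      p <- preds[[nm]]
      got <- attrs[[nm]]
      ok <- if (is.function(p)) isTRUE(p(got)) else !is.null(got) && isTRUE(got == p)
      if (!ok) return(NULL)
    }
    c(list(entity_id = i, deleted = is_deleted(store, i)), attrs)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    return(tibble(entity_id = character(0), entity_type = character(0), deleted = logical(0)))
  }
  all_attrs <- sort(unique(unlist(lapply(rows, function(r) setdiff(names(r), c("entity_id", "deleted"))))))
  cols <- c(
    list(entity_id = vapply(rows, `[[`, character(1), "entity_id"),
         entity_type = rep(entity_type, length(rows)),
         deleted = vapply(rows, `[[`, logical(1), "deleted")),
    lapply(stats::setNames(all_attrs, all_attrs), function(a) {
      vals <- lapply(rows, function(r) r[[a]])
      simplify_column(vals)
    })
  )
  as_tibble(cols)
}

# collapse a list of payloads to an atomic vector when they share a type
simplify_column <- function(vals) {
  nulls <- vapply(vals, is.null, logical(1))
  cls <- unique(unlist(lapply(vals[!nulls], function(v) class(v)[1])))
  scalar <- all(vapply(vals[!nulls], function(v) length(v) == 1L, logical(1)))
  if (length(cls) == 1L && scalar) {
    proto <- switch(cls, character = NA_character_, integer = NA_integer_,
                    numeric = NA_real_, logical = NA, NULL)
    if (!is.null(proto)) {
      return(vapply(vals, function(v) if (is.null(v)) proto else v, proto))
    }
  }
  vals
}

#' List entries awaiting synchronisation
#'
#' Entries are marked automatically as needing sync when they are edited or
#' added; this returns exactly that set, ordered by modification sequence
#' (the order the push phase sends them in).
#'
#' @inheritParams set_value
#' @return a tibble: `entity_id`, `entity_type`, `attribute`, `tag`,
#'   `payload` (list-column), `version`, `seq`
#' @export
dirty_entries <- function(store) {
  check_store(store)
  entries_tbl(store, dirty_only = TRUE)
}

entries_tbl <- function(store, dirty_only = FALSE) {
  keys <- ls(store$entries)
  es <- lapply(keys, function(k) store$entries[[k]])
  if (dirty_only) es <- es[vapply(es, function(e) isTRUE(e$dirty), logical(1))]
  if (length(es) == 0L) {
    return(tibble(entity_id = character(0), entity_type = character(0),
                  attribute = character(0), tag = character(0),
                  payload = list(), version = integer(0), seq = integer(0)))
  }
  es <- es[order(vapply(es, function(e) e$seq, numeric(1)))]
  tibble(
    entity_id = vapply(es, `[[`, character(1), "entity_id"),
    entity_type = vapply(es, function(e) store$entities[[e$entity_id]]$entity_type, character(1)),
    attribute = vapply(es, `[[`, character(1), "attribute"),
    tag = vapply(es, function(e) e$value$tag, character(1)),
    payload = lapply(es, function(e) value_payload(e$value)),
    version = vapply(es, `[[`, integer(1), "version"),
    seq = vapply(es, function(e) as.integer(e$seq), integer(1))
  )
}

#' Acknowledge a pushed entry
#'
#' Called when the hub confirms receipt: clears the dirty flag and records the
#' hub-assigned version. Versions never decrease; an acknowledgement carrying
#' a version lower than the entry's current one is a protocol violation and is
#' rejected.
#'
#' @inheritParams set_value
#' @param assigned_version hub-assigned version (>= current version)
#' @return the entry, invisibly
#' @export
mark_synced <- function(store, entity_id, attribute, assigned_version) {
  check_store(store)
  e <- get_entry(store, entity_id, attribute)
  if (is.null(e)) fs_not_found("entry", paste(entity_id, attribute))
  if (!isTRUE(e$dirty)) fs_invalid("entry is not dirty")
  assigned_version <- as.integer(assigned_version)
  if (assigned_version < e$version) {
    fs_abort("fieldsync_version_conflict",
             sprintf("assigned version %d < current %d", assigned_version, e$version))
  }
  e$dirty <- FALSE
  e$version <- assigned_version
  e$origin <- "local"
  store$entries[[entry_key(entity_id, attribute)]] <- e
  invisible(e)
}

#' Apply an entry received from the hub
#'
#' Upserts a clean entry at the hub's version, materialising the entity shell
#' if this replica has never seen the entity. An incoming version less than or
#' equal to the locally stored one is a no-op (never an error): the pull phase
#' may legitimately race with nothing newer to say.
#'
#' @inheritParams set_value
#' @param entity_type type for the entity shell when the entity is new here
#' @param version hub version of the entry
#' @return the entry (or `NULL` on no-op), invisibly
#' @export
apply_remote <- function(store, entity_id, attribute, value, version, entity_type = NULL) {
  check_store(store)
  version <- as.integer(version)
  prev <- get_entry(store, entity_id, attribute)
  if (!is.null(prev) && version <= prev$version) return(invisible(NULL))
  materialise_entity(store, entity_id, entity_type)
  if (identical(attribute, TYPE_ATTR)) {
    # type entries arrive for entities created elsewhere; keep shell consistent
    stored <- store$entities[[entity_id]]$entity_type
    if (!identical(value_payload(fs_value(value)), stored)) {
      fs_invalid(sprintf("entity '%s' already has type '%s'", entity_id, stored))
    }
  }
  invisible(put_entry(store, entity_id, attribute, fs_value(value),
                      version = version, dirty = FALSE, origin = "remote"))
}

#' Soft-delete an entity
#'
#' Data are never deleted: deletion sets a reserved boolean attribute
#' (`_deleted`) as an ordinary dirty entry, so it synchronises to the hub and
#' to other replicas like any edit, and every attribute of the entity stays
#' readable.
#'
#' @inheritParams set_value
#' @return the deleted entity (class `fs_entity`), invisibly
#' @export
soft_delete_entity <- function(store, entity_id) {
  check_store(store)
  check_entity(store, entity_id)
  prev <- get_entry(store, entity_id, DELETED_ATTR)
  put_entry(store, entity_id, DELETED_ATTR, fs_value(TRUE),
            version = if (is.null(prev)) 0L else prev$version,
            dirty = TRUE, origin = "local")
  invisible(get_entity(store, entity_id))
}

#' Version list of every stored entry
#'
#' The message a replica sends the hub in the pull phase: one
#' (entity, attribute, version) tuple per entry, including reserved-attribute
#' entries such as deletion flags.
#'
#' @inheritParams set_value
#' @return a tibble: `entity_id`, `attribute`, `version`
#' @export
version_list <- function(store) {
  check_store(store)
  tbl <- entries_tbl(store)
  tbl[c("entity_id", "attribute", "version")]
}

# canonical full state for convergence comparisons: sorted (entity, attribute,
# tag, payload-text, version)
store_state <- function(store) {
  tbl <- entries_tbl(store)
  tbl$payload_text <- vapply(seq_len(nrow(tbl)), function(i) {
    encode_payload(new_value(tbl$tag[i], tbl$payload[[i]])) %||% NA_character_
  }, character(1))
  out <- tbl[c("entity_id", "attribute", "tag", "payload_text", "version")]
  out[order(out$entity_id, out$attribute), ]
}
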