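#' Hub side: receive one pushed entry
#'
#' The hub overwrites its value unconditionally and increments the entry's
#' version (first receipt of an entry is version 1). This is the whole
#' conflict policy: when two replicas edit the same entry, the last one to
#' sync pushes last and its value wins. Device clocks are never consulted —
#' only arrival order at the hub matters. Attribute names the hub has never
#' seen are stored without any structural change to the database (the point
#' of the entity-attribute-value design: tablets can gain new observation
#' types before the hub software ever hears of them).
#'
#' @param hub_store the hub's [eav_store()]
#' @param entity_id,entity_type,attribute,value the pushed entry
#' @return an ack: `list(entity_id, attribute, assigned_version)`
#' @export
server_receive_entry <- function(hub_store, entity_id, entity_type, attribute, value) {
  check_store(hub_store)
  if (!is_scalar_chr(entity_id) || !nzchar(entity_id)) fs_invalid("malformed push: entity_id")
  if (!is_scalar_chr(attribute) || !nzchar(attribute)) fs_invalid("malformed push: attribute")
  materialise_entity(hub_store, entity_id, entity_type)
  prev <- get_entry(hub_store, entity_id, attribute)
  assigned <- if (is.null(prev)) 1L else prev$version + 1L
  put_entry(hub_store, entity_id, attribute, fs_value(value),
            version = assigned, dirty = FALSE, origin = "remote")
  list(entity_id = entity_id, attribute = attribute, assigned_version = assigned)
}

#' Hub side: diff against a replica's version list
#'
#' Returns every hub entry strictly newer than the version the replica
#' reported for it, plus every hub entry the replica did not report at all
#' (an unreported entry is treated as version 0, so entities created on other
#' tablets propagate). Never returns an entry at a version less than or equal
#' to the reported one.
#'
#' @param hub_store the hub's [eav_store()]
#' @param versions a tibble/data frame with `entity_id`, `attribute`,
#'   `version` — the requester's [version_list()]
#' @return a tibble: `entity_id`, `entity_type`, `attribute`, `tag`,
#'   `payload` (list), `version`
#' @export
server_diff <- function(hub_store, versions) {
  check_store(hub_store)
  reported <- new.env(parent = emptyenv())
  if (!is.null(versions) && nrow(versions) > 0L) {
    for (i in seq_len(nrow(versions))) {
      reported[[entry_key(versions$entity_id[i], versions$attribute[i])]] <-
        as.integer(versions$version[i])
    }
  }
  tbl <- entries_tbl(hub_store)
  keep <- vapply(seq_len(nrow(tbl)), function(i) {
    rep_v <- reported[[entry_key(tbl$entity_id[i], tbl$attribute[i])]] %||% 0L
    tbl$version[i] > rep_v
  }, logical(1))
  tbl[keep, c("entity_id", "entity_type", "attribute", "tag", "payload", "version")]
}

#' In-process hub endpoint and transport
#'
#' `serve_hub()` wraps a hub store as an endpoint object exposing the four
#' protocol requests — push one entry, diff against a version list, snapshot
#' the database file, ping — serialized in arrival order (concurrent clients
#' interleave per entry, never mid-entry). `local_transport()` is the client
#' side handle a replica syncs through; it is the same interface an HTTP
#' transport would implement, so the protocol layer never knows whether a
#' socket is involved. `fail_after_pushes` injects a transport failure before
#' the (n+1)-th push for crash-safety testing; `transport_reset()` re-arms a
#' failed transport (the retry).
#'
#' @param hub_store the hub's [eav_store()]
#' @param snapshot_path where the hub persists its file for snapshot requests
#' @param fail_after_pushes fail the transport after this many pushes
#' @return `serve_hub()` an `fs_endpoint`; `local_transport()` an `fs_transport`
#' @export
serve_hub <- function(hub_store, snapshot_path = NULL) {
  check_store(hub_store)
  endpoint <- new.env(parent = emptyenv())
  endpoint$hub <- hub_store
  endpoint$snapshot_path <- snapshot_path %||% hub_store$path
  endpoint$arrival_log <- list()  # ordered receipts, the conflict-order ground truth
  class(endpoint) <- "fs_endpoint"
  endpoint
}

endpoint_push <- function(endpoint, device_tag, entity_id, entity_type, attribute, value) {
  ack <- server_receive_entry(endpoint$hub, entity_id, entity_type, attribute, value)
  endpoint$arrival_log[[length(endpoint$arrival_log) + 1L]] <- list(
    device_tag = device_tag, entity_id = entity_id, attribute = attribute,
    value = fs_value(value), assigned_version = ack$assigned_version
  )
  ack
}

#' @rdname serve_hub
#' @export
local_transport <- function(endpoint, fail_after_pushes = Inf) {
  if (inherits(endpoint, "eav_store")) endpoint <- serve_hub(endpoint)
  stopifnot(inherits(endpoint, "fs_endpoint"))
  tr <- new.env(parent = emptyenv())
  tr$endpoint <- endpoint
  tr$fail_after <- fail_after_pushes
  tr$pushes <- 0L
  tr$failed <- FALSE
  class(tr) <- c("fs_local_transport", "fs_transport")
  tr
}

#' @rdname serve_hub
#' @export
transport_reset <- function(transport, fail_after_pushes = Inf) {
  transport$fail_after <- fail_after_pushes
  transport$pushes <- 0L
  transport$failed <- FALSE
  invisible(transport)
}

transport_check <- function(transport) {
  if (isTRUE(transport$failed)) {
    fs_abort("fieldsync_transport", "transport is down")
  }
}

transport_push <- function(transport, device_tag, entity_id, entity_type, attribute, value) {
  transport_check(transport)
  if (transport$pushes >= transport$fail_after) {
    transport$failed <- TRUE
    fs_abort("fieldsync_transport", "transport failed mid-push")
  }
  transport$pushes <- transport$pushes + 1L
  endpoint_push(transport$endpoint, device_tag, entity_id, entity_type, attribute, value)
}

transport_diff <- function(transport, versions) {
  transport_check(transport)
  server_diff(transport$endpoint$hub, versions)
}

transport_snapshot <- function(transport, destination) {
  transport_check(transport)
  path <- transport$endpoint$snapshot_path
  if (is.null(path)) fs_invalid("hub endpoint has no snapshot path")
  store_save(transport$endpoint$hub, path)
  path
}

transport_ping <- function(transport) {
  transport_check(transport)
  TRUE
}

#' Two-way synchronisation of a replica with the hub
#'
#' Phase 1 (push): every dirty entry is sent individually, in modification
#' order; each ack clears that entry's dirty flag and records the
#' hub-assigned version before the next entry is sent, so a transport failure
#' mid-push leaves already-acked entries clean and unacked entries dirty — a
#' retry simply resumes. Phase 2 (pull): the replica sends its full version
#' list and applies the hub's diff entry by entry. After a successful sync
#' the replica has no dirty entries and holds nothing older than the hub's
#' copy at pull time.
#'
#' @param replica_store the replica's [eav_store()]
#' @param transport an `fs_transport` reaching the hub
#' @return a `fs_sync_report`: counts of entries pushed, acked and pulled
#' @export
full_sync <- function(replica_store, transport) {
  check_store(replica_store)
  pushed <- 0L; acked <- 0L
  dirty <- dirty_entries(replica_store)
  for (i in seq_len(nrow(dirty))) {
    ack <- transport_push(
      transport, replica_store$device_tag,
      dirty$entity_id[i], dirty$entity_type[i], dirty$attribute[i],
      new_value(dirty$tag[i], dirty$payload[[i]])
    )
    pushed <- pushed + 1L
    mark_synced(replica_store, ack$entity_id, ack$attribute, ack$assigned_version)
    acked <- acked + 1L
  }
  diff <- transport_diff(transport, version_list(replica_store))
  pulled <- 0L
  for (i in seq_len(nrow(diff))) {
    res <- apply_remote(
      replica_store, diff$entity_id[i], diff$attribute[i],
      new_value(diff$tag[i], diff$payload[[i]]), diff$version[i],
      entity_type = diff$entity_type[i]
    )
    if (!is.null(res)) pulled <- pulled + 1L
  }
  structure(
    list(device_tag = replica_store$device_tag,
         pushed = pushed, acked = acked, pulled = pulled),
    class = "fs_sync_report"
  )
}

#' @export
print.fs_sync_report <- function(x, ...) {
  cat(sprintf("<sync %s: pushed %d, acked %d, pulled %d>\n",
              x$device_tag, x$pushed, x$acked, x$pulled))
  invisible(x)
}

#' @importFrom generics glance
#' @method glance fs_sync_report
#' @export
glance.fs_sync_report <- function(x, ...) {
  tibble(device_tag = x$device_tag, pushed = x$pushed, acked = x$acked, pulled = x$pulled)
}

#' Download a byte-faithful snapshot of the hub database
#'
#' The hub persists its store and the single file is copied to `destination`;
#' the copy loads as an ordinary (read-only by convention) store. A partial
#' transfer removes the destination and signals a transport error.
#'
#' @param transport an `fs_transport`
#' @param destination_path file path to write
#' @return the destination path, invisibly
#' @export
download_snapshot <- function(transport, destination_path) {
  src <- transport_snapshot(transport, destination_path)
  ok <- tryCatch(file.copy(src, destination_path, overwrite = TRUE),
                 error = function(e) FALSE)
  if (!isTRUE(ok) || !file.exists(destination_path) ||
      file.size(destination_path) != file.size(src)) {
    if (file.exists(destination_path)) unlink(destination_path)
    fs_abort("fieldsync_transport", "snapshot transfer incomplete")
  }
  invisible(destination_path)
}
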