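#' Record a group-level event
#'
#' Intergroup interactions, alarms at threatening stimuli, group movement
#' decisions and free-text notes, recordable during an open session or
#' standalone. Each type requires its own details: an intergroup interaction
#' names the other pack (and optionally the outcome, e.g. which group
#' retreated), an alarm its cause (e.g. a predator sighting), a movement the
#' feature it was orientated towards or away from (e.g. a water source or
#' den site), and a note carries its free text verbatim (notes are stored as
#' their own entity type).
#'
#' @param store an [eav_store()]
#' @param pack_id an active pack
#' @param event_type `"intergroup-interaction"`, `"alarm"`, `"movement"` or `"note"`
#' @param datetime event time (`POSIXct`)
#' @param participants character vector of individual ids involved
#' @param other_pack the other pack (required for intergroup interactions)
#' @param outcome e.g. `"other-group-retreated"`
#' @param cause e.g. `"predator-sighting"` (alarms)
#' @param target orientation feature for movements, e.g. `"water-source"`
#' @param direction `"towards"` or `"away"` for movements
#' @param free_text the note text (required for notes; never truncated)
#' @return the event's entity id
#' @export
record_group_event <- function(store, pack_id,
                               event_type = c("intergroup-interaction", "alarm",
                                              "movement", "note"),
                               datetime,
                               participants = character(0),
                               other_pack = NULL, outcome = NULL, cause = NULL,
                               target = NULL, direction = NULL,
                               free_text = NULL) {
  check_store(store)
  event_type <- match.arg(event_type)
  pack <- get_entity(store, pack_id)
  if (pack$entity_type != "pack") fs_invalid("not a pack")
  if (!isTRUE(pack$attributes$active)) fs_invalid("pack is not active")
  if (!inherits(datetime, "POSIXt")) fs_invalid("datetime must be POSIXct")
  if (event_type == "intergroup-interaction" && is.null(other_pack)) {
    fs_invalid("an intergroup interaction requires other_pack")
  }
  if (event_type == "note" && !is_scalar_chr(free_text)) {
    fs_invalid("a note requires free_text")
  }
  for (i in participants) check_entity(store, i)
  id <- create_entity(store, if (event_type == "note") "note" else "group-event")
  set_value(store, id, "pack", pack_id)
  set_value(store, id, "timestamp", fs_timestamp(datetime))
  if (event_type != "note") set_value(store, id, "event-type", event_type)
  if (length(participants)) {
    set_value(store, id, "participants",
              as.character(jsonlite::toJSON(participants)))
  }
  if (!is.null(other_pack)) set_value(store, id, "other-pack", other_pack)
  if (!is.null(outcome)) set_value(store, id, "outcome", outcome)
  if (!is.null(cause)) set_value(store, id, "cause", cause)
  if (!is.null(target)) set_value(store, id, "target", target)
  if (!is.null(direction)) set_value(store, id, "direction", direction)
  if (!is.null(free_text)) set_value(store, id, "free-text", free_text)
  id
}

#' Review the records of a collection session
#'
#' The review screen: everything recorded under one group visit (or focal
#' follow), listed record by record so data-collection errors can be fixed
#' before they sync to the hub. Presence marks are listed as editable
#' attributes of the session itself.
#'
#' @param store an [eav_store()]
#' @param session_id a group-composition-session or focal-follow entity id
#' @return a tibble: `record_id`, `record_type`, `attribute`, `value`
#'   (list-column), grouped by record
#' @export
review_records <- function(store, session_id) {
  check_store(store)
  parent <- check_entity(store, session_id)
  ref_attr <- if (parent$entity_type == "focal-follow") "follow" else "session"
  child_types <- c("weight", "pregnancy", "mate-guard", "escort", "babysit",
                   "gps-fix", "focal-scan", "focal-interaction")
  rows <- list()
  add_rows <- function(id, type, attrs) {
    for (a in names(attrs)) {
      rows[[length(rows) + 1L]] <<- list(record_id = id, record_type = type,
                                         attribute = a, value = attrs[[a]])
    }
  }
  add_rows(session_id, parent$entity_type, get_entity(store, session_id)$attributes)
  for (tp in child_types) {
    tbl <- query_entities(store, tp, !!ref_attr := session_id)
    for (i in seq_len(nrow(tbl))) {
      add_rows(tbl$entity_id[i], tp, get_entity(store, tbl$entity_id[i])$attributes)
    }
  }
  tibble(
    record_id = vapply(rows, `[[`, character(1), "record_id"),
    record_type = vapply(rows, `[[`, character(1), "record_type"),
    attribute = vapply(rows, `[[`, character(1), "attribute"),
    value = lapply(rows, `[[`, "value")
  )
}

#' Edit a recorded value
#'
#' Rewrites one entry of one record, re-running the gating validation that
#' applied at collection time: a weight cannot be re-pointed at an absent
#' individual, grams must stay positive, a pregnancy must still reference an
#' eligible female, and presence flips re-open what may be recorded about an
#' individual. The edited entry becomes dirty again, so an edit made after a
#' sync simply produces a new version at the next sync.
#'
#' @param store an [eav_store()]
#' @param record_id the record's entity id (from [review_records()])
#' @param attribute the field to change
#' @param new_value the replacement value
#' @param config a [protocol_config()]
#' @return the record id, invisibly
#' @export
edit_record <- function(store, record_id, attribute, new_value,
                        config = default_config) {
  check_store(store)
  ent <- check_entity(store, record_id)
  validate_record_edit(store, ent, attribute, new_value, config)
  set_value(store, record_id, attribute, new_value)
  invisible(record_id)
}

validate_record_edit <- function(store, ent, attribute, new_value, config) {
  type <- ent$entity_type
  sid <- entity_attr(store, ent$id, "session")
  present_in <- function(session_id, individual_id) {
    isTRUE(entity_attr(store, session_id, presence_attr(individual_id)))
  }
  if (type == "weight") {
    if (attribute == "grams" &&
        (!is.numeric(new_value) || length(new_value) != 1L || new_value <= 0)) {
      fs_invalid("grams must be a positive integer")
    }
    if (attribute == "individual" && !present_in(sid, new_value)) {
      fs_gating("weight must reference an individual marked present")
    }
  } else if (type == "pregnancy" && attribute == "individual") {
    date <- entity_attr(store, sid, "date")
    if (!present_in(sid, new_value) ||
        !eligible_for_pregnancy(store, new_value, date, config)) {
      fs_gating("pregnancy must reference a present adult female")
    }
  } else if (type == "mate-guard" && attribute %in% c("male", "female")) {
    want_sex <- if (attribute == "male") "M" else "F"
    if (!present_in(sid, new_value) ||
        !identical(entity_attr(store, new_value, "sex"), want_sex)) {
      fs_gating(sprintf("mate-guard %s must be a present individual of sex %s",
                        attribute, want_sex))
    }
  } else if (type == "escort" && attribute %in% c("pup", "escort")) {
    if (!present_in(sid, new_value)) {
      fs_gating("escort records must reference present individuals")
    }
  }
  invisible(TRUE)
}
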