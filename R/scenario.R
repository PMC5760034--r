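#' Multi-device edit/sync scenario scripts
#'
#' A scenario script is a deterministic, replayable description of a
#' multi-tablet field season in miniature: a set of shared entities, a list
#' of per-device edit and soft-delete events, and an interleaved sync
#' schedule, all on a totally ordered logical clock (the row order). Running
#' a script builds one hub plus one replica store per device, seeds the
#' shared entities through a first sync round, then executes every event in
#' logical-time order over an in-process transport, and returns every store
#' plus the hub's arrival log so tests can assert convergence and conflict
#' order against an independent replay.
#'
#' `random_scenario()` draws a script: `n_edits` edits per device over shared
#' entities and attributes, `n_syncs` interleaved syncs per device, optional
#' soft deletions, and a final tail of two full sync rounds per device in
#' random order (the quiescence rounds after which all stores must agree).
#'
#' @param n_devices number of replicas
#' @param n_edits edits per device
#' @param n_entities shared entities all devices know about
#' @param n_syncs interleaved mid-script syncs per device
#' @param n_deletes soft-deletions sprinkled over the script (total)
#' @param attributes attribute name pool
#' @param seed master integer seed
#' @return a list of class `fs_scenario`: `n_devices`, `n_entities`,
#'   `events` (tibble: `time`, `device`, `op`, `entity_idx`, `attribute`,
#'   `value`), `seed`
#' @export
random_scenario <- function(n_devices = 3L, n_edits = 200L, n_entities = 20L,
                            n_syncs = 5L, n_deletes = 0L,
                            attributes = paste0("field-", 1:5), seed = 1L) {
  devices <- paste0("T", seq_len(n_devices))
  with_substream(seed, "scenario", {
    rows <- list()
    for (d in devices) {
      for (i in seq_len(n_edits)) {
        rows[[length(rows) + 1L]] <- list(
          device = d, op = "set",
          entity_idx = sample.int(n_entities, 1L),
          attribute = sample(attributes, 1L),
          value = sample.int(100000L, 1L)
        )
      }
      for (i in seq_len(n_syncs)) {
        rows[[length(rows) + 1L]] <- list(device = d, op = "sync",
                                          entity_idx = NA_integer_,
                                          attribute = NA_character_,
                                          value = NA_integer_)
      }
    }
    for (i in seq_len(n_deletes)) {
      rows[[length(rows) + 1L]] <- list(device = sample(devices, 1L), op = "delete",
                                        entity_idx = sample.int(n_entities, 1L),
                                        attribute = NA_character_,
                                        value = NA_integer_)
    }
    rows <- rows[sample.int(length(rows))]
    # quiescence tail: two full sync rounds per device, each round in random order
    for (round in 1:2) {
      for (d in sample(devices)) {
        rows[[length(rows) + 1L]] <- list(device = d, op = "sync",
                                          entity_idx = NA_integer_,
                                          attribute = NA_character_,
                                          value = NA_integer_)
      }
    }
    events <- tibble(
      time = seq_along(rows),
      device = vapply(rows, `[[`, character(1), "device"),
      op = vapply(rows, `[[`, character(1), "op"),
      entity_idx = vapply(rows, `[[`, integer(1), "entity_idx"),
      attribute = vapply(rows, `[[`, character(1), "attribute"),
      value = vapply(rows, `[[`, integer(1), "value")
    )
    structure(list(n_devices = n_devices, n_entities = n_entities,
                   events = events, seed = seed),
              class = "fs_scenario")
  })
}

#' Execute a scenario script
#'
#' @param scenario an `fs_scenario` (see [random_scenario()])
#' @return a list: `hub` (store), `replicas` (named list of stores),
#'   `endpoint` (with `$arrival_log`), `entity_ids` (the shared ids),
#'   `events` (the executed script)
#' @export
run_scenario <- function(scenario) {
  if (!inherits(scenario, "fs_scenario")) fs_invalid("not an fs_scenario")
  ev <- scenario$events
  if (nrow(ev) && any(ev$op == "set" & (is.na(ev$entity_idx) | is.na(ev$attribute)))) {
    fs_invalid("malformed script: set events need entity_idx and attribute")
  }
  hub <- eav_store("HUB")
  endpoint <- serve_hub(hub)
  # seed the shared entities from a setup device, then let every replica pull
  seeder <- eav_store("S")
  entity_ids <- vapply(seq_len(scenario$n_entities), function(i) {
    create_entity(seeder, "note")
  }, character(1))
  full_sync(seeder, local_transport(endpoint))
  devices <- paste0("T", seq_len(scenario$n_devices))
  replicas <- lapply(devices, function(d) {
    r <- eav_store(d)
    full_sync(r, local_transport(endpoint))
    r
  })
  names(replicas) <- devices
  transports <- lapply(devices, function(d) local_transport(endpoint))
  names(transports) <- devices
  for (i in seq_len(nrow(ev))) {
    d <- ev$device[i]
    switch(ev$op[i],
      set = set_value(replicas[[d]], entity_ids[ev$entity_idx[i]],
                      ev$attribute[i], ev$value[i]),
      delete = soft_delete_entity(replicas[[d]], entity_ids[ev$entity_idx[i]]),
      sync = full_sync(replicas[[d]], transports[[d]]),
      fs_invalid(sprintf("malformed script: unknown op '%s'", ev$op[i]))
    )
  }
  list(hub = hub, replicas = replicas, endpoint = endpoint,
       entity_ids = entity_ids, events = ev)
}
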