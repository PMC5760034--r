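# Small in-code fixtures shared across test files. All times are simulated
# (POSIXct passed explicitly); nothing touches the wall clock.

utc <- function(x) as.POSIXct(x, tz = "UTC")

# one pack, six individuals with known ages/sexes relative to `ref_date`
tiny_population <- function(device_tag = "T1", ref_date = as.Date("2015-01-15")) {
  store <- eav_store(device_tag)
  pack <- add_pack(store, "1H")
  mk <- function(name, sex, age_days) {
    add_individual(store, pack, name, sex, ref_date - age_days, today = ref_date)
  }
  list(
    store = store, pack = pack, ref_date = ref_date,
    adult_f = mk("701", "F", 4 * 365),   # adult female
    adult_m = mk("702", "M", 5 * 365),   # adult male
    young_f = mk("703", "F", 200),       # female under 10 months
    pup = mk("704", "M", 40),            # dependent pup (out of den)
    f2 = mk("705", "F", 3 * 365),
    m2 = mk("706", "M", 2 * 365)
  )
}

# a visit with everyone present, started at 08:00 UTC on ref_date
open_session <- function(pop, present = NULL) {
  session <- start_visit(pop$store, pop$pack, utc(paste(pop$ref_date, "08:00:00")))
  roster <- pack_roster(pop$store, pop$pack)
  for (id in roster$entity_id) {
    record_presence(session, id, if (is.null(present)) TRUE else id %in% present)
  }
  session
}

# independent arrival-order replay: expected converged (key -> value/version)
# computed only from the hub's ordered receipt log, never from the stores
replay_arrival_log <- function(arrival_log) {
  values <- new.env(parent = emptyenv())
  versions <- new.env(parent = emptyenv())
  pushers <- new.env(parent = emptyenv())
  for (rec in arrival_log) {
    key <- paste(rec$entity_id, rec$attribute, sep = "\x1f")
    values[[key]] <- rec$value
    versions[[key]] <- (versions[[key]] %||% 0L) + 1L
    pushers[[key]] <- rec$device_tag
  }
  list(values = values, versions = versions, pushers = pushers)
}

`%||%` <- rlang::`%||%`

expect_states_identical <- function(stores) {
  states <- lapply(stores, fieldsync:::store_state)
  for (i in seq_along(states)[-1]) {
    expect_identical(states[[i]], states[[1]])
  }
}
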