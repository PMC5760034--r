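#' Start a group-composition visit
#'
#' One visit to one pack: logs the start time, then records presence,
#' weights, reproductive status records and an automatic GPS track until
#' [end_visit()]. The GPS source is injectable (a function of seconds since
#' the visit start returning `c(lat, lon)`); fixes are taken at the start and
#' every `gps_interval_s` (default 180 s) of session clock thereafter, so a
#' 20-minute visit yields 7 fixes. Only one session per pack and date may be
#' open at a time.
#'
#' Everything recorded in a session is written through the
#' entity-attribute-value store, so it is dirty for sync the moment it is
#' entered.
#'
#' @param store an [eav_store()]
#' @param pack_id an active pack
#' @param datetime visit start (`POSIXct`); the clock is injectable — tests
#'   pass simulated times
#' @param gps_source `function(t_seconds) -> c(lat, lon)` or `NULL` for the
#'   default deterministic source
#' @param config a [protocol_config()]
#' @return a session handle (class `fs_session`) carrying the store and the
#'   session entity id
#' @export
start_visit <- function(store, pack_id, datetime, gps_source = NULL,
                        config = default_config) {
  check_store(store)
  pack <- get_entity(store, pack_id)
  if (pack$entity_type != "pack") fs_invalid("not a pack")
  if (!isTRUE(pack$attributes$active)) fs_invalid("pack is not active")
  if (!inherits(datetime, "POSIXt")) fs_invalid("datetime must be POSIXct")
  date_chr <- format(as.Date(datetime, tz = "UTC"), "%Y-%m-%d")
  for (sid in store$by_type[["group-composition-session"]]) {
    if (identical(entity_attr(store, sid, "pack"), pack_id) &&
        identical(entity_attr(store, sid, "date"), date_chr) &&
        is.null(entity_attr(store, sid, "end-time")) &&
        !is_deleted(store, sid)) {
      fs_invalid("an open session already exists for this pack and date")
    }
  }
  id <- create_entity(store, "group-composition-session")
  set_value(store, id, "pack", pack_id)
  set_value(store, id, "date", date_chr)
  set_value(store, id, "start-time", fs_timestamp(datetime))
  new_session(store, id, gps_source %||% default_gps_source, config)
}

new_session <- function(store, id, gps_source = default_gps_source,
                        config = default_config) {
  structure(list(store = store, id = id, gps_source = gps_source, config = config),
            class = "fs_session")
}

#' @export
print.fs_session <- function(x, ...) {
  cat(sprintf("<group-composition session %s (%s)>\n", x$id,
              if (session_open(x)) "open" else "closed"))
  invisible(x)
}

# Mweya peninsula, Queen Elizabeth NP: a slow deterministic drift around the
# study site's central point
default_gps_source <- function(t_seconds) {
  c(-0.19167 + 2e-6 * t_seconds, 29.90000 + 1e-6 * t_seconds)
}

session_open <- function(session) {
  is.null(entity_attr(session$store, session$id, "end-time"))
}

check_session_open <- function(session) {
  if (!inherits(session, "fs_session")) fs_invalid("not a session handle")
  if (!session_open(session)) fs_invalid("session is closed")
  invisible(session)
}

session_pack <- function(session) entity_attr(session$store, session$id, "pack")
session_date <- function(session) entity_attr(session$store, session$id, "date")

check_roster_member <- function(session, individual_id) {
  pack <- entity_attr(session$store, individual_id, "pack")
  if (!identical(pack, session_pack(session))) {
    fs_gating(sprintf("individual '%s' is not on this pack's roster", individual_id))
  }
  if (isTRUE(entity_attr(session$store, individual_id, "membership-ended"))) {
    fs_gating(sprintf("individual '%s' has left the pack", individual_id))
  }
  invisible(individual_id)
}

presence_attr <- function(individual_id) paste0("present-", individual_id)

#' Record presence or absence on a visit
#'
#' The first screen of a visit: which previously recorded pack members are
#' present today. Presence gates everything downstream — no weight,
#' mate-guard or escort record can reference an individual not marked
#' present (the only exception is a babysitting record inferred from
#' temporary absence). Presence defaults to unset: it must be recorded
#' explicitly before dependent records are accepted.
#'
#' @param session an open `fs_session`
#' @param individual_id a roster member
#' @param present logical
#' @return the session handle, invisibly (pipe-friendly)
#' @export
record_presence <- function(session, individual_id, present) {
  check_session_open(session)
  check_roster_member(session, individual_id)
  if (!is.logical(present) || length(present) != 1L || is.na(present)) {
    fs_invalid("present must be TRUE or FALSE")
  }
  set_value(session$store, session$id, presence_attr(individual_id), present)
  invisible(session)
}

presence_of <- function(session, individual_id) {
  entity_attr(session$store, session$id, presence_attr(individual_id))
}

#' @rdname record_presence
#' @return `presence_map()`: a tibble `individual_id`, `present` (NA = unset)
#'   over the pack roster
#' @export
presence_map <- function(session) {
  roster <- pack_roster(session$store, session_pack(session))
  pres <- vapply(roster$entity_id, function(i) {
    p <- presence_of(session, i)
    if (is.null(p)) NA else p
  }, logical(1))
  tibble(individual_id = roster$entity_id, present = unname(pres))
}

check_present <- function(session, individual_id, role = "individual") {
  check_roster_member(session, individual_id)
  if (!isTRUE(presence_of(session, individual_id))) {
    fs_gating(sprintf("%s '%s' is not marked present on this visit", role, individual_id))
  }
  invisible(individual_id)
}

#' Record a weight
#'
#' Weekly weighings, morning before foraging and evening after. The
#' individual must be marked present; grams must be a positive integer. If
#' the configuration carries `weight_bounds`, an entry-time feasibility check
#' rejects values outside them (off by default; [screen_weights()] is the
#' post-hoc equivalent).
#'
#' @param session an open `fs_session`
#' @param individual_id a present roster member
#' @param grams positive integer weight
#' @param period `"morning"` or `"evening"`
#' @param at optional `POSIXct` time of the weighing
#' @return the weight record's entity id
#' @export
record_weight <- function(session, individual_id, grams,
                          period = c("morning", "evening"), at = NULL) {
  check_session_open(session)
  check_present(session, individual_id)
  period <- match.arg(period)
  if (!is.numeric(grams) || length(grams) != 1L || is.na(grams) || grams <= 0 ||
      grams != as.integer(grams)) {
    fs_invalid("grams must be a positive integer")
  }
  bounds <- session$config$weight_bounds
  if (!is.null(bounds) && (grams < bounds[1] || grams > bounds[2])) {
    fs_gating(sprintf("weight %d g outside feasible bounds [%d, %d]",
                      as.integer(grams), as.integer(bounds[1]), as.integer(bounds[2])))
  }
  id <- create_entity(session$store, "weight")
  set_value(session$store, id, "session", session$id)
  set_value(session$store, id, "individual", individual_id)
  set_value(session$store, id, "grams", as.integer(grams))
  set_value(session$store, id, "period", period)
  if (!is.null(at)) set_value(session$store, id, "session-time", fs_timestamp(at))
  id
}

#' Flag infeasible weight values
#'
#' Post-hoc feasibility screen over weight values: flags records outside the
#' configured bounds, the check used to estimate the residual typo rate in
#' synced weight records.
#'
#' @param grams integer vector of weights
#' @param bounds `c(lower, upper)` feasible range in grams
#' @return logical vector, `TRUE` where infeasible
#' @export
screen_weights <- function(grams, bounds = c(300L, 2500L)) {
  if (length(bounds) != 2L || bounds[1] >= bounds[2]) fs_invalid("bounds must be c(lower, upper)")
  grams < bounds[1] | grams > bounds[2]
}

#' Record a reproductive/care status observation
#'
#' One call per record, `kind` selecting the screen: `"pregnancy"` (adult
#' females, strictly over 10 months), `"mate-guard"` (male guarding female,
#' ordinal strength/accuracy scores, primary-guard flag), `"escort"` (adult
#' accompanying a dependent pup) or `"babysit"` (individual staying at the
#' den — directly observed, or inferred from temporary absence, in which
#' case the individual is by definition absent from the visit). All other
#' referenced individuals must be marked present. A screen that does not
#' apply on a visit can be skipped explicitly with [skip_screen()], which
#' distinguishes "not applicable" from "not recorded".
#'
#' @param session an open `fs_session`
#' @param kind one of `"pregnancy"`, `"mate-guard"`, `"escort"`, `"babysit"`
#' @param individual,status pregnancy: the female and her binary status
#' @param male,female,strength,accuracy,primary mate-guard fields
#' @param pup,escort escort fields (plus `strength`, `accuracy`)
#' @param evidence babysit: `"observed"` or `"inferred"`
#' @return the record's entity id
#' @export
record_status <- function(session, kind = c("pregnancy", "mate-guard", "escort", "babysit"),
                          individual = NULL, status = TRUE,
                          male = NULL, female = NULL,
                          strength = NULL, accuracy = NULL, primary = FALSE,
                          pup = NULL, escort = NULL,
                          evidence = NULL) {
  check_session_open(session)
  kind <- match.arg(kind)
  store <- session$store
  date <- session_date(session)
  cfg <- session$config
  check_score <- function(x, what) {
    if (is.null(x)) fs_invalid(sprintf("%s score required", what))
    if (!x %in% cfg$score_levels) {
      fs_invalid(sprintf("%s score must be one of %s", what,
                         paste(cfg$score_levels, collapse = ", ")))
    }
    as.integer(x)
  }
  switch(kind,
    pregnancy = {
      if (is.null(individual)) fs_invalid("pregnancy record needs an individual")
      check_present(session, individual, "female")
      if (!eligible_for_pregnancy(store, individual, date, cfg)) {
        fs_gating("pregnancy records require an adult female (> 10 months)")
      }
      id <- create_entity(store, "pregnancy")
      set_value(store, id, "session", session$id)
      set_value(store, id, "individual", individual)
      set_value(store, id, "status", isTRUE(status))
      id
    },
    `mate-guard` = {
      if (is.null(male) || is.null(female)) fs_invalid("mate-guard needs male and female")
      check_present(session, male, "male")
      check_present(session, female, "female")
      if (!identical(entity_attr(store, male, "sex"), "M")) {
        fs_gating("mate-guard male must have sex M")
      }
      if (!identical(entity_attr(store, female, "sex"), "F")) {
        fs_gating("mate-guard female must have sex F")
      }
      id <- create_entity(store, "mate-guard")
      set_value(store, id, "session", session$id)
      set_value(store, id, "male", male)
      set_value(store, id, "female", female)
      set_value(store, id, "strength", check_score(strength, "strength"))
      set_value(store, id, "accuracy", check_score(accuracy, "accuracy"))
      set_value(store, id, "primary", isTRUE(primary))
      id
    },
    escort = {
      if (is.null(pup) || is.null(escort)) fs_invalid("escort record needs pup and escort")
      if (identical(pup, escort)) fs_gating("pup and escort must be distinct")
      check_present(session, pup, "pup")
      check_present(session, escort, "escort")
      if (!is_pup(store, pup, date, cfg)) {
        fs_gating(sprintf("'%s' is not a dependent pup (< %d days)", pup, cfg$pup_age_days))
      }
      id <- create_entity(store, "escort")
      set_value(store, id, "session", session$id)
      set_value(store, id, "pup", pup)
      set_value(store, id, "escort", escort)
      set_value(store, id, "strength", check_score(strength, "strength"))
      set_value(store, id, "accuracy", check_score(accuracy, "accuracy"))
      id
    },
    babysit = {
      if (is.null(individual)) fs_invalid("babysit record needs an individual")
      if (is.null(evidence) || !evidence %in% c("observed", "inferred")) {
        fs_invalid("evidence must be 'observed' or 'inferred'")
      }
      check_roster_member(session, individual)
      if (identical(evidence, "observed")) {
        check_present(session, individual, "babysitter")
      } else if (isTRUE(presence_of(session, individual))) {
        fs_gating("inferred babysitting implies the individual is absent from the visit")
      }
      id <- create_entity(store, "babysit")
      set_value(store, id, "session", session$id)
      set_value(store, id, "individual", individual)
      set_value(store, id, "evidence", evidence)
      id
    }
  )
}

#' @rdname record_status
#' @export
skip_screen <- function(session, kind = c("pregnancy", "mate-guard", "escort", "babysit")) {
  check_session_open(session)
  kind <- match.arg(kind)
  set_value(session$store, session$id, paste0("skip-", kind), TRUE)
  invisible(session)
}

#' End a group visit
#'
#' Closes the session, records the end time and materialises the GPS track:
#' one fix at the start and one every `gps_interval_s` of session clock
#' strictly before the end time (a zero-duration visit still gets its start
#' fix). Records attempted after closing are rejected.
#'
#' @param session an open `fs_session`
#' @param datetime visit end, strictly after the start
#' @return the session handle, invisibly
#' @export
end_visit <- function(session, datetime) {
  check_session_open(session)
  if (!inherits(datetime, "POSIXt")) fs_invalid("datetime must be POSIXct")
  start <- parse_iso8601(entity_attr(session$store, session$id, "start-time"))
  duration <- as.numeric(difftime(datetime, start, units = "secs"))
  if (duration < 0) fs_invalid("end time is before start time")
  interval <- session$config$gps_interval_s
  ticks <- seq(0L, by = interval, length.out = max(1L, ceiling(duration / interval)))
  ticks <- ticks[ticks == 0L | ticks < duration]
  for (t in ticks) {
    fix <- session$gps_source(t)
    if (length(fix) != 2L || fix[1] < -90 || fix[1] > 90 || fix[2] < -180 || fix[2] > 180) {
      fs_invalid("gps_source must return c(lat, lon) in WGS84 degrees")
    }
    fid <- create_entity(session$store, "gps-fix")
    set_value(session$store, fid, "session", session$id)
    set_value(session$store, fid, "t-seconds", as.integer(t))
    set_value(session$store, fid, "timestamp", fs_timestamp(start + t))
    set_value(session$store, fid, "lat", as.numeric(fix[1]))
    set_value(session$store, fid, "lon", as.numeric(fix[2]))
  }
  set_value(session$store, session$id, "end-time", fs_timestamp(datetime))
  invisible(session)
}

#' GPS track of a session
#'
#' @param session an `fs_session` (open or closed)
#' @return a tibble `t_seconds`, `timestamp`, `lat`, `lon` ordered by time
#' @export
gps_track <- function(session) {
  tbl <- query_entities(session$store, "gps-fix", session = session$id)
  if (nrow(tbl) == 0L) {
    return(tibble(t_seconds = integer(0), timestamp = character(0),
                  lat = numeric(0), lon = numeric(0)))
  }
  out <- tibble(t_seconds = tbl[["t-seconds"]], timestamp = tbl[["timestamp"]],
                lat = tbl[["lat"]], lon = tbl[["lon"]])
  out[order(out$t_seconds), ]
}

#' @method autoplot fs_session
#' @export
autoplot.fs_session <- function(object, ...) {
  track <- gps_track(object)
  ggplot2::ggplot(track, ggplot2::aes(x = .data$lon, y = .data$lat)) +
    ggplot2::geom_path(colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$t_seconds / 60)) +
    ggplot2::labs(x = "Longitude (°E)", y = "Latitude (°N)",
                  colour = "Minutes into visit",
                  title = sprintf("GPS track, session %s", object$id)) +
    ggplot2::theme_minimal()
}
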