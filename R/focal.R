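#' Start a focal follow
#'
#' A 20-minute timed protocol on one individual. Three protocols exist —
#' dependent pups, pregnant females and oestrus females — and the protocol
#' gates who may be focal: the pup protocol requires a dependent pup (younger
#' than the configured pup age), the female protocols require sex F. The
#' countdown runs on an injectable clock: every state change takes an
#' explicit `at` time, so tests drive follows with simulated time and the
#' CLI passes wall time.
#'
#' Each minute of active (unpaused) time has one scan slot; the follow
#' completes once 20 minutes of active time have elapsed ([complete_focal()])
#' or can be aborted early ([abort_focal()]), keeping all partial data.
#'
#' @param store an [eav_store()]
#' @param protocol `"pup"`, `"pregnant-female"` or `"oestrus-female"`
#' @param focal_id the focal individual
#' @param datetime start time (`POSIXct`)
#' @param config a [protocol_config()]
#' @return a follow handle (class `fs_focal`)
#' @export
start_focal <- function(store, protocol = c("pup", "pregnant-female", "oestrus-female"),
                        focal_id, datetime, config = default_config) {
  check_store(store)
  protocol <- match.arg(protocol)
  ind <- get_entity(store, focal_id)
  if (ind$entity_type != "individual") fs_invalid("focal must be an individual")
  if (!inherits(datetime, "POSIXt")) fs_invalid("datetime must be POSIXct")
  on_date <- as.Date(datetime, tz = "UTC")
  if (protocol == "pup") {
    if (!is_pup(store, focal_id, on_date, config)) {
      fs_gating("pup protocol requires a dependent pup")
    }
  } else {
    if (!identical(ind$attributes$sex, "F")) {
      fs_gating(sprintf("%s protocol requires a female", protocol))
    }
  }
  id <- create_entity(store, "focal-follow")
  set_value(store, id, "protocol", protocol)
  set_value(store, id, "focal", focal_id)
  set_value(store, id, "start-time", fs_timestamp(datetime))
  set_value(store, id, "state", "running")
  set_value(store, id, "paused-seconds", 0L)
  set_value(store, id, "pause-count", 0L)
  new_focal(store, id, config)
}

new_focal <- function(store, id, config = default_config) {
  structure(list(store = store, id = id, config = config), class = "fs_focal")
}

#' @export
print.fs_focal <- function(x, ...) {
  cat(sprintf("<focal follow %s [%s] on %s, %d scans>\n", x$id, focal_state(x),
              entity_attr(x$store, x$id, "focal"), nrow(focal_scans(x))))
  invisible(x)
}

focal_state <- function(follow) entity_attr(follow$store, follow$id, "state")

focal_start_time <- function(follow) {
  parse_iso8601(entity_attr(follow$store, follow$id, "start-time"))
}

focal_paused_seconds <- function(follow) {
  entity_attr(follow$store, follow$id, "paused-seconds", 0L)
}

check_focal_state <- function(follow, allowed) {
  if (!inherits(follow, "fs_focal")) fs_invalid("not a focal follow handle")
  st <- focal_state(follow)
  if (!st %in% allowed) {
    fs_invalid(sprintf("follow is %s; operation requires %s", st,
                       paste(allowed, collapse = " or ")))
  }
  invisible(st)
}

#' Remaining countdown seconds
#'
#' @param follow an `fs_focal`
#' @param at current time (`POSIXct`)
#' @return seconds of active countdown remaining (never negative; never
#'   increases while running)
#' @export
remaining_seconds <- function(follow, at) {
  elapsed <- as.numeric(difftime(at, focal_start_time(follow), units = "secs"))
  active <- elapsed - focal_paused_seconds(follow)
  if (focal_state(follow) == "paused") {
    ps <- entity_attr(follow$store, follow$id, "pause-open")
    active <- as.numeric(difftime(parse_iso8601(ps), focal_start_time(follow), units = "secs")) -
      focal_paused_seconds(follow)
  }
  max(0, follow$config$focal_seconds - active)
}

#' Pause and resume the countdown
#'
#' The countdown pauses when the focal goes out of sight; scan prompts are
#' suppressed while paused and every pause interval is logged, so a follow
#' paused for five minutes completes at 25 minutes of wall time with its
#' full 20 scans.
#'
#' @param follow an `fs_focal`
#' @param at the time of the pause/resume (`POSIXct`)
#' @return the follow handle, invisibly
#' @export
pause_focal <- function(follow, at) {
  check_focal_state(follow, "running")
  set_value(follow$store, follow$id, "state", "paused")
  set_value(follow$store, follow$id, "pause-open", fs_timestamp(at))
  invisible(follow)
}

#' @rdname pause_focal
#' @export
resume_focal <- function(follow, at) {
  check_focal_state(follow, "paused")
  store <- follow$store
  opened <- parse_iso8601(entity_attr(store, follow$id, "pause-open"))
  dur <- as.numeric(difftime(at, opened, units = "secs"))
  if (dur < 0) fs_invalid("resume before pause")
  k <- entity_attr(store, follow$id, "pause-count", 0L) + 1L
  set_value(store, follow$id, "pause-count", k)
  set_value(store, follow$id, sprintf("pause-%d-start", k),
            entity_attr(store, follow$id, "pause-open"))
  set_value(store, follow$id, sprintf("pause-%d-end", k), fs_timestamp(at))
  set_value(store, follow$id, "paused-seconds",
            as.integer(focal_paused_seconds(follow) + dur))
  set_value(store, follow$id, "pause-open", fs_value(NULL))
  set_value(store, follow$id, "state", "running")
  invisible(follow)
}

#' Record a per-minute scan
#'
#' Each active minute the observer records the focal's nearest neighbour and
#' every individual within 2 m. Neighbours must be packmates other than the
#' focal; `"none-visible"` marks a scan with no neighbour in sight. If the
#' nearest neighbour is omitted from `within_2m` it is added automatically
#' (the nearest individual is by definition within 2 m).
#'
#' @param follow a running `fs_focal`
#' @param minute_index 1–20, each recordable once
#' @param nearest individual id or `"none-visible"`
#' @param within_2m character vector of individual ids (possibly empty)
#' @return the scan's entity id
#' @export
record_scan <- function(follow, minute_index, nearest = "none-visible",
                        within_2m = character(0)) {
  check_focal_state(follow, "running")
  store <- follow$store
  if (!is.numeric(minute_index) || length(minute_index) != 1L ||
      minute_index < 1 || minute_index > 20 || minute_index != as.integer(minute_index)) {
    fs_invalid("minute_index must be an integer in 1..20")
  }
  existing <- focal_scans(follow)
  if (as.integer(minute_index) %in% existing$minute_index) {
    fs_invalid(sprintf("minute %d already recorded", as.integer(minute_index)))
  }
  focal <- entity_attr(store, follow$id, "focal")
  pack <- entity_attr(store, focal, "pack")
  ids <- unique(c(if (!identical(nearest, "none-visible")) nearest, within_2m))
  for (i in ids) {
    if (identical(i, focal)) fs_invalid("the focal cannot be its own neighbour")
    if (!identical(entity_attr(store, i, "pack"), pack)) {
      fs_gating(sprintf("'%s' is not a packmate of the focal", i))
    }
  }
  if (!identical(nearest, "none-visible") && !nearest %in% within_2m) {
    within_2m <- c(nearest, within_2m)
  }
  id <- create_entity(store, "focal-scan")
  set_value(store, id, "follow", follow$id)
  set_value(store, id, "minute-index", as.integer(minute_index))
  set_value(store, id, "nearest", nearest)
  set_value(store, id, "within-2m", as.character(jsonlite::toJSON(within_2m)))
  id
}

#' @rdname record_scan
#' @return `focal_scans()`: a tibble `scan_id`, `minute_index`, `nearest`,
#'   `within_2m` (list-column), `missed`
#' @export
focal_scans <- function(follow) {
  tbl <- query_entities(follow$store, "focal-scan", follow = follow$id)
  if (nrow(tbl) == 0L) {
    return(tibble(scan_id = character(0), minute_index = integer(0),
                  nearest = character(0), within_2m = list(), missed = logical(0)))
  }
  out <- tibble(
    scan_id = tbl$entity_id,
    minute_index = tbl[["minute-index"]],
    nearest = tbl[["nearest"]],
    within_2m = lapply(tbl[["within-2m"]], function(j) {
      as.character(jsonlite::fromJSON(j))
    }),
    missed = if ("missed" %in% names(tbl)) !is.na(tbl[["missed"]]) & tbl[["missed"]]
             else rep(FALSE, nrow(tbl))
  )
  out[order(out$minute_index), ]
}

#' Record an interaction with another group member
#'
#' Affiliative or agonistic interactions of the focal, with who initiated,
#' the intensity (e.g. body-block, attack), the context (e.g. food, social
#' partner) and — for agonistic interactions only — who won. A winner given
#' for an affiliative interaction is stored as `"none"`.
#'
#' @param follow a running or paused `fs_focal`
#' @param kind `"affiliative"` or `"agonistic"`
#' @param partner the other individual (never the focal itself)
#' @param initiator `"focal"` or `"partner"`
#' @param intensity,context free enumerations, e.g. `"attack"`, `"food"`
#' @param winner `"focal"`, `"partner"` or `"none"`
#' @param at optional `POSIXct`; stored as seconds since the follow started
#' @return the interaction's entity id
#' @export
record_interaction <- function(follow, kind = c("affiliative", "agonistic"),
                               partner, initiator = c("focal", "partner"),
                               intensity = NULL, context = NULL,
                               winner = c("none", "focal", "partner"),
                               at = NULL) {
  check_focal_state(follow, c("running", "paused"))
  kind <- match.arg(kind)
  initiator <- match.arg(initiator)
  winner <- match.arg(winner)
  store <- follow$store
  focal <- entity_attr(store, follow$id, "focal")
  if (identical(partner, focal)) fs_invalid("partner must differ from the focal")
  check_entity(store, partner)
  if (kind == "affiliative") winner <- "none"
  id <- create_entity(store, "focal-interaction")
  set_value(store, id, "follow", follow$id)
  set_value(store, id, "kind", kind)
  set_value(store, id, "partner", partner)
  set_value(store, id, "initiator", initiator)
  if (!is.null(intensity)) set_value(store, id, "intensity", intensity)
  if (!is.null(context)) set_value(store, id, "context", context)
  set_value(store, id, "winner", winner)
  if (!is.null(at)) {
    rel <- as.numeric(difftime(at, focal_start_time(follow), units = "secs"))
    set_value(store, id, "at-seconds", as.integer(rel))
  }
  id
}

#' Complete or abort a follow
#'
#' A follow completes once 20 minutes of active (unpaused) time have
#' elapsed; completion fills any unrecorded minute with an explicit empty
#' scan (`missed = TRUE`, no neighbour visible), so a completed follow
#' always has exactly 20 scan slots. Aborting (the follow terminated early,
#' e.g. the focal disappears for good) keeps all partial data.
#'
#' @param follow an `fs_focal`
#' @param at the completion/abort time (`POSIXct`)
#' @return the follow handle, invisibly
#' @export
complete_focal <- function(follow, at) {
  check_focal_state(follow, "running")
  store <- follow$store
  elapsed <- as.numeric(difftime(at, focal_start_time(follow), units = "secs"))
  active <- elapsed - focal_paused_seconds(follow)
  if (active < follow$config$focal_seconds) {
    fs_invalid(sprintf("only %.0f s of active time elapsed; %d s required",
                       active, follow$config$focal_seconds))
  }
  have <- focal_scans(follow)$minute_index
  for (m in setdiff(1:20, have)) {
    id <- create_entity(store, "focal-scan")
    set_value(store, id, "follow", follow$id)
    set_value(store, id, "minute-index", as.integer(m))
    set_value(store, id, "nearest", "none-visible")
    set_value(store, id, "within-2m", as.character(jsonlite::toJSON(character(0))))
    set_value(store, id, "missed", TRUE)
  }
  set_value(store, follow$id, "state", "completed")
  set_value(store, follow$id, "end-time", fs_timestamp(at))
  invisible(follow)
}

#' @rdname complete_focal
#' @export
abort_focal <- function(follow, at) {
  check_focal_state(follow, c("running", "paused"))
  set_value(follow$store, follow$id, "state", "aborted")
  set_value(follow$store, follow$id, "end-time", fs_timestamp(at))
  invisible(follow)
}

#' @method autoplot fs_focal
#' @export
autoplot.fs_focal <- function(object, ...) {
  scans <- focal_scans(object)
  scans$n_within <- vapply(scans$within_2m, length, integer(1))
  ggplot2::ggplot(scans, ggplot2::aes(x = .data$minute_index, y = .data$n_within)) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$missed)) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "steelblue", `TRUE` = "grey80")) +
    ggplot2::labs(x = "Minute of follow", y = "Individuals within 2 m",
                  fill = "Missed scan",
                  title = sprintf("Focal follow %s", object$id)) +
    ggplot2::theme_minimal()
}
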