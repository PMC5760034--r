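#' Field protocol configuration
#'
#' Tunables the observation protocols consult. `month_days` defines a month
#' for age arithmetic (the mean Gregorian month, 30.4375 days);
#' `adult_female_months` is the strict pregnancy-eligibility threshold (a
#' female at exactly 10.0 months is not yet eligible); `pup_age_days` bounds
#' who counts as a dependent pup for escorting and the pup focal protocol;
#' `score_levels` is the ordinal scale used for qualitative
#' strength/accuracy scores; `weight_bounds` are the optional feasibility
#' bounds (grams) used by [screen_weights()] — entry-time screening is off by
#' default.
#'
#' @param month_days days per month for [age_months()]
#' @param adult_female_months strict age threshold (months) for pregnancy records
#' @param pup_age_days maximum age in days to count as a dependent pup
#' @param score_levels integer vector of allowed ordinal scores
#' @param gps_interval_s seconds between GPS fixes during a group visit
#' @param focal_seconds length of a focal follow countdown in seconds
#' @param weight_bounds feasible weight range in grams, or `NULL` to disable
#' @return a list of class `fs_config`
#' @export
protocol_config <- function(month_days = 30.4375,
                            adult_female_months = 10,
                            pup_age_days = 90,
                            score_levels = 1:4,
                            gps_interval_s = 180L,
                            focal_seconds = 1200L,
                            weight_bounds = NULL) {
  structure(
    list(month_days = month_days, adult_female_months = adult_female_months,
         pup_age_days = pup_age_days, score_levels = score_levels,
         gps_interval_s = as.integer(gps_interval_s),
         focal_seconds = as.integer(focal_seconds),
         weight_bounds = weight_bounds),
    class = "fs_config"
  )
}

default_config <- protocol_config()

#' Manage packs (social groups)
#'
#' Packs are added as new groups enter the study area and retired (never
#' deleted) when groups die out: a retired pack keeps all its members and
#' records. Names must be unique among active packs, so a historical name can
#' be reused after its bearer is retired.
#'
#' @param store an [eav_store()]
#' @param name pack name, e.g. `"1H"`
#' @return the pack entity id
#' @export
add_pack <- function(store, name) {
  check_store(store)
  if (!is_scalar_chr(name) || !nzchar(name)) fs_invalid("pack name must be non-empty")
  active <- list_packs(store)
  if (name %in% active$name) fs_invalid(sprintf("active pack '%s' already exists", name))
  id <- create_entity(store, "pack")
  set_value(store, id, "name", name)
  set_value(store, id, "active", TRUE)
  id
}

#' @rdname add_pack
#' @param pack_id a pack entity id
#' @export
retire_pack <- function(store, pack_id) {
  pack <- get_entity(store, pack_id)
  if (pack$entity_type != "pack") fs_invalid("not a pack")
  if (!isTRUE(pack$attributes$active)) fs_invalid("pack is not active")
  set_value(store, pack_id, "active", FALSE)
  pack_id
}

#' @rdname add_pack
#' @param include_inactive include retired packs?
#' @export
list_packs <- function(store, include_inactive = FALSE) {
  tbl <- query_entities(store, "pack")
  if (nrow(tbl) == 0L) {
    return(tibble(entity_id = character(0), name = character(0), active = logical(0)))
  }
  if (!include_inactive) tbl <- tbl[tbl$active, ]
  tbl[c("entity_id", "name", "active")]
}

#' Manage individuals
#'
#' Individuals are added as they are born or immigrate and removed (softly)
#' as they die or emigrate; a removed individual keeps every record but is no
#' longer selectable in new observation sessions. Because rosters
#' synchronise, an identity entered on one tablet appears on all of them
#' after a sync round.
#'
#' @param store an [eav_store()]
#' @param pack_id the pack the individual belongs to (must be active)
#' @param name identity code, e.g. `"789"`
#' @param sex `"F"`, `"M"` or `"unknown"`
#' @param date_of_birth a `Date` (or `"YYYY-MM-DD"` text); never in the future
#'   of `today`
#' @param litter_code optional litter code
#' @param today reference date for the future-birth check (injectable clock)
#' @return the individual entity id
#' @export
add_individual <- function(store, pack_id, name, sex = c("F", "M", "unknown"),
                           date_of_birth, litter_code = NULL,
                           today = Sys.Date()) {
  check_store(store)
  pack <- get_entity(store, pack_id)
  if (pack$entity_type != "pack") fs_invalid("not a pack")
  if (!isTRUE(pack$attributes$active)) fs_invalid("pack is not active")
  sex <- match.arg(sex)
  dob <- as.Date(date_of_birth)
  if (is.na(dob)) fs_invalid("invalid date_of_birth")
  if (dob > as.Date(today)) fs_invalid("date_of_birth is in the future")
  id <- create_entity(store, "individual")
  set_value(store, id, "name", name)
  set_value(store, id, "pack", pack_id)
  set_value(store, id, "sex", sex)
  set_value(store, id, "date-of-birth", dob)
  if (!is.null(litter_code)) set_value(store, id, "litter-code", litter_code)
  id
}

#' @rdname add_individual
#' @param individual_id an individual entity id
#' @export
remove_individual <- function(store, individual_id) {
  ind <- get_entity(store, individual_id)
  if (ind$entity_type != "individual") fs_invalid("not an individual")
  set_value(store, individual_id, "membership-ended", TRUE)
  individual_id
}

#' @rdname add_individual
#' @param include_removed include individuals whose membership has ended?
#' @export
pack_roster <- function(store, pack_id, include_removed = FALSE) {
  tbl <- query_entities(store, "individual", pack = pack_id)
  if (nrow(tbl) == 0L) return(tbl)
  if (!include_removed && "membership-ended" %in% names(tbl)) {
    ended <- tbl[["membership-ended"]]
    tbl <- tbl[is.na(ended) | !ended, ]
  }
  tbl
}

#' Age in months
#'
#' Day-count arithmetic: `(days between dates) / month_days`, with a month
#' defaulting to 30.4375 days (the mean Gregorian month). Vectorised over
#' both dates.
#'
#' @param date_of_birth `Date` (or text)
#' @param on_date `Date` (or text), not before `date_of_birth`
#' @param month_days days per month
#' @return age in months (double)
#' @export
age_months <- function(date_of_birth, on_date, month_days = default_config$month_days) {
  dob <- as.Date(date_of_birth); on <- as.Date(on_date)
  if (any(is.na(dob)) || any(is.na(on))) fs_invalid("invalid date")
  if (any(on < dob)) fs_invalid("on_date is before date_of_birth")
  as.numeric(on - dob) / month_days
}

individual_age_months <- function(store, individual_id, on_date,
                                  config = default_config) {
  dob <- entity_attr(store, individual_id, "date-of-birth")
  if (is.null(dob)) fs_invalid("individual has no date of birth")
  age_months(dob, on_date, config$month_days)
}

#' Pregnancy eligibility
#'
#' Only adult females — strictly older than 10 months — are selectable for a
#' pregnancy record; the threshold and month length are configurable in
#' [protocol_config()].
#'
#' @param store an [eav_store()]
#' @param individual_id individual entity id
#' @param on_date observation date
#' @param config a [protocol_config()]
#' @return `TRUE` iff female and age strictly over the threshold
#' @export
eligible_for_pregnancy <- function(store, individual_id, on_date,
                                   config = default_config) {
  sex <- entity_attr(store, individual_id, "sex")
  if (!identical(sex, "F")) return(FALSE)
  individual_age_months(store, individual_id, on_date, config) > config$adult_female_months
}

is_pup <- function(store, individual_id, on_date, config = default_config) {
  dob <- entity_attr(store, individual_id, "date-of-birth")
  if (is.null(dob)) return(FALSE)
  as.numeric(as.Date(on_date) - as.Date(dob)) < config$pup_age_days
}
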