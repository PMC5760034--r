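#' Count stored records by type
#'
#' @param store an [eav_store()] (a replica, the hub, or a loaded snapshot)
#' @param include_deleted count soft-deleted entities too?
#' @return a tibble `entity_type`, `n` (types present in the store only)
#' @export
list_record_types <- function(store, include_deleted = FALSE) {
  check_store(store)
  ids <- ordered_entity_ids(store)
  if (!include_deleted && length(ids)) {
    ids <- ids[!vapply(ids, function(i) is_deleted(store, i), logical(1))]
  }
  types <- vapply(ids, function(i) store$entities[[i]]$entity_type, character(1))
  counts <- table(factor(types, levels = entity_types))
  counts <- counts[counts > 0]
  tibble(entity_type = names(counts), n = as.integer(counts))
}

# Fixed, documented column order per record type. `id` is always first;
# foreign keys are exported as entity ids followed by a human-readable name
# column; a `deleted` column is appended when include_deleted = TRUE.
export_columns <- list(
  "pack" = c("name", "active"),
  "individual" = c("name", "pack", "pack_name", "sex", "date-of-birth",
                   "litter-code", "membership-ended"),
  "group-composition-session" = c("pack", "pack_name", "date", "start-time", "end-time"),
  "weight" = c("session", "individual", "individual_name", "grams", "period",
               "session-time"),
  "pregnancy" = c("session", "individual", "individual_name", "status"),
  "mate-guard" = c("session", "male", "male_name", "female", "female_name",
                   "strength", "accuracy", "primary"),
  "escort" = c("session", "pup", "pup_name", "escort", "escort_name",
               "strength", "accuracy"),
  "babysit" = c("session", "individual", "individual_name", "evidence"),
  "gps-fix" = c("session", "t-seconds", "timestamp", "lat", "lon"),
  "focal-follow" = c("protocol", "focal", "focal_name", "start-time", "end-time",
                     "state", "paused-seconds", "pause-count"),
  "focal-scan" = c("follow", "minute-index", "nearest", "within-2m", "missed"),
  "focal-interaction" = c("follow", "kind", "partner", "partner_name",
                          "initiator", "intensity", "context", "winner",
                          "at-seconds"),
  "group-event" = c("pack", "pack_name", "event-type", "timestamp",
                    "participants", "other-pack", "outcome", "cause",
                    "target", "direction", "free-text"),
  "note" = c("pack", "pack_name", "timestamp", "free-text")
)

# export column typing shared by export_table() (typed NA for absent
# attributes) and export_col_spec() (re-parse types)
export_int_cols <- c("grams", "t_seconds", "strength", "accuracy", "minute_index",
                     "paused_seconds", "pause_count", "at_seconds")
export_dbl_cols <- c("lat", "lon")
export_lgl_cols <- c("active", "status", "primary", "membership_ended", "missed")

col_na_proto <- function(col) {
  col <- gsub("-", "_", col)
  if (col %in% export_int_cols) NA_integer_
  else if (col %in% export_dbl_cols) NA_real_
  else if (col %in% export_lgl_cols) NA
  else NA_character_
}

# foreign-key columns that gain a *_name companion looked up in the store
name_lookups <- list(
  pack_name = "pack", individual_name = "individual", male_name = "male",
  female_name = "female", pup_name = "pup", escort_name = "escort",
  focal_name = "focal", partner_name = "partner"
)

#' Export record types as CSV tables
#'
#' One CSV per requested type, RFC 4180 quoted, UTF-8, `\n` line endings,
#' with the fixed column order in `fieldsync:::export_columns` and rows in
#' the store's stable entity-creation order — so two exports of the same
#' store are byte-identical, and re-parsing reproduces every stored value
#' exactly. Foreign keys are exported as entity ids plus a human-readable
#' name column; timestamps are ISO 8601 text. Soft-deleted records are
#' excluded unless `include_deleted = TRUE`, which appends a `deleted`
#' column (deletion is always recoverable, never destructive).
#'
#' @param store an [eav_store()] or loaded snapshot
#' @param record_types character vector of entity types to export
#' @param output_dir directory for the CSV files (created if needed)
#' @param include_deleted include soft-deleted records (adds `deleted` column)?
#' @param date_range optional `c(from, to)` `Date`s filtering records carrying
#'   a `date` attribute (sessions)
#' @param pack optional pack entity id filter for types carrying a `pack`
#'   attribute
#' @return character vector of written file paths (one per type)
#' @export
export_csv <- function(store, record_types, output_dir,
                       include_deleted = FALSE, date_range = NULL, pack = NULL) {
  check_store(store)
  if (length(record_types) == 0L) fs_invalid("at least one record type required")
  unknown <- setdiff(record_types, entity_types)
  if (length(unknown)) {
    fs_invalid(sprintf("unknown record type(s): %s", paste(unknown, collapse = ", ")))
  }
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(output_dir)) fs_invalid(sprintf("cannot create '%s'", output_dir))
  vapply(record_types, function(tp) {
    tbl <- export_table(store, tp, include_deleted, date_range, pack)
    path <- file.path(output_dir, paste0(tp, ".csv"))
    readr::write_csv(tbl, path, na = "", eol = "\n")
    path
  }, character(1), USE.NAMES = FALSE)
}

#' @rdname export_csv
#' @param record_type a single entity type
#' @return `export_table()`: the corresponding tibble without writing a file
#' @export
export_table <- function(store, record_type, include_deleted = FALSE,
                         date_range = NULL, pack = NULL) {
  cols <- export_columns[[record_type]]
  if (is.null(cols)) fs_invalid(sprintf("unknown record type '%s'", record_type))
  tbl <- query_entities(store, record_type, include_deleted = include_deleted)
  if (!is.null(pack) && nrow(tbl) > 0L && "pack" %in% names(tbl)) {
    tbl <- tbl[!is.na(tbl$pack) & tbl$pack == pack, ]
  }
  if (!is.null(date_range) && nrow(tbl) > 0L && "date" %in% names(tbl)) {
    d <- as.Date(tbl$date)
    tbl <- tbl[!is.na(d) & d >= as.Date(date_range[1]) & d <= as.Date(date_range[2]), ]
  }
  out <- tibble(id = tbl$entity_id %||% character(0))
  if (nrow(tbl) == 0L) out <- tibble(id = character(0))
  for (col in cols) {
    out[[col]] <- if (col %in% names(name_lookups)) {
      ref_col <- name_lookups[[col]]
      refs <- if (ref_col %in% names(tbl)) tbl[[ref_col]] else rep(NA_character_, nrow(tbl))
      vapply(refs, function(r) {
        if (is.na(r)) NA_character_
        else entity_attr(store, r, "name", default = NA_character_)
      }, character(1), USE.NAMES = FALSE)
    } else if (col %in% names(tbl)) {
      v <- tbl[[col]]
      if (is.list(v)) {
        vapply(v, function(x) if (is.null(x)) NA_character_ else format(x), character(1))
      } else v
    } else {
      rep(col_na_proto(col), nrow(tbl))
    }
  }
  names(out) <- gsub("-", "_", names(out))
  if (include_deleted) out$deleted <- tbl$deleted %||% logical(0)
  out
}

#' Column types for re-parsing an exported CSV
#'
#' A `readr` column specification matching the export schema of a record
#' type, so a round-trip `export_csv()` then [readr::read_csv()] reproduces
#' stored values exactly.
#'
#' @param record_type a single entity type
#' @param include_deleted was the file exported with the `deleted` column?
#' @return a [readr::cols()] specification
#' @export
export_col_spec <- function(record_type, include_deleted = FALSE) {
  cols <- gsub("-", "_", export_columns[[record_type]])
  spec <- stats::setNames(lapply(cols, function(cl) {
    if (cl %in% export_int_cols) readr::col_integer()
    else if (cl %in% export_dbl_cols) readr::col_double()
    else if (cl %in% export_lgl_cols) readr::col_logical()
    else readr::col_character()
  }), cols)
  spec <- c(list(id = readr::col_character()), spec)
  if (include_deleted) spec$deleted <- readr::col_logical()
  do.call(readr::cols, spec)
}
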