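#' Typed attribute values
#'
#' Every datum in the store is a tagged scalar: one of `text`, `integer`,
#' `real`, `boolean`, `timestamp` or `null`. The tag travels with the payload
#' through persistence and through sync, so a weight recorded as the integer
#' 1234 is still the integer 1234 after a round-trip through the hub and a
#' CSV export. There is deliberately no list tag: structured payloads (e.g.
#' the set of individuals within 2 m in a scan) are stored as JSON text by the
#' domain layer.
#'
#' `fs_value()` wraps an R scalar, inferring the tag; `fs_timestamp()` tags a
#' `POSIXct` (or ISO 8601 text) explicitly as a timestamp.
#'
#' @param x a scalar: character, integer, double, logical, `Date`, `POSIXct`
#'   or `NULL`
#' @return a `fs_value` object: `list(tag =, payload =)`
#' @export
fs_value <- function(x) {
  if (inherits(x, "fs_value")) return(x)
  if (is.null(x) || (length(x) == 1L && is.na(x) && !is.character(x))) {
    return(new_value("null", NULL))
  }
  if (length(x) != 1L) fs_invalid("attribute values are scalars")
  if (inherits(x, "POSIXt")) return(new_value("timestamp", iso8601(x)))
  if (inherits(x, "Date")) return(new_value("text", format(x, "%Y-%m-%d")))
  if (is.logical(x)) return(new_value("boolean", x))
  if (is.integer(x)) return(new_value("integer", x))
  if (is.double(x)) return(new_value("real", x))
  if (is.character(x)) return(new_value("text", x))
  fs_invalid(sprintf("unsupported value class: %s", paste(class(x), collapse = "/")))
}

#' @rdname fs_value
#' @export
fs_timestamp <- function(x) {
  if (inherits(x, "POSIXt")) return(new_value("timestamp", iso8601(x)))
  if (is_scalar_chr(x)) {
    if (is.na(parse_iso8601(x))) fs_invalid("timestamp text must be ISO 8601 with offset")
    return(new_value("timestamp", x))
  }
  fs_invalid("timestamp must be POSIXct or ISO 8601 text")
}

new_value <- function(tag, payload) {
  structure(list(tag = tag, payload = payload), class = "fs_value")
}

value_tags <- c("text", "integer", "real", "boolean", "timestamp", "null")

# decode a (tag, payload-as-text) pair read back from SQLite or JSON
decode_value <- function(tag, payload_chr) {
  if (!tag %in% value_tags) fs_invalid(sprintf("unknown value tag '%s'", tag))
  payload <- switch(tag,
    null = NULL,
    text = ,
    timestamp = payload_chr,
    integer = as.integer(payload_chr),
    real = as.numeric(payload_chr),
    boolean = identical(payload_chr, "true") || identical(payload_chr, "TRUE")
  )
  new_value(tag, payload)
}

# encode the payload as text for storage; full double precision via format
encode_payload <- function(value) {
  switch(value$tag,
    null = NA_character_,
    text = ,
    timestamp = value$payload,
    integer = format(value$payload),
    real = format(value$payload, digits = 17, scientific = FALSE, trim = TRUE),
    boolean = if (isTRUE(value$payload)) "true" else "false"
  )
}

value_payload <- function(value) value$payload

values_equal <- function(a, b) identical(a$tag, b$tag) && identical(a$payload, b$payload)

#' @export
print.fs_value <- function(x, ...) {
  cat(sprintf("<fs_value %s: %s>\n", x$tag, encode_payload(x) %||% "NULL"))
  invisible(x)
}
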