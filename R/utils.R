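#' @importFrom rlang abort %||%
#' @importFrom tibble tibble as_tibble
NULL

# Typed error conditions. Every rejection in the package signals one of these
# classes so callers (and the CLI) can distinguish user error, gating
# violations, protocol conflicts and transport failures.
fs_abort <- function(class, message, ...) {
  rlang::abort(message, class = c(class, "fieldsync_error"), ...)
}

fs_not_found <- function(what, id) {
  fs_abort("fieldsync_not_found", sprintf("%s '%s' not found", what, id))
}

fs_invalid <- function(message, ...) fs_abort("fieldsync_invalid", message, ...)

fs_gating <- function(message, ...) fs_abort("fieldsync_gating", message, ...)

#' Derive a labelled RNG substream seed from a master seed
#'
#' Each generator in the synthetic-fixture layer draws from its own stream,
#' derived deterministically from the master seed and a label, so adding a new
#' generator never perturbs the draws of an existing one. The derivation is a
#' small integer hash kept below 2^31.
#'
#' @param seed master integer seed
#' @param label character label naming the substream
#' @return an integer seed
#' @export
substream_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- 0
  for (code in utf8ToInt(label)) h <- (h * 131 + code) %% 2147483647
  as.integer((abs(seed) %% 2147483647 * 7919 + h) %% 2147483647)
}

with_substream <- function(seed, label, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, label))
  force(code)
}

# ISO 8601 timestamp text with explicit UTC offset; all stored timestamps use
# this format. Ordering decisions in the sync layer never consult these.
iso8601 <- function(x) {
  stopifnot(inherits(x, "POSIXt"))
  format(x, "%Y-%m-%dT%H:%M:%S+0000", tz = "UTC")
}

parse_iso8601 <- function(x) {
  as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S%z", tz = "UTC")
}

is_scalar_chr <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
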