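#' @import rlang
#' @importFrom dplyr %>% filter mutate select arrange group_by ungroup summarise
#'   distinct left_join inner_join anti_join semi_join bind_rows n row_number
#'   lag lead first last pull rename across all_of any_of if_else slice
#' @importFrom tibble tibble as_tibble
#' @importFrom stats setNames
#' @importFrom utils head tail
NULL

# Attribute data types understood by the warehouse. SingleChoice is text with a
# closed value set (codes such as modalities); the distinction matters only for
# operator/type checking, storage is text throughout.
DATA_TYPES <- c("Boolean", "Number", "Text", "SingleChoice", "DateTime")
METADATA_TYPES <- c("None", "PatientID", "AppointmentID", "ExamID",
                    "MeasureTime", "Modality")

#' Parse a timestamp in the accepted RIS conventions
#'
#' Accepts ISO-8601 (`2018-03-05T14:30:00` or with a space, seconds optional,
#' date-only allowed) and the German RIS convention `dd.mm.yyyy HH:MM[:SS]`.
#' Times are naive local times; no timezone arithmetic is performed.
#'
#' @param x character vector of raw timestamp strings.
#' @return `POSIXct` vector (UTC-flagged purely as a fixed frame; values are
#'   naive local times). Unparseable entries become `NA`.
#' @export
parse_timestamp <- function(x) {
  x <- trimws(as.character(x))
  out <- rep(as.POSIXct(NA, tz = "UTC"), length(x))
  iso <- grepl("^\\d{4}-\\d{2}-\\d{2}([T ]\\d{2}:\\d{2}(:\\d{2})?)?$", x)
  ger <- grepl("^\\d{1,2}\\.\\d{1,2}\\.\\d{4}( \\d{1,2}:\\d{2}(:\\d{2})?)?$", x)
  if (any(iso, na.rm = TRUE)) {
    xi <- sub("T", " ", x[which(iso)])
    xi[nchar(xi) == 10] <- paste(xi[nchar(xi) == 10], "00:00:00")
    xi[nchar(xi) == 16] <- paste0(xi[nchar(xi) == 16], ":00")
    out[which(iso)] <- as.POSIXct(xi, tz = "UTC", format = "%Y-%m-%d %H:%M:%S")
  }
  if (any(ger, na.rm = TRUE)) {
    xg <- x[which(ger)]
    xg[!grepl(" ", xg)] <- paste(xg[!grepl(" ", xg)], "00:00")
    xg[grepl("^\\S+ \\d{1,2}:\\d{2}$", xg)] <-
      paste0(xg[grepl("^\\S+ \\d{1,2}:\\d{2}$", xg)], ":00")
    out[which(ger)] <- as.POSIXct(xg, tz = "UTC", format = "%d.%m.%Y %H:%M:%S")
  }
  out
}

#' Render a timestamp in the warehouse's canonical form
#'
#' @param t `POSIXct` vector.
#' @return character vector `YYYY-MM-DDTHH:MM:SS` (ISO-8601); `NA` stays `NA`.
#' @export
format_timestamp <- function(t) {
  ifelse(is.na(t), NA_character_, format(t, "%Y-%m-%dT%H:%M:%S", tz = "UTC"))
}

# Canonical locale-independent decimal rendering of a number.
canonical_number <- function(x) {
  n <- suppressWarnings(as.numeric(x))
  ifelse(is.na(n), NA_character_,
         ifelse(n == round(n) & abs(n) < 1e15,
                format(n, scientific = FALSE, trim = TRUE),
                format(n, scientific = FALSE, trim = TRUE, digits = 15)))
}

# Boolean raw tokens accepted on import (case-insensitive).
BOOL_TRUE  <- c("1", "true", "ja", "yes")
BOOL_FALSE <- c("0", "false", "nein", "no")

parse_boolean <- function(x) {
  lx <- tolower(trimws(x))
  ifelse(lx %in% BOOL_TRUE, "true", ifelse(lx %in% BOOL_FALSE, "false", NA_character_))
}

#' Canonicalize a raw cell value for storage
#'
#' Applies the type-specific canonical rendering the warehouse stores: numbers
#' as locale-independent decimal text, booleans as `"true"`/`"false"`,
#' timestamps as ISO-8601, Text/SingleChoice verbatim.
#'
#' @param x character vector of raw values.
#' @param data_type one of `"Boolean"`, `"Number"`, `"Text"`, `"SingleChoice"`,
#'   `"DateTime"`.
#' @return character vector; entries that fail type parsing are `NA`.
#' @export
canonical_value <- function(x, data_type) {
  x <- as.character(x)
  switch(data_type,
    Boolean  = parse_boolean(x),
    Number   = canonical_number(x),
    DateTime = format_timestamp(parse_timestamp(x)),
    # Text / SingleChoice: stored verbatim (trimmed)
    trimws(x)
  )
}

# Consistent error classes -------------------------------------------------

abort_validation <- function(msg, ...) {
  rlang::abort(msg, class = "radwh_validation_error", ...)
}

#' @details Capability errors signal that the loaded data cannot support the
#' requested operation (e.g. patient-level queries on an export that carries no
#' patient identifiers). They carry class `radwh_capability_error`.
#' @noRd
abort_capability <- function(msg, ...) {
  rlang::abort(msg, class = "radwh_capability_error", ...)
}
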