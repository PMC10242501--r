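CONFIG_HEADER <- c("DisplayTitle", "ExtID", "DataType", "ColumnName",
                   "ColumnNumber", "ValueMappings", "MetaDataType")

#' Parse a ValueMappings cell
#'
#' Dialect: semicolon-separated `raw=replacement` pairs; literal `;` and `=`
#' can be escaped with a backslash. The empty cell means no mappings.
#'
#' @param s a single character string (may be empty or `NA`).
#' @return named character vector in cell order (`names` = raw values).
#' @export
parse_value_mappings <- function(s) {
  if (is.na(s) || !nzchar(trimws(s))) return(stats::setNames(character(), character()))
  # split on unescaped ';', then each pair on the first unescaped '='
  pairs <- strsplit(s, "(?<!\\\\);", perl = TRUE)[[1]]
  raws <- reps <- character(length(pairs))
  for (i in seq_along(pairs)) {
    m <- regexpr("(?<!\\\\)=", pairs[i], perl = TRUE)
    if (m < 0)
      abort_validation(paste0("malformed value mapping '", pairs[i],
                              "': expected raw=replacement"))
    unesc <- function(x) gsub("\\\\(.)", "\\1", x)
    raws[i] <- unesc(substr(pairs[i], 1, m - 1))
    reps[i] <- unesc(substr(pairs[i], m + 1, nchar(pairs[i])))
  }
  if (anyDuplicated(raws))
    abort_validation("duplicate raw value in value mappings")
  stats::setNames(reps, raws)
}

serialize_value_mappings <- function(m) {
  if (length(m) == 0) return("")
  esc <- function(x) gsub("([;=\\\\])", "\\\\\\1", x)
  paste(paste0(esc(names(m)), "=", esc(unname(m))), collapse = ";")
}

#' Read an import-mapping configuration
#'
#' The configuration maps RIS export columns to catalog entries. It is a table
#' with the fixed header `DisplayTitle, ExtID, DataType, ColumnName,
#' ColumnNumber, ValueMappings, MetaDataType`; one row per export column to
#' import (columns absent from the configuration are ignored at import).
#' Metadata roles `AppointmentID`, `MeasureTime` and `Modality` are required;
#' `PatientID` and `ExamID` are optional.
#'
#' @param path path to the configuration file.
#' @param format `"csv"` or `"excel"` (guessed from the extension by default).
#' @param project terminology name under which catalog entries are created.
#' @return an object of class `import_config`: list with `specs` (a tibble,
#'   one row per attribute, `value_mappings` as a list-column) and `project`.
#' @export
parse_import_config <- function(path, format = c("auto", "csv", "excel"),
                                project = "ris") {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) "excel" else "csv"
  if (!file.exists(path)) abort_validation(paste0("no such file: ", path))
  raw <- read_text_table(path, format)
  if (!identical(names(raw), CONFIG_HEADER))
    abort_validation(paste0(
      "configuration header must be exactly: ",
      paste(CONFIG_HEADER, collapse = ", ")))
  specs <- tibble(
    display_title = raw$DisplayTitle,
    ext_id = raw$ExtID,
    data_type = raw$DataType,
    column_name = dplyr::na_if(raw$ColumnName, ""),
    column_number = suppressWarnings(as.integer(raw$ColumnNumber)),
    value_mappings = purrr::map(raw$ValueMappings, parse_value_mappings),
    metadata_type = if_else(raw$MetaDataType == "" | is.na(raw$MetaDataType),
                            "None", raw$MetaDataType)
  )
  bad_dt <- setdiff(unique(specs$data_type), DATA_TYPES)
  if (length(bad_dt))
    abort_validation(paste0("unknown DataType token: ", paste(bad_dt, collapse = ", ")))
  bad_mt <- setdiff(unique(specs$metadata_type), METADATA_TYPES)
  if (length(bad_mt))
    abort_validation(paste0("unknown MetaDataType token: ", paste(bad_mt, collapse = ", ")))
  if (any(is.na(specs$ext_id) | !nzchar(specs$ext_id)))
    abort_validation("ExtID must be non-empty")
  if (anyDuplicated(specs$ext_id))
    abort_validation(paste0("duplicate ext_id in configuration: ",
                            specs$ext_id[duplicated(specs$ext_id)][1]))
  roles <- specs$metadata_type[specs$metadata_type != "None"]
  if (anyDuplicated(roles))
    abort_validation(paste0("metadata role assigned twice: ",
                            roles[duplicated(roles)][1]))
  missing_roles <- setdiff(c("AppointmentID", "MeasureTime", "Modality"), roles)
  if (length(missing_roles))
    abort_validation(paste0("missing required metadata role: ",
                            paste(missing_roles, collapse = ", ")))
  if (any(is.na(specs$column_name) & is.na(specs$column_number)))
    abort_validation("each row needs ColumnName or ColumnNumber")
  structure(list(specs = specs, project = project), class = "import_config")
}

#' @export
print.import_config <- function(x, ...) {
  cat("<import_config> project '", x$project, "', ", nrow(x$specs),
      " attributes\n", sep = "")
  invisible(x)
}

# Read a header+rows table as all-text tibble, from CSV (delimiter
# autodetected from the header row) or Excel (first sheet, via readxl).
read_text_table <- function(path, format) {
  if (format == "excel") {
    df <- readxl::read_excel(path, col_types = "text", sheet = 1)
    df <- as_tibble(df)
    df[] <- lapply(df, function(col) ifelse(is.na(col), "", as.character(col)))
    return(df)
  }
  header <- readLines(path, n = 1L, encoding = "UTF-8")
  delim <- if (stringr::str_count(header, ";") > stringr::str_count(header, ","))
    ";" else ","
  df <- readr::read_delim(path, delim = delim,
                          col_types = readr::cols(.default = "c"),
                          na = character(), trim_ws = FALSE,
                          locale = readr::locale(encoding = "UTF-8"),
                          progress = FALSE, show_col_types = FALSE)
  df
}

#' Read an RIS export into a raw table
#'
#' One examination per row, one attribute per column, attribute names in the
#' first row. Cell values are kept as raw text; typing happens at import.
#'
#' @param path path to the export.
#' @param format `"csv"` (delimiter autodetected), `"excel"` (first sheet) or
#'   `"json"` (flat array of objects whose keys become columns, in first-seen
#'   order); `"auto"` guesses from the extension.
#' @return a tibble of character columns, class `ris_table`.
#' @export
read_ris_export <- function(path, format = c("auto", "csv", "excel", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) "excel"
      else if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (!file.exists(path)) abort_validation(paste0("no such file: ", path))
  if (format == "json") {
    arr <- jsonlite::read_json(path)
    if (!is.list(arr) || (length(arr) && !all(vapply(arr, is.list, logical(1)))))
      abort_validation("JSON export must be an array of flat objects")
    if (length(arr) == 0L) abort_validation("empty RIS export")
    if (any(vapply(arr, function(o) any(vapply(o, is.list, logical(1))), logical(1))))
      abort_validation("JSON export must be an array of flat objects")
    cols <- unique(unlist(lapply(arr, names)))
    df <- purrr::map_dfr(arr, function(o) {
      vals <- vapply(cols, function(k) {
        v <- o[[k]]
        if (is.null(v)) "" else as.character(v)
      }, character(1))
      as_tibble(as.list(vals))
    })
  } else {
    df <- read_text_table(path, format)
    if (nrow(df) == 0L) abort_validation("empty RIS export")
  }
  if (anyDuplicated(names(df)))
    abort_validation("duplicate column names in RIS export header")
  df[] <- lapply(df, function(col) ifelse(is.na(col), "", as.character(col)))
  class(df) <- c("ris_table", class(df))
  df
}

# Resolve each spec to a column of `table`; validates ColumnName/ColumnNumber
# agreement. Returns the specs tibble with a `column` string column.
resolve_columns <- function(config, table) {
  specs <- config$specs
  header <- names(table)
  col <- character(nrow(specs))
  for (i in seq_len(nrow(specs))) {
    nm <- specs$column_name[i]
    no <- specs$column_number[i]
    if (!is.na(nm) && !nm %in% header)
      abort_validation(paste0("configured column '", nm, "' not in export header"))
    if (!is.na(no) && (no < 1L || no > length(header)))
      abort_validation(paste0("ColumnNumber ", no, " out of range"))
    if (!is.na(nm) && !is.na(no) && header[no] != nm)
      abort_validation(paste0(
        "ColumnName '", nm, "' and ColumnNumber ", no,
        " disagree (column ", no, " is '", header[no], "')"))
    col[i] <- if (!is.na(nm)) nm else header[no]
  }
  specs$column <- col
  specs
}

#' Import an RIS table into a warehouse
#'
#' Creates (or re-uses) one catalog entry per configured attribute and one info
#' record per non-empty mapped cell. Value mappings are applied before
#' storage. Empty cells are silently skipped; type-invalid cells (e.g. a
#' non-numeric value in a Number column) are skipped with a warning; neither
#' aborts the import. When no `ExamID` column is configured, examination
#' identifiers are synthesized as `<AppointmentID>#<ordinal>`.
#'
#' @param config an [parse_import_config()] result.
#' @param table a [read_ris_export()] table.
#' @param wh a [warehouse()] (mutated in place).
#' @param only optional character vector of `ext_id`s: restrict record
#'   creation to these attributes (metadata columns are still used for IDs).
#'   Used by the incremental-update pathway.
#' @param reprocess logical; `TRUE` when re-importing a previously imported
#'   file (the incremental attribute-update pathway). Synthesized exam IDs are
#'   then recomputed from scratch so they match the original import, and no
#'   duplicate-ID rejection is applied.
#' @return an `import_stats` list: rows read, records created, empty cells
#'   skipped, invalid cells, values remapped, rows rejected (duplicate exam
#'   IDs), catalog entries touched.
#' @export
import_table <- function(config, table, wh, only = NULL, reprocess = FALSE) {
  specs <- resolve_columns(config, table)
  n <- nrow(table)
  role_col <- function(role) {
    i <- which(specs$metadata_type == role)
    if (length(i)) specs$column[i] else NULL
  }
  aid_col <- role_col("AppointmentID")
  mt_col  <- role_col("MeasureTime")
  pid_col <- role_col("PatientID")
  eid_col <- role_col("ExamID")
  for (colnm in c(aid_col, mt_col, role_col("Modality"))) {
    if (any(!nzchar(table[[colnm]])))
      abort_validation(paste0("required metadata column '", colnm,
                              "' has empty cells"))
  }
  aid <- as.character(table[[aid_col]])
  mt_raw <- as.character(table[[mt_col]])
  mt <- format_timestamp(parse_timestamp(mt_raw))
  if (any(is.na(mt)))
    abort_validation(paste0("unparseable MeasureTime value: '",
                            mt_raw[which(is.na(mt))[1]], "'"))
  pid <- if (is.null(pid_col)) rep(NA_character_, n) else {
    p <- as.character(table[[pid_col]])
    ifelse(nzchar(p), p, NA_character_)
  }
  rejected <- rep(FALSE, n)
  if (!is.null(eid_col)) {
    eid <- as.character(table[[eid_col]])
    if (any(!nzchar(eid)))
      abort_validation("configured ExamID column has empty cells")
    if (!reprocess) {
      dup <- duplicated(eid) | eid %in% wh$infos$exam_id
      if (any(dup)) {
        rejected <- dup
        rlang::warn(paste0(sum(dup), " row(s) rejected: duplicate ExamID"))
      }
    }
  } else if (reprocess) {
    # recompute the ordinals a first import of this file produced
    ord <- stats::ave(seq_along(aid), aid, FUN = seq_along)
    eid <- paste0(aid, "#", ord)
  } else {
    eid <- next_exam_id(wh, aid)
  }
  # upsert catalog entries for every spec (even when `only` restricts records)
  entries <- purrr::pmap(specs, function(display_title, ext_id, data_type, ...)
    upsert_catalog_entry(wh, ext_id, config$project, display_title, data_type))
  attr_ids <- vapply(entries, function(e) e$attribute_id, integer(1))

  active <- if (is.null(only)) seq_len(nrow(specs)) else which(specs$ext_id %in% only)
  skipped <- invalid <- remapped <- created <- 0L
  chunks <- vector("list", length(active))
  keep <- !rejected
  for (k in seq_along(active)) {
    i <- active[k]
    raw <- as.character(table[[specs$column[i]]])[keep]
    m <- specs$value_mappings[[i]]
    if (length(m)) {
      hit <- raw %in% names(m)
      remapped <- remapped + sum(hit & nzchar(raw))
      raw[hit] <- unname(m[raw[hit]])
    }
    empty <- !nzchar(raw)
    skipped <- skipped + sum(empty)
    val <- canonical_value(raw, specs$data_type[i])
    bad <- !empty & is.na(val)
    if (any(bad)) {
      invalid <- invalid + sum(bad)
      rlang::warn(paste0(sum(bad), " cell(s) in column '", specs$column[i],
                         "' invalid for type ", specs$data_type[i], "; skipped"))
    }
    ok <- !empty & !bad
    created <- created + sum(ok)
    chunks[[k]] <- tibble(
      attribute_id = attr_ids[i], patient_id = pid[keep][ok],
      appointment_id = aid[keep][ok], exam_id = eid[keep][ok],
      measure_time = mt[keep][ok], value = val[ok], owner = NA_character_)
  }
  append_infos(wh, bind_rows(chunks))
  structure(list(
    rows_read = n, rows_rejected = sum(rejected), records_created = created,
    cells_skipped = skipped, cells_invalid = invalid, values_remapped = remapped,
    catalog_entries = length(attr_ids),
    attribute_ids = attr_ids[active], exam_ids = eid[keep]
  ), class = "import_stats")
}

#' @export
print.import_stats <- function(x, ...) {
  cat("<import_stats> rows: ", x$rows_read,
      " (rejected ", x$rows_rejected, ")",
      "; records: ", x$records_created,
      "; empty cells: ", x$cells_skipped,
      "; invalid cells: ", x$cells_invalid,
      "; remapped: ", x$values_remapped, "\n", sep = "")
  invisible(x)
}
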