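#' Create an empty warehouse
#'
#' The warehouse is the entity-attribute-value core: a *catalog* of attribute
#' types (identified by the combination of external ID and project/terminology)
#' and a flat table of *info records*, each tying one typed value to a patient,
#' appointment and examination plus a measure time. It is an environment-backed
#' object: importing and derivation mutate it in place and return statistics.
#'
#' @return an object of class `warehouse`.
#' @examples
#' wh <- warehouse()
#' upsert_catalog_entry(wh, "MOD", "ris", "Modality", "SingleChoice")
#' catalog(wh)
#' @export
warehouse <- function() {
  wh <- new.env(parent = emptyenv())
  wh$catalog <- tibble(
    attribute_id = integer(), ext_id = character(), project = character(),
    display_name = character(), parent_id = integer(), data_type = character()
  )
  wh$infos <- tibble(
    info_id = integer(), attribute_id = integer(), patient_id = character(),
    appointment_id = character(), exam_id = character(),
    measure_time = character(), value = character(), owner = character()
  )
  wh$next_attribute_id <- 1L
  wh$next_info_id <- 1L
  wh$exam_counters <- new.env(parent = emptyenv())  # per-appointment ordinals
  wh$revision <- 0L
  class(wh) <- "warehouse"
  wh
}

#' @export
print.warehouse <- function(x, ...) {
  cat("<warehouse> ", nrow(x$catalog), " catalog entries, ",
      nrow(x$infos), " info records\n", sep = "")
  invisible(x)
}

#' Catalog and info-record tables of a warehouse
#'
#' @param wh a [warehouse()].
#' @return a tibble: one row per catalog entry / info record.
#' @export
catalog <- function(wh) wh$catalog

#' @rdname catalog
#' @export
infos <- function(wh) wh$infos

#' @importFrom generics glance
#' @export
generics::glance

#' One-row summary of a warehouse
#'
#' Counts distinct patients, appointments, examinations, imported values and
#' generated (calculator-derived) values.
#'
#' @param x a [warehouse()].
#' @param ... unused.
#' @method glance warehouse
#' @export
glance.warehouse <- function(x, ...) {
  inf <- x$infos
  tibble(
    catalog_entries = nrow(x$catalog),
    patients = dplyr::n_distinct(inf$patient_id[!is.na(inf$patient_id)]),
    appointments = dplyr::n_distinct(inf$appointment_id),
    examinations = dplyr::n_distinct(inf$exam_id),
    values_imported = sum(is.na(inf$owner)),
    values_generated = sum(!is.na(inf$owner))
  )
}

bump_revision <- function(wh) {
  wh$revision <- wh$revision + 1L
  invisible(wh)
}

#' Insert or fetch a catalog entry
#'
#' Catalog identity is the combination `(ext_id, project)`; the numeric
#' attribute ID is installation-local. Re-upserting an existing identity
#' returns the existing entry (display name may be refreshed); a differing
#' data type is a configuration error, never silently changed.
#'
#' @param wh a [warehouse()].
#' @param ext_id external identifier within the terminology (e.g. an ICD code).
#' @param project terminology name.
#' @param display_name human-readable name.
#' @param data_type one of `r paste(DATA_TYPES, collapse = ", ")`.
#' @param parent_ext_id optional external ID of the parent entry (same
#'   project); parents must already exist, links form a forest.
#' @return one-row tibble for the entry (invisibly the warehouse is updated).
#' @export
upsert_catalog_entry <- function(wh, ext_id, project, display_name, data_type,
                                 parent_ext_id = NULL) {
  stopifnot(is.character(ext_id), nzchar(ext_id))
  if (!data_type %in% DATA_TYPES)
    abort_validation(paste0("unknown data type '", data_type, "'"))
  hit <- wh$catalog[wh$catalog$ext_id == ext_id & wh$catalog$project == project, ]
  if (nrow(hit) == 1L) {
    if (hit$data_type != data_type)
      abort_validation(paste0(
        "data-type conflict for (", ext_id, ", ", project, "): catalog has ",
        hit$data_type, ", got ", data_type))
    if (!identical(hit$display_name, display_name)) {
      wh$catalog$display_name[wh$catalog$attribute_id == hit$attribute_id] <-
        display_name
      bump_revision(wh)
    }
    return(wh$catalog[wh$catalog$attribute_id == hit$attribute_id, ])
  }
  parent_id <- NA_integer_
  if (!is.null(parent_ext_id) && !is.na(parent_ext_id)) {
    p <- wh$catalog[wh$catalog$ext_id == parent_ext_id &
                    wh$catalog$project == project, ]
    if (nrow(p) != 1L)
      abort_validation(paste0("unknown parent entry (", parent_ext_id, ", ",
                              project, ")"))
    parent_id <- p$attribute_id
  }
  entry <- tibble(
    attribute_id = wh$next_attribute_id, ext_id = ext_id, project = project,
    display_name = display_name, parent_id = parent_id, data_type = data_type
  )
  wh$next_attribute_id <- wh$next_attribute_id + 1L
  wh$catalog <- bind_rows(wh$catalog, entry)
  bump_revision(wh)
  entry
}

lookup_attribute <- function(wh, ext_id, project) {
  hit <- wh$catalog[wh$catalog$ext_id == ext_id & wh$catalog$project == project, ]
  if (nrow(hit) != 1L)
    abort_validation(paste0("unknown attribute (", ext_id, ", ", project, ")"))
  hit
}

#' Catalog entry plus all transitive children
#'
#' Parent links form a forest (e.g. an ICD-style hierarchy); a query on a
#' parent matches any descendant. This returns the subtree rooted at an entry.
#'
#' @param wh a [warehouse()].
#' @param ext_id,project catalog identity of the root entry.
#' @return tibble of catalog entries: the entry itself and all descendants.
#' @export
descendants <- function(wh, ext_id, project) {
  root <- lookup_attribute(wh, ext_id, project)
  ids <- root$attribute_id
  frontier <- ids
  repeat {
    kids <- wh$catalog$attribute_id[!is.na(wh$catalog$parent_id) &
                                    wh$catalog$parent_id %in% frontier]
    kids <- setdiff(kids, ids)
    if (length(kids) == 0L) break
    ids <- c(ids, kids)
    frontier <- kids
  }
  wh$catalog[wh$catalog$attribute_id %in% ids, ]
}

#' Does the warehouse carry patient identifiers?
#' @param wh a [warehouse()].
#' @return `TRUE` if any info record has a patient ID.
#' @export
has_patient_ids <- function(wh) any(!is.na(wh$infos$patient_id))

#' All info records in the scope of one patient / appointment / examination
#'
#' @param wh a [warehouse()].
#' @param level `"PID"`, `"AID"` or `"EID"`.
#' @param id identifier at that level.
#' @return tibble of info records whose identifier at `level` equals `id`.
#' @export
scope_values <- function(wh, level = c("PID", "AID", "EID"), id) {
  level <- match.arg(level)
  if (level == "PID" && !has_patient_ids(wh))
    abort_capability("patient-level scope requested but the warehouse contains no patient identifiers")
  col <- c(PID = "patient_id", AID = "appointment_id", EID = "exam_id")[[level]]
  wh$infos[!is.na(wh$infos[[col]]) & wh$infos[[col]] == id, ]
}

append_infos <- function(wh, records) {
  # records: tibble with attribute_id, patient_id, appointment_id, exam_id,
  # measure_time, value, owner (NA for imported values)
  if (nrow(records) == 0L) return(invisible(wh))
  bad <- !records$attribute_id %in% wh$catalog$attribute_id
  if (any(bad))
    abort_validation("info record references unknown attribute_id")
  if (any(is.na(records$appointment_id) | !nzchar(records$appointment_id)) ||
      any(is.na(records$exam_id) | !nzchar(records$exam_id)))
    abort_validation("appointment_id and exam_id must be non-empty")
  records$info_id <- seq.int(wh$next_info_id, length.out = nrow(records))
  wh$next_info_id <- wh$next_info_id + nrow(records)
  wh$infos <- bind_rows(wh$infos, records[names(wh$infos)])
  bump_revision(wh)
  invisible(wh)
}

# Delete info records selected by attribute and/or calculator owner, optionally
# restricted to an exam or patient subset. Returns the number dropped.
delete_infos <- function(wh, attribute_ids = NULL, owner = NULL,
                         exam_ids = NULL, patient_ids = NULL) {
  drop <- rep(FALSE, nrow(wh$infos))
  if (!is.null(attribute_ids)) drop <- drop | wh$infos$attribute_id %in% attribute_ids
  if (!is.null(owner)) drop <- drop | (!is.na(wh$infos$owner) & wh$infos$owner %in% owner)
  if (!is.null(exam_ids)) drop <- drop & wh$infos$exam_id %in% exam_ids
  if (!is.null(patient_ids))
    drop <- drop & !is.na(wh$infos$patient_id) & wh$infos$patient_id %in% patient_ids
  if (any(drop)) {
    wh$infos <- wh$infos[!drop, ]
    bump_revision(wh)
  }
  invisible(sum(drop))
}

# Exam-identifier synthesis: `<AppointmentID>#<ordinal>`, with per-appointment
# ordinals continuing across imports so appended files never collide.
next_exam_id <- function(wh, appointment_id) {
  vapply(appointment_id, function(a) {
    n <- if (is.null(wh$exam_counters[[a]])) 0L else wh$exam_counters[[a]]
    n <- n + 1L
    assign(a, n, envir = wh$exam_counters)
    paste0(a, "#", n)
  }, character(1), USE.NAMES = FALSE)
}

#' Save / load a warehouse as portable CSV tables
#'
#' The on-disk format is a directory of plain-text tables (`catalog.csv`,
#' `infos.csv`) plus `meta.json` holding the ID counters and a revision number
#' used to detect stale serialized indexes.
#'
#' @param wh a [warehouse()].
#' @param dir directory to write to / read from (created if needed).
#' @return `save_warehouse` the directory invisibly; `load_warehouse` a
#'   [warehouse()].
#' @export
save_warehouse <- function(wh, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(wh$catalog, file.path(dir, "catalog.csv"), na = "")
  readr::write_csv(wh$infos, file.path(dir, "infos.csv"), na = "")
  counters <- as.list(wh$exam_counters)
  jsonlite::write_json(
    list(next_attribute_id = wh$next_attribute_id,
         next_info_id = wh$next_info_id,
         revision = wh$revision,
         exam_counters = counters),
    file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname save_warehouse
#' @export
load_warehouse <- function(dir) {
  wh <- warehouse()
  cat_spec <- readr::cols(
    attribute_id = "i", ext_id = "c", project = "c", display_name = "c",
    parent_id = "i", data_type = "c")
  inf_spec <- readr::cols(
    info_id = "i", attribute_id = "i", patient_id = "c", appointment_id = "c",
    exam_id = "c", measure_time = "c", value = "c", owner = "c")
  wh$catalog <- readr::read_csv(file.path(dir, "catalog.csv"),
                                col_types = cat_spec, na = "")
  wh$infos <- readr::read_csv(file.path(dir, "infos.csv"),
                              col_types = inf_spec, na = "")
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  wh$next_attribute_id <- as.integer(meta$next_attribute_id)
  wh$next_info_id <- as.integer(meta$next_info_id)
  wh$revision <- as.integer(meta$revision)
  for (a in names(meta$exam_counters))
    assign(a, as.integer(meta$exam_counters[[a]]), envir = wh$exam_counters)
  wh
}
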