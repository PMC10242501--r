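# Three-level query index. The logical contract follows a nested-document
# model: one document per patient, appointment and examination, each knowing
# the set of attribute IDs anywhere in its scope (ContainingFields) and, at
# the examination level, the typed value postings. The physical structure is
# in-process: a postings tibble plus per-level document tables.

#' Build the query index of a warehouse
#'
#' @param wh a [warehouse()].
#' @param prune use ContainingFields candidate pruning (results are provably
#'   identical either way; the flag exists to test that property).
#' @return an object of class `wh_index`.
#' @export
build_index <- function(wh, prune = TRUE) {
  ix <- new.env(parent = emptyenv())
  class(ix) <- "wh_index"
  ix$prune <- isTRUE(prune)
  inf <- wh$infos
  ix$postings <- inf %>%
    left_join(wh$catalog %>% select("attribute_id", "data_type"),
              by = "attribute_id") %>%
    select("attribute_id", "data_type", "value",
           pid = "patient_id", aid = "appointment_id", eid = "exam_id")
  refresh_docs(ix)
  ix$revision <- wh$revision
  ix
}

# recompute document tables and ContainingFields from the postings
refresh_docs <- function(ix) {
  p <- ix$postings
  ix$exams <- p %>% distinct(.data$eid, .data$aid, .data$pid)
  ix$appointments <- ix$exams %>% distinct(.data$aid)
  ix$patients <- ix$exams %>% filter(!is.na(.data$pid)) %>% distinct(.data$pid)
  ix$contains <- list(
    EID = p %>% distinct(id = .data$eid, .data$attribute_id),
    AID = p %>% distinct(id = .data$aid, .data$attribute_id),
    PID = p %>% filter(!is.na(.data$pid)) %>%
      distinct(id = .data$pid, .data$attribute_id)
  )
  invisible(ix)
}

#' @export
print.wh_index <- function(x, ...) {
  cat("<wh_index> ", nrow(x$patients), " patients, ", nrow(x$appointments),
      " appointments, ", nrow(x$exams), " examinations, ",
      nrow(x$postings), " postings\n", sep = "")
  invisible(x)
}

#' Document counts per level
#' @param x a `wh_index`.
#' @param ... unused.
#' @method glance wh_index
#' @export
glance.wh_index <- function(x, ...) {
  tibble(patients = nrow(x$patients), appointments = nrow(x$appointments),
         examinations = nrow(x$exams), postings = nrow(x$postings))
}

index_universe <- function(ix, level) {
  switch(level,
    EID = ix$exams$eid,
    AID = ix$appointments$aid,
    PID = {
      if (nrow(ix$patients) == 0L)
        abort_capability("patient-level query on an index without patient identifiers")
      ix$patients$pid
    })
}

#' IDs whose scope contains a value matching a constraint
#'
#' Hierarchy-aware by default: the constraint's attribute matches itself or
#' any catalog descendant (`strict = TRUE` disables the expansion). A negated
#' constraint matches the complement: IDs at the level with *no* matching
#' value in scope.
#'
#' @param ix a [build_index()] result.
#' @param wh the [warehouse()] the index was built from (catalog lookups).
#' @param constraint an [mx_attribute()].
#' @param level `"PID"`, `"AID"` or `"EID"`.
#' @param strict disable hierarchical descendant expansion.
#' @return character vector of matching IDs.
#' @export
ids_matching <- function(ix, wh, constraint, level = c("EID", "AID", "PID"),
                         strict = FALSE) {
  level <- match.arg(level)
  ids <- ids_matching_positive(ix, wh, constraint, level, strict)
  if (isTRUE(constraint$negated))
    setdiff(index_universe(ix, level), ids)
  else ids
}

ids_matching_positive <- function(ix, wh, constraint, level, strict = FALSE) {
  universe <- index_universe(ix, level)  # also triggers PID capability check
  attrs <- if (strict)
    lookup_attribute(wh, constraint$ext_id, constraint$domain)
  else
    descendants(wh, constraint$ext_id, constraint$domain)
  p <- ix$postings
  if (ix$prune) {
    cand <- ix$contains[[level]] %>%
      filter(.data$attribute_id %in% attrs$attribute_id) %>% pull("id")
    if (length(cand) == 0L) return(character())
    col <- c(PID = "pid", AID = "aid", EID = "eid")[[level]]
    p <- p[!is.na(p[[col]]) & p[[col]] %in% cand, ]
  }
  p <- p %>% filter(.data$attribute_id %in% attrs$attribute_id)
  if (nrow(p) == 0L) return(character())
  hit <- match_value(constraint, p$value, p$data_type)
  col <- c(PID = "pid", AID = "aid", EID = "eid")[[level]]
  out <- unique(p[[col]][hit])
  out[!is.na(out)]
}

#' Atomically replace the postings of a set of attributes
#'
#' All postings for `attribute_ids` are removed, then `new_records` (info
#' records, any attribute) are inserted; documents for previously unseen
#' exam/appointment/patient IDs are created. After the call the index is
#' indistinguishable from [build_index()] on the updated warehouse.
#'
#' @param ix a `wh_index`.
#' @param wh the updated [warehouse()].
#' @param attribute_ids integer vector (may be empty).
#' @param new_records tibble of info records to insert (e.g. the relevant
#'   slice of `infos(wh)`).
#' @return the index, invisibly.
#' @export
atomic_update <- function(ix, wh, attribute_ids, new_records) {
  if (nrow(new_records)) {
    bad <- !new_records$attribute_id %in% wh$catalog$attribute_id
    if (any(bad)) abort_validation("record references unknown attribute")
  }
  ix$postings <- ix$postings %>% filter(!.data$attribute_id %in% attribute_ids)
  if (nrow(new_records)) {
    add <- new_records %>%
      left_join(wh$catalog %>% select("attribute_id", "data_type"),
                by = "attribute_id") %>%
      select("attribute_id", "data_type", "value",
             pid = "patient_id", aid = "appointment_id", eid = "exam_id")
    ix$postings <- bind_rows(ix$postings, add)
  }
  refresh_docs(ix)
  ix$revision <- wh$revision
  invisible(ix)
}

#' Serialize / load an index next to a warehouse dump
#'
#' The serialized index carries the warehouse revision it was built from;
#' `load_index` rebuilds automatically when the dump is newer (stale index).
#'
#' @param ix a `wh_index`; `dir` the warehouse dump directory.
#' @param wh the warehouse loaded from `dir`.
#' @param dir directory of [save_warehouse()].
#' @return `load_index`: a `wh_index`.
#' @export
save_index <- function(ix, dir) {
  readr::write_csv(ix$postings, file.path(dir, "index_postings.csv"), na = "")
  jsonlite::write_json(list(revision = ix$revision, prune = ix$prune),
                       file.path(dir, "index_meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname save_index
#' @export
load_index <- function(dir, wh) {
  meta_path <- file.path(dir, "index_meta.json")
  if (!file.exists(meta_path)) return(build_index(wh))
  meta <- jsonlite::read_json(meta_path)
  if (!identical(as.integer(meta$revision), wh$revision)) return(build_index(wh))
  ix <- new.env(parent = emptyenv())
  class(ix) <- "wh_index"
  ix$prune <- isTRUE(meta$prune)
  ix$postings <- readr::read_csv(
    file.path(dir, "index_postings.csv"),
    col_types = readr::cols(attribute_id = "i", .default = "c"), na = "")
  refresh_docs(ix)
  ix$revision <- as.integer(meta$revision)
  ix
}
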