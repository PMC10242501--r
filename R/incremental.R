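# Incremental update pathway: reprocess a named subset of attributes, or
# append newly exported examinations, keeping warehouse + index equivalent to
# a full rebuild (the path-independence property the tests enforce).

#' Reprocess a named subset of attributes
#'
#' A partial update list (mirroring a separate configuration file of just the
#' attribute names to reprocess) names import columns by their `ext_id` and/or
#' calculators by theirs. Only those columns are re-imported (old records
#' removed first) and only those calculators re-run; everything else is
#' untouched, and the index is patched via [atomic_update()].
#'
#' @param wh,ix warehouse and index.
#' @param table the (re-exported) RIS table the columns are read from.
#' @param partial character vector of attribute names; a path to a
#'   single-column CSV of names is also accepted.
#' @param config the full [parse_import_config()] used for the original import.
#' @param registry calculator registry (e.g. [default_calculators()]).
#' @param derived_project catalog project of derived attributes.
#' @return list with `import` stats (or `NULL`), `calculators` stats tibble
#'   (or `NULL`) and `attributes` (ids replaced in the index).
#' @export
update_attributes <- function(wh, ix, table, partial, config, registry,
                              derived_project = "derived") {
  if (length(partial) == 1L && file.exists(partial))
    partial <- readr::read_csv(partial, col_names = "name",
                               col_types = "c", show_col_types = FALSE)$name
  if (length(partial) == 0L) {
    rlang::inform("empty partial update: no-op")
    return(invisible(list(import = NULL, calculators = NULL,
                          attributes = integer())))
  }
  import_names <- intersect(partial, config$specs$ext_id)
  calc_names <- intersect(partial, vapply(registry, `[[`, "", "ext_id"))
  unknown <- setdiff(partial, c(import_names, calc_names))
  if (length(unknown))
    abort_validation(paste0("unknown attribute name(s) in partial update: ",
                            paste(unknown, collapse = ", ")))
  stats <- list(import = NULL, calculators = NULL)
  touched <- integer()
  if (length(import_names)) {
    old_ids <- wh$catalog$attribute_id[wh$catalog$ext_id %in% import_names &
                                       wh$catalog$project == config$project]
    delete_infos(wh, attribute_ids = old_ids)
    stats$import <- import_table(config, table, wh, only = import_names,
                                 reprocess = TRUE)
    touched <- c(touched, stats$import$attribute_ids)
  }
  if (length(calc_names)) {
    reg <- registry[vapply(registry, `[[`, "", "ext_id") %in% calc_names]
    stats$calculators <- run_calculators(wh, reg, derived_project)
    touched <- c(touched,
                 wh$catalog$attribute_id[wh$catalog$ext_id %in% calc_names &
                                         wh$catalog$project == derived_project])
  }
  touched <- unique(touched)
  atomic_update(ix, wh, touched,
                wh$infos %>% filter(.data$attribute_id %in% touched))
  invisible(c(stats, list(attributes = touched)))
}

#' Append newly exported examinations
#'
#' New rows are imported (rows whose configured ExamID already exists are
#' rejected and counted), per-examination calculators run on just the new
#' examinations, and cohort calculators re-run only for the patients the new
#' rows touch. The index is patched, never rebuilt; the result is equivalent
#' to a from-scratch build on the concatenated export.
#'
#' @param wh,ix warehouse and index.
#' @param new_table RIS table of new examinations only.
#' @param config the [parse_import_config()] of the export.
#' @param registry calculator registry.
#' @param derived_project catalog project of derived attributes.
#' @return list with `import` stats and `calculators` stats.
#' @export
append_examinations <- function(wh, ix, new_table, config, registry,
                                derived_project = "derived") {
  st <- import_table(config, new_table, wh)
  new_exams <- st$exam_ids
  touched_patients <- unique(wh$infos$patient_id[
    wh$infos$exam_id %in% new_exams & !is.na(wh$infos$patient_id)])
  if (length(touched_patients) == 0L) touched_patients <- NULL
  calc_stats <- run_calculators(wh, registry, derived_project,
                                exam_ids = new_exams,
                                patients = touched_patients)
  # replace in the index: every attribute whose record set changed
  derived_ids <- wh$catalog$attribute_id[wh$catalog$project == derived_project]
  touched <- unique(c(st$attribute_ids, derived_ids))
  atomic_update(ix, wh, touched,
                wh$infos %>% filter(.data$attribute_id %in% touched))
  invisible(list(import = st, calculators = calc_stats))
}
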