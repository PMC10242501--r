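# Result tables and report export; predefined report families.

#' Construct a labelled count table
#'
#' @param cells integer matrix of non-negative counts.
#' @param row_labels,col_labels character label vectors matching `cells`.
#' @param id_level the counted ID level.
#' @return a `result_table`.
#' @export
result_table <- function(cells, row_labels, col_labels, id_level) {
  cells <- as.matrix(cells)
  storage.mode(cells) <- "integer"
  dimnames(cells) <- NULL
  stopifnot(nrow(cells) == length(row_labels),
            ncol(cells) == length(col_labels))
  if (any(cells < 0)) abort_validation("counts must be non-negative")
  structure(list(cells = cells, row_labels = as.character(row_labels),
                 col_labels = as.character(col_labels), id_level = id_level),
            class = "result_table")
}

#' @export
print.result_table <- function(x, ...) {
  m <- x$cells
  dimnames(m) <- list(x$row_labels, x$col_labels)
  cat("<result_table> counted at level ", x$id_level, "\n", sep = "")
  print(m)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' Long-form view of a result table
#'
#' @param x a [result_table()].
#' @param ... unused.
#' @return tibble with `row`, `col`, `count`.
#' @method tidy result_table
#' @export
tidy.result_table <- function(x, ...) {
  tidyr::expand_grid(row = x$row_labels, col = x$col_labels) %>%
    mutate(count = as.vector(t(x$cells)))
}

#' Heatmap of a result table
#'
#' @param object a [result_table()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot result_table
#' @export
autoplot.result_table <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(
      x = factor(.data$col, levels = object$col_labels),
      y = factor(.data$row, levels = rev(object$row_labels)),
      fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), colour = "white") +
    ggplot2::labs(x = NULL, y = NULL,
                  fill = paste0("count (", object$id_level, ")")) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Export a result table
#'
#' Layout: first row is the column labels preceded by an empty corner cell,
#' first column the row labels, cells as integers.
#'
#' @param t a [result_table()].
#' @param path output file.
#' @param format `"csv"` or `"excel"` (guessed from the extension by default).
#' @return `path`, invisibly.
#' @export
export_table <- function(t, path, format = c("auto", "csv", "excel")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) "excel" else "csv"
  df <- tibble::as_tibble(
    c(list(t$row_labels),
      lapply(seq_along(t$col_labels), function(j) t$cells[, j])),
    .name_repair = "minimal")
  names(df) <- c("", t$col_labels)  # empty corner cell
  if (format == "csv") {
    readr::write_csv(df, path, na = "")
  } else {
    write_xlsx_table(df, path)
  }
  invisible(path)
}

#' Re-read an exported result-table CSV
#'
#' @param path a CSV written by [export_table()].
#' @param id_level level annotation to attach (the layout does not carry it).
#' @return a [result_table()].
#' @export
read_result_table <- function(path, id_level = "EID") {
  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                        na = character(), show_col_types = FALSE,
                        name_repair = "minimal")
  labels <- df[[1]]
  cells <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(cells) <- "integer"
  result_table(cells, labels, names(df)[-1], id_level)
}

# Excel (.xlsx) writing is delegated to the system Python toolchain
# (openpyxl); all cells are written as text/number values of a single sheet.
write_xlsx_table <- function(df, path) {
  csv <- tempfile(fileext = ".csv")
  on.exit(unlink(csv), add = TRUE)
  readr::write_csv(df, csv, na = "")
  py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py))
    abort_validation("Excel export needs a python interpreter with openpyxl on PATH")
  script <- paste(
    "import csv, sys",
    "import openpyxl",
    "wb = openpyxl.Workbook(); ws = wb.active",
    "with open(sys.argv[1], newline='', encoding='utf-8') as f:",
    "    for row in csv.reader(f):",
    "        ws.append(row)",
    "wb.save(sys.argv[2])",
    sep = "\n")
  status <- system2(py, c("-c", shQuote(script), shQuote(csv), shQuote(path)))
  if (!identical(status, 0L))
    abort_validation("xlsx serialization failed")
  invisible(path)
}

#' Run a saved MXQL query file
#'
#' @param ix,wh index and warehouse to query.
#' @param path path to an MXQL XML file.
#' @return a [result_table()]; a provenance message (file, warehouse revision,
#'   timestamp) is emitted.
#' @export
run_saved_query <- function(ix, wh, path) {
  if (!file.exists(path))
    abort_validation(paste0("saved query not found: ", path))
  q <- tryCatch(parse_mxql(path), error = function(e)
    rlang::abort(paste0("in query file ", path, ": ", conditionMessage(e)),
                 class = class(e)[1], parent = e))
  res <- evaluate(ix, wh, q)
  rlang::inform(paste0("query ", path, " @ warehouse revision ", wh$revision,
                       " (", format_timestamp(Sys.time()), ")"))
  res
}

#' Predefined report families
#'
#' The four most common radiology-operations reports, emitted as count tables
#' (a plotting layer can consume them):
#' * `counts_by_modality` — modalities (rows) by stay type (columns).
#' * `availability_buckets` — modalities by report-availability bucket
#'   (1–4 days), plus a per-modality percentage table.
#' * `device_use` — devices by modality.
#' * `repeated_examinations` — distinct modality-sequence strings by patient
#'   count.
#'
#' @param ix,wh index and warehouse.
#' @param family report family name.
#' @param params list: `project`, `derived_project`, plus per-family keys —
#'   `modalities`, `modality_ext`, `stay_ext`, `stay_values`, `device_ext`,
#'   `devices`, `level`.
#' @return a list of [result_table()]s (plus, for `availability_buckets`,
#'   a `percentages` data frame).
#' @export
predefined_reports <- function(ix, wh,
                               family = c("counts_by_modality",
                                          "availability_buckets",
                                          "device_use",
                                          "repeated_examinations"),
                               params = list()) {
  family <- match.arg(family)
  p <- utils::modifyList(list(
    project = "ris", derived_project = "derived", modality_ext = "MOD",
    stay_ext = "STAY", device_ext = "DEVICE", level = "EID"), params)
  distinct_values <- function(ext, project) {
    entry <- lookup_attribute(wh, ext, project)
    sort(unique(wh$infos$value[wh$infos$attribute_id == entry$attribute_id]))
  }
  eq_nodes <- function(ext, project, vals)
    purrr::map(vals, ~ mx_attribute(ext, project, "equals", .x, display_name = .x))
  need_derived <- function(ext) {
    ok <- nrow(wh$catalog[wh$catalog$ext_id == ext &
                          wh$catalog$project == p$derived_project, ]) > 0
    if (!ok) abort_capability(paste0(
      "predefined report needs the derived attribute ", ext,
      "; run the calculators first"))
  }
  mods <- p$modalities %||% distinct_values(p$modality_ext, p$project)
  switch(family,
    counts_by_modality = {
      stays <- p$stay_values %||% distinct_values(p$stay_ext, p$project)
      q <- mx_query(eq_nodes(p$modality_ext, p$project, mods),
                    eq_nodes(p$stay_ext, p$project, stays),
                    id_level = p$level)
      list(counts = evaluate(ix, wh, q))
    },
    availability_buckets = {
      need_derived("AVAIL_BUCKET")
      q <- mx_query(eq_nodes(p$modality_ext, p$project, mods),
                    eq_nodes("AVAIL_BUCKET", p$derived_project,
                             as.character(1:4)),
                    id_level = p$level)
      counts <- evaluate(ix, wh, q)
      tot <- rowSums(counts$cells)
      pct <- sweep(counts$cells, 1, pmax(tot, 1), "/") * 100
      pct[tot == 0, ] <- NA_real_
      pct_df <- as.data.frame(round(pct, 1))
      names(pct_df) <- counts$col_labels
      rownames(pct_df) <- counts$row_labels
      list(counts = counts, percentages = pct_df)
    },
    device_use = {
      devs <- p$devices %||% distinct_values(p$device_ext, p$project)
      q <- mx_query(eq_nodes(p$device_ext, p$project, devs),
                    eq_nodes(p$modality_ext, p$project, mods),
                    id_level = p$level)
      list(counts = evaluate(ix, wh, q))
    },
    repeated_examinations = {
      need_derived("MOD_SEQ")
      entry <- lookup_attribute(wh, "MOD_SEQ", p$derived_project)
      seqs <- sort(unique(wh$infos$value[wh$infos$attribute_id == entry$attribute_id]))
      q <- mx_query(eq_nodes("MOD_SEQ", p$derived_project, seqs),
                    list(mx_attribute("MOD_SEQ", p$derived_project,
                                      display_name = "patients")),
                    id_level = "PID")
      list(counts = evaluate(ix, wh, q))
    })
}
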