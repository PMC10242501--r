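#' Run the full import pipeline
#'
#' Convenience wrapper over the four import steps: read the mapping
#' configuration, read the RIS export, import it into a fresh (or given)
#' warehouse, run the calculator registry, and build the query index.
#'
#' @param export_path RIS export file (CSV/Excel/JSON).
#' @param config_path import-mapping configuration file.
#' @param registry calculator registry; `NULL` skips derivation.
#' @param wh optionally, an existing [warehouse()] to import into.
#' @param project,derived_project catalog projects for imported and derived
#'   attributes.
#' @param verbose log each step.
#' @return list with `wh`, `ix`, `config`, `table`, `import_stats`,
#'   `calc_stats`.
#' @export
import_pipeline <- function(export_path, config_path,
                            registry = default_calculators(),
                            wh = warehouse(), project = "ris",
                            derived_project = "derived", verbose = FALSE) {
  say <- function(...) if (verbose) rlang::inform(paste0(...))
  say("step 1: reading configuration ", config_path)
  config <- parse_import_config(config_path, project = project)
  say("step 2: reading export ", export_path, " and importing")
  table <- read_ris_export(export_path)
  st <- import_table(config, table, wh)
  say("  ", st$records_created, " records from ", st$rows_read, " rows")
  calc_stats <- NULL
  if (!is.null(registry)) {
    say("step 3: running ", length(registry), " calculators")
    calc_stats <- run_calculators(wh, registry, derived_project)
  }
  say("step 4: building index")
  ix <- build_index(wh)
  list(wh = wh, ix = ix, config = config, table = table,
       import_stats = st, calc_stats = calc_stats)
}
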