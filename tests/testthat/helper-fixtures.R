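# Shared fixtures, built in code.

# Hand-built warehouse: 2 patients, 3 appointments, 8 exams with modality and
# localization assigned by hand (used for manual-enumeration query checks).
tiny_fixture <- function() {
  tab <- tibble::tribble(
    ~PatientID, ~CID,  ~StartDate,            ~Modality, ~Localization,
    "P1", "C1", "2018-01-05T09:30:00", "Rö", "Abdomen",
    "P1", "C1", "2018-01-05T10:30:00", "CT", "BWS",
    "P1", "C2", "2018-02-01T14:00:00", "Rö", "BWS",
    "P1", "C2", "2018-02-01T15:00:00", "Sono", "Abdomen",
    "P2", "C3", "2018-03-10T08:00:00", "CT", "Abdomen",
    "P2", "C3", "2018-03-10T09:00:00", "CT", "Schaedel",
    "P2", "C3", "2018-03-10T22:30:00", "Rö", "Thorax",
    "P2", "C3", "2018-03-11T03:15:00", "MRI", "Abdomen")
  cfg <- tibble::tibble(
    DisplayTitle = c("Patient", "Case", "Start", "Modality", "Localization"),
    ExtID = c("PID", "CID", "START", "MOD", "LOC"),
    DataType = c("Text", "Text", "DateTime", "SingleChoice", "SingleChoice"),
    ColumnName = c("PatientID", "CID", "StartDate", "Modality", "Localization"),
    ColumnNumber = "", ValueMappings = "",
    MetaDataType = c("PatientID", "AppointmentID", "MeasureTime", "Modality", ""))
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  readr::write_csv(tab, file.path(dir, "export.csv"), na = "")
  readr::write_csv(cfg, file.path(dir, "config.csv"), na = "")
  wh <- warehouse()
  config <- parse_import_config(file.path(dir, "config.csv"))
  table <- read_ris_export(file.path(dir, "export.csv"))
  st <- import_table(config, table, wh)
  list(wh = wh, ix = build_index(wh), config = config, table = table,
       stats = st, dir = dir)
}

# Standard seeded synthetic study (memoized): 500 patients, ~2000 exams.
.fixture_cache <- new.env(parent = emptyenv())

std_pipeline <- function() {
  if (is.null(.fixture_cache$std)) {
    dir <- file.path(tempdir(), "radwh_std_fixture")
    g <- generate_ris_export(generator_params(seed = 42L, n_patients = 500L),
                             out_dir = dir, formats = c("csv", "json"))
    pl <- suppressWarnings(import_pipeline(g$paths$csv, g$paths$config))
    pl$gen <- g
    .fixture_cache$std <- pl
  }
  .fixture_cache$std
}
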