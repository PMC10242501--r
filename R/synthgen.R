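# Deterministic generator of synthetic multi-hospital RIS exports plus the
# matching import configuration and a ground-truth sidecar. The shape emulates
# a German hospital RIS export: one examination per row, pseudonymized IDs,
# request/start/end/report timestamps, modality codes (remapped at import),
# body region, requesting department, device, medical-question code and
# boolean insurance / stay-type flags.

#' Parameters of the synthetic RIS export generator
#'
#' Defaults describe a mid-size single-site export: 500 patients with 1–3
#' radiology appointments of 1–3 examinations each (about four examinations
#' per patient, i.e. roughly 2,000 examinations) over one calendar year,
#' four modalities at typical frequency, working-hour-anchored start times
#' with a configurable late/night mass so shift reports are non-degenerate,
#' and lognormal-ish delays from request to start and from examination end to
#' report availability spanning the 1–4-day buckets.
#'
#' @param seed integer RNG seed; the same seed yields byte-identical files.
#' @param n_patients number of patients.
#' @param appointments_per_patient,exams_per_appointment integer probability
#'   vectors (value k with probability `p[k]`).
#' @param modality_frequencies named probabilities of the export's raw
#'   modality codes (remapped at import via ValueMappings).
#' @param localizations,departments,question_codes value pools.
#' @param devices named list mapping raw modality code to its device pool.
#' @param p_inpatient,p_statutory probabilities of the boolean flags.
#' @param delay_request_h,delay_report_h meanlog/sdlog of the lognormal
#'   request-to-start and end-to-report delays in hours.
#' @param exam_minutes range of examination durations.
#' @param p_late,p_night probability mass of late/night start times.
#' @param year calendar year of the export.
#' @param repeat_sequence_rate probability that a patient receives an injected
#'   X-ray-then-CT pair on a dedicated group key (ground truth records each).
#' @param include_patient_ids `FALSE` emulates hospitals that export no
#'   patient identifier.
#' @param missing_cell_rate fraction of optional cells left empty.
#' @return a `generator_params` list.
#' @export
generator_params <- function(seed = 1L,
                             n_patients = 500L,
                             appointments_per_patient = c(0.35, 0.35, 0.30),
                             exams_per_appointment = c(0.40, 0.35, 0.25),
                             modality_frequencies = c(XR = 0.4, CT = 0.25,
                                                      MR = 0.15, US = 0.2),
                             localizations = c("Abdomen", "BWS", "HWS", "LWS",
                                               "Thorax", "Schaedel", "Knie",
                                               "Schulter"),
                             departments = c("Chirurgie", "Innere",
                                             "Neurochirurgie", "Notaufnahme",
                                             "Orthopaedie"),
                             question_codes = sprintf("Q%02d", 1:10),
                             devices = list(XR = c("XR-1", "XR-2"),
                                            CT = c("CT-1", "CT-2"),
                                            MR = "MRT-1", US = "US-1"),
                             p_inpatient = 0.55, p_statutory = 0.85,
                             delay_request_h = c(meanlog = 2.5, sdlog = 1.0),
                             delay_report_h = c(meanlog = 3.0, sdlog = 1.0),
                             exam_minutes = c(10, 45),
                             p_late = 0.15, p_night = 0.05,
                             year = 2018L,
                             repeat_sequence_rate = 0.1,
                             include_patient_ids = TRUE,
                             missing_cell_rate = 0.02) {
  stopifnot(abs(sum(modality_frequencies) - 1) < 1e-9,
            all(appointments_per_patient >= 0),
            abs(sum(appointments_per_patient) - 1) < 1e-9,
            abs(sum(exams_per_appointment) - 1) < 1e-9,
            p_inpatient >= 0, p_inpatient <= 1,
            missing_cell_rate >= 0, missing_cell_rate <= 1,
            repeat_sequence_rate >= 0, repeat_sequence_rate <= 1)
  structure(as.list(environment()), class = "generator_params")
}

MODALITY_MAPPING <- c(XR = "Rö", MR = "MRI", US = "Sono")  # CT unmapped

#' Generate a synthetic RIS export, import configuration and ground truth
#'
#' Writes `ris_export.<fmt>` for each requested format, `import_config.csv`
#' and `ground_truth.json`. Timestamps obey request <= start <= end <= report;
#' the sidecar records the true counts (per modality after remapping, per
#' department, per shift, per availability bucket) and every injected
#' repeated-examination pair, for use as an independent oracle.
#'
#' @param params a [generator_params()].
#' @param out_dir output directory (created).
#' @param formats subset of `c("csv", "json", "excel")`.
#' @return list with the generated `table` (tibble), file `paths`, and the
#'   `ground_truth` list, invisibly.
#' @export
generate_ris_export <- function(params = generator_params(),
                                out_dir = tempfile("ris_"),
                                formats = "csv") {
  stopifnot(inherits(params, "generator_params"),
            all(formats %in% c("csv", "json", "excel")))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tab <- withr::with_seed(params$seed, synth_table(params))
  table <- tab$table
  paths <- list()
  for (f in formats) {
    p <- file.path(out_dir, paste0("ris_export.",
                                   c(csv = "csv", json = "json",
                                     excel = "xlsx")[[f]]))
    if (f == "csv") readr::write_csv(table, p, na = "")
    if (f == "json") jsonlite::write_json(table, p, dataframe = "rows", na = "string")
    if (f == "excel") write_xlsx_table(as.data.frame(table), p)
    paths[[f]] <- p
  }
  cfg_path <- file.path(out_dir, "import_config.csv")
  readr::write_csv(synth_config(params), cfg_path, na = "")
  paths$config <- cfg_path
  gt <- ground_truth(table, params, tab$injected)
  gt_path <- file.path(out_dir, "ground_truth.json")
  jsonlite::write_json(gt, gt_path, auto_unbox = TRUE, digits = NA)
  paths$ground_truth <- gt_path
  invisible(list(table = table, paths = paths, ground_truth = gt))
}

synth_table <- function(p) {
  pats <- sprintf("P%05d", seq_len(p$n_patients))
  n_app <- sample(seq_along(p$appointments_per_patient), p$n_patients,
                  replace = TRUE, prob = p$appointments_per_patient)
  n_apps_total <- sum(n_app)
  pat_of_app <- rep(seq_len(p$n_patients), n_app)
  year0 <- as.Date(paste0(p$year, "-01-01"))
  # appointment anchors: uniform weekday of the year (vectorized rejection)
  day <- sample.int(365, n_apps_total, replace = TRUE)
  repeat {
    wd <- format(year0 + day - 1L, "%u")
    bad <- wd %in% c("6", "7")
    if (!any(bad)) break
    day[bad] <- sample.int(365, sum(bad), replace = TRUE)
  }
  u <- stats::runif(n_apps_total)
  start_hour <- ifelse(u < p$p_night,
                       stats::runif(n_apps_total, 22, 30) %% 24,
                ifelse(u < p$p_night + p$p_late,
                       stats::runif(n_apps_total, 18, 22),
                       stats::runif(n_apps_total, 7, 18)))
  anchor <- as.POSIXct(paste(year0 + day - 1L, "00:00:00"), tz = "UTC") +
    round(start_hour * 3600)
  n_ex <- sample(seq_along(p$exams_per_appointment), n_apps_total,
                 replace = TRUE, prob = p$exams_per_appointment)
  # exam-level expansion
  app_of_ex <- rep(seq_len(n_apps_total), n_ex)
  n_total <- length(app_of_ex)
  ex_ord <- stats::ave(seq_len(n_total), app_of_ex, FUN = seq_along)
  dur <- round(stats::runif(n_total, p$exam_minutes[1], p$exam_minutes[2]))
  gap <- round(stats::runif(n_total, 5, 30)) * 60  # within-visit idle time, s
  # start_k = anchor + sum_{j<k} (dur_j*60 + gap_j) within the appointment
  step <- dur * 60 + gap
  offset <- stats::ave(step, app_of_ex, FUN = function(x) c(0, cumsum(x)[-length(x)]))
  t <- anchor[app_of_ex] + offset
  end <- t + dur * 60
  req <- t - round(stats::rlnorm(n_total, p$delay_request_h["meanlog"],
                                 p$delay_request_h["sdlog"]) * 3600)
  rep_t <- end + round(stats::rlnorm(n_total, p$delay_report_h["meanlog"],
                                     p$delay_report_h["sdlog"]) * 3600)
  mod <- sample(names(p$modality_frequencies), n_total, replace = TRUE,
                prob = p$modality_frequencies)
  dev <- character(n_total)
  for (m in unique(mod)) {
    idx <- mod == m
    dev[idx] <- sample(p$devices[[m]], sum(idx), replace = TRUE)
  }
  tab <- tibble(
    PatientID = pats[pat_of_app[app_of_ex]],
    CID = sprintf("C%06d", app_of_ex),
    RequestDate = format_timestamp(req),
    StartDate = format_timestamp(t),
    EndDate = format_timestamp(end),
    ReportDate = format_timestamp(rep_t),
    Modality = mod,
    Localization = sample(p$localizations, n_total, replace = TRUE),
    Department = sample(p$departments, n_total, replace = TRUE),
    Device = dev,
    Question = sample(p$question_codes, n_total, replace = TRUE),
    StayType = ifelse(stats::runif(n_total) < p$p_inpatient, "1", "0"),
    Insurance = ifelse(stats::runif(n_total) < p$p_statutory, "ja", "nein"),
    injected = FALSE)
  app_no <- n_apps_total
  injected <- list()
  if (p$include_patient_ids && p$repeat_sequence_rate > 0) {
    hit <- stats::runif(p$n_patients) < p$repeat_sequence_rate
    for (i in which(hit)) {
      app_no <- app_no + 1L
      gkey <- sprintf("QS%05d", i)  # group key dedicated to the injection
      loc <- sample(p$localizations, 1)
      dept <- sample(p$departments, 1)
      repeat {
        day <- as.Date(year0) + sample.int(360, 1) - 1L
        if (!format(day, "%u") %in% c("6", "7")) break
      }
      t1 <- as.POSIXct(paste(day, "09:00:00"), tz = "UTC") +
        round(stats::runif(1, 0, 6) * 3600)
      mk <- function(cid, mod, t0) {
        dur <- round(stats::runif(1, p$exam_minutes[1], p$exam_minutes[2]))
        tibble(
          PatientID = pats[i], CID = cid,
          RequestDate = format_timestamp(t0 - 3600 * 24),
          StartDate = format_timestamp(t0),
          EndDate = format_timestamp(t0 + dur * 60),
          ReportDate = format_timestamp(t0 + dur * 60 + 3600 * 12),
          Modality = mod, Localization = loc, Department = dept,
          Device = sample(p$devices[[mod]], 1), Question = gkey,
          StayType = "1", Insurance = "ja", injected = TRUE)
      }
      rows2 <- bind_rows(mk(sprintf("C%06d", app_no), "XR", t1),
                         mk(sprintf("C%06d", app_no + 1L), "CT", t1 + 86400))
      app_no <- app_no + 1L
      tab <- bind_rows(tab, rows2)
      injected[[length(injected) + 1L]] <- list(
        patient_id = pats[i], group_key = gkey,
        sequence = paste0(MODALITY_MAPPING[["XR"]], "→CT"))
    }
  }
  # optional-cell missingness (never on injected rows or metadata columns)
  if (p$missing_cell_rate > 0) {
    for (col in c("Localization", "Department", "Device", "Insurance")) {
      mask <- stats::runif(nrow(tab)) < p$missing_cell_rate & !tab$injected
      tab[[col]][mask] <- ""
    }
  }
  if (!p$include_patient_ids) tab$PatientID <- NULL
  list(table = tab %>% select(-"injected") %>% as_tibble(),
       injected = injected)
}

synth_config <- function(p) {
  rows <- tibble(
    DisplayTitle = c("Patient", "Case", "Request time", "Examination start",
                     "Examination end", "Report time", "Modality",
                     "Localization", "Department", "Device",
                     "Medical question", "Inpatient stay",
                     "Statutory insurance"),
    ExtID = c("PID", "CID", "REQUEST", "START", "END", "REPORT", "MOD",
              "LOC", "DEPT", "DEVICE", "QUEST", "STAY", "INSUR"),
    DataType = c("Text", "Text", "DateTime", "DateTime", "DateTime",
                 "DateTime", "SingleChoice", "SingleChoice", "SingleChoice",
                 "SingleChoice", "SingleChoice", "Boolean", "Boolean"),
    ColumnName = c("PatientID", "CID", "RequestDate", "StartDate", "EndDate",
                   "ReportDate", "Modality", "Localization", "Department",
                   "Device", "Question", "StayType", "Insurance"),
    ColumnNumber = NA_integer_,
    ValueMappings = c(rep("", 6), serialize_value_mappings(MODALITY_MAPPING),
                      rep("", 6)),
    MetaDataType = c("PatientID", "AppointmentID", "", "MeasureTime", "", "",
                     "Modality", rep("", 6)))
  if (!p$include_patient_ids) rows <- rows[rows$ExtID != "PID", ]
  rows
}

# true counts recomputed directly from the generated flat table
ground_truth <- function(table, p, injected = list()) {
  mod <- table$Modality
  mapped <- ifelse(mod %in% names(MODALITY_MAPPING),
                   MODALITY_MAPPING[mod], mod)
  start <- parse_timestamp(table$StartDate)
  rep_t <- parse_timestamp(table$ReportDate)
  buckets <- availability_bucket(start, rep_t)
  list(
    seed = p$seed,
    n_patients = if ("PatientID" %in% names(table))
      length(unique(table$PatientID)) else NA,
    n_appointments = length(unique(table$CID)),
    n_examinations = nrow(table),
    per_modality = as.list(table(mapped)),
    per_department = as.list(table(table$Department[nzchar(table$Department)])),
    per_shift = as.list(table(assign_shift(start))),
    per_bucket = as.list(table(buckets)),
    injected_sequences = injected,
    missing_cells = sum(!nzchar(as.matrix(table)))
  )
}
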