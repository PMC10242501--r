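# Derived clinical-operations metrics: shift assignment, elapsed times,
# report-availability buckets, device vacancy, repeated-examination sequences,
# first-contact flags, and the calculator framework that turns them into
# ordinary catalog attributes + info records.

#' Assign a timestamp to a working shift
#'
#' Three-shift model: early `[06:00, 14:00)`, late `[14:00, 22:00)`, night
#' `[22:00, 06:00)` (half-open, left-closed). Boundaries are configurable.
#'
#' @param t `POSIXct` vector or character timestamps.
#' @param boundaries numeric length-3 vector of shift start hours
#'   (early, late, night), default `c(6, 14, 22)`.
#' @return character vector of `"early"`, `"late"`, `"night"`.
#' @export
assign_shift <- function(t, boundaries = c(6, 14, 22)) {
  if (is.character(t)) t <- parse_timestamp(t)
  h <- as.numeric(format(t, "%H", tz = "UTC")) +
       as.numeric(format(t, "%M", tz = "UTC")) / 60
  ifelse(h >= boundaries[1] & h < boundaries[2], "early",
         ifelse(h >= boundaries[2] & h < boundaries[3], "late", "night"))
}

#' Elapsed time between two timestamps
#'
#' @param t1,t2 `POSIXct` or character timestamps.
#' @param unit `"minutes"`, `"hours"` or `"days"`.
#' @return numeric `(t2 - t1)` in the unit; negative when `t2` precedes `t1`
#'   (flagged downstream as a data-quality issue, never silently dropped).
#' @export
elapsed <- function(t1, t2, unit = c("minutes", "hours", "days")) {
  unit <- match.arg(unit)
  if (is.character(t1)) t1 <- parse_timestamp(t1)
  if (is.character(t2)) t2 <- parse_timestamp(t2)
  s <- as.numeric(t2) - as.numeric(t1)
  s / c(minutes = 60, hours = 3600, days = 86400)[[unit]]
}

#' Report-availability bucket (days until the report was available)
#'
#' The smallest `d` in 1..4 such that the report was available within `d`
#' 24-hour windows of the examination start; upper bounds are closed (a report
#' exactly 24 h later is bucket 1) and anything beyond 4 days clamps to 4.
#'
#' @param exam_start,report_time `POSIXct` or character timestamps.
#' @return integer vector in `{1, 2, 3, 4}`.
#' @export
availability_bucket <- function(exam_start, report_time) {
  h <- elapsed(exam_start, report_time, "hours")
  if (any(h < 0, na.rm = TRUE))
    abort_validation("report_time precedes exam_start")
  pmin(pmax(ceiling(h / 24), 1), 4)
}

#' Idle gaps between consecutive examinations on each device
#'
#' Within each device and calendar day (of the examination start), exams are
#' ordered by start time; the gap of an exam is the idle time in minutes until
#' the next exam starts on the same device that day. The last exam of a
#' device-day has no gap. Overlapping exams yield negative gaps, kept and
#' flagged.
#'
#' @param exams tibble with columns `exam_id`, `device`, `start`, `end`
#'   (`POSIXct` or character).
#' @return tibble `exam_id`, `device`, `gap_minutes` (one row per exam that
#'   has a successor on its device-day).
#' @export
device_vacancy <- function(exams) {
  ex <- as_tibble(exams)
  if (is.character(ex$start)) ex$start <- parse_timestamp(ex$start)
  if (is.character(ex$end)) ex$end <- parse_timestamp(ex$end)
  if (any(elapsed(ex$start, ex$end, "minutes") < 0, na.rm = TRUE))
    abort_validation("examination end precedes start")
  out <- ex %>%
    mutate(day = format(.data$start, "%Y-%m-%d", tz = "UTC")) %>%
    arrange(.data$device, .data$day, .data$start, .data$exam_id) %>%
    group_by(.data$device, .data$day) %>%
    mutate(gap_minutes = elapsed(.data$end, lead(.data$start), "minutes")) %>%
    ungroup() %>%
    filter(!is.na(.data$gap_minutes)) %>%
    select("exam_id", "device", "gap_minutes")
  if (any(out$gap_minutes < 0))
    rlang::warn(paste0(sum(out$gap_minutes < 0),
                       " overlapping examination(s) on one device (negative gap)"))
  out
}

# One row per examination with patient/appointment ids, start time, and the
# canonical value of each requested attribute (NA when absent).
exam_frame <- function(wh, ext_ids, project) {
  inf <- wh$infos
  base <- inf %>%
    distinct(.data$exam_id, .data$appointment_id, .data$patient_id,
             .data$measure_time)
  # an exam has one measure time (one row of the export); keep first defensively
  base <- base %>% group_by(.data$exam_id) %>% slice(1) %>% ungroup()
  for (e in ext_ids) {
    entry <- lookup_attribute(wh, e, project)
    v <- inf %>%
      filter(.data$attribute_id == entry$attribute_id) %>%
      group_by(.data$exam_id) %>% slice(1) %>% ungroup() %>%
      select("exam_id", value = "value")
    names(v)[2] <- e
    base <- left_join(base, v, by = "exam_id")
  }
  base
}

#' Repeated-examination sequences per patient and group key
#'
#' For every patient and value of a grouping attribute (medical-question code
#' or body region), the time-ordered list of modalities the patient received,
#' rendered e.g. `"Rö→CT"`, with the span in hours from first to last start.
#'
#' @param wh a [warehouse()].
#' @param group_attribute `ext_id` of the grouping attribute.
#' @param modality_attribute `ext_id` of the modality attribute.
#' @param project catalog project of both attributes.
#' @param patients optional character vector restricting to these patient IDs.
#' @return tibble `patient_id`, `group_key`, `sequence`, `length`,
#'   `span_hours`, `first_exam_id` (the exam the derived records attach to).
#' @export
modality_sequences <- function(wh, group_attribute, modality_attribute = "MOD",
                               project = "ris", patients = NULL) {
  if (!has_patient_ids(wh))
    abort_capability("repeated-examination sequences require patient identifiers")
  ef <- exam_frame(wh, c(modality_attribute, group_attribute), project)
  ef <- ef %>%
    filter(!is.na(.data$patient_id),
           !is.na(.data[[modality_attribute]]),
           !is.na(.data[[group_attribute]]))
  if (!is.null(patients)) ef <- ef %>% filter(.data$patient_id %in% patients)
  ef %>%
    arrange(.data$patient_id, .data[[group_attribute]], .data$measure_time,
            .data$exam_id) %>%
    group_by(.data$patient_id, group_key = .data[[group_attribute]]) %>%
    summarise(
      sequence = paste(.data[[modality_attribute]], collapse = "→"),
      length = n(),
      span_hours = elapsed(first(.data$measure_time), last(.data$measure_time),
                           "hours"),
      first_exam_id = first(.data$exam_id),
      first_appointment_id = first(.data$appointment_id),
      first_measure_time = first(.data$measure_time),
      .groups = "drop")
}

#' First-contact flags per examination
#'
#' For each examination: is it the patient's earliest examination in its
#' calendar year (`first_any`), and the earliest with its modality in that
#' year (`first_modality`)? Ties on start time are broken by exam ID so each
#' (patient, year) carries exactly one `first_any` flag.
#'
#' @param wh a [warehouse()].
#' @param modality_attribute,project catalog identity of the modality attribute.
#' @param year optional integer; restrict to examinations of this year.
#' @return tibble `exam_id`, `patient_id`, `year`, `first_any`,
#'   `first_modality` (plus id/time columns used when storing).
#' @export
first_contact_flags <- function(wh, modality_attribute = "MOD", project = "ris",
                                year = NULL) {
  if (!has_patient_ids(wh))
    abort_capability("first-contact flags require patient identifiers")
  ef <- exam_frame(wh, modality_attribute, project) %>%
    filter(!is.na(.data$patient_id)) %>%
    mutate(year = as.integer(substr(.data$measure_time, 1, 4)))
  if (!is.null(year)) ef <- ef %>% filter(.data$year == !!as.integer(year))
  ef %>%
    arrange(.data$patient_id, .data$year, .data$measure_time, .data$exam_id) %>%
    group_by(.data$patient_id, .data$year) %>%
    mutate(first_any = row_number() == 1L) %>%
    group_by(.data$patient_id, .data$year, .data[[modality_attribute]]) %>%
    mutate(first_modality = row_number() == 1L &
             !is.na(.data[[modality_attribute]])) %>%
    ungroup() %>%
    select("exam_id", "appointment_id", "patient_id", "measure_time", "year",
           "first_any", "first_modality")
}

# Calculator framework -----------------------------------------------------

#' Declare a derived-attribute calculator
#'
#' A calculator owns one catalog attribute: running it deletes its previous
#' records and stores fresh ones, which makes re-runs and incremental updates
#' idempotent. `fun(wh, spec, exam_ids, patients)` must return a tibble with
#' columns `patient_id`, `appointment_id`, `exam_id`, `measure_time`, `value`;
#' `exam_ids`/`patients` (may be `NULL`) restrict recomputation for the
#' incremental pathway.
#'
#' @param ext_id,display_name,data_type catalog fields of the created attribute.
#' @param scope `"per_exam"` (recomputable for a subset of exams) or
#'   `"cohort"` (depends on a patient's whole history).
#' @param required `ext_id`s of source attributes that must exist in the
#'   catalog; if absent the calculator is skipped with a warning.
#' @param fun the implementation.
#' @param needs_patient_ids logical; skipped (or erroring when called
#'   directly) on warehouses without patient identifiers.
#' @param recompute `"subset"` if the metric of one exam depends only on that
#'   exam (incremental runs may restrict), `"full"` if it depends on
#'   neighbouring exams (device vacancy) and must always be recomputed whole.
#' @param params list of extra parameters passed through to `fun`.
#' @return a `calculator_spec`.
#' @export
calculator_spec <- function(ext_id, display_name, data_type,
                            scope = c("per_exam", "cohort"),
                            required = character(), fun,
                            needs_patient_ids = FALSE,
                            recompute = c("subset", "full"), params = list()) {
  structure(list(ext_id = ext_id, display_name = display_name,
                 data_type = match.arg_dt(data_type), scope = match.arg(scope),
                 required = required, fun = fun,
                 needs_patient_ids = needs_patient_ids,
                 recompute = match.arg(recompute), params = params),
            class = "calculator_spec")
}

match.arg_dt <- function(dt) {
  if (!dt %in% DATA_TYPES) abort_validation(paste0("unknown data type '", dt, "'"))
  dt
}

#' Built-in calculator registry
#'
#' The standard set of derived metrics, parameterized by the `ext_id`s the
#' import configuration used for the source attributes. Calculators whose
#' source attributes are missing from a given warehouse are skipped at run
#' time, so one registry serves hospitals with different export richness.
#'
#' @param project catalog project of the source attributes.
#' @param modality,request,start,end,report,device,group `ext_id`s of source
#'   attributes (set any to `NULL` to disable the dependent calculators).
#' @param shift_boundaries passed to [assign_shift()].
#' @param year optional year restriction for first-contact flags.
#' @return list of [calculator_spec()]s.
#' @export
default_calculators <- function(project = "ris", modality = "MOD",
                                request = "REQUEST", start = "START",
                                end = "END", report = "REPORT",
                                device = "DEVICE", group = "QUEST",
                                shift_boundaries = c(6, 14, 22), year = NULL) {
  calcs <- list()
  calcs$shift <- calculator_spec(
    "SHIFT", "Shift of examination", "SingleChoice", "per_exam",
    required = start,
    params = list(start = start, boundaries = shift_boundaries, project = project),
    fun = function(wh, spec, exam_ids, patients) {
      p <- spec$params
      ef <- calc_base(wh, p$start, p$project, exam_ids)
      ef$value <- assign_shift(ef$src, p$boundaries)
      ef
    })
  calcs$turnaround <- calculator_spec(
    "TAT_HOURS", "Request-to-examination turnaround (h)", "Number", "per_exam",
    required = c(request, start),
    params = list(request = request, start = start, project = project),
    fun = function(wh, spec, exam_ids, patients) {
      p <- spec$params
      ef <- calc_base2(wh, p$request, p$start, p$project, exam_ids)
      ef$value <- canonical_number(elapsed(ef$src1, ef$src2, "hours"))
      ef
    })
  calcs$duration <- calculator_spec(
    "EXAM_MINUTES", "Examination duration (min)", "Number", "per_exam",
    required = c(start, end),
    params = list(a = start, b = end, project = project),
    fun = function(wh, spec, exam_ids, patients) {
      p <- spec$params
      ef <- calc_base2(wh, p$a, p$b, p$project, exam_ids)
      ef$value <- canonical_number(elapsed(ef$src1, ef$src2, "minutes"))
      ef
    })
  calcs$avail <- calculator_spec(
    "AVAIL_BUCKET", "Report availability bucket (days)", "Number", "per_exam",
    required = c(start, report),
    params = list(a = start, b = report, project = project),
    fun = function(wh, spec, exam_ids, patients) {
      p <- spec$params
      ef <- calc_base2(wh, p$a, p$b, p$project, exam_ids)
      neg <- elapsed(ef$src1, ef$src2, "hours") < 0
      ef <- ef[!neg, , drop = FALSE]
      ef$value <- canonical_number(availability_bucket(ef$src1, ef$src2))
      ef
    })
  calcs$vacancy <- calculator_spec(
    "DEV_VACANCY", "Device vacancy until next examination (min)", "Number",
    "per_exam",
    required = c(device, start, end), recompute = "full",
    params = list(device = device, a = start, b = end, project = project),
    fun = function(wh, spec, exam_ids, patients) {
      p <- spec$params
      # vacancy depends on neighbours: always computed over all exams
      ef <- exam_frame(wh, c(p$device, p$a, p$b), p$project) %>%
        filter(!is.na(.data[[p$device]]), !is.na(.data[[p$a]]),
               !is.na(.data[[p$b]]))
      gaps <- device_vacancy(tibble(
        exam_id = ef$exam_id, device = ef[[p$device]],
        start = ef[[p$a]], end = ef[[p$b]]))
      ef %>% inner_join(gaps, by = "exam_id") %>%
        mutate(value = canonical_number(.data$gap_minutes)) %>%
        select("patient_id", "appointment_id", "exam_id", "measure_time",
               "value")
    })
  calcs$sequence <- calculator_spec(
    "MOD_SEQ", "Modality sequence", "Text", "cohort",
    required = c(modality, group), needs_patient_ids = TRUE,
    params = list(modality = modality, group = group, project = project),
    fun = function(wh, spec, exam_ids, patients) {
      p <- spec$params
      s <- modality_sequences(wh, p$group, p$modality, p$project, patients)
      tibble(patient_id = s$patient_id, appointment_id = s$first_appointment_id,
             exam_id = s$first_exam_id, measure_time = s$first_measure_time,
             value = s$sequence)
    })
  calcs$sequence_span <- calculator_spec(
    "MOD_SEQ_SPAN", "Modality sequence span (h)", "Number", "cohort",
    required = c(modality, group), needs_patient_ids = TRUE,
    params = list(modality = modality, group = group, project = project),
    fun = function(wh, spec, exam_ids, patients) {
      p <- spec$params
      s <- modality_sequences(wh, p$group, p$modality, p$project, patients)
      tibble(patient_id = s$patient_id, appointment_id = s$first_appointment_id,
             exam_id = s$first_exam_id, measure_time = s$first_measure_time,
             value = canonical_number(s$span_hours))
    })
  calcs$first_any <- calculator_spec(
    "FIRST_ANY", "First radiology contact in year", "Boolean", "cohort",
    required = modality, needs_patient_ids = TRUE,
    params = list(modality = modality, project = project, year = year),
    fun = function(wh, spec, exam_ids, patients) {
      p <- spec$params
      f <- first_contact_flags(wh, p$modality, p$project, p$year)
      if (!is.null(patients)) f <- f %>% filter(.data$patient_id %in% patients)
      tibble(patient_id = f$patient_id, appointment_id = f$appointment_id,
             exam_id = f$exam_id, measure_time = f$measure_time,
             value = ifelse(f$first_any, "true", "false"))
    })
  calcs$first_modality <- calculator_spec(
    "FIRST_MOD", "First use of modality in year", "Boolean", "cohort",
    required = modality, needs_patient_ids = TRUE,
    params = list(modality = modality, project = project, year = year),
    fun = function(wh, spec, exam_ids, patients) {
      p <- spec$params
      f <- first_contact_flags(wh, p$modality, p$project, p$year)
      if (!is.null(patients)) f <- f %>% filter(.data$patient_id %in% patients)
      tibble(patient_id = f$patient_id, appointment_id = f$appointment_id,
             exam_id = f$exam_id, measure_time = f$measure_time,
             value = ifelse(f$first_modality, "true", "false"))
    })
  calcs
}

# per-exam single-source scaffold
calc_base <- function(wh, src, project, exam_ids) {
  ef <- exam_frame(wh, src, project) %>% filter(!is.na(.data[[src]]))
  if (!is.null(exam_ids)) ef <- ef %>% filter(.data$exam_id %in% exam_ids)
  tibble(patient_id = ef$patient_id, appointment_id = ef$appointment_id,
         exam_id = ef$exam_id, measure_time = ef$measure_time,
         src = ef[[src]])
}

calc_base2 <- function(wh, src1, src2, project, exam_ids) {
  ef <- exam_frame(wh, c(src1, src2), project) %>%
    filter(!is.na(.data[[src1]]), !is.na(.data[[src2]]))
  if (!is.null(exam_ids)) ef <- ef %>% filter(.data$exam_id %in% exam_ids)
  tibble(patient_id = ef$patient_id, appointment_id = ef$appointment_id,
         exam_id = ef$exam_id, measure_time = ef$measure_time,
         src1 = ef[[src1]], src2 = ef[[src2]])
}

#' Run a calculator registry over a warehouse
#'
#' Each calculator's catalog entry (project `derived_project`) is upserted,
#' its previously derived records are deleted (within the restricted subset,
#' if any) and replaced by fresh values. Calculators whose required source
#' attributes are missing — or that need patient identifiers the warehouse
#' does not have — are skipped with a warning, mirroring exports of differing
#' richness. Negative elapsed times are counted as data-quality flags.
#'
#' @param wh a [warehouse()].
#' @param registry list of [calculator_spec()]s, e.g. [default_calculators()].
#' @param derived_project catalog project for derived attributes.
#' @param exam_ids,patients optional restriction for incremental updates:
#'   per-exam calculators recompute only `exam_ids`, cohort calculators only
#'   `patients`.
#' @return tibble: one row per calculator with `ext_id`, `status`
#'   (`"ok"`/`"skipped"`/`"error"`), `records`, `negative_intervals`, `reason`.
#' @export
run_calculators <- function(wh, registry, derived_project = "derived",
                            exam_ids = NULL, patients = NULL) {
  rows <- purrr::map(registry, function(spec) {
    miss <- spec$required[!vapply(spec$required, function(e)
      nrow(wh$catalog[wh$catalog$ext_id == e, ]) > 0, logical(1))]
    if (length(miss)) {
      rlang::warn(paste0("calculator ", spec$ext_id,
                         " skipped: missing source attribute(s) ",
                         paste(miss, collapse = ", ")))
      return(tibble(ext_id = spec$ext_id, status = "skipped", records = 0L,
                    negative_intervals = 0L,
                    reason = paste0("missing ", paste(miss, collapse = ","))))
    }
    if (spec$needs_patient_ids && !has_patient_ids(wh)) {
      rlang::warn(paste0("calculator ", spec$ext_id,
                         " skipped: warehouse has no patient identifiers"))
      return(tibble(ext_id = spec$ext_id, status = "skipped", records = 0L,
                    negative_intervals = 0L, reason = "no patient identifiers"))
    }
    entry <- upsert_catalog_entry(wh, spec$ext_id, derived_project,
                                  spec$display_name, spec$data_type)
    eff_exam_ids <- if (spec$recompute == "full") NULL else exam_ids
    out <- tryCatch(
      spec$fun(wh, spec, eff_exam_ids, patients),
      error = function(e) e)
    if (inherits(out, "error")) {
      rlang::warn(paste0("calculator ", spec$ext_id, " failed: ",
                         conditionMessage(out)))
      return(tibble(ext_id = spec$ext_id, status = "error", records = 0L,
                    negative_intervals = 0L, reason = conditionMessage(out)))
    }
    neg <- if (spec$data_type == "Number")
      sum(suppressWarnings(as.numeric(out$value)) < 0, na.rm = TRUE) else 0L
    # delete-and-replace the calculator's own records
    restrict_exams <- if (spec$scope == "per_exam") eff_exam_ids else NULL
    restrict_pats <- if (spec$scope == "cohort") patients else NULL
    delete_infos(wh, owner = spec$ext_id, exam_ids = restrict_exams,
                 patient_ids = restrict_pats)
    out <- out %>% filter(!is.na(.data$value))
    if (nrow(out)) {
      append_infos(wh, tibble(
        attribute_id = entry$attribute_id, patient_id = out$patient_id,
        appointment_id = out$appointment_id, exam_id = out$exam_id,
        measure_time = out$measure_time, value = out$value,
        owner = spec$ext_id))
    }
    tibble(ext_id = spec$ext_id, status = "ok", records = nrow(out),
           negative_intervals = as.integer(neg), reason = NA_character_)
  })
  bind_rows(rows)
}
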