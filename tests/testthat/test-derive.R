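test_that("shift assignment uses half-open three-shift boundaries", {
  expect_equal(assign_shift("2018-01-01T09:30:00"), "early")
  expect_equal(assign_shift("2018-01-01T14:00:00"), "late")
  expect_equal(assign_shift("2018-01-01T03:15:00"), "night")
  expect_equal(assign_shift("2018-01-01T22:00:00"), "night")
  expect_equal(assign_shift("2018-01-01T06:00:00"), "early")
  # every timestamp gets exactly one label
  withr::with_seed(3, {
    ts <- format_timestamp(as.POSIXct("2018-01-01", tz = "UTC") +
                             runif(200, 0, 365 * 86400))
    expect_true(all(assign_shift(ts) %in% c("early", "late", "night")))
  })
})

test_that("elapsed time is signed arithmetic in the requested unit", {
  expect_equal(elapsed("2018-01-01T10:00:00", "2018-01-01T12:30:00", "hours"), 2.5)
  expect_equal(elapsed("2018-01-01T10:00:00", "2018-01-01T10:00:00", "minutes"), 0)
  expect_lt(elapsed("2018-01-01T10:00:00", "2018-01-01T08:00:00", "hours"), 0)
})

test_that("availability buckets: ceiling of 24h windows, closed bounds, clamped at 4", {
  s <- "2018-01-01T08:00:00"
  at <- function(h) format_timestamp(parse_timestamp(s) + h * 3600)
  expect_equal(availability_bucket(s, at(5)), 1)
  expect_equal(availability_bucket(s, at(24)), 1)
  expect_equal(availability_bucket(s, at(70)), 3)
  expect_equal(availability_bucket(s, at(200)), 4)
  expect_equal(availability_bucket(s, s), 1)
  expect_error(availability_bucket(s, at(-1)), class = "radwh_validation_error")
  # monotone non-decreasing in report time
  hs <- sort(runif(50, 0, 150))
  expect_true(all(diff(availability_bucket(rep(s, 50), at(hs))) >= 0))
})

test_that("device vacancy matches a brute-force pairwise computation", {
  ex <- tibble::tibble(
    exam_id = c("a", "b", "c"), device = "X",
    start = c("2018-01-01T09:00:00", "2018-01-01T10:20:00", "2018-01-02T09:00:00"),
    end = c("2018-01-01T10:00:00", "2018-01-01T11:00:00", "2018-01-02T09:30:00"))
  g <- device_vacancy(ex)
  expect_equal(g$gap_minutes[g$exam_id == "a"], 20)
  expect_false("b" %in% g$exam_id)  # last exam of its device-day
  expect_false("c" %in% g$exam_id)  # only exam of its day
  expect_equal(nrow(device_vacancy(ex[1, ])), 0)

  withr::with_seed(9, {
    n <- 50
    st0 <- as.POSIXct("2018-05-01", tz = "UTC") +
      sample(0:(3 * 86400), n) %/% 60 * 60
    sched <- tibble::tibble(
      exam_id = sprintf("e%02d", 1:n),
      device = sample(c("D1", "D2", "D3"), n, replace = TRUE),
      start = format_timestamp(st0),
      end = format_timestamp(st0 + sample(600:2400, n)))
    # overlapping exams are legal: negative gaps are kept and flagged
    w <- testthat::capture_warnings(got <- device_vacancy(sched))
    expect_true(all(grepl("overlapping", w)))
    # oracle: sort within device/day, pairwise difference
    oracle <- do.call(rbind, lapply(split(sched, sched$device), function(d) {
      d <- d[order(d$start), ]
      day <- substr(d$start, 1, 10)
      out <- NULL
      for (i in seq_len(nrow(d) - 1)) {
        if (day[i] == day[i + 1]) {
          gap <- as.numeric(difftime(as.POSIXct(sub("T", " ", d$start[i + 1]), tz = "UTC"),
                                     as.POSIXct(sub("T", " ", d$end[i]), tz = "UTC"),
                                     units = "mins"))
          out <- rbind(out, data.frame(exam_id = d$exam_id[i], gap = gap))
        }
      }
      out
    }))
    oracle <- oracle[order(oracle$exam_id), ]
    got <- got[order(got$exam_id), ]
    expect_equal(got$exam_id, oracle$exam_id)
    expect_equal(got$gap_minutes, oracle$gap, tolerance = 1e-9)
  })
})

# warehouse with patients, question codes, modalities for sequence tests
seq_fixture <- function(rows) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  cfg <- tibble::tibble(
    DisplayTitle = c("Patient", "Case", "Start", "Modality", "Question"),
    ExtID = c("PID", "CID", "START", "MOD", "QUEST"),
    DataType = c("Text", "Text", "DateTime", "SingleChoice", "SingleChoice"),
    ColumnName = c("PatientID", "CID", "StartDate", "Modality", "Question"),
    ColumnNumber = "", ValueMappings = "",
    MetaDataType = c("PatientID", "AppointmentID", "MeasureTime", "Modality", ""))
  readr::write_csv(cfg, file.path(dir, "c.csv"), na = "")
  readr::write_csv(rows, file.path(dir, "e.csv"), na = "")
  wh <- warehouse()
  import_table(parse_import_config(file.path(dir, "c.csv")),
               read_ris_export(file.path(dir, "e.csv")), wh)
  wh
}

test_that("modality sequences group by patient and question, ordered by start", {
  wh <- seq_fixture(tibble::tibble(
    PatientID = c("P1", "P1", "P1", "P2"),
    CID = c("C1", "C2", "C3", "C4"),
    StartDate = c("2018-01-01T09:00:00", "2018-01-02T09:00:00",
                  "2018-01-03T09:00:00", "2018-01-05T09:00:00"),
    Modality = c("Rö", "CT", "MRI", "CT"),
    Question = c("Q1", "Q1", "Q2", "Q1")))
  s <- modality_sequences(wh, "QUEST")
  expect_equal(nrow(s), 3)
  q1 <- s[s$patient_id == "P1" & s$group_key == "Q1", ]
  expect_equal(q1$sequence, "Rö→CT")
  expect_equal(q1$span_hours, 24)
  expect_equal(q1$first_exam_id, "C1#1")
  expect_equal(s$sequence[s$patient_id == "P1" & s$group_key == "Q2"], "MRI")
  expect_equal(s$span_hours[s$group_key == "Q2"], 0)
  # conservation: sum of lengths = exams with both patient and group value
  expect_equal(sum(s$length), 4)
})

test_that("sequences split by group key on random data match a group-by oracle", {
  withr::with_seed(21, {
    n <- 60
    rows <- tibble::tibble(
      PatientID = sample(sprintf("P%d", 1:8), n, replace = TRUE),
      CID = sprintf("C%02d", 1:n),
      StartDate = format_timestamp(as.POSIXct("2018-01-01", tz = "UTC") +
                                     sample(0:(90 * 86400), n)),
      Modality = sample(c("Rö", "CT", "MRI"), n, replace = TRUE),
      Question = sample(c("Q1", "Q2", "Q3"), n, replace = TRUE))
    wh <- seq_fixture(rows)
    s <- modality_sequences(wh, "QUEST")
    oracle <- rows[order(rows$PatientID, rows$Question, rows$StartDate, rows$CID), ]
    osplit <- split(oracle, paste(oracle$PatientID, oracle$Question))
    expect_equal(nrow(s), length(osplit))
    for (key in names(osplit)) {
      o <- osplit[[key]]
      row <- s[s$patient_id == o$PatientID[1] & s$group_key == o$Question[1], ]
      expect_equal(row$sequence, paste(o$Modality, collapse = "→"))
    }
  })
})

test_that("first-contact flags: earliest exam per patient-year, ties broken once", {
  wh <- seq_fixture(tibble::tibble(
    PatientID = c("P1", "P1", "P1", "P2"),
    CID = c("C1", "C2", "C3", "C4"),
    StartDate = c("2018-01-05T09:00:00", "2018-03-01T09:00:00",
                  "2019-01-02T09:00:00", "2018-06-01T09:00:00"),
    Modality = c("CT", "CT", "CT", "MRI"),
    Question = "Q1"))
  f <- first_contact_flags(wh)
  p1_2018 <- f[f$patient_id == "P1" & f$year == 2018, ]
  expect_equal(p1_2018$first_any[order(p1_2018$measure_time)], c(TRUE, FALSE))
  expect_equal(p1_2018$first_modality[order(p1_2018$measure_time)], c(TRUE, FALSE))
  expect_true(all(f$first_any[f$patient_id == "P2"]))
  expect_true(all(f$first_any[f$year == 2019 & f$patient_id == "P1"]))
  # exactly one first_any flag per patient-year
  agg <- aggregate(first_any ~ patient_id + year, data = f, FUN = sum)
  expect_true(all(agg$first_any == 1))

  # identical timestamps: exactly one flag via exam-id tie-break
  wh2 <- seq_fixture(tibble::tibble(
    PatientID = "P1", CID = c("C1", "C2"),
    StartDate = "2018-01-05T09:00:00", Modality = "CT", Question = "Q1"))
  f2 <- first_contact_flags(wh2)
  expect_equal(sum(f2$first_any), 1)
  expect_equal(sum(f2$first_modality), 1)
})

test_that("run_calculators skips missing sources, is idempotent, owns its records", {
  wh <- seq_fixture(tibble::tibble(
    PatientID = c("P1", "P2"), CID = c("C1", "C2"),
    StartDate = c("2018-01-05T09:00:00", "2018-01-06T23:00:00"),
    Modality = c("CT", "Rö"), Question = "Q1"))
  reg <- default_calculators()
  w <- testthat::capture_warnings(st <- run_calculators(wh, reg))
  expect_true(any(grepl("skipped", w)))
  st_shift <- st[st$ext_id == "SHIFT", ]
  expect_equal(st_shift$status, "ok")
  expect_equal(st_shift$records, 2)
  # turnaround needs REQUEST which this export lacks
  expect_equal(st$status[st$ext_id == "TAT_HOURS"], "skipped")
  n1 <- nrow(infos(wh))
  suppressWarnings(run_calculators(wh, reg))
  expect_equal(nrow(infos(wh)), n1)  # delete-and-replace, no duplicates
  # derived records are tagged by their calculator
  own <- infos(wh)$owner
  expect_setequal(unique(own[!is.na(own)]),
                  st$ext_id[st$status == "ok"])
})

test_that("sequence and first-contact calculators error without patient identifiers", {
  dir <- withr::local_tempdir()
  cfg <- tibble::tibble(
    DisplayTitle = c("Case", "Start", "Modality", "Question"),
    ExtID = c("CID", "START", "MOD", "QUEST"),
    DataType = c("Text", "DateTime", "SingleChoice", "SingleChoice"),
    ColumnName = c("CID", "StartDate", "Modality", "Question"),
    ColumnNumber = "", ValueMappings = "",
    MetaDataType = c("AppointmentID", "MeasureTime", "Modality", ""))
  readr::write_csv(cfg, file.path(dir, "c.csv"), na = "")
  readr::write_csv(tibble::tibble(CID = "C1", StartDate = "2018-01-01T10:00:00",
                                  Modality = "CT", Question = "Q1"),
                   file.path(dir, "e.csv"), na = "")
  wh <- warehouse()
  import_table(parse_import_config(file.path(dir, "c.csv")),
               read_ris_export(file.path(dir, "e.csv")), wh)
  expect_error(modality_sequences(wh, "QUEST"), class = "radwh_capability_error")
  expect_error(first_contact_flags(wh), class = "radwh_capability_error")
  # via the registry they are skipped with a warning, others still run
  w <- testthat::capture_warnings(st <- run_calculators(wh, default_calculators()))
  expect_true(any(grepl("patient identifiers", w)))
  expect_equal(st$status[st$ext_id == "MOD_SEQ"], "skipped")
  expect_equal(st$status[st$ext_id == "SHIFT"], "ok")
})
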