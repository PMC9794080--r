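test_that("ecg_record validates its invariants", {
  expect_error(ecg_record(numeric(0)), "length")
  expect_error(ecg_record(c(1, NA)), "non-finite")
  expect_error(ecg_record(1:4, fs = 0), "fs")
  r <- ecg_record(sin(1:100), fs = 128, label = "NSR", record_id = "a")
  expect_s3_class(r, "ecg_record")
  expect_equal(length(r$samples), 100)
})

test_that("ecg_dataset enforces unique ids and counts classes", {
  r1 <- ecg_record(1:8, label = "ARR", record_id = "x")
  r2 <- ecg_record(1:8, label = "NSR", record_id = "y")
  d <- ecg_dataset(list(r1, r2))
  expect_equal(sum(d$class_counts), 2L)
  expect_equal(unname(d$class_counts[c("ARR", "NSR")]), c(1L, 1L))
  expect_error(ecg_dataset(list(r1, r1)), "unique")
  expect_error(ecg_dataset(list()), "no records")
})

test_that("csv round trip preserves ids, labels, and samples", {
  d <- ecg_dataset(list(
    ecg_record(rnorm(16), label = "ARR", record_id = "rec_a"),
    ecg_record(rnorm(16), label = "NSR", record_id = "rec_b")))
  path <- withr::local_tempfile(fileext = ".csv")
  write_records(d, path, "csv")
  d2 <- read_records(path, "csv")
  expect_equal(length(d2$records), 2L)
  expect_equal(vapply(d2$records, `[[`, "", "record_id"),
               c("rec_a", "rec_b"))
  expect_equal(vapply(d2$records, `[[`, "", "label"), c("ARR", "NSR"))
  for (i in 1:2) {
    expect_equal(d2$records[[i]]$samples, d$records[[i]]$samples,
                 tolerance = 1e-10)
    expect_equal(length(d2$records[[i]]$samples), 16L)
  }
})

test_that("empty csv input is a validation error", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(character(0), path)
  expect_error(read_records(path, "csv"), "no records")
  expect_error(read_records(file.path(tempdir(), "nope.csv"), "csv"),
               "nope.csv")
})

test_that("npy round trip is bit-exact and readers preserve order", {
  d <- generate_dataset(c(ARR = 3, CHF = 2, NSR = 2), n_samples = 4096,
                        seed = 5)
  path <- withr::local_tempfile(fileext = ".npy")
  write_records(d, path, "npy")
  d2 <- read_records(path, "npy")
  expect_identical(lapply(d2$records, `[[`, "samples"),
                   lapply(d$records, `[[`, "samples"))
  expect_identical(vapply(d2$records, `[[`, "", "record_id"),
                   vapply(d$records, `[[`, "", "record_id"))
  expect_identical(vapply(d2$records, `[[`, "", "label"),
                   vapply(d$records, `[[`, "", "label"))
})

test_that("the full-scale corpus geometry survives an npy round trip", {
  # 162 records x 65,536 samples, the reference corpus shape
  d <- generate_dataset(c(ARR = 96, CHF = 30, NSR = 36), n_samples = 65536,
                        seed = 1, baseline_amp = 0, white_sd = 0)
  expect_equal(length(d$records), 162L)
  expect_equal(unname(d$class_counts[c("ARR", "CHF", "NSR")]),
               c(96L, 30L, 36L))
  expect_true(all(vapply(d$records, function(r) length(r$samples),
                         integer(1)) == 65536L))
  path <- withr::local_tempfile(fileext = ".npy")
  write_records(d, path, "npy")
  d2 <- read_records(path, "npy")
  expect_identical(dataset_matrix_for_test(d2), dataset_matrix_for_test(d))
})

test_that("wfdb format-16 records read with gain and baseline applied", {
  dir <- withr::local_tempdir()
  hea <- file.path(dir, "r01.hea")
  writeLines(c("r01 1 250 128", "r01.dat 16 100(5)/mV 16 0 0 0 0 ECG"), hea)
  adc <- as.integer(round(100 * sin(2 * pi * (0:127) / 32)) + 5L)
  writeBin(adc, file.path(dir, "r01.dat"), size = 2, endian = "little")
  r <- read_wfdb_record(hea)
  expect_equal(r$fs, 250)
  expect_equal(r$record_id, "r01")
  expect_equal(r$samples, (adc - 5) / 100)
  ds <- read_records(hea, "wfdb")
  expect_s3_class(ds, "ecg_dataset")
})

test_that("write_report emits stable human-readable JSON", {
  path <- withr::local_tempfile(fileext = ".json")
  write_report(list(alerts = list(tachycardia = TRUE),
                    accuracy = 1.0, threshold = 0.068), path)
  txt <- paste(readLines(path), collapse = "")
  expect_match(txt, "\"tachycardia\": true")
  expect_match(txt, "\"accuracy\": 1")
  back <- read_report(path)
  expect_identical(back$threshold, 0.068)
  expect_error(write_report(list(bad = function(x) x), "x.json"),
               "'bad'")
})
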