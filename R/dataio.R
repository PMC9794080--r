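#' @useDynLib ecgflow, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

ECG_LABELS <- c("ARR", "CHF", "NSR", "UNKNOWN")

#' Construct a single labelled ECG record
#'
#' An `ecg_record` holds one 1-D ECG trace (millivolts) with its sampling
#' rate and class label. This is the unit object every downstream stage
#' (preprocessing, feature extraction, scattering, anomaly detection)
#' consumes.
#'
#' @param samples Numeric vector of samples in mV; must be finite, length >= 1.
#' @param fs Sampling rate in Hz (> 0). Default 128.
#' @param label One of `"ARR"`, `"CHF"`, `"NSR"`, `"UNKNOWN"`.
#' @param record_id Character scalar identifying the record.
#' @return An object of class `ecg_record`: a list with fields `record_id`,
#'   `samples`, `fs`, `label`.
#' @export
ecg_record <- function(samples, fs = 128, label = "UNKNOWN", record_id = "rec") {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("ecg_record: samples must have length >= 1")
  if (!all(is.finite(samples))) {
    stop(sprintf("ecg_record: non-finite sample in record '%s'", record_id))
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("ecg_record: fs must be a positive scalar")
  }
  label <- match.arg(label, ECG_LABELS)
  structure(
    list(record_id = as.character(record_id), samples = samples,
         fs = as.numeric(fs), label = label),
    class = "ecg_record"
  )
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record '%s'> %d samples @ %g Hz (%.1f s), label %s\n",
              x$record_id, length(x$samples), x$fs,
              length(x$samples) / x$fs, x$label))
  invisible(x)
}

#' Construct an ECG dataset
#'
#' @param records List of [ecg_record()] objects with unique `record_id`s.
#' @return An `ecg_dataset`: list with `records` (ordered, as given) and
#'   `class_counts` (named integer vector over the labels present).
#' @export
ecg_dataset <- function(records) {
  if (!length(records)) stop("ecg_dataset: no records")
  ok <- vapply(records, inherits, logical(1), what = "ecg_record")
  if (!all(ok)) stop("ecg_dataset: all elements must be ecg_record objects")
  ids <- vapply(records, `[[`, character(1), "record_id")
  if (anyDuplicated(ids)) stop("ecg_dataset: record_ids must be unique")
  labels <- vapply(records, `[[`, character(1), "label")
  counts <- table(factor(labels, levels = ECG_LABELS))
  counts <- counts[counts > 0L]
  structure(
    list(records = records,
         class_counts = stats::setNames(as.integer(counts), names(counts))),
    class = "ecg_dataset"
  )
}

#' @export
print.ecg_dataset <- function(x, ...) {
  cat(sprintf("<ecg_dataset> %d records; class counts: %s\n",
              length(x$records),
              paste(names(x$class_counts), x$class_counts,
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' @export
length.ecg_dataset <- function(x) length(x$records)

#' Labels and ids of a dataset's records
#' @param dataset An [ecg_dataset()].
#' @return Character vector, one element per record, in dataset order.
#' @export
dataset_labels <- function(dataset) {
  vapply(dataset$records, `[[`, character(1), "label")
}

#' @rdname dataset_labels
#' @export
dataset_ids <- function(dataset) {
  vapply(dataset$records, `[[`, character(1), "record_id")
}

# Samples of all records as a records x samples matrix (equal lengths required)
dataset_matrix <- function(dataset) {
  lens <- vapply(dataset$records, function(r) length(r$samples), integer(1))
  if (length(unique(lens)) != 1L) {
    stop("dataset_matrix: records have heterogeneous lengths")
  }
  do.call(rbind, lapply(dataset$records, `[[`, "samples"))
}

#' Read ECG records from disk
#'
#' Supported formats:
#' \describe{
#'   \item{csv}{One record per row: first column `record_id`, second column
#'     `label`, remaining columns samples (mV). No header handling beyond an
#'     optional first line starting with `record_id`.}
#'   \item{npy}{A NumPy `.npy` 2-D float64 matrix (records x samples), with a
#'     sidecar `<path>.meta.csv` written by [write_records()] carrying
#'     `record_id`, `label`, `fs`. Without the sidecar, ids are generated and
#'     labels are `UNKNOWN`.}
#'   \item{wfdb}{A PhysioNet-style header/record pair: `path` is the `.hea`
#'     file (or its basename); 16-bit format 212-free reader supporting
#'     format 16 single/multi-channel `.dat`, first channel used, gain and
#'     baseline applied to give mV. The sampling rate comes from the header.}
#' }
#'
#' @param path File path (for wfdb, the `.hea` file or record basename).
#' @param format One of `"csv"`, `"npy"`, `"wfdb"`.
#' @param fs Sampling rate assumed for csv/npy input (default 128 Hz); wfdb
#'   headers carry their own.
#' @return An [ecg_dataset()].
#' @export
read_records <- function(path, format = c("csv", "npy", "wfdb"), fs = 128) {
  format <- match.arg(format)
  switch(format,
    csv  = read_records_csv(path, fs),
    npy  = read_records_npy(path, fs),
    wfdb = {
      rec <- read_wfdb_record(path)
      ecg_dataset(list(rec))
    })
}

read_records_csv <- function(path, fs) {
  if (!file.exists(path)) stop(sprintf("read_records: cannot read '%s'", path))
  dt <- suppressWarnings(
    data.table::fread(path, header = FALSE, colClasses = list(character = 1:2)))
  if (nrow(dt) == 0L) stop("read_records: no records")
  # tolerate a header line
  if (identical(tolower(as.character(dt[[1]][1])), "record_id")) {
    dt <- dt[-1L]
    if (nrow(dt) == 0L) stop("read_records: no records")
  }
  records <- lapply(seq_len(nrow(dt)), function(i) {
    samp <- suppressWarnings(as.numeric(unlist(dt[i, -(1:2)], use.names = FALSE)))
    # ragged rows: fread pads short rows with NA; drop trailing NAs only
    if (anyNA(samp)) {
      last <- max(which(!is.na(samp)), 0L)
      if (last == 0L || anyNA(samp[seq_len(last)])) {
        stop(sprintf("read_records: non-finite sample in record '%s'",
                     as.character(dt[[1]][i])))
      }
      samp <- samp[seq_len(last)]
    }
    ecg_record(samp, fs = fs, label = as.character(dt[[2]][i]),
               record_id = as.character(dt[[1]][i]))
  })
  ecg_dataset(records)
}

read_records_npy <- function(path, fs) {
  if (!file.exists(path)) stop(sprintf("read_records: cannot read '%s'", path))
  mat <- read_npy(path)
  meta_path <- paste0(path, ".meta.csv")
  n <- nrow(mat)
  if (file.exists(meta_path)) {
    meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE,
                            colClasses = c("character", "character", "numeric"))
    if (nrow(meta) != n) stop("read_records: npy sidecar row count mismatch")
    ids <- meta$record_id; labels <- meta$label; fss <- meta$fs
  } else {
    ids <- sprintf("rec_%03d", seq_len(n)); labels <- rep("UNKNOWN", n)
    fss <- rep(fs, n)
  }
  records <- lapply(seq_len(n), function(i) {
    ecg_record(mat[i, ], fs = fss[i], label = labels[i], record_id = ids[i])
  })
  ecg_dataset(records)
}

#' Write ECG records to disk
#'
#' The inverse of [read_records()]. `npy` is bit-exact on round trip (float64
#' binary plus a `<path>.meta.csv` sidecar for ids/labels/fs); `csv` preserves
#' samples to at least 15 significant digits.
#'
#' @param dataset An [ecg_dataset()].
#' @param path Output path.
#' @param format `"csv"` or `"npy"`.
#' @return Invisibly, `path`.
#' @export
write_records <- function(dataset, path, format = c("csv", "npy")) {
  stopifnot(inherits(dataset, "ecg_dataset"))
  if (!length(dataset$records)) stop("write_records: dataset is empty")
  format <- match.arg(format)
  if (format == "csv") {
    lines <- vapply(dataset$records, function(r) {
      paste(c(r$record_id, r$label,
              formatC(r$samples, format = "g", digits = 17)), collapse = ",")
    }, character(1))
    ok <- tryCatch({ writeLines(lines, path); TRUE },
                   error = function(e) FALSE)
    if (!ok) stop(sprintf("write_records: cannot write '%s'", path))
  } else {
    mat <- dataset_matrix(dataset)
    write_npy(mat, path)
    meta <- data.frame(
      record_id = dataset_ids(dataset),
      label = dataset_labels(dataset),
      fs = vapply(dataset$records, `[[`, numeric(1), "fs"))
    utils::write.csv(meta, paste0(path, ".meta.csv"), row.names = FALSE)
  }
  invisible(path)
}

#' Write a structured results report as JSON
#'
#' Serializes alert reports, evaluation metrics, thresholds, or run manifests
#' to human-readable JSON with stable key order (the order of the input list).
#'
#' @param report A named list (nested lists/vectors allowed).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path) {
  if (is.null(names(report)) && length(report)) {
    stop("write_report: report must be a named list")
  }
  check_serializable <- function(x, name) {
    if (is.list(x)) {
      for (i in seq_along(x)) {
        nm <- if (!is.null(names(x)) && nzchar(names(x)[i])) names(x)[i]
              else sprintf("%s[[%d]]", name, i)
        check_serializable(x[[i]], nm)
      }
    } else if (!(is.numeric(x) || is.character(x) || is.logical(x) ||
                 is.factor(x) || is.null(x) || is.matrix(x))) {
      stop(sprintf("write_report: field '%s' is not serializable", name))
    }
  }
  check_serializable(report, "report")
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a JSON report written by [write_report()]
#' @param path Path to the JSON file.
#' @return A named list.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

# ---- minimal NumPy .npy v1.0 reader/writer (2-D float64, C order) ----------

write_npy <- function(mat, path) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  header <- sprintf("{'descr': '<f8', 'fortran_order': False, 'shape': (%d, %d), }",
                    nrow(mat), ncol(mat))
  # pad so that magic(6)+version(2)+len(2)+header is a multiple of 64, newline-terminated
  base_len <- 10L + nchar(header, type = "bytes") + 1L
  pad <- (64L - base_len %% 64L) %% 64L
  header <- paste0(header, strrep(" ", pad), "\n")
  con <- tryCatch(file(path, "wb"), error = function(e)
    stop(sprintf("write_records: cannot write '%s'", path)))
  on.exit(close(con))
  writeBin(as.raw(c(0x93, charToRaw("NUMPY"), 0x01, 0x00)), con)
  writeBin(as.integer(nchar(header, type = "bytes")), con, size = 2,
           endian = "little")
  writeBin(charToRaw(header), con)
  # C order: row-major, so write the transpose column-major
  writeBin(as.numeric(t(mat)), con, size = 8, endian = "little")
  invisible(path)
}

read_npy <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 8)
  if (!identical(magic[1:6], as.raw(c(0x93, charToRaw("NUMPY"))))) {
    stop(sprintf("read_records: '%s' is not an npy file", path))
  }
  hlen <- readBin(con, "integer", n = 1, size = 2, endian = "little",
                  signed = FALSE)
  header <- rawToChar(readBin(con, "raw", n = hlen))
  if (!grepl("'descr':\\s*'<f8'", header)) {
    stop("read_records: only float64 npy supported")
  }
  fortran <- grepl("'fortran_order':\\s*True", header)
  shp <- regmatches(header, regexpr("\\(([0-9]+),\\s*([0-9]+)\\s*,?\\)", header))
  dims <- as.integer(strsplit(gsub("[()]", "", shp), ",")[[1]])
  vals <- readBin(con, "numeric", n = prod(dims), size = 8, endian = "little")
  if (fortran) matrix(vals, nrow = dims[1], ncol = dims[2])
  else t(matrix(vals, nrow = dims[2], ncol = dims[1]))
}

# ---- minimal WFDB (PhysioNet) reader: format 16 -----------------------------

#' Read a single WFDB record (PhysioNet header/dat convention)
#'
#' Minimal read-only support: parses the `.hea` text header, reads a format-16
#' (16-bit little-endian) `.dat` signal file, takes the first channel and
#' converts ADC units to mV using the header gain and baseline.
#'
#' @param path Path to the `.hea` file or the record basename.
#' @param label Class label to attach (WFDB headers do not carry one).
#' @return An [ecg_record()].
#' @export
read_wfdb_record <- function(path, label = "UNKNOWN") {
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea)) stop(sprintf("read_records: cannot read '%s'", hea))
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^#", lines)]
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rec_name <- top[1]; n_sig <- as.integer(top[2])
  fs <- if (length(top) >= 3) as.numeric(top[3]) else 250
  n_samp <- if (length(top) >= 4) as.integer(top[4]) else NA_integer_
  sig <- strsplit(trimws(lines[2]), "\\s+")[[1]]
  dat_file <- sig[1]
  fmt <- as.integer(sub("x.*", "", sig[2]))
  if (fmt != 16L) stop("read_records: only WFDB format 16 supported")
  gain <- if (length(sig) >= 3) as.numeric(sub("[(/].*", "", sig[3])) else 200
  if (!is.finite(gain) || gain == 0) gain <- 200
  baseline <- 0
  if (length(sig) >= 3 && grepl("\\(", sig[3])) {
    baseline <- as.numeric(sub(".*\\(([-0-9]+)\\).*", "\\1", sig[3]))
  }
  dat <- file.path(dirname(hea), dat_file)
  if (!file.exists(dat)) stop(sprintf("read_records: cannot read '%s'", dat))
  n_raw <- file.info(dat)$size / 2
  vals <- readBin(dat, "integer", n = n_raw, size = 2, endian = "little",
                  signed = TRUE)
  if (n_sig > 1L) vals <- vals[seq(1L, length(vals), by = n_sig)]
  if (!is.na(n_samp) && n_samp > 0L) vals <- vals[seq_len(min(n_samp, length(vals)))]
  ecg_record((vals - baseline) / gain, fs = fs, label = label,
             record_id = rec_name)
}
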