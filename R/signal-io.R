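#' Recording metadata
#'
#' @param subject_id opaque subject identifier.
#' @param age_group `"young"` (18--50 y) or `"old"` (over 50 y).
#' @param sex `"male"` or `"female"`.
#' @param test_day test day index, 1 to 3.
#' @param mvc_load optional 80% MVC load in Nm.
#' @return List of class `"recording_meta"`.
#' @export
recording_meta <- function(subject_id = "S000",
                           age_group = c("young", "old"),
                           sex = c("male", "female"),
                           test_day = 1L,
                           mvc_load = NULL) {
  age_group <- match.arg(age_group)
  sex <- match.arg(sex)
  test_day <- as.integer(test_day)
  if (!test_day %in% 1:3) stop("test_day must be 1, 2 or 3", call. = FALSE)
  structure(list(subject_id = as.character(subject_id),
                 age_group = age_group, sex = sex,
                 test_day = test_day, mvc_load = mvc_load),
            class = "recording_meta")
}

#' Construct and validate a contraction recording
#'
#' Container for one 30-s sustained-contraction trial: a matrix of six SEMG
#' channels sampled at `semg_fs` with columns in canonical label order (see
#' [semg_labels()]), a 3-column accelerometer matrix (`x_g`, `y_g`, `z_g`,
#' in g units) at `accel_fs`, and metadata. Time 0 is the contraction
#' onset for both streams.
#'
#' @param semg numeric matrix, one column per electrode, colnames drawn from
#'   [semg_labels()]; any column order is accepted and normalized.
#' @param semg_fs SEMG sampling rate, Hz.
#' @param accel numeric matrix with columns `x_g`, `y_g`, `z_g`.
#' @param accel_fs accelerometer sampling rate, Hz.
#' @param meta a [recording_meta()].
#' @return List of class `"semg_recording"`.
#' @export
new_recording <- function(semg, semg_fs = 2000, accel = NULL,
                          accel_fs = 160, meta = recording_meta()) {
  if (!is.matrix(semg)) semg <- as.matrix(semg)
  labs <- colnames(semg)
  if (is.null(labs)) stop("SEMG matrix must have channel labels as colnames",
                          call. = FALSE)
  unknown <- setdiff(labs, semg_labels())
  if (length(unknown))
    stop("unknown channel label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  missing_lab <- setdiff(semg_labels(), labs)
  if (length(missing_lab))
    stop("missing channel(s): ", paste(missing_lab, collapse = ", "),
         call. = FALSE)
  semg <- semg[, semg_labels(), drop = FALSE]  # canonical order
  if (!is.null(accel)) {
    if (!is.matrix(accel)) accel <- as.matrix(accel)
    if (!identical(colnames(accel), c("x_g", "y_g", "z_g")))
      stop("accelerometer matrix must have columns x_g, y_g, z_g",
           call. = FALSE)
  }
  stopifnot(inherits(meta, "recording_meta"))
  structure(list(semg = semg, semg_fs = semg_fs,
                 accel = accel, accel_fs = accel_fs, meta = meta),
            class = "semg_recording")
}

#' @export
print.semg_recording <- function(x, ...) {
  cat(sprintf("SEMG recording: subject %s (%s, %s), day %d\n",
              x$meta$subject_id, x$meta$age_group, x$meta$sex,
              x$meta$test_day))
  cat(sprintf("  SEMG: 6 channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$semg), x$semg_fs, nrow(x$semg) / x$semg_fs))
  if (!is.null(x$accel))
    cat(sprintf("  accel: 3 axes x %d samples @ %g Hz\n",
                nrow(x$accel), x$accel_fs))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec a `"semg_recording"`.
#' @return Duration in seconds based on the SEMG stream.
#' @export
recording_duration <- function(rec) nrow(rec$semg) / rec$semg_fs

#' Write a recording to a directory of plain-text files
#'
#' The on-disk format is deliberately simple and diff-able: a `meta.txt`
#' sidecar of `key: value` lines, a tab-separated `semg.tsv` (column
#' `time_s` plus one column per electrode, volts) and, when present, an
#' `accel.tsv` (`time_s`, `x_g`, `y_g`, `z_g`). Times are seconds from
#' contraction onset.
#'
#' @param rec a `"semg_recording"`.
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "semg_recording"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  m <- rec$meta
  meta_lines <- c(
    paste0("subject_id: ", m$subject_id),
    paste0("age_group: ", m$age_group),
    paste0("sex: ", m$sex),
    paste0("test_day: ", m$test_day),
    if (!is.null(m$mvc_load)) paste0("mvc_load: ", format(m$mvc_load)),
    paste0("semg_fs: ", format(rec$semg_fs)),
    paste0("accel_fs: ", format(rec$accel_fs)))
  writeLines(meta_lines, file.path(path, "meta.txt"))
  semg_dt <- data.table::data.table(
    time_s = (seq_len(nrow(rec$semg)) - 1L) / rec$semg_fs)
  for (lab in colnames(rec$semg)) semg_dt[[lab]] <- rec$semg[, lab]
  data.table::fwrite(semg_dt, file.path(path, "semg.tsv"), sep = "\t")
  if (!is.null(rec$accel)) {
    acc_dt <- data.table::data.table(
      time_s = (seq_len(nrow(rec$accel)) - 1L) / rec$accel_fs)
    for (ax in colnames(rec$accel)) acc_dt[[ax]] <- rec$accel[, ax]
    data.table::fwrite(acc_dt, file.path(path, "accel.tsv"), sep = "\t")
  }
  invisible(path)
}

#' Read a recording written by [write_recording()]
#'
#' Channels are validated against the canonical label set and returned in
#' canonical order regardless of column order on disk.
#'
#' @param path recording directory.
#' @return A `"semg_recording"`.
#' @export
read_recording <- function(path) {
  meta_path <- file.path(path, "meta.txt")
  semg_path <- file.path(path, "semg.tsv")
  if (!file.exists(meta_path) || !file.exists(semg_path))
    stop("not a recording directory (meta.txt / semg.tsv missing): ", path,
         call. = FALSE)
  kv <- read_keyvalue(meta_path)
  need <- c("subject_id", "age_group", "sex", "test_day", "semg_fs",
            "accel_fs")
  miss <- setdiff(need, names(kv))
  if (length(miss))
    stop("meta.txt is missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  meta <- recording_meta(subject_id = kv[["subject_id"]],
                         age_group = kv[["age_group"]],
                         sex = kv[["sex"]],
                         test_day = as.integer(kv[["test_day"]]),
                         mvc_load = if ("mvc_load" %in% names(kv))
                           as.numeric(kv[["mvc_load"]]) else NULL)
  semg_dt <- data.table::fread(semg_path, sep = "\t", data.table = FALSE)
  if (!"time_s" %in% names(semg_dt))
    stop("semg.tsv has no time_s column", call. = FALSE)
  semg <- as.matrix(semg_dt[setdiff(names(semg_dt), "time_s")])
  accel <- NULL
  accel_path <- file.path(path, "accel.tsv")
  if (file.exists(accel_path)) {
    acc_dt <- data.table::fread(accel_path, sep = "\t", data.table = FALSE)
    accel <- as.matrix(acc_dt[c("x_g", "y_g", "z_g")])
  }
  new_recording(semg = semg, semg_fs = as.numeric(kv[["semg_fs"]]),
                accel = accel, accel_fs = as.numeric(kv[["accel_fs"]]),
                meta = meta)
}

read_keyvalue <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  m <- regmatches(lines, regexec("^([^:]+):\\s*(.*)$", lines))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad))
    stop("malformed line in ", path, ": ", lines[bad][1], call. = FALSE)
  vals <- vapply(m, `[`, character(1), 3L)
  names(vals) <- trimws(vapply(m, `[`, character(1), 2L))
  as.list(vals)
}

#' Write a tidy metric table to CSV
#'
#' Long/tidy layout, one row per recording x electrode (or aggregate).
#' The table must carry the identifying columns `recording` and
#' `electrode`; all other columns must be numeric metric columns. Values
#' are written with enough digits to round-trip doubles.
#'
#' @param metrics a `data.frame` in the documented schema.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path) {
  if (!is.data.frame(metrics)) stop("metrics must be a data.frame",
                                    call. = FALSE)
  need <- c("recording", "electrode")
  miss <- setdiff(need, names(metrics))
  if (length(miss))
    stop("metric table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  other <- setdiff(names(metrics), need)
  bad <- other[!vapply(metrics[other], function(c)
    is.numeric(c) || is.logical(c), logical(1))]
  if (length(bad))
    stop("non-numeric metric column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  data.table::fwrite(metrics, path)
  invisible(path)
}

#' Read a metric table written by [write_metrics()]
#' @param path CSV path.
#' @return A `data.frame`.
#' @export
read_metrics <- function(path) {
  data.table::fread(path, data.table = FALSE)
}
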