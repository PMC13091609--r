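## Signal store: per-read raw current plus calibration, on disk as a
## directory of Parquet files mirroring the POD5 read-table schema
## (read_id, signal, calibration offset/scale, sample rate).

STORE_COLUMNS <- c("read_id", "signal", "calibration_offset",
                   "calibration_scale", "sample_rate")

#' Construct an in-memory read signal
#'
#' A read signal is the raw integer sample array in DAC (digitizer) units
#' plus the calibration needed to convert to picoamperes:
#' \code{pA = (raw + offset) * scale}.
#'
#' @param read_id character read identifier (UUID-style string).
#' @param raw integer vector of raw samples (DAC units); non-empty.
#' @param calibration_offset numeric DAC offset.
#' @param calibration_scale numeric pA per DAC unit; positive.
#' @param sample_rate numeric sampling rate in Hz; positive.
#' @return an object of class \code{read_signal}.
#' @export
read_signal <- function(read_id, raw, calibration_offset, calibration_scale,
                        sample_rate) {
  if (!length(raw)) stop2("read signal must be non-empty: ", read_id)
  if (!is.numeric(calibration_scale) || calibration_scale <= 0)
    stop2("calibration_scale must be > 0")
  if (!is.numeric(sample_rate) || sample_rate <= 0)
    stop2("sample_rate must be > 0")
  structure(list(read_id = as.character(read_id),
                 raw = as.integer(raw),
                 calibration_offset = as.numeric(calibration_offset),
                 calibration_scale = as.numeric(calibration_scale),
                 sample_rate = as.numeric(sample_rate)),
            class = "read_signal")
}

#' @export
print.read_signal <- function(x, ...) {
  cat(sprintf("<read_signal %s: %d samples, scale %.4g pA/DAC, offset %.4g, %g Hz>\n",
              x$read_id, length(x$raw), x$calibration_scale,
              x$calibration_offset, x$sample_rate))
  invisible(x)
}

#' Index every read in a signal-store directory
#'
#' Scans all \code{.parquet} files in a directory once and maps each
#' \code{read_id} to its (file, row) location; later lookups are O(1).
#' A read id occurring in more than one file is ambiguous and is an error.
#'
#' @param pod5_dir directory containing zero or more signal-store Parquet
#'   files (the package's on-disk analogue of a POD5 directory).
#' @return an object of class \code{read_index}.
#' @export
build_read_index <- function(pod5_dir) {
  if (!dir.exists(pod5_dir)) stop2("signal directory does not exist: ", pod5_dir)
  files <- sort(list.files(pod5_dir, pattern = "\\.parquet$", full.names = TRUE))
  file_of <- character(0)
  row_of <- integer(0)
  for (f in files) {
    ids <- tryCatch(
      as.character(arrow::read_parquet(f, col_select = "read_id")$read_id),
      error = function(e) stop2("unreadable or corrupt signal file: ", f,
                                " (", conditionMessage(e), ")"))
    dup <- ids[ids %in% names(file_of)]
    if (length(dup))
      stop2("duplicate read_id across signal files (ambiguous source): ",
            dup[[1]], " in ", f, " and ", file_of[[dup[[1]]]])
    if (anyDuplicated(ids))
      stop2("duplicate read_id within signal file: ", f)
    file_of[ids] <- f
    row_of[ids] <- seq_along(ids)
  }
  structure(list(dir = pod5_dir, file_of = file_of, row_of = row_of,
                 cache = new.env(parent = emptyenv())),
            class = "read_index")
}

#' @export
print.read_index <- function(x, ...) {
  cat(sprintf("<read_index: %d reads in %d file(s) under %s>\n",
              length(x$file_of), length(unique(x$file_of)), x$dir))
  invisible(x)
}

#' @export
length.read_index <- function(x) length(x$file_of)

#' Load one read's raw signal and calibration from an index
#'
#' @param index a [build_read_index()] result.
#' @param read_id read identifier present in the index.
#' @return a [read_signal()] object; calibration is *not* applied.
#' @export
load_read_signal <- function(index, read_id) {
  stopifnot(inherits(index, "read_index"))
  f <- index$file_of[read_id]
  if (is.na(f) || is.null(f))
    stop2("read_id not present in signal index: ", read_id)
  f <- unname(f)
  key <- f
  tab <- index$cache[[key]]
  if (is.null(tab)) {
    tab <- tryCatch(as.data.frame(arrow::read_parquet(f)),
                    error = function(e) stop2("I/O error reading signal file ",
                                              f, ": ", conditionMessage(e)))
    miss <- setdiff(STORE_COLUMNS, names(tab))
    if (length(miss))
      stop2("signal file ", f, " lacks column(s): ", paste(miss, collapse = ", "))
    index$cache[[key]] <- tab
  }
  i <- unname(index$row_of[read_id])
  read_signal(read_id = tab$read_id[[i]],
              raw = as.integer(unlist(tab$signal[[i]])),
              calibration_offset = tab$calibration_offset[[i]],
              calibration_scale = tab$calibration_scale[[i]],
              sample_rate = tab$sample_rate[[i]])
}

#' Convert raw DAC samples to picoamperes
#'
#' Applies the affine calibration \code{pA = (raw + offset) * scale}.
#'
#' @param signal a [read_signal()].
#' @return numeric vector of calibrated samples (pA), same length as the raw
#'   array.
#' @export
#' @examples
#' s <- read_signal("r", c(10L, 20L), 10, 0.5, 4000)
#' calibrate(s)  # 10.0 15.0
calibrate <- function(signal) {
  stopifnot(inherits(signal, "read_signal"))
  (as.numeric(signal$raw) + signal$calibration_offset) * signal$calibration_scale
}

#' Write a set of reads to one signal-store Parquet file
#'
#' @param reads list of [read_signal()] objects.
#' @param path output file path (\code{.parquet}).
#' @return \code{path}, invisibly.
#' @export
write_signal_store <- function(reads, path) {
  stopifnot(all(vapply(reads, inherits, logical(1), "read_signal")))
  df <- data.frame(
    read_id = vapply(reads, `[[`, character(1), "read_id"),
    calibration_offset = vapply(reads, `[[`, numeric(1), "calibration_offset"),
    calibration_scale = vapply(reads, `[[`, numeric(1), "calibration_scale"),
    sample_rate = vapply(reads, `[[`, numeric(1), "sample_rate"),
    stringsAsFactors = FALSE)
  df$signal <- I(lapply(reads, `[[`, "raw"))
  arrow::write_parquet(df[, STORE_COLUMNS], path)
  invisible(path)
}
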