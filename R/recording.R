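#' Construct an EEG recording object
#'
#' A recording is a channel-by-sample numeric matrix (microvolts) with a
#' sampling rate and ordered 10/10 electrode labels. It is the unit of EEG
#' input/output for the whole pipeline.
#'
#' @param data Numeric matrix, channels in rows, samples in columns.
#' @param fs Sampling rate in Hz (positive scalar).
#' @param labels Character vector of unique electrode labels, one per row.
#' @param reference Free-text provenance tag (e.g. "raw", "CAR").
#' @return An object of class `eeg_recording`.
#' @export
recording <- function(data, fs, labels, reference = "raw") {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("fs must be a positive scalar (Hz)", call. = FALSE)
  labels <- as.character(labels)
  if (nrow(data) != length(labels))
    stop("number of rows in data must equal number of labels", call. = FALSE)
  if (anyDuplicated(labels))
    stop("electrode labels must be unique", call. = FALSE)
  rownames(data) <- labels
  structure(
    list(data = data, fs = fs, labels = labels, reference = reference),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), reference: %s\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
              x$reference))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec An `eeg_recording`.
#' @return Numeric scalar, seconds.
#' @export
recording_duration <- function(rec) ncol(rec$data) / rec$fs

#' Read or write a recording as CSV with a side-car metadata file
#'
#' The CSV stores channels as rows: the first field of each row is the
#' electrode label, the remaining fields are samples in microvolts. There is
#' no header row. A side-car YAML file (`<path>.meta.yaml`) carries the
#' sampling rate, units and reference tag; reading fails without it, since a
#' bare sample matrix is ambiguous.
#'
#' @param rec An `eeg_recording`.
#' @param path CSV file path.
#' @return `write_recording_csv` returns `path` invisibly;
#'   `read_recording_csv` returns an `eeg_recording`.
#' @export
write_recording_csv <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  out <- cbind(rec$labels, format(rec$data, digits = 15, trim = TRUE,
                                  scientific = FALSE))
  utils::write.table(out, path, sep = ",", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  yaml::write_yaml(list(fs_hz = rec$fs, units = "uV",
                        reference = rec$reference),
                   paste0(path, ".meta.yaml"))
  invisible(path)
}

#' @rdname write_recording_csv
#' @export
read_recording_csv <- function(path) {
  meta_path <- paste0(path, ".meta.yaml")
  if (!file.exists(meta_path))
    stop("missing side-car metadata file: ", meta_path,
         " (sampling rate unknown)", call. = FALSE)
  meta <- yaml::read_yaml(meta_path)
  if (is.null(meta$fs_hz))
    stop("side-car metadata lacks fs_hz", call. = FALSE)
  raw <- utils::read.table(path, sep = ",", header = FALSE,
                           stringsAsFactors = FALSE)
  labels <- as.character(raw[[1L]])
  data <- as.matrix(raw[, -1L, drop = FALSE])
  dimnames(data) <- NULL
  recording(data, fs = meta$fs_hz, labels = labels,
            reference = meta$reference %||% "file")
}

#' Read or write a recording in European Data Format (EDF)
#'
#' A minimal EDF implementation: 16-bit samples, one-second data records,
#' per-channel physical scaling chosen from the data range. Recordings whose
#' length is not a whole number of seconds are zero-padded to the next
#' record boundary on write (the true sample count is not recoverable from
#' the file; CSV round-trips exactly).
#'
#' @param rec An `eeg_recording`; `fs` must be a positive integer.
#' @param path File path.
#' @return `write_recording_edf` returns `path` invisibly;
#'   `read_recording_edf` returns an `eeg_recording`.
#' @export
write_recording_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (fs != round(fs) || fs <= 0)
    stop("EDF writer requires an integer sampling rate", call. = FALSE)
  ns <- nrow(rec$data)
  n_samp <- ncol(rec$data)
  n_rec <- as.integer(ceiling(n_samp / fs))
  data <- rec$data
  if (n_rec * fs > n_samp)
    data <- cbind(data, matrix(0, ns, n_rec * fs - n_samp))

  pmin_ <- apply(data, 1L, min)
  pmax_ <- apply(data, 1L, max)
  flat <- pmax_ - pmin_ < 1e-12
  pmin_[flat] <- pmin_[flat] - 1
  pmax_[flat] <- pmax_[flat] + 1
  dmin <- -32768; dmax <- 32767

  pad <- function(x, w) {
    x <- substr(format(x, trim = TRUE, scientific = FALSE), 1L, w)
    formatC(x, width = w, flag = "-")
  }
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(paste0(s, collapse = ""), con, eos = NULL)
  wr(pad("0", 8))                                  # version
  wr(pad("X X X X", 80))                           # patient id
  wr(pad(paste("Startdate 01-JAN-2000", rec$reference), 80))  # recording id
  wr(pad("01.01.00", 8)); wr(pad("00.00.00", 8))   # date, time
  wr(pad(256 * (1 + ns), 8))                       # header bytes
  wr(pad("", 44))
  wr(pad(n_rec, 8)); wr(pad(1, 8)); wr(pad(ns, 4))
  wr(pad(rec$labels, 16))
  wr(pad(rep("", ns), 80))                         # transducer
  wr(pad(rep("uV", ns), 8))
  wr(pad(signif(pmin_, 7), 8)); wr(pad(signif(pmax_, 7), 8))
  wr(pad(rep(dmin, ns), 8)); wr(pad(rep(dmax, ns), 8))
  wr(pad(rep("", ns), 80))                         # prefiltering
  wr(pad(rep(fs, ns), 8))
  wr(pad(rep("", ns), 32))

  pmin_r <- as.numeric(signif(pmin_, 7)); pmax_r <- as.numeric(signif(pmax_, 7))
  gain <- (dmax - dmin) / (pmax_r - pmin_r)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    block <- t((data[, cols, drop = FALSE] - pmin_r) * gain + dmin)
    writeBin(as.integer(round(pmin(pmax(block, dmin), dmax))), con,
             size = 2L, endian = "little")
  }
  invisible(path)
}

#' @rdname write_recording_edf
#' @export
read_recording_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rid <- rd(80); rd(8); rd(8); rd(8); rd(44)
  n_rec <- as.integer(rd(8)); rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  rdv <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- rdv(16); rdv(80); rdv(8)
  pmin_ <- as.numeric(rdv(8)); pmax_ <- as.numeric(rdv(8))
  dmin <- as.numeric(rdv(8)); dmax <- as.numeric(rdv(8))
  rdv(80); spr <- as.integer(rdv(8)); rdv(32)
  if (length(unique(spr)) != 1L)
    stop("mixed per-channel sampling rates are not supported", call. = FALSE)
  fs <- spr[1L] / rec_dur
  gain <- (pmax_ - pmin_) / (dmax - dmin)
  data <- matrix(0, ns, n_rec * spr[1L])
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, "integer", n = ns * spr[1L], size = 2L,
                   signed = TRUE, endian = "little")
    block <- matrix(raw, nrow = spr[1L], ncol = ns)
    cols <- ((r - 1L) * spr[1L] + 1L):(r * spr[1L])
    data[, cols] <- t((block - rep(dmin, each = spr[1L])) *
                        rep(gain, each = spr[1L]) +
                        rep(pmin_, each = spr[1L]))
  }
  recording(data, fs = fs, labels = labels,
            reference = sub("^Startdate \\S+ ?", "", rid))
}

#' Read or write a recording, dispatching on file extension
#'
#' `.csv` uses the CSV + side-car format, `.edf` the EDF format.
#'
#' @param rec An `eeg_recording` (for writing).
#' @param path File path ending in `.csv` or `.edf`.
#' @return An `eeg_recording` (read) or `path` invisibly (write).
#' @export
read_recording <- function(path) {
  switch(tolower(tools::file_ext(path)),
         csv = read_recording_csv(path),
         edf = read_recording_edf(path),
         stop("unsupported recording format: ", path, call. = FALSE))
}

#' @rdname read_recording
#' @export
write_recording <- function(rec, path) {
  switch(tolower(tools::file_ext(path)),
         csv = write_recording_csv(rec, path),
         edf = write_recording_edf(rec, path),
         stop("unsupported recording format: ", path, call. = FALSE))
}
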