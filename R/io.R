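# File I/O: 16-bit EDF and a plain-matrix CSV format with a YAML sidecar.
#
# EDF layout: 256-byte fixed header, 256 bytes per signal header, then data
# records of little-endian int16 samples scaled between the declared
# physical and digital ranges. One-second data records are used.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

#' Write a recording to an EDF file
#'
#' Writes 16-bit EDF with one-second data records. Samples are quantized
#' onto the declared physical range (`phys_range`, microvolts), so the
#' round-trip error is at most half a quantization step,
#' `diff(phys_range) / (2^16 - 2) / 2`. A trailing partial second is
#' dropped.
#'
#' @param rec An [eeg_recording()].
#' @param path Output file path.
#' @param phys_range Length-2 physical range in microvolts mapped onto the
#'   16-bit digital range. Samples outside it are clipped.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, phys_range = c(-1000, 1000)) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$srate != round(rec$srate)) {
    abort("EDF writer requires an integer sampling rate.")
  }
  ns <- nrow(rec$signals)
  spr <- as.integer(rec$srate)          # samples per 1-s record
  n_rec <- floor(ncol(rec$signals) / spr)
  if (n_rec < 1) abort("Recording shorter than one EDF data record.")
  p_lo <- phys_range[1]; p_hi <- phys_range[2]
  dmin <- -32767L; dmax <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(edf_pad("0", 8), con, eos = NULL)
  writeChar(edf_pad("X X X X", 80), con, eos = NULL)
  writeChar(edf_pad("Startdate X X X X", 80), con, eos = NULL)
  writeChar(edf_pad("01.01.00", 8), con, eos = NULL)
  writeChar(edf_pad("00.00.00", 8), con, eos = NULL)
  writeChar(edf_pad(256 * (1 + ns), 8), con, eos = NULL)
  writeChar(edf_pad("", 44), con, eos = NULL)
  writeChar(edf_pad(n_rec, 8), con, eos = NULL)
  writeChar(edf_pad(1, 8), con, eos = NULL)
  writeChar(edf_pad(ns, 4), con, eos = NULL)
  for (lab in rec$labels) writeChar(edf_pad(paste("EEG", lab), 16), con, eos = NULL)
  for (i in seq_len(ns)) writeChar(edf_pad("AgAgCl electrode", 80), con, eos = NULL)
  for (i in seq_len(ns)) writeChar(edf_pad("uV", 8), con, eos = NULL)
  for (i in seq_len(ns)) writeChar(edf_pad(p_lo, 8), con, eos = NULL)
  for (i in seq_len(ns)) writeChar(edf_pad(p_hi, 8), con, eos = NULL)
  for (i in seq_len(ns)) writeChar(edf_pad(dmin, 8), con, eos = NULL)
  for (i in seq_len(ns)) writeChar(edf_pad(dmax, 8), con, eos = NULL)
  for (i in seq_len(ns)) writeChar(edf_pad("", 80), con, eos = NULL)
  for (i in seq_len(ns)) writeChar(edf_pad(spr, 8), con, eos = NULL)
  for (i in seq_len(ns)) writeChar(edf_pad("", 32), con, eos = NULL)

  scale <- (dmax - dmin) / (p_hi - p_lo)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    for (i in seq_len(ns)) {
      v <- pmin(pmax(rec$signals[i, idx], p_lo), p_hi)
      dig <- as.integer(round((v - p_lo) * scale + dmin))
      writeBin(dig, con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file
#'
#' Reads continuous 16-bit EDF. Signal labels are normalized to canonical
#' 10-20 names where recognizable; values are returned in the file's
#' physical units (expected microvolts).
#'
#' @param path EDF file path.
#' @return An [eeg_recording()].
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) abort(paste("No such file:", path))
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  hdr(8); hdr(80); hdr(80); hdr(8); hdr(8)
  hdr(8)                                # header bytes
  hdr(44)
  n_rec <- as.integer(hdr(8))
  rec_dur <- as.numeric(hdr(8))
  ns <- as.integer(hdr(4))
  if (is.na(ns) || ns < 1) abort("Malformed EDF header.", class = "alphamark_format")
  labels <- vapply(seq_len(ns), function(i) hdr(16), "")
  for (i in seq_len(ns)) hdr(80)
  units <- vapply(seq_len(ns), function(i) hdr(8), "")
  pmin <- as.numeric(vapply(seq_len(ns), function(i) hdr(8), ""))
  pmax <- as.numeric(vapply(seq_len(ns), function(i) hdr(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) hdr(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) hdr(8), ""))
  for (i in seq_len(ns)) hdr(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) hdr(8), ""))
  for (i in seq_len(ns)) hdr(32)
  if (length(unique(spr)) != 1) {
    abort("Mixed per-signal sampling rates are not supported.",
          class = "alphamark_format")
  }
  if (is.na(rec_dur) || rec_dur <= 0) {
    abort("EDF record duration missing; sampling rate undefined.",
          class = "alphamark_format")
  }
  srate <- spr[1] / rec_dur
  sig <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[i], size = 2, endian = "little")
      phys <- (dig - dmin[i]) / (dmax[i] - dmin[i]) * (pmax[i] - pmin[i]) + pmin[i]
      sig[i, ((r - 1) * spr[i] + 1):(r * spr[i])] <- phys
    }
  }
  eeg_recording(sig, normalize_label(labels), srate)
}

#' Write a recording in the plain-matrix format
#'
#' A CSV with one column per channel (header row of labels) and one row
#' per sample, plus a YAML sidecar `<path>.yaml` recording sampling rate,
#' unit and reference.
#'
#' @param rec An [eeg_recording()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_recording_matrix <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  df <- tibble::as_tibble(t(rec$signals), .name_repair = "minimal")
  names(df) <- rec$labels
  readr::write_csv(df, path)
  yaml::write_yaml(
    list(sampling_rate = rec$srate, unit = "uV", reference = rec$reference),
    paste0(path, ".yaml")
  )
  invisible(path)
}

read_recording_matrix <- function(path) {
  if (!file.exists(path)) abort(paste("No such file:", path))
  side <- paste0(path, ".yaml")
  if (!file.exists(side)) {
    abort("Missing YAML sidecar with the sampling rate.",
          class = "alphamark_format")
  }
  meta <- yaml::read_yaml(side)
  if (is.null(meta$sampling_rate)) {
    abort("Sampling rate missing from sidecar.", class = "alphamark_format")
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  eeg_recording(t(as.matrix(df)), normalize_label(names(df)),
                meta$sampling_rate,
                reference = meta$reference %||% "other")
}

#' Read a recording from disk
#'
#' Dispatches on `format` (or the file extension) to the EDF or
#' plain-matrix reader. Recordings must have at least two channels.
#'
#' @param path File path.
#' @param format `"edf"`, `"matrix"`, or `"auto"` (by extension).
#' @return An [eeg_recording()].
#' @export
read_recording <- function(path, format = c("auto", "edf", "matrix")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "matrix"
  }
  rec <- if (format == "edf") read_edf(path) else read_recording_matrix(path)
  if (nrow(rec$signals) < 2) {
    abort("Recording must have at least 2 channels.",
          class = "alphamark_format")
  }
  rec
}
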