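## EEG recordings, event tables and the chunked replay stream.
##
## Recordings are plain channel x sample matrices of microvolt values with a
## sampling rate and ordered 10-20 montage labels. EDF/BDF support is written
## against the published format layout (256-byte fixed header, 256 bytes per
## signal, 16- or 24-bit little-endian samples); recordings are stored as a
## single data record so arbitrary durations round-trip without padding.

#' The 32-channel 10-20 montage used throughout the package
#'
#' Ordered channel labels of the wireless 32-channel cap the pipeline was
#' designed around (ear-referenced; reference electrodes are not stored).
#'
#' @return Character vector of 32 canonical upper-case 10-20 labels.
#' @export
montage_32 <- function() {
  c("FP1", "FP2", "AF3", "AF4", "F7", "F3", "FZ", "F4", "F8",
    "FT7", "FC3", "FCZ", "FC4", "FT8", "T7", "C3", "CZ", "C4", "T8",
    "TP7", "CP3", "CPZ", "CP4", "TP8", "P7", "P3", "PZ", "P4", "P8",
    "O1", "OZ", "O2")
}

## Legacy 10-20 aliases -> modern names.
.label_aliases <- c(T3 = "T7", T4 = "T8", T5 = "P7", T6 = "P8")

canonical_labels <- function(labels) {
  up <- toupper(trimws(labels))
  hit <- up %in% names(.label_aliases)
  up[hit] <- .label_aliases[up[hit]]
  up
}

#' Construct an EEG recording
#'
#' @param data Numeric matrix, channels x samples, in microvolts.
#' @param srate Sampling rate in Hz.
#' @param channels Ordered channel labels (10-20 names); upper-cased and
#'   mapped to canonical modern labels (T3 -> T7 etc.). Unknown labels are
#'   kept verbatim (upper-cased).
#' @param start_time Offset of the first sample in seconds (default 0).
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, srate, channels, start_time = 0) {
  data <- as.matrix(data)
  if (!is.numeric(data))
    stop_validation("recording data must be numeric")
  if (length(channels) != nrow(data))
    stop_validation("channel count (%d) does not match data rows (%d)",
                    length(channels), nrow(data))
  channels <- canonical_labels(channels)
  if (anyDuplicated(channels))
    stop_validation("duplicate channel labels: %s",
                    paste(unique(channels[duplicated(channels)]), collapse = ", "))
  if (!is.numeric(srate) || length(srate) != 1 || srate <= 0)
    stop_validation("srate must be a single positive number")
  if (any(!is.finite(data)))
    stop_validation("recording contains non-finite samples")
  rownames(data) <- channels
  structure(list(data = data, srate = srate, channels = channels,
                 start_time = start_time),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$srate, ncol(x$data) / x$srate))
  cat("  channels:", paste(x$channels, collapse = " "), "\n")
  invisible(x)
}

rec_duration <- function(rec) ncol(rec$data) / rec$srate

#' Extract a time slice of a recording
#'
#' Half-open interval `[from, to)` in seconds from recording start.
#'
#' @param rec An `eeg_recording`.
#' @param from,to Slice bounds in seconds.
#' @return An `eeg_recording` holding the slice; `start_time` is `from`.
#' @export
rec_slice <- function(rec, from, to) {
  n <- ncol(rec$data)
  i0 <- max(0L, as.integer(round(from * rec$srate)))
  i1 <- min(n, as.integer(round(to * rec$srate)))
  if (i1 <= i0)
    stop_contract("empty slice [%g, %g) of a %.1f s recording", from, to, n / rec$srate)
  eeg_recording(rec$data[, (i0 + 1L):i1, drop = FALSE], rec$srate,
                rec$channels, start_time = i0 / rec$srate)
}

## ---------------------------------------------------------------------------
## EDF / BDF

pad_field <- function(x, width) {
  s <- as.character(x)
  if (nchar(s) > width) s <- substr(s, 1, width)
  formatC(s, width = -width)
}

num_field <- function(x, width) {
  s <- formatC(x, format = "g", digits = 7, width = 1)
  if (nchar(s) > width) s <- formatC(x, format = "g", digits = 4, width = 1)
  pad_field(s, width)
}

write_edf_like <- function(rec, path, bits) {
  nchan <- length(rec$channels)
  nsamp <- ncol(rec$data)
  digmax <- if (bits == 16) 32767 else 8388607
  prange <- apply(abs(rec$data), 1, max)
  prange[prange == 0] <- 1
  prange <- signif(prange * 1.0001, 6)  # headroom so rounding never clips

  con <- tryCatch(file(path, "wb"), condition = function(e)
    stop_io("cannot open '%s' for writing: %s", path, conditionMessage(e)))
  on.exit(close(con))

  if (bits == 16) {
    writeBin(charToRaw(pad_field("0", 8)), con)
  } else {
    writeBin(as.raw(255), con)
    writeBin(charToRaw(pad_field("BIOSEMI", 7)), con)
  }
  writeChar(paste0(
    pad_field("X X X X", 80),                      # patient
    pad_field("Startdate X X X X", 80),            # recording
    pad_field("01.01.00", 8), pad_field("00.00.00", 8),
    pad_field(256 * (nchan + 1), 8),
    pad_field(if (bits == 16) "" else "24BIT", 44),
    pad_field(1, 8),                               # one data record
    num_field(nsamp / rec$srate, 8),
    pad_field(nchan, 4)), con, eos = NULL)
  writeChar(paste0(
    paste(vapply(rec$channels, pad_field, "", width = 16), collapse = ""),
    strrep(pad_field("", 80), nchan),
    strrep(pad_field("uV", 8), nchan),
    paste(vapply(-prange, num_field, "", width = 8), collapse = ""),
    paste(vapply(prange, num_field, "", width = 8), collapse = ""),
    strrep(pad_field(-digmax, 8), nchan),
    strrep(pad_field(digmax, 8), nchan),
    strrep(pad_field("", 80), nchan),
    strrep(pad_field(nsamp, 8), nchan),
    strrep(pad_field("", 32), nchan)), con, eos = NULL)

  ## Physical ranges as re-read from their 8-char ascii form, so that the
  ## round trip uses identical scaling.
  pmax_hdr <- as.numeric(vapply(prange, num_field, "", width = 8))
  for (ch in seq_len(nchan)) {
    dig <- as.integer(round(rec$data[ch, ] / pmax_hdr[ch] * digmax))
    dig <- as.integer(pmin(pmax(dig, -digmax), digmax))
    if (bits == 16) {
      writeBin(dig, con, size = 2, endian = "little")
    } else {
      u <- ifelse(dig < 0L, dig + 16777216L, dig)
      raw3 <- rbind(as.raw(u %% 256L),
                    as.raw((u %/% 256L) %% 256L),
                    as.raw(u %/% 65536L))
      writeBin(as.vector(raw3), con)
    }
  }
  invisible(NULL)
}

read_edf_like <- function(path, bits) {
  con <- tryCatch(file(path, "rb"), condition = function(e)
    stop_io("cannot open '%s': %s", path, conditionMessage(e)))
  on.exit(close(con))
  hdr <- readBin(con, "raw", 256)
  if (length(hdr) < 256) stop_validation("'%s' is not a valid EDF/BDF file (truncated header)", path)
  field <- function(raw, from, len) trimws(rawToChar(raw[from:(from + len - 1)]))
  n_records <- as.integer(field(hdr, 237, 8))
  record_s <- as.numeric(field(hdr, 245, 8))
  nchan <- as.integer(field(hdr, 253, 4))
  if (is.na(nchan) || nchan < 1)
    stop_validation("'%s' is not a valid EDF/BDF file", path)
  sh <- readBin(con, "raw", 256 * nchan)
  sig_field <- function(width, offset) {
    vapply(seq_len(nchan), function(i)
      field(sh, offset * nchan + (i - 1) * width + 1, width), "")
  }
  labels <- sig_field(16, 0)
  ## offsets in bytes within the signal header block, in field order
  pmin <- as.numeric(vapply(seq_len(nchan), function(i)
    field(sh, (16 + 80 + 8) * nchan + (i - 1) * 8 + 1, 8), ""))
  pmaxv <- as.numeric(vapply(seq_len(nchan), function(i)
    field(sh, (16 + 80 + 8 + 8) * nchan + (i - 1) * 8 + 1, 8), ""))
  dmin <- as.numeric(vapply(seq_len(nchan), function(i)
    field(sh, (16 + 80 + 8 + 8 + 8) * nchan + (i - 1) * 8 + 1, 8), ""))
  dmax <- as.numeric(vapply(seq_len(nchan), function(i)
    field(sh, (16 + 80 + 8 + 8 + 8 + 8) * nchan + (i - 1) * 8 + 1, 8), ""))
  spr <- as.integer(vapply(seq_len(nchan), function(i)
    field(sh, (16 + 80 + 8 + 8 + 8 + 8 + 8 + 80) * nchan + (i - 1) * 8 + 1, 8), ""))
  if (length(unique(spr)) != 1)
    stop_validation("mixed per-signal sampling rates in '%s' are not supported", path)

  nsamp_rec <- spr[1]
  out <- matrix(0, nchan, nsamp_rec * n_records)
  gain <- (pmaxv - pmin) / (dmax - dmin)
  for (r in seq_len(n_records)) {
    for (ch in seq_len(nchan)) {
      if (bits == 16) {
        dig <- readBin(con, "integer", nsamp_rec, size = 2, signed = TRUE,
                       endian = "little")
      } else {
        b <- as.integer(readBin(con, "raw", 3 * nsamp_rec))
        u <- b[c(TRUE, FALSE, FALSE)] + 256 * b[c(FALSE, TRUE, FALSE)] +
          65536 * b[c(FALSE, FALSE, TRUE)]
        dig <- ifelse(u >= 8388608, u - 16777216, u)
      }
      if (length(dig) < nsamp_rec)
        stop_validation("'%s' ends mid-record", path)
      out[ch, (r - 1) * nsamp_rec + seq_len(nsamp_rec)] <-
        (dig - dmin[ch]) * gain[ch] + pmin[ch]
    }
  }
  eeg_recording(out, srate = nsamp_rec / record_s, channels = labels)
}

## ---------------------------------------------------------------------------

#' Read an EEG recording
#'
#' Supported formats: 16-bit EDF, 24-bit BDF, and a fixed CSV dialect (header
#' row of channel labels, one sample per row, optional leading `time` column).
#'
#' @param path File path.
#' @param format One of `"edf"`, `"bdf"`, `"csv"`; default inferred from the
#'   file extension.
#' @param srate Sampling rate for CSV input, which carries none (default 500).
#' @return An [eeg_recording()].
#' @export
read_recording <- function(path, format = NULL, srate = 500) {
  if (!file.exists(path)) stop_io("file not found: %s", path)
  format <- tolower(format %||% tools::file_ext(path))
  switch(format,
    edf = read_edf_like(path, 16),
    bdf = read_edf_like(path, 24),
    csv = {
      df <- tryCatch(read.csv(path, check.names = FALSE),
                     condition = function(e)
                       stop_validation("cannot parse CSV '%s': %s", path,
                                       conditionMessage(e)))
      if (tolower(names(df)[1]) == "time") df <- df[, -1, drop = FALSE]
      eeg_recording(t(as.matrix(df)), srate = srate, channels = names(df))
    },
    stop_validation("unsupported recording format '%s'", format))
}

#' Write an EEG recording
#'
#' @param rec An [eeg_recording()].
#' @param path Output path.
#' @param format `"edf"`, `"bdf"` or `"csv"`; default from extension.
#'   EDF quantizes to 16 bits of the per-channel physical range, BDF to 24.
#' @return Invisibly, `path`.
#' @export
write_recording <- function(rec, path, format = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  format <- tolower(format %||% tools::file_ext(path))
  switch(format,
    edf = write_edf_like(rec, path, 16),
    bdf = write_edf_like(rec, path, 24),
    csv = {
      df <- as.data.frame(t(rec$data))
      names(df) <- rec$channels
      ok <- tryCatch({ write.csv(df, path, row.names = FALSE); TRUE },
                     condition = function(e) stop_io("cannot write '%s': %s",
                                                     path, conditionMessage(e)))
    },
    stop_validation("unsupported recording format '%s'", format))
  invisible(path)
}

## ---------------------------------------------------------------------------
## Event tables

event_kinds <- c("baseline_start", "session_start", "rest_start",
                 "cue", "target", "response")

#' Construct / validate an event table
#'
#' Columns: `onset_s` (seconds, non-decreasing), `kind` (one of
#' baseline_start, session_start, rest_start, cue, target, response),
#' `condition` (congruent / incongruent / no_target or `NA`), `direction`
#' (left / right / up / none or `NA`; target direction or key pressed),
#' `rt_ms` (non-negative or `NA`), `correct` (logical or `NA`).
#'
#' @param df Data frame with at least `onset_s` and `kind`.
#' @return The validated data frame with class `event_table`.
#' @export
event_table <- function(df) {
  need <- c("onset_s", "kind")
  if (!all(need %in% names(df)))
    stop_validation("event table requires columns: %s", paste(need, collapse = ", "))
  for (col in c("condition", "direction", "rt_ms", "correct"))
    if (is.null(df[[col]])) df[[col]] <- NA
  df <- df[, c("onset_s", "kind", "condition", "direction", "rt_ms", "correct")]
  df$onset_s <- as.numeric(df$onset_s)
  df$kind <- as.character(df$kind)
  df$condition <- as.character(df$condition)
  df$direction <- as.character(df$direction)
  df$rt_ms <- as.numeric(df$rt_ms)
  df$correct <- as.logical(df$correct)
  if (is.unsorted(df$onset_s))
    stop_validation("event onsets must be non-decreasing")
  if (!all(df$kind %in% event_kinds))
    stop_validation("unknown event kind(s): %s",
                    paste(setdiff(df$kind, event_kinds), collapse = ", "))
  if (any(df$rt_ms < 0, na.rm = TRUE))
    stop_validation("rt_ms must be non-negative")
  class(df) <- c("event_table", "data.frame")
  df
}

#' Read / write an event table as TSV
#'
#' Missing fields are written as empty strings and read back as `NA`.
#'
#' @param path TSV file path.
#' @return [event_table()] for `read_events`; invisibly `path` for
#'   `write_events`.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop_io("file not found: %s", path)
  df <- tryCatch(read.delim(path, na.strings = c("", "NA")),
                 condition = function(e)
                   stop_validation("cannot parse TSV '%s': %s", path,
                                   conditionMessage(e)))
  event_table(df)
}

#' @param events An [event_table()].
#' @rdname read_events
#' @export
write_events <- function(events, path) {
  events <- event_table(as.data.frame(events))
  tryCatch(write.table(events, path, sep = "\t", row.names = FALSE,
                       quote = FALSE, na = ""),
           condition = function(e) stop_io("cannot write '%s': %s", path,
                                           conditionMessage(e)))
  invisible(path)
}

## ---------------------------------------------------------------------------
## Replay stream

#' Replay a recording as a sequence of abutting chunks
#'
#' Emulates real-time acquisition at a fixed refresh rate: consecutive chunks
#' partition the recording exactly (`next t0 = previous t0 + duration`); the
#' final chunk may be short.
#'
#' @param rec An [eeg_recording()].
#' @param chunk_s Chunk duration in seconds (default 1, the display refresh).
#' @return List of chunks, each `list(data, t0, duration)`.
#' @export
replay <- function(rec, chunk_s = 1) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (chunk_s <= 0) stop_validation("chunk_s must be positive")
  n <- ncol(rec$data)
  step <- as.integer(round(chunk_s * rec$srate))
  if (step >= n) {
    if (step > n) warning("chunk_s exceeds recording duration; emitting one chunk")
    return(list(list(data = rec$data, t0 = rec$start_time, duration = n / rec$srate)))
  }
  starts <- seq(0L, n - 1L, by = step)
  lapply(starts, function(s) {
    e <- min(s + step, n)
    list(data = rec$data[, (s + 1L):e, drop = FALSE],
         t0 = rec$start_time + s / rec$srate,
         duration = (e - s) / rec$srate)
  })
}
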