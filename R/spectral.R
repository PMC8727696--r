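## Windowed FFT power spectral density, baseline subtraction and band
## decomposition. PSD is a one-sided Hann-tapered periodogram in uV^2/Hz,
## expressed in dB as 10*log10 with a floor for zero power; band power is the
## mean over the PSD bins whose center frequency falls inside the band
## (edges inclusive, so alpha 8-12 and mu 8-13 intentionally overlap at
## their shared bins).

#' Canonical EEG frequency bands
#'
#' delta 1-3, theta 4-7, alpha 8-12, beta 13-31, gamma 32-50 and the
#' sensorimotor mu rhythm 8-13 (all Hz, integer edges, both ends inclusive).
#'
#' @return Data frame with columns `band`, `low_hz`, `high_hz`.
#' @export
canonical_bands <- function() {
  data.frame(band = c("delta", "theta", "alpha", "beta", "gamma", "mu"),
             low_hz = c(1, 4, 8, 13, 32, 8),
             high_hz = c(3, 7, 12, 31, 50, 13))
}

#' Compute a one-sided power spectral density frame
#'
#' Hann-tapered periodogram of one analysis window, scaled so that the
#' integral of the linear PSD over frequency matches the window's mean power
#' (Parseval-consistent up to taper correction).
#'
#' @param window Channels x samples numeric matrix (microvolts).
#' @param srate Sampling rate in Hz.
#' @param t0 Window start time in seconds (carried through, default 0).
#' @param db_floor Lower bound applied to the dB values so that zero power
#'   stays finite (default -120 dB).
#' @return A `psd_frame`: list with `t0`, `freqs`, `psd_db`, `psd_linear`,
#'   `channels`, `srate`.
#' @export
compute_psd <- function(window, srate, t0 = 0, db_floor = -120) {
  window <- as.matrix(window)
  n <- ncol(window)
  if (n < srate)
    stop_contract("PSD window must be at least 1 s (%d samples), got %d",
                  as.integer(srate), n)
  k <- seq_len(n) - 1L
  taper <- 0.5 * (1 - cos(2 * pi * k / n))       # periodic Hann
  xw <- sweep(window, 2, taper, `*`)
  X <- t(stats::mvfft(t(xw)))
  nf <- floor(n / 2) + 1L
  p <- (Mod(X[, seq_len(nf), drop = FALSE])^2) / (srate * sum(taper^2))
  dbl <- rep(2, nf); dbl[1] <- 1
  if (n %% 2 == 0) dbl[nf] <- 1
  p <- sweep(p, 2, dbl, `*`)
  floor_lin <- 10^(db_floor / 10)
  db <- 10 * log10(pmax(p, floor_lin))
  structure(list(t0 = t0, freqs = (seq_len(nf) - 1L) * srate / n,
                 psd_db = db, psd_linear = 10^(db / 10),
                 channels = rownames(window), srate = srate),
            class = "psd_frame")
}

check_psd_match <- function(a, b) {
  if (!identical(dim(a$psd_db), dim(b$psd_db)) ||
      !isTRUE(all.equal(a$freqs, b$freqs)) ||
      !identical(a$channels, b$channels))
    stop_contract("PSD frames do not share frequencies/channels")
}

#' Subtract a baseline PSD (relative power in dB)
#'
#' Elementwise dB-domain difference; the linear field is recomputed from the
#' resulting dB values and is therefore a unitless power ratio.
#'
#' @param frame,baseline_psd `psd_frame`s on the same frequency grid and
#'   channel set.
#' @return A `psd_frame` of baseline-relative power.
#' @export
subtract_baseline <- function(frame, baseline_psd) {
  check_psd_match(frame, baseline_psd)
  db <- frame$psd_db - baseline_psd$psd_db
  frame$psd_db <- db
  frame$psd_linear <- 10^(db / 10)
  frame
}

#' Band-decompose a PSD frame
#'
#' Per band and channel, the mean of the dB PSD bins whose center lies in
#' `[low_hz, high_hz]` (inclusive); the linear value is `10^(dB/10)`.
#'
#' @param frame A `psd_frame`.
#' @param bands Band definition data frame as from [canonical_bands()].
#' @return A `band_power_frame` data frame with columns `t0`, `channel`,
#'   `band`, `power_db`, `power_linear`.
#' @export
band_power <- function(frame, bands = canonical_bands()) {
  out <- lapply(seq_len(nrow(bands)), function(i) {
    sel <- frame$freqs >= bands$low_hz[i] & frame$freqs <= bands$high_hz[i]
    if (!any(sel))
      stop_contract("band %s (%g-%g Hz) contains no frequency bins",
                    bands$band[i], bands$low_hz[i], bands$high_hz[i])
    db <- rowMeans(frame$psd_db[, sel, drop = FALSE])
    data.frame(t0 = frame$t0, channel = frame$channels, band = bands$band[i],
               power_db = db, power_linear = 10^(db / 10))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("band_power_frame", "data.frame")
  out
}

#' Average PSD over a baseline recording (Welch-style)
#'
#' Splits the recording into `window_s` windows stepped by `step_s` and
#' averages the per-window PSDs, in the dB domain by default (matching the
#' dB-domain baseline-subtraction pipeline) or in linear power.
#'
#' @param rec An [eeg_recording()] (the pre-task baseline).
#' @param window_s,step_s Window length and step in seconds (defaults 2, 1).
#' @param average `"db"` or `"linear"`.
#' @param db_floor Passed to [compute_psd()].
#' @return A `psd_frame` with `t0` set to the recording start.
#' @export
baseline_psd <- function(rec, window_s = 2, step_s = 1, average = c("db", "linear"),
                         db_floor = -120) {
  average <- match.arg(average)
  frames <- psd_windows(rec, window_s, step_s, db_floor)
  acc <- if (average == "db") Reduce(`+`, lapply(frames, `[[`, "psd_db"))
         else Reduce(`+`, lapply(frames, `[[`, "psd_linear"))
  acc <- acc / length(frames)
  out <- frames[[1]]
  out$t0 <- rec$start_time
  if (average == "db") out$psd_db <- acc else out$psd_db <- 10 * log10(pmax(acc, 10^(db_floor / 10)))
  out$psd_linear <- 10^(out$psd_db / 10)
  out
}

psd_windows <- function(rec, window_s, step_s, db_floor = -120) {
  n <- ncol(rec$data)
  L <- as.integer(round(window_s * rec$srate))
  H <- as.integer(round(step_s * rec$srate))
  if (L > n) stop_contract("recording (%.1f s) shorter than one %g s window",
                           n / rec$srate, window_s)
  starts <- seq(0L, n - L, by = H)
  lapply(starts, function(s)
    compute_psd(rec$data[, (s + 1L):(s + L), drop = FALSE], rec$srate,
                t0 = rec$start_time + s / rec$srate, db_floor = db_floor))
}

#' Sliding-window band powers over a recording
#'
#' Equivalent to [compute_psd()] then [subtract_baseline()] then
#' [band_power()] for every window on the step grid.
#'
#' @param rec An [eeg_recording()] (task period, already cleaned).
#' @param baseline A `psd_frame` from [baseline_psd()], or `NULL` to skip
#'   baseline subtraction.
#' @param window_s,step_s Analysis window and step in seconds (defaults 2, 1:
#'   1 Hz resolution at a 1-s refresh).
#' @param bands Band definitions (default [canonical_bands()]).
#' @param db_floor dB floor for zero power.
#' @return A `band_power_ts` data frame (columns as [band_power()]) with one
#'   frame per window start.
#' @export
sliding_band_power <- function(rec, baseline = NULL, window_s = 2, step_s = 1,
                               bands = canonical_bands(), db_floor = -120) {
  if (step_s > window_s) stop_validation("step_s must not exceed window_s")
  frames <- psd_windows(rec, window_s, step_s, db_floor)
  out <- do.call(rbind, lapply(frames, function(f) {
    if (!is.null(baseline)) f <- subtract_baseline(f, baseline)
    band_power(f, bands)
  }))
  rownames(out) <- NULL
  class(out) <- c("band_power_ts", "data.frame")
  out
}

#' Write a band-power time series to tidy CSV
#'
#' @param bp A `band_power_ts` / `band_power_frame` data frame.
#' @param path Output CSV path.
#' @export
write_band_power <- function(bp, path) {
  tryCatch(write.csv(as.data.frame(bp), path, row.names = FALSE),
           condition = function(e) stop_io("cannot write '%s': %s", path,
                                           conditionMessage(e)))
  invisible(path)
}
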