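## Bandpass filtering and artifact subspace reconstruction (ASR).
##
## ASR here follows the classic three-step scheme: (1) a clean pre-task
## baseline is decomposed into orthogonal components via the eigenvectors of
## its channel covariance; (2) per-component rejection thresholds are set
## from robust statistics (median + cutoff_k * scaled MAD) of windowed
## component RMS values on that baseline; (3) incoming data are processed in
## short overlapping windows, components whose windowed RMS exceeds their
## threshold are removed, and the signal is reconstructed from the retained
## calibration subspace with raised-cosine overlap-add blending. Windows
## with no exceedance pass through unchanged, so clean data are (up to
## blending at the edges) untouched.

#' Bandpass filter specification
#'
#' @param low_hz,high_hz Band edges in Hz (defaults 1 and 50, the pipeline's
#'   preliminary artifact-removal band, which also excludes mains frequency).
#' @param order Butterworth design order (default 6; the realized bandpass
#'   has twice as many poles, applied forward-backward for zero phase).
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(low_hz = 1, high_hz = 50, order = 6) {
  if (!(low_hz > 0 && low_hz < high_hz))
    stop_validation("need 0 < low_hz < high_hz")
  structure(list(low_hz = low_hz, high_hz = high_hz, order = order,
                 kind = "bandpass"), class = "filter_spec")
}

#' Bandpass-filter a recording
#'
#' Zero-phase (forward-backward) Butterworth filtering by default, which
#' preserves event alignment; a causal single-pass variant is available for
#' strictly-streaming use at the cost of group delay and a shallower
#' effective rolloff.
#'
#' @param rec An [eeg_recording()].
#' @param spec A [filter_spec()].
#' @param zero_phase Apply forward-backward (default `TRUE`).
#' @return The filtered [eeg_recording()].
#' @export
bandpass <- function(rec, spec = filter_spec(), zero_phase = TRUE) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$srate / 2
  if (spec$high_hz >= nyq)
    stop_validation("high edge %g Hz reaches Nyquist (%g Hz)", spec$high_hz, nyq)
  bf <- signal::butter(spec$order, c(spec$low_hz, spec$high_hz) / nyq,
                       type = "pass")
  out <- rec$data
  for (ch in seq_len(nrow(out))) {
    out[ch, ] <- if (zero_phase) signal::filtfilt(bf, rec$data[ch, ])
                 else signal::filter(bf, rec$data[ch, ])
  }
  eeg_recording(out, rec$srate, rec$channels, rec$start_time)
}

## ---------------------------------------------------------------------------
## ASR

#' Calibrate artifact subspace reconstruction on a clean baseline
#'
#' Decomposes the baseline channel covariance and derives per-component
#' rejection thresholds as `median + cutoff_k * 1.4826 * MAD` of the
#' windowed component RMS values. Robust statistics keep the thresholds
#' stable even if the baseline itself contains small artifacts.
#'
#' @param rec An [eeg_recording()], the pre-task baseline (>= 10 windows).
#' @param window_s Sliding-window length in seconds (default 0.5).
#' @param cutoff_k Threshold multiplier on the robust spread (default 20, a
#'   conservative value within published practice of roughly 10-30).
#' @param overlap Fractional window overlap (default 0.5).
#' @return An `asr_calibration` with the mixing matrix (eigenvectors,
#'   channels x components), thresholds, and parameters.
#' @export
asr_calibrate <- function(rec, window_s = 0.5, cutoff_k = 20, overlap = 0.5) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (cutoff_k <= 0) stop_validation("cutoff_k must be positive")
  L <- as.integer(round(window_s * rec$srate))
  if (ncol(rec$data) < 10L * L)
    stop_contract("baseline (%.1f s) shorter than 10 calibration windows (%g s)",
                  ncol(rec$data) / rec$srate, 10 * window_s)
  x <- rec$data - rowMeans(rec$data)
  C <- tcrossprod(x) / (ncol(x) - 1)
  eg <- eigen(C, symmetric = TRUE)
  if (min(eg$values) < 1e-10 * max(eg$values)) {
    v <- apply(x, 1, var)
    bad <- rec$channels[v < 1e-12 * max(v)]
    if (length(bad) == 0) {
      cc <- abs(stats::cor(t(x)))
      diag(cc) <- 0
      hit <- which(cc > 1 - 1e-6, arr.ind = TRUE)
      bad <- unique(rec$channels[as.vector(hit)])
    }
    stop_validation("rank-deficient baseline covariance (offending channels: %s)",
                    paste(if (length(bad)) bad else "unknown", collapse = ", "))
  }
  V <- eg$vectors
  H <- max(1L, as.integer(round(L * (1 - overlap))))
  starts <- seq(0L, ncol(x) - L, by = H)
  rms <- vapply(starts, function(s) {
    sc <- crossprod(V, x[, (s + 1L):(s + L), drop = FALSE])
    sqrt(rowMeans(sc^2))
  }, numeric(nrow(x)))
  med <- apply(rms, 1, median)
  spread <- apply(rms, 1, mad)                   # 1.4826 * MAD
  thr <- med + cutoff_k * pmax(spread, 0.01 * med)
  structure(list(mixing = V, component_thresholds = thr, window_s = window_s,
                 cutoff_k = cutoff_k, overlap = overlap,
                 channels = rec$channels, srate = rec$srate),
            class = "asr_calibration")
}

#' @export
print.asr_calibration <- function(x, ...) {
  cat(sprintf("<asr_calibration> %d channels, window %g s, cutoff_k %g\n",
              length(x$channels), x$window_s, x$cutoff_k))
  cat(sprintf("  component RMS thresholds: %.3g .. %.3g uV\n",
              min(x$component_thresholds), max(x$component_thresholds)))
  invisible(x)
}

## Streaming ASR state. Windows live on a fixed global sample grid
## (starts at multiples of the hop), so chunked and whole-recording
## processing produce identical output by construction.
asr_stream_init <- function(calib) {
  L <- as.integer(round(calib$window_s * calib$srate))
  H <- max(1L, as.integer(round(L * (1 - calib$overlap))))
  k <- seq_len(L) - 1L
  env <- new.env(parent = emptyenv())
  env$calib <- calib
  env$L <- L
  env$H <- H
  env$w <- 0.5 * (1 - cos(2 * pi * (k + 0.5) / L))  # raised cosine, > 0
  env$buf <- matrix(0, length(calib$channels), 0)   # raw samples not yet fully covered
  env$num <- matrix(0, length(calib$channels), 0)   # weighted cleaned accumulator
  env$den <- numeric(0)
  env$next_win <- 0L          # absolute sample index of next window start
  env$base <- 0L              # absolute index of buf[,1]
  env$mask <- list()
  env
}

asr_stream_push <- function(state, block) {
  nch <- nrow(state$buf)
  state$buf <- cbind(state$buf, block)
  state$num <- cbind(state$num, matrix(0, nch, ncol(block)))
  state$den <- c(state$den, numeric(ncol(block)))
  V <- state$calib$mixing
  thr <- state$calib$component_thresholds
  n_abs <- state$base + ncol(state$buf)
  while (state$next_win + state$L <= n_abs) {
    i0 <- state$next_win - state$base          # 0-based within buffer
    idx <- (i0 + 1L):(i0 + state$L)
    xw <- state$buf[, idx, drop = FALSE]
    sc <- crossprod(V, xw)
    rms <- sqrt(rowMeans(sc^2))
    flag <- rms > thr
    yw <- if (any(flag)) { sc[flag, ] <- 0; V %*% sc } else xw
    state$num[, idx] <- state$num[, idx] + sweep(yw, 2, state$w, `*`)
    state$den[idx] <- state$den[idx] + state$w
    state$mask[[length(state$mask) + 1L]] <-
      list(start = state$next_win, n_rejected = sum(flag))
    state$next_win <- state$next_win + state$H
  }
  ## samples before the next window start are final
  emit_n <- max(0L, state$next_win - state$base)
  asr_stream_take(state, emit_n)
}

asr_stream_take <- function(state, emit_n) {
  if (emit_n == 0L) return(state$buf[, 0, drop = FALSE])
  idx <- seq_len(emit_n)
  cov <- state$den[idx] > 0
  out <- state$buf[, idx, drop = FALSE]
  out[, cov] <- sweep(state$num[, idx, drop = FALSE][, cov, drop = FALSE],
                      2, state$den[idx][cov], `/`)
  state$buf <- state$buf[, -idx, drop = FALSE]
  state$num <- state$num[, -idx, drop = FALSE]
  state$den <- state$den[-idx]
  state$base <- state$base + emit_n
  out
}

asr_stream_flush <- function(state) {
  asr_stream_take(state, ncol(state$buf))
}

#' Apply artifact subspace reconstruction
#'
#' Sliding overlapping windows are projected onto the calibration
#' components; any component whose windowed RMS exceeds its threshold is
#' removed and the window is reconstructed from the retained subspace, then
#' blended back by raised-cosine overlap-add. Removal can only shrink power
#' in the orthonormal component basis, so cleaning never increases a
#' window's total power.
#'
#' @param x An [eeg_recording()], or a channels x samples matrix.
#' @param calib An [asr_calibrate()] result; the channel set must match.
#' @return `list(data, mask)`: the cleaned object of the same shape, and a
#'   data frame (`t0` seconds, `n_rejected`) with one row per window in
#'   which at least one component was rejected.
## Whole-matrix core: identical windows, weights and tail handling as the
## streaming core, but with local accumulators (no per-window copies).
asr_core <- function(mat, calib) {
  L <- as.integer(round(calib$window_s * calib$srate))
  H <- max(1L, as.integer(round(L * (1 - calib$overlap))))
  k <- seq_len(L) - 1L
  w <- 0.5 * (1 - cos(2 * pi * (k + 0.5) / L))
  n <- ncol(mat)
  V <- calib$mixing
  thr <- calib$component_thresholds
  num <- matrix(0, nrow(mat), n)
  den <- numeric(n)
  starts <- if (n >= L) seq(0L, n - L, by = H) else integer(0)
  rejected <- integer(length(starts))
  for (j in seq_along(starts)) {
    idx <- (starts[j] + 1L):(starts[j] + L)
    xw <- mat[, idx, drop = FALSE]
    sc <- crossprod(V, xw)
    flag <- sqrt(rowMeans(sc^2)) > thr
    yw <- if (any(flag)) { sc[flag, ] <- 0; V %*% sc } else xw
    num[, idx] <- num[, idx] + yw * rep(w, each = nrow(mat))
    den[idx] <- den[idx] + w
    rejected[j] <- sum(flag)
  }
  out <- mat
  cov <- den > 0
  out[, cov] <- sweep(num[, cov, drop = FALSE], 2, den[cov], `/`)
  list(data = out, starts = starts, rejected = rejected)
}

#' @export
asr_process <- function(x, calib) {
  stopifnot(inherits(calib, "asr_calibration"))
  is_rec <- inherits(x, "eeg_recording")
  mat <- if (is_rec) x$data else as.matrix(x)
  chans <- if (is_rec) x$channels else rownames(mat)
  if (!is.null(chans) && !identical(canonical_labels(chans), calib$channels))
    stop_contract("channel set does not match ASR calibration (%s)",
                  paste(calib$channels, collapse = ", "))
  if (nrow(mat) != length(calib$channels))
    stop_contract("expected %d channels, got %d", length(calib$channels), nrow(mat))
  res <- asr_core(mat, calib)
  out <- res$data
  t_off <- if (is_rec) x$start_time else 0
  hit <- res$rejected > 0
  mask <- data.frame(t0 = t_off + res$starts[hit] / calib$srate,
                     n_rejected = as.numeric(res$rejected[hit]))
  if (is_rec) {
    out <- eeg_recording(out, x$srate, x$channels, x$start_time)
  } else rownames(out) <- rownames(mat)
  list(data = out, mask = mask)
}

## ---------------------------------------------------------------------------
## Calibration serialization (JSON, matrix row-major)

#' Save / load an ASR calibration as JSON
#'
#' @param calib An `asr_calibration`.
#' @param path JSON file path.
#' @return `asr_save` returns `path` invisibly; `asr_load` the calibration.
#' @export
asr_save <- function(calib, path) {
  obj <- list(channels = calib$channels, srate = calib$srate,
              window_s = calib$window_s, cutoff_k = calib$cutoff_k,
              overlap = calib$overlap,
              component_thresholds = calib$component_thresholds,
              mixing_row_major = as.vector(t(calib$mixing)))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname asr_save
#' @export
asr_load <- function(path) {
  if (!file.exists(path)) stop_io("file not found: %s", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  n <- length(obj$channels)
  structure(list(mixing = matrix(obj$mixing_row_major, n, n, byrow = TRUE),
                 component_thresholds = obj$component_thresholds,
                 window_s = obj$window_s, cutoff_k = obj$cutoff_k,
                 overlap = obj$overlap, channels = obj$channels,
                 srate = obj$srate),
            class = "asr_calibration")
}
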