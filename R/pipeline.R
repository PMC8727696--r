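## End-to-end processing: baseline -> ASR calibration + baseline PSD, task
## -> cleaned sliding band powers -> state levels, one per refresh step.

#' Process a recording into state levels
#'
#' Mirrors the online flow: the first `baseline_s` seconds calibrate ASR
#' and provide the baseline PSD; the remainder is cleaned, decomposed into
#' sliding-window band powers (2-s window, 1-s step by default) relative to
#' baseline, and mapped through the norms onto the 0-10 scale — one state
#' vector per step.
#'
#' In `"stream"` mode the task period is replayed in `chunk_s` chunks
#' through the streaming ASR core, emulating real-time acquisition; ASR
#' windows live on a fixed global grid, so chunked and whole-recording
#' cleaning agree up to numerical noise.
#'
#' @param rec An [eeg_recording()] (raw).
#' @param norms A [fit_norms()] result, or `NULL` to stop after band powers.
#' @param config A [run_config()].
#' @param mode `"offline"` (whole recording) or `"stream"` (chunked replay).
#' @return List: `states` (`state_ts`, or `NULL` without norms),
#'   `band_powers` (`band_power_ts`), `mask` (ASR rejections), `calib`,
#'   `baseline` (the baseline `psd_frame`).
#' @export
process_recording <- function(rec, norms = NULL, config = run_config(),
                              mode = c("offline", "stream")) {
  mode <- match.arg(mode)
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec_duration(rec) <= config$baseline_s)
    stop_contract("recording (%.1f s) no longer than the %g s baseline",
                  rec_duration(rec), config$baseline_s)
  fs <- filter_spec(config$filter$low_hz, config$filter$high_hz,
                    config$filter$order)
  rec_f <- bandpass(rec, fs)
  base <- rec_slice(rec_f, 0, config$baseline_s)
  base$start_time <- 0
  calib <- asr_calibrate(base, window_s = config$asr$window_s,
                         cutoff_k = config$asr$cutoff_k,
                         overlap = config$asr$overlap)
  base_clean <- asr_process(base, calib)$data
  bpsd <- baseline_psd(base_clean, window_s = config$psd$window_s,
                       step_s = config$psd$step_s,
                       average = config$psd$average,
                       db_floor = config$psd$db_floor)
  task <- rec_slice(rec_f, config$baseline_s, rec_duration(rec_f))

  if (mode == "offline") {
    cl <- asr_process(task, calib)
    cleaned <- cl$data
    mask <- cl$mask
  } else {
    st <- asr_stream_init(calib)
    parts <- lapply(replay(task, config$chunk_s), function(ch)
      asr_stream_push(st, ch$data))
    parts[[length(parts) + 1]] <- asr_stream_flush(st)
    cleaned <- eeg_recording(do.call(cbind, parts), task$srate, task$channels,
                             task$start_time)
    masks <- Filter(function(m) m$n_rejected > 0, st$mask)
    mask <- data.frame(
      t0 = task$start_time + vapply(masks, `[[`, 0, "start") / calib$srate,
      n_rejected = vapply(masks, function(m) as.numeric(m$n_rejected), 0))
  }

  bp <- sliding_band_power(cleaned, bpsd, window_s = config$psd$window_s,
                           step_s = config$psd$step_s,
                           db_floor = config$psd$db_floor)
  states <- if (!is.null(norms)) compute_states(bp, norms) else NULL
  list(states = states, band_powers = bp, mask = mask, calib = calib,
       baseline = bpsd)
}

#' Per-period mean state levels
#'
#' Averages each parameter within the session and rest periods delimited by
#' the event table's `session_start` / `rest_start` markers.
#'
#' @param states A `state_ts` data frame.
#' @param events The paradigm [event_table()].
#' @param skip_s Seconds skipped at the start of each period (e.g. 120 to
#'   drop carry-over at rest onset; default 0).
#' @return Data frame: `period`, `kind`, `t_start`, `t_end`, and the mean
#'   of each of the five parameters.
#' @export
summarize_states <- function(states, events, skip_s = 0) {
  marks <- events[events$kind %in% c("session_start", "rest_start"), ]
  if (nrow(marks) == 0) stop_contract("no session/rest markers in events")
  ends <- c(marks$onset_s[-1], max(states$t0) + 1)
  counts <- list(session = 0, rest = 0)
  out <- lapply(seq_len(nrow(marks)), function(i) {
    kind <- sub("_start$", "", marks$kind[i])
    counts[[kind]] <<- counts[[kind]] + 1
    sel <- states$t0 >= marks$onset_s[i] + skip_s & states$t0 < ends[i]
    m <- colMeans(states[sel, c("attention", "fatigue", "stress", "left",
                                "right"), drop = FALSE])
    cbind(data.frame(period = paste0(kind, counts[[kind]]), kind = kind,
                     t_start = marks$onset_s[i], t_end = ends[i]),
          as.data.frame(as.list(m)))
  })
  do.call(rbind, out)
}
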