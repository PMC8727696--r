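## Synthetic EEG: montage-correct recordings built from amplitude-scheduled
## band-limited sinusoids with random phases, per-channel 1/f (pink)
## background noise, and transient blink/EMG artifacts. This is the test bed
## for every other module: programmed band powers are recoverable by the
## spectral pipeline, and named scenarios program the monotone state trends
## the indicator is expected to track.

#' A sinusoidal component of a synthetic recording
#'
#' @param channel Channel label.
#' @param freq_hz Center frequency in Hz.
#' @param amp_uv Amplitude in microvolts (so mean-square power amp^2/2).
#' @param envelope Optional amplitude schedule: data frame (`time`, `gain`)
#'   interpolated piecewise-linearly over the recording; `NULL` = constant 1.
#' @param mod_depth Depth of slow random amplitude modulation (waxing and
#'   waning, ~0.25 Hz), as a fraction of the amplitude; 0 = perfectly
#'   stationary oscillation (default).
#' @return A `synth_component` list.
#' @export
synth_component <- function(channel, freq_hz, amp_uv, envelope = NULL,
                            mod_depth = 0) {
  if (amp_uv < 0) stop_validation("component amplitude must be >= 0")
  if (mod_depth < 0) stop_validation("mod_depth must be >= 0")
  structure(list(channel = toupper(channel), freq_hz = freq_hz,
                 amp_uv = amp_uv, envelope = envelope, mod_depth = mod_depth),
            class = "synth_component")
}

## Smooth unit-variance modulation signal: white noise on a 2 Hz grid,
## linearly interpolated (spectral content ~< 1 Hz).
slow_modulation <- function(t, duration_s) {
  grid <- seq(0, duration_s + 1, by = 0.5)
  z <- rnorm(length(grid))
  stats::approx(grid, z, xout = t, rule = 2)$y
}

#' Synthetic-recording specification
#'
#' @param channels Channel labels (10-20 names).
#' @param duration_s Recording length in seconds.
#' @param srate Sampling rate in Hz (default 500).
#' @param components List of [synth_component()]s.
#' @param noise_rms_uv Per-channel pink-noise RMS in microvolts (default 2).
#' @param artifacts List of artifact events: `list(kind = "blink"|"emg",
#'   onset_s, duration_s, amplitude_uv)`.
#' @param seed Integer seed; fixes the output exactly.
#' @return A `synth_spec` list.
#' @export
synth_spec <- function(channels, duration_s, srate = 500, components = list(),
                       noise_rms_uv = 2, artifacts = list(), seed = NULL) {
  channels <- canonical_labels(channels)
  for (cmp in components) {
    if (!cmp$channel %in% channels)
      stop_validation("component channel %s not in montage", cmp$channel)
    if (!is.null(cmp$envelope)) {
      if (min(cmp$envelope$time) < 0 || max(cmp$envelope$time) > duration_s)
        stop_validation("envelope schedule extends outside [0, %g] s", duration_s)
      if (any(cmp$envelope$gain < 0))
        stop_validation("envelope gains must be >= 0")
    }
  }
  for (a in artifacts)
    if (a$onset_s < 0 || a$onset_s + a$duration_s > duration_s)
      stop_validation("artifact at %g s extends outside the recording", a$onset_s)
  structure(list(channels = channels, duration_s = duration_s, srate = srate,
                 components = components, noise_rms_uv = noise_rms_uv,
                 artifacts = artifacts, seed = seed),
            class = "synth_spec")
}

## 1/f-amplitude noise via spectrally shaped white noise, unit RMS.
pink_noise <- function(n) {
  w <- rnorm(n)
  W <- fft(w)
  f <- c(1, seq_len(n - 1))          # guard DC
  f <- pmin(f, n - f + 1)            # mirror for the negative frequencies
  W <- W / sqrt(f)
  x <- Re(fft(W, inverse = TRUE)) / n
  x / sqrt(mean(x^2))
}

blink_weights <- function(channels) {
  w <- numeric(length(channels))
  w[channels %in% c("FP1", "FP2", "AF3", "AF4")] <- 1
  w[channels %in% c("F7", "F3", "FZ", "F4", "F8")] <- 0.5
  w
}

emg_weights <- function(channels) {
  w <- numeric(length(channels))
  w[channels %in% c("FT7", "FT8", "T7", "T8", "TP7", "TP8")] <- 1
  w
}

#' Generate a synthetic EEG recording
#'
#' Sum of amplitude-scheduled sinusoids with per-component random phases,
#' plus per-channel-independent pink noise and any artifact transients
#' (blink: 0.3-s half-cosine bump, frontally weighted; EMG: 20-45 Hz
#' Gaussian-envelope burst, temporally weighted). Bit-reproducible for a
#' fixed spec seed.
#'
#' @param spec A [synth_spec()].
#' @return An [eeg_recording()].
#' @export
synth_generate <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  with_seed(spec$seed, {
    n <- as.integer(round(spec$duration_s * spec$srate))
    t <- (seq_len(n) - 1L) / spec$srate
    x <- matrix(0, length(spec$channels), n, dimnames = list(spec$channels, NULL))
    for (cmp in spec$components) {
      phase <- runif(1, 0, 2 * pi)
      g <- if (is.null(cmp$envelope)) 1
           else stats::approx(cmp$envelope$time, cmp$envelope$gain, xout = t,
                              rule = 2)$y
      if ((cmp$mod_depth %||% 0) > 0)
        g <- g * pmax(0, 1 + cmp$mod_depth * slow_modulation(t, spec$duration_s))
      x[cmp$channel, ] <- x[cmp$channel, ] +
        cmp$amp_uv * g * sin(2 * pi * cmp$freq_hz * t + phase)
    }
    if (spec$noise_rms_uv > 0)
      for (ch in seq_len(nrow(x)))
        x[ch, ] <- x[ch, ] + spec$noise_rms_uv * pink_noise(n)
    for (a in spec$artifacts) {
      i0 <- as.integer(round(a$onset_s * spec$srate))
      len <- as.integer(round(a$duration_s * spec$srate))
      idx <- (i0 + 1L):min(i0 + len, n)
      u <- (seq_along(idx) - 0.5) / len
      if (a$kind == "blink") {
        shape <- sin(pi * u)                       # half-cosine bump
        x[, idx] <- x[, idx] + blink_weights(spec$channels) %o%
          (a$amplitude_uv * shape)
      } else if (a$kind == "emg") {
        burst <- rnorm(length(idx))
        bf <- signal::butter(4, c(20, 45) / (spec$srate / 2), type = "pass")
        burst <- signal::filtfilt(bf, burst)
        burst <- burst / max(sd(burst), 1e-12)
        env <- exp(-0.5 * ((u - 0.5) / 0.18)^2)    # Gaussian envelope
        x[, idx] <- x[, idx] + emg_weights(spec$channels) %o%
          (a$amplitude_uv * env * burst)
      } else stop_validation("unknown artifact kind '%s'", a$kind)
    }
    eeg_recording(x, spec$srate, spec$channels)
  })
}

## ---------------------------------------------------------------------------
## Standard resting spec and cohorts

#' Resting-state base specification
#'
#' Amplitudes typical of relaxed adult EEG: occipital alpha dominant,
#' moderate frontal theta/alpha, central mu, low occipital beta, pink
#' background noise.
#'
#' @param channels Montage (default the nine ROI channels the indicator
#'   reads: F3/Fz/F4, C3/Cz/C4, O1/Oz/O2).
#' @param duration_s Length in seconds (default 90: a 30-s baseline plus
#'   60 s of task for cohort calibration).
#' @param srate Sampling rate (default 500).
#' @param noise_rms_uv Pink-noise RMS (default 3).
#' @param mod_depth Slow amplitude-modulation depth of every oscillation
#'   (default 0.4), emulating physiological waxing and waning; without it
#'   the baseline would look unrealistically stationary and artifact
#'   rejection would be calibrated far too tightly.
#' @param seed Seed.
#' @return A [synth_spec()].
#' @export
base_synth_spec <- function(channels = c("F3", "FZ", "F4", "C3", "CZ", "C4",
                                         "O1", "OZ", "O2"),
                            duration_s = 90, srate = 500, noise_rms_uv = 3,
                            mod_depth = 0.4, seed = NULL) {
  channels <- canonical_labels(channels)
  comp <- list()
  add <- function(chs, f, a) for (ch in intersect(chs, channels))
    comp[[length(comp) + 1]] <<- synth_component(ch, f, a, mod_depth = mod_depth)
  add(c("F3", "FZ", "F4"), 6, 4)      # frontal theta
  add(c("F3", "FZ", "F4"), 10, 5)     # frontal alpha
  add(c("C3", "CZ", "C4"), 10.5, 6)   # central mu
  add(c("O1", "OZ", "O2"), 6, 3)      # occipital theta
  add(c("O1", "OZ", "O2"), 10, 10)    # occipital alpha
  add(c("O1", "OZ", "O2"), 20, 2)     # occipital beta
  synth_spec(channels, duration_s, srate, comp, noise_rms_uv, seed = seed)
}

#' Generate a calibration cohort
#'
#' Each subject's recording starts with `baseline_s` seconds at the base
#' amplitudes and continues with a task segment whose component amplitudes
#' are drawn Gaussian around `task_gain` times the base (independently per
#' component), so baseline-subtracted task powers vary across subjects.
#' With `between_subject_sd = 0` every subject is generated from the same
#' seed and the cohort is a single subject repeated — [fit_norms()] then
#' raises its degenerate-cohort error.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param base_spec A [synth_spec()]; its `duration_s` covers baseline+task.
#' @param between_subject_sd SD of the per-component amplitude gain.
#' @param seed Integer seed for the whole cohort.
#' @param baseline_s Baseline length in seconds (default 30).
#' @param task_gain Mean task/baseline amplitude gain (default 1.2).
#' @return List of [eeg_recording()]s.
#' @export
make_cohort <- function(n_subjects, base_spec = base_synth_spec(),
                        between_subject_sd = 0.25, seed = NULL,
                        baseline_s = 30, task_gain = 1.2) {
  if (n_subjects < 2) stop_validation(">=2 subjects required")
  if (between_subject_sd < 0) stop_validation("between_subject_sd must be >= 0")
  seeds <- if (between_subject_sd == 0) rep(seed %||% 0, n_subjects)
           else (seed %||% 0) + seq_len(n_subjects) * 1009L
  lapply(seq_len(n_subjects), function(s) {
    comp <- with_seed(seeds[s] + 1L, lapply(base_spec$components, function(cmp) {
      g <- max(0, rnorm(1, task_gain, between_subject_sd))
      cmp$envelope <- data.frame(
        time = c(0, baseline_s, baseline_s + 0.5, base_spec$duration_s),
        gain = c(1, 1, g, g))
      cmp
    }))
    sp <- base_spec
    sp$components <- comp
    sp$seed <- seeds[s]
    synth_generate(sp)
  })
}

## ---------------------------------------------------------------------------
## Named scenarios

scenario_names <- c("attention_decay", "fatigue_buildup",
                    "stress_habituation", "mi_lateralization")

## Per-period gains for the scenario's driven components.
scenario_gains <- function(name, n_pairs) {
  i <- seq_len(n_pairs)
  switch(name,
    attention_decay = list(target = "session", parameter = "attention",
                           gains = 1.15 + 0.35 * (i - 1), direction = -1),
    fatigue_buildup = list(target = "rest", parameter = "fatigue",
                           gains = {
                             g <- 1.1 + 0.45 * (i - 1)
                             if (n_pairs >= 4) g[n_pairs] <- g[max(1, n_pairs - 2)]
                             g
                           }, direction = +1),
    stress_habituation = list(target = "session", parameter = "stress",
                              gains = 1 + 0.3 * (i - 1), direction = -1),
    mi_lateralization = list(target = "session", parameter = "right",
                             gains = rep(1.6, n_pairs), direction = +1),
    stop_validation("unknown scenario '%s' (expected one of %s)", name,
                    paste(scenario_names, collapse = ", ")))
}

#' Build a named validation scenario
#'
#' Generates a paradigm-aligned recording whose programmed band-amplitude
#' trajectory follows a named trend, together with the trial schedule:
#'
#' * `attention_decay`: frontal theta+alpha amplitude rises across sessions,
#'   so the estimated attention level falls monotonically.
#' * `fatigue_buildup`: occipital broadband rises across rests 1-3 and
#'   drops in rest 4.
#' * `stress_habituation`: F4 alpha rises relative to F3 across sessions
#'   (growing positive asymmetry), so stress falls.
#' * `mi_lateralization`: C3 mu is elevated during sessions (right-hand
#'   responding), raising the right-activity level in sessions vs rests.
#'
#' @param name Scenario name.
#' @param paradigm A [paradigm_spec()] defining period boundaries.
#' @param seed Integer seed (schedule and signal).
#' @param channels,srate,noise_rms_uv Passed to [base_synth_spec()].
#' @return List: `recording`, `events`, `programmed` (per-period data frame
#'   with the driven parameter's programmed gain and expected direction),
#'   `paradigm`, `name`.
#' @export
make_scenario <- function(name, paradigm = paradigm_spec(), seed = NULL,
                          channels = c("F3", "FZ", "F4", "C3", "CZ", "C4",
                                       "O1", "OZ", "O2"),
                          srate = 500, noise_rms_uv = 3) {
  sc <- scenario_gains(name, paradigm$n_pairs)
  events <- generate_schedule(paradigm, seed = seed)
  total_s <- paradigm$baseline_s +
    paradigm$n_pairs * 60 * (paradigm$session_min + paradigm$rest_min)
  base <- base_synth_spec(channels, duration_s = total_s, srate = srate,
                          noise_rms_uv = noise_rms_uv, seed = seed)

  driven <- switch(name,
    attention_decay = expand.grid(channel = c("F3", "FZ", "F4"), freq = c(6, 10)),
    fatigue_buildup = expand.grid(channel = c("O1", "OZ", "O2"),
                                  freq = c(6, 10, 20)),
    stress_habituation = data.frame(channel = "F4", freq = 10),
    mi_lateralization = data.frame(channel = "C3", freq = 10.5))

  ## Period table: session i and rest i bounds.
  sess_on <- events$onset_s[events$kind == "session_start"]
  rest_on <- events$onset_s[events$kind == "rest_start"]
  periods <- data.frame(
    period = c(paste0("session", seq_along(sess_on)),
               paste0("rest", seq_along(rest_on))),
    kind = rep(c("session", "rest"), times = c(length(sess_on), length(rest_on))),
    t_start = c(sess_on, rest_on),
    t_end = c(rest_on, rest_on + paradigm$rest_min * 60))
  periods <- periods[order(periods$t_start), ]

  ## Envelope: gain g_i inside driven periods, 1 elsewhere (0.5-s ramps).
  env_t <- 0; env_g <- 1
  for (i in seq_len(paradigm$n_pairs)) {
    p <- periods[periods$kind == sc$target, ][i, ]
    env_t <- c(env_t, p$t_start, p$t_start + 0.5, p$t_end - 0.5, p$t_end)
    env_g <- c(env_g, 1, sc$gains[i], sc$gains[i], 1)
  }
  env_t <- c(env_t, total_s); env_g <- c(env_g, 1)
  env <- data.frame(time = env_t, gain = env_g)
  ## straighten any overlap introduced by ramps at shared boundaries
  keep <- !duplicated(env$time)
  env <- env[keep, ]; env <- env[order(env$time), ]

  base$components <- lapply(base$components, function(cmp) {
    hit <- any(driven$channel == cmp$channel & driven$freq == cmp$freq_hz)
    if (hit) cmp$envelope <- env
    cmp
  })
  rec <- synth_generate(base)

  prog <- periods[periods$kind == sc$target, ]
  prog$gain <- sc$gains
  prog$programmed_level <- sc$direction * sc$gains
  list(recording = rec, events = events, programmed = prog,
       paradigm = paradigm, name = name, parameter = sc$parameter)
}
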