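## Run configuration. Defaults reproduce the pipeline's printed constants:
## 1-50 Hz bandpass, 500 Hz sampling, 30-s baseline, 1-s refresh, and the
## 4 x (12-min session + 5-min rest) / 180-trial paradigm. Unknown keys are
## rejected so typos never silently fall back to defaults.

default_config <- function() {
  list(
    paths = list(recording = NULL, events = NULL, norms = NULL,
                 output_dir = "."),
    srate = 500,
    baseline_s = 30,
    chunk_s = 1,
    filter = list(low_hz = 1, high_hz = 50, order = 6),
    asr = list(window_s = 0.5, cutoff_k = 20, overlap = 0.5),
    psd = list(window_s = 2, step_s = 1, db_floor = -120, average = "db"),
    paradigm = list(n_pairs = 4, session_min = 12, rest_min = 5,
                    trials_per_session = 180, timeout_ms = 2000,
                    baseline_s = 30),
    simulate = list(scenario = "attention_decay",
                    channels = c("F3", "FZ", "F4", "C3", "CZ", "C4",
                                 "O1", "OZ", "O2"),
                    noise_rms_uv = 3),
    calibrate = list(n_subjects = 40, between_subject_sd = 0.25,
                     task_gain = 1.2, task_s = 60),
    pentagon = list(row = NA),
    seed = NULL,
    log_level = "info")
}

merge_config <- function(base, override, path = "") {
  for (key in names(override)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(base))
      stop_validation("unknown configuration key '%s'", full)
    if (is.list(base[[key]]) && !is.null(names(base[[key]]))) {
      if (!is.list(override[[key]]))
        stop_validation("configuration key '%s' must be a table", full)
      base[[key]] <- merge_config(base[[key]], override[[key]], full)
    } else {
      base[[key]] <- override[[key]]
    }
  }
  base
}

#' Build a run configuration
#'
#' Starts from the pipeline defaults (1-50 Hz filter at 500 Hz, 30-s
#' baseline, 1-s refresh, 2-s/1-s PSD windows, ASR window 0.5 s with
#' cutoff 20, default paradigm) and applies overrides given as nested
#' lists. Unknown keys raise a validation error.
#'
#' @param ... Named overrides, e.g. `filter = list(order = 8)`.
#' @return A `run_config` list.
#' @export
run_config <- function(...) {
  over <- list(...)
  cfg <- merge_config(default_config(), over)
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a TOML file
#'
#' Supports the subset of TOML the run configuration needs: `[section]` /
#' `[section.sub]` headers, `key = value` pairs with string, number,
#' boolean and flat-array values, and `#` comments.
#'
#' @param path TOML file path.
#' @return A `run_config` list (defaults merged, unknown keys rejected).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_io("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  out <- list()
  section <- character(0)
  for (ln in lines) {
    s <- strip_toml_comment(ln)
    s <- trimws(s)
    if (!nzchar(s)) next
    if (grepl("^\\[[^]]+\\]$", s)) {
      section <- strsplit(gsub("^\\[|\\]$", "", s), ".", fixed = TRUE)[[1]]
      next
    }
    m <- regmatches(s, regexec("^([A-Za-z0-9_.-]+)\\s*=\\s*(.+)$", s))[[1]]
    if (length(m) != 3)
      stop_validation("cannot parse TOML line: %s", ln)
    keys <- c(section, m[2])
    out <- assign_nested(out, keys, parse_toml_value(m[3]))
  }
  do.call(run_config, out)
}

strip_toml_comment <- function(s) {
  inq <- FALSE
  chars <- strsplit(s, "")[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == '"') inq <- !inq
    if (chars[i] == "#" && !inq) return(substr(s, 1, i - 1))
  }
  s
}

parse_toml_value <- function(v) {
  v <- trimws(v)
  if (grepl("^\\[.*\\]$", v)) {
    inner <- trimws(gsub("^\\[|\\]$", "", v))
    if (!nzchar(inner)) return(list())
    parts <- trimws(strsplit(inner, ",")[[1]])
    vals <- lapply(parts, parse_toml_value)
    return(unlist(vals))
  }
  if (grepl('^".*"$', v)) return(gsub('^"|"$', "", v))
  if (v %in% c("true", "false")) return(v == "true")
  num <- suppressWarnings(as.numeric(v))
  if (!is.na(num)) return(num)
  stop_validation("cannot parse TOML value: %s", v)
}

assign_nested <- function(lst, keys, value) {
  if (length(keys) == 1) {
    lst[[keys]] <- value
    return(lst)
  }
  head_key <- keys[1]
  if (is.null(lst[[head_key]])) lst[[head_key]] <- list()
  lst[[head_key]] <- assign_nested(lst[[head_key]], keys[-1], value)
  lst
}

config_paradigm <- function(config) {
  p <- config$paradigm
  paradigm_spec(n_pairs = p$n_pairs, session_min = p$session_min,
                rest_min = p$rest_min,
                trials_per_session = p$trials_per_session,
                timeout_ms = p$timeout_ms, baseline_s = p$baseline_s)
}
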