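## Target-detection paradigm: schedule generation, response scoring and
## behavioral summaries.
##
## The default protocol is a 30-s pre-task baseline followed by four
## repetitions of a 12-min active session and a 5-min rest (68 min of task).
## Each session holds 180 trials, the three cue-target conditions
## (congruent, incongruent, no-target) appearing exactly 60 times each in a
## seeded per-session shuffle. A trial occupies session_min*60 /
## trials_per_session seconds (4 s by default): 0.5 s cue, then the target
## with a response window capped by the timeout; responses slower than the
## timeout (2 s) are failed trials.

#' Paradigm specification
#'
#' @param n_pairs Number of session+rest repetitions (default 4).
#' @param session_min Active-session length in minutes (default 12).
#' @param rest_min Rest length in minutes (default 5).
#' @param trials_per_session Trials per session (default 180; must be
#'   divisible by the number of conditions).
#' @param conditions Condition names.
#' @param timeout_ms Maximal reaction time before a trial fails (default 2000).
#' @param baseline_s Pre-task baseline length in seconds (default 30).
#' @param cue_s Cue duration before target onset (default 0.5).
#' @return A `paradigm_spec` list.
#' @export
paradigm_spec <- function(n_pairs = 4, session_min = 12, rest_min = 5,
                          trials_per_session = 180,
                          conditions = c("congruent", "incongruent", "no_target"),
                          timeout_ms = 2000, baseline_s = 30, cue_s = 0.5) {
  if (trials_per_session %% length(conditions) != 0)
    stop_validation("trials_per_session (%d) not divisible by %d conditions",
                    trials_per_session, length(conditions))
  if (n_pairs < 0 || session_min <= 0 || rest_min < 0)
    stop_validation("invalid paradigm timing")
  structure(list(n_pairs = n_pairs, session_min = session_min,
                 rest_min = rest_min, trials_per_session = trials_per_session,
                 conditions = conditions, timeout_ms = timeout_ms,
                 baseline_s = baseline_s, cue_s = cue_s),
            class = "paradigm_spec")
}

#' Generate the trial schedule as an event table
#'
#' Emits `baseline_start`, then per pair a `session_start`, the session's
#' cue/target events (conditions shuffled within session, equal counts), and
#' a `rest_start`. Reproducible for a given `seed`.
#'
#' @param spec A [paradigm_spec()].
#' @param seed Integer seed for the condition shuffles and target sides.
#' @return An [event_table()].
#' @export
generate_schedule <- function(spec = paradigm_spec(), seed = NULL) {
  stopifnot(inherits(spec, "paradigm_spec"))
  with_seed(seed, {
    trial_s <- spec$session_min * 60 / spec$trials_per_session
    per_cond <- spec$trials_per_session / length(spec$conditions)
    rows <- list(data.frame(onset_s = 0, kind = "baseline_start",
                            condition = NA, direction = NA, rt_ms = NA,
                            correct = NA))
    t <- spec$baseline_s
    for (p in seq_len(spec$n_pairs)) {
      rows[[length(rows) + 1]] <- data.frame(onset_s = t, kind = "session_start",
                                             condition = NA, direction = NA,
                                             rt_ms = NA, correct = NA)
      conds <- sample(rep(spec$conditions, per_cond))
      nt <- length(conds)
      cue_t <- t + (seq_len(nt) - 1) * trial_s
      side <- sample(c("left", "right"), nt, replace = TRUE)
      tgt_dir <- ifelse(conds == "no_target", "none", side)
      cue_dir <- ifelse(conds == "incongruent",
                        ifelse(side == "left", "right", "left"), side)
      ord <- rep(seq_len(nt), each = 2)
      rows[[length(rows) + 1]] <- data.frame(
        onset_s = as.vector(rbind(cue_t, cue_t + spec$cue_s)),
        kind = rep(c("cue", "target"), nt),
        condition = conds[ord],
        direction = as.vector(rbind(cue_dir, tgt_dir)),
        rt_ms = NA, correct = NA)
      t <- t + spec$session_min * 60
      rows[[length(rows) + 1]] <- data.frame(onset_s = t, kind = "rest_start",
                                             condition = NA, direction = NA,
                                             rt_ms = NA, correct = NA)
      t <- t + spec$rest_min * 60
    }
    event_table(do.call(rbind, rows))
  })
}

#' Simulate a responder over a schedule
#'
#' Adds `response` events to a generated schedule using log-normal
#' per-condition reaction-time distributions and a fixed accuracy. The
#' default RT medians are ordered congruent < incongruent < no-target, the
#' qualitative ordering such tasks produce.
#'
#' @param schedule An [event_table()] from [generate_schedule()].
#' @param spec The [paradigm_spec()] used for the schedule.
#' @param seed Integer seed.
#' @param rt_median_ms Named per-condition median RT in ms.
#' @param rt_sdlog Log-scale RT spread (default 0.12).
#' @param accuracy Probability of pressing the correct key (default 0.985).
#' @param miss_rate Probability of not responding at all (default 0.003).
#' @return The schedule with response events merged in, as an [event_table()].
#' @export
simulate_responses <- function(schedule, spec = paradigm_spec(), seed = NULL,
                               rt_median_ms = c(congruent = 635,
                                                incongruent = 666,
                                                no_target = 868),
                               rt_sdlog = 0.12, accuracy = 0.985,
                               miss_rate = 0.003) {
  with_seed(seed, {
    tgt <- schedule[schedule$kind == "target", ]
    n <- nrow(tgt)
    rt <- stats::rlnorm(n, log(rt_median_ms[tgt$condition]), rt_sdlog)
    good <- ifelse(tgt$condition == "no_target", "up", tgt$direction)
    wrong <- vapply(good, function(g)
      sample(setdiff(c("left", "right", "up"), g), 1), "")
    press <- ifelse(runif(n) < accuracy, good, wrong)
    keep <- runif(n) >= miss_rate
    resp <- data.frame(onset_s = tgt$onset_s + rt / 1000, kind = "response",
                       condition = tgt$condition, direction = press,
                       rt_ms = rt, correct = NA)[keep, ]
    out <- rbind(as.data.frame(schedule), resp)
    event_table(out[order(out$onset_s), ])
  })
}

#' Score responses against the schedule
#'
#' Pairs every target with the first following response (before the next
#' target). Correctness is a direction match — the no-target condition
#' requires the "up" key; a trial fails on timeout when the reaction time
#' exceeds the spec timeout or no response arrived.
#'
#' @param events An [event_table()] containing target and response events.
#' @param spec The [paradigm_spec()] (for the timeout).
#' @return A `trial_results` data frame: `condition`, `rt_ms`,
#'   `responded_direction`, `correct`, `failed_timeout`.
#' @export
score_responses <- function(events, spec = paradigm_spec()) {
  tgt_i <- which(events$kind == "target")
  resp_i <- which(events$kind == "response")
  if (length(resp_i) && (length(tgt_i) == 0 || resp_i[1] < tgt_i[1]))
    stop_contract("response event at %.2f s has no preceding target",
                  events$onset_s[resp_i[1]])
  res <- lapply(seq_along(tgt_i), function(k) {
    i <- tgt_i[k]
    lim <- if (k < length(tgt_i)) tgt_i[k + 1] else nrow(events) + 1L
    ri <- resp_i[resp_i > i & resp_i < lim]
    cond <- events$condition[i]
    if (length(ri) == 0)
      return(data.frame(condition = cond, rt_ms = NA_real_,
                        responded_direction = NA_character_, correct = FALSE,
                        failed_timeout = TRUE))
    ri <- ri[1]
    rt <- events$rt_ms[ri]
    if (is.na(rt)) rt <- (events$onset_s[ri] - events$onset_s[i]) * 1000
    timeout <- rt > spec$timeout_ms
    want <- if (cond == "no_target") "up" else events$direction[i]
    data.frame(condition = cond, rt_ms = rt,
               responded_direction = events$direction[ri],
               correct = !timeout && identical(events$direction[ri], want),
               failed_timeout = timeout)
  })
  out <- do.call(rbind, res)
  class(out) <- c("trial_results", "data.frame")
  out
}

#' Summarize behavior per condition
#'
#' Median reaction time and interquartile range (linear, type-7 quantiles)
#' over responded non-timeout trials, and accuracy as percent correct of all
#' trials (timeouts count as incorrect).
#'
#' @param results A `trial_results` data frame from [score_responses()].
#' @return A `behavior_summary` data frame: `condition`, `median_rt_ms`,
#'   `iqr_lo`, `iqr_hi`, `accuracy_pct`.
#' @export
summarize_behavior <- function(results) {
  conds <- unique(results$condition)
  out <- lapply(conds, function(cond) {
    r <- results[results$condition == cond, ]
    ok <- r[!r$failed_timeout & !is.na(r$rt_ms), ]
    if (nrow(ok) == 0)
      stop_contract("condition '%s' has no scorable responded trials", cond)
    q <- quantile(ok$rt_ms, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(condition = cond, median_rt_ms = q[2], iqr_lo = q[1],
               iqr_hi = q[3], accuracy_pct = 100 * mean(r$correct))
  })
  out <- do.call(rbind, out)
  class(out) <- c("behavior_summary", "data.frame")
  out
}

#' @export
summary.trial_results <- function(object, ...) summarize_behavior(object)
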