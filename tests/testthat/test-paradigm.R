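test_that("the default schedule has 60 trials per condition per session", {
  spec <- paradigm_spec()
  sch <- generate_schedule(spec, seed = 1)
  tgt <- sch[sch$kind == "target", ]
  expect_equal(nrow(tgt), 4 * 180)
  sess_starts <- sch$onset_s[sch$kind == "session_start"]
  for (s in sess_starts) {
    in_sess <- tgt[tgt$onset_s >= s & tgt$onset_s < s + 12 * 60, ]
    expect_equal(as.vector(table(in_sess$condition)), c(60, 60, 60))
  }
  ## total scheduled task time (after the baseline) is 68 min
  last_rest <- max(sch$onset_s[sch$kind == "rest_start"])
  expect_equal((last_rest + spec$rest_min * 60 - spec$baseline_s) / 60, 68)
})

test_that("condition counts are exactly balanced for every seed", {
  spec <- paradigm_spec(n_pairs = 1, session_min = 2, trials_per_session = 30)
  for (seed in 1:100) {
    sch <- generate_schedule(spec, seed = seed)
    counts <- table(sch$condition[sch$kind == "target"])
    expect_true(all(counts == 10))
  }
  ## reproducibility and edge cases
  expect_identical(generate_schedule(spec, seed = 7),
                   generate_schedule(spec, seed = 7))
  empty <- generate_schedule(paradigm_spec(n_pairs = 0), seed = 1)
  expect_equal(nrow(empty), 1)
  expect_equal(empty$kind, "baseline_start")
  expect_error(paradigm_spec(trials_per_session = 100),
               class = "eegstate_validation")
})

mini_events <- function(rows) {
  event_table(do.call(rbind, lapply(rows, function(r)
    data.frame(onset_s = r[[1]], kind = r[[2]],
               condition = if (is.na(r[[3]])) NA else r[[3]],
               direction = if (is.na(r[[4]])) NA else r[[4]],
               rt_ms = NA, correct = NA))))
}

test_that("scoring applies the 2-s failure criterion and the up-key rule", {
  spec <- paradigm_spec()
  ev <- mini_events(list(
    list(10.0, "target", "congruent", "left"),
    list(12.1, "response", "congruent", "left"),   # 2100 ms -> fail
    list(14.0, "target", "no_target", "none"),
    list(14.9, "response", "no_target", "up"),     # up at 900 ms -> correct
    list(18.0, "target", "congruent", "right"),
    list(18.6, "response", "congruent", "left"),   # wrong key, in time
    list(22.0, "target", "incongruent", "left")))  # no response at all
  res <- score_responses(ev, spec)
  expect_equal(res$failed_timeout, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(res$correct, c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(res$rt_ms[2], 900, tolerance = 1e-6)
  ## a response with no preceding target violates the contract
  orphan <- mini_events(list(list(1, "response", "congruent", "left"),
                             list(2, "target", "congruent", "left")))
  expect_error(score_responses(orphan, spec), class = "eegstate_contract")
})

test_that("scoring is invariant to trial order", {
  spec <- paradigm_spec(n_pairs = 1, session_min = 2, trials_per_session = 30)
  ev <- simulate_responses(generate_schedule(spec, seed = 9), spec, seed = 10)
  res <- score_responses(ev, spec)
  shuffled <- res[sample(nrow(res)), ]
  expect_equal(summarize_behavior(shuffled)[order(summarize_behavior(shuffled)$condition), ],
               summarize_behavior(res)[order(summarize_behavior(res)$condition), ],
               ignore_attr = TRUE)
})

test_that("behavior summaries use type-7 quantiles and count timeouts as errors", {
  res <- data.frame(condition = "congruent", rt_ms = c(600, 700, 800),
                    responded_direction = "left", correct = TRUE,
                    failed_timeout = FALSE)
  s <- summarize_behavior(res)
  expect_equal(s$median_rt_ms, 700)
  expect_equal(c(s$iqr_lo, s$iqr_hi), c(650, 750))
  ## correct + incorrect + timeout -> 33.3% accuracy
  res2 <- data.frame(condition = "c", rt_ms = c(500, 520, 2400),
                     responded_direction = "left",
                     correct = c(TRUE, FALSE, FALSE),
                     failed_timeout = c(FALSE, FALSE, TRUE))
  expect_equal(summarize_behavior(res2)$accuracy_pct, 100 / 3)
  ## all-identical RTs collapse median and IQR
  res3 <- data.frame(condition = "c", rt_ms = 700, responded_direction = "l",
                     correct = TRUE, failed_timeout = FALSE)[rep(1, 5), ]
  s3 <- summarize_behavior(res3)
  expect_true(all(c(s3$median_rt_ms, s3$iqr_lo, s3$iqr_hi) == 700))
  expect_error(summarize_behavior(res2[res2$failed_timeout, ]),
               class = "eegstate_contract")
})

test_that("a simulated responder reproduces the qualitative RT ordering", {
  spec <- paradigm_spec(n_pairs = 2, session_min = 4, trials_per_session = 60)
  ev <- simulate_responses(generate_schedule(spec, seed = 5), spec, seed = 6)
  s <- summarize_behavior(score_responses(ev, spec))
  med <- setNames(s$median_rt_ms, s$condition)
  expect_lt(med[["congruent"]], med[["incongruent"]])
  expect_lt(med[["incongruent"]], med[["no_target"]])
  expect_true(all(s$accuracy_pct > 90 & s$accuracy_pct <= 100))
})
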