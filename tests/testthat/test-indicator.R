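test_that("fit_norms computes across-subject statistics with f = sigma/2", {
  ## two subjects whose every ROI feature value is 1.0 resp. 3.0; the
  ## difference features are also made to vary so the fit is non-degenerate
  ## (F4 theta/alpha deviate oppositely, keeping the F4 channel mean at v)
  subj <- function(v) {
    f <- random_bp_frame()
    f$power_db <- v
    f$power_db[f$channel == "F4" & f$band == "alpha"] <- 2 * v
    f$power_db[f$channel == "F4" & f$band == "theta"] <- 0
    f$power_db[f$channel == "CZ" & f$band == "mu"] <- 0
    f$power_linear <- 10^(f$power_db / 10)
    f
  }
  norms <- fit_norms(list(subj(1), subj(3)))
  tb <- coef(norms)
  roi <- tb[tb$parameter %in% c("attention", "fatigue"), ]
  expect_equal(roi$mean, rep(2, 6))
  expect_equal(roi$sigma, rep(sqrt(2), 6))        # sample sd, n-1
  expect_equal(roi$f, rep(sqrt(2) / 2, 6))
  ## difference features: identical values -> zero difference every subject
  expect_error(fit_norms(list(subj(1), subj(1))),
               class = "eegstate_contract")      # degenerate cohort
  expect_error(fit_norms(list(subj(1))), class = "eegstate_validation")
})

test_that("refitting on the same cohort is deterministic", {
  set.seed(60)
  cohort <- replicate(4, random_bp_frame(), simplify = FALSE)
  expect_identical(coef(fit_norms(cohort)), coef(fit_norms(cohort)))
})

test_that("all five parameters equal 5 at the population means", {
  norms <- test_norms()
  st <- compute_state(frame_at_means(norms), norms)
  expect_equal(as.numeric(st[, c("attention", "fatigue", "stress",
                                 "left", "right")]),
               rep(5, 5), tolerance = 1e-12)
})

test_that("parameters match an independent evaluation of the formulas", {
  norms <- test_norms()
  set.seed(61)
  for (i in 1:250) {
    fr <- random_bp_frame()
    want <- oracle_state(fr, norms)
    expect_equal(attention(fr, norms), want[["attention"]], tolerance = 1e-9)
    expect_equal(fatigue(fr, norms), want[["fatigue"]], tolerance = 1e-9)
    expect_equal(stress(fr, norms), want[["stress"]], tolerance = 1e-9)
    expect_equal(left_activity(fr, norms), want[["left"]], tolerance = 1e-9)
    expect_equal(right_activity(fr, norms), want[["right"]], tolerance = 1e-9)
    st <- compute_state(fr, norms)
    expect_equal(as.numeric(st[, names(want)]), as.numeric(want),
                 tolerance = 1e-9)
  }
})

test_that("one normalization factor of deviation moves the level by one", {
  norms <- test_norms()
  tb <- coef(norms)
  base <- frame_at_means(norms)
  bump <- function(frame, sel, d) {
    frame$power_db[sel] <- frame$power_db[sel] + d
    frame$power_linear <- 10^(frame$power_db / 10)
    frame
  }
  ## attention: each frontal channel one f above its mean -> 4.0
  fr <- base
  for (ch in c("F3", "FZ", "F4")) {
    f <- tb$f[tb$parameter == "attention" & tb$feature == ch]
    fr <- bump(fr, fr$channel == ch & fr$band %in% c("theta", "alpha"), f)
  }
  expect_equal(attention(fr, norms), 4)
  ## fatigue: occipital channels one f below -> 4.0
  fr <- base
  for (ch in c("O1", "OZ", "O2")) {
    f <- tb$f[tb$parameter == "fatigue" & tb$feature == ch]
    fr <- bump(fr, fr$channel == ch & fr$band %in% c("theta", "alpha", "beta"), -f)
  }
  expect_equal(fatigue(fr, norms), 4)
  ## stress: asymmetry one f above its zero mean -> 4.0
  fC <- tb$f[tb$parameter == "stress"]
  fr <- bump(base, base$channel == "F4" & base$band == "alpha",
             fC * 10 / log(10))
  expect_equal(stress(fr, norms), 4)
  ## left: C4-Cz difference one f above its mean -> 6.0
  fL <- tb$f[tb$parameter == "left"]
  fr <- bump(base, base$channel == "C4" & base$band == "mu", fL)
  expect_equal(left_activity(fr, norms), 6)
  ## linearity: doubling the deviation doubles the displacement
  fr2 <- bump(base, base$channel == "C4" & base$band == "mu", 2 * fL)
  expect_equal(left_activity(fr2, norms) - 5,
               2 * (left_activity(fr, norms) - 5))
})

test_that("sign contracts hold under monotone sweeps", {
  norms <- test_norms()
  base <- frame_at_means(norms)
  sweep_level <- function(sel, fn, deltas) {
    vapply(deltas, function(d) {
      fr <- base
      fr$power_db[sel] <- fr$power_db[sel] + d
      fr$power_linear <- 10^(fr$power_db / 10)
      fn(fr, norms)
    }, 0)
  }
  d <- seq(0, 3, by = 0.5)
  att <- sweep_level(base$channel %in% c("F3", "FZ", "F4") &
                     base$band %in% c("theta", "alpha"), attention, d)
  expect_true(all(diff(att) < 0))
  fat <- sweep_level(base$channel %in% c("O1", "OZ", "O2") &
                     base$band %in% c("theta", "alpha", "beta"), fatigue, d)
  expect_true(all(diff(fat) > 0))
  str <- sweep_level(base$channel == "F4" & base$band == "alpha", stress, d)
  expect_true(all(diff(str) < 0))  # rising right-frontal alpha -> calmer
})

test_that("symmetric mu modulation yields equal left and right levels", {
  ## cohort with identical C3/C4 statistics
  set.seed(62)
  cohort <- lapply(1:6, function(s) {
    fr <- random_bp_frame()
    c3 <- fr$channel == "C3" & fr$band == "mu"
    c4 <- fr$channel == "C4" & fr$band == "mu"
    fr$power_db[c4] <- fr$power_db[c3]
    fr$power_linear <- 10^(fr$power_db / 10)
    fr
  })
  norms <- fit_norms(cohort)
  fr <- cohort[[1]]
  expect_lt(abs(left_activity(fr, norms) - right_activity(fr, norms)), 0.1)
})

test_that("errors carry the parameter name and missing features are caught", {
  norms <- test_norms()
  fr <- frame_at_means(norms)
  fr <- fr[!(fr$channel == "CZ" & fr$band == "mu"), ]
  err <- expect_error(compute_state(fr, norms), class = "eegstate_contract")
  expect_match(conditionMessage(err), "left")
  expect_error(scale_level(1, 0, 0), class = "eegstate_validation")
})

test_that("norms survive a JSON round trip", {
  norms <- test_norms()
  path <- withr::local_tempfile(fileext = ".json")
  norms_save(norms, path)
  back <- norms_load(path)
  expect_equal(coef(back), coef(norms))
  expect_equal(back$n_subjects, norms$n_subjects)
  fr <- frame_at_means(norms)
  expect_equal(compute_state(fr, back), compute_state(fr, norms))
})

test_that("the sigma/2 factor covers ~98.75% of Gaussian features", {
  set.seed(63)
  p <- rnorm(2e5, mean = 3, sd = 1.7)
  y <- scale_level(p, 3, 1.7 / 2, +1)
  expect_equal(mean(y >= 0 & y <= 10), 2 * pnorm(2.5) - 1, tolerance = 0.005)
})

test_that("the pentagon renderer writes a plot and clips only the display", {
  st <- data.frame(t0 = 0, attention = 5, fatigue = 5, stress = 5,
                   left = 5, right = 12)
  path <- withr::local_tempfile(fileext = ".png")
  render_pentagon(st, path)
  expect_gt(file.info(path)$size, 0)
  expect_error(render_pentagon(st, withr::local_tempfile(fileext = ".txt")),
               class = "eegstate_validation")
  st$left <- NaN
  expect_error(render_pentagon(st, path), class = "eegstate_contract")
})
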