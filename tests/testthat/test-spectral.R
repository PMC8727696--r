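test_that("a pure sinusoid's energy localizes at its frequency", {
  srate <- 500
  t <- seq(0, 2 - 1 / srate, by = 1 / srate)
  w <- matrix(sin(2 * pi * 10 * t), 1, dimnames = list("OZ", NULL))
  pf <- compute_psd(w, srate)
  expect_equal(pf$freqs[which.max(pf$psd_linear[1, ])], 10)
  df <- diff(pf$freqs[1:2])
  sel <- pf$freqs >= 9 & pf$freqs <= 11
  expect_gt(sum(pf$psd_linear[1, sel]) / sum(pf$psd_linear[1, ]), 0.99)
  ## total energy matches the sinusoid's mean-square power (amp^2/2)
  expect_equal(sum(pf$psd_linear[1, ]) * df, 0.5, tolerance = 0.05)
})

test_that("PSD is Parseval-consistent on random signals", {
  set.seed(40)
  for (i in 1:6) {
    n <- sample(c(5000, 8192, 10000), 1)
    x <- matrix(rnorm(2 * n, sd = runif(1, 0.5, 20)), 2,
                dimnames = list(c("CZ", "PZ"), NULL))
    pf <- compute_psd(x, 500)
    df <- diff(pf$freqs[1:2])
    for (ch in 1:2)
      expect_equal(sum(pf$psd_linear[ch, ]) * df, mean(x[ch, ]^2),
                   tolerance = 0.05)
  }
})

test_that("degenerate windows hit the dB floor or the length contract", {
  pf <- compute_psd(matrix(0, 1, 1000, dimnames = list("CZ", NULL)), 500)
  expect_true(all(pf$psd_db == -120))
  expect_error(compute_psd(matrix(0, 1, 200), 500),
               class = "eegstate_contract")
})

test_that("baseline subtraction is an exact dB-domain difference", {
  set.seed(41)
  x <- matrix(rnorm(2000), 2, dimnames = list(c("CZ", "OZ"), NULL))
  pf <- compute_psd(x, 500)
  expect_true(all(subtract_baseline(pf, pf)$psd_db == 0))
  plus3 <- pf
  plus3$psd_db <- pf$psd_db + 3
  plus3$psd_linear <- 10^(plus3$psd_db / 10)
  expect_equal(subtract_baseline(plus3, pf)$psd_db,
               matrix(3, 2, ncol(pf$psd_db)), ignore_attr = TRUE)
  ## subtract-then-add algebraic round trip
  other <- compute_psd(matrix(rnorm(2000), 2, dimnames = list(c("CZ", "OZ"), NULL)), 500)
  rel <- subtract_baseline(pf, other)
  back <- rel
  back$psd_db <- rel$psd_db + other$psd_db
  expect_lt(max(abs(back$psd_db - pf$psd_db)), 1e-9)
  ## dB/linear duality maintained
  expect_equal(rel$psd_linear, 10^(rel$psd_db / 10))
  bad <- compute_psd(matrix(rnorm(1000), 1, dimnames = list("CZ", NULL)), 500)
  expect_error(subtract_baseline(pf, bad), class = "eegstate_contract")
})

flat_frame <- function(value_db, channels = "CZ", srate = 500, n = 1000) {
  structure(list(t0 = 0, freqs = (0:(n / 2)) * srate / n,
                 psd_db = matrix(value_db, length(channels), n / 2 + 1,
                                 dimnames = list(channels, NULL)),
                 psd_linear = matrix(10^(value_db / 10), length(channels),
                                     n / 2 + 1),
                 channels = channels, srate = srate), class = "psd_frame")
}

test_that("band decomposition averages the right bins", {
  bp <- band_power(flat_frame(2))
  expect_true(all(bp$power_db == 2))
  ## alpha (8-12) vs mu (8-13) differ only through the 13 Hz bins
  pf <- flat_frame(0)
  pf$psd_db[, pf$freqs > 12.5] <- 10  # raise everything above alpha
  pf$psd_linear <- 10^(pf$psd_db / 10)
  bp2 <- band_power(pf)
  alpha <- bp2$power_db[bp2$band == "alpha"]
  mu <- bp2$power_db[bp2$band == "mu"]
  sel_mu <- pf$freqs >= 8 & pf$freqs <= 13
  expect_equal(mu, mean(pf$psd_db[1, sel_mu]))  # direct bin-mean oracle
  expect_gt(mu, alpha)
  expect_error(band_power(pf, data.frame(band = "x", low_hz = 10.1,
                                         high_hz = 10.2)),
               class = "eegstate_contract")
})

test_that("a 10 Hz sinusoid dominates the alpha band by >= 20 dB", {
  srate <- 500
  t <- seq(0, 2 - 1 / srate, by = 1 / srate)
  w <- matrix(10 * sin(2 * pi * 10 * t), 1, dimnames = list("OZ", NULL))
  bp <- band_power(compute_psd(w, srate))
  alpha <- bp$power_db[bp$band == "alpha"]
  others <- bp$power_db[!bp$band %in% c("alpha", "mu")]
  expect_true(all(alpha - others >= 20))
})

test_that("sliding band power matches the three-stage composition", {
  ## stationary fixture: constant-amplitude oscillations, no noise
  sp <- base_synth_spec(duration_s = 40, mod_depth = 0, noise_rms_uv = 0,
                        seed = 50)
  rec <- synth_generate(sp)
  base <- rec_slice(rec, 0, 30)
  bpsd <- baseline_psd(base)
  task <- rec_slice(rec, 30, 40)
  bp <- sliding_band_power(task, bpsd)
  expect_equal(length(unique(bp$t0)), 9)   # 10 s, 2-s window, 1-s step
  expect_equal(sort(unique(bp$t0)), 30:38)
  ## frame-by-frame equality with compute_psd -> subtract -> band_power
  f0 <- compute_psd(task$data[, 1:1000], task$srate, t0 = 30)
  manual <- band_power(subtract_baseline(f0, bpsd))
  expect_equal(bp[bp$t0 == 30, ], manual, ignore_attr = TRUE)
  ## stationary signal: frame-to-frame band-power spread stays small
  for (b in c("theta", "alpha", "beta")) {
    x <- bp[bp$band == b & bp$channel == "OZ", "power_db"]
    expect_lt(sd(x), 1.5)
  }
  expect_error(sliding_band_power(task, bpsd, window_s = 2, step_s = 3),
               class = "eegstate_validation")
  expect_error(sliding_band_power(rec_slice(task, 0.2, 1), bpsd),
               class = "eegstate_contract")
})
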