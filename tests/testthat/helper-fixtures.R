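## Shared fixtures, built in code. Expensive objects (cohort norms) are
## cached across test files within the session.

roi_channels <- c("F3", "FZ", "F4", "C3", "CZ", "C4", "O1", "OZ", "O2")

fixture_cache <- local({
  cache <- getOption("eegstate.test.cache")
  if (is.null(cache)) {
    cache <- new.env(parent = emptyenv())
    options(eegstate.test.cache = cache)
  }
  cache
})

cached <- function(key, expr) {
  if (is.null(fixture_cache[[key]])) fixture_cache[[key]] <- force(expr)
  fixture_cache[[key]]
}

## A small calibration cohort and its fitted norms (8 subjects, 30 s
## baseline + 40 s task, nine ROI channels).
test_norms <- function() {
  cached("norms", {
    cfg <- run_config()
    base <- base_synth_spec(roi_channels, duration_s = 70)
    cohort <- make_cohort(8, base, 0.25, seed = 424)
    fit_norms(lapply(cohort, cohort_band_powers, config = cfg))
  })
}

## Hand-built band-power frame: one value per (channel, band) the
## indicator reads, all other pairs absent.
make_bp_frame <- function(values, t0 = 0) {
  df <- do.call(rbind, lapply(names(values), function(key) {
    parts <- strsplit(key, "\\.")[[1]]
    data.frame(t0 = t0, channel = parts[1], band = parts[2],
               power_db = values[[key]],
               power_linear = 10^(values[[key]] / 10))
  }))
  class(df) <- c("band_power_frame", "data.frame")
  df
}

## Frame where every indicator feature sits exactly at its fitted mean.
frame_at_means <- function(norms, t0 = 0) {
  tb <- coef(norms)
  v <- list()
  ## equal alpha across frontal channels keeps the stress asymmetry at its
  ## zero center while each channel's theta+alpha mean hits the fitted mean
  for (ch in c("F3", "FZ", "F4")) {
    m <- tb$mean[tb$parameter == "attention" & tb$feature == ch]
    v[[paste0(ch, ".alpha")]] <- 0
    v[[paste0(ch, ".theta")]] <- 2 * m
  }
  for (ch in c("O1", "OZ", "O2"))
    for (b in c("theta", "alpha", "beta"))
      v[[paste0(ch, ".", b)]] <- tb$mean[tb$parameter == "fatigue" & tb$feature == ch]
  ## stress center is 0 asymmetry: equal alpha at F3/F4 (already equal above)
  for (ch in c("C3", "CZ", "C4")) v[[paste0(ch, ".mu")]] <- 0
  ## left/right centers: realize the fitted mean differences against Cz = 0
  v[["C4.mu"]] <- tb$mean[tb$parameter == "left"]
  v[["C3.mu"]] <- tb$mean[tb$parameter == "right"]
  make_bp_frame(v, t0)
}

## Random band-power frame covering the indicator's feature set.
random_bp_frame <- function(t0 = 0) {
  v <- list()
  for (ch in c("F3", "FZ", "F4"))
    for (b in c("theta", "alpha")) v[[paste0(ch, ".", b)]] <- rnorm(1, 0, 3)
  for (ch in c("O1", "OZ", "O2"))
    for (b in c("theta", "alpha", "beta")) v[[paste0(ch, ".", b)]] <- rnorm(1, 0, 3)
  for (ch in c("C3", "CZ", "C4")) v[[paste0(ch, ".mu")]] <- rnorm(1, 0, 3)
  make_bp_frame(v, t0)
}

## Independent hand-coded evaluation of the five printed formulas, reading
## the norm table directly (kept deliberately separate from the package's
## feature-extraction code path).
oracle_state <- function(frame, norms) {
  tb <- coef(norms)
  g <- function(ch, b) frame$power_db[frame$channel == ch & frame$band == b]
  nrm <- function(par, feat) tb[tb$parameter == par & tb$feature == feat, ]
  dev <- function(par, ch, bands) {
    p <- mean(vapply(bands, function(b) g(ch, b), 0))
    r <- nrm(par, ch)
    (p - r$mean) / r$f
  }
  att <- 5 - (dev("attention", "F3", c("theta", "alpha")) +
              dev("attention", "FZ", c("theta", "alpha")) +
              dev("attention", "F4", c("theta", "alpha"))) / 3
  fat <- 5 + (dev("fatigue", "O1", c("theta", "alpha", "beta")) +
              dev("fatigue", "OZ", c("theta", "alpha", "beta")) +
              dev("fatigue", "O2", c("theta", "alpha", "beta"))) / 3
  rs <- nrm("stress", "F4-F3")
  lnp <- function(ch) log(10^(g(ch, "alpha") / 10))
  str <- 5 - (lnp("F4") - lnp("F3") - rs$mean) / rs$f
  rl <- nrm("left", "C4-CZ")
  lef <- 5 + (g("C4", "mu") - g("CZ", "mu") - rl$mean) / rl$f
  rr <- nrm("right", "C3-CZ")
  rig <- 5 + (g("C3", "mu") - g("CZ", "mu") - rr$mean) / rr$f
  c(attention = att, fatigue = fat, stress = str, left = lef, right = rig)
}
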