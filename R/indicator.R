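## The five-parameter physiological state indicator.
##
## Every parameter is an affine map of baseline-relative band power onto a
## 0-10 scale centered at 5: y(t) = 5 +/- (1/n) * sum_c (P_c(t) - Pbar_c)/f_c,
## with the per-feature normalization factor f set to half the
## across-subject standard deviation (f = sigma/2). With Gaussian features
## this places ~98.75% of levels inside [0, 10] (mu +/- 2.5 sigma).
##
## Features:
##   attention: 5 - mean normalized deviation of theta+alpha power at
##              F3, Fz, F4 (frontal engagement is inverse to theta/alpha)
##   fatigue:   5 + mean normalized deviation of theta+alpha+beta power at
##              O1, Oz, O2 (occipital broadband rises with fatigue)
##   stress:    5 - normalized frontal alpha asymmetry
##              (ln alpha F4 - ln alpha F3; positive asymmetry = calmer)
##   left:      5 + normalized mu-power difference C4 - Cz
##   right:     5 + normalized mu-power difference C3 - Cz
##
## The left parameter reads C4 and the right parameter C3: contralateral
## naming, kept exactly as the indicator defines it. Likewise the "+" sign
## on mu power is the indicator's printed convention, although under strict
## event-related-desynchronization logic higher mu would mean lower
## activity.

#' Feature definitions of the five state parameters
#'
#' @return A list keyed by parameter, each with `channels`, `bands`, `sign`
#'   and `mode` (`"mean"` for per-channel ROI features, `"diff"` for
#'   channel-difference features).
#' @export
feature_defs <- function() {
  list(
    attention = list(channels = c("F3", "FZ", "F4"),
                     bands = c("theta", "alpha"), sign = -1, mode = "mean"),
    fatigue = list(channels = c("O1", "OZ", "O2"),
                   bands = c("theta", "alpha", "beta"), sign = +1, mode = "mean"),
    stress = list(channels = c("F4", "F3"), bands = "alpha", sign = -1,
                  mode = "diff", transform = "ln"),
    left = list(channels = c("C4", "CZ"), bands = "mu", sign = +1,
                mode = "diff", transform = "db"),
    right = list(channels = c("C3", "CZ"), bands = "mu", sign = +1,
                 mode = "diff", transform = "db"))
}

#' Map a feature value onto the 0-10 state scale
#'
#' The indicator's general transform: `5 + sign * (p - center) / f`. Levels
#' are never clipped in data outputs (clipping happens only at display).
#'
#' @param p Feature value(s).
#' @param center Population mean of the feature.
#' @param f Normalization factor, half the population standard deviation.
#' @param sign `+1` or `-1`.
#' @return Numeric level(s), nominally 0-10.
#' @export
scale_level <- function(p, center, f, sign = +1) {
  if (any(f <= 0)) stop_validation("normalization factor f must be positive")
  5 + sign * (p - center) / f
}

## ---------------------------------------------------------------------------
## Feature extraction from a band-power frame

bp_lookup <- function(frame, channels, bands) {
  out <- matrix(NA_real_, length(channels), length(bands),
                dimnames = list(channels, bands))
  sel <- frame$channel %in% channels & frame$band %in% bands
  sub <- frame[sel, ]
  out[cbind(match(sub$channel, channels), match(sub$band, bands))] <- sub$power_db
  if (any(is.na(out)))
    stop_contract("band powers missing for: %s",
                  paste(apply(which(is.na(out), arr.ind = TRUE), 1, function(i)
                    paste0(channels[i[1]], "/", bands[i[2]])), collapse = ", "))
  out
}

## Per-channel feature value: bands averaged in dB within the channel, since
## each channel carries a single (mean, f) pair in the parameter formulas.
roi_feature <- function(frame, def) {
  rowMeans(bp_lookup(frame, def$channels, def$bands))
}

## Difference feature value (a - b). "ln" re-derives natural-log linear
## power from the dB value (ln P = dB * ln(10)/10); "db" differs in dB.
diff_feature <- function(frame, def) {
  p <- bp_lookup(frame, def$channels, def$bands)
  if (any(!is.finite(p)))
    stop_contract("non-finite band power in difference feature")
  d <- p[1, 1] - p[2, 1]
  if (identical(def$transform, "ln")) d * log(10) / 10 else d
}

subject_features <- function(bp_series) {
  ## subject-mean power per (channel, band), then feature values
  agg <- stats::aggregate(power_db ~ channel + band, data = as.data.frame(bp_series),
                          FUN = mean)
  frame <- data.frame(t0 = 0, channel = agg$channel, band = agg$band,
                      power_db = agg$power_db,
                      power_linear = 10^(agg$power_db / 10))
  defs <- feature_defs()
  vals <- list()
  for (nm in names(defs)) {
    def <- defs[[nm]]
    vals[[nm]] <- if (def$mode == "mean") roi_feature(frame, def)
                  else diff_feature(frame, def)
  }
  vals
}

## ---------------------------------------------------------------------------
## Norm fitting (the estimator)

#' Fit population norms for the state indicator
#'
#' Given baseline-relative band-power series from a calibration cohort,
#' computes per feature the across-subject mean of subject-mean power
#' (`Pbar`), the across-subject standard deviation `sigma` (sample, n-1)
#' and the normalization factor `f = sigma/2`.
#'
#' For the difference features the population center defaults to the
#' cohort-estimated mean of the difference, except for stress whose formula
#' fixes the center at zero asymmetry (configurable via `center_stress`).
#'
#' @param cohort List (one element per subject) of `band_power_ts` data
#'   frames, already baseline-subtracted.
#' @param center_stress If `TRUE`, center the stress asymmetry at its
#'   cohort mean rather than at 0 (default `FALSE`).
#' @return A `state_norms` object with methods `print`, `summary`, `coef`
#'   and `predict`.
#' @export
fit_norms <- function(cohort, center_stress = FALSE) {
  if (length(cohort) < 2)
    stop_validation(">=2 subjects required to fit norms, got %d", length(cohort))
  per_subject <- lapply(cohort, subject_features)
  defs <- feature_defs()
  rows <- list()
  for (nm in names(defs)) {
    vals <- do.call(rbind, lapply(per_subject, function(s) s[[nm]]))
    mu <- colMeans(vals)
    sig <- apply(vals, 2, sd)
    if (any(sig == 0))
      stop_contract("degenerate cohort: zero across-subject variance for %s", nm)
    feat <- if (defs[[nm]]$mode == "mean") defs[[nm]]$channels
            else paste(defs[[nm]]$channels, collapse = "-")
    if (nm == "stress" && !center_stress) mu[] <- 0
    rows[[nm]] <- data.frame(parameter = nm, feature = feat,
                             mean = as.numeric(mu), sigma = as.numeric(sig),
                             f = as.numeric(sig) / 2)
  }
  structure(list(table = do.call(rbind, c(rows, make.row.names = FALSE)),
                 n_subjects = length(cohort),
                 center_stress = center_stress),
            class = "state_norms")
}

#' @export
print.state_norms <- function(x, ...) {
  cat(sprintf("<state_norms> fitted on %d subjects (f = sigma/2)\n", x$n_subjects))
  print(x$table, digits = 4)
  invisible(x)
}

#' @export
summary.state_norms <- function(object, ...) {
  cat(sprintf("State-indicator norms, %d-subject cohort\n", object$n_subjects))
  cat("Levels are 5 + sign * (P - mean)/f per feature, averaged over the ROI;\n")
  cat("f = sigma/2 places ~98.75% of Gaussian features inside [0, 10].\n\n")
  print(object$table, digits = 4)
  invisible(object)
}

#' @export
coef.state_norms <- function(object, ...) object$table

norm_rows <- function(norms, parameter) {
  norms$table[norms$table$parameter == parameter, , drop = FALSE]
}

## ---------------------------------------------------------------------------
## The five parameters

roi_level <- function(frame, norms, parameter) {
  def <- feature_defs()[[parameter]]
  nr <- norm_rows(norms, parameter)
  p <- roi_feature(frame, def)[nr$feature]
  mean(scale_level(p, nr$mean, nr$f, def$sign))
}

diff_level <- function(frame, norms, parameter) {
  def <- feature_defs()[[parameter]]
  nr <- norm_rows(norms, parameter)
  d <- diff_feature(frame, def)
  scale_level(d, nr$mean, nr$f, def$sign)
}

#' Compute one state parameter from a band-power frame
#'
#' @param frame A `band_power_frame` (one time point) holding
#'   baseline-relative band powers for the required channels.
#' @param norms A [fit_norms()] result.
#' @return The level (unitless, nominally 0-10, not clipped).
#' @export
attention <- function(frame, norms) roi_level(frame, norms, "attention")

#' @rdname attention
#' @export
fatigue <- function(frame, norms) roi_level(frame, norms, "fatigue")

#' @rdname attention
#' @export
stress <- function(frame, norms) diff_level(frame, norms, "stress")

#' @rdname attention
#' @export
left_activity <- function(frame, norms) diff_level(frame, norms, "left")

#' @rdname attention
#' @export
right_activity <- function(frame, norms) diff_level(frame, norms, "right")

#' Compute the full five-parameter state vector
#'
#' @inheritParams attention
#' @return One-row data frame (`t0`, `attention`, `fatigue`, `stress`,
#'   `left`, `right`) of class `state_vector`.
#' @export
compute_state <- function(frame, norms) {
  lvl <- function(fn, nm) tryCatch(fn(frame, norms), error = function(e)
    stop_contract("%s: %s", nm, conditionMessage(e)))
  out <- data.frame(t0 = frame$t0[1],
                    attention = lvl(attention, "attention"),
                    fatigue = lvl(fatigue, "fatigue"),
                    stress = lvl(stress, "stress"),
                    left = lvl(left_activity, "left"),
                    right = lvl(right_activity, "right"))
  class(out) <- c("state_vector", "data.frame")
  out
}

#' Compute the state time series from a band-power time series
#'
#' One [compute_state()] row per distinct `t0` of the input.
#'
#' @param bp A `band_power_ts` data frame.
#' @param norms A [fit_norms()] result.
#' @return A `state_ts` data frame.
#' @export
compute_states <- function(bp, norms) {
  frames <- split(as.data.frame(bp), bp$t0)
  out <- do.call(rbind, lapply(frames, compute_state, norms = norms))
  out <- out[order(out$t0), ]
  rownames(out) <- NULL
  class(out) <- c("state_ts", "data.frame")
  out
}

#' @export
#' @method predict state_norms
predict.state_norms <- function(object, newdata, ...) {
  compute_states(newdata, object)
}

#' @export
print.state_ts <- function(x, ...) {
  cat(sprintf("<state_ts> %d time points, %.0f-%.0f s\n",
              nrow(x), min(x$t0), max(x$t0)))
  print.data.frame(head(as.data.frame(x), 5), digits = 3)
  if (nrow(x) > 5) cat("...\n")
  invisible(x)
}

#' @export
plot.state_ts <- function(x, parameters = c("attention", "fatigue", "stress",
                                            "left", "right"), ...) {
  cols <- c(attention = "#1b9e77", fatigue = "#d95f02", stress = "#7570b3",
            left = "#e7298a", right = "#66a61e")
  plot.new()
  plot.window(xlim = range(x$t0), ylim = range(0, 10, unlist(x[parameters])))
  axis(1); axis(2)
  title(xlab = "time (s)", ylab = "level (0-10 scale)")
  for (p in parameters) lines(x$t0, x[[p]], col = cols[[p]])
  legend("topright", legend = parameters, col = cols[parameters], lty = 1,
         bty = "n", cex = 0.8)
  invisible(x)
}

#' Write a state time series to CSV
#'
#' Columns exactly `t0, attention, fatigue, stress, left, right`.
#'
#' @param states A `state_ts` data frame.
#' @param path Output CSV path.
#' @export
write_states <- function(states, path) {
  df <- as.data.frame(states)[, c("t0", "attention", "fatigue", "stress",
                                  "left", "right")]
  tryCatch(write.csv(df, path, row.names = FALSE),
           condition = function(e) stop_io("cannot write '%s': %s", path,
                                           conditionMessage(e)))
  invisible(path)
}

## ---------------------------------------------------------------------------
## Norm serialization

#' Save / load fitted norms as JSON
#'
#' @param norms A `state_norms` object.
#' @param path JSON file path.
#' @export
norms_save <- function(norms, path) {
  jsonlite::write_json(list(n_subjects = norms$n_subjects,
                            center_stress = norms$center_stress,
                            table = norms$table),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname norms_save
#' @export
norms_load <- function(path) {
  if (!file.exists(path)) stop_io("file not found: %s", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(table = as.data.frame(obj$table),
                 n_subjects = obj$n_subjects,
                 center_stress = isTRUE(obj$center_stress)),
            class = "state_norms")
}

## ---------------------------------------------------------------------------
## Pentagon display

#' Render a state vector as a pentagon (radar) plot
#'
#' Axes are clipped to [0, 10] for display only; the numeric labels show the
#' unclipped levels.
#'
#' @param state A `state_vector` (or any one-row data frame with the five
#'   parameter columns).
#' @param path Output image path (`.png` or `.svg`).
#' @return Invisibly, `path`.
#' @export
render_pentagon <- function(state, path) {
  vals <- as.numeric(state[1, c("attention", "fatigue", "stress", "left", "right")])
  if (any(!is.finite(vals))) stop_contract("non-finite state levels")
  labs <- c("attention", "fatigue", "stress", "left", "right")
  ext <- tolower(tools::file_ext(path))
  dev <- switch(ext, png = function() png(path, 600, 600),
                svg = function() svg(path, 6, 6),
                stop_validation("unsupported image format '%s'", ext))
  tryCatch(dev(), condition = function(e)
    stop_io("cannot open device for '%s': %s", path, conditionMessage(e)))
  on.exit(dev.off())
  ang <- pi / 2 - 2 * pi * (seq_len(5) - 1) / 5
  old <- par(mar = c(1, 1, 2, 1)); on.exit(par(old), add = TRUE)
  plot.new()
  plot.window(xlim = c(-1.35, 1.35), ylim = c(-1.35, 1.35), asp = 1)
  for (r in c(2.5, 5, 7.5, 10) / 10)
    polygon(r * cos(ang), r * sin(ang), border = "grey80")
  segments(0, 0, cos(ang), sin(ang), col = "grey80")
  rv <- pmin(pmax(vals, 0), 10) / 10
  polygon(rv * cos(ang), rv * sin(ang), col = grDevices::adjustcolor("#1f78b4", 0.4),
          border = "#1f78b4", lwd = 2)
  text(1.2 * cos(ang), 1.2 * sin(ang),
       sprintf("%s\n%.1f", labs, vals), cex = 0.9)
  title("Physiological state")
  invisible(path)
}
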