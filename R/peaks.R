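#' Centred moving average with boundary truncation
#'
#' The trend at time `t` is the mean of all samples in
#' `[t - halfwidth, t + halfwidth]` intersected with the series span, i.e.
#' the window shrinks at the boundaries rather than padding. The +/-350 s
#' default separates slow overnight trends from fast event-locked
#' fluctuations on a 1 Hz grid.
#'
#' @param series Numeric vector sampled at 1 Hz.
#' @param halfwidth Window half-width in samples (seconds), >= 1.
#' @return Numeric vector of the same length.
#' @export
moving_average <- function(series, halfwidth = 350L) {
  if (length(series) == 0L) stop("empty series", call. = FALSE)
  if (halfwidth < 1L) stop("`halfwidth` must be >= 1", call. = FALSE)
  n <- length(series)
  h <- as.integer(halfwidth)
  cs <- cumsum(c(0, series))
  i <- seq_len(n)
  lo <- pmax(i - h, 1L)
  hi <- pmin(i + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Subtract the local moving-average trend
#'
#' `detrend(x, h) = x - moving_average(x, h)`; isolates fast fluctuations
#' such as event-locked heart-rate surges from the slow overnight decline.
#'
#' @inheritParams moving_average
#' @return Detrended series of the same length.
#' @export
detrend <- function(series, halfwidth = 350L) {
  series - moving_average(series, halfwidth)
}

#' Peak-detection configuration
#'
#' The detection rule: a peak is a maximal run of consecutive 1 Hz samples
#' strictly above the per-night `percentile` threshold (default 99) with run
#' length at least `min_run` (default 4, i.e. a triggering sample plus at
#' least three subsequent values above threshold); candidate peaks closer
#' than `min_separation` seconds (default 75, the event duration) are merged,
#' keeping the run with the larger maximum. For the heart-rate channel the
#' threshold is taken on detrended values (`channel_mode = "detrended"`); for
#' the noise channel on raw values.
#'
#' @param percentile Percentile rank of the threshold, in (0, 100).
#' @param min_run Minimum run length (consecutive seconds above threshold).
#' @param min_separation Minimum distance between distinct peak times, s.
#' @param channel_mode `"raw"` or `"detrended"`.
#' @param halfwidth Detrending half-window, s (used when detrended).
#' @param quantile_type Quantile algorithm passed to [stats::quantile()]
#'   (default 7, linear interpolation between order statistics).
#' @return A list of class `peak_config`.
#' @export
peak_config <- function(percentile = 99, min_run = 4L, min_separation = 75L,
                        channel_mode = c("raw", "detrended"),
                        halfwidth = 350L, quantile_type = 7L) {
  if (percentile <= 0 || percentile >= 100) {
    stop("`percentile` must lie strictly between 0 and 100", call. = FALSE)
  }
  if (min_run < 1L) stop("`min_run` must be >= 1", call. = FALSE)
  if (min_separation < 0L) stop("`min_separation` must be >= 0", call. = FALSE)
  structure(list(
    percentile = percentile,
    min_run = as.integer(min_run),
    min_separation = as.integer(min_separation),
    channel_mode = match.arg(channel_mode),
    halfwidth = as.integer(halfwidth),
    quantile_type = as.integer(quantile_type)
  ), class = "peak_config")
}

#' Detect peaks by the percentile run-length rule
#'
#' @param series Numeric 1 Hz series; element `i` is the sample at time
#'   `times[i]`.
#' @param config A `peak_config`.
#' @param times Sample times in seconds (default `0:(n-1)`).
#' @return A data frame of class `peak_set` with one row per peak:
#'   `t_peak` (time of the run maximum, earliest on ties), `run_start`,
#'   `run_end` (inclusive), `max_value`; attribute `threshold` carries the
#'   per-night threshold on the thresholded channel.
#' @export
detect_peaks <- function(series, config = peak_config(), times = NULL) {
  if (length(series) == 0L) stop("empty series", call. = FALSE)
  if (!inherits(config, "peak_config")) config <- do.call(peak_config, config)
  n <- length(series)
  if (is.null(times)) times <- seq_len(n) - 1L
  stopifnot(length(times) == n)

  x <- if (config$channel_mode == "detrended") {
    detrend(series, config$halfwidth)
  } else series
  thr <- stats::quantile(x, config$percentile / 100, names = FALSE,
                         type = config$quantile_type)

  above <- x > thr  # strict
  empty <- function() {
    structure(
      data.frame(t_peak = numeric(0), run_start = numeric(0),
                 run_end = numeric(0), max_value = numeric(0)),
      threshold = thr, class = c("peak_set", "data.frame")
    )
  }
  if (!any(above)) return(empty())

  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= config$min_run
  if (!any(keep)) return(empty())
  starts <- starts[keep]; ends <- ends[keep]

  cand <- lapply(seq_along(starts), function(k) {
    idx <- starts[k]:ends[k]
    j <- idx[which.max(x[idx])]  # which.max: earliest on ties
    list(t_peak = times[j], run_start = times[starts[k]],
         run_end = times[ends[k]], max_value = x[j])
  })

  # merge candidates closer than min_separation, keeping the larger maximum
  # (earlier on ties); scan in time order
  merged <- list(cand[[1L]])
  if (length(cand) > 1L) {
    for (k in 2:length(cand)) {
      last <- merged[[length(merged)]]
      cur <- cand[[k]]
      if (cur$t_peak - last$t_peak < config$min_separation) {
        if (cur$max_value > last$max_value) merged[[length(merged)]] <- cur
        # else keep `last` (covers ties: earlier run wins)
      } else {
        merged[[length(merged) + 1L]] <- cur
      }
    }
  }
  out <- do.call(rbind, lapply(merged, as.data.frame))
  rownames(out) <- NULL
  structure(out, threshold = thr, class = c("peak_set", "data.frame"))
}

#' Pair noise peaks with heart-rate peak occurrence in response windows
#'
#' For each noise peak at `t`, the response window is
#' `[t, min(t + horizon, t_next - curtail))` where `t_next` is the next noise
#' peak: the window is curtailed to end `curtail` seconds before the next
#' noise peak. A response occurred if any heart-rate peak time falls in the
#' window (inclusive start, exclusive end). Windows of non-positive length
#' are excluded with a reason code.
#'
#' @param noise_peaks,hr_peaks `peak_set` data frames (sorted by `t_peak`).
#' @param horizon Window length, s (default 180).
#' @param curtail Safety margin before the next noise peak, s (default 30).
#' @return A data frame of class `response_set`: `t_noise_peak`,
#'   `window_start`, `window_end`, `hr_peak_occurred` (logical, `NA` when
#'   excluded), `excluded`, `reason`.
#' @export
response_occurrence <- function(noise_peaks, hr_peaks, horizon = 180L,
                                curtail = 30L) {
  tn <- sort(noise_peaks$t_peak)
  th <- sort(hr_peaks$t_peak)
  if (length(tn) == 0L) {
    return(structure(
      data.frame(t_noise_peak = numeric(0), window_start = numeric(0),
                 window_end = numeric(0), hr_peak_occurred = logical(0),
                 excluded = logical(0), reason = character(0)),
      class = c("response_set", "data.frame")
    ))
  }
  nxt <- c(tn[-1L], Inf)
  w_start <- tn
  w_end <- pmin(tn + horizon, nxt - curtail)
  excluded <- w_end <= w_start
  occ <- rep(NA, length(tn))
  for (i in which(!excluded)) {
    occ[i] <- any(th >= w_start[i] & th < w_end[i])
  }
  out <- data.frame(
    t_noise_peak = tn,
    window_start = w_start,
    window_end = w_end,
    hr_peak_occurred = as.logical(occ),
    excluded = excluded,
    reason = ifelse(excluded, "window_curtailed_to_empty", "")
  )
  structure(out, class = c("response_set", "data.frame"))
}

#' Mean heart rate before vs after each noise peak
#'
#' Compares the mean heart rate over `[t - 120, t - 60)` (before) with the
#' mean over `[t, t + 60)` (after) for each noise peak at time `t`; each
#' window covers exactly 60 samples on the 1 Hz grid. Peaks whose windows
#' are not fully covered by the series are excluded with a reason.
#'
#' @param noise_peaks A `peak_set`.
#' @param hr_series Heart-rate series at 1 Hz.
#' @param times Sample times of `hr_series` (default `0:(n-1)`).
#' @return A data frame of class `response_set`: `t_noise_peak`,
#'   `hr_before`, `hr_after`, `delta` (`after - before`), `excluded`,
#'   `reason`.
#' @export
hr_before_after <- function(noise_peaks, hr_series, times = NULL) {
  n <- length(hr_series)
  if (is.null(times)) times <- seq_len(n) - 1L
  t0 <- times[1L]
  tn <- sort(noise_peaks$t_peak)
  res <- lapply(tn, function(tp) {
    before_idx <- which(times >= tp - 120 & times < tp - 60)
    after_idx <- which(times >= tp & times < tp + 60)
    if (length(before_idx) < 60L || length(after_idx) < 60L) {
      return(data.frame(t_noise_peak = tp, hr_before = NA_real_,
                        hr_after = NA_real_, delta = NA_real_,
                        excluded = TRUE, reason = "window_outside_trace"))
    }
    b <- mean(hr_series[before_idx])
    a <- mean(hr_series[after_idx])
    data.frame(t_noise_peak = tp, hr_before = b, hr_after = a, delta = a - b,
               excluded = FALSE, reason = "")
  })
  out <- if (length(res)) do.call(rbind, res) else {
    data.frame(t_noise_peak = numeric(0), hr_before = numeric(0),
               hr_after = numeric(0), delta = numeric(0),
               excluded = logical(0), reason = character(0))
  }
  rownames(out) <- NULL
  structure(out, class = c("response_set", "data.frame"))
}

#' Run the full per-night peak analysis
#'
#' Detects noise peaks (raw channel) and heart-rate peaks (detrended
#' channel) with the study defaults, then derives response-occurrence and
#' before/after records.
#'
#' @param night A `night_trace`.
#' @param noise_config,hr_config `peak_config`s for the two channels.
#' @param horizon,curtail See [response_occurrence()].
#' @return List with `noise_peaks`, `hr_peaks`, `occurrence`,
#'   `before_after`.
#' @export
analyse_night <- function(night,
                          noise_config = peak_config(channel_mode = "raw"),
                          hr_config = peak_config(channel_mode = "detrended"),
                          horizon = 180L, curtail = 30L) {
  stopifnot(inherits(night, "night_trace"))
  tr <- night$trace
  np <- detect_peaks(tr$noise_db, noise_config, times = tr$t)
  hp <- detect_peaks(tr$hr_bpm, hr_config, times = tr$t)
  list(
    noise_peaks = np,
    hr_peaks = hp,
    occurrence = response_occurrence(np, hp, horizon, curtail),
    before_after = hr_before_after(np, tr$hr_bpm, times = tr$t)
  )
}
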