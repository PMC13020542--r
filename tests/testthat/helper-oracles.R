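# Independent brute-force oracles. Deliberately written with explicit loops
# and no shared code with the package implementations.

bf_moving_average <- function(x, h) {
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - h)
    hi <- min(n, i + h)
    out[i] <- sum(x[lo:hi]) / (hi - lo + 1L)
  }
  out
}

# explicit run enumeration + pairwise merge scan; same stated semantics as
# detect_peaks (strictly-above threshold, run >= min_run, t_peak = earliest
# argmax, peaks < min_sep apart merged keeping the larger max, earlier on
# ties), different mechanics
bf_detect_peaks <- function(x, percentile = 99, min_run = 4L, min_sep = 75L,
                            times = seq_along(x) - 1L, qtype = 7L) {
  thr <- stats::quantile(x, percentile / 100, names = FALSE, type = qtype)
  n <- length(x)
  runs <- list()
  i <- 1L
  while (i <= n) {
    if (x[i] > thr) {
      j <- i
      while (j < n && x[j + 1L] > thr) j <- j + 1L
      if (j - i + 1L >= min_run) runs[[length(runs) + 1L]] <- c(i, j)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (!length(runs)) {
    return(data.frame(t_peak = numeric(0), run_start = numeric(0),
                      run_end = numeric(0), max_value = numeric(0)))
  }
  peaks <- list()
  for (r in runs) {
    idx <- r[1L]:r[2L]
    best <- idx[1L]
    for (ii in idx) if (x[ii] > x[best]) best <- ii
    peaks[[length(peaks) + 1L]] <-
      c(t_peak = times[best], run_start = times[r[1L]], run_end = times[r[2L]],
        max_value = x[best])
  }
  kept <- list(peaks[[1L]])
  if (length(peaks) > 1L) {
    for (k in 2:length(peaks)) {
      prev <- kept[[length(kept)]]
      cur <- peaks[[k]]
      if (cur[["t_peak"]] - prev[["t_peak"]] < min_sep) {
        if (cur[["max_value"]] > prev[["max_value"]]) {
          kept[[length(kept)]] <- cur
        }
      } else {
        kept[[length(kept) + 1L]] <- cur
      }
    }
  }
  out <- as.data.frame(do.call(rbind, kept))
  rownames(out) <- NULL
  out
}

# naive average-linkage agglomerative clustering; returns merge heights
bf_average_linkage_heights <- function(m) {
  clusters <- lapply(seq_len(nrow(m)), identity)
  d <- as.matrix(stats::dist(m))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA); bh <- Inf
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (a >= b) next
        dd <- mean(d[clusters[[a]], clusters[[b]]])
        if (dd < bh) { bh <- dd; best <- c(a, b) }
      }
    }
    heights <- c(heights, bh)
    clusters[[best[1L]]] <- c(clusters[[best[1L]]], clusters[[best[2L]]])
    clusters[[best[2L]]] <- NULL
  }
  heights
}

# small synthetic raw_trace builder
mk_raw <- function(ts, vals, label = "x") {
  structure(list(timestamps = ts, values = vals, source_label = label),
            class = "raw_trace")
}

# a short series with injected boxcar elevations for detection tests
boxcar_series <- function(n, onsets, width, height, base = 0) {
  x <- rep(base, n)
  for (on in onsets) x[on + seq_len(width)] <- base + height
  x
}

expect_same_peaks <- function(got, want) {
  expect_equal(nrow(got), nrow(want))
  if (nrow(want)) {
    expect_equal(got$t_peak, want$t_peak)
    expect_equal(got$run_start, want$run_start)
    expect_equal(got$run_end, want$run_end)
    expect_equal(got$max_value, want$max_value)
  }
}
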