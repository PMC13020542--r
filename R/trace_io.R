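#' Read a 1 Hz device trace
#'
#' Reads a two-column CSV (`timestamp`, `value`) exported by a recording
#' device. Timestamps may be integer/numeric seconds, epoch seconds, or ISO
#' 8601 date-times; they are normalized to seconds and validated as strictly
#' increasing with no duplicates.
#'
#' @param path CSV file path. A header row is detected automatically.
#' @param source_label Label for the channel, e.g. `"noise"` or `"hr"`.
#' @return A `raw_trace` object: list with `timestamps` (numeric seconds),
#'   `values`, `source_label`.
#' @export
read_trace <- function(path, source_label = "trace") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty trace file: ", path, call. = FALSE)
  first_data <- 1L
  # header if the first field of line 1 is non-numeric and not a date-time
  f1 <- strsplit(lines[1L], ",", fixed = TRUE)[[1L]][1L]
  if (is.na(suppressWarnings(as.numeric(f1))) && is.na(parse_wallclock(f1))) {
    first_data <- 2L
    if (length(lines) < 2L) stop("trace file has a header but no data: ", path,
                                 call. = FALSE)
  }
  data_lines <- lines[first_data:length(lines)]
  parts <- strsplit(data_lines, ",", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad)) {
    stop("parse error at line ", bad[1L] + first_data - 1L,
         ": expected two comma-separated columns", call. = FALSE)
  }
  ts_raw <- trimws(vapply(parts, `[[`, "", 1L))
  val_raw <- trimws(vapply(parts, `[[`, "", 2L))
  vals <- suppressWarnings(as.numeric(val_raw))
  if (anyNA(vals)) {
    ln <- which(is.na(vals))[1L]
    stop("parse error at line ", ln + first_data - 1L,
         ": non-numeric value '", val_raw[ln], "'", call. = FALSE)
  }
  ts <- suppressWarnings(as.numeric(ts_raw))
  if (anyNA(ts)) {
    ts2 <- parse_wallclock(ts_raw)
    if (anyNA(ts2)) {
      ln <- which(is.na(ts2))[1L]
      stop("parse error at line ", ln + first_data - 1L,
           ": unparseable timestamp '", ts_raw[ln], "'", call. = FALSE)
    }
    ts <- ts2
  }
  dup <- ts[duplicated(ts)]
  if (length(dup)) {
    stop("duplicate timestamp(s) in ", path, ": ",
         paste(utils::head(unique(dup), 5L), collapse = ", "), call. = FALSE)
  }
  if (is.unsorted(ts, strictly = TRUE)) {
    ooo <- which(diff(ts) <= 0)[1L]
    stop("timestamps not strictly increasing (first violation after t = ",
         ts[ooo], ")", call. = FALSE)
  }
  structure(list(timestamps = ts, values = vals, source_label = source_label),
            class = "raw_trace")
}

# ISO 8601 "YYYY-MM-DD HH:MM:SS" / "YYYY-MM-DDTHH:MM:SS" -> epoch seconds
parse_wallclock <- function(x) {
  x <- gsub("T", " ", x, fixed = TRUE)
  vapply(x, function(xi) {
    tryCatch(
      suppressWarnings(as.numeric(as.POSIXct(
        xi, tz = "UTC",
        tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M")))),
      error = function(e) NA_real_
    )
  }, numeric(1), USE.NAMES = FALSE)
}

#' Write a raw trace to CSV
#'
#' @param trace A `raw_trace`.
#' @param path Output CSV path (`timestamp,value` with header).
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "raw_trace"))
  utils::write.csv(
    data.frame(timestamp = trace$timestamps, value = trace$values),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Merge a noise trace and a heart-rate trace on synchronized timestamps
#'
#' Inner join on shared integer seconds: a second missing from either
#' channel is dropped (never interpolated). Timestamps are re-based to
#' seconds from the merged night start.
#'
#' @param noise,hr `raw_trace` objects for the sound-level (dB(A)) and
#'   heart-rate (bpm) channels.
#' @param participant,night_period,condition Optional annotation carried on
#'   the result.
#' @return A `night_trace` whose `trace` data frame has columns `t`
#'   (seconds from merged start), `noise_db`, `hr_bpm`; attribute `dropped`
#'   reports per-channel dropped-second counts.
#' @export
merge_traces <- function(noise, hr, participant = NA, night_period = NA,
                         condition = "unknown") {
  stopifnot(inherits(noise, "raw_trace"), inherits(hr, "raw_trace"))
  tn <- round(noise$timestamps)
  th <- round(hr$timestamps)
  shared <- intersect(tn, th)
  if (length(shared) == 0L) {
    stop("traces have no overlapping timestamps (noise: [",
         min(tn), ", ", max(tn), "], hr: [", min(th), ", ", max(th), "])",
         call. = FALSE)
  }
  shared <- sort(shared)
  df <- data.frame(
    t = as.integer(shared - shared[1L]),
    noise_db = noise$values[match(shared, tn)],
    hr_bpm = hr$values[match(shared, th)]
  )
  dropped <- c(noise = length(tn) - length(shared),
               hr = length(th) - length(shared))
  structure(
    list(trace = df,
         truth = NULL,
         condition = condition,
         participant = participant,
         night_period = night_period,
         dropped = dropped),
    class = "night_trace"
  )
}

#' Write a night trace (and optional ground truth) to CSV
#'
#' @param night A `night_trace`.
#' @param path Output CSV (`t,noise_db,hr_bpm`).
#' @param truth_path Optional sidecar CSV for ground-truth onsets
#'   (`kind,onset_s` rows with kinds `event`/`incidental`/`surge`).
#' @return `path`, invisibly.
#' @export
write_night <- function(night, path, truth_path = NULL) {
  stopifnot(inherits(night, "night_trace"))
  utils::write.csv(night$trace, path, row.names = FALSE, quote = FALSE)
  if (!is.null(truth_path) && !is.null(night$truth)) {
    tr <- night$truth
    df <- rbind(
      if (length(tr$event_onsets)) data.frame(kind = "event", onset_s = tr$event_onsets),
      if (length(tr$incidental_onsets)) data.frame(kind = "incidental", onset_s = tr$incidental_onsets),
      if (length(tr$surge_onsets)) data.frame(kind = "surge", onset_s = tr$surge_onsets)
    )
    if (is.null(df)) df <- data.frame(kind = character(0), onset_s = numeric(0))
    utils::write.csv(df, truth_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a merged night trace written by [write_night()]
#'
#' @param path CSV with columns `t`, `noise_db`, `hr_bpm`.
#' @param condition Optional condition annotation.
#' @return A `night_trace`.
#' @export
read_night <- function(path, condition = "unknown") {
  df <- utils::read.csv(path)
  need <- c("t", "noise_db", "hr_bpm")
  if (!all(need %in% names(df))) {
    stop("night trace file must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  structure(list(trace = df[need], truth = NULL, condition = condition),
            class = "night_trace")
}
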