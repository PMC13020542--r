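#' Exposure conditions of the crossover design
#'
#' The three overnight exposure conditions: a quiet control night, a night
#' with 30 recorded road-traffic-noise events ("noise30") and a night with 60
#' events ("noise60"). All condition columns in the package use this factor
#' level order.
#'
#' @return Character vector of the three condition labels.
#' @export
nn_conditions <- function() c("control", "noise30", "noise60")

#' The six randomization sequences of study nights
#'
#' Every permutation of the three conditions over the three study periods.
#'
#' @return A 6 x 3 character matrix; row i is the i-th sequence, column j the
#'   condition experienced in period j.
#' @export
nn_sequences <- function() {
  conds <- nn_conditions()
  perms <- rbind(
    c(1L, 2L, 3L), c(1L, 3L, 2L),
    c(2L, 1L, 3L), c(2L, 3L, 1L),
    c(3L, 1L, 2L), c(3L, 2L, 1L)
  )
  m <- matrix(conds[perms], nrow = 6L)
  rownames(m) <- apply(m, 1L, paste, collapse = "-")
  colnames(m) <- paste0("period", 1:3)
  m
}

#' Randomize participants over the six crossover sequences
#'
#' Assigns each participant one of the six condition orderings, keeping the
#' allocation as balanced as possible: assignment counts across sequences
#' never differ by more than one.
#'
#' @param n_participants Number of participants (default 74).
#' @param seed Optional integer seed; the assignment is deterministic given
#'   the seed.
#' @return An object of class `study_design`: a data frame with one row per
#'   participant and columns `participant`, `sequence` (1-6), and `period1`,
#'   `period2`, `period3` giving the condition of each night.
#' @examples
#' d <- make_design(74, seed = 1)
#' table(d$sequence)   # counts in {12, 13}
#' @export
make_design <- function(n_participants = 74L, seed = NULL) {
  if (!is.numeric(n_participants) || length(n_participants) != 1L ||
      is.na(n_participants) || n_participants < 1) {
    stop("`n_participants` must be a positive integer", call. = FALSE)
  }
  if (n_participants < 6) {
    stop("`n_participants` must be at least 6 to use all six sequences",
         call. = FALSE)
  }
  n <- as.integer(n_participants)
  if (!is.null(seed)) set.seed(seed)
  # blocks of 6 keep counts within 1 of each other; remainder drawn without
  # replacement so no sequence is over-used
  n_full <- n %/% 6L
  rem <- n %% 6L
  seq_ids <- c(rep(1:6, n_full), sample(1:6, rem))
  seq_ids <- sample(seq_ids)  # shuffle participant-to-sequence order
  seqs <- nn_sequences()
  out <- data.frame(
    participant = seq_len(n),
    sequence = seq_ids,
    period1 = seqs[seq_ids, 1L],
    period2 = seqs[seq_ids, 2L],
    period3 = seqs[seq_ids, 3L],
    stringsAsFactors = FALSE
  )
  class(out) <- c("study_design", "data.frame")
  out
}

#' Build the playback schedule for one exposure condition
#'
#' Each study-night sound file starts with a 30 s calibration tone and a
#' 40 min silent lead-in. Noise events last 75 s; the silent gap between the
#' end of one event and the onset of the next is 575 s in the 60-event
#' condition and 700 s in the 30-event condition, so consecutive onsets are
#' 650 s and 775 s apart. The control file contains no events; its span is
#' fixed at 23400 s (6.5 h). For the noise conditions the span is derived
#' from the event/gap constants (tone + lead-in + events + gaps).
#'
#' @param condition One of `"control"`, `"noise30"`, `"noise60"`.
#' @return An object of class `playback_schedule`: a list with fields
#'   `condition`, `tone_duration`, `lead_in_silence`, `n_events`,
#'   `event_duration`, `inter_event_gap`, `event_onsets` (seconds from night
#'   start, strictly increasing) and `total_span` (seconds).
#' @examples
#' s <- make_schedule("noise60")
#' s$event_onsets[1]        # 2430
#' diff(s$event_onsets)[1]  # 650
#' @export
make_schedule <- function(condition) {
  if (length(condition) != 1L || !condition %in% nn_conditions()) {
    stop("unknown condition: ", paste(condition, collapse = ", "),
         " (expected one of ", paste(nn_conditions(), collapse = ", "), ")",
         call. = FALSE)
  }
  tone <- 30L
  lead_in <- 2400L
  dur <- 75L
  n_events <- switch(condition, control = 0L, noise30 = 30L, noise60 = 60L)
  gap <- switch(condition, control = NA_integer_, noise30 = 700L, noise60 = 575L)
  first <- tone + lead_in
  if (n_events > 0L) {
    onsets <- first + (seq_len(n_events) - 1L) * (dur + gap)
    span <- tone + lead_in + n_events * dur + (n_events - 1L) * gap
  } else {
    onsets <- integer(0)
    span <- 23400L  # 6.5 h silent control file
  }
  structure(
    list(
      condition = condition,
      tone_duration = tone,
      lead_in_silence = lead_in,
      n_events = n_events,
      event_duration = dur,
      inter_event_gap = gap,
      event_onsets = onsets,
      total_span = as.integer(span)
    ),
    class = "playback_schedule"
  )
}

#' @export
print.playback_schedule <- function(x, ...) {
  cat(sprintf(
    "<playback_schedule> %s: %d events x %d s, gap %s s, span %d s (%.2f h)\n",
    x$condition, x$n_events, x$event_duration,
    ifelse(is.na(x$inter_event_gap), "-", x$inter_event_gap),
    x$total_span, x$total_span / 3600
  ))
  invisible(x)
}
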