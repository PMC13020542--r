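#' Parameters of the synthetic 1 Hz night trace
#'
#' Defaults encode the study conditions: a 30.7 dB(A) background (the
#' control-night LAeq), pass-by events peaking near 60 dB(A), and per-peak
#' heart-rate response probabilities back-calibrated so that the odds of a
#' response after a noise peak are 1.89-fold (control vs 30 events) and
#' 2.42-fold (control vs 60 events) higher in control nights.
#'
#' @param background_level Background sound level, dB(A).
#' @param background_jitter_sd SD of per-second background fluctuation, dB.
#' @param event_peak_level Apex level of scheduled pass-by events, dB(A).
#' @param apex_width Seconds of flat apex per event; must be >= the detection
#'   run length so every event contains a detectable run.
#' @param apex_jitter Max uniform jitter added on apex samples, dB.
#' @param incidental_peak_rate Expected unintended noise peaks per night
#'   (Poisson); they use the same pass-by profile with a lower apex.
#' @param incidental_level_range Apex range of incidental peaks, dB(A); must
#'   stay below `event_peak_level` so scheduled apexes dominate.
#' @param hr_baseline_start,hr_baseline_end Overnight heart-rate baseline,
#'   bpm, interpolated linearly over the night.
#' @param hr_noise_sd SD of per-second heart-rate fluctuation, bpm.
#' @param response_probability Named per-condition probability that a noise
#'   peak (scheduled or incidental) triggers a heart-rate surge.
#' @param response_amplitude Peak amplitude of a surge, bpm.
#' @param response_duration Surge duration, seconds.
#' @return A list of class `trace_params`.
#' @export
trace_params <- function(background_level = 30.7,
                         background_jitter_sd = 1.5,
                         event_peak_level = 60,
                         apex_width = 5L,
                         apex_jitter = 0.3,
                         incidental_peak_rate = 8,
                         incidental_level_range = c(45, 55),
                         hr_baseline_start = 64,
                         hr_baseline_end = 56,
                         hr_noise_sd = 1.5,
                         response_probability = c(control = 0.50,
                                                  noise30 = 0.35,
                                                  noise60 = 0.29),
                         response_amplitude = 6,
                         response_duration = 30L) {
  p <- list(
    background_level = background_level,
    background_jitter_sd = background_jitter_sd,
    event_peak_level = event_peak_level,
    apex_width = as.integer(apex_width),
    apex_jitter = apex_jitter,
    incidental_peak_rate = incidental_peak_rate,
    incidental_level_range = incidental_level_range,
    hr_baseline_start = hr_baseline_start,
    hr_baseline_end = hr_baseline_end,
    hr_noise_sd = hr_noise_sd,
    response_probability = response_probability,
    response_amplitude = response_amplitude,
    response_duration = as.integer(response_duration)
  )
  if (p$event_peak_level <= p$background_level + 10) {
    stop("`event_peak_level` must exceed `background_level` by more than 10 dB",
         call. = FALSE)
  }
  if (p$apex_width < 4L) stop("`apex_width` must be >= 4 s", call. = FALSE)
  if (any(p$response_probability < 0 | p$response_probability > 1)) {
    stop("`response_probability` values must lie in [0, 1]", call. = FALSE)
  }
  if (max(p$incidental_level_range) >= p$event_peak_level) {
    stop("incidental peaks must stay below `event_peak_level`", call. = FALSE)
  }
  class(p) <- "trace_params"
  p
}

# deterministic 75 s pass-by: half-cosine rise, flat apex, half-cosine fall
pass_by_profile <- function(duration, apex_width, base, peak) {
  rise <- (duration - apex_width) %/% 2L
  fall <- duration - apex_width - rise
  shape <- c(
    (1 - cos(pi * seq_len(rise) / (rise + 1L))) / 2,
    rep(1, apex_width),
    (1 + cos(pi * seq_len(fall) / (fall + 1L))) / 2
  )
  base + (peak - base) * shape
}

# heart-rate surge: 5 s linear rise then linear decay back to baseline
surge_profile <- function(amplitude, duration) {
  rise <- min(5L, duration)
  decay <- duration - rise
  c(amplitude * seq_len(rise) / rise,
    if (decay > 0) amplitude * rev(seq_len(decay)) / (decay + 1L))
}

#' Simulate one study night at 1 Hz
#'
#' Generates synchronized sound-level and heart-rate traces over the schedule
#' span. Scheduled events are smooth pass-by profiles whose flat apex
#' strictly exceeds every non-event sample; incidental (unintended) peaks use
#' the same profile at a lower level. Heart-rate surges start within 10 s of
#' a noise-peak onset with the condition's response probability. Ground-truth
#' onsets are returned alongside the trace.
#'
#' @param schedule A `playback_schedule` from [make_schedule()].
#' @param params A `trace_params` list.
#' @param seed Optional integer seed.
#' @param min_run Detection run length the apex must cover (configuration
#'   check only; default 4).
#' @return An object of class `night_trace`: list with `trace` (data frame
#'   `t`, `noise_db`, `hr_bpm`), `truth` (lists of `event_onsets`,
#'   `incidental_onsets`, `surge_onsets`), `condition`, `params`.
#' @export
simulate_night <- function(schedule, params = trace_params(), seed = NULL,
                           min_run = 4L) {
  stopifnot(inherits(schedule, "playback_schedule"))
  if (!inherits(params, "trace_params")) params <- do.call(trace_params, params)
  if (params$apex_width < min_run) {
    stop("`apex_width` (", params$apex_width,
         ") is below the detection run length (", min_run, ")", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- schedule$total_span
  t <- seq_len(n) - 1L

  noise <- params$background_level +
    if (params$background_jitter_sd > 0) {
      stats::rnorm(n, 0, params$background_jitter_sd)
    } else 0

  dur <- schedule$event_duration
  lay_profile <- function(noise, onset, profile) {
    idx <- onset + seq_along(profile)  # onset is 0-based, idx 1-based
    keep <- idx >= 1L & idx <= n
    noise[idx[keep]] <- pmax(noise[idx[keep]], profile[keep])
    noise
  }

  # per-sample jitter makes every pass-by distinct (no tied order statistics
  # across events); shoulders jitter downwards and apexes upwards so apex
  # samples strictly dominate all non-apex samples
  for (on in schedule$event_onsets) {
    prof <- pass_by_profile(dur, params$apex_width, params$background_level,
                            params$event_peak_level) +
      stats::runif(dur, -params$apex_jitter, 0)
    apex0 <- (dur - params$apex_width) %/% 2L
    prof[apex0 + seq_len(params$apex_width)] <-
      params$event_peak_level + stats::runif(params$apex_width, 0, params$apex_jitter)
    noise <- lay_profile(noise, on, prof)
  }

  # incidental peaks: away from scheduled events and from each other so they
  # remain distinct under the 75 s separation rule
  n_inc <- if (params$incidental_peak_rate > 0) {
    stats::rpois(1L, params$incidental_peak_rate)
  } else 0L
  inc_onsets <- integer(0)
  if (n_inc > 0L) {
    lo <- schedule$tone_duration + schedule$lead_in_silence
    taken <- schedule$event_onsets
    for (k in seq_len(n_inc)) {
      for (try in seq_len(200L)) {
        cand <- sample(seq(lo, n - dur - 1L), 1L)
        if (all(abs(cand - c(taken, inc_onsets)) >= 200L) || length(c(taken, inc_onsets)) == 0L) {
          inc_onsets <- c(inc_onsets, cand)
          break
        }
      }
    }
    inc_onsets <- sort(inc_onsets)
    for (on in inc_onsets) {
      peak <- stats::runif(1L, params$incidental_level_range[1L],
                           params$incidental_level_range[2L])
      prof <- pass_by_profile(dur, params$apex_width,
                              params$background_level, peak) +
        stats::runif(dur, -params$apex_jitter, 0)
      noise <- lay_profile(noise, on, prof)
    }
  }

  hr <- seq(params$hr_baseline_start, params$hr_baseline_end, length.out = n) +
    if (params$hr_noise_sd > 0) stats::rnorm(n, 0, params$hr_noise_sd) else 0

  # surges are locked to the event's acoustic apex (the detected peak time),
  # starting within 10 s of it, so a response falls inside the pairing
  # window [t_peak, t_peak + 180)
  apex_offset <- (dur - params$apex_width) %/% 2L
  p_resp <- params$response_probability[[schedule$condition]]
  all_onsets <- sort(c(schedule$event_onsets, inc_onsets))
  surge_onsets <- integer(0)
  if (length(all_onsets) > 0L && p_resp > 0) {
    fire <- stats::runif(length(all_onsets)) < p_resp
    for (on in all_onsets[fire]) {
      s_on <- on + apex_offset + sample(0:10, 1L)
      prof <- surge_profile(params$response_amplitude, params$response_duration)
      idx <- s_on + seq_along(prof)
      keep <- idx >= 1L & idx <= n
      hr[idx[keep]] <- hr[idx[keep]] + prof[keep]
      surge_onsets <- c(surge_onsets, s_on)
    }
  }

  structure(
    list(
      trace = data.frame(t = t, noise_db = noise, hr_bpm = hr),
      truth = list(event_onsets = schedule$event_onsets,
                   incidental_onsets = inc_onsets,
                   surge_onsets = surge_onsets),
      condition = schedule$condition,
      params = params
    ),
    class = "night_trace"
  )
}

#' Parameters of the synthetic crossover cohort
#'
#' Defaults are calibrated to the study's printed estimates: condition means
#' 9.35 / 8.19 / 7.73 % FMD, a vitamin-C effect of 1.02 % on the
#' post-intervention FMD change in the 60-event condition, and 31 of 74
#' participants receiving vitamin C. Variance components (participant SD 2.1,
#' residual SD 2.5) are back-derived from the printed 95% CIs (control-mean
#' SE 0.38 at n = 74) and paired-contrast P-values.
#'
#' @param fmd_condition_means Named per-condition FMD means, %.
#' @param fmd_participant_sd Between-participant SD of FMD, %.
#' @param fmd_residual_sd Within-participant residual SD, %.
#' @param period_effects Length-3 period effects, %, constrained to sum to 0.
#' @param vitc_effect Named per-condition additive vitamin-C effect on the
#'   FMD change, % (default: 1.02 at noise60 only).
#' @param n_vitc Number of participants receiving vitamin C.
#' @param change_participant_sd,change_residual_sd Variance components of the
#'   FMD-change outcome, %.
#' @param relative_change If TRUE emit `(second - first)/first` instead of
#'   the absolute difference.
#' @return A list of class `cohort_params`.
#' @export
cohort_params <- function(fmd_condition_means = c(control = 9.35,
                                                  noise30 = 8.19,
                                                  noise60 = 7.73),
                          fmd_participant_sd = 2.1,
                          fmd_residual_sd = 2.5,
                          period_effects = c(0, 0, 0),
                          vitc_effect = c(control = 0, noise30 = 0,
                                          noise60 = 1.02),
                          n_vitc = 31L,
                          change_participant_sd = 1.0,
                          change_residual_sd = 2.3,
                          relative_change = FALSE) {
  if (abs(sum(period_effects)) > 1e-8) {
    stop("`period_effects` must sum to 0 for identifiability", call. = FALSE)
  }
  stopifnot(length(period_effects) == 3L,
            all(nn_conditions() %in% names(fmd_condition_means)),
            fmd_participant_sd >= 0, fmd_residual_sd >= 0)
  structure(list(
    fmd_condition_means = fmd_condition_means,
    fmd_participant_sd = fmd_participant_sd,
    fmd_residual_sd = fmd_residual_sd,
    period_effects = period_effects,
    vitc_effect = vitc_effect,
    n_vitc = as.integer(n_vitc),
    change_participant_sd = change_participant_sd,
    change_residual_sd = change_residual_sd,
    relative_change = relative_change
  ), class = "cohort_params")
}

#' Simulate the crossover outcome table
#'
#' One row per participant-period with the night's condition and outcomes
#' drawn from the additive crossover model
#' `mean(condition) + period effect + participant intercept + residual`.
#' Secondary endpoints (mean and maximum night heart rate, a sleep-quality
#' score) follow the same structure with their own calibrated effects.
#'
#' @param design A `study_design` from [make_design()].
#' @param params A `cohort_params` list.
#' @param seed Optional integer seed.
#' @return A `crossover_cohort` data frame with columns `participant`,
#'   `period`, `condition`, `fmd_pct`, `vitc`, `fmd_change_pct`,
#'   `hr_mean_bpm`, `hr_max_bpm`, `sleep_quality`.
#' @export
simulate_cohort <- function(design, params = cohort_params(), seed = NULL) {
  stopifnot(inherits(design, "study_design"))
  if (!inherits(params, "cohort_params")) params <- do.call(cohort_params, params)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(design)
  b_fmd <- stats::rnorm(n, 0, params$fmd_participant_sd)
  b_chg <- stats::rnorm(n, 0, params$change_participant_sd)
  # keep both intervention groups present even in small smoke cohorts
  n_vitc_eff <- if (params$n_vitc >= n) n %/% 2L else params$n_vitc
  vitc_ids <- sort(sample(design$participant, n_vitc_eff))

  # secondary-endpoint condition effects (bpm / score units): night heart
  # rate +1.23 bpm and maximum heart rate +7.95 bpm at 60 events vs control,
  # max +0.57 at 30 events; sleep quality degrades under noise
  hr_mean_eff <- c(control = 0, noise30 = 0.4, noise60 = 1.23)
  hr_max_eff <- c(control = 0, noise30 = 0.57, noise60 = 7.95)
  sleep_eff <- c(control = 0, noise30 = -1.0, noise60 = -1.4)
  b_hr <- stats::rnorm(n, 0, 4)

  rows <- vector("list", 3L)
  for (per in 1:3) {
    cond <- design[[paste0("period", per)]]
    fmd <- params$fmd_condition_means[cond] + params$period_effects[per] +
      b_fmd + stats::rnorm(n, 0, params$fmd_residual_sd)
    vitc <- as.integer(design$participant %in% vitc_ids)
    chg <- vitc * params$vitc_effect[cond] + b_chg +
      stats::rnorm(n, 0, params$change_residual_sd)
    if (params$relative_change) chg <- chg / pmax(fmd, 1)
    rows[[per]] <- data.frame(
      participant = design$participant,
      period = per,
      condition = cond,
      fmd_pct = unname(fmd),
      vitc = vitc,
      fmd_change_pct = unname(chg),
      hr_mean_bpm = 60 + hr_mean_eff[cond] + b_hr + stats::rnorm(n, 0, 2),
      hr_max_bpm = 85 + hr_max_eff[cond] + b_hr + stats::rnorm(n, 0, 6),
      sleep_quality = 7.5 + sleep_eff[cond] + stats::rnorm(n, 0, 1.5),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$participant, out$period), ]
  rownames(out) <- NULL
  class(out) <- c("crossover_cohort", "data.frame")
  out
}

#' Parameters of the synthetic NPX protein matrix
#'
#' @param n_proteins Number of panel proteins (default 179, the two combined
#'   CVD/inflammation panels).
#' @param n_subjects Subjects with matched pre/post samples (default 40, the
#'   responder analysis set).
#' @param responder_protein_count Proteins truly associated with the FMD
#'   response (default 12).
#' @param responder_shift Post-minus-pre shift of those proteins in strong
#'   responders, NPX (log2) units.
#' @param baseline_sd Technical/biological SD of an NPX value.
#' @return A list of class `proteome_params`.
#' @export
proteome_params <- function(n_proteins = 179L,
                            n_subjects = 40L,
                            responder_protein_count = 12L,
                            responder_shift = 3,
                            baseline_sd = 1) {
  if (responder_protein_count > n_proteins) {
    stop("`responder_protein_count` cannot exceed `n_proteins`", call. = FALSE)
  }
  structure(list(
    n_proteins = as.integer(n_proteins),
    n_subjects = as.integer(n_subjects),
    responder_protein_count = as.integer(responder_protein_count),
    responder_shift = responder_shift,
    baseline_sd = baseline_sd
  ), class = "proteome_params")
}

#' Simulate an NPX (log2) protein matrix with matched pre/post samples
#'
#' Protein baselines are drawn once per protein; each sample adds Gaussian
#' NPX noise. In subjects whose `fmd_changes` magnitude is in the top half,
#' `responder_protein_count` proteins are shifted by `responder_shift` NPX in
#' the post sample (one NPX = doubled concentration).
#'
#' @param params A `proteome_params` list.
#' @param fmd_changes Numeric vector of per-subject noise-induced FMD
#'   changes, length `n_subjects`; names become subject ids.
#' @param seed Optional integer seed.
#' @return An `npx_matrix` object: list with `npx` (proteins x samples
#'   matrix, columns `<subject>_pre` / `<subject>_post`), `annotation`
#'   (sample data frame), `truth` (shifted protein ids and strong-responder
#'   subject ids).
#' @export
simulate_npx <- function(params = proteome_params(), fmd_changes, seed = NULL) {
  if (!inherits(params, "proteome_params")) params <- do.call(proteome_params, params)
  if (length(fmd_changes) != params$n_subjects) {
    stop("`fmd_changes` must have length n_subjects = ", params$n_subjects,
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  subjects <- names(fmd_changes)
  if (is.null(subjects)) subjects <- sprintf("S%02d", seq_along(fmd_changes))
  proteins <- sprintf("P%03d", seq_len(params$n_proteins))

  # top half of |fmd_change| = strong responders (ties by subject order)
  ord <- order(-abs(fmd_changes), seq_along(fmd_changes))
  strong <- subjects[ord[seq_len(params$n_subjects %/% 2L)]]
  shifted <- if (params$responder_protein_count > 0L) {
    sample(proteins, params$responder_protein_count)
  } else character(0)

  base <- stats::rnorm(params$n_proteins, 5, 2)  # protein-specific abundance
  n_s <- params$n_subjects
  pre <- base + matrix(stats::rnorm(params$n_proteins * n_s, 0, params$baseline_sd),
                       nrow = params$n_proteins)
  post <- base + matrix(stats::rnorm(params$n_proteins * n_s, 0, params$baseline_sd),
                        nrow = params$n_proteins)
  post[proteins %in% shifted, subjects %in% strong] <-
    post[proteins %in% shifted, subjects %in% strong] + params$responder_shift

  npx <- cbind(pre, post)
  rownames(npx) <- proteins
  colnames(npx) <- c(paste0(subjects, "_pre"), paste0(subjects, "_post"))
  annotation <- data.frame(
    sample = colnames(npx),
    subject = rep(subjects, 2L),
    timepoint = rep(c("pre", "post"), each = n_s),
    fmd_change = rep(unname(fmd_changes), 2L),
    stringsAsFactors = FALSE
  )
  structure(
    list(npx = npx, annotation = annotation,
         truth = list(shifted_proteins = sort(shifted),
                      strong_responders = strong)),
    class = "npx_matrix"
  )
}

#' Simulate a per-peak response dataset with known occurrence probabilities
#'
#' Generates the binary heart-rate-response records that the occurrence
#' GLMM consumes, with a participant random intercept on the logit scale, so
#' that odds-ratio recovery can be checked against a known truth.
#'
#' @param n_participants Participants (each contributes all conditions).
#' @param peaks_per_night Noise peaks per participant-night.
#' @param prob Named per-condition response probability (conditional on a
#'   zero random intercept).
#' @param re_sd SD of the participant random intercept, logit scale.
#' @param conditions Conditions to include.
#' @param seed Optional integer seed.
#' @return A data frame with `participant`, `period`, `condition`,
#'   `hr_peak_occurred`.
#' @export
simulate_occurrence_data <- function(n_participants = 40L,
                                     peaks_per_night = 25L,
                                     prob = c(control = 0.4, noise30 = 0.2),
                                     re_sd = 0.5,
                                     conditions = names(prob),
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  b <- stats::rnorm(n_participants, 0, re_sd)
  rows <- list()
  for (p in seq_len(n_participants)) {
    # randomized condition order per participant so period is not collinear
    # with condition (crossover structure)
    ord <- sample(conditions)
    for (per in seq_along(ord)) {
      cond <- ord[per]
      eta <- stats::qlogis(prob[[cond]]) + b[p]
      occ <- stats::rbinom(peaks_per_night, 1L, stats::plogis(eta))
      rows[[length(rows) + 1L]] <- data.frame(
        participant = p,
        period = per,
        condition = cond,
        hr_peak_occurred = occ,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
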