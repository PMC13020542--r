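test_that("make_design balances participants over the six sequences", {
  d <- make_design(74, seed = 1)
  expect_equal(nrow(d), 74)
  counts <- table(d$sequence)
  expect_length(counts, 6)
  expect_true(all(counts %in% c(12, 13)))

  d6 <- make_design(6, seed = 2)
  expect_equal(sort(unique(d6$sequence)), 1:6)
  expect_equal(as.integer(table(d6$sequence)), rep(1L, 6))

  # every row's ordering is a permutation of the three conditions
  perms <- apply(d[, c("period1", "period2", "period3")], 1L, sort)
  expect_true(all(apply(perms, 2L, identical, nn_conditions())))

  expect_identical(make_design(31, seed = 7), make_design(31, seed = 7))
  expect_error(make_design(0), "positive")
  expect_error(make_design(5), "at least 6")
})

test_that("make_schedule reproduces the printed playback constants", {
  s60 <- make_schedule("noise60")
  expect_equal(s60$n_events, 60)
  expect_equal(s60$event_duration, 75)
  expect_equal(s60$inter_event_gap, 575)
  expect_equal(s60$event_onsets[1], 2430)  # 30 s tone + 2400 s lead-in
  expect_equal(unique(diff(s60$event_onsets)), 650)
  expect_equal(s60$total_span,
               30 + 2400 + 60 * 75 + 59 * 575)

  s30 <- make_schedule("noise30")
  expect_equal(s30$n_events, 30)
  expect_equal(s30$inter_event_gap, 700)
  # gap between event end and next onset is exactly 700 s
  expect_equal(unique(diff(s30$event_onsets)) - s30$event_duration, 700)
  expect_equal(s30$total_span, 30 + 2400 + 30 * 75 + 29 * 700)

  sc <- make_schedule("control")
  expect_equal(sc$n_events, 0)
  expect_length(sc$event_onsets, 0)

  expect_error(make_schedule("noise90"), "unknown condition")
})

test_that("simulate_night lays down events, truth channels and surges", {
  night <- simulate_night(make_schedule("noise60"), seed = 11)
  expect_length(night$truth$event_onsets, 60)
  expect_equal(nrow(night$trace), make_schedule("noise60")$total_span)
  expect_true(all(diff(night$trace$t) == 1))

  # apex reaches ~ the configured peak level
  p <- trace_params()
  expect_gte(max(night$trace$noise_db), p$event_peak_level)
  expect_lte(max(night$trace$noise_db), p$event_peak_level + p$apex_jitter)

  # every scheduled apex strictly exceeds every non-event sample
  dur <- 75L
  ev_idx <- unlist(lapply(night$truth$event_onsets,
                          function(on) on + seq_len(dur)))
  expect_gt(min(night$trace$noise_db[ev_idx][
    night$trace$noise_db[ev_idx] >= p$event_peak_level]),
    max(night$trace$noise_db[-ev_idx]))

  # apex coverage below 1% of the night (99th percentile sits under apexes)
  expect_lt(60 * p$apex_width / nrow(night$trace), 0.01)

  # surge onsets within 10 s of a noise-peak apex (onset + 35 s rise)
  if (length(night$truth$surge_onsets)) {
    apexes <- sort(c(night$truth$event_onsets,
                     night$truth$incidental_onsets)) + 35
    gaps <- vapply(night$truth$surge_onsets,
                   function(s) min(s - apexes[apexes <= s]), numeric(1))
    expect_true(all(gaps >= 0 & gaps <= 10))
  }
})

test_that("degenerate control night is a constant trace", {
  p <- trace_params(background_jitter_sd = 0, incidental_peak_rate = 0,
                    hr_noise_sd = 0)
  night <- simulate_night(make_schedule("control"), p, seed = 1)
  expect_equal(unique(night$trace$noise_db), p$background_level)
  expect_length(night$truth$incidental_onsets, 0)
})

test_that("night simulation is bit-reproducible for a fixed seed", {
  a <- simulate_night(make_schedule("noise30"), seed = 42)
  b <- simulate_night(make_schedule("noise30"), seed = 42)
  expect_identical(a, b)
})

test_that("trace parameter validation enforces the stated invariants", {
  expect_error(trace_params(event_peak_level = 39), "10 dB")
  expect_error(trace_params(apex_width = 3), ">= 4")
  expect_error(trace_params(response_probability = c(control = 1.2,
                                                     noise30 = 0.2,
                                                     noise60 = 0.2)),
               "\\[0, 1\\]")
  expect_error(simulate_night(make_schedule("control"),
                              trace_params(apex_width = 4), min_run = 5),
               "run length")
})

test_that("simulate_cohort follows the additive crossover model", {
  d <- make_design(74, seed = 3)
  # degenerate: no noise at all -> outcomes equal the generating means
  p0 <- cohort_params(fmd_participant_sd = 0, fmd_residual_sd = 0)
  coh0 <- simulate_cohort(d, p0, seed = 1)
  expect_equal(unique(coh0$fmd_pct[coh0$condition == "control"]), 9.35)
  expect_equal(unique(coh0$fmd_pct[coh0$condition == "noise30"]), 8.19)
  expect_equal(unique(coh0$fmd_pct[coh0$condition == "noise60"]), 7.73)

  # structure: one row per participant-period, 31 vitamin-C participants
  coh <- simulate_cohort(d, seed = 2)
  expect_equal(nrow(coh), 74 * 3)
  expect_equal(max(table(coh$participant, coh$period)), 1)
  expect_equal(sum(coh$vitc) / 3, 31)

  expect_identical(simulate_cohort(d, seed = 9), simulate_cohort(d, seed = 9))

  # empirical condition means approach the configured means (MC over seeds)
  means <- rowMeans(vapply(1:30, function(s) {
    co <- simulate_cohort(d, seed = s)
    tapply(co$fmd_pct, factor(co$condition, nn_conditions()), mean)
  }, numeric(3)))
  expect_equal(unname(means), c(9.35, 8.19, 7.73), tolerance = 0.05)

  expect_error(cohort_params(period_effects = c(1, 0, 0)), "sum to 0")
})

test_that("simulate_npx shifts responder proteins in strong responders", {
  fc <- stats::setNames(seq(-4, 4, length.out = 40), sprintf("S%02d", 1:40))
  npx <- simulate_npx(proteome_params(), fc, seed = 1)
  expect_equal(dim(npx$npx), c(179, 80))
  expect_length(npx$truth$shifted_proteins, 12)
  expect_length(npx$truth$strong_responders, 20)

  # null mode: no protein differs in expectation between groups
  npx0 <- simulate_npx(proteome_params(responder_shift = 0,
                                       responder_protein_count = 0), fc,
                       seed = 2)
  chg <- pairwise_change(npx0)
  expect_lt(max(abs(colMeans(chg))), 1.5)  # 0 +/- noise at sd 1/sqrt(40)*sqrt(2)

  # large shift separates groups on the shifted proteins
  chg1 <- pairwise_change(npx)
  strong <- rownames(chg1) %in% npx$truth$strong_responders
  sh <- npx$truth$shifted_proteins
  gap <- colMeans(chg1[strong, sh, drop = FALSE]) -
    colMeans(chg1[!strong, sh, drop = FALSE])
  expect_true(all(gap > 1.5))  # shift is 3 NPX

  expect_error(simulate_npx(proteome_params(responder_protein_count = 200),
                            fc), "cannot exceed")
  expect_error(simulate_npx(proteome_params(), fc[1:10]), "length")
})

test_that("simulate_occurrence_data injects the requested per-peak odds", {
  d <- simulate_occurrence_data(n_participants = 200, peaks_per_night = 40,
                                prob = c(control = 0.4, noise30 = 0.2),
                                re_sd = 0, seed = 1)
  p_hat <- tapply(d$hr_peak_occurred, d$condition, mean)
  expect_equal(as.numeric(p_hat[c("control", "noise30")]), c(0.4, 0.2),
               tolerance = 0.03)
})
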