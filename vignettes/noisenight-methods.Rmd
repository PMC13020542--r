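---
title: "Models and methods behind noisenight"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind noisenight}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noisenight)
```

# The study design the package models

`noisenight` implements the analysis pipeline of a randomized, double-blind
crossover exposure study: each participant sleeps through three study nights
— a quiet control night and two nights with 30 or 60 recorded road-traffic
pass-by events — in one of the six possible condition orderings. Sound level
(dB(A)) and heart rate (bpm) are recorded at 1 Hz through each night;
endothelial function is measured the next morning as flow-mediated dilation
(FMD, % diameter increase of the brachial artery after cuff-induced
hyperaemia); a subgroup receives high-dose vitamin C after the first morning
FMD, with a second measurement two hours later; and plasma is profiled on
two targeted proteomic panels (179 proteins, NPX log2 units).

Because individual-level data from such studies are not public, the package
ships a first-class synthetic-data module that generates every input with
known ground truth. All statistical machinery is written against the data
contracts, not the generator, so the same functions run on real exported
traces and cohort tables.

# The playback schedule

Every study-night sound file starts with a 30 s calibration tone and a
40 min (2400 s) silent lead-in, so the first event onset is at 2430 s.
Events last 75 s. The silent gap between the end of one event and the next
onset is 575 s in the 60-event condition and 700 s in the 30-event
condition, giving onset-to-onset spacings of 650 s and 775 s. The total
span is derived from these constants:

* 60 events: 30 + 2400 + 60·75 + 59·575 = 40855 s (≈11.3 h)
* 30 events: 30 + 2400 + 30·75 + 29·700 = 24980 s (≈6.9 h)

The event/gap constants imply a 60-event night much longer than the
"≈6.5 h" nominal file length reported for the recordings; the constants are
exact while the file length is approximate, so the generator follows the
constants and derives the span from them. We also considered reading the
gaps as onset-to-onset intervals, but that reading does not reproduce a
6.5 h file for the 60-event condition either (2430 + 59·575 + 75 ≈ 10.2 h),
so the literal between-events reading was kept. The control file has no
events; its span is fixed at 23400 s (6.5 h, the nominal file length).

# The synthetic night trace

**Noise channel.** Background is Gaussian around 30.7 dB(A) (the
control-night equivalent level) with SD 1.5 dB. Each scheduled event is a
smooth pass-by: half-cosine rise over 35 s, a flat 5 s apex at 60 dB(A)
(the nominal peak level), half-cosine fall. Apex samples carry small
positive jitter (U(0, 0.3) dB) and all other profile samples small negative
jitter (U(−0.3, 0)), so that (i) every pass-by is distinct — no tied order
statistics across the 60 otherwise identical profiles, which would bias the
within-night percentile rank of the detection threshold — and (ii) apex
samples strictly dominate every non-event sample. Incidental (unintended)
noise peaks use the same profile with apexes drawn from U(45, 55) dB(A), a
Poisson(8) count per night, and onsets kept ≥200 s from other peaks. Their
levels sit below the per-night 99th-percentile threshold on event nights
(where the threshold lands on the event shoulders, above 55 dB) but above
it on control nights — reproducing the qualitative behaviour that control
nights yield detectable incidental peaks.

**Heart-rate channel.** A linear overnight decline from 64 to 56 bpm (the
simplest trend the ±350 s moving average must remove) plus Gaussian noise
(SD 1.5 bpm). With a per-condition probability, each noise peak triggers a
surge: 5 s linear rise to 6 bpm, linear decay over 25 s, starting within
10 s of the event's acoustic apex. Locking surges to the apex rather than
the event onset is deliberate: the response-pairing window starts at the
*detected* noise-peak time, which is the apex, and a surge locked to the
onset of a centred 75 s pass-by would peak ~30 s before the noise peak and
never register as a response.

The per-peak response probabilities (0.50 control, 0.35 at 30 events, 0.29
at 60 events) are back-calibrated from the printed occurrence odds ratios:
taking control odds of 1, odds ratios of 1.89 and 2.42 give noise odds of
0.53 and 0.41, i.e. probabilities 0.35 and 0.29.

**What the generator does not emulate.** Real traces have autocorrelated
background noise, movement artefacts, missing seconds, device clock drift,
sleep-stage structure in heart rate, and habituation across nights. A green
test on synthetic nights therefore establishes the *algorithmic* contract
(the detector finds exactly what the generator injected, models recover the
generating parameters) — not field performance on noisy recordings.

# Peak detection

The detection rule, applied per participant-night and per channel:

1. The slow trend is the centred moving average with window ±350 s,
   truncated at the night's boundaries. The heart-rate channel is detrended
   (observed minus trend) before thresholding; the noise channel is
   thresholded on raw values. Both behaviours sit behind `channel_mode`
   because the source text detrends both channels yet thresholds "the noise
   level".
2. The threshold is the 99th percentile of the night's (possibly
   detrended) samples, computed with linear interpolation between order
   statistics (`stats::quantile` type 7); exceedance is strict. Neither
   choice is prescribed by the source; both are configurable.
3. A candidate peak is a maximal run of consecutive samples strictly above
   the threshold with length ≥ `min_run`. The default is 4, reading "at
   least three subsequent values above this threshold" literally as the
   triggering sample plus ≥3 more; the alternative reading (run ≥ 3) is one
   `peak_config(min_run = 3)` away.
4. The peak time is the earliest maximum within the run. Candidates whose
   peak times are closer than 75 s (the event duration) are merged in time
   order, keeping the run with the larger maximum (earlier run on ties).

A constant series has no sample strictly above its own percentile and
yields zero peaks.

**Response pairing.** For each noise peak at `t`, the response window is
`[t, min(t + 180, t_next − 30))`, half-open on the 1 Hz grid; a heart-rate
peak inside it counts as a response. Windows curtailed to non-positive
length are excluded with a reason code rather than counted as
non-occurrence — the source does not say which was done; exclusion was
chosen because an empty window cannot observe a response. Before/after
comparisons use the half-open 60-sample means over `[t−120, t−60)` and
`[t, t+60)`; half-open windows make both means cover exactly 60 samples,
resolving the bracket ambiguity at 1 s resolution.

# Crossover models

All quantitative endpoints use a linear mixed model with exposure condition
and period (first/second/third night) as fixed effects and a participant
random intercept:

$$y_{ij} = \mu + \beta_{\text{cond}(i,j)} + \gamma_{\text{period}(j)}
  + b_i + \varepsilon_{ij}, \qquad b_i \sim N(0, \sigma_b^2),\;
  \varepsilon_{ij} \sim N(0, \sigma^2).$$

Condition means are estimated marginal means: fixed-effect design rows
averaged over the period levels with equal weights, computed directly from
the `lme4` fit (the reference-grid construction usually delegated to
`emmeans`, which is not a dependency here). Pairwise differences, Wald 95%
intervals and normal-approximation P-values follow. Heart-rate-peak
occurrence uses the same fixed/random structure with a logit link
(`lme4::glmer`, Laplace approximation); exponentiated contrasts are odds
ratios. No multiplicity adjustment is applied across pairwise comparisons
(matching the original analysis); the output metadata says so.

Two deliberate approximations: inference is large-sample Wald (the original
degrees-of-freedom method, fitted in commercial software, is unstated), and
per-period odds-ratio rows come from per-period subset fits
(`condition + (1 | participant)`) because a single main-effects model cannot
produce period-varying odds ratios; the "all" row comes from the full
period-adjusted model. With zero-variance (degenerate) outcomes `lmer`
cannot fit; the code falls back to the fixed-effects linear model and flags
the fit as singular rather than failing.

The vitamin-C analysis models the post-intervention FMD change with
exposure and intervention as fixed effects and a participant random
intercept; per-condition intervention contrasts come from the
exposure×intervention interaction model, the pooled contrast from the
main-effects model. The FMD change is emitted as the absolute difference
(second FMD − first FMD) by default; the exact definition of the original
"relative change" is not given, so a relative variant
(`relative_change = TRUE`) is provided.

**Calibration of the cohort generator.** Condition means default to the
printed estimates 9.35 / 8.19 / 7.73 % FMD. Variance components are
back-derived from printed uncertainty: the control-mean 95% CI half-width
(0.745 at n = 74) gives a total SD ≈ 3.27; the paired-contrast P-value
(Δ = 1.16, P = 0.005) gives a within-participant SD ≈ 2.5, leaving a
between-participant SD ≈ 2.1. The vitamin-C effect defaults to +1.02 % at
60 events only (the only printed trend), with FMD-change variance components
(participant 1.0, residual 2.3) matched to the printed contrast SE ≈ 0.6 at
group sizes 31 vs 43. Period effects default to zero and are constrained to
sum to zero for identifiability.

# Proteomics workflow

NPX values are log2-scale relative quantifications (+1 NPX = doubled
concentration). The workflow: per-subject pre/post change (post − pre);
responder stratification — the 20 subjects with the lowest noise-induced
FMD changes ("strong" responders, largest impairment) versus the 20 with
the highest ("weak"), ties broken by subject order; per-protein Student's
t-tests between groups with retention at unadjusted P < 0.05 (the Methods
threshold; the looser P < 0.1 used for network display is available via
`p_threshold`, and an off-by-default Benjamini–Hochberg option exists);
per-group mean changes z-normalized per protein and clustered by Euclidean
distance with average linkage (the linkage is unspecified in the source;
average is the common heat-map default and is configurable); centred PCA of
the change matrix; and interaction-network filtering of a user-supplied
edge list at score > 0.4 (strict). Zero-variance proteins get P = 1 when
group means are equal and P = 0 (retained) otherwise, so constant proteins
cannot crash the scan. The z-normalization step is applied to group means
(not per-subject fold-changes) — the source wording is ambiguous about the
order; normalizing means matches the two-column heat map it describes.

The NPX generator draws protein-specific baselines N(5, 2), adds
per-sample noise (SD 1 NPX), and shifts a configurable set of proteins
(default 12) by +3 NPX in the post samples of subjects in the top half of
|FMD change|. Under the null (shift 0) the retention rate of the t-test
scan matches the 5% threshold; at shift 3 the injected proteins separate
with t ≈ 6–10 and recall ≥ 95%.

# Pipeline, determinism and budgets

`run_full_study()` fans a single seed out into fixed per-stage child seeds
(design, nights, cohort, proteomics, edges), so stages are independently
reproducible and two runs of the same configuration produce byte-identical
outputs (the echoed config differs only in its output path). Night
simulation and detection for the full 74×3 design run in a few minutes on
one CPU; the test suite exercises the pipeline at smoke scale (6
participants) and the acceptance checks use the replicate counts stated in
their criteria (50 nights, 200–500 cohorts, 200 proteomic/GLMM
replicates), with the cohort-recovery replicate count set to 500 because
the 93–97% coverage band requires a Monte-Carlo standard error of about one
percentage point.

# Known limitations

* Synthetic acoustics are schematic: no A-weighting, no spectral content,
  and no attempt to reproduce the printed equivalent levels (41.36 and
  44.13 dB LAeq) for the noise nights, which would require the events'
  spectral profile.
* Wald intervals can be slightly anticonservative in small subgroups; the
  vitamin-C subgroup analysis (31 vs 43) inherits the original study's low
  power.
* The occurrence model treats peaks within a night as conditionally
  independent given the participant intercept; real heart-rate peak trains
  are serially dependent.
* Questionnaire endpoints are generated as generic crossover outcomes;
  instrument scoring is out of scope.
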