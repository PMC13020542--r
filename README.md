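# noisenight

Simulation and analysis of acute night-time road-traffic-noise crossover
studies.

## The problem

Night-time road traffic noise is the dominant environmental noise source in
Europe and an established cardiovascular risk factor, but controlled human
exposure data are scarce and rarely shared at the individual level. The
reference design this package targets is a randomized, double-blind,
three-period crossover: each of 74 healthy adults sleeps through a quiet
control night and two exposure nights with 30 or 60 recorded pass-by events
(75 s each, peak ≈60 dB(A)), in one of the six condition orderings. Sound
level and heart rate are logged at 1 Hz all night; flow-mediated dilation
(FMD, the endothelial-function endpoint, in %) is measured each morning; a
subgroup takes 2 g vitamin C after the first morning measurement; and
plasma is profiled on two Olink-style panels (179 proteins, NPX log2
units).

`noisenight` is for biostatisticians and environmental-health researchers
who want this entire analysis chain as tested, reusable code — and a
synthetic-data generator with known ground truth so every stage can be
validated without access to participant data.

## What it computes

**Peak detection (per participant-night, 1 Hz).** Slow trends are removed
with a centred ±350 s moving average. A *peak* is a maximal run of at least
`min_run = 4` consecutive samples strictly above the night's 99th-percentile
threshold (raw values for noise, detrended values for heart rate); peaks
closer than 75 s are merged. For each noise peak at $t$, a heart-rate
response is a heart-rate peak in $[t,\ \min(t+180,\ t_{\text{next}}-30))$,
and the before/after change is the mean heart rate over $[t, t+60)$ minus
the mean over $[t-120, t-60)$.

**Crossover models.** Outcomes follow
$y_{ij} = \mu + \beta_{\text{condition}} + \gamma_{\text{period}} + b_i +
\varepsilon_{ij}$ with participant random intercepts $b_i$ (lme4);
estimated marginal condition means, pairwise differences, and Wald 95% CIs.
Heart-rate-peak occurrence uses the same structure with a logit link; the
contrasts are odds ratios. The vitamin-C effect on the FMD change is the
intervention-vs-none contrast per condition and pooled.

**Proteomics.** Per-subject post−pre NPX changes; 20-vs-20
strong/weak-responder split by noise-induced FMD change; per-protein
Student's t-tests (retain at unadjusted P < 0.05); z-normalized group means
clustered by Euclidean distance; PCA of changes; interaction-network
filtering at score > 0.4.

**Synthetic data.** Playback schedules from the printed constants (30 s
tone, 40 min lead-in, 75 s events, 575/700 s gaps), 1 Hz traces with
pass-by profiles and event-locked heart-rate surges, crossover cohorts
calibrated to the printed condition means (9.35 / 8.19 / 7.73 % FMD), and
NPX matrices with a ground-truth responder protein set.

## Worked example

```r
library(noisenight)

## one synthetic 60-event night, then detect its noise peaks
night <- simulate_night(make_schedule("noise60"), seed = 1)
peaks <- detect_peaks(night$trace$noise_db, peak_config(), times = night$trace$t)
nrow(peaks)
#> [1] 60
head(peaks, 3)
#>   t_peak run_start run_end max_value
#> 1   2469      2465    2469  60.24913
#> 2   3115      3114    3120  60.28105
#> 3   3768      3763    3769  60.29115

## a 74-participant crossover cohort and the FMD mixed model
coh <- simulate_cohort(make_design(74, seed = 1), seed = 1)
fit_lmm(coh, "fmd_pct")
#> <effect_table> linear mixed model (random participant intercept) on fmd_pct
#> Condition estimates:
#>  condition estimate     se   lwr    upr
#>    control    9.596 0.3801 8.851 10.341
#>    noise30    8.451 0.3801 7.706  9.196
#>    noise60    7.728 0.3801 6.983  8.473
#> Pairwise comparisons:
#>           contrast estimate     se      lwr   upr   p_value
#>  control - noise30   1.1449 0.3992  0.36251 1.927 4.130e-03
#>  control - noise60   1.8673 0.3992  1.08492 2.650 2.902e-06
#>  noise30 - noise60   0.7224 0.3992 -0.06002 1.505 7.036e-02
```

All 60 injected events are recovered exactly (each `t_peak` lands on an
event apex, 35–39 s after its onset). The fitted condition means for this
single simulated cohort sit within one standard error of the generating
values 9.35 / 8.19 / 7.73, and the control−noise contrasts scatter around
the generating 1.16 / 1.62 — averaged over replicate cohorts they converge
to them (see `scripts/acceptance.R`).

An end-to-end synthetic study (design → nights → detection → models →
proteomics, outputs + manifest written to a directory):

```r
bundle <- run_full_study(pipeline_config(seed = 1, n_participants = 74,
                                         out_dir = "run1"))
report(bundle)
```

or from the shell via the bundled CLI:

```sh
Rscript inst/cli/noisenight run-all --seed 1 --participants 74 --out-dir run1
Rscript inst/cli/noisenight detect --trace run1/night.csv --out peaks.csv
```

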