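# sevoEEG

Quantitative analysis of stepped volatile-anesthetic (sevoflurane) EEG
experiments in mice, for neurophysiologists comparing anesthetic
sensitivity across strains or interventions. The package covers the full
readout chain of such a study:

* **Burst-suppression segmentation** — the amplitude/duration rule (a
  sample is sub-threshold iff |x| < 5 mV; maximal sub-threshold runs
  lasting strictly longer than 0.5 s are suppression), the
  burst-suppression ratio `BSR = 100 · T_supp / T_total` per
  concentration step, and the suppression-onset concentration.
* **Multitaper density spectral arrays** — DPSS (Slepian) tapers built
  from the tridiagonal commuting eigenproblem; 2-s windows, NW = 3,
  K = 5 tapers, one-sided density scaling; group aggregation by cellwise
  median across animals.
* **Theta-band topography** — per-site 4–8 Hz power on the six-site
  mouse montage (F1/F2 +1.8 AP, C1/C2 −1.4, P1/P2 −2.8 mm), IDW-
  interpolated maps, and a scalar anteriorization index
  `A = mean(F1,F2) / mean(P1,P2)`.
* **Behavioral staircases** — ascending MAC-type (immobility to tail
  clamp, first-negative estimate) and descending RR-type (righting
  recovery, first-occurrence estimate) protocols with exact bias
  analysis.
* **Gated two-sample statistics** — Shapiro–Wilk + F-ratio gates at
  α = 0.05 routing to a pooled-variance Student's t-test or an exact
  Mann–Whitney test (full enumeration of the rank-sum null, ties via
  mid-ranks), plus `t_from_summary()` for reproducing p-values from
  printed group summaries.
* **A synthetic cohort generator** — per step, an alternating renewal
  process whose stationary suppression fraction follows a gated logistic
  `p(c) = 1 / (1 + exp(-β (c − c50)))` (exactly 0 below `c50 − 3/β`),
  with a 6 Hz theta carrier that redistributes anteriorward with
  concentration, Gaussian suppression-floor noise, and psychometric
  behavioral agents — all with per-sample ground truth, so every
  estimator above is testable against what was programmed.

EEG I/O supports EDF and a wide-CSV dialect; protocols and staircase
logs round-trip through CSV. See `vignette("anesthesia-eeg-methods")`
for the models, assumptions, and design decisions.

## Worked example

Simulate one sensitive-strain animal on the 2.0–2.8 vol% ladder
(5-minute steps), quantify burst suppression, and summarize theta
topography:

```r
library(sevoEEG)

p   <- btbr_params()                     # sensitive preset: c50 = 2.05 vol%
sim <- simulate_recording(p, conc_protocol(), fs = 250, seed = 1)

tab <- bsr_by_step(sim$recording, "F1", conc_protocol(),
                   suppression_criteria(merge_gap_s = 0.01))
tab
#>  concentration bsr_percent suppression_time_s
#>            2.0    38.28533            114.856
#>            2.2    89.88133            269.644
#>            2.4    99.38933            298.168
#>            2.6   100.00000            300.000
#>            2.8   100.00000            300.000
onset_concentration(tab)
#> [1] 2
```

Suppression already occupies 38% of the first step — this strain's
suppression gate sits below 2.0 vol%, so its onset concentration is the
lowest step. The resistant preset (`b6_params()`, gate at 2.25 vol%)
shows zero BSR at 2.0–2.2% and onsets at 2.4%. Theta topography for the
same recording:

```r
theta <- theta_site_power(sim$recording, conc_protocol())
anteriorization_by_step(theta, bsr = tab)
#>  concentration     index bsr_flagged
#>            2.0 0.2823702        TRUE
#>            2.2 1.0690955        TRUE
#>            2.4 0.9930297        TRUE
#>            ...
```

The index rises from 0.28 (posterior-dominant) toward 1 as theta power
moves frontally; every step is flagged here because this animal is
already in burst suppression, which is exactly what the flag is for —
topographic maps are interpreted pre-onset.

Reproducing a reported group comparison from printed summaries
(immobility thresholds 2.67 ± 0.05 vs 2.68 ± 0.10 vol%, n = 10 per
group):

```r
t_from_summary(2.67, 0.05, 10, 2.68, 0.10, 10)
#> <gated_test> Student's t-test (pooled variance)
#>   statistic = -0.2828, df = 18, p = 0.7805
```

`run_pipeline(pipeline_config(), outdir)` executes the whole two-strain
design — behavioral cohorts, gated comparisons, per-step BSR and onsets,
group-median spectral arrays, theta site tables and anteriorization
indices — writing CSV tables and a JSON manifest sufficient to re-run.

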