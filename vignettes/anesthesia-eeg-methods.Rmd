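---
title: "Methods: quantifying anesthetic depth in mouse EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying anesthetic depth in mouse EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sevoEEG)
```

## The problem

During stepped exposure to a volatile anesthetic such as sevoflurane,
rodent cortical EEG passes through characteristic regimes: band-limited
oscillations (prominently theta, 4–8 Hz) whose spatial distribution
drifts anteriorward as the plane deepens, and eventually burst
suppression — high-voltage bursts alternating with near-isoelectric
suppression periods. Two behavioral thresholds bracket the dose-response:
the immobility threshold to a noxious stimulus (a MAC-type, spinally
mediated endpoint measured with an ascending staircase) and the
concentration at which the righting reflex returns during emergence (an
RR-type, supraspinally mediated endpoint measured with a descending
staircase). Comparing strains on these readouts requires a quantitative
pipeline: spectral estimation, suppression segmentation, topographic
summarization, endpoint estimation, and a principled two-sample test.
`sevoEEG` implements that pipeline, together with a synthetic cohort
generator carrying per-sample ground truth so that every stage is
testable without access to raw recordings.

## Burst-suppression segmentation

A sample is *sub-threshold* iff its absolute value is below the
amplitude criterion (default 5, unit-checked against the recording;
the default unit is mV to match the voltage scale of screw-electrode
recordings this rule is used with). Maximal sub-threshold runs lasting
*strictly longer* than 0.5 s are suppression; everything else is burst.
The strictness follows the criterion's wording ("longer than"), so a run
of exactly 0.5 s is burst. The burst-suppression ratio is

$$\mathrm{BSR} = 100 \cdot \frac{T_{\mathrm{supp}}}{T_{\mathrm{total}}},$$

computed over a full concentration step (the 5-minute epoch), and the
onset concentration is the lowest step whose BSR exceeds a configurable
`epsilon` (default 0). Amplitude is the raw per-sample absolute value of
the referenced signal — no envelope smoothing — which is the most literal
reading of a voltage-threshold rule; an explicit `detrend` flag subtracts
the channel mean first. Segmentation studies sometimes identify
suppression epochs by eye; here the deterministic threshold rule stands
in for any manual step, which makes the segmentation reproducible but
means borderline epochs are decided by the criterion alone.

Two practical knobs deserve explanation:

* `merge_gap_s` (default 0) bridges supra-threshold gaps of at most this
  duration between sub-threshold runs *before* the duration test. With
  floor noise at its default level (see the generator below), a single
  noise sample exceeds the 5 mV criterion about once per two seconds of
  suppression. Under a zero merge gap each such spike splits a
  suppression run, and pieces at or under 0.5 s are relabeled burst:
  at heavy suppression this censors 2–5 percentage points of BSR. The
  recovery experiments therefore use `merge_gap_s = 0.01` (10 ms): wide
  enough to bridge isolated spikes, and far below the ~30–80 ms
  supra-threshold arcs that genuine theta bursts produce each half-cycle,
  so bursts are never absorbed. The default remains 0 because the
  published criterion mentions no merging.
* `channel` defaults to `F1`: burst-suppression quantification is
  conventionally frontal; it is configurable because the choice of a
  single channel is a convention, not a property of the rule.

The implementation is run-length based; the suite verifies it against an
independent brute-force per-sample scan on hundreds of randomized
signals, along with partition conservation (interval lengths sum exactly
to the duration) and monotonicity in both criteria parameters.

## Multitaper spectral estimation

Spectrograms use discrete prolate spheroidal (Slepian) tapers computed
from the eigendecomposition of the classical tridiagonal commuting
matrix, with spectral concentrations evaluated as quadratic forms of the
sinc kernel; the test suite checks the tapers against a direct dense
eigendecomposition of that kernel at small n. Defaults are 2-s windows,
no overlap, time-bandwidth product $NW = 3$ and $K = 5$ tapers (the
Shannon limit $2NW - 1$; more are refused unless `allow_leaky = TRUE`),
giving a design half-bandwidth of $NW/T = 1.5$ Hz. Scaling is one-sided
power spectral density (unit²/Hz): `|FFT|²/fs`, doubled except at DC and
Nyquist, so the density integrates to the windowed variance (checked to
5% on white noise). Numerical choices: window sample counts are
`floor(window_s * fs)`; the FFT length equals the window length (no zero
padding), so the bin spacing is `1/window_s`; per-window mean removal is
on by default because anesthesia EEG drifts and the DC bin otherwise
dominates — it is a flag, since the convention is not universal; taper
averaging is uniform (the common toolbox default), with
concentration-weighted averaging available. Group density spectral
arrays are cellwise *medians* across animals on validated identical
grids — robust to a single outlier animal and, with odd group sizes,
every cell is an observed value. Rendering in dB is a display choice;
the stored data stay linear.

## Theta topography and the anteriorization index

Per step and channel, band power is the trapezoidal integral of the
density over bins whose centers lie in [4, 8] Hz (inclusive; at the
default 0.5 Hz spacing that is the 4.0, 4.5, …, 8.0 bins), summarized by
the median over windows, then averaged across animals per site. The 2-D
field is inverse-distance-weighted (power 2) interpolation on the flat
AP × ML plane of the six-site montage, masked to a 1 mm margin around
the sites' rectangular hull; IDW is node-exact and avoids spherical-head
assumptions that a 6-electrode mouse montage cannot support. The scalar
*anteriorization index*

$$A = \frac{\tfrac12 (P_{F1} + P_{F2})}{\tfrac12 (P_{P1} + P_{P2})}$$

quantifies the frontal shift; central sites are excluded to keep it a
pure frontal/parietal contrast, and it is invariant to common rescaling
of power. It is this package's own summary — topographic shifts are
usually shown only as maps — and outputs label it as such. Maps are
interpreted *before* burst-suppression onset: steps whose BSR exceeds a
cutoff (default 5%) are flagged rather than dropped. One site-label
convention is fixed here: F1/F2 are the prefrontal pair (+1.8 mm AP),
C1/C2 the anterior parietal pair (−1.4 mm), P1/P2 the posterior parietal
pair (−2.8 mm); montage vocabularies vary and this mapping is stated
rather than assumed.

## The synthetic generator

Brain state within each step follows an alternating renewal process with
exponential dwell times. The stationary suppression fraction at
concentration $c$ is the gated logistic

$$p(c) = \begin{cases} 0 & c < c_{50} - 3/\beta \\
\left(1 + e^{-\beta (c - c_{50})}\right)^{-1} & \text{otherwise,}
\end{cases}$$

with midpoint `bs_ec50` $= c_{50}$ and steepness `bs_slope` $= \beta$.
The hard gate makes low steps produce *no* suppression events, matching
the qualitative observation that below the onset concentration
suppression is simply absent. The suppression dwell mean is fixed
(default 5 s — ten times the 0.5 s detection minimum, so dwell-time
censoring at the duration rule stays well under one percentage point of
BSR) and the burst dwell is derived as $\mu_b = \mu_s (1-p)/p$, which
makes the stationary fraction equal $p(c)$ exactly; because exponential
dwells are memoryless, starting each step in its stationary distribution
makes the realized per-step fraction an unbiased estimate of $p(c)$
(verified by Monte Carlo against the closed form). `mean_burst_dur_s`
sets the phase-reset interval on pure-burst steps below the gate, where
no suppression events exist to reset the carrier.

Bursts carry a 6 Hz carrier with a random phase per burst, shared across
channels, on top of an AR(1) background (pole 0.98) approximating a 1/f
spectrum — a narrowband-plus-background mixture, not a pure tone, so the
multitaper bandwidth behavior is actually exercised. Suppression periods
carry only Gaussian floor noise with `noise_sd = 5/3.29`, i.e. a single
floor sample stays below the 5 mV criterion with probability 0.999. The
per-site carrier amplitudes start posterior-dominant (F 8, C 11, P 15 mV)
and morph linearly toward the front/back mirror image with weight
$\min(1, r\,(c - c_1))$, where $r$ is `theta_shift_rate`; amplitudes are
kept at or above 8 mV (1.6× the criterion) so burst content stays
reliably supra-threshold against background excursions — the amplitude
separation that the detector-recovery property presupposes. Behavioral
agents answer staircase queries by Gaussian-CDF psychometric functions
around `true_mac` / `true_rr` (`behavioral_sd = 0` degenerates to a
deterministic threshold), each with a private RNG stream so runs are
reproducible regardless of surrounding RNG use.

The two shipped presets encode the strain contrast the package is built
around: `btbr_params()` (sensitive: $c_{50} = 2.05$, righting threshold
1.10 vol%, fast anteriorization) and `b6_params()` (resistant:
$c_{50} = 2.45$, righting threshold 1.65 vol%, slow anteriorization),
both with $\beta = 15$ so the gate sits one 0.2 vol% protocol step below
the midpoint and the programmed onsets fall on 2.0% and 2.4%. Immobility
thresholds are nearly identical (2.68 vs 2.67 vol%) — sensitivity differs
at emergence, not at the immobility endpoint.

What the generator does **not** emulate: volume conduction and reference
effects across channels (channels are conditionally independent given
the shared state and carrier phase), movement or electrical artifacts,
true $1/f^\alpha$ spectra (the AR(1) background is Lorentzian), spindle
or slow-oscillation structure within bursts, pharmacokinetic
equilibration (staircase dwell times are bookkeeping only), and any
biophysics behind the strain parameters. Passing recovery tests
therefore demonstrates correctness of the estimators under the stated
stochastic model, not robustness to real-world artifacts.

## Behavioral endpoints

The ascending design queries from 2.5 vol% in 0.1 steps and stops at the
first trial without movement; the estimate is that trial's
concentration — the wording "increased until the positive response
disappeared" fixes the first-negative convention, so no mid-step
averaging is applied, and for a deterministic agent the estimate is
provably the grid ceiling of the true threshold (a bias of at most one
step, upward). The descending design starts at 2.0 vol% and stops at the
first righting; the estimate is that concentration — first-occurrence,
the grid floor of a deterministic threshold. Both facts are tested by
enumeration, and the stochastic-agent bias is checked against the exact
trial-sequence distribution
(`staircase_mac_distribution()`), which multiplies per-trial psychometric
probabilities along the grid. A `max_steps` bound guards against
non-terminating agents; truncated logs refuse estimation rather than
returning a silently censored value.

## The gated two-sample rule

Group comparisons follow a fixed decision rule: Shapiro–Wilk normality
per group and an F-ratio variance-homogeneity test (Brown–Forsythe
available by flag; the specific gate tests are this package's choice, as
protocols often leave them unnamed), all at $\alpha = 0.05$; if all
three gates pass, a two-sided *pooled-variance* Student's t-test —
pooled, not Welch, because the rule only reaches the t-test after an
equal-variance gate; otherwise a two-sided Mann–Whitney test. Constant
samples fail the normality gate by convention. The Mann–Whitney branch
is exact — the full null distribution of the rank sum over all
$\binom{n_a+n_b}{n_a}$ label assignments, computed by dynamic
programming over doubled mid-ranks so ties are handled exactly — whenever
both groups have at most 8 observations and the pooled size is at most
25, and a tie-corrected normal approximation otherwise. The suite checks
the exact branch against explicit label-permutation enumeration, and the
whole rule's type-I error under a normal null (≈ 0.05 ± 0.015 at
n = 10/group over 1000 replicates; the t branch is selected at about the
$(1-\alpha)^3 \approx 0.857$ gate-pass rate). `t_from_summary()` exposes
the pooled t-test from printed means/SDs/sizes, which is how reported
group comparisons can be reproduced when only summaries are available.
No multiple-testing correction is applied anywhere — comparisons are
reported individually.

## Degenerate inputs and tie-breaks

Unit mismatches between criteria and recordings are errors, never silent
conversions. Empty recordings, empty step tables, samples under 3 per
group, non-positive SDs, and truncated staircase logs all fail loudly.
Zero parietal power makes the anteriorization index `Inf` with a
warning. An animal missing a montage site is excluded from group maps by
default (with a message); the alternative policy drops the site. EDF
export requires integer sampling rates and whole-second durations (the
format stores fixed 1-s records); the writer picks a physical range
covering the signal and *errors* rather than clips if a declared range
is exceeded, and quantization is 16-bit over the declared range.

## Problem sizes in the shipped tests

Replicate-heavy properties run on scaled problems chosen to keep the
full suite under a minute while leaving Monte-Carlo error far from the
asserted margins: onset-recovery cohorts use the full 5 × 300 s protocol
at 125 samples/s on the analysis channel only; BSR-recovery checks use
250 samples/s; topographic-recovery cohorts use 3 × 60 s steps at 200
samples/s with all six channels; renewal-fraction calibration uses 200
seeds at 64 samples/s. All properties are invariant to these choices
(rates well above the 32 samples/s floor for the theta band; durations
long against the 5 s dwell scale), and the acceptance script re-runs
them at the same sizes. Topographic-recovery cohorts are simulated in
the pre-onset regime (suppression gate above the protocol), since maps
are defined before burst-suppression onset; at near-total suppression
the median window contains no burst and per-site theta power degenerates
to the common noise floor, which carries no topographic signal.

## Limitations

The suppression threshold/unit pairing (5, mV) is carried as data, not
hard-coded, because amplitude conventions vary across acquisition
systems — applying the default to µV-scaled recordings is a unit error
the package refuses. The anteriorization index compresses a map into one
ratio and is blind to central-channel dynamics by design. The exact
Mann–Whitney branch is limited to pooled n ≤ 25; beyond that the normal
approximation is used and noted in the result. The generator's realism
limits are listed above; in particular, recovery of strain contrasts on
synthetic cohorts validates the estimators, and cannot by itself
validate biological claims about any real strain.
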