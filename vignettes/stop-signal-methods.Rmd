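---
title: "Models and methods: race-model simulation, inhibition ERPs, and random-effects model selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stopsignal)
```

This vignette documents the scientific models implemented in `stopsignal`,
the assumptions behind them, and the design decisions taken where the
methodology admitted more than one reasonable choice.

## The horse-race model of the stop-signal task

The behavioral generator assumes two stochastically independent processes
on every STOP trial. The Go process finishing time is ex-Gaussian,

$$T_{go} \sim \mu + \sigma Z + \mathrm{Exp}(\tau),$$

the standard positively skewed account of reaction times; the Stop process
finishes at $\mathrm{SSD} + S$ with $S \sim \mathcal{N}(\mathrm{SSRT},
\sigma_S)$ truncated at zero. The subject responds iff the Go process wins
(or the stop process failed to trigger, probability
`p_trigger_failure`). Whichever process wins is unobservable on Go trials,
which is why the stop latency must be inferred distributionally.

**Defaults** (`race_params()`): `go_mu = 450`, `go_sigma = 60`,
`go_tau = 200` ms (mean Go RT 650 ms), `ssrt_true = 190`, `ssrt_sd = 25`
ms, `p_trigger_failure = 0.02`, `gf_offset = −85`, `gc_offset = +58` ms.
These place the OFF-condition group means of a simulated cohort near the
patient group this design emulates (Go RT ≈ 650 ms, Go-Fast ≈ 565 ms,
Go-Certain ≈ 708 ms, SSRT ≈ 190 ms); the GF/GC offsets carry the
preparation-cost and oddball contrasts. The ON condition subtracts
`rt_shift = 50` ms from `go_mu` and adds `ssrt_shift = 53` ms to
`ssrt_true` — response speeding with worsened inhibition, the direction
and size of the stimulation effects under study. Between-subject
heterogeneity is a mean-preserving lognormal jitter with 10 % coefficient
of variation on `go_mu` and `ssrt_true`, a typical between-patient spread
for these quantities.

**Task design** (`task_config()`): blocks of 100 trials, GO 52.6 % of the
mix, STOP 15.8 % (the design keeps stop cues below 16 % to discourage
waiting), and the remaining mass split evenly between Go-Fast and
Go-Certain — the split between the latter two is not constrained by the
design, so an equal split was chosen once. Per-block counts are allocated
by the largest-remainder rule, which reproduces the design fractions
exactly whenever they are representable (e.g. 526 GO trials in 1000) and
remains feasible for every block size; plain per-type rounding would make
the canonical 100-trial block infeasible (53 + 16 + 16 + 16 = 101). No
two STOP trials are ever adjacent (including across block boundaries), a
common SST practice that avoids staircase carry-over between consecutive
stop cues; the permutation is rejection-sampled with a deterministic
spread fallback.

**Staircase.** The SSD starts at 300 ms, moves +50 ms after a successful
inhibition and −50 ms after a failure, clipped to [50, 900] ms; block
$b > 1$ starts at the mean SSD of the last four STOP trials of block
$b − 1$. The symmetric staircase self-balances at 50 % stop success for
any non-degenerate overlap of the two finishing-time distributions — this
is an emergent property the acceptance tests check, not something coded
in. Go finishing times beyond a 1200 ms deadline are recorded as
omissions; this is the generator's mechanism for the task error rate,
whose empirical definition in the field varies (omissions vs. wrong keys).
Omission rates under the defaults stay below ~4 %.

## SSRT estimation

`estimate_ssrt()` implements the integration method with the mean SSD:
sort the Go RTs, take the $\lceil p \cdot n \rceil$-th order statistic
where $p$ is the observed signal-respond fraction, subtract the mean SSD.
Two variant decisions:

* omitted Go trials are **excluded** from the finishing-time distribution
  rather than replaced by the maximum RT; at the generator's <4 % omission
  rate the variants differ by far less than the estimator's sampling
  error;
* $p$ is the per-session observed fraction, not the 50 % tracking target.

The estimator is intentionally the plain textbook version: its small
negative bias under staircase tracking with skewed RT distributions
(order ~10 ms at these parameters, measured by the recovery tests against
the generator's ground truth) is a property of the method being studied,
not something to be corrected away. Negative estimates are possible on
short noisy sessions and are returned as-is with a warning, so that
downstream group statistics see an unbiased (if noisy) sampling
distribution rather than a censored one.

## EEG generation and the Go-process correction

`synthesize_eeg()` builds epochs as sums of Gaussian-bump components
(amplitude × unimodal scalp topography) plus i.i.d. Gaussian noise:

* Stop-cue-locked N100 (−3 µV at 100 ms), N200 (−5 µV at 200 ms) and P300
  (+6.5 µV at 297 ms), the N200/P300 with right-frontal topographies
  peaking at F4; on unsuccessful stops N200/P300 are attenuated ×0.5
  (inhibition ran but lost);
* a Go-locked motor component riding on the trial's latent Go finishing
  time (peak 50 ms before the response, C3-centred topography). On STOP
  trials it appears at the latent finishing time minus the SSD — exactly
  the race-model overlap the correction must remove.

The ON condition scales the P300 ×0.82 and delays it +17 ms and scales
the N200 ×0.88 with −11 ms, the stimulation effects the recovery tests
must detect. Epochs are (−200, 500) ms around the Stop cue at 250 Hz
(176 samples, endpoints and $t=0$ on the grid). Go epochs extend to
(−200, 1000) ms: the correction needs Go-locked activity at Go-time
$t + \mathrm{SSD}$, which reaches beyond 500 ms for any stop-locked time
of interest; samples outside the available Go window contribute zero
(the motor bump has died off there).

What the generator deliberately omits: 1/f and line noise, ocular/muscle
and stimulation artifacts, trial-to-trial amplitude variability,
volume-conducted source mixing. Passing recovery tests therefore
demonstrates the *algebra* of the pipeline (correction, referencing, GFP,
peak logic) under known ground truth — not robustness to real recording
artifacts, which upstream cleaning (ICA, trial rejection) is assumed to
have handled.

`go_correction()` subtracts an estimate of the overlapping Go activity
from each stop epoch, realigned into stop-cue time by the trial's SSD
(nearest-sample shift):

* **unsuccessful stops** — mean of Go epochs with RT within ±50 ms of the
  trial's signal-respond RT (the Go processes that plausibly produced
  that response);
* **successful stops** — mean of Go epochs with RT > SSD + SSRT (the Go
  processes slow enough to have lost the race).

The ±50 ms matching tolerance trades bias against subtrahend noise; with
no match the grand Go average is used and a warning raised. Corrected
epochs are averaged with common-average referencing and (−150, −50) ms
baseline subtraction.

`compute_gfp()` implements the sum of absolute deviations from the
scalp-wide mean — not the conventional RMS global field power. The
absolute-sum form is used verbatim because it is the stated measure of
the analysis being reproduced; it shares the RMS version's invariance to
channel-constant offsets and its non-negativity. Amplitude units of such
a sum are formally µV summed over electrodes; published µV² labels for
this quantity are treated as labels only.

`measure_peaks()` searches windows N100 75–125, N200 175–225, P300
275–325 ms for the largest strict local extremum of the requested
polarity; plateaus take their earliest sample, ties break to the earliest
latency, and a window without any local extremum returns the window-edge
maximum flagged `edge = TRUE` rather than failing. The generator's N200
default sits at 200 ms (inside its measurement window) rather than at the
later latencies sometimes reported from patient data, keeping the
generator and the measurement windows self-consistent.

`preprocess()` applies zero-phase Butterworth filtering (order 2
high-pass and order 4 low-pass applied separately — a single narrow-band
band-pass design is numerically fragile at high sampling rates) with
odd-reflection padding of ~1.2 s per band edge so that IIR edge
transients decay inside the padding, followed by anti-aliased decimation
for integer rate ratios (e.g. 2500 → 250 Hz).

## Group statistics

`paired_compare()` wraps the paired t-test ($t$ with $n−1$ df) and the
Wilcoxon signed-rank test (exact null for $n \le 25$); p-values are
two-sided and uncorrected, mirroring the reporting convention of the
analysis being reproduced. A zero-variance difference vector is flagged
degenerate (statistic 0, missing p) instead of erroring mid-pipeline.
Type-I calibration under the null generator and power under the
stimulation-sized SSRT effect are asserted by simulation in the test
suite.

## The connectivity model space and random-effects BMS

`build_model_space()` encodes a six-node network: bilateral IFG
{±54; 12; 18}, bilateral DLPFC {±37; 27; 39}, medial preSMA/dACC
{0; −6; 56}, and the basal ganglia as a single hidden source (its MNI
coordinates are undefined by construction). The 14 connections follow the
two-pathway architecture: a fast IFG↔BG route (bidirectional lateral
pairs, since the hidden BG node conflates input and output structures and
is hierarchically non-informative), a slower DLPFC→preSMA→BG feedback
route, intra-hemispheric IFG→DLPFC forward / DLPFC→IFG backward pairs,
and undirected interhemispheric lateral edges IFG–IFG and DLPFC–DLPFC.
Nine modulation models arise from {IFG, preSMA/dACC, both} × {afferent,
efferent, both}: only BG-touching extrinsic connections may differ
between stimulation conditions. Three families of three group the models
by cortical partner. The canonical edge list is pinned in
`inst/extdata/model_space.yaml` and asserted by the test suite.

`rfx_bms()` implements random-effects model selection: model frequencies
$r \sim \mathrm{Dir}(\alpha)$, per-subject assignments latent, and the
variational fixed point

$$g_{nk} \propto \exp\!\big(\ln E_{nk} + \psi(\alpha_k) -
\psi(\textstyle\sum_j \alpha_j)\big), \qquad
\alpha = \alpha_0 + \textstyle\sum_n g_n,$$

iterated until $\max|\Delta\alpha| < 10^{-6}$ (cap 500 iterations,
non-convergence flagged). Responsibilities are computed with log-sum-exp,
which also yields the row-shift invariance of log-evidences. Convention
choices, flagged as conventions because the source analysis does not
state them: prior $\alpha_0 = 1$ per model (uniform); exceedance
probabilities by Monte-Carlo (default $10^6$ Dirichlet draws via gamma
sampling, seeded, chunked to bound memory) — the $K = 2$ Beta closed form
serves as a test oracle only; family inference rescales the per-model
prior to `prior_alpha / |family|` so families are a priori equiprobable,
and family exceedance is the Monte-Carlo frequency of the family's summed
Dirichlet mass being largest.

`bma()` weights each subject's per-model connection strengths by the
softmax of that subject's log-evidences restricted to the family (uniform
within-family prior; weights sum to one per subject), averages in log
units, summarizes the group as $\exp(\text{mean log strength})$, and
tests each connection's ON−OFF difference with the paired t-test. The
companion generator `simulate_dcm_params()` shifts one target connection
by $\log(0.7)$ (a 30 % weakening) with 0.1 log-unit between-subject sd —
an effect size that makes the sign, not the significance, the hard part
of the recovery.

## Reproducibility and problem sizes

Every stochastic function takes a seed; nested seeds derive from the
master via `derive_seed()` (multiplicative hashing modulo $2^{31}−1$), so
adding a consumer of randomness never perturbs earlier draws, and
`run_pipeline()` is bit-reproducible from its `run_config()`. The test
suite sizes its simulations to the study's own scale: 12-subject cohorts,
300-trial sessions (~47 STOP trials), 96-channel epochs; estimator-bias
and calibration properties use replicate counts (25–60 sessions, 1000
null cohorts, $10^5$–$10^6$ Dirichlet draws) chosen so Monte-Carlo error
is small against the asserted tolerances.

## Known limitations

* The epochs container is a plain-text JSON + CSV pair; EDF/BrainVision
  import is not provided, so external recordings must be converted to the
  container (or to the trial-table CSV) upstream.
* The Go-process correction recipe (RT-matched vs. escape-set
  subtrahends, ±50 ms tolerance) follows the race-model logic but is one
  of several defensible formalizations; alternatives would change
  single-trial corrections more than class averages.
* The DCM forward model itself (neural-mass dynamics, dipole projection,
  free-energy optimization) is out of scope; `simulate_evidences()` and
  `simulate_dcm_params()` stand in for its per-subject outputs, so BMS/BMA
  results here validate the inference layer, not the biophysics.
* White-noise EEG and stylized index-space topographies mean scalp maps
  are illustrative, not physiological.
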