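---
title: "Modelling and measuring the rapid recalibration of peri-personal space"
author: "ppsrecal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and measuring the rapid recalibration of peri-personal space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

Peri-personal space (PPS) is the multisensory representation of the space
immediately surrounding the body: tactile processing is facilitated when a
task-irrelevant visual stimulus is close to the stimulated body part, and
the facilitation falls off sigmoidally with visuo-tactile distance. The
central point of that sigmoid is the operational PPS boundary. `ppsrecal`
implements three connected pieces of machinery around the finding that this
boundary shifts *trial-to-trial* — toward the body after a trial that probed
a small visuo-tactile disparity, away from it after a large one — together
with seeded synthetic generators so that every analysis stage can be
exercised, and its statistical behaviour calibrated, without external data.

# The network model

## Architecture

The simulator (`build_network()`, `run_trial()`, `run_session()`) is a
firing-rate network of the peri-face space:

* two 41 × 41 sheets of unisensory neurons. Tactile receptive fields tile a
  20 × 20 cm face surface at 0.5 cm spacing; visual receptive fields tile a
  400 × 400 cm planar region of external space at 10 cm spacing, with one
  axis reading out depth from the face and the other lateral position.
* Mexican-hat lateral coupling within each sheet (difference of Gaussians,
  near excitation and far inhibition), implemented as a separable
  convolution with zero padding. An explicit truncated weight matrix would
  be the equivalent alternative; the separable form is cheaper and exact
  for a Gaussian kernel.
* a single multisensory unit receiving excitatory feedforward projections
  `W` from every unisensory neuron, and sending excitatory feedback `B`
  with the same spatial pattern as the *basal* feedforward weights.
  Tactile feedforward weights are uniform (the multisensory unit's tactile
  receptive field covers the whole face); visual feedforward weights are
  maximal on and near the face and decay exponentially with depth with
  length constant `lambda_v`.

Each unit passes its input through first-order membrane dynamics (time
constant `tau`, Euler-integrated at `dt` = 1 ms) followed by a logistic
activation with centre `theta` and slope `r`, so activities live in
`[f_min, f_max]`.

## Plasticity

Only the feedforward weights are plastic. Every update step (1 ms) applies

$$\Delta W = \rho_0\, (W_{max} - W)\; z^{pre}\, (z^m - \theta_{gate})^{+}
           \;-\; k_H\, (W - W(0)),$$

a gated Hebbian reinforcement — active only when the pre-synaptic unisensory
neuron and the post-synaptic multisensory unit fire together, the latter
above a gate of 5% of its maximal activation — whose learning factor
$\rho_0 (W_{max}-W)$ vanishes as weights approach their ceiling, plus an
activity-independent forgetting term that decays weights back to their basal
map with time constant $\tau_H = 1/k_H$ (expressed in update steps).
$\tau_H$ is *the* parameter of interest: it sets how long the network
remembers recent multisensory events. Lateral and feedback weights stay
fixed: training them buys little for the feedforward-driven recalibration
effect while risking network instability (lateral) and cross-modal phantom
activations (feedback).

The forgetting term acts continuously, including through inter-trial
intervals; with no supra-threshold multisensory activity the discrete
update telescopes exactly to $(W(t)-W(0)) (1-k_H)^n$, which the test suite
verifies against the simulation to 1e-10 relative error.

## Trials, sessions and the decoded reaction time

A simulated trial mimics the looming psychophysics design: a visual
stimulus (bidimensional Gaussian, displaced every millisecond) approaches
from 200 cm at 75 cm/s; when it reaches the trial's nominal disparity a
tactile Gaussian is delivered at the centre of the face. The network
reaction time is the time, from tactile onset, for summed tactile-sheet
activity to reach `p_th` = 4 — since single-neuron activity lies in [0, 1],
an ensemble of a few tactile neurons must be recruited. Trials that never
cross within the decode horizon return a missing RT and sessions report
timeout counts. A session (`run_session()`) runs 20 trials of each of the
six disparities plus a unisensory tactile condition in a seed-permuted
order, carrying weights (and the forgetting clock) continuously across
trials. Between trials the forgetting clock follows the experiment's
timeline: the simulated stimulus is removed once the decode horizon has
passed, but the gap before the next approach spans the remaining
time-to-contact plus the 2000 ms that separate contact from the next
approach onset in the behavioural design — so far probes, whose looming
stimulus still had a long way to travel, are followed by longer gaps and
stronger forgetting.

Facilitation arises because feedback from the multisensory unit raises
tactile-sheet excitability: when the visual stimulus is near (or far-space
visual synapses are transiently potentiated), the multisensory unit is
already active at tactile onset and the threshold is crossed sooner.
Recalibration arises because the tactile event of trial *t−1* opens the
Hebbian gate while the visual bubble sits at that trial's disparity: visual
synapses around that location are potentiated, decay with $\tau_H$, and —
if the next trial arrives within a few seconds — bias the multisensory
drive at the next trial's disparity. Fitted central points therefore sit
farther after larger-disparity trials. As in the behavioural data, the
differences concentrate in mid-to-far space: near the body the multisensory
unit is at ceiling from visual drive alone, a floor effect on RTs.

## Parameters and the shipped default configuration

The model family this simulator belongs to inherits most numeric constants
from earlier work, and those constants are not derivable from first
principles. We therefore ship a single default configuration
(`pps_config()`, registered as `"pps-default"` and exported as YAML under
`inst/extdata/pps-default.yaml`) and treat it as *the* study condition: it
was calibrated, once, so that the qualitative invariants hold — a PPS
sigmoid with its central point inside the simulated 55–175 cm range at
75 cm/s, distance-independent unisensory RTs at the far-field multisensory
level, a positive central-point shift of a few centimetres at
$\tau_H = 4$ s, and the three-regime structure in $\tau_H$ described below
— and then frozen. Every value is overridable through `pps_config(...)` or
a YAML file. The choices that matter most:

| parameter | default | role |
|---|---|---|
| `tau_ms` | 20 ms (all populations) | membrane integration; must be ≥ 2 `dt` for Euler stability (enforced) |
| `theta`, `r` | 12 / 1.2 (unisensory), 12 / 0.35 (multisensory) | activation centre and slope; the shallow multisensory slope spreads the facilitation gradient over several distance levels |
| `w0_t`, `w0_v` | 2, 20 | basal feedforward weights; also the saturation ceilings `W_max` |
| `lambda_v` | 60 cm | depth decay of visual feedforward weights; sets the scale of the baseline PPS |
| `b_t`, `b_v` | 6, 2 | feedback amplitudes; `b_t` drives the RT facilitation, both kept below the level that would let activity self-sustain without input |
| `exc_amp/sigma`, `inh_amp/sigma` | 0.15/1, 0.05/4 (index units) | Mexican-hat lateral kernel |
| `rho0` | 1.125e-3 | learning-rate scale; several trials are needed to approach saturation |
| `gate_theta` | 0.05 | Hebbian gate, as a fraction of maximal multisensory activation |
| `tau_h_s` | 4 s | forgetting time constant |
| `vis_amp/vis_sigma` | 30 / 6 cm | looming stimulus strength and spatial spread (after receptive-field filtering) |
| `tact_amp/tact_sigma/tact_dur_ms` | 20 / 1 cm / 50 ms | tactile probe |
| `p_th` | 4 | RT decode threshold on summed tactile activity |

Two geometric notes. The visual stimulus's spatial spread interacts with
the 24 cm spacing of the probed disparities: it must be wide enough that a
few visual neurons are recruited wherever the stimulus sits (smooth
facilitation, no receptive-field scalloping), yet narrow enough that the
potentiated patch left by trial *t−1* does not leak across two distance
levels. The 6 cm default sits in that window. And "distance from the face"
means depth in the planar visual space; the looming trajectory runs down
the depth axis at the lateral centre and the stimulus vanishes at contact.

## The three $\tau_H$ regimes

`sweep_tau()` reruns one identical permuted schedule across forgetting time
constants. Three regimes emerge with the shipped defaults, mirroring the
conceptual account: for $\tau_H \lesssim 2$ s the network forgets before
the next trial arrives and no recalibration is measurable; for intermediate
values (the 4–6 s range) the central-point shift is positive; for large
$\tau_H$ ($\gtrsim$ 7.5 s) potentiation accumulates across many trials
until the far-space synapses saturate and the distance effect collapses —
a flat PPS, flagged when the RT range across disparities drops below
`flat_tol_ms` (default 5 ms of network time). The regime *boundaries*
depend on the parameter set and on the inter-stimulus timing; the
three-regime structure is what the model claims.

`sweep_velocity()` repeats the session at 25–100 cm/s with $\tau_H$ fixed
at 4 s. Known limitation: the prior-generation mechanism by which PPS
*enlarges* with stimulus velocity is firing-rate adaptation of the
multisensory unit, which is not part of this model; here velocity acts only
through timing (faster approaches compress the inter-touch interval, so
less is forgotten between trials). The sweep reports central points and
recalibration indices per velocity; we do not assert monotone enlargement.

## Numerical choices

* Explicit Euler at `dt` = 1 ms, matching the model's native update step;
  configuration validation rejects `tau < 2 dt`.
* The logistic activation is evaluated exactly within
  $-13.8 < r(q-\theta) < 30$ and clamped to its saturations outside;
  the truncation error is below 1e-6 activity units and makes true rest
  states exactly silent, which the integrator exploits (lateral input is
  computed on the bounding box of active neurons only).
* The inter-trial gap integrates the first 300 ms dynamically (activity
  decays to numerical rest within ~15 membrane time constants) and applies
  the remaining forgetting in closed form, which is exact for the weight
  dynamics.
* Weight bounds `[0, W_max]` are enforced by construction (the learning
  factor vanishes at the ceiling; forgetting decays toward the basal map)
  and additionally clamped.
* A plain-R replica of one full integration-plus-plasticity step
  (`ppsrecal:::step_reference()`) serves as an independent oracle for the
  compiled loop in the test suite.

# The psychophysical analysis

`fit_pps_sigmoid()` fits
$y(x) = \frac{y_{min} + y_{max} e^{(x-x_c)/b}}{1 + e^{(x-x_c)/b}}$
to reaction times against distance. The function is increasing in $x$, so
distance must be coded with larger values meaning larger disparity and
slower RT; either a distance index (behavioural data, central points like
"D = 3.7") or centimetres (simulated sessions) work, and $x_c$, $b$
inherit the units. Condition means are fit by default (per-trial fitting
is available but non-default); no RT trimming is applied by default, since
the analysed designs report none. Fitting is trust-region
Levenberg–Marquardt (`minpack.lm::nls.lm`) on the closed-form residuals
with three starts (`b` = 1 and two range-scaled values), `y_min`/`y_max`
initialised from the extreme condition means, `x_c` at mid-range and
bounded within two levels outside the sampled range, `b` bounded away from
zero. Non-convergence is a *flagged* result (`r2 = -Inf`), never an error,
because the downstream screening rule consumes it.

`split_by_history()` implements the serial-dependence split: a trial is
labelled by whether the immediately preceding trial probed a smaller or
larger disparity; trials preceded by the same disparity or by a catch
trial, and trials at the extreme levels (for which no smaller/larger
condition exists), are excluded. With six disparities the split fits rest
on four condition means — four points, four parameters — which is why the
screening rule matters: `qc_filter()` discards a subject when any of the
three fits (pooled, smaller, larger) has $R^2 < 0.50$.
`recalibration_index()` is the central-point difference (larger − smaller);
positive values mean PPS sits farther after larger-disparity trials.

`nback_glm()` quantifies how many past trials shape the current RT: a
gamma-family GLM with the canonical inverse link (delegated to
`stats::glm`) of RT on the disparities at lags 0–9, main effects only
(the lag interactions are exposed as an open choice but not fit by
default), reporting each lag's coefficient magnitude relative to lag 0.
Rank-deficient designs (e.g. constant distance) surface as a warning with
`NA` coefficients. `recal_slope_correlation()` is the Pearson correlation
between per-subject recalibration indices and pooled `b` values — in
designs where shallow PPS gradients recalibrate more, its sign is
positive.

# The EEG global-field-power analysis

Global field power is the standard deviation of the trial-averaged
voltages across the whole montage at each time point — we fix the
*population* form (denominator = number of channels), the standard GFP
definition. GFP is non-negative and invariant to any common-mode
(reference) signal, both asserted property-style in the tests.

`preprocess_epochs()` applies the conventional chain, in this order:
amplitude-based trial rejection (any channel beyond ±100 µV — we read the
stated rejection bound as microvolts, the physiologically meaningful EEG
scale; configurable), bad-channel reconstruction by inverse-distance
weighting of the nearest good channels on the unit sphere (spherical-spline
interpolation is the exact classical alternative; the nearest-neighbour
form is kept as the default for its transparency), per-channel baseline
subtraction over −200–0 ms, then average referencing. Band-pass/notch
filtering of the continuous recording is a thin, delegated stage upstream
of this container and is not re-implemented here.

The multisensory test is paired-versus-summed: per subject, the GFP of the
averaged visuo-tactile response is compared against the GFP of the *summed*
unisensory averages (V + T, summed channel-wise before GFP). Positive
differences are supra-additive — evidence of true integration rather than
superposition. `timewise_test()` runs a t-test per time point (two-sided
by default; the sidedness is configurable since the convention is not
universal) and only reports runs of ≥ 10 consecutive points at
$\alpha < 0.01$, a guard against autocorrelation-inflated isolated hits;
on white-noise nulls the family-wise false-window rate is essentially zero
(10 consecutive independent hits at 0.01 have probability $10^{-20}$), and
the test suite confirms no false windows across 200 null replicates while
the point-wise rate calibrates at 1%. The paired-versus-summed contrast is
restricted to the interior distance levels, where both smaller and larger
preceding disparities exist, and a count-matched variant (seeded
subsampling of the more numerous paired trials) mirrors the standard
signal-to-noise control. `window_stats()` averages GFP in a fixed
130–150 ms post-stimulus window and delegates the repeated-measures ANOVAs
(distance; history × distance) to `stats::aov` with a subject error
stratum, plus pairwise paired t-tests; `contribution_map()` localises
window effects per channel for external topographic plotting.

# The synthetic generators

The generators define the study conditions the analyses are tested under;
their defaults are the printed designs.

* `exp1_schedule()`: the looming design — 36 multisensory trials at each of
  six disparities, 36 visual catch trials, 8 × 6 unisensory tactile trials
  (300 in total), 500 ms ITI. Tactile offsets {1.83 … 3.43 s} map linearly
  and negatively onto distance via a 200 cm start (the value consistent
  with every printed distance for an onset "at approximately 2 m") and
  75 cm/s, with visual motion starting 0.3 s after a 1.2 s fixation;
  distances {55.25 … 175.25 cm} and time-to-contact values
  {736.7 … 2336.7 ms} follow exactly.
* `exp2_schedule()`: the static design — per block, 40 VT trials at each of
  seven distances {3.3 … 62.9 cm}, 10 V trials at the five interior
  distances, 30 T trials (360/block), ITI uniform on 1250–2250 ms. The
  printed distance list is used verbatim (62.9 cm for the farthest LED,
  although uniform 3.3 cm spacing would give 62.7).
* `generate_rts()`: multisensory RTs drawn around the four-parameter
  sigmoid with the central point displaced by ±δ/2 according to the
  previous trial's disparity — so the pooled fit sits between the split
  fits, as observed; tactile RTs distance-independent and slower; catch
  trials response-free. Noise is gamma-multiplicative with CV 0.2 by
  default — the analysed reports state no per-condition RT dispersion, so
  this is a documented assumption of typical simple-RT variability, not a
  reproduced value (lognormal and noise-free variants are available).
* `generate_eeg()` / `generate_evoked_study()`: fixed zero-mean channel
  topographies (posterior-positive "visual", centro-parietal "tactile") on
  a Fibonacci-hemisphere montage carrying a canonical evoked waveform; the
  paired response is the sum of the unisensory patterns scaled, inside a
  124–158 ms gain window, by a gain that decreases with distance and is
  boosted after larger-disparity history at the middle distances; white
  sensor noise. The evoked-study variant draws per-subject condition
  *averages* directly (noise ÷ √n_trials) so that replicate-heavy null
  calibrations stay cheap. The generator makes no attempt at realistic EEG
  spectra, artifacts, or oscillatory structure — passing tests demonstrate
  correctness of the analysis machinery under the assumed signal model,
  not robustness to real-world EEG pathology.

All generators are bit-reproducible under a fixed seed, and every source of
randomness in the package is seed-threaded.

# Problem sizes

The shipped test and reproduction scripts run at the study's native scales
where that is cheap (sigmoid recovery at 36 reps/condition across 100
simulated subjects; shift recovery at the full ~2800-VT-trial static
design; 200-replicate null calibrations) and at 20 network trials per
condition — the simulated design — for the network results, with 10–20
seeded session replicates where a direction probability or a mean shift is
the quantity of interest.

# Known limitations

* The network's numeric constants are this package's calibration, not an
  inherited table; conclusions should rest on the qualitative structure
  (direction of the shift, the three $\tau_H$ regimes), which is what the
  tests pin down. The magnitude of the central-point shift is
  tolerance-checked, not exact.
* Network RTs are threshold-crossing times in network milliseconds; they
  exclude motor latency and are not on the human RT scale. Comparisons are
  made on recalibration differences, never absolute RTs.
* Velocity-driven PPS enlargement requires an adaptation mechanism outside
  this model's scope (see above).
* With six disparities the history-split fits interpolate four points with
  four parameters; single-session estimates of the central-point shift are
  correspondingly noisy, which is why direction probabilities and means
  over seeded replicates are the reported quantities.
* The EEG machinery automates only the amplitude criterion for artifact
  rejection; visual-inspection rejections of real pipelines are not
  reproducible and not modelled.
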