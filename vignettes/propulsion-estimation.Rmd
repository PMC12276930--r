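---
title: "Estimating propulsion from insole and IMU data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating propulsion from insole and IMU data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(gaitfuse)
```

# The estimation problem

Propulsion — the anterior (positive) portion of the anterior–posterior
ground reaction force (AP GRF) during stance — is a key clinical variable
in hemiparetic gait: people post-stroke generate less propulsion on the
paretic leg, and changes in peak propulsion, propulsion impulse and
left/right propulsion symmetry track rehabilitation progress. Measuring AP
GRF requires force plates, so monitoring outside the lab needs an
estimator driven by wearable sensors. Two wearables carry complementary
information: pressure insoles measure the normal (vertical) load
distribution under the foot, and inertial measurement units (IMUs) measure
segment kinematics. Neither alone determines the shear (AP) force;
`gaitfuse` implements an individualized CNN–LSTM estimator that fuses
both, together with a synthetic session simulator that makes the whole
pipeline testable offline with exact ground truth.

All forces are expressed in percent bodyweight (%BW = force / (mass · g) ×
100), anterior positive. Per-stride clinical metrics are: peak propulsion
(max AP GRF over stance, %BW), its timing (argmax as % of stance, earliest
frame on ties), propulsion impulse (trapezoidal integral of the positive
AP GRF region over stance, %BW·s), and propulsion symmetry (100 ·
paretic impulse / two-limb total, % — 50 % is perfect symmetry).
Estimation errors are compared against published minimal-detectable-change
(MDC) thresholds for treadmill walking post-stroke: 0.80 %BW (peak),
0.24 %BW·s (impulse) and 3.92 % (symmetry), using strict inequality.

# The synthetic session generator

No public dataset accompanies this problem setting, so the package ships a
seeded generator (`simulate_session()`) that emulates the treadmill
protocol and the three native sensor rates, with exact per-stride ground
truth as the oracle for every downstream stage.

**Speed protocol.** Each bout holds a commanded speed `v2` constant, then
sweeps between `v1` and `v3` with plateau holds. Clinical bouts: `v2` on a
70–130 %CWS grid (CWS = comfortable walking speed), `v1,v3 = v2 ∓ 20
%CWS`, 240 s bouts with a 120 s constant period and 15 s holds. Healthy
bouts: `v2` on a 0.6–1.4 m/s grid, `v1,v3 = v2 ∓ 0.2 m/s`, 600 s bouts,
180 s constant, 60 s holds. Ramps always change speed by `v2 − v1` in
30 s. A `duration_scale` argument shortens `t1`, `t4` and the holds
(never the ramp slope) for desk-scale experiments.

**Stride kinetics.** The generator is deliberately parametric so every
quantity has a closed form. Stride period follows `T(v) = 1.1 ·
v^(−0.4)` s clamped to [0.8, 2] s, with a 2 % lognormal-like jitter;
stance occupies `0.68 − 0.05 v` of the stride (clamped to [0.55, 0.70]).
Vertical GRF over stance fraction τ is a double-hump
`A(v) · sin(πτ)(1 + 0.4 cos 2πτ)` clamped at zero; AP GRF is a negative
braking half-sine on τ ∈ [0.02, 0.46] followed by a positive propulsion
half-sine on τ ∈ [0.54, 0.98]. A half-sine of amplitude `A` and duration
`d` integrates to `2Ad/π`, which is the recorded true impulse. The
paretic side of a clinical subject has its propulsion amplitude scaled by
`1 − impairment`. Swing forces are exactly zero; force-plate noise
(default 0.2 %BW) is added within stance only.

**Shared latents (why fusion wins by construction).** Each stride draws
two independent N(0, 0.08) latents: a kinematic gain `g_k` and a loading
gain `g_l`. The propulsion amplitude is `P0(v) · (1 − impairment) · (1 +
g_k + g_l)`; the IMU motion amplitudes scale with `1 + g_k`; the insole
pressure gain scales with `1 + g_l`. Either modality alone therefore
leaves the other latent's variance (about 8 % of the propulsion
amplitude) as an irreducible error, while the fused model can in
principle recover both — the multi-modal advantage is a designed,
testable property of the generator, not an accident of training. A
regression oracle on the recorded truth verifies that the single-modality
residual is at least twice the dual-modality residual.

**Insole model.** 233 sensels on a fixed foot-shaped mask inside a 31×11
grid (rows toe→heel, 0-based coordinates). Frames mix a heel blob and a
forefoot blob whose weights shift smoothly across stance (a smoothstep of
τ), so the center of pressure (CoP) — the pressure-weighted centroid,
recorded before noise and held through swing — travels heel to toe. Total
pressure is proportional to the analytic vertical GRF times the stride's
loading gain; each sensel adds a constant offset (drawn once per stream
from [1, 3] arbitrary units) plus white noise. Pressure units are
arbitrary: commercial insoles report uncalibrated kPa-like values, and
nothing downstream depends on the scale because normalization is
range-based.

**IMU model.** 21 channels per side: foot/shank 3-axis acceleration,
foot/shank/thigh 3-axis angular rate, and foot/shank/thigh pitch and roll
Euler angles. Angles are harmonic functions of stride phase (all shapes
vanish at phase 0 so angles are continuous across stride boundaries) with
speed-dependent ranges scaled by `1 + g_k`; angular rates are the central
finite difference of the noise-free angles (so the rate–angle identity is
exact by construction); accelerations are the exact gravity projection
through the pitch/roll attitude plus a speed-scaled periodic motion term,
plus a decaying heel-strike impact transient on the foot z axis (12
m/s², 20 ms time constant) that alignment uses for clock matching. With
no strides the stream reduces to static posture and the accelerometer
norm equals g exactly.

**Clocks.** The insole and IMU streams carry configurable constant clock
offsets (defaults 20 ms and 10 ms; the convention is that a sample
recorded at `t` was physically taken at `t + offset`). Alignment must
recover them from the data.

**Interventions.** `perturb_propulsion()` emulates an active intervention
(functional electrical stimulation or an exosuit) by shifting the
propulsion amplitude of strides inside a time window by `delta` %BW. The
shift is routed through `g_k`, so kinetics, ground truth and IMU channels
change coherently while insole loading does not; the session is
re-simulated under its original seed, so `delta = 0` is bit-identical and
amplitudes clamp at a small positive floor for large negative `delta`.

**What the generator does not emulate:** musculoskeletal dynamics,
double-support force sharing, sensor saturation and drift, Bluetooth
packet loss, or day-to-day sensor placement shifts. Tests passing on this
generator demonstrate that the pipeline is internally correct and that
fusion recovers designed shared structure — not that the architecture
reaches any particular accuracy on real hemiparetic gait.

# Preprocessing

The chain (defaults in `preproc_config()`) mirrors standard practice for
multi-rate wearable recordings:

1. **Sensel zeroing** (`zero_insole()`): per-sensel offsets measured over
   a ~0.3 s window inside the longest low-pressure (foot-off) run are
   subtracted.
2. **Temporal filtering** (`lowpass_zero_phase()`): zero-phase 2nd-order
   Butterworth, 10 Hz cutoff, applied to insole, IMU and force-plate
   signals. Forward–backward filtering squares the magnitude response, so
   the amplitude ratio at the cutoff is exactly 1/2; mean-centering plus
   odd-reflection padding makes the unit DC gain exact and suppresses
   edge transients. Because |H|² at 4–5 Hz is still ≈ 2–6 % below 1,
   re-filtering is only near-idempotent for content well below the
   cutoff (< 1 % RMS change at ≤ 3 Hz).
3. **Spatial smoothing** (`spatial_gaussian()`): a σ = 0.5 grid-unit
   Gaussian on the sensel layout, renormalised over in-mask neighbours.
   σ = 0.5 is used as the fixed standard choice; the sensitivity sweep
   that motivates it is out of scope here.
4. **Event detection** (`detect_heel_strikes()`): rising/falling
   crossings of 3 % of the per-stride vertical-load peak, 0.4 s
   debounce, per-cycle threshold refinement. On clean simulated data this
   lands within ±10 ms of truth; the same detector runs on force-plate
   and insole channels.
5. **Clock alignment** (`align_streams()`): the insole offset is
   estimated by cross-correlating total insole pressure with vertical GRF
   on the common grid (parabolic sub-frame refinement); the IMU offset by
   matching foot-accelerometer impact spikes (half-sample-corrected) to
   force-plate heel strikes. Both recover injected offsets to within one
   100 Hz frame. All streams are then linearly interpolated onto the
   force-plate clock and reduced to 100 Hz; the AP GRF target is the mean
   of each 10 ms bin. Strides overlapping a recording gap longer than one
   stride period are dropped with a message.
6. **Swing baseline** (`swing_baseline_subtract()`): the per-sensel mean
   over the first stride's swing is removed (first available swing, with
   a warning, if stride one has none).
7. **Imaging** (`resize_pressure_map()`): frames are embedded on the
   31×11 bounding grid (off-mask cells zero — the only reconstruction the
   layout supports) and resized to 28×28 by pixel-area interpolation,
   which preserves constants and the grid mean; maps are clamped at zero.
   The spatial Gaussian runs on the native sensel grid *before* resizing,
   where the kernel's units are physical sensel pitches.
8. **Normalization** (`fit_minmax()`): grouped min–max to [0, 1] from
   training frames only — one group per IMU sensor-and-signal block
   (e.g. the three foot-acceleration axes share constants), one for the
   CoP pair, one for the whole pressure map. Test data may fall outside
   [0, 1]; constant groups normalise to 0 with a warning.
9. **Sequences** (`make_sequences()`): the LSTM consumes the 5 frames
   `t−4 … t` (≈ 50 ms) within the same stance segment, left-padded by
   repeating the segment's first frame; the CNN input and the target are
   those of frame `t`. Swing frames are removed before learning.

Conventions: 0-based frame indexing on the sensel grid, half-open
intervals, stance runs 0 % at heel strike to 100 % at toe-off, anterior
positive. Forces stay in %BW throughout (the simulator already emits
%BW; with raw Newton streams the bodyweight scaling would sit in the
alignment step).

# Estimator architectures

Three configurations share one family (`model_spec()`):

* **Insole branch (CNN).** The 28×28 map passes through two
  convolutions (kernels 5 then 3, LeNet-style channel counts 6 and 16 at
  full width) each followed by 2×2 average pooling, then a
  fully-connected layer of 84 units.
* **IMU/CoP branch (bidirectional LSTM).** Sequences of 5 timesteps feed
  three bidirectional LSTM layers of 128 hidden features per direction,
  then FC layers 256–256–84. The branch summary concatenates the forward
  direction's final state with the backward direction's final state
  (each sees the whole window). In fusion mode the per-timestep input is
  the 21 IMU channels plus the 2 CoP channels through one shared LSTM; in
  IMU-only mode, the 21 IMU channels; in insole-only mode the LSTM
  consumes the CoP pair alone.
* **Head.** The branch outputs (84 + 84 in fusion and insole-only; 84 in
  IMU-only) feed a merge FC layer of 168 units (84 in the single-input
  models), an FC layer of 10 units, and a final *linear* unit producing
  the signed AP GRF estimate — a 10-unit layer cannot be a scalar target,
  so the linear 10→1 map is the minimal completion, and ReLU is omitted
  after it because AP GRF is signed. ReLU follows every other layer.

Open wiring choices resolved here: one shared LSTM for IMU+CoP (rather
than two parallel LSTMs merged later); each leg's model consumes only
ipsilateral sensors; weights use seeded fan-in uniform initialisation.

No deep-learning framework is assumed: forward and reverse passes are
written as BLAS matrix operations, with the batched convolutions and
average pooling in compiled code (`src/conv.cpp`). All gradients are
verified against central finite differences in the test suite, in all
three modes.

# Training, splits and transfer

Optimisation is Adam (lr 5e-4, weight decay 1e-5 at full scale) on mean
squared error; individual models keep the best-validation-loss weights,
pooled pre-training keeps the last epoch, fine-tuning keeps
best-validation. Splits:

* **By bout** (`split_by_bout()`): the two bouts nearest the comfortable
  speed become validation (nearer; ties to the earlier bout) and test;
  the rest train.
* **By ratio** (`split_by_ratio()`): per bout, the first `f` ∈ {0.15,
  0.30, 0.45, 0.60} of the timeline trains, the next 10 % validates, the
  remainder tests; the *reverse* variant takes the last `f` (which
  contains the speed ramps) for training and the 10 % before it for
  validation.
* **Transfer** (`pretrain_pooled()`, `finetune()`): healthy training
  frames are pooled to pre-train one fusion model (twice the epochs,
  last-epoch weights); fine-tuning restarts from those weights on the
  clinical subject's train+val frames — all of them, or the later half of
  each bout's portion (`fraction = 0.5`) — keeping the pooled
  normalization constants so inputs stay on the pre-training scale, and
  selecting on the clinical validation frames. The test set is never
  touched.

**Desk preset.** `train_preset("desk")` is the configuration used for the
package's own multi-seed experiments: the same architecture family at
reduced width (4/8 convolution channels, two bidirectional layers of 32
hidden features, FC 64–84), 30 epochs at lr 2e-3, batch 128, and 4×
thinning of training frames (sequences still reference the un-thinned
100 Hz history). Problem sizes used by the shipped experiments: the
acceptance script simulates 4-bout clinical sessions at
`duration_scale = 0.5` (120 s bouts) with five session seeds, per-leg
fusion models; the test suite's learning blocks use `duration_scale =
0.2` with the same five-seed design. These sizes are the package's
choices for routine reproducibility; `train_preset("paper")` restores the
full-width 500-epoch recipe.

# Numerical choices and degenerate inputs

Positive-region impulses clamp at zero rather than root-finding the lobe
boundary; at 100 Hz the O(Δt²) error is far below reporting precision.
Peak-timing ties take the earliest frame. MDC comparisons are strict.
Symmetry uses per-session mean impulses (negative estimated impulses are
floored at zero before averaging). Degenerate cases are explicit errors
or flagged results: empty stance masks, zero total impulse, constant
normalization groups, too-short filter inputs, paired tests with constant
differences (degenerate flag, no p-value), signals with no detectable
events (empty result plus warning).

# Known limitations

The generator's latent structure makes fusion provably useful but is far
simpler than real kinematic–kinetic coupling; accuracy numbers obtained
here characterise the pipeline, not clinical performance. The simulator
emits forces directly in %BW and co-registered modalities up to constant
clock offsets, so alignment never faces drifting clocks. Desk-preset
models are narrower than the full architecture; the full-width recipe is
available but needs hours of CPU per model. Angular-rate channels stand
in for the ambiguous "angular acceleration" channel naming in the
measurement inventory; the 21-channel count is unchanged either way.
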