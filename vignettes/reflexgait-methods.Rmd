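---
title: "reflexgait: methods and modeling choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{reflexgait: methods and modeling choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reflexgait)
```

This vignette documents the modeling and numerical choices behind the
package, in processing order. It is meant for readers who want to know
*why* each stage is shaped the way it is, not just what the functions do.

## 1. Synthetic recordings

`generate_speed_sequence()` draws a random walk of belt-speed settings
whose per-step increment is bounded (0.05–0.1 m/s) and whose realized range
stays close to the requested range. Stride (cadence) duration follows the
inverse-speed law `T = 1.4 / v` seconds, clipped to [0.8, 1.6] s, with
multiplicative log-normal stride jitter. Contralateral heel strikes are
placed near mid-stride.

FSR loading curves are `sin^2` pulses occupying 60% of each stride. EMG is
synthesized as

```
EMG(t) = m(t) * c(t),   m(t) = sum_k kernel_k * FSR_k (t)  *  speed gain,
```

where `c(t)` is a broadband carrier scaled so that the rectified-and-smoothed
carrier has unit mean (`sqrt(pi/2)` scaling of a unit-variance noise
carrier). This makes the conditioning chain an approximately unit-gain
estimator of `m(t)`: `condition_emg()` of a synthetic channel converges to
the modulating envelope as SNR grows, which is what makes oracle-based
testing of the identification stage possible.

The rectus femoris ground-truth kernel carries two bumps half a stride
apart (at 0.05 and 0.55 of a stride). The spacing matters: a transfer
*curve* is the kernel convolved with the mean heel pulse, and a pulse that
occupies 60% of the stride smears kernel features by roughly a third of a
stride. Bumps closer than that merge into a single peak and the
hip-flexion / knee-extension roles of the two RF peaks could not be
disambiguated downstream.

## 2. Conditioning

`condition_emg()` implements the classical linear-envelope chain: DC
removal, linear-phase FIR band-pass 20–500 Hz (windowed-sinc, group-delay
compensated; at a 1 kHz rate the upper edge is capped at 0.98 × Nyquist
because 500 Hz would sit exactly at Nyquist), full-wave rectification, and
a fourth-order zero-lag (forward–backward) Butterworth low-pass at 6 Hz.

Two analytic facts anchor the tests. A band-passed unit sinusoid rectifies
to mean `2/pi`; note that this is an asymptotic (continuous-time) value —
the *discrete* mean of a rectified sine at 10 samples per cycle is exactly
3% lower, so the analytic check is run at ≥ 20 samples per cycle. A DC
input conditions to exactly zero because of the explicit mean removal.

## 3. Heel strikes and event-related averaging

`detect_heel_strikes()` finds rising crossings of 10% of the channel
maximum (scale invariant), debounces at 200 ms, and then backtracks to the
onset of the loading curve (the last sample at or below `1e-6` of the
maximum, walking back at most one debounce window). The backtracking is
what lets event times round-trip through the FSR synthesis within one
sample; a plain threshold crossing lands tens of milliseconds into the
`sin^2` rise.

`event_related_average()` averages fixed-length windows aligned to the
strikes, dropping (and counting) events whose window leaves the record;
`mean_heel_template()` is the one-stride ERA of a heel channel and serves
as the canonical loading curve for transfer-curve construction.

## 4. Identification

`lms_identify()` runs a sample-sequential normalized LMS filter (compiled
inner loop) with filter length two mean strides, `mu = 0.01`, 100 passes
over the record. `wiener_solution()` provides the independent batch oracle:
FFT-based autocorrelation, Toeplitz normal equations, small ridge
(`1e-8`) for conditioning. The identified response is truncated to one
stride with a half-Hanning taper over its second half
(`apply_half_hanning()`).

A point worth stressing for anyone reusing the module: *periodic* gait
excitation has a line spectrum at the stride harmonics, so the
identification problem is ill-posed between harmonics — both LMS and the
batch solution then agree with each other but not with the generating
kernel. Kernel recovery is only expected (and only asserted) under
broadband excitation; the acceptance suite uses sparse Poisson impulse
trains at constant belt speed for exactly this reason. Decimation by 4
before identification block-means the input (preserving impulse area) and
subsamples the desired signal; the equivalent kernel at the reduced rate
is the original subsampled and scaled by the factor.

## 5. Twitch model and curve fitting

The muscle-twitch surrogate is the peak-normalized bi-exponential

```
h(s) = A * (exp(-s/tau1) - exp(-s/tau2)) / (exp(-s*/tau1) - exp(-s*/tau2)),
s = t - T0 >= 0,   s* = tau1*tau2*log(tau1/tau2)/(tau1 - tau2),
```

with the analytic critical limit `A*(s/tau)*exp(1 - s/tau)` as
`tau2 -> tau1`. This normalization guarantees peak value `A` in both
branches and continuity at the critical limit. (A normalization constant of
the form `tau1*tau2/(tau1-tau2)^2` — sometimes seen for second-order
twitch models — diverges at the critical point and does not give peak `A`;
it is incompatible with those two invariants, which is why the
peak-normalized form is used here.)

`fit_curve()` is a bounded Levenberg–Marquardt fit (`minpack.lm`) started
from the neutral initialization (`tau = 50 ms`, `T0 = 0`, `A = peak`) plus
three deterministic data-derived starts, keeping the lowest-residual
solution; the residual surface has local minima in `(tau, T0)` and a
single start is not reliable. Noiseless round trips through printed
parameter sets recover `tau` within 0.5% and `T0` within a fraction of a
millisecond.

`finalize_motor_tf()` evaluates the fit at the 200 Hz control rate: hip
functions last one stride (1000 ms), knee functions one step (500 ms) with
their delay constant forced to zero — the sprung knee supplies its own
mechanical latency, playing the role that the double-support delay plays
between heel strike and contralateral toe-off in human walking.

## 6. Reflexive control

The controller (`reflex_controller()` / `controller_step()`, offline
equivalent `motor_drive()`) is deliberately minimal: unit impulses on
contact rising edges and on anterior-extreme-angle (AEA) up-crossings start
fixed transfer-function playbacks — hip flexion and knee flexion from the
*contralateral* contact, hip extension from the *ipsilateral* contact,
knee extension from the ipsilateral AEA — and overlapping playbacks sum.
The path is linear and time invariant, there is no internal oscillator
(all-zero sensors produce identically zero output), and the only
nonlinearities are the soft extreme-angle guards and the output rail.

`simulate_walker()` closes the loop around a deliberately simple surrogate
plant (first-order hips, motor+spring-lagged knees with a kneecap stop,
kinematic touchdown). It exists to exercise the controller — sustained
stepping, falls, determinism — not to reproduce any particular hardware.
The walker starts with only the stance foot in contact: a symmetric
double-support start fires cancelling playbacks on both legs and the gait
never develops.

`stability_heuristic()` encodes the observed tendency that the hip
*extensor* activation should stay above half its peak longer than the hip
flexor's (`ext ΔT50 > flex ΔT50`) for a stable gait. It is a tendency, not
a guarantee: among the twelve shipped reference sets
(`reference_hip_characteristics()`) there are documented exceptions in
both directions — one set walked although the rule says no, and two
stumbled although the rule says yes.

## 7. Pipeline

`run_pipeline()` chains everything per subject (detect → segment →
condition → decimate → identify → truncate → convolve → segment →
fit) and aggregates fitted parameters across subjects under four policies:
mean over all subjects, means within a tag (e.g. sex), per-subject sets,
and per-function minimum-identification-MSE selection. The aggregate set
is deployed on the surrogate walker and reported together with gait
metrics and the stability verdict.
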