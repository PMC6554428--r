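---
title: "Decoding a hybrid motor-imagery/SSVEP/blink BCI: methods and design choices"
author: "hybridBCI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding a hybrid motor-imagery/SSVEP/blink BCI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridBCI)
```

## The decoding problem

A hybrid brain-computer interface steers a quadcopter with three EEG
modalities recorded from a 12-electrode montage (10 sensorimotor
electrodes, `Oz`, `Fp2`; reference `Cz`; 1000 Hz):

* **Motor imagery (MI mode)** — imagining left/right-hand movement
  attenuates the mu rhythm (9–12 Hz) over the contralateral sensorimotor
  cortex (event-related desynchronization, ERD) and enhances it
  ipsilaterally (ERS). Decoded commands: fly left-forward (yaw −42°,
  0.25 m/s) or right-forward (+42°, 0.25 m/s).
* **SSVEP mode** — gazing at an LED flickering at 12.4 Hz (top) or 18 Hz
  (bottom) evokes an occipital oscillation at the stimulus frequency and
  its harmonics. Decoded commands: rise (+0.2 m/s) or fall (−0.3 m/s).
* **Conscious double blink** — two deliberate blinks within one 1.5 s
  block produce two large negative troughs at `Fp2`. Decoded as: hover
  and toggle between MI and SSVEP mode.

Decoding runs on 1.5 s windows emitted every 1 s (0.5 s overlap), one
command per stride. Every window is first screened for a blink; only if
none is found is it passed to the active mode's classifier.

## Blink detection: counting troughs

The `Fp2` series is band-passed to 0.3–30 Hz (zero phase), preserving
the blink waveform while removing baseline drift and high-frequency
noise. Local minima at or below `−h` are accepted greedily left-to-right
subject to a minimum spacing, and a count of at least 2 is a detection.

Parameter choices that the description of the method leaves open:

* **Detection threshold.** The double-blink gesture produces exactly two
  troughs, so detection fires at count ≥ 2 (`countThreshold = 2`,
  configurable). A strict "more than 2" rule would make the two-blink
  gesture itself undetectable.
* **Spacing.** The nominal trough spacing is `d = 0.75` s. An *average*
  spacing cannot be enforced on two troughs without a tolerance, so the
  rule is implemented as a minimum separation of `beta * d` with
  `beta = 0.6`, i.e. accepted troughs must be ≥ 0.45 s apart.
* **Threshold calibration.** "Averaging over the calibration set" is
  read as: per calibration blink trial, take the deepest trough of the
  filtered `Fp2` series; average those depths; scale by a safety factor
  `alpha = 0.5`. Blinks at least as strong as the trained strength then
  clear the threshold with a 2× margin, while the 0.3–30 Hz background
  (a few µV RMS) stays far below it.
* **Troughs** are samples strictly lower than the left neighbour and no
  higher than the right neighbour, so a flat-bottomed trough counts once
  (at its first sample).
* A **refractory stride** follows every detection: a physical blink pair
  can span two overlapping windows, and without the refractory period
  one gesture could toggle the mode twice, undoing itself.

## SSVEP recognition: canonical correlation

For each candidate frequency $f$, a reference set
$Y_f = [\sin 2\pi f t;\ \cos 2\pi f t;\ \sin 4\pi f t;\ \cos 4\pi f t]$
(two harmonics, `Nh = 2`) is compared with the 5–40 Hz filtered `Oz`
series $X$ by the first canonical correlation
$$\rho_f = \max_{a,b}\ \mathrm{corr}(a^\top X,\ b^\top Y_f),$$
and the frequency with the largest $\rho$ wins; exact ties fall to the
lower frequency (an arbitrary but fixed rule). $\rho$ is computed from
the largest singular value of the whitened cross-covariance
$C_{xx}^{-1/2} C_{xy} C_{yy}^{-1/2}$, with a relative ridge of
$10^{-8}\,\mathrm{tr}(C)$ on each auto-covariance: over 1.5 s a
sinusoid's sample covariance can be numerically near-singular, and the
ridge bounds the conditioning without measurably changing $\rho$. A
zero-variance input yields $\rho = 0$ with a warning rather than an
error, since a flat block is a legitimate (if degenerate) recording.
The unit tests check this solver against `stats::cancor` and against a
brute-force multistart maximization of the defining correlation.

## Motor imagery: complete-information CSP

Trials are band-passed to 9–12 Hz and re-referenced with a common
average reference (CAR) over the 10 sensorimotor electrodes. Per-trial
covariances are normalized to unit trace and averaged within class, and
the filter bank $W$ solves the generalized eigenproblem
$\bar C_1 w = \lambda (\bar C_1 + \bar C_2) w$ — simultaneous
diagonalization of the two class covariances. Rows are sorted by
decreasing $\lambda$; signs are fixed so each filter's
largest-magnitude coefficient is positive (CSP signs are arbitrary).

Classic CSP keeps only the `m` first and `m` last filters ($Q_1$) and
their normalized log-variance features
$$\lambda_i = \log \frac{(ZZ^\top)_{ii}}{\mathrm{tr}(ZZ^\top)},$$
which satisfy $\sum_i e^{\lambda_i} = 1$ and are invariant to amplitude
scaling. The *complete-information* variant additionally projects each
trial through the intermediate filters ($Q_2$), computes their
log-variance features, reduces them by PCA (fitted jointly on both
classes' training features) to `k` dimensions $f_2'$, and classifies the
concatenation $F = [f_1, f_2']$ with a linear SVM.

Open choices, fixed as follows:

* `m = 2` (8 of 10 channels would be extreme; 2 per side is standard
  practice and leaves 6 intermediate filters), `k = 1` (the online
  procedure reduces the intermediate features "to one dimension").
  Both are arguments of `fitCICSP()`; `k = 0` recovers plain CSP.
* Natural logarithm in the feature definition.
* Linear-kernel SVM with cost 1, no probability calibration.
* A relative ridge of $10^{-9}\,\mathrm{tr}$ is applied before the
  eigen-solve, split evenly between the two class covariances. The
  split matters after CAR: re-referencing removes the common-average
  direction from the data, and placing the ridge symmetrically gives
  that null direction eigenvalue 1/2, sorting it into the middle of the
  bank instead of displacing a discriminative edge filter.
* **Online prediction** of a 1.5 s window computes $f_1$ from the full
  window, splits the window into three 0.5 s sub-windows for the
  intermediate path, PCA-reduces each sub-window's feature vector and
  *averages* the three into one $f_2'$ (the alternative — per-sub-window
  voting — is not used; averaging keeps the feature space identical to
  training). Batch (`predictCICSP`) and online (`predictMIOnline`)
  predictions agree on the large majority of high-SNR windows, which the
  test suite checks.

## The controller

`runSession()` streams windows through `controllerStep()`: blink check
first, then the active mode's decoder; a detection emits `HOVER_SWITCH`
(zero velocities) and toggles the mode. The initial mode defaults to
SSVEP (the craft starts from hover, where vertical control is the
natural first axis) and is configurable, since nothing in the protocol
fixes the takeoff mode. The command log is a plain data frame, one row
per stride, and is bit-reproducible for a fixed recording and model.

## Flight-performance metrics

For a task with start-to-gate displacement $D$ and gate width $W$, the
Fitts-law index of difficulty is $\log_2(D/W + 1)$ bits (1.237 bits for
the bundled geometry, $D = 4.75$ m, $W = 3.5$ m). The analogous
information transfer rate divides this by the average gate acquisition
time AGAT = flight time / gates passed. Percent task correct is
gates/(gates + failures), with failures = 2·trials − gates for the
two-gate task.

Two recorded quirks of the published summary tables:

* The OBUT formula as printed (crossings / (total time / average trial
  time)) reduces algebraically to crossings per trial, which contradicts
  every printed OBUT value; the printed values equal crossings per
  minute of flight time. `obut()` implements both; the table-consistent
  variant is the default.
* The per-subject ITRs of two subjects (and the AGAT average) appear to
  be derived from *rounded* intermediate values. `summarizeFlights()`
  always uses unrounded intermediates; the acceptance tests compare
  those two cells with a ±0.02 allowance and all others at printed
  precision.

## The synthetic-EEG generator

`generateBackground()` draws, per channel, pink noise (power spectral
density ∝ 1/f, default 5 µV RMS) and adds, on the sensorimotor channels
only, a 10 Hz mu oscillation (default 10 µV amplitude) with an
independent random phase per channel. The per-channel phase is a
deliberate deviation from a single common oscillator: scalp mu is not
phase-locked across hemispheres, and a perfectly common rhythm would be
annihilated by the CAR filter — worse, after re-referencing it would
leave *equal* residual variance on both hemispheres regardless of ERD
side, making the left/right classes inseparable by any variance-based
spatial filter. Phase-incoherent oscillators survive CAR essentially
intact, so the generator actually exercises the contrast the decoder is
built to find.

The injectors add structure on top: `injectMIERD()` scales the mu-band
component by $1 - \text{depth}$ contralaterally (default depth 0.8) and
$1 + 0.25\,\text{depth}$ ipsilaterally; `injectSSVEP()` adds the
fundamental (5 µV) plus first harmonic (ratio 0.5) at `Oz`;
`injectBlinks()` subtracts 150 µV, 0.2 s raised-cosine pulses at `Fp2`.
No signal-to-noise figures are published for any pattern, so these
amplitudes are calibration choices — set once to values a practitioner
would call clean calibration-quality EEG (band-limited SNR of roughly
10:1 for mu, 1.5:1 broadband for SSVEP, and blink troughs an order of
magnitude above background) — and the recovery rates measured on them
validate the *decoders*, not any published human accuracy.

Everything is deterministic given the config seed; scripted sessions
(`generateSession()`) seed each intent span independently, so a span's
content does not depend on the spans before it.

What the generator does **not** emulate: volume conduction and channel
correlation, eye-movement dipole topographies (blinks appear at `Fp2`
only), non-stationary rhythms, amplifier artifacts, or line noise.
Passing recovery tests on this data therefore demonstrates correctness
of the decoding chain under its own assumptions, not robustness to real
scalp EEG.

## Problem sizes and numerical tolerances

The test suite runs most unit tests at 250 Hz (the generator's fast-test
mode) and the recovery studies at the calibration conditions — 1000 Hz,
1.5 s windows, 40 trials per class for training and 40 held-out windows,
100 SSVEP windows, 50 blink windows, and a 20 s scripted session —
sizes chosen to estimate rates on a comfortably fine grid (2.5
percentage points or better) while keeping a full run in tens of
seconds. Filters are 4th-order Butterworth run forward–backward with
odd-reflection padding of three time constants; the CSP diagonalization
identity is checked to 1e-6; the CCA solver is checked against a
brute-force oracle to 1e-3.

## Known limitations

* The SSVEP path always answers one of the candidate frequencies; there
  is no idle/reject rule, matching the described protocol.
* Blink detection assumes the double-blink cadence was trained; single
  spontaneous blinks produce one trough and are correctly ignored.
* `fitCICSP()` is a two-class decoder; multi-class extensions are out of
  scope.
* The EDF writer covers continuous equal-rate 16-bit recordings only
  (no EDF+ annotations).
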