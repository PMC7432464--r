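---
title: "Methods: oscillation spectra, phase-amplitude coupling, and in vivo LTP quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: oscillation spectra, phase-amplitude coupling, and in vivo LTP quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lfpltp)
```

`lfpltp` implements a complete analysis chain for two kinds of in vivo
rodent electrophysiology data: continuous local field potential (LFP)
recordings (nominal 512 Hz sampling, analog band 1--256 Hz) and evoked
field EPSP (fEPSP) sweeps around a tetanization protocol (nominal 3 kHz).
This vignette documents the models, the defaults and the numerical
choices, and states what the synthetic-data tests do and do not show
about real recordings.

## Relative power spectra

Spectral density is estimated by Welch's method: the channel is cut into
2 s sliding windows with 50% overlap, each window is mean-detrended and
Hann-tapered, and the one-sided periodograms are averaged. The averaged
periodogram is then expressed as *relative* power: bins within the
analysis band (default 1--256 Hz, i.e. up to Nyquist at 512 Hz) are
normalized to sum to one. Relative power removes between-animal
differences in absolute signal amplitude, which are dominated by
electrode impedance and geometry rather than physiology; the package
asserts scale invariance to within 1e-9.

Choices worth knowing:

* **Overlap** is not dictated by the 2 s sliding-window protocol; 50%
  with a Hann taper is the standard Welch compromise and is
  configurable.
* **Detrending** subtracts the per-window mean so DC does not leak into
  the 1 Hz bin.
* **Normalization order**: the averaged periodogram is normalized once,
  rather than normalizing each window and averaging. Under stationarity
  the two agree in expectation; the chosen order keeps the estimator a
  plain ratio of periodogram sums.
* **Band summaries** (`band_relative_power`) use half-open bins
  `[lo, hi)` so the conventional 1--20 Hz and 20--100 Hz summaries
  partition the axis without double-counting the 20 Hz bin.
* **Nyquist bin**: the normalization band runs to 256 Hz inclusive. The
  one-sided PSD does not double the Nyquist bin (it has no mirror
  image), so on white noise that single edge bin carries about half the
  relative power of an interior bin. This is a property of one-sided
  spectra, not a defect; band summaries are insensitive to it.

Group spectra are the per-bin mean across animals with a t-based 95%
confidence interval; the animal is the unit of replication.

## Phase-amplitude coupling

For a phase frequency $f_L$ and amplitude frequency $f_H$ the signal is
band-pass filtered around each, the analytic signal is formed by the
Hilbert transform, and the coupling strength is the modulation index of
the composite signal

$$ z(t) = A_H(t)\, e^{i\varphi_L(t)}, \qquad
   \mathrm{MI} = \left| \frac{1}{T}\sum_t z(t) \right|, $$

where $\varphi_L$ is the instantaneous phase of the slow band and $A_H$
the instantaneous envelope of the fast band. If the fast envelope is
independent of the slow phase the phasors cancel and MI tends to zero at
rate $O(1/\sqrt{N})$; envelope concentrated at a preferred phase leaves
a net resultant. A *normalized* variant divides by the mean envelope,
giving a dimensionless index in $[0, 1]$ that is invariant to overall
signal scale; it is the default for cross-condition comparison, since
the raw index scales with gamma amplitude and would conflate coupling
changes with power changes. (Taken verbatim, "mean absolute value of
$z(t)$" would reduce to the mean envelope and carry no phase
information at all; the composite-vector mean is the quantity that
measures coupling, and is what this package computes.)

The comodulogram evaluates MI over grids of $f_L$ (default 1--100 Hz,
step 2) and $f_H$ (default 10--200 Hz, step 5). Cells are flagged `NA`
— "not estimable", deliberately distinct from "no coupling" — when the
phase band would reach 0 Hz, when $f_H \le f_L$, or when the amplitude
band crosses Nyquist. The theta-gamma summary is the mean MI over cells
with $f_L \in [4, 8]$ and $f_H \in [40, 100]$ Hz, both inclusive.

Filtering and numerical choices:

* **Phase bandwidth** equals the $f_L$ grid step (2 Hz full width).
  **Amplitude bandwidth** follows the rule
  $\max(10, 2 f_L + 4)$ Hz: the envelope of the fast band is modulated
  at $f_L$ only if the sidebands at $f_H \pm f_L$ pass the filter, so
  the bandwidth must exceed $2 f_L$.
* **Filter design**: Hamming-window FIR band-pass applied with zero
  phase. The order satisfies two constraints — at least 3 cycles of the
  band's low edge, and a transition width of about a third of the band
  — the second being what keeps a 7 Hz carrier out of the neighbouring
  9 Hz phase band. The forward-backward pass is evaluated as a single
  FFT convolution with the filter's autocorrelation, which is exactly
  the zero-initial-condition filtfilt response at a fraction of the
  cost.
* **Edge handling**: 1 s is discarded at each end after filtering,
  covering the transient of the longest default filter.
* **Long recordings** are processed in 60 s segments whose MI values
  are averaged, bounding memory for multi-hour recordings.

### Surrogate significance

`surrogate_null` recomputes MI after circularly time-shifting the
envelope against the phase by random offsets, preserving both marginal
spectra while destroying their alignment; the 95th percentile of the
null is the significance threshold. On uncoupled recordings the
observed MI exceeds this threshold in about 5% of runs (the package's
calibration test measures 4--7% over 100 runs).

One degenerate case is worth understanding: for a *strictly periodic*
carrier, a circular shift of a sinusoidal envelope modulation only
rotates the composite vector ($|\int (1+\cos(\varphi+\delta))
e^{i\varphi}| $ does not depend on $\delta$), so the time-shift null
equals the observed MI and the test has no power. Real theta phase
drifts and is nonstationary, which is what the surrogate scheme relies
on; the detection test therefore uses a random-walk-phase fixture,
while the pure-sinusoid generator is reserved for the comodulogram
peak-recovery oracles where its analytically known phase and envelope
are the point.

## Synthetic data generators

`gen_coupled_lfp` builds a single-channel LFP as

* $1/f^a$ Gaussian background (default $a = 1$, sd 15 µV), synthesized
  by spectral shaping of white noise — realistic LFP background without
  committing to a biophysical model;
* a slow carrier $c \cos(2\pi f_L t)$ (default 7 Hz, 50 µV), the phase
  provider;
* a fast sinusoid at $f_H$ (default 60 Hz) whose envelope is
  $g (1 + d\cos\varphi_L)/(1 + d)$ with depth $d \in [0,1]$ and peak
  amplitude $g$ (default 20 µV) — the standard test-signal construction
  for coupling estimators, with exactly known ground truth.

Amplitudes are round numbers of the order seen in rodent depth
recordings; no quantitative noise floor or coupling depth is published
for the system being emulated, so these defaults are stated once here
and used unchanged throughout the tests. The generator draws all noise
under its config seed and restores the session RNG state.

`gen_fepsp_sweep` builds an evoked sweep: flat pre-stimulus baseline, a
one-sample biphasic artifact with sub-millisecond ring-down, a linear
descent at the configured rate to the negative peak at the configured
latency, then exponential recovery. The descent onset is
$\mathrm{latency} - \mathrm{peak}/|\mathrm{slope}|$ after the stimulus;
configs where that onset falls inside the artifact are rejected. Note
the geometric consequence for slope fitting: the fitted slope equals
the configured descent rate only when the descent spans the fit window
(onset at the blanking end). With a later, realistic EPSP onset the fit
window includes part of the flat onset segment and the fitted slope is
attenuated by a fixed geometric factor — exactly as it is for real
sweeps analyzed with an artifact-end-to-peak window. Recovery oracles
therefore use onset-at-blank configurations.

`gen_io_series` emulates the input/output protocol: voltages 1--8 V in
1 V steps, three sweeps each, expected slope magnitude following a
sigmoid $s_{\max}/(1 + e^{-k(v - v_{50})})$ (default $k = 1.5$/V). Peak
amplitude scales with slope at fixed 4 ms descent so waveform geometry
is voltage-invariant.

`gen_ltp_experiment` simulates two groups of per-subject slope time
courses: six baseline points, then 36 post-tetanization points at
2.5 min spacing (90 min). The group profile is `induction_pct` at the
first post point, then decays exponentially from `stp_pct` toward
`ltp_pct` with time constant `stp_decay_min` (the spec-level fields
fix the three landmarks; the single-exponential bridge between the
latter two is this package's choice). Between-subject offsets are drawn
once per subject, within-subject noise per point, both as percentages.

## fEPSP quantification

`extract_features` defines the artifact end as stimulus time plus a
configurable blanking (default 1 ms: 200 µs pulse plus ring-down
margin), finds the negative peak as the minimum within 15 ms after the
artifact end, and fits the slope by least squares over the central 80%
of the artifact-end-to-peak span (10% trimmed at each end, avoiding
onset and peak curvature; "central 80%" is one of three defensible
readings of an 80% interval and the one adopted here). A sweep with no
sample below the pre-stimulus mean minus three pre-stimulus standard
deviations is reported as having no detectable response.

Inclusion criteria are inclusive bounds — latency 6--10 ms, amplitude
1500--2500 µV, slope magnitude 400--900 µV/ms — with every violated
bound named, so exclusion is auditable. Inclusivity is the conservative
choice for keeping data at the printed limits.

I/O curves average slope magnitude across the (three) responses per
voltage; the test stimulus is the delivered voltage whose mean slope is
nearest 50% of the maximum, ties toward the lower voltage. An optional
interpolation mode returns the exact half-maximum crossing, off by
default because the protocol selects a stimulus that was actually
delivered.

LTP time courses average five consecutive sweeps per point (0.033 Hz
stimulation, one point per 2.5 min), take the mean of the *last six*
baseline points as the 100% reference, and express every point as a
percentage of it. The six-point rule is applied to whatever baseline
spacing is present. Window summaries are inclusive (`[0, 10]` min for
short-term potentiation, `[70, 90]` for the LTP phase); a window
narrower than the point spacing — the first-minute induction window —
falls back to the points whose covering sweep block overlaps it.

## Group statistics

Between-group contrasts use the pooled-variance two-sample t-test with
a 95% confidence interval on the mean difference (Welch's correction by
flag); degenerate zero-variance equal-mean input returns $t = 0$,
$p = 1$. Time-course comparisons run the t-test per time point and
control multiplicity with Holm's step-down correction — a deliberately
assumption-light stand-in for a repeated-measures ANOVA with many-to-one
post-hoc tests, conservative for the "which time points differ"
question the plots pose. Maximal runs of adjusted-significant points
are reported as spans.

## What the tests show, and what they do not

All validation runs on synthetic data. The generators reproduce the
*statistical structure* the estimators rely on — 1/f background, a
phase-locked envelope, sigmoid I/O growth, exponentially decaying
potentiation with subject-level heterogeneity — with problem sizes of
30--60 s recordings, 10-seed replications, and 100-replicate power and
calibration runs. They do not reproduce nonstationary behavioral
states, movement or chewing artifacts, volume conduction between sites,
electrode drift over months, or anesthesia depth effects; passing tests
certify the estimators' correctness and calibration, not robustness to
those real-data hazards. The optional amplitude-threshold epoch
rejection in the spectra stage is off by default for the same reason:
it is a tool, not a validated artifact policy.

## Reproducing the numbers

`scripts/acceptance.R --seed <int> --out <path>` regenerates every
headline quantity from scratch — comodulogram peak-recovery rate,
modulation-index oracle error, surrogate calibration rate, depth
monotonicity, normalization and slope-recovery errors, test-stimulus
selection, LTP window power and type-I rate, and pipeline determinism —
and writes them as JSON. The testthat suite asserts the same properties
at fixed seeds.
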